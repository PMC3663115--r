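#' Population-genetic estimators for segregating retrocopy insertions
#'
#' Treating each GRIP locus as a segregating site, Watterson's estimator
#' theta_W = S / a_n (a_n the partial harmonic sum over n - 1 terms) links
#' the observed number of segregating insertions S in n individuals to the
#' population parameter theta = 4 * Ne * mu, giving the per-generation
#' retroposition rate mu = theta / (4 * Ne). Neutrality of the markers is
#' checked with Tajima's D = (theta_T - theta_W) / sqrt(V), theta_T being
#' the mean pairwise difference count.
#'
#' @name popgen
NULL

#' Watterson denominator a_n
#'
#' @param n Number of individuals (>= 2).
#' @return Partial harmonic sum of 1/i for i = 1 .. n-1.
#' @export
watterson_a <- function(n) {
  if (n < 2 || n != round(n)) stop("n must be an integer >= 2")
  sum(1 / seq_len(n - 1))
}

#' Watterson's theta from segregating sites
#'
#' @param S Number of segregating sites (here: GRIP loci), >= 0.
#' @param n Number of individuals (>= 2).
#' @return theta_W = S / a_n.
#' @export
watterson_theta <- function(S, n) {
  if (S < 0) stop("S must be non-negative")
  S / watterson_a(n)
}

#' Per-generation retroposition rate from theta
#'
#' @param theta Population mutation parameter estimate (>= 0).
#' @param Ne Effective population size (> 0).
#' @return List with `mu` (= theta / (4 Ne)) and `mu_reciprocal`
#'   (individuals per new insertion, rounded; NULL when mu = 0).
#' @export
retro_rate <- function(theta, Ne) {
  if (Ne <= 0) stop("Ne must be positive")
  if (theta < 0) stop("theta must be non-negative")
  mu <- theta / (4 * Ne)
  list(mu = mu,
       mu_reciprocal = if (mu == 0) NULL else round(1 / mu))
}

#' Mean pairwise differences (theta_T) from per-locus carrier counts
#'
#' For a locus carried by k of n individuals, a random pair differs with
#' probability 2 k (n - k) / (n (n - 1)); theta_T sums this over loci.
#'
#' @param k Integer vector of carrier counts, each strictly between 0 and n.
#' @param n Number of individuals.
#' @return theta_T.
#' @export
pairwise_theta <- function(k, n) {
  if (length(k) == 0) return(0)
  if (any(k <= 0 | k >= n))
    stop("carrier counts must satisfy 0 < k < n (segregating loci only)")
  sum(2 * k * (n - k)) / (n * (n - 1))
}

#' Tajima's D from its components
#'
#' @param theta_T Mean pairwise differences.
#' @param theta_W Watterson's estimate.
#' @param V Variance estimate of the difference (> 0).
#' @return D = (theta_T - theta_W) / sqrt(V).
#' @export
tajima_d <- function(theta_T, theta_W, V) {
  if (V <= 0) stop("variance must be positive")
  (theta_T - theta_W) / sqrt(V)
}

#' Standard variance estimate for Tajima's D
#'
#' The textbook coefficient chain: with a1 = sum 1/i and a2 = sum 1/i^2
#' (i = 1 .. n-1), b1 = (n+1)/(3(n-1)), b2 = 2(n^2+n+3)/(9n(n-1)),
#' c1 = b1 - 1/a1, c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1,
#' e2 = c2/(a1^2 + a2), the variance is e1 S + e2 S (S - 1).
#'
#' @param S Number of segregating sites (>= 1).
#' @param n Number of individuals (>= 4).
#' @return Variance estimate V.
#' @export
tajima_variance <- function(S, n) {
  if (S < 1) stop("S must be >= 1")
  if (n < 4) stop("n must be >= 4")
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  e1 * S + e2 * S * (S - 1)
}

#' Assemble the full estimator chain for one cohort
#'
#' @param S Segregating GRIP count.
#' @param n Individuals.
#' @param Ne Effective population size.
#' @param carrier_counts Optional per-locus carrier counts for theta_T.
#' @param theta_T,V Optional externally supplied components for Tajima's D
#'   (override `carrier_counts` / the standard variance).
#' @return List with `n`, `S`, `a_n`, `theta_W`, `theta_T`, `V`, `D`, `Ne`,
#'   `mu`, `mu_reciprocal`, `neutrality` (label from the conventional
#'   critical values -2 and +2; D fields NULL when theta_T is unavailable).
#' @export
popgen_estimates <- function(S, n, Ne, carrier_counts = NULL,
                             theta_T = NULL, V = NULL) {
  a_n <- watterson_a(n)
  th_w <- watterson_theta(S, n)
  rate <- retro_rate(th_w, Ne)
  if (is.null(theta_T) && !is.null(carrier_counts))
    theta_T <- pairwise_theta(carrier_counts, n)
  D <- NULL; neutrality <- NULL
  if (!is.null(theta_T)) {
    if (is.null(V)) V <- tajima_variance(S, n)
    D <- tajima_d(theta_T, th_w, V)
    neutrality <- if (D < -2) "purifying" else if (D > 2) "diversifying"
      else "neutral"
  }
  list(n = n, S = S, a_n = a_n, theta_W = th_w, theta_T = theta_T, V = V,
       D = D, Ne = Ne, mu = rate$mu, mu_reciprocal = rate$mu_reciprocal,
       neutrality = neutrality)
}

#' Fraction of a genome covered by an annotation set
#'
#' Interval-union arithmetic: the union length of the (possibly
#' overlapping) annotation intervals divided by the summed chromosome
#' sizes.
#'
#' @param intervals Data frame `chrom`, `start`, `end` (0-based half-open).
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @return Covered fraction in [0, 1].
#' @export
annotation_coverage <- function(intervals, chrom_sizes) {
  total <- sum(chrom_sizes)
  if (nrow(intervals) == 0) return(0)
  if (!all(intervals$chrom %in% names(chrom_sizes)))
    stop("interval on unknown chromosome")
  if (any(intervals$start < 0 |
          intervals$end > chrom_sizes[intervals$chrom]))
    stop("interval beyond chromosome bounds")
  covered <- 0
  for (ch in unique(intervals$chrom)) {
    sub <- intervals[intervals$chrom == ch, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(sub$start + 1L, sub$end))
    covered <- covered + sum(IRanges::width(ir))
  }
  covered / total
}

#' One-sample proportions test with continuity correction
#'
#' Yates-corrected chi-square against a fixed expected proportion, the
#' correction clamped at |x - n p0| so the statistic is exactly zero when
#' the observation equals its expectation.
#'
#' @param x Successes (0 <= x <= n).
#' @param n Trials.
#' @param p0 Expected proportion, strictly between 0 and 1.
#' @return List with `chi2`, `p` (two-sided, chi-square with 1 df) and
#'   `proportion` (x/n).
#' @export
proportions_test <- function(x, n, p0) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must be strictly between 0 and 1")
  if (x < 0 || x > n) stop("x must lie in [0, n]")
  dev <- abs(x - n * p0)
  chi2 <- (max(0, dev - 0.5))^2 / (n * p0 * (1 - p0))
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       proportion = x / n)
}
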