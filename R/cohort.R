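#' Multi-sample GRIP profiles, distances, and somatic subtraction
#'
#' Calls from many genomes are unified into loci (same source gene,
#' intervals within a merge slop), giving a presence/absence profile per
#' sample. Profiles are compared with the Jaccard distance
#' d(A,B) = (|A u B| - |A n B|) / |A u B| and clustered hierarchically;
#' per-population carrier frequencies and tumor-specific (somatic) calls are
#' derived from the same locus unification.
#'
#' @name cohort
NULL

# single-linkage interval merging per gene+chrom; returns locus id per row
assign_loci <- function(calls, merge_slop = 500) {
  n <- nrow(calls)
  locus <- character(n)
  key <- paste(calls$gene_id, calls$chrom, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(calls$start[idx], calls$end[idx])]
    grp <- cumsum(c(FALSE, calls$start[idx][-1] -
                      cummax(calls$end[idx])[-length(idx)] > merge_slop))
    for (g in unique(grp)) {
      mem <- idx[grp == g]
      locus[mem] <- sprintf("%s|%s:%d-%d", calls$gene_id[mem[1]],
                            calls$chrom[mem[1]], min(calls$start[mem]),
                            max(calls$end[mem]))
    }
  }
  locus
}

#' Build a samples-by-loci presence/absence matrix
#'
#' @param calls Call table rows pooled across samples; the `samples` column
#'   lists contributing sample IDs comma-separated.
#' @param merge_slop Calls of the same gene whose intervals lie within this
#'   many bp are considered the same locus.
#' @return A `profile_matrix`: list with `m` (logical samples x loci
#'   matrix) and `loci` (data.frame of locus id, chrom, start, end,
#'   gene_id).
#' @export
build_profile_matrix <- function(calls, merge_slop = 500) {
  if (nrow(calls) == 0) {
    obj <- list(m = matrix(logical(0), 0, 0), loci = data.frame())
    class(obj) <- "profile_matrix"
    return(obj)
  }
  locus <- assign_loci(calls, merge_slop)
  loci <- sort(unique(locus))
  samples <- sort(unique(unlist(strsplit(calls$samples, ","))))
  m <- matrix(FALSE, length(samples), length(loci),
              dimnames = list(samples, loci))
  for (i in seq_len(nrow(calls))) {
    ss <- strsplit(calls$samples[i], ",")[[1]]
    m[ss, locus[i]] <- TRUE
  }
  parts <- regmatches(loci, regexec("^(.*)\\|(.*):(\\d+)-(\\d+)$", loci))
  loci_df <- data.frame(
    locus = loci,
    gene_id = vapply(parts, `[`, character(1), 2),
    chrom = vapply(parts, `[`, character(1), 3),
    start = as.integer(vapply(parts, `[`, character(1), 4)),
    end = as.integer(vapply(parts, `[`, character(1), 5)),
    stringsAsFactors = FALSE)
  obj <- list(m = m, loci = loci_df)
  class(obj) <- "profile_matrix"
  obj
}

#' Jaccard distance between two insertion profiles
#'
#' d(A,B) = (|A u B| - |A n B|) / |A u B|: 0 for identical profiles, 1 for
#' disjoint ones.
#'
#' @param A,B Character vectors of locus identifiers (sets).
#' @return Distance in [0, 1].
#' @export
jaccard_distance <- function(A, B) {
  A <- unique(A); B <- unique(B)
  u <- length(union(A, B))
  if (u == 0) stop("Jaccard distance undefined for two empty profiles")
  (u - length(intersect(A, B))) / u
}

profile_sets <- function(m) {
  if (inherits(m, "profile_matrix")) m <- m$m
  lapply(stats::setNames(rownames(m), rownames(m)),
         function(s) colnames(m)[m[s, ]])
}

#' Pairwise Jaccard distance matrix of sample profiles
#'
#' @param m A `profile_matrix` or logical samples x loci matrix.
#' @return A symmetric distance matrix.
#' @export
jaccard_matrix <- function(m) {
  sets <- profile_sets(m)
  ids <- sort(names(sets))
  D <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids))
    for (j in seq_along(ids))
      if (i < j)
        D[i, j] <- D[j, i] <- jaccard_distance(sets[[ids[i]]],
                                               sets[[ids[j]]])
  D
}

#' Hierarchically cluster samples by their GRIP profiles
#'
#' Agglomerative clustering on the pairwise Jaccard matrix. Samples are
#' ordered lexicographically before clustering so ties break
#' deterministically.
#'
#' @param m A `profile_matrix` or logical samples x loci matrix.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return An [stats::hclust] object.
#' @export
cluster_profiles <- function(m, linkage = c("average", "complete",
                                            "single")) {
  linkage <- match.arg(linkage)
  mm <- if (inherits(m, "profile_matrix")) m$m else m
  if (nrow(mm) < 2) stop("clustering needs at least two samples")
  D <- jaccard_matrix(m)
  stats::hclust(stats::as.dist(D), method = linkage)
}

#' Write a profile dendrogram as Newick
#'
#' @param hc An [stats::hclust] object from [cluster_profiles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tree <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Per-population carrier frequency of each locus
#'
#' @param m A `profile_matrix` or logical samples x loci matrix.
#' @param populations Named character vector: population label per sample.
#' @return Numeric loci x populations matrix of carrier frequencies in
#'   [0, 1].
#' @export
population_frequencies <- function(m, populations) {
  mm <- if (inherits(m, "profile_matrix")) m$m else m
  if (!all(rownames(mm) %in% names(populations)) ||
      anyNA(populations[rownames(mm)]))
    stop("every sample must carry a population label")
  pops <- sort(unique(populations[rownames(mm)]))
  out <- matrix(0, ncol(mm), length(pops),
                dimnames = list(colnames(mm), pops))
  for (p in pops) {
    members <- rownames(mm)[populations[rownames(mm)] == p]
    out[, p] <- colSums(mm[members, , drop = FALSE]) / length(members)
  }
  out
}

# does any discordant pair support gene_id near the locus?
any_support_near <- function(pairs, chrom, start, end, gene_id,
                             merge_slop) {
  if (is.null(pairs) || nrow(pairs) == 0) return(FALSE)
  any(pairs$gene_id == gene_id & pairs$distal_chrom == chrom &
        pairs$distal_start < end + merge_slop &
        pairs$distal_end > start - merge_slop)
}

#' Somatic calls by tumor/normal and cohort subtraction
#'
#' A tumor call is somatic only when zero supporting discordant pairs for
#' the same source gene exist within `merge_slop` of its locus in the
#' matched normal and in every other sample of the cohort. The veto is
#' asymmetric by design: a single read pair in a normal disqualifies the
#' call, with no support threshold applied to the veto side.
#'
#' @param tumor_calls Call table of the tumor sample.
#' @param normal_pairs [harvest_discordants()] output from the matched
#'   normal.
#' @param cohort_pairs Pooled [harvest_discordants()] output from all other
#'   cohort samples (may be empty).
#' @param merge_slop Locus-matching tolerance (bp).
#' @return The somatic subset of `tumor_calls`.
#' @export
somatic_calls <- function(tumor_calls, normal_pairs, cohort_pairs = NULL,
                          merge_slop = 500) {
  if (nrow(tumor_calls) == 0) return(tumor_calls)
  if (is.null(normal_pairs))
    stop("somatic calling requires the matched normal's discordant pairs")
  keep <- vapply(seq_len(nrow(tumor_calls)), function(i) {
    cc <- tumor_calls[i, ]
    !any_support_near(normal_pairs, cc$chrom, cc$start, cc$end, cc$gene_id,
                      merge_slop) &&
      !any_support_near(cohort_pairs, cc$chrom, cc$start, cc$end,
                        cc$gene_id, merge_slop)
  }, logical(1))
  tumor_calls[keep, , drop = FALSE]
}

#' Recover retrocopies present in the reference from deletion calls
#'
#' A retrocopy fixed into the reference assembly appears as a deletion in
#' individuals lacking it. A deletion is a candidate when it fully contains
#' a pseudogene annotation, spans at most `max_span_ratio` times the
#' annotation length (allowing repetitive UTR sequence), and the deleted
#' reference sequence is homologous to the source gene's spliced transcript.
#'
#' @param deletions Data frame `chrom`, `start`, `end` from
#'   [read_deletions_vcf()].
#' @param pseudogenes Data frame `chrom`, `start`, `end`, `source_gene`.
#' @param genome A `genome_ref`.
#' @param genes Named list of `gene_model` objects.
#' @param max_span_ratio Maximum deletion/annotation length ratio.
#' @param min_identity,min_len Homology thresholds (see [local_align()]).
#' @return Data frame of candidate reference retrocopies.
#' @export
reference_grips <- function(deletions, pseudogenes, genome, genes,
                            max_span_ratio = 3, min_identity = 80,
                            min_len = 100) {
  out <- data.frame(chrom = character(0), del_start = integer(0),
                    del_end = integer(0), pg_start = integer(0),
                    pg_end = integer(0), source_gene = character(0),
                    identity = numeric(0), stringsAsFactors = FALSE)
  if (nrow(deletions) == 0 || nrow(pseudogenes) == 0) return(out)
  for (i in seq_len(nrow(pseudogenes))) {
    pg <- pseudogenes[i, ]
    src <- genes[[pg$source_gene]]
    if (is.na(pg$source_gene) || is.null(src)) {
      warning("pseudogene record ", i, " without resolvable source gene ",
              "skipped")
      next
    }
    pg_len <- pg$end - pg$start
    cand <- deletions[deletions$chrom == pg$chrom &
                        deletions$start <= pg$start &
                        deletions$end >= pg$end &
                        (deletions$end - deletions$start) <=
                          max_span_ratio * pg_len, , drop = FALSE]
    if (nrow(cand) == 0) next
    tx <- spliced_transcript(src, genome)
    for (j in seq_len(nrow(cand))) {
      del_seq <- get_seq(genome, cand$chrom[j], cand$start[j], cand$end[j])
      hits <- local_align(del_seq, tx, min_identity = min_identity,
                          min_len = min_len)
      if (nrow(hits) > 0)
        out[nrow(out) + 1L, ] <- list(cand$chrom[j], cand$start[j],
                                      cand$end[j], pg$start, pg$end,
                                      pg$source_gene, max(hits$identity))
    }
  }
  out
}
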