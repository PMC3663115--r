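---
title: "Detecting gene retrocopy insertion polymorphisms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene retrocopy insertion polymorphisms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

LINE-1 machinery occasionally reverse-transcribes a spliced, polyadenylated
mRNA back into the genome. The resulting gene retrocopy lacks the introns
of its source gene, typically ends in a poly-A tract, and is flanked by a
short target site duplication (TSD) created by staggered endonuclease
nicks. When such an insertion segregates in a population but is absent
from the reference assembly, we call it a gene retrocopy insertion
polymorphism (GRIP). `retrocall` detects GRIPs from coordinate-sorted
paired-end alignments, characterizes their retrotransposition hallmarks,
compares insertion profiles across genomes, and estimates the
per-generation retroposition rate.

## Detection model

A retrocopy insertion connects two distant places in the reference: the
exons of the source gene (where the inserted sequence aligns) and the
insertion site (where the flanks align). Read pairs straddling an
insertion junction therefore map discordantly — one end in an exon, the
mate at the site. Under Illumina forward-reverse (FR) chemistry, mates on
the 5' side of the site map to the plus strand and mates on the 3' side to
the minus strand, so the two mate groups bracket the insertion point; the
minimum interval between them is reported as the call interval.

A candidate cluster becomes a call only if, after de-duplicating mappings
by (distal start, strand) so PCR/optical duplicates count once, it has

* at least **8 distinct mappings** connecting gene and site,
* at least **2 mappings on each side** (each junction spanned),
* anchors in at least **2 distinct exons** of the source gene, and
* clean left/right orientation: every plus-strand mate ends at most 30 bp
  past any minus-strand mate's start (TSDs let junction-proximal mates
  straddle slightly).

The exon-diversity rule makes single-exon genes a structural blind spot:
their insertions are indistinguishable from genomic copies of the locus
itself at this evidence level, and the simulator reproduces that false
negative mode.

Key tunable parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `min_support` | 8 | distinct mappings per call |
| `min_per_side` | 2 | distinct mappings per junction |
| `min_exons` | 2 | distinct anchor exons |
| `window` | 500 bp | single-linkage clustering gap |
| `min_mapq` | 20 | mapping quality required of both ends |
| `distal_flank` | 10 kb | distance the mate must clear the gene span |
| `min_exon_overlap` | 20 bp | read/exon overlap for the anchor |
| discordance cut-off | `median_insert + 4·insert_sd` | outer-span limit for concordant pairs |

The paper-style thresholds (8/2/2) are fixed by the method; the remaining
values are this implementation's choices where the method leaves them
open. `min_mapq = 20` keeps ambiguous anchors from fabricating "distinct"
mappings; the 10 kb distal flank operationalizes "distant from the exons";
the 500 bp window matches the locality used for junction-read collection
and the pseudogene screen.

**Insert-size convention.** `library_stats(read_length, median_insert,
insert_sd)` takes `median_insert` as the median *outer fragment span*
(leftmost to rightmost mapped base), the quantity the discordance test
compares against. A library with 100 bp ends and a 300 bp unsequenced
middle therefore has `median_insert = 500`. This is the Illumina "insert
size" convention; stating it explicitly avoids the ambiguity between
fragment length and unsequenced-gap length.

For low-pass cohorts, discordant pairs are pooled across samples before
clustering while retaining the sample tag; every genome contributing reads
to a call is reported as a carrier. Tumor/normal pairs are pooled the same
way for germline calling (effective 60x from two 30x genomes); somatic
status is decided afterwards by subtraction (below).

## Breakpoints, TSD, poly-A, cleavage motif

Reads crossing a junction soft-clip at it. The 5'-side breakpoint is the
modal aligned right edge of reads clipped on the right (minimum clip 10
bp, at least 2 reads agreeing at the exact base — bwa-style clips are base
precise, so no positional fuzz is allowed); the 3'-side breakpoint is
symmetric. With a TSD of length t at site p, the two coordinates come out
as p + t and p, so the reference tract between them is the TSD candidate.
It is accepted only if the 5'-junction clip tails actually begin with
inserted (source transcript) sequence rather than continuing as reference
— interval spacing alone is not treated as evidence — and only up to
`max_tsd = 50` bp.

One addition proved necessary: reads sampled from *any* retrocopy allele
of gene X soft-clip exactly at X's exon boundaries when mapped to the
reference (the transcript continues into the next exon, the reference
into the intron). A call site that happens to lie near an annotated gene
inherits those clips, which can outvote the true junction by an order of
magnitude. Clip votes at annotated exon boundaries (±3 bp) are therefore
excluded from breakpoint voting.

The poly-A tail is measured on clip tails oriented into the insertion as
the longest leading A-run containing at most 20% non-A bases (ending on an
A), maximized over tails, reported when at least 5 bp. Both insertion
orientations are scored (a minus-orientation insert shows the tail as
leading Ts at the 5' junction) and the stronger one is kept. The 20%
mismatch allowance means the measurement can overrun the true tail when
the adjacent transcript end is A-rich; on simulated data the overshoot is
bounded by roughly a quarter of the tail length plus a few bases, which is
the tolerance the recovery tests use.

The endonuclease cleavage motif is reported as 4 bp on each side of the
5'-junction position on the nicked strand (bottom strand for a plus-strand
insertion), slash at the scissile position; canonical LINE-1 sites read
`TTTT/AA...`.

Two kinds of junction ambiguity are irreducible: if the first bases of the
insert equal the reference bases just past the site, or the poly-A tail
matches reference As just before it, the aligner extends the match and the
breakpoint shifts by the length of that micro-homology. On simulated data
this shifts TSD length estimates by 0–3 bp for a minority of sites; the
end-to-end tests therefore require |detected − true| ≤ 2 bp for ≥90% of
detected insertions, while exactness is asserted for exactly-clipped
reads.

## Exon–exon junctions by local assembly

Reads within 500 bp of a call that are discordant, one-end-anchored, or
soft-clipped (pairs kept whole) are assembled with a small double-stranded
de Bruijn assembler: k-mers below 2 occurrences are dropped as errors,
maximal unbranched paths become contigs (canonicalized and sorted, so
assembly is deterministic for a given read multiset), and contigs shorter
than 2k−1 bp are discarded. The first pass uses k = 31; calls yielding no
junction are retried at k = 21 for sensitivity. A junction (i, j) is
reported when the last 20 bp of exon i are immediately followed in a
contig by the first 20 bp of exon j (both orientations tried; mismatches
disallowed by default, one per flank tolerable for noisier data).
Non-adjacent pairs are reported as-is, which represents exon-skipping
isoforms. Because the source gene of each call is known, full BLAT-style
genome-wide alignment of contigs is unnecessary; exact flank matching
against the known exon sequences suffices.

## Pseudogene screening

A candidate site is rejected if the site ±500 bp intersects an annotated
pseudogene, or if local alignment of that window against the source gene's
spliced transcript finds a hit of ≥80% identity over ≥100 bp (an
unannotated pre-existing copy; both thresholds are this implementation's
choices). Alignment is Smith–Waterman (via Biostrings) behind an 11-mer
shared-seed prefilter, both strands. The same aligner backs
reference-retrocopy recovery: a deletion call is accepted as a reference
GRIP when it fully contains a pseudogene annotation, spans at most 3× the
annotation (allowing repetitive UTR sequence), and the deleted sequence is
homologous to the source transcript.

## Cohort reasoning

Calls from many genomes are unified into loci (same source gene, intervals
within 500 bp, single linkage), yielding a samples × loci presence/absence
matrix. Profiles are compared with the Jaccard distance
d(A,B) = (|A∪B| − |A∩B|)/|A∪B| and clustered agglomeratively; average
linkage is the default (configurable: average/complete/single) because the
distance is a custom set distance and average linkage is the conventional
neutral choice for such matrices — the linkage originally used for this
kind of strain heatmap is not documented, so it is left configurable.
Sample labels are sorted before clustering so ties break deterministically.

A tumor call is **somatic** only if zero supporting discordant pairs for
the same gene exist within 500 bp of its locus in the matched normal *and*
in every other cohort sample. The veto deliberately scans raw discordant
pairs, not calls: a single read pair disqualifies, with no support
threshold on the veto side. This is the stricter reading of
"no corresponding read pairs", and it makes somatic output shrink (never
grow) as cohort samples are added.

## Rate of retroposition

Treating each GRIP locus as a segregating site among n individuals:

* Watterson: a_n = Σ_{i=1}^{n−1} 1/i, θ̂_W = S / a_n,
* rate: θ = 4·N_e·μ, so μ = θ̂_W / (4·N_e), reported also as 1/μ
  (individuals per new insertion),
* pairwise diversity: θ̂_T = Σ_i 2·k_i(n−k_i)/(n(n−1)) from per-locus
  carrier counts k_i,
* Tajima: D = (θ̂_T − θ̂_W)/√V̂, with V̂ defaulting to the standard
  coefficient chain e₁S + e₂S(S−1); a user-supplied V̂ is accepted so a
  published variance can be reproduced exactly when its derivation is not
  available. D is labeled against the conventional ±2 critical values
  (reported as a label, not used as a decision rule).

Annotation coverage (for enrichment/depletion of insertion sites in genes)
is exact interval-union arithmetic, and the one-sample proportions test is
the Yates-corrected chi-square with the correction clamped at |x − n·p₀|,
matching `prop.test`.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` builds the benchmark used throughout the tests:

* a synthetic genome of two 150 kb chromosomes of uniform random sequence;
* 21 non-overlapping gene models (3–6 exons of 150–400 bp, introns
  300–800 bp; one single-exon gene to exercise the known blind spot);
* 55 spiked processed-transcript insertions: allele =
  `ref[0, p+t) + insert + ref[p, …)`, so the t reference bases at the site
  flank the insert on both sides as an exact TSD; the insert is the
  spliced transcript (reverse-complemented for minus-orientation
  insertions) minus a 5' truncation (half of inserts truncated, by up to
  40% of the transcript), plus a poly-A tail. TSD lengths are uniform on
  [5, 25] bp and tails uniform on [8, 30] bp; sites are placed uniformly
  but kept 11 kb from the source gene span (so harvesting's distal-flank
  rule cannot discard true support), 200 bp from exons, and 2.5 kb apart;
* FR read pairs (100 bp ends, fragment ~ Normal(500, 30), i.e. a 300 bp
  unsequenced middle) at 60x with 0.1% substitution errors, realigned to
  the unmodified reference with `bwa mem` (single-threaded; the simulation
  is deterministic given its seed). bwa is used because a production
  pipeline maps with it and it generates the soft-clip and discordance
  signal the caller actually consumes; an in-package per-read aligner
  would model the same signal with less fidelity.
* Downsampling keeps whole pairs independently with the given
  probability; the coverage ladder (60→40→30→20→10→5x) is sampled
  *nested*, each level from the previous, so the read sets are subsets and
  recall comparisons across the ladder are not confounded by independent
  sampling noise. In this clean homozygous benchmark, junction support
  scales with coverage and still clears the 8/2/2 thresholds at 5x
  (roughly 15 straddling pairs per site), so recall typically stays flat
  across the ladder rather than decaying as it does on real data, where
  heterozygosity, mapping ambiguity and uneven coverage erode support;
  the ladder check is therefore a monotonicity property, not a
  reproduction of absolute recall values.

Deliberately not emulated: repeats and segmental duplications (so
mapping ambiguity is milder than in real genomes), heterozygous insertions
(spikes are homozygous; real 50% allele fraction halves junction support),
pre-existing pseudogene background (the homology screen is exercised by
planted decoys in unit tests instead), base-quality variation, and
indel/SV noise. Consequently a 100% simulated precision shows the calling
logic produces no false positives from its own evidence handling — not
that real-genome artifacts (mismapping in repeats, library chimeras)
cannot produce any.

Scoring matches calls to truths by source gene and site within 100 bp
(nearest assignment, one truth per call); precision is TP/(TP+FP) over
truths/calls respectively and is undefined (NA) with no calls.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; SAM/VCF 1-based
  conversion happens exactly once at I/O.
* Call intervals are clamped to zero width at the overlap midpoint when
  the mate groups overlap (TSD geometry).
* Output ordering is (chrom, start, gene id); modal-position ties in
  breakpoint voting take the smaller coordinate; contigs are sorted
  canonical sequences; profile clustering sorts labels first. Repeated
  runs on the same input are byte-identical.
* Jaccard distance errors on two empty profiles (0/0); `pairwise_theta`
  rejects non-segregating counts (k = 0 or n); `tajima_variance` requires
  n ≥ 4; zero-coverage simulation and empty call tables round-trip without
  error.
* Problem sizes used by the test-suite benchmark (300 kb genome, 55
  spikes, 60x) were chosen as the smallest configuration that leaves ≥50
  multi-exon spikes with crowded-but-separable sites; estimator checks run
  at the published cohort sizes (n = 1024) since they are closed-form.

## Known limitations

* Single-exon retrocopies are invisible by design (exon-diversity rule).
* Insertions landing inside an exon of another gene lose straddling
  support pairs to the both-ends-exonic exclusion and may be missed.
* Twin-priming/inverted and 5'-transduced structures are out of scope.
* The TSD/poly-A measurements inherit junction micro-homology and
  mismatch-tolerance biases of a few bases, as described above.
* Carrier frequency is presence/absence; no genotype likelihoods or
  imputation.
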