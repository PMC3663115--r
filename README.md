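# retrocall

Detection of **gene retrocopy insertion polymorphisms (GRIPs)** from
paired-end whole-genome sequencing.

LINE-1 machinery occasionally reverse-transcribes a spliced,
polyadenylated mRNA back into the genome. The resulting retrocopy lacks
its source gene's introns, usually ends in a poly-A tract, and is flanked
by a short target site duplication (TSD). When such an insertion
segregates in a population but is absent from the reference assembly, the
only trace in short-read data is indirect: read pairs with one end in an
exon of the source gene and the mate at a distant locus. `retrocall` is
for genomicists who want to find, characterize, and compare these events
across genomes — population cohorts (including pooled low-pass data),
tumor/normal pairs, or simulated benchmarks.

## Method at a glance

* **Calling.** Discordant pairs anchored in exons are clustered at their
  distal mates (single linkage, 500 bp window). A cluster is called when
  it has ≥ 8 distinct mappings (de-duplicated by distal start/strand),
  ≥ 2 spanning each junction, anchors in ≥ 2 distinct exons, and
  FR-consistent orientation: plus-strand mates on the 5' side, minus on
  the 3' side. The minimum interval between the two mate groups is the
  call interval. Sites inside annotated or unannotated pseudogene copies
  of the source gene (local Smith–Waterman, ≥ 80% identity over ≥ 100 bp
  in the site ± 500 bp) are filtered out.
* **Evidence.** Soft-clip consensus positions give base-precise
  breakpoints; the reference tract between them (confirmed by
  insert-matching clip tails) is the TSD; clip tails read into the
  insertion yield the poly-A length; the nicked-strand context around the
  5' junction gives the endonuclease cleavage motif (consensus
  `TTTT/AA`). A built-in de Bruijn assembler (k = 31, fallback 21)
  recovers exon–exon junctions from junction-informative reads, proving
  the inserted copy is spliced.
* **Cohorts.** Calls are unified into loci across samples; profiles are
  compared with the Jaccard distance
  `d(A,B) = (|A∪B| − |A∩B|) / |A∪B|` and clustered hierarchically;
  per-population carrier frequencies are tabulated. A tumor call is
  somatic only with *zero* supporting pairs in the matched normal and the
  rest of the cohort. Reference-genome retrocopies are recovered from
  deletion VCFs that contain a pseudogene annotation (deletion ≤ 3× the
  annotation, deleted sequence homologous to the source transcript).
* **Rate estimation.** With S segregating insertion loci among n
  genomes: `a_n = Σ_{i=1}^{n−1} 1/i`, `θ̂_W = S/a_n`, and `θ = 4·N_e·μ`
  gives the per-generation retroposition rate `μ`. Neutrality is checked
  with Tajima's `D = (θ̂_T − θ̂_W)/√V̂`, where `θ̂_T` is the mean pairwise
  profile difference.
* **Simulation.** A spike-in engine builds synthetic genomes and gene
  models, inserts processed transcripts with TSDs, poly-A tails and 5'
  truncations, simulates FR reads (100 bp ends, 300 bp unsequenced
  middle) realigned with `bwa mem`, downsamples by whole pairs, and
  scores calls against truth (precision/recall).

Inputs: coordinate-sorted indexed BAM(s), gene models as BED12, reference
FASTA, optional deletion VCF / pseudogene BED, and a TSV sample sheet
(`sample_id`, `path`, `population`, `pair_id`, `tissue`). All internal
coordinates are 0-based half-open.

## Worked example

Simulate a small benchmark (two 60 kb chromosomes, 8 genes, 8 spiked
insertions at 60x) and call it back:

```r
library(retrocall)

sim <- simulate_dataset(seed = 42, out_dir = "demo", n_spikes = 8,
                        coverage = 60,
                        chrom_sizes = c(chr1 = 60000, chr2 = 60000),
                        n_genes = 8)
sheet <- data.frame(sample_id = "demo", path = sim$bam)
calls <- discover(sheet, sim$genes, sim$genome, sim$stats, verbose = TRUE)
calls[, c("chrom", "start", "end", "gene_id", "n_left", "n_right",
          "exons_hit", "polyA_len", "junctions")]
```

```
sample demo: 38640 pairs, 2001 gene-anchored discordant
8 candidate clusters
8 calls, 8 pass homology screen
  chrom start   end gene_id n_left n_right exons_hit polyA_len   junctions
1  chr1 11212 11212  gene05    118      74   1,2,3,4        34 1-2;2-3;3-4
2  chr1 21672 21672  gene04    102      83     1,2,3        28     1-2;2-3
3  chr1 28585 28585  gene02    111     102   2,3,5,6        36     2-3;5-6
...
8  chr2 57027 57027  gene07     90      89     2,3,4        24     2-3;3-4
```

Each row is one insertion: the zero-width interval where the plus- and
minus-strand mate groups meet, the source gene, distinct support per
side, which exons the anchoring reads hit, the measured poly-A tail, and
the spliced exon–exon junctions recovered by local assembly (e.g. `2-3;5-6`
— a transcript isoform skipping exon 4). Scoring against the spike-in
truth:

```r
ev <- evaluate_calls(calls[calls$filter_status == "PASS", ], sim$truth)
#> TP=8 FP=0 FN=0 precision=1.00 recall=1.00
```

The estimator chain on a cohort of 1,024 genomes with 48 segregating
insertions and N_e = 10,000 (pairwise diversity and variance supplied):

```r
est <- popgen_estimates(S = 48, n = 1024, Ne = 10000,
                        theta_T = 3.412, V = 9.073)
#> a_n=7.508 theta_W=6.393 1/mu=6257 D=-0.990 (neutral)
```

i.e. roughly one new heritable gene retrocopy per ~6,300 individuals per
generation, with D comfortably inside the ±2 neutrality band.

A command-line wrapper with the same functionality is installed at
`exec/retrocall` (subcommands `discover`, `somatic`, `refgrips`,
`cohort`, `popgen`, `simulate`, `evaluate`).

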