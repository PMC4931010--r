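# chimeramap

RNA–RNA interactome and RNA-structure analysis from proximity-ligation
chimeric sequencing reads.

Proximity-ligation interactome assays cross-link RNAs to their bound
proteins and ligate a known 24-nt RNA linker between fragments held in the
same complex. Every resulting molecule has the form **RNA1–Linker–RNA2**,
and each non-duplicate paired-end read over it is one observation of a
molecular interaction — or, when both fragments come from the same
transcript, one observation of that transcript folding back on itself.
chimeramap is for computational biologists who want to go from such raw
paired-end FASTQ (or from a simulated library with known truth) to called
interactions, interaction sites, and intramolecular structure evidence,
entirely offline.

The package implements:

* **Read parsing** — PCR-duplicate removal (identical read pairs, with the
  random barcode as part of the sequence), sample demultiplexing over a
  configurable `N`/`X` barcode layout (default `NNNNXXXXNN`: a 6-nt UMI
  around a 4-nt sample barcode), mate merging, ungapped linker detection
  with a `floor(0.1 × overlap)` mismatch budget, and splitting into RNA1 /
  RNA2 fragments with category calls.
* **Mapping and assignment** — a seed-and-verify toy aligner for
  simulator-scale genomes (real data would be aligned externally),
  strand-aware gene assignment with ≥50% overlap and a tie→ambiguous rule,
  repeat and novel-locus fallbacks, and a cross-species random-ligation
  estimator with Wilson CI and a `1/(2p(1−p))` mixing correction.
* **Interaction calling** — for a gene pair (a, b) with n_ab joint
  chimeras, margins n_a, n_b and N assigned chimeras, the one-sided Fisher
  exact p-value is the hypergeometric tail

  p = P(X ≥ n_ab), X ~ Hypergeom(N, n_a, n_b),

  corrected across tested pairs (n_ab ≥ 2) by Benjamini–Hochberg at
  FDR < 0.05; interaction sites as coverage peaks; degree-distribution
  power-law diagnostics for the interaction network.
* **Structure** — filters isolating genuine cut-and-ligated reads, the
  two structural classes from junction order, RNase cut-density tracks,
  symmetric binned contact maps, and proximal site pairs by
  single-linkage clustering of junction pairs (support ≥ 3).
* **Sequence statistics** — a nearest-neighbour RNA duplex free-energy
  dynamic programme (ΔG37 stacking table, +0.5 kcal/mol per interior
  unpaired base) compared against composition-preserving shuffles with a
  paired Wilcoxon signed-rank test, and conservation metaprofiles around
  ligation junctions versus random-window controls.
* **A seeded simulator** — toy genomes, planted preferential-attachment
  interactomes, planted proximal-site pairs, contamination, duplicates and
  sequencing errors, with a per-read truth table and an evaluation
  harness.

## Worked example

Simulate a library under the default study conditions (scaled to 8,000
read pairs), parse it, map, and call interactions:

```r
library(chimeramap)

cfg <- sim_config(seed = 42, n_read_pairs = 8000)
ref <- make_reference(cfg)
lib <- simulate_library(cfg, ref)

parsed <- parse_chimeras(lib$read1, lib$read2, ids = lib$ids)
unlist(parsed$report[c("n_input", "n_duplicates", "n_unique", "n_parsed")])
#>      n_input n_duplicates     n_unique     n_parsed
#>         9600         1605         7995         7994

chim <- parsed$chimeras[parsed$chimeras$category == "chimeric", ]
idx <- genome_index(ref$genome)
a1 <- toy_align(chim$rna1, idx); a2 <- toy_align(chim$rna2, idx)
ok <- a1$unique & a2$unique
gr <- function(a) GenomicRanges::GRanges(a$chrom[ok],
        IRanges::IRanges(a$start[ok] + 1, a$end[ok]), strand = a$strand[ok])
g1 <- assign_genes(gr(a1), ref$genes)$unit
g2 <- assign_genes(gr(a2), ref$genes)$unit

calls <- call_interactions(count_pairs(g1, g2),
                           setNames(ref$genes$biotype, ref$genes$gene_id))
head(calls[order(calls$q_value),
           c("gene_a", "gene_b", "n_ab", "p_value", "q_value", "type_label")], 3)
#>         gene_a     gene_b n_ab  p_value  q_value    type_label
#> 102   miRNA_13   miRNA_16   59 1.60e-58 3.25e-56   miRNA-miRNA
#> 66    miRNA_05    mRNA_13   34 5.31e-54 5.41e-52    miRNA-mRNA
#> 23  lincRNA_07   miRNA_20   39 1.15e-53 5.84e-52 lincRNA-miRNA

sum(calls$significant)
#> [1] 187

evaluate_calls(calls, lib$truth, ref$edges)[c("sensitivity", "specificity")]
#> $sensitivity  0.93
#> $specificity  0.80
```

The 9,600 emitted pairs collapse to 7,995 unique ones (the planted 20%
duplicate rate), one read fails demultiplexing, and the caller recovers
93% of the planted 200-edge interactome; at this shallow depth only a
handful of non-planted pairs reach the testing threshold, so the
specificity estimate (0.80) rests on a denominator of a few pairs — at
the default 50,000-pair depth it is ≥ 0.99. `run_pipeline()` wires the
same stages end-to-end from FASTQ/FASTA/GTF files to TSV/BEDPE/JSON
outputs, and `inst/cli/chimeramap.R` exposes `simulate`, `parse` and
`run` subcommands for shell use.

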