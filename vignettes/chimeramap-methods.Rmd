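---
title: "chimeramap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chimeramap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeramap)
```

## The measurement being modelled

Proximity-ligation RNA interactome assays cross-link RNA molecules to their
bound proteins, fragment the RNA, and ligate a biotinylated 24-nt RNA
linker between fragments held together by the same protein. Each chimeric
molecule therefore has the form RNA1–Linker–RNA2, and a paired-end read
over it is a single observation of a molecular interaction. Read 1 begins
with a combined barcode: a layout string over `{N, X}` (default
`NNNNXXXXNN`) in which the six N positions carry a random barcode (UMI)
used to recognise PCR duplicates and the four X positions carry a fixed
per-sample barcode. The shipped sample barcodes (`AGGT`, `CGCC`, `CATT`)
pairwise differ at three positions, so demultiplexing with a budget of one
mismatch (the default) can never cross-assign a read: misassignment would
require at least `ceil(3/2) = 2` errors landing in the barcode.

chimeramap implements the downstream computation: read parsing, fragment
mapping and gene assignment, interaction calling, interaction sites,
intramolecular structure evidence, and sequence-level statistics, plus a
seeded simulator that generates libraries with full ground truth.

## Read parsing

Parsing proceeds in the pipeline's published stage order.

**Duplicate removal** collapses completely identical `(read1, read2)`
string pairs to their first occurrence. Because the UMI is part of read 1,
two copies of one cDNA collapse while identical inserts from distinct
molecules (different UMIs) are kept.

**Demultiplexing** slices the X positions and assigns the unique barcode
within `max_mismatch` (default 1); reads with no barcode in range or a tie
go to `undetermined` rather than raising an error.

**Insert reconstruction and linker search.** The insert is rebuilt from
the read-1 payload and the reverse complement of read 2. Mates overlapping
by at least 10 nt (at most 10% mismatch) are merged. A merged insert is
complete — both molecule ends were observed — so only full-length linker
occurrences are searched there; allowing partial linker prefixes at the
ends of a complete insert could only produce chance false hits (a random
6-mer matches the linker start once in ~4000 reads). For unmerged mates
the linker may be cut by the unsequenced gap, so a linker *prefix* at the
read-1 3' end and a linker *suffix* at the reverse-complemented read-2
5' end are additionally admitted, with overlap at least `min_overlap = 6`.
Matching is ungapped with a mismatch budget of `floor(0.1 × matched
length)`; indels are rare enough in Illumina data that gapped alignment
would buy noise, not sensitivity. Ties prefer longer matches, then smaller
offsets. Reads with two disjoint full-linker occurrences (multi-linker
concatemers) are `ambiguous`.

**Categories.** Bases 5' of the linker become RNA1, bases 3' of it RNA2;
fragments shorter than `min_frag = 15` nt (too short to map) are blanked
with a counter. The category lattice follows the construct chemistry:
`chimeric` (both fragments), `linker_rna2` (the non-informative
5'-linker–RNA2 form), `rna1_linker`, `linker_only`, `no_linker`,
`ambiguous`.

A physical identifiability limit matters for testing: when both fragments
are longer than the sequenced span, the linker lies outside both mates and
no parser can recover the category. Round-trip tests therefore use
simulated fragment lengths of 15–70 nt at 100-nt reads, where the linker
is always sequenced; the simulator's general default (15–300 nt, clamped
log-normal with median 80) retains the realistic case in which a fraction
of junctions is simply not observable and such chimeras are lost to yield,
not to error.

## Mapping and gene assignment

Fragments are placed by a seed-and-verify aligner over a k-mer index
(k = 15, at most 2 substitutions, both strands) intended for
simulator-scale genomes; real libraries would be aligned externally and
ingested at this boundary. A fragment is `unique` only when the best locus
strictly beats the second best; multi-mapped fragments are discarded,
matching the assay's "both fragments uniquely mapping" convention.

Assignment is strand-aware (the library is strand-preserving by
construction): a fragment belongs to the same-strand gene covering at
least half of it; two qualifying genes make it ambiguous (dropped, with a
counter); failing genes, it falls to a same-strand repeat element
(`repeat:<family>`, biotype `transposonRNA`); failing that, to novel loci
built by strand-aware merging of leftover fragments across gaps of at most
100 nt. Novel ids follow sorted genomic order, so assignment is
independent of input order. The 50% overlap threshold and the tie rule are
this package's documented choices — the assay's description does not
quantify either.

**Random-ligation rate.** In a mixed two-species lysate, chimeras joining
two species can only be random ligations. The raw inter-species fraction
among uniquely mapped chimeras is reported with a Wilson 95% CI. It
understates the true random-ligation rate: a random pair is inter-species
only with probability `2p(1−p)` (p = species-1 endpoint share), so the
corrected rate divides by that factor. The correction is off by default —
the raw, conservative-by-construction number is the headline one — and
reported separately.

## Interaction calling

Same-gene chimeras are routed to the structure branch; the rest are
counted per unordered gene pair. For a pair (a, b) with `n_ab` joint
chimeras, per-gene endpoint margins `n_a`, `n_b` and `N` assigned chimeras
in total, enrichment is the hypergeometric upper tail
`P(X ≥ n_ab)`, `X ~ Hypergeom(N, n_a, n_b)` — the one-sided Fisher exact
test on the 2×2 table `(n_ab, n_a−n_ab, n_b−n_ab, rest)`. The marginal
table construction is this package's definition; the assay's description
names the test but not the table. Only pairs with `n_ab ≥ 2` are tested
(interactions are expected to be supported by multiple read pairs), and
Benjamini–Hochberg correction runs over the tested pairs with the
significance threshold q < 0.05. ES-type replicate libraries are merged
before testing, not after.

Interaction sites are "peaks" of overlapping fragments on a transcript:
positions with coverage ≥ 5, merged across gaps ≤ 10 nt, reported if at
least 10 nt wide; support is the maximum coverage inside the site. All
three thresholds are package defaults — none is printed in the assay
description.

**Network topology.** The significant-interaction graph's degree
distribution is fitted by least squares on `(log10 k, log10 count)`.
A hierarchical (scale-free) network shows negative slope, r² ≥ 0.8, and a
node count that decays monotonically from the minimum degree. The
monotonicity check runs over degrees with at least 5 nodes and tolerates
upticks within twice the Poisson standard deviation of the smaller count:
the sparse tail of any finite network is sampling noise, while the
interior mode of a non-hierarchical topology (a Poisson-like bulge) is a
large, systematic violation. The contrast is reproduced by two reference
generators: preferential attachment (positive control) and a flat
"promiscuous regulator" network — 100 sources each wired to
Uniform{300..1000} random targets from a 20,000-gene pool — which fails
the power-law diagnostics.

## Intramolecular structure

Same-gene, linker-containing read pairs that do not look like an ordinary
continuous cDNA are cut-and-ligated events. The continuous-fragment
geometry — mates on opposite genomic strands, within 2,000 bp, with the
plus-strand mate upstream — is dropped; linkerless and two-gene pairs are
dropped under their own counters.

Junctions follow the ligation chemistry: `junction1` is the last base of
RNA1 (its 3'-OH ligated to the linker 5' end), `junction2` the first base
of RNA2. Comparing read order with transcript order yields exactly two
structural classes: class I when RNA1 lies 5' of RNA2 on the transcript,
class II otherwise (the circularly-permuted geometry). All structure
coordinates are transcript-space, 0-based half-open; minus-strand genes
are flipped on projection, so class assignment is orientation-consistent
by construction. Fixture genes are single-exon, keeping the
transcript-genome projection trivial — a documented simplification.

Three summaries are derived per transcript: the **cut-density track**
(+1 at every fragment terminus; each terminus is a candidate RNase I cut,
so single-stranded regions accumulate density; total mass is exactly twice
the fragment count), the **contact map** (each junction pair increments a
symmetric binned matrix; the upper triangle including the diagonal sums to
the pair count), and **proximal site pairs**: single-linkage clusters in
(junction1, junction2) space, linking events when both junctions differ by
at most 10 nt — "overlapping ligation positions" is not quantified at the
source, so the tolerance is a package default — and reported at support
≥ 3.

## Sequence statistics

**Duplex energy.** Hybridization energy between two RNA segments is the
minimum over antiparallel, intermolecular duplex alignments, scored by an
embedded nearest-neighbour ΔG37 stacking table (published Turner/Xia
Watson–Crick values; stacks with one wobble pair flattened to −1.2
kcal/mol, two wobbles to −0.5 — the published wobble stacks are
sequence-dependent and include destabilising motifs this model ignores).
Interior unpaired bases cost +0.5 kcal/mol each, with the loop between
consecutive pairs capped at 8 nt; dangling ends are free and there is no
helix-initiation term, so the empty duplex (0 kcal/mol) bounds every
result from above and any duplex with one stack is negative. The dynamic
programme is validated against exhaustive alignment enumeration on short
sequences, and by the monotonicity property that a sequence's reverse
complement is its most stable partner; no agreement with any external
folding program is claimed — this is a deliberately simplified model whose
role is rank comparison against shuffled controls, not absolute energies.

**Shuffled controls and the test.** Controls shuffle each fragment's bases
uniformly (mononucleotide permutation, as the assay describes; a
dinucleotide-preserving mode is available behind a flag). Because every
interaction is matched with a control built from its own fragments — same
lengths, same composition — the observed and control samples are paired,
and chimeramap tests them with a one-sided Wilcoxon **signed-rank** test
on per-interaction differences. The source figure says only "Wilcoxon
rank test", which admits either variant; the unpaired rank-sum choice is
measurably miscalibrated here (the within-pair coupling concentrates its
null p-values, and a KS test over 500 null replicates rejects uniformity
at about half of seeds), while the signed-rank test is exactly valid under
within-pair exchangeability. Because duplex energies live on a 0.01
kcal/mol lattice, tied absolute differences are common, and the stock
tie-handling (continuity-corrected normal approximation) is conservative
at these sample sizes; the null distribution is therefore computed by
exact sign-flip convolution over midranks (switching to a tie-corrected
normal approximation beyond 200 informative pairs). The package's
null-calibration test checks exactly this.

**Conservation metaprofiles** average a per-base score track over windows
of width 1,000 centred at each ligation junction, against an equal number
of random same-width windows. Track gaps are absent values (excluded from
means with a counter), never zeros. On synthetic tracks with bumps planted
at junctions, the observed-minus-control profile peaks within ±2 nt of
relative position 0.

## The simulator

`sim_config()` fixes the study conditions; `make_reference()` and
`simulate_library()` generate a toy genome and a library deterministically
under the seed. Defaults: 2 chromosomes × 120 kb per species; 20
single-exon genes in each of six biotypes (mRNA, lincRNA, snoRNA, snRNA,
miRNA, pseudogene) with biotype-typical length ranges; a 200-edge
preferential-attachment interactome with Uniform(0.2, 1.8) read weights;
50,000 read pairs of length 100; category mix 70% chimeric / 15%
linker–RNA2 / 10% no-linker / 5% linker-only; 7% random ligation; 20%
PCR duplicates (verbatim re-emission, shuffled emission order); 0.5%
per-base substitution error; fragment lengths clamped log-normal
(median 80, range 15–300) emulating post-digestion, size-selected
fragments at sequencing scale. Five long mRNAs carry a planted proximal
junction pair at 25% and 70% of transcript length, each supported by 10
cut-and-ligated reads with ±3 nt junction jitter; those jittered junction
neighbourhoods double as cut hotspots for the density track. Read 1 is
barcode + insert sense strand; read 2 is the reverse complement of the
insert 3' end — one documented dialect shared between simulator and
parser, since the assay's final read orientation after circularization is
not fully specified at the source.

What the simulator does *not* emulate: splicing and isoforms, expression
realism beyond per-edge weights, position- or quality-dependent error
models, ligation sequence biases, and real repeat structure. Passing tests
therefore demonstrate algorithmic correctness under the stated generative
model, not performance on real libraries.

`evaluate_calls()` scores calls against truth: sensitivity over planted
edges with at least one emitted read; specificity as one minus the
significant fraction of tested non-planted pairs.

## Numerical and degenerate-input choices

* Genomic intervals use `GRanges` (1-based, closed) — the Bioconductor
  convention — converting at BED/BEDPE/bedGraph boundaries; transcript
  coordinates in the structure module are 0-based half-open.
* Equal junctions (`junction1 == junction2`) are structurally ambiguous
  and dropped with a counter; overlapping fragments classify by junction
  order.
* Degenerate energy comparisons (all values identical) report p = 1 with
  a diagnostic rather than failing.
* A power-law fit is refused below 3 distinct degrees.
* `estimate_random_ligation` errors on zero eligible pairs; its correction
  factor is undefined (NA) for a single-species input.
* All stochastic steps take explicit seeds and restore the caller's RNG
  state.

## Problem sizes used in the shipped checks

Oracle comparisons enumerate all 2×2 tables with N ≤ 30 (~47k tables) and
200 random duplex pairs of length ≤ 8; the parser round-trip uses 2,000
read pairs; the cross-species estimate uses ~21,000 chimeras from 29,000
pairs; null calibration uses 500 replicates of 20 interactions (a sample
size at which the discreteness of the exact signed-rank support is
negligible against a continuous-uniform KS reference); the
end-to-end regression runs the full default 50,000-pair library through
the pipeline, where the regression bar is specificity ≥ 0.9 at FDR 0.05
and full recovery of planted proximal pairs with ≥ 5 supporting reads.

## Known limitations

Single-exon gene models only; the built-in aligner is a fixture-scale tool
(no splicing, no gaps); no isoform resolution (gene-level, as in the
assay); the duplex model's wobble stacks are flattened; conservation
tracks are consumed, never computed; no community detection or
visualisation. The web-scale outputs of the original toolchain
(visualizers, browser tracks) are out of scope.
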