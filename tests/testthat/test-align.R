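test_that("toy aligner finds planted substrings and flags repeats", {
  set.seed(5)
  chrom <- random_dna(5000)
  dup <- random_dna(40)
  # plant a duplicated segment at two loci
  substr(chrom, 2001, 2040) <- dup
  substr(chrom, 4001, 4040) <- dup
  idx <- genome_index(c(chr1 = chrom))
  frag <- substr(chrom, 1001, 1060)
  al <- toy_align(frag, idx)
  expect_equal(al$status, "mapped")
  expect_equal(al$start, 1000)
  expect_equal(al$end, 1060)
  expect_equal(al$strand, "+")
  expect_true(al$unique)
  # reverse-complement fragment maps to the minus strand, same locus
  alrc <- toy_align(revcomp(frag), idx)
  expect_equal(alrc$start, 1000)
  expect_equal(alrc$strand, "-")
  # duplicated fragment is never unique
  aldup <- toy_align(dup, idx)
  expect_equal(aldup$status, "ambiguous")
  expect_false(aldup$unique)
  # too short for the seed -> unmapped
  expect_equal(toy_align("ACGTACGT", idx)$status, "unmapped")
})

test_that("toy aligner recovers all planted loci of simulated fragments", {
  cfg <- small_cfg(seed = 13, n_read_pairs = 700)
  ref <- cached_reference(cfg, "align700")
  lib <- simulate_library(cfg, ref)
  tr <- lib$truth[lib$truth$category == "chimeric", ][1:500, ]
  txs <- chimeramap:::.tx_seqs(ref)
  frags <- substr(txs[tr$gene1], tr$frag1_tstart + 1, tr$frag1_tend)
  idx <- genome_index(ref$genome)
  al <- toy_align(frags, idx)
  expect_equal(mean(al$status == "mapped"), 1)
  expect_equal(al$chrom, tr$chrom1)
  expect_equal(al$start, tr$frag1_gstart)
  expect_equal(al$end, tr$frag1_gend)
})

test_that("gene assignment follows overlap fraction, strand and tie rules", {
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(101, 301, 1001), c(200, 400, 1100)),
    strand = c("+", "+", "-"))
  genes$gene_id <- c("snoRNA_1", "gene_b", "gene_minus")
  genes$biotype <- c("snoRNA", "mRNA", "mRNA")
  reps <- GenomicRanges::GRanges("chr1", IRanges::IRanges(601, 700),
                                 strand = "+")
  reps$family <- "L1"
  fr <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(121, 621, 621, 241, 2001),
                     c(160, 660, 660, 260, 2040)),
    strand = c("+", "+", "-", "+", "+"))
  as <- assign_genes(fr, genes, reps)
  expect_equal(as$unit[1], "snoRNA_1")         # containment, same strand
  expect_equal(as$biotype[1], "snoRNA")
  expect_equal(as$unit[2], "repeat:L1")        # repeat fallback
  expect_equal(as$biotype[2], "transposonRNA")
  expect_match(as$unit[3], "^novel_")          # wrong strand for the repeat
  expect_match(as$unit[4], "^novel_")          # intergenic
  expect_match(as$unit[5], "^novel_")
  expect_false(as$unit[4] == as$unit[5])       # far apart: distinct loci

  # overlap fraction: 60%/40% straddle resolves, 50%/50% is ambiguous
  genes2 <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 61), c(60, 160)), strand = "+")
  genes2$gene_id <- c("left", "right")
  genes2$biotype <- c("mRNA", "mRNA")
  f60 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(37, 96), strand = "+")
  expect_equal(assign_genes(f60, genes2)$unit, "right")
  f50 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(31, 90), strand = "+")
  a50 <- assign_genes(f50, genes2)
  expect_true(a50$ambiguous)
  expect_true(is.na(a50$unit))
})

test_that("gene assignment is order-independent with stable novel ids", {
  set.seed(8)
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 6000),
                                  strand = "+")
  genes$gene_id <- "g1"; genes$biotype <- "mRNA"
  starts <- sample(seq(1, 4000, by = 400))
  fr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, starts + 79),
                               strand = "+")
  a1 <- assign_genes(fr, genes)
  perm <- sample(length(fr))
  a2 <- assign_genes(fr[perm], genes)
  expect_equal(a1$unit[perm], a2$unit)
})

test_that("random-ligation estimation: arithmetic, CI and correction", {
  # all intra-species
  est0 <- estimate_random_ligation(rep("mm", 10), rep("mm", 10))
  expect_equal(est0$fraction, 0)
  # hand count: 3 inter among 10
  s1 <- c(rep("mm", 7), rep("dm", 3))
  s2 <- c(rep("mm", 7), rep("mm", 3))
  est <- estimate_random_ligation(s1, s2)
  expect_equal(est$fraction, 0.3)
  expect_true(est$ci[1] < 0.3 && est$ci[2] > 0.3)
  expect_error(estimate_random_ligation(character(0), character(0)),
               "no eligible")
  # corrected estimate recovers a planted rate on an equal two-species mix
  cfg <- sim_config(seed = 5, n_read_pairs = 9000, two_species = TRUE,
                    duplicate_rate = 0, error_rate = 0,
                    n_structure_genes = 0,
                    frag_len = list(meanlog = log(40), sdlog = 0.4,
                                    min = 15L, max = 70L))
  ref <- make_reference(cfg)
  lib <- simulate_library(cfg, ref)
  tr <- lib$truth[lib$truth$category == "chimeric", ]
  est2 <- estimate_random_ligation(tr$species1, tr$species2)
  # raw fraction is roughly half the planted rate (cross-species share ~ 1/2)
  expect_lt(est2$fraction, 0.07)
  se <- sqrt(est2$fraction * (1 - est2$fraction) / est2$n) *
    est2$correction_factor
  expect_lt(abs(est2$corrected - 0.07), 3 * se)
})

test_that("random-ligation CI covers the planted inter-species fraction", {
  # direct binomial simulation of the estimator's sampling distribution
  set.seed(19)
  rate <- 0.035; n <- 2000
  covered <- vapply(1:200, function(i) {
    x <- rbinom(1, n, rate)
    sp1 <- rep("a", n)
    sp2 <- c(rep("b", x), rep("a", n - x))
    ci <- estimate_random_ligation(sp1, sp2)$ci
    ci[1] <= rate && rate <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
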