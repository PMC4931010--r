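test_that("intramolecular filters reproduce the geometry truth table", {
  # six constructed geometries on one gene g (plus a two-gene pair)
  geom <- data.frame(
    gene1 = c("g", "g", "g", "g", "g", "g", "g1"),
    gene2 = c("g", "g", "g", "g", "g", "g", "g2"),
    has_linker = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    strand1 = c("+", "+", "-", "+", "+", "+", "+"),
    strand2 = c("-", "-", "+", "+", "-", "-", "-"),
    start1 = c(1000, 1000, 1000, 1000, 1500, 1000, 1000),
    end1 =   c(1060, 1060, 1060, 1060, 1560, 1060, 1060),
    start2 = c(1500, 9000, 1500, 1500, 1000, 1500, 1500),
    end2 =   c(1560, 9060, 1560, 1560, 1060, 1560, 1560),
    stringsAsFactors = FALSE)
  # row 1: convergent within 2 kb (continuous fragment)      -> dropped
  # row 2: convergent beyond 2 kb                            -> kept
  # row 3: divergent (minus-strand mate upstream of plus)    -> kept
  # row 4: same strand                                       -> kept
  # row 5: plus-strand mate downstream of minus-strand mate  -> kept
  # row 6: linkerless                                        -> dropped
  # row 7: different genes                                   -> dropped
  out <- filter_intramolecular(geom)
  expect_equal(nrow(out), 4)
  expect_equal(out$start2, c(9000, 1500, 1500, 1000))
  drops <- attr(out, "drops")
  expect_equal(drops$different_gene, 1)
  expect_equal(drops$no_linker, 1)
  expect_equal(drops$continuous_fragment, 1)
})

test_that("structural classes follow transcript junction order", {
  expect_equal(classify_structure(39, 100), "I")
  expect_equal(classify_structure(129, 10), "II")
  expect_true(is.na(classify_structure(50, 50)))
  # exhaustive enumeration over a toy transcript: exactly 2 classes
  grid <- expand.grid(j1 = seq(0, 299, by = 7), j2 = seq(0, 299, by = 7))
  grid <- grid[grid$j1 != grid$j2, ]
  classes <- unique(classify_structure(grid$j1, grid$j2))
  expect_setequal(classes, c("I", "II"))
})

test_that("intra_pairs projects genomic coordinates and classifies", {
  # plus-strand gene [1000, 2000); frag1 [1100,1140) then frag2 [1600,1660)
  pr <- data.frame(gene1 = "g", gene2 = "g", has_linker = TRUE,
                   strand1 = "+", strand2 = "+",
                   start1 = 1100, end1 = 1140, start2 = 1600, end2 = 1660,
                   gene_strand = "+", stringsAsFactors = FALSE)
  ip <- intra_pairs(pr, 1000, 2000)
  expect_equal(ip$frag1_start, 100)
  expect_equal(ip$junction1, 139)
  expect_equal(ip$junction2, 600)
  expect_equal(ip$class, "I")
  # the same genomic geometry on a minus-strand gene flips transcript order
  pr$gene_strand <- "-"
  ipm <- intra_pairs(pr, 1000, 2000)
  expect_equal(ipm$frag1_start, 860)   # 2000 - 1140
  expect_equal(ipm$junction1, 899)
  expect_equal(ipm$junction2, 340)
  expect_equal(ipm$class, "II")
})

test_that("cut density counts fragment termini", {
  cd <- cut_density(50, 120, 200)
  expect_equal(which(cd$counts > 0) - 1L, c(50, 119))
  expect_equal(sum(cd$counts), 2)
  # ten fragments sharing a 5' terminus pile up there
  cd2 <- cut_density(rep(50, 10), 50 + seq(20, 65, by = 5), 200)
  expect_equal(cd2$counts[51], 10)
  expect_equal(sum(cd2$counts), 20)
  # smoothing preserves nothing but reporting; raw counts unchanged
  cd3 <- cut_density(c(10, 20), c(40, 60), 100, smooth_window = 5)
  expect_equal(sum(cd3$counts), 4)
  expect_length(cd3$smoothed, 100)
})

test_that("cut-density maxima co-locate with planted junction hotspots", {
  cfg <- small_cfg(seed = 37, n_read_pairs = 600, n_structure_genes = 3,
                   structure_reads_per_pair = 12)
  ref <- make_reference(cfg)
  lib <- simulate_library(cfg, ref)
  tr <- lib$truth[lib$truth$is_intra, ]
  for (g in unique(tr$gene1)) {
    sub <- tr[tr$gene1 == g, ]
    L <- ref$structure$tx_length[ref$structure$gene_id == g]
    cd <- cut_density(c(sub$frag1_tstart, sub$frag2_tstart),
                      c(sub$frag1_tend, sub$frag2_tend), L)
    planted <- ref$structure[ref$structure$gene_id == g, ]
    peak <- which.max(cd$counts) - 1L
    # the global maximum falls within the jittered junction neighbourhood
    expect_true(min(abs(peak - c(planted$pos1, planted$pos2))) <=
                  cfg$junction_jitter + 1)
  }
})

test_that("contact map conserves mass and localises planted contacts", {
  cm <- contact_map(12, 87, 100, bin = 5)
  expect_equal(cm$matrix[3, 18], 1)
  expect_equal(cm$matrix[18, 3], 1)
  expect_equal(sum(cm$matrix[upper.tri(cm$matrix, diag = TRUE)]), 1)
  expect_true(isSymmetric(cm$matrix))
  expect_error(contact_map(120, 50, 100), "outside transcript")
  # mass conservation on random inputs
  set.seed(21)
  for (rep in 1:10) {
    L <- sample(200:1000, 1)
    n <- sample(1:100, 1)
    j1 <- sample(0:(L - 1), n, replace = TRUE)
    j2 <- sample(0:(L - 1), n, replace = TRUE)
    cm <- contact_map(j1, j2, L, bin = sample(c(1, 5, 10), 1))
    expect_equal(sum(cm$matrix[upper.tri(cm$matrix, diag = TRUE)]), n)
    expect_true(isSymmetric(cm$matrix))
  }
  # planted hairpin: argmax at the planted bin pair (mid-bin positions so
  # the +/-2 jitter never crosses a bin boundary)
  p <- 45; q <- 165
  j1 <- pmin(pmax(p + sample(-2:2, 20, TRUE), 0), 199)
  j2 <- pmin(pmax(q + sample(-2:2, 20, TRUE), 0), 199)
  cmh <- contact_map(j1, j2, 200, bin = 10)
  am <- which(cmh$matrix == max(cmh$matrix), arr.ind = TRUE)
  expect_true(any(am[, 1] == p %/% 10 + 1 & am[, 2] == q %/% 10 + 1))
})

test_that("proximal pair clustering is single-linkage with support gating", {
  # two co-located events stay below the default support threshold
  expect_equal(nrow(call_proximal_pairs(c(100, 102), c(300, 301))), 0)
  # three events within tolerance form one supported pair
  pp <- call_proximal_pairs(c(100, 104, 108), c(300, 303, 295))
  expect_equal(nrow(pp), 1)
  expect_equal(pp$support, 3)
  expect_equal(pp$window1_start, 100)
  expect_equal(pp$window1_end, 108)
  # chain linkage: neighbours within tol link 0-8-16 transitively
  ch <- call_proximal_pairs(c(100, 108, 116), c(300, 300, 300))
  expect_equal(nrow(ch), 1)
  expect_equal(ch$support, 3)
  # two separated clusters stay separate
  sep <- call_proximal_pairs(c(100, 101, 102, 500, 501, 502),
                             c(300, 301, 302, 800, 801, 802))
  expect_equal(nrow(sep), 2)
})

test_that("all planted proximal pairs are recovered from simulated reads", {
  cfg <- small_cfg(seed = 41, n_read_pairs = 800, n_structure_genes = 4,
                   structure_reads_per_pair = 6)
  ref <- make_reference(cfg)
  lib <- simulate_library(cfg, ref)
  tr <- lib$truth[lib$truth$is_intra, ]
  for (g in ref$structure$gene_id) {
    sub <- tr[tr$gene1 == g, ]
    pp <- call_proximal_pairs(sub$junction1, sub$junction2)
    planted <- ref$structure[ref$structure$gene_id == g, ]
    expect_equal(nrow(pp), 1)
    j <- cfg$junction_jitter
    expect_true(pp$window1_start - j <= planted$pos1 &&
                  planted$pos1 <= pp$window1_end + j)
    expect_true(pp$window2_start - j <= planted$pos2 &&
                  planted$pos2 <= pp$window2_end + j)
  }
})
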