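test_that("count_pairs merges unordered pairs with margins", {
  pc <- count_pairs(c("g1", "g2", "g1"), c("g2", "g1", "g3"))
  expect_equal(nrow(pc), 2)
  r12 <- pc[pc$gene_a == "g1" & pc$gene_b == "g2", ]
  expect_equal(r12$n_ab, 2)
  expect_equal(r12$n_a, 3)   # g1 touches all three chimeras
  expect_equal(r12$n_b, 2)
  expect_equal(r12$N, 3)
  # invariants
  expect_true(all(pc$n_ab <= pmin(pc$n_a, pc$n_b)))
  expect_true(all(pc$N >= pc$n_a + pc$n_b - pc$n_ab))
  # ambiguous sides and same-gene pairs are dropped with counters
  pc2 <- count_pairs(c("g1", NA, "g3"), c("g2", "g2", "g3"))
  expect_equal(nrow(pc2), 1)
  expect_equal(attr(pc2, "drops")$n_unassigned, 1)
  expect_equal(attr(pc2, "drops")$n_same_gene, 1)
})

test_that("count_pairs matches planted edge counts at zero error", {
  cfg <- small_cfg(seed = 23, n_read_pairs = 2000, random_ligation_rate = 0,
                   category_mix = c(chimeric = 1, linker_rna2 = 0,
                                    no_linker = 0, linker_only = 0))
  ref <- make_reference(cfg)
  lib <- simulate_library(cfg, ref)
  tr <- lib$truth
  pc <- count_pairs(tr$gene1, tr$gene2)
  want <- table(paste0(pmin(tr$gene1, tr$gene2), "|", pmax(tr$gene1, tr$gene2)))
  got <- setNames(pc$n_ab, paste0(pc$gene_a, "|", pc$gene_b))
  expect_equal(got[names(want)], setNames(as.integer(want), names(want)))
})

test_that("fisher_enrichment equals combinatorial corner cases", {
  expect_equal(fisher_enrichment(5, 5, 5, 100), 1 / choose(100, 5))
  expect_equal(fisher_enrichment(7, 7, 7, 7), 1)   # saturated table
  expect_error(fisher_enrichment(5, 4, 5, 100), "negative cell")
})

test_that("fisher_enrichment equals exhaustive enumeration for all N <= 30", {
  for (N in 1:30) {
    for (n_a in 0:N) {
      for (n_b in 0:n_a) {   # symmetry in the margins
        as <- max(0, n_a + n_b - N):min(n_a, n_b)
        got <- fisher_enrichment(as, n_a, n_b, N)
        want <- vapply(as, oracle_fisher_tail, 0, n_a = n_a, n_b = n_b, N = N)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("fisher_enrichment agrees with fisher.test on random tables", {
  set.seed(3)
  for (rep in 1:25) {
    N <- sample(20:200, 1)
    n_a <- sample(1:N, 1); n_b <- sample(1:N, 1)
    arange <- max(0, n_a + n_b - N):min(n_a, n_b)
    a <- arange[sample.int(length(arange), 1)]
    tab <- matrix(c(a, n_a - a, n_b - a, N - n_a - n_b + a), 2)
    expect_equal(fisher_enrichment(a, n_a, n_b, N),
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("bh_fdr equals the independent step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(77)
  for (rep in 1:50) {
    p <- runif(sample(1:100, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
  # monotone when sorted; q >= p; threshold equals classical rejection set
  p <- sort(runif(200))
  q <- bh_fdr(p)
  expect_true(all(diff(q) >= -1e-15))
  expect_true(all(q >= p - 1e-15))
  alpha <- 0.1
  m <- length(p)
  kmax <- max(c(0, which(p <= alpha * seq_len(m) / m)))
  classical <- seq_len(m) <= kmax
  expect_equal(which(q <= alpha), which(classical))
})

test_that("interaction type labels are canonical with mRNA last", {
  expect_equal(classify_interaction("snoRNA", "mRNA"), "snoRNA-mRNA")
  expect_equal(classify_interaction("mRNA", "snoRNA"), "snoRNA-mRNA")
  expect_equal(classify_interaction("transposon", "mRNA"), "transposonRNA-mRNA")
  expect_equal(classify_interaction("pseudogene", "mRNA"), "pseudogeneRNA-mRNA")
  expect_equal(classify_interaction("mRNA", "mRNA"), "mRNA-mRNA")
  expect_equal(classify_interaction("frobnicator", "mRNA"), "other-mRNA")
  expect_equal(classify_interaction(c("mRNA", "lincRNA"), c("lincRNA", "mRNA")),
               rep("lincRNA-mRNA", 2))
})

test_that("site calling thresholds, merging and width filtering", {
  # below support threshold everywhere -> empty
  expect_equal(nrow(call_sites(c(10, 30), c(25, 45))), 0)
  # six identical fragments -> one site with support 6
  s <- call_sites(rep(100, 6), rep(160, 6))
  expect_equal(nrow(s), 1)
  expect_equal(s$start, 100)
  expect_equal(s$end, 160)
  expect_equal(s$support, 6)
  # two stacks 50 nt apart -> two sites (gap > max_gap)
  s2 <- call_sites(c(rep(100, 5), rep(230, 5)), c(rep(180, 5), rep(300, 5)))
  expect_equal(nrow(s2), 2)
  # gap below max_gap merges into one site
  s3 <- call_sites(c(rep(100, 5), rep(188, 5)), c(rep(180, 5), rep(260, 5)))
  expect_equal(nrow(s3), 1)
  expect_equal(s3$start, 100)
  expect_equal(s3$end, 260)
  # narrow site is dropped
  s4 <- call_sites(rep(50, 8), rep(55, 8))
  expect_equal(nrow(s4), 0)
})

test_that("degree distribution and power-law fit behave on known graphs", {
  # star graph: two distinct degrees, fit refused
  star <- data.frame(gene_a = "hub", gene_b = sprintf("leaf%02d", 1:50))
  dd <- degree_distribution(star)
  expect_equal(sum(dd$count), 51)
  expect_equal(dd$count[dd$k == 1], 50)
  expect_equal(dd$count[dd$k == 50], 1)
  expect_error(fit_power_law(dd), "refused")
  # preferential attachment: scale-free signature
  fit <- fit_power_law(degree_distribution(pa_network(1000, 2, seed = 4)))
  expect_lt(fit$slope, 0)
  expect_gte(fit$r2, 0.8)
  expect_true(fit$power_law_like)
  # flat promiscuous topology is not a hierarchical network
  ffit <- fit_power_law(degree_distribution(flat_network(seed = 4)))
  expect_false(ffit$power_law_like)
})

test_that("random edge removal keeps the scale-free signature", {
  set.seed(15)
  edges <- pa_network(1000, 2, seed = 15)
  for (retain in c(0.8, 0.5)) {
    sub <- edges[sample(nrow(edges), round(retain * nrow(edges))), ]
    fit <- fit_power_law(degree_distribution(sub))
    expect_lt(fit$slope, 0)
    expect_gte(fit$r2, 0.8)
  }
})

test_that("call_interactions recovers a planted interactome", {
  cfg <- small_cfg(seed = 29, n_read_pairs = 4000)
  ref <- make_reference(cfg)
  lib <- simulate_library(cfg, ref)
  tr <- lib$truth[lib$truth$category == "chimeric", ]
  pc <- count_pairs(tr$gene1, tr$gene2)
  bt <- setNames(ref$genes$biotype, ref$genes$gene_id)
  calls <- call_interactions(pc, bt)
  expect_true(all(calls$q_value >= calls$p_value - 1e-15))
  expect_equal(calls$significant, calls$q_value < 0.05)
  ev <- evaluate_calls(calls, lib$truth, ref$edges)
  expect_gte(ev$specificity, 0.9)
  expect_gte(ev$sensitivity, 0.8)
})
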