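test_that("find_linker locates exact and boundary occurrences", {
  seq <- paste0(strrep("A", 20), PROXIMITY_LINKER, strrep("G", 20))
  hit <- find_linker(seq)
  expect_equal(hit$start, 20)
  expect_equal(hit$end, 44)
  expect_equal(hit$mismatches, 0)
  expect_equal(hit$kind, "internal")
  # linker prefix at the read 3' end
  hit2 <- find_linker(paste0(strrep("A", 30), substr(PROXIMITY_LINKER, 1, 8)))
  expect_equal(hit2$start, 30)
  expect_equal(hit2$end, 38)
  expect_equal(hit2$kind, "prefix")
  # linker suffix at the read 5' end
  hit3 <- find_linker(paste0(substr(PROXIMITY_LINKER, 17, 24), strrep("A", 30)))
  expect_equal(hit3$start, 0)
  expect_equal(hit3$end, 8)
  expect_equal(hit3$kind, "suffix")
  # absence is NULL, not an error
  expect_null(find_linker(strrep("A", 60)))
})

test_that("mismatch budget is floor(rate x matched length)", {
  mutate_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- c(A = "C", C = "G", G = "T", T = "A")[ch[p]]
    paste(ch, collapse = "")
  }
  emb <- function(lk) paste0(strrep("A", 15), lk, strrep("G", 15))
  # floor(0.1 * 24) = 2 mismatches allowed in a full-linker match
  expect_equal(find_linker(emb(mutate_at(PROXIMITY_LINKER, c(5, 12))))$mismatches, 2)
  expect_null(find_linker(emb(mutate_at(PROXIMITY_LINKER, c(5, 12, 20)))))
})

test_that("find_linker agrees with the exhaustive scan oracle", {
  set.seed(31)
  for (rep in 1:120) {
    n <- sample(10:60, 1)
    seq <- random_dna(n)
    # half the trials plant a (possibly mutated) linker piece
    if (rep %% 2 == 0) {
      piece <- substr(PROXIMITY_LINKER, 1, sample(6:24, 1))
      at <- sample(0:max(0, n - nchar(piece)), 1)
      substr(seq, at + 1, at + nchar(piece)) <- piece
    }
    got <- find_linker(seq)
    want <- oracle_find_linker(seq, PROXIMITY_LINKER)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$mismatches, want$mismatches)
    }
  }
})

test_that("split_read_pairs recovers planted construct categories", {
  lk <- PROXIMITY_LINKER
  f1 <- random_dna(60); f2 <- random_dna(70)
  mk <- function(insert, rl = 100) {
    list(p1 = substr(insert, 1, rl),
         r2 = revcomp(substr(insert, max(1, nchar(insert) - rl + 1),
                             nchar(insert))))
  }
  # chimeric round trip
  rp <- mk(paste0(f1, lk, f2))
  res <- split_read_pairs(rp$p1, rp$r2)
  expect_equal(res$category, "chimeric")
  expect_equal(res$rna1, f1)
  expect_equal(res$rna2, f2)
  # the non-informative 5'-linker-RNA2 form
  rp2 <- mk(paste0(lk, f2))
  res2 <- split_read_pairs(rp2$p1, rp2$r2)
  expect_equal(res2$category, "linker_rna2")
  expect_equal(res2$rna2, f2)
  # bare linker and bare fragment
  rp3 <- mk(lk)
  expect_equal(split_read_pairs(rp3$p1, rp3$r2)$category, "linker_only")
  rp4 <- mk(f1)
  expect_equal(split_read_pairs(rp4$p1, rp4$r2)$category, "no_linker")
  # two disjoint linkers -> ambiguous
  rp5 <- mk(paste0(f1, lk, random_dna(30), lk, f2), rl = 200)
  expect_equal(split_read_pairs(rp5$p1, rp5$r2)$category, "ambiguous")
  # sub-minimum flank is blanked: chimeric degrades to linker_rna2
  rp6 <- mk(paste0(random_dna(8), lk, f2))
  res6 <- split_read_pairs(rp6$p1, rp6$r2)
  expect_equal(res6$category, "linker_rna2")
  expect_equal(attr(res6, "n_short_dropped"), 1)
})

test_that("unmerged long inserts are still split around the linker", {
  lk <- PROXIMITY_LINKER
  f1 <- random_dna(70); f2 <- random_dna(180)
  insert <- paste0(f1, lk, f2)   # 274 nt: mates cannot overlap at 100 nt
  p1 <- substr(insert, 1, 100)
  r2 <- revcomp(substr(insert, nchar(insert) - 99, nchar(insert)))
  res <- split_read_pairs(p1, r2)
  expect_false(res$merged)
  expect_equal(res$category, "chimeric")
  expect_equal(res$rna1, f1)
  # RNA2 is represented by the mate-2 view (its 3'-most 100 nt)
  expect_equal(res$rna2, substr(f2, 81, 180))
})

test_that("parser round-trips a zero-error simulated library exactly", {
  cfg <- small_cfg(seed = 7, n_read_pairs = 1000,
                   category_mix = c(chimeric = 0.70, linker_rna2 = 0.15,
                                    no_linker = 0.10, linker_only = 0.05))
  ref <- cached_reference(cfg, "parse1k")
  lib <- simulate_library(cfg, ref)
  p <- parse_chimeras(lib$read1, lib$read2, ids = lib$ids)
  tr <- lib$truth
  m <- match(p$chimeras$read_id, tr$read_id)
  # diagonal confusion matrix: every category recovered
  expect_equal(mean(p$chimeras$category == tr$category[m]), 1)
  expect_equal(mean(p$chimeras$sample_id == tr$sample[m]), 1)
  expect_equal(mean(p$chimeras$umi == tr$umi[m]), 1)
  # fragment sequences equal the planted fragments
  txs <- chimeramap:::.tx_seqs(ref)
  chim <- which(p$chimeras$category == "chimeric")
  mt <- m[chim]
  want1 <- substr(txs[tr$gene1[mt]], tr$frag1_tstart[mt] + 1, tr$frag1_tend[mt])
  want2 <- substr(txs[tr$gene2[mt]], tr$frag2_tstart[mt] + 1, tr$frag2_tend[mt])
  expect_equal(unname(p$chimeras$rna1[chim]), unname(want1))
  expect_equal(unname(p$chimeras$rna2[chim]), unname(want2))
})
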