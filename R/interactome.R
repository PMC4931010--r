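#' Count chimeras per unordered gene pair
#'
#' Aggregates gene-assigned chimeras into unordered pair counts with the
#' per-gene endpoint margins used by the enrichment test. Same-gene
#' chimeras are excluded here (they are structure evidence, handled by
#' [filter_intramolecular()]), as are chimeras with an ambiguous or missing
#' side; both exclusions are counted in the attached drop report.
#'
#' @param gene1,gene2 character vectors: assigned unit of each chimera's
#'   two fragments (NA = unassigned/ambiguous).
#' @return data.frame with columns \code{gene_a}, \code{gene_b}
#'   (lexicographically ordered), \code{n_ab}, \code{n_a}, \code{n_b},
#'   \code{N}; drop counts in \code{attr(, "drops")}.
#' @export
count_pairs <- function(gene1, gene2) {
  stopifnot(length(gene1) == length(gene2))
  ok <- !is.na(gene1) & !is.na(gene2)
  same <- ok & gene1 == gene2
  keep <- ok & !same
  drops <- list(n_unassigned = sum(!ok), n_same_gene = sum(same))
  a <- pmin(gene1[keep], gene2[keep])
  b <- pmax(gene1[keep], gene2[keep])
  N <- length(a)
  key <- paste0(a, "\x01", b)
  tab <- table(key)
  ab <- strsplit(names(tab), "\x01", fixed = TRUE)
  ga <- vapply(ab, `[`, "", 1L)
  gb <- vapply(ab, `[`, "", 2L)
  margin <- table(c(a, b))
  out <- data.frame(gene_a = ga, gene_b = gb, n_ab = as.integer(tab),
                    n_a = as.integer(margin[ga]), n_b = as.integer(margin[gb]),
                    N = N, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "drops") <- drops
  out
}

#' One-sided Fisher enrichment p-value for a gene pair
#'
#' The 2x2 table for a pair (a, b) is built from the chimera margins:
#' \code{x = n_ab} (chimeras joining a and b), \code{n_a - n_ab} and
#' \code{n_b - n_ab} (chimeras touching only one of the two), and the
#' remainder of the \code{N} assigned chimeras. The one-sided (enrichment)
#' p-value is the hypergeometric upper tail
#' \code{P(X >= n_ab)} with \code{X ~ Hypergeom(N, n_a, n_b)}. Vectorised.
#'
#' @param n_ab,n_a,n_b,N integer vectors (recycled), see [count_pairs()].
#' @return numeric vector of p-values.
#' @examples
#' fisher_enrichment(5, 5, 5, 100) # = 1 / choose(100, 5)
#' @export
fisher_enrichment <- function(n_ab, n_a, n_b, N) {
  d <- N - n_a - n_b + n_ab
  if (any(n_ab < 0 | n_a - n_ab < 0 | n_b - n_ab < 0 | d < 0))
    stop("invalid 2x2 table: negative cell")
  stats::phyper(n_ab - 1, n_a, N - n_a, n_b, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment
#' (\code{q_(i) = min_{j >= i} m p_(j) / j}, capped at 1), returned in the
#' input order. Thin validated wrapper over \code{stats::p.adjust}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# canonical biotype ordering for interaction type labels (mRNA last)
.biotype_rank <- c(lincRNA = 1, miRNA = 2, snoRNA = 3, snRNA = 4, tRNA = 5,
                   pseudogeneRNA = 6, transposonRNA = 7, antisenseRNA = 8,
                   novel = 9, other = 10, mRNA = 11)

.canon_biotype <- function(b) {
  map <- c(mRNA = "mRNA", lincRNA = "lincRNA", snoRNA = "snoRNA",
           snRNA = "snRNA", tRNA = "tRNA", miRNA = "miRNA",
           pseudogene = "pseudogeneRNA", pseudogeneRNA = "pseudogeneRNA",
           antisense = "antisenseRNA", antisenseRNA = "antisenseRNA",
           novel = "novel", transposon = "transposonRNA",
           transposonRNA = "transposonRNA")
  out <- unname(map[b])
  out[is.na(out)] <- "other"
  out
}

#' Canonical interaction type label from two biotypes
#'
#' Fixed ordering with mRNA always last (e.g. \code{"lincRNA-mRNA"}, never
#' \code{"mRNA-lincRNA"}); repeat-derived fragments are labelled
#' \code{transposonRNA}; unknown biotypes map to \code{other}. Vectorised.
#'
#' @param biotype_a,biotype_b character vectors of biotypes.
#' @return character vector of type labels.
#' @examples
#' classify_interaction("snoRNA", "mRNA") # "snoRNA-mRNA"
#' @export
classify_interaction <- function(biotype_a, biotype_b) {
  a <- .canon_biotype(biotype_a)
  b <- .canon_biotype(biotype_b)
  swap <- .biotype_rank[a] > .biotype_rank[b]
  first <- ifelse(swap, b, a)
  second <- ifelse(swap, a, b)
  paste(first, second, sep = "-")
}

#' Call enriched RNA-RNA interactions
#'
#' Applies [fisher_enrichment()] to every pair supported by at least
#' \code{min_pair_count} chimeras, corrects with [bh_fdr()] over the tested
#' pairs, and labels each call with its canonical interaction type.
#'
#' @param pairs data.frame from [count_pairs()].
#' @param biotypes named character vector mapping unit id -> biotype.
#' @param min_pair_count minimum chimera support to test (default 2).
#' @param fdr significance threshold on q (default 0.05).
#' @return data.frame of tested pairs with added columns \code{p_value},
#'   \code{q_value}, \code{type_label}, \code{significant}.
#' @export
call_interactions <- function(pairs, biotypes = NULL, min_pair_count = 2L,
                              fdr = 0.05) {
  tested <- pairs[pairs$n_ab >= min_pair_count, , drop = FALSE]
  if (nrow(tested) == 0) {
    tested$p_value <- numeric(0); tested$q_value <- numeric(0)
    tested$type_label <- character(0); tested$significant <- logical(0)
    return(tested)
  }
  tested$p_value <- fisher_enrichment(tested$n_ab, tested$n_a, tested$n_b,
                                      tested$N)
  tested$q_value <- bh_fdr(tested$p_value)
  tested$type_label <- if (is.null(biotypes)) NA_character_ else
    classify_interaction(unname(biotypes[tested$gene_a]),
                         unname(biotypes[tested$gene_b]))
  tested$significant <- tested$q_value < fdr
  rownames(tested) <- NULL
  tested
}

#' Call interaction sites from fragment pileups on one transcript
#'
#' Interaction sites are "peaks" of overlapping chimeric fragments:
#' transcript positions with coverage at least \code{min_site_support},
#' merged across gaps of at most \code{max_gap} nt; sites narrower than
#' \code{min_site_width} are dropped. Support is the maximum coverage
#' within the site.
#'
#' @param starts,ends integer vectors: fragment intervals in 0-based
#'   half-open transcript coordinates.
#' @param min_site_support coverage threshold (default 5).
#' @param max_gap largest sub-threshold gap bridged (default 10).
#' @param min_site_width minimum reported site width (default 10).
#' @return data.frame with columns \code{start}, \code{end} (0-based
#'   half-open) and \code{support}.
#' @export
call_sites <- function(starts, ends, min_site_support = 5L, max_gap = 10L,
                       min_site_width = 10L) {
  empty <- data.frame(start = integer(), end = integer(), support = integer())
  if (length(starts) == 0) return(empty)
  stopifnot(length(starts) == length(ends), all(ends > starts))
  ir <- IRanges::IRanges(start = starts + 1L, end = ends)
  cov <- IRanges::coverage(ir)
  above <- IRanges::slice(cov, lower = min_site_support, rangesOnly = TRUE)
  if (length(above) == 0) return(empty)
  merged <- IRanges::reduce(above, min.gapwidth = max_gap + 1L)
  merged <- merged[IRanges::width(merged) >= min_site_width]
  if (length(merged) == 0) return(empty)
  support <- vapply(seq_along(merged), function(i) {
    max(as.integer(S4Vectors::runValue(cov[IRanges::start(merged)[i]:IRanges::end(merged)[i]])))
  }, integer(1))
  data.frame(start = IRanges::start(merged) - 1L, end = IRanges::end(merged),
             support = support)
}

#' Degree distribution of the significant-interaction network
#'
#' @param edges data.frame with columns \code{gene_a}, \code{gene_b}
#'   (undirected edges, e.g. significant rows of [call_interactions()]).
#' @return data.frame with columns \code{k} (degree) and \code{count}
#'   (number of nodes of that degree), ascending in k.
#' @export
degree_distribution <- function(edges) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(edges)))
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  deg <- igraph::degree(g)
  tab <- table(deg)
  data.frame(k = as.integer(names(tab)), count = as.integer(tab))
}

#' Least-squares power-law fit of a degree distribution
#'
#' Fits \code{log10(count) ~ log10(k)} over degrees with positive count.
#' A hierarchical (scale-free) network shows a negative slope, high
#' r-squared and a monotonically decaying node count; a flat "promiscuous"
#' topology breaks at least one of these (typically monotonicity: its
#' degree distribution rises to a mode before falling, which no power law
#' does). The fit is refused (with a diagnostic error) below 3 distinct
#' degrees, where log-log linearity is meaningless.
#'
#' @param dd data.frame from [degree_distribution()].
#' @return list with \code{slope}, \code{intercept}, \code{r2},
#'   \code{n_degrees}, \code{monotone_decreasing} (is the node count
#'   non-increasing in k?) and \code{power_law_like} (negative slope,
#'   r2 >= 0.8 and monotone decay).
#' @export
fit_power_law <- function(dd) {
  dd <- dd[dd$count > 0 & dd$k > 0, , drop = FALSE]
  if (nrow(dd) < 3)
    stop("power-law fit refused: fewer than 3 distinct degrees (",
         nrow(dd), " observed)")
  dd <- dd[order(dd$k), ]
  fit <- stats::lm(log10(count) ~ log10(k), data = dd)
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  # monotone decay is judged where counts are well populated (>= 5 nodes)
  # and up to counting noise (an uptick within ~2 sd of Poisson sampling
  # is not evidence of an interior mode); the sparse tail is ignored
  head_dd <- dd[dd$count >= 5, , drop = FALSE]
  nh <- nrow(head_dd)
  mono <- dd$count[1] == max(dd$count) &&
    (nh < 2 || all(diff(head_dd$count) <=
                     2 * sqrt(head_dd$count[-nh])))
  list(slope = slope, intercept = unname(coef(fit)[1]), r2 = r2,
       n_degrees = nrow(dd), monotone_decreasing = mono,
       power_law_like = slope < 0 && r2 >= 0.8 && mono)
}

#' Flat "promiscuous regulator" network (negative control topology)
#'
#' Artificial network of \code{n_sources} regulator nodes, each connected
#' to a uniform random number (in \code{degree_range}) of distinct targets
#' from a large pool. Such a network is not hierarchical: its degree
#' distribution is not log-log linear, in contrast to a
#' preferential-attachment network.
#'
#' @param n_sources number of regulator nodes (default 100).
#' @param n_targets size of the target pool (default 20000).
#' @param degree_range inclusive range of per-source out-degree
#'   (default c(300, 1000)).
#' @param seed RNG seed.
#' @return data.frame of edges (\code{gene_a}, \code{gene_b}).
#' @export
flat_network <- function(n_sources = 100L, n_targets = 20000L,
                         degree_range = c(300L, 1000L), seed = NULL) {
  with_seed(seed, {
    edges <- lapply(seq_len(n_sources), function(i) {
      d <- sample(degree_range[1]:degree_range[2], 1L)
      data.frame(gene_a = sprintf("src_%03d", i),
                 gene_b = sprintf("tgt_%05d", sample.int(n_targets, d)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, edges)
  })
}

#' Preferential-attachment network (scale-free positive control)
#'
#' @param n number of nodes.
#' @param m edges added per node (default 2).
#' @param seed RNG seed.
#' @return data.frame of edges (\code{gene_a}, \code{gene_b}).
#' @export
pa_network <- function(n = 1000L, m = 2L, seed = NULL) {
  with_seed(seed, {
    g <- igraph::sample_pa(n, m = m, directed = FALSE)
    el <- igraph::as_edgelist(g)
    data.frame(gene_a = sprintf("g_%05d", as.integer(el[, 1])),
               gene_b = sprintf("g_%05d", as.integer(el[, 2])),
               stringsAsFactors = FALSE)
  })
}
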