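#' Filter same-gene chimeras down to genuine cut-and-ligated evidence
#'
#' Intramolecular structure evidence comes from read pairs that (i) map to
#' a single gene, (ii) contain at least part of the linker, and (iii) do
#' not look like an ordinary continuous cDNA fragment. A continuous
#' fragment produces a convergent mate geometry: the two mates on opposite
#' genomic strands within \code{max_span} bp, with the plus-strand mate
#' upstream of the minus-strand mate. Pairs matching that geometry, pairs
#' without linker and pairs spanning two genes are dropped, each under its
#' own counter.
#'
#' @param pairs data.frame with columns \code{gene1}, \code{gene2}
#'   (assigned unit per side; equal for same-gene pairs), \code{has_linker}
#'   (logical), \code{strand1}, \code{strand2} (genomic strands of the two
#'   aligned mates/fragments), \code{start1}, \code{end1}, \code{start2},
#'   \code{end2} (genomic, 0-based half-open).
#' @param max_span window for the continuous-fragment geometry (default
#'   2000 bp).
#' @return the surviving rows, with drop counters in
#'   \code{attr(, "drops")} (\code{different_gene}, \code{no_linker},
#'   \code{continuous_fragment}).
#' @export
filter_intramolecular <- function(pairs, max_span = 2000L) {
  need <- c("gene1", "gene2", "has_linker", "strand1", "strand2",
            "start1", "end1", "start2", "end2")
  stopifnot(all(need %in% names(pairs)))
  diff_gene <- is.na(pairs$gene1) | is.na(pairs$gene2) |
    pairs$gene1 != pairs$gene2
  no_linker <- !diff_gene & !pairs$has_linker
  cand <- !diff_gene & pairs$has_linker
  # continuous-fragment geometry: convergent within max_span
  opp <- pairs$strand1 != pairs$strand2
  span <- pmax(pairs$end1, pairs$end2) - pmin(pairs$start1, pairs$start2)
  plus_start <- ifelse(pairs$strand1 == "+", pairs$start1, pairs$start2)
  minus_start <- ifelse(pairs$strand1 == "-", pairs$start1, pairs$start2)
  continuous <- cand & opp & span <= max_span & plus_start < minus_start
  keep <- cand & !continuous
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drops") <- list(different_gene = sum(diff_gene),
                             no_linker = sum(no_linker),
                             continuous_fragment = sum(continuous))
  out
}

#' Classify an intramolecular chimera into structural class I or II
#'
#' An intramolecular chimera carries two junction coordinates on its
#' transcript: \code{junction1}, the 3' terminus of the linker-upstream
#' fragment (RNA1), and \code{junction2}, the 5' terminus of the
#' linker-downstream fragment (RNA2). Comparing fragment order in the read
#' with transcript order gives exactly two classes: class I when RNA1 lies
#' 5' of RNA2 on the transcript (junction1 < junction2), class II when the
#' transcript's downstream segment appears first in the read
#' (junction1 > junction2). Identical junctions are ambiguous and dropped
#' (NA). Vectorised.
#'
#' @param junction1,junction2 integer vectors of 0-based transcript
#'   positions.
#' @return character vector \code{"I"}/\code{"II"}/\code{NA}.
#' @export
classify_structure <- function(junction1, junction2) {
  stopifnot(length(junction1) == length(junction2))
  ifelse(junction1 < junction2, "I",
         ifelse(junction1 > junction2, "II", NA_character_))
}

#' Build intramolecular junction pairs in transcript coordinates
#'
#' Converts filtered same-gene fragment pairs to transcript coordinates
#' (single-exon gene model: position minus gene start on the plus strand,
#' gene end minus position minus one on the minus strand) and derives
#' junctions and structural classes. Junction1 is the last base of RNA1,
#' junction2 the first base of RNA2, matching the linker ligation
#' chemistry (RNA1 3'-OH to linker 5', linker 3' to RNA2 5').
#'
#' @param pairs filtered data.frame from [filter_intramolecular()], plus a
#'   column \code{gene_strand} with each gene's strand.
#' @param gene_start,gene_end gene span per row (genomic, 0-based
#'   half-open).
#' @return data.frame with \code{gene_id}, fragment intervals
#'   (\code{frag1_start} .. \code{frag2_end}, transcript 0-based
#'   half-open), \code{junction1}, \code{junction2}, \code{class};
#'   ambiguous (equal-junction) rows are dropped and counted in
#'   \code{attr(, "n_ambiguous")}.
#' @export
intra_pairs <- function(pairs, gene_start, gene_end) {
  stopifnot("gene_strand" %in% names(pairs))
  to_tx <- function(s, e, strand, gs, ge) {
    # genomic [s, e) -> transcript [ts, te), flipping on the minus strand
    ts <- ifelse(strand == "+", s - gs, ge - e)
    te <- ifelse(strand == "+", e - gs, ge - s)
    list(ts = ts, te = te)
  }
  f1 <- to_tx(pairs$start1, pairs$end1, pairs$gene_strand, gene_start, gene_end)
  f2 <- to_tx(pairs$start2, pairs$end2, pairs$gene_strand, gene_start, gene_end)
  j1 <- f1$te - 1L   # last base of RNA1
  j2 <- f2$ts        # first base of RNA2
  cls <- classify_structure(j1, j2)
  out <- data.frame(gene_id = pairs$gene1,
                    frag1_start = f1$ts, frag1_end = f1$te,
                    frag2_start = f2$ts, frag2_end = f2$te,
                    junction1 = j1, junction2 = j2, class = cls,
                    stringsAsFactors = FALSE)
  amb <- is.na(cls)
  res <- out[!amb, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_ambiguous") <- sum(amb)
  res
}

#' RNase cut-density track of one transcript
#'
#' Every fragment terminus is a candidate RNase I cut; the track counts
#' termini per transcript position (+1 at each fragment's first and last
#' covered base), so single-stranded regions accumulate high density.
#' Total mass is exactly twice the number of fragments.
#'
#' @param starts,ends fragment intervals, 0-based half-open transcript
#'   coordinates.
#' @param length transcript length.
#' @param smooth_window optional moving-average window (odd, in nt) applied
#'   to the returned \code{smoothed} component only; raw counts are always
#'   returned.
#' @return list with \code{counts} (integer vector, one per position) and,
#'   when requested, \code{smoothed}.
#' @export
cut_density <- function(starts, ends, length, smooth_window = NULL) {
  stopifnot(all(starts >= 0), all(ends <= length), all(ends > starts))
  counts <- tabulate(c(starts + 1L, ends), nbins = length)
  out <- list(counts = counts)
  if (!is.null(smooth_window)) {
    w <- as.integer(smooth_window)
    stopifnot(w >= 1, w %% 2 == 1)
    kern <- rep(1 / w, w)
    out$smoothed <- as.numeric(stats::filter(counts, kern, sides = 2))
  }
  out
}

#' Ligation contact map of one transcript
#'
#' Symmetric binned matrix of ligation frequencies: each intramolecular
#' junction pair increments the cell (bin(junction1), bin(junction2)) and
#' its transpose, so the upper triangle (diagonal included) sums to the
#' number of pairs.
#'
#' @param junction1,junction2 0-based transcript positions.
#' @param length transcript length.
#' @param bin bin width in nt (>= 1).
#' @return list with \code{matrix} (ceiling(length/bin) square),
#'   \code{bin}, \code{n_pairs}.
#' @export
contact_map <- function(junction1, junction2, length, bin = 10L) {
  stopifnot(bin >= 1, length(junction1) == length(junction2))
  if (any(junction1 < 0 | junction1 >= length | junction2 < 0 |
          junction2 >= length))
    stop("junction outside transcript: coordinate bug upstream")
  nb <- as.integer(ceiling(length / bin))
  m <- matrix(0L, nb, nb)
  bi <- junction1 %/% bin + 1L
  bj <- junction2 %/% bin + 1L
  for (i in seq_along(bi)) {
    m[bi[i], bj[i]] <- m[bi[i], bj[i]] + 1L
    if (bi[i] != bj[i]) m[bj[i], bi[i]] <- m[bj[i], bi[i]] + 1L
  }
  list(matrix = m, bin = as.integer(bin), n_pairs = length(bi))
}

#' Cluster junction pairs into proximal site pairs
#'
#' Single-linkage clustering in (junction1, junction2) space: two events
#' are linked when both junction coordinates differ by at most \code{tol}
#' nt ("overlapping ligation positions"); connected components with at
#' least \code{min_support} members become proximal site pairs, windowed
#' by the min/max of their member junctions.
#'
#' @param junction1,junction2 0-based transcript positions.
#' @param min_support minimum supporting reads per pair (default 3).
#' @param tol linkage tolerance in nt (default 10).
#' @return data.frame with \code{window1_start}, \code{window1_end},
#'   \code{window2_start}, \code{window2_end} (inclusive junction
#'   coordinate ranges) and \code{support}.
#' @export
call_proximal_pairs <- function(junction1, junction2, min_support = 3L,
                                tol = 10L) {
  stopifnot(min_support >= 2, length(junction1) == length(junction2))
  empty <- data.frame(window1_start = integer(), window1_end = integer(),
                      window2_start = integer(), window2_end = integer(),
                      support = integer())
  n <- length(junction1)
  if (n == 0) return(empty)
  # single-linkage components over the "both junctions within tol" relation
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (i in seq_len(n - 1L)) {
    near <- which(abs(junction1[(i + 1L):n] - junction1[i]) <= tol &
                  abs(junction2[(i + 1L):n] - junction2[i]) <= tol) + i
    for (j in near) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) comp[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- lapply(split(seq_len(n), roots), function(idx) {
    if (length(idx) < min_support) return(NULL)
    data.frame(window1_start = min(junction1[idx]),
               window1_end = max(junction1[idx]),
               window2_start = min(junction2[idx]),
               window2_end = max(junction2[idx]),
               support = length(idx))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$window1_start, out$window2_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
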