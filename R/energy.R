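# Nearest-neighbour dG37 stack table (kcal/mol) over the six admissible
# pairs AU, UA, CG, GC, GU, UG. Watson-Crick/Watson-Crick entries are the
# published Turner/Xia 37C RNA stacking free energies; stacks involving one
# wobble pair are simplified to a flat -1.2, two wobble pairs to -0.5
# (documented simplification: published wobble stacks are sequence-dependent
# and include a few destabilising motifs this model flattens). The table
# satisfies the duplex rotation symmetry dG(x1x2/y1y2) = dG(y2y1/x2x1),
# which makes duplex_energy() symmetric in its arguments.
.pair_codes <- c("AU", "UA", "CG", "GC", "GU", "UG")

.stack_table <- local({
  m <- matrix(NA_real_, 6, 6, dimnames = list(.pair_codes, .pair_codes))
  wc <- rbind(
    # p1     p2     dG (stack 5'-x1 x2-3' / 3'-y1 y2-5')
    c("AU", "AU", -0.93), c("AU", "UA", -1.10), c("AU", "CG", -2.24),
    c("AU", "GC", -2.08), c("UA", "AU", -1.33), c("UA", "UA", -0.93),
    c("UA", "CG", -2.35), c("UA", "GC", -2.11), c("CG", "AU", -2.11),
    c("CG", "UA", -2.08), c("CG", "CG", -3.26), c("CG", "GC", -2.36),
    c("GC", "AU", -2.35), c("GC", "UA", -2.24), c("GC", "CG", -3.42),
    c("GC", "GC", -3.26))
  m[cbind(wc[, 1], wc[, 2])] <- as.numeric(wc[, 3])
  gu <- c("GU", "UG")
  for (p1 in .pair_codes) for (p2 in .pair_codes) {
    ngu <- (p1 %in% gu) + (p2 %in% gu)
    if (ngu == 1) m[p1, p2] <- -1.2
    if (ngu == 2) m[p1, p2] <- -0.5
  }
  m
})

.check_rna <- function(x) {
  if (any(!grepl("^[ACGUTacgut]*$", x)))
    stop("non-nucleotide characters in sequence")
  chartr("Tt", "Uu", toupper(x))
}

# One-sided Wilcoxon signed-rank test (x shifted below y), with the null
# distribution computed by exact sign-flip convolution over midranks.
# Duplex energies live on a 0.01 kcal/mol lattice, so tied |differences|
# are common; stats::wilcox.test falls back to a continuity-corrected
# normal approximation on ties, which is measurably conservative at these
# sample sizes, while the sign-flip distribution stays exact. Beyond 200
# informative pairs a tie-corrected normal approximation takes over.
.signrank_less <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(list(statistic = NA_real_, p_value = 1))
  r2 <- as.integer(round(2 * rank(abs(d))))   # doubled midranks: integers
  Wpos <- sum(r2[d > 0])                      # small when x sits below y
  if (m <= 200L) {
    # distribution of sum(b_i * r2_i), b_i ~ Bernoulli(1/2), by convolution
    probs <- numeric(sum(r2) + 1L)
    probs[1] <- 1
    for (r in r2) {
      shifted <- c(numeric(r), probs[seq_len(length(probs) - r)])
      probs <- 0.5 * (probs + shifted)
    }
    p <- sum(probs[seq_len(Wpos + 1L)])
  } else {
    mu <- sum(r2) / 2
    sigma <- sqrt(sum(r2^2) / 4)
    p <- stats::pnorm((Wpos - mu) / sigma)
  }
  list(statistic = Wpos / 2, p_value = min(1, p))
}

#' Intermolecular RNA duplex hybridization free energy
#'
#' Minimum free energy over all ungapped-stack duplex alignments of two RNA
#' sequences (antiparallel, no intramolecular pairing), scored by an
#' embedded nearest-neighbour dG37 stacking table over Watson-Crick and
#' G.U pairs. Interior unpaired bases between consecutive pairs are charged
#' a flat \code{loop_penalty} per nucleotide with the total interior loop
#' capped at \code{max_loop} nt; dangling ends are free and there is no
#' helix initiation term, so the empty duplex (0 kcal/mol) bounds the
#' result from above: any duplex admitting one stack has negative energy.
#' T is read as U; more negative means more stable. Deterministic.
#'
#' @param seq1,seq2 RNA/DNA strings (length >= 2), or equal-length vectors.
#' @param loop_penalty kcal/mol per interior unpaired base (default +0.5).
#' @param max_loop largest interior loop allowed between consecutive pairs
#'   (default 8 nt).
#' @return numeric vector of free energies (kcal/mol, <= 0).
#' @examples
#' duplex_energy("ACGUACGU", revcomp_rna("ACGUACGU"))
#' duplex_energy("AAAA", "AAAA") # 0: no duplex formed
#' @export
duplex_energy <- function(seq1, seq2, loop_penalty = 0.5, max_loop = 8L) {
  seq1 <- .check_rna(seq1); seq2 <- .check_rna(seq2)
  stopifnot(length(seq1) == length(seq2), all(nchar(seq1) >= 2),
            all(nchar(seq2) >= 2))
  cpp_duplex_energy_vec(seq1, seq2, .stack_table, loop_penalty,
                        as.integer(max_loop))
}

#' Reverse complement in RNA spelling
#' @param x character vector of RNA/DNA sequences.
#' @return character vector (A/C/G/U alphabet).
#' @export
revcomp_rna <- function(x) {
  chartr("T", "U", revcomp(chartr("U", "T", .check_rna(x))))
}

#' Shuffle a sequence preserving base composition
#'
#' Uniform mononucleotide permutation (Fisher-Yates) of each sequence;
#' seeded and reproducible. A dinucleotide-preserving mode is available via
#' \code{mode = "dinucleotide"} (random Eulerian-walk shuffle retaining
#' dinucleotide counts approximately through edge permutation with
#' restarts).
#'
#' @param seq character vector of sequences.
#' @param seed RNG seed (NULL = use current RNG state).
#' @param mode \code{"mononucleotide"} (default) or
#'   \code{"dinucleotide"}.
#' @return character vector of shuffled sequences.
#' @export
shuffle_control <- function(seq, seed = NULL, mode = "mononucleotide") {
  mode <- match.arg(mode, c("mononucleotide", "dinucleotide"))
  with_seed(seed, {
    vapply(seq, function(s) {
      ch <- strsplit(s, "")[[1]]
      if (length(ch) < 2) return(s)
      if (mode == "mononucleotide") return(paste(sample(ch), collapse = ""))
      # dinucleotide mode: shuffle interior via swap walk that preserves
      # dinucleotide counts (Altschul-Erickson style edge swaps)
      n <- length(ch)
      for (it in seq_len(10L * n)) {
        ij <- sort(sample(2:(n - 1L), 2L))
        i <- ij[1]; j <- ij[2]
        if (j - i < 2L) next   # adjacent swaps would rewrite the i..j dinucleotide
        ok <- ch[i - 1L] == ch[j - 1L] && ch[i + 1L] == ch[j + 1L]
        if (ok) { tmp <- ch[i]; ch[i] <- ch[j]; ch[j] <- tmp }
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Compare observed duplex energies against shuffled controls
#'
#' For each interaction, the observed hybridization energy is the mean
#' duplex energy over its ligated fragment pairs; the control repeats the
#' computation on shuffled fragments (\code{n_shuffles} per pair,
#' averaged). Because each interaction is matched with a control built
#' from its own fragments (same length and base composition), the samples
#' are paired: a one-sided Wilcoxon signed-rank test on the
#' per-interaction differences asks whether observed energies are more
#' negative (stronger pairing) than their matched controls. Under
#' within-pair exchangeability this test is exactly calibrated, which an
#' unpaired rank-sum test on these coupled samples is not.
#'
#' @param fragment_pairs data.frame with columns \code{interaction_id},
#'   \code{seq1}, \code{seq2} (>= 10 rows).
#' @param n_shuffles shuffles per fragment pair (default 1).
#' @param seed RNG seed for shuffling.
#' @param ... passed to [duplex_energy()].
#' @return list with \code{observed}, \code{control} (named per-interaction
#'   mean energies), \code{statistic}, \code{p_value}, \code{n_shuffles},
#'   \code{seed}, \code{degenerate}.
#' @export
compare_energy <- function(fragment_pairs, n_shuffles = 1L, seed = NULL, ...) {
  stopifnot(all(c("interaction_id", "seq1", "seq2") %in% names(fragment_pairs)))
  if (nrow(fragment_pairs) < 10)
    stop("need at least 10 fragment pairs")
  obs_e <- duplex_energy(fragment_pairs$seq1, fragment_pairs$seq2, ...)
  ctl_e <- with_seed(seed, {
    reps <- vapply(seq_len(n_shuffles), function(k) {
      duplex_energy(shuffle_control(fragment_pairs$seq1),
                    shuffle_control(fragment_pairs$seq2), ...)
    }, numeric(nrow(fragment_pairs)))
    rowMeans(matrix(reps, nrow = nrow(fragment_pairs)))
  })
  observed <- tapply(obs_e, fragment_pairs$interaction_id, mean)
  control <- tapply(ctl_e, fragment_pairs$interaction_id, mean)
  degenerate <- length(unique(c(observed, control))) == 1L
  if (degenerate) {
    warning("degenerate energy comparison: all values identical; p = 1")
    stat <- NA_real_; p <- 1
  } else {
    sr <- .signrank_less(as.numeric(observed), as.numeric(control))
    stat <- sr$statistic; p <- sr$p_value
  }
  list(observed = observed, control = control, statistic = stat,
       p_value = p, n_shuffles = n_shuffles, seed = seed,
       degenerate = degenerate)
}
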