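#' Evaluate an expression under a temporary RNG state
#'
#' Runs \code{expr} with the RNG seeded at \code{seed} and restores the
#' caller's RNG state afterwards, so library code never perturbs user
#' randomness. A \code{NULL} seed evaluates the expression as-is.
#'
#' @param seed integer seed or \code{NULL}.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# pairwise Hamming distance of two equal-length strings
hamming <- function(a, b) {
  d <- cpp_hamming(a, b)
  if (anyNA(d)) stop("hamming(): sequences of unequal length")
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
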