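# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# exhaustive ungapped linker scan: returns best (start, end, mismatches) or
# NULL, same admissibility and tie rules as the contract
oracle_find_linker <- function(seq, linker, min_overlap = 6, rate = 0.1,
                               partial = TRUE) {
  n <- nchar(seq); L <- nchar(linker)
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  cands <- list()
  add <- function(s, e, m) cands[[length(cands) + 1L]] <<- c(s, e, m)
  if (n >= L) {
    for (o in 0:(n - L)) {
      m <- ham(substr(seq, o + 1, o + L), linker)
      if (m <= floor(rate * L)) add(o, o + L, m)
    }
  } else if (n >= min_overlap) {
    for (o in 0:(L - n)) {
      m <- ham(seq, substr(linker, o + 1, o + n))
      if (m <= floor(rate * n)) add(0, n, m)
    }
  }
  if (partial) {
    for (o in min_overlap:min(n, L - 1)) {
      m <- ham(substr(seq, n - o + 1, n), substr(linker, 1, o))
      if (m <= floor(rate * o)) add(n - o, n, m)
      m <- ham(substr(seq, 1, o), substr(linker, L - o + 1, L))
      if (m <= floor(rate * o)) add(0, o, m)
    }
  }
  if (!length(cands)) return(NULL)
  tab <- do.call(rbind, cands)
  score <- (tab[, 2] - tab[, 1]) - tab[, 3]
  len <- tab[, 2] - tab[, 1]
  best <- order(-score, -len, tab[, 1])[1]
  list(start = tab[best, 1], end = tab[best, 2], mismatches = tab[best, 3])
}

# one-sided Fisher p by direct combinatorial tail summation
oracle_fisher_tail <- function(a, n_a, n_b, N) {
  xs <- max(0, n_a + n_b - N):min(n_a, n_b)
  lp <- lchoose(n_a, xs) + lchoose(N - n_a, n_b - xs) - lchoose(N, n_b)
  sum(exp(lp[xs >= a]))
}

# independent BH step-up implementation
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# brute-force minimum duplex energy by enumeration of all antiparallel
# monotone pairings under the same scoring scheme
oracle_duplex <- function(s, t, loop_penalty = 0.5, max_loop = 8) {
  stack <- chimeramap:::.stack_table
  code <- function(x, y) {
    p <- paste0(x, y)
    if (p %in% rownames(stack)) p else NA_character_
  }
  s <- strsplit(chartr("T", "U", s), "")[[1]]
  t <- strsplit(chartr("T", "U", t), "")[[1]]
  n <- length(s); m <- length(t)
  best <- 0
  rec <- function(i0, j0, e) {
    if (e < best) best <<- e
    if (i0 >= n || j0 <= 1) return()
    for (i in (i0 + 1):n) {
      gi <- i - i0 - 1
      if (gi > max_loop) break
      for (j in (j0 - 1):1) {
        gj <- j0 - j - 1
        if (gi + gj > max_loop) break
        p2 <- code(s[i], t[j])
        if (is.na(p2)) next
        p1 <- code(s[i0], t[j0])
        cost <- if (gi == 0 && gj == 0) stack[p1, p2] else
          loop_penalty * (gi + gj)
        rec(i, j, e + cost)
      }
    }
  }
  for (i in 1:n) for (j in m:1) {
    if (!is.na(code(s[i], t[j]))) rec(i, j, 0)
  }
  best
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
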