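#' Build a k-mer seed index over a toy genome
#'
#' Fixture-scale exact/near-exact aligner support: every k-mer of the
#' forward strand of each reference is recorded with its position. Queries
#' seed from the fragment (and its reverse complement) and verify ungapped.
#'
#' @param genome named character vector or \code{DNAStringSet} of reference
#'   sequences.
#' @param k seed length (default 15).
#' @return object of class \code{"genome_index"}.
#' @export
genome_index <- function(genome, k = 15L) {
  if (is(genome, "DNAStringSet")) genome <- setNames(as.character(genome), names(genome))
  stopifnot(is.character(genome), !is.null(names(genome)))
  k <- as.integer(k)
  kms <- character(0); pos <- integer(0); chr <- integer(0)
  for (ci in seq_along(genome)) {
    s <- genome[[ci]]
    L <- nchar(s)
    if (L < k) next
    st <- seq_len(L - k + 1L)
    kms <- c(kms, substring(s, st, st + k - 1L))
    pos <- c(pos, st)
    chr <- c(chr, rep.int(ci, length(st)))
  }
  ukm <- unique(kms)
  id <- match(kms, ukm)
  o <- order(id)
  structure(list(k = k, seqs = genome, seqnames = names(genome),
                 lengths = nchar(genome),
                 ukm = ukm,
                 pos = pos[o], chr = chr[o],
                 grp_start = c(1L, cumsum(tabulate(id, length(ukm))) + 1L)),
            class = "genome_index")
}

#' Align fragments to a toy genome by seed-and-verify
#'
#' Best ungapped locus (at most \code{max_mismatch} substitutions) on either
#' strand for each fragment. A fragment is \code{unique} only when exactly
#' one locus attains the best score; fragments shorter than the seed length
#' are unmapped. Intended for simulator-scale genomes, not as a real-data
#' aligner.
#'
#' @param frags character vector of fragment sequences.
#' @param index a [genome_index()].
#' @param max_mismatch maximum substitutions in a reported locus (default 2).
#' @return data.frame with columns \code{status} (\code{mapped},
#'   \code{ambiguous}, \code{unmapped}), \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{strand}, \code{mismatches},
#'   \code{unique}.
#' @export
toy_align <- function(frags, index, max_mismatch = 2L) {
  stopifnot(inherits(index, "genome_index"))
  k <- index$k
  n <- length(frags)
  out <- data.frame(status = rep("unmapped", n), chrom = NA_character_,
                    start = NA_integer_, end = NA_integer_,
                    strand = NA_character_, mismatches = NA_integer_,
                    unique = FALSE, stringsAsFactors = FALSE)
  if (n == 0) return(out)
  lens <- nchar(frags)
  eligible <- which(lens >= k)
  if (!length(eligible)) return(out)
  rc <- revcomp(frags[eligible])

  # gather seeds: offsets 0, k, 2k (fragment-local, both orientations)
  seed_tab <- list()
  for (ori in c("+", "-")) {
    qseq <- if (ori == "+") frags[eligible] else rc
    for (off in c(0L, k, 2L * k)) {
      ok <- which(lens[eligible] >= off + k)
      if (!length(ok)) next
      seed_tab[[length(seed_tab) + 1L]] <- data.frame(
        fi = eligible[ok], ori = ori, off = off,
        seed = substr(qseq[ok], off + 1L, off + k),
        stringsAsFactors = FALSE)
    }
  }
  seeds <- do.call(rbind, seed_tab)
  sid <- match(seeds$seed, index$ukm)
  hit <- which(!is.na(sid))
  # expand seed hits into candidate loci (chrom, 1-based locus start, ori)
  cand <- vector("list", length(hit))
  for (hh in seq_along(hit)) {
    i <- hit[hh]
    g <- sid[i]
    rows <- index$grp_start[g]:(index$grp_start[g + 1L] - 1L)
    cand[[hh]] <- data.frame(fi = seeds$fi[i], ori = seeds$ori[i],
                             chr = index$chr[rows],
                             locstart = index$pos[rows] - seeds$off[i],
                             stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(out)
  cand <- unique(do.call(rbind, cand))
  cand <- cand[cand$locstart >= 1L, , drop = FALSE]
  flen <- lens[cand$fi]
  cand <- cand[cand$locstart + flen - 1L <= index$lengths[cand$chr], , drop = FALSE]
  if (!nrow(cand)) return(out)

  # verify: count mismatches of the (oriented) fragment vs the locus
  flen <- lens[cand$fi]
  ref <- substring(index$seqs[cand$chr], cand$locstart, cand$locstart + flen - 1L)
  qry <- ifelse(cand$ori == "+", frags[cand$fi],
                revcomp(frags[cand$fi]))
  mm <- cpp_hamming(qry, ref)
  keep <- !is.na(mm) & mm <= max_mismatch
  cand <- cand[keep, , drop = FALSE]; mm <- mm[keep]
  if (!nrow(cand)) return(out)

  o <- order(cand$fi, mm)
  cand <- cand[o, , drop = FALSE]; mm <- mm[o]
  first <- !duplicated(cand$fi)
  bestrow <- which(first)
  nxt <- c(bestrow[-1L] - 1L, nrow(cand))
  for (b in seq_along(bestrow)) {
    r <- bestrow[b]
    fi <- cand$fi[r]
    # second-best must be strictly worse for a unique call
    tie <- nxt[b] > r && mm[r + 1L] == mm[r]
    out$status[fi] <- if (tie) "ambiguous" else "mapped"
    if (!tie) {
      out$chrom[fi] <- index$seqnames[cand$chr[r]]
      out$start[fi] <- cand$locstart[r] - 1L
      out$end[fi] <- cand$locstart[r] - 1L + lens[fi]
      out$strand[fi] <- cand$ori[r]
      out$mismatches[fi] <- mm[r]
      out$unique[fi] <- TRUE
    }
  }
  out
}

#' Assign uniquely mapped fragments to genes, repeats or novel loci
#'
#' Strand-aware assignment: a fragment belongs to the same-strand gene
#' covering at least \code{min_overlap_frac} of its length; if two genes
#' both qualify the fragment is \code{ambiguous} (dropped downstream with a
#' counter). Fragments matching no gene fall back to same-strand repeat
#' elements (labelled \code{repeat:<family>}, biotype
#' \code{transposonRNA}), and finally to novel loci built by strand-aware
#' merging of the remaining fragments (gap <= \code{novel_gap}); novel ids
#' follow sorted genomic order, so assignment is independent of input
#' order.
#'
#' @param frags \code{GRanges} of uniquely mapped fragments.
#' @param genes \code{GRanges} with metadata columns \code{gene_id} and
#'   \code{biotype}.
#' @param repeats optional \code{GRanges} with metadata column
#'   \code{family}.
#' @param min_overlap_frac minimum fraction of the fragment covered
#'   (default 0.5).
#' @param novel_gap merge gap for novel loci (default 100).
#' @return data.frame with columns \code{unit} (gene id, \code{repeat:<fam>},
#'   \code{novel_<k>} or \code{NA}), \code{biotype}, \code{ambiguous}.
#' @export
assign_genes <- function(frags, genes, repeats = NULL, min_overlap_frac = 0.5,
                         novel_gap = 100L) {
  stopifnot(is(frags, "GRanges"), is(genes, "GRanges"))
  n <- length(frags)
  unit <- rep(NA_character_, n)
  biotype <- rep(NA_character_, n)
  ambiguous <- rep(FALSE, n)

  ov <- GenomicRanges::findOverlaps(frags, genes)
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    same <- as.character(GenomicRanges::strand(frags))[qh] ==
      as.character(GenomicRanges::strand(genes))[sh]
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(frags)[qh], GenomicRanges::ranges(genes)[sh]))
    frac <- w / GenomicRanges::width(frags)[qh]
    keep <- same & frac >= min_overlap_frac
    qh <- qh[keep]; sh <- sh[keep]
    nhit <- tabulate(qh, n)
    one <- which(nhit == 1L)
    idx <- match(one, qh)
    unit[one] <- genes$gene_id[sh[idx]]
    biotype[one] <- genes$biotype[sh[idx]]
    ambiguous[nhit >= 2L] <- TRUE
  }

  rest <- which(is.na(unit) & !ambiguous)
  if (length(rest) && !is.null(repeats) && length(repeats)) {
    ov <- GenomicRanges::findOverlaps(frags[rest], repeats)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      same <- as.character(GenomicRanges::strand(frags[rest]))[qh] ==
        as.character(GenomicRanges::strand(repeats))[sh]
      w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(frags[rest])[qh], GenomicRanges::ranges(repeats)[sh]))
      frac <- w / GenomicRanges::width(frags[rest])[qh]
      keep <- same & frac >= min_overlap_frac
      qh <- qh[keep]; sh <- sh[keep]; frac <- frac[keep]
      if (length(qh)) {
        # best-overlap repeat wins; family ties resolved by overlap then order
        o <- order(qh, -frac)
        qh <- qh[o]; sh <- sh[o]
        first <- !duplicated(qh)
        unit[rest[qh[first]]] <- paste0("repeat:", repeats$family[sh[first]])
        biotype[rest[qh[first]]] <- "transposonRNA"
      }
    }
  }

  rest <- which(is.na(unit) & !ambiguous)
  if (length(rest)) {
    nf <- frags[rest]
    merged <- GenomicRanges::reduce(nf, min.gapwidth = novel_gap + 1L)
    merged <- GenomicRanges::sort(merged)
    hit <- GenomicRanges::findOverlaps(nf, merged, select = "first")
    unit[rest] <- sprintf("novel_%04d", hit)
    biotype[rest] <- "novel"
  }
  data.frame(unit = unit, biotype = biotype, ambiguous = ambiguous,
             stringsAsFactors = FALSE)
}

#' Estimate the random-ligation rate from a cross-species mixture
#'
#' In a mixed-lysate control, chimeras joining fragments of two different
#' species can only arise from random (non-complex) ligation. The raw
#' inter-species fraction undercounts the random-ligation rate because a
#' random pair lands on two species only with probability
#' \code{2 p (1 - p)} (p = species-1 endpoint share); the corrected
#' estimate divides by that factor and is reported separately (the raw
#' fraction, conservative by construction, is the headline number).
#'
#' @param species1,species2 character vectors: species tag of each
#'   chimera's two fragments (uniquely mapped pairs only).
#' @param conf.level confidence level for the Wilson interval.
#' @return list with \code{fraction}, \code{ci} (Wilson), \code{n_inter},
#'   \code{n} (eligible pairs), \code{p_species1}, \code{correction_factor}
#'   and \code{corrected}.
#' @export
estimate_random_ligation <- function(species1, species2, conf.level = 0.95) {
  stopifnot(length(species1) == length(species2))
  ok <- !is.na(species1) & !is.na(species2)
  species1 <- species1[ok]; species2 <- species2[ok]
  n <- length(species1)
  if (n < 1) stop("no eligible chimeric pairs")
  inter <- species1 != species2
  x <- sum(inter)
  ci <- stats::prop.test(x, n, conf.level = conf.level, correct = FALSE)$conf.int
  tags <- sort(unique(c(species1, species2)))
  p1 <- mean(c(species1, species2) == tags[1])
  fac <- if (length(tags) >= 2 && p1 > 0 && p1 < 1) 1 / (2 * p1 * (1 - p1)) else NA_real_
  list(fraction = x / n, ci = as.numeric(ci), n_inter = x, n = n,
       p_species1 = p1, correction_factor = fac,
       corrected = if (is.na(fac)) NA_real_ else fac * x / n)
}
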