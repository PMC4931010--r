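#' Read a per-base score track (bedGraph) into gap-aware vectors
#'
#' Positions not covered by any bedGraph record stay \code{NA} (absent),
#' never zero: downstream means exclude them with a counter.
#'
#' @param file bedGraph path.
#' @param chrom_lengths named integer vector of reference lengths.
#' @return named list of numeric vectors (one per chromosome, NA = absent).
#' @export
read_score_track <- function(file, chrom_lengths) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  track <- lapply(chrom_lengths, function(L) rep(NA_real_, L))
  for (chrom in unique(as.character(GenomicRanges::seqnames(gr)))) {
    if (!chrom %in% names(track))
      stop("bedGraph chromosome not in reference: ", chrom)
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    for (i in seq_along(sub)) {
      s <- GenomicRanges::start(sub)[i]; e <- GenomicRanges::end(sub)[i]
      track[[chrom]][s:e] <- sub$score[i]
    }
  }
  track
}

#' Write a per-position track as bedGraph
#'
#' Runs of equal non-NA values become records; NA positions are omitted.
#'
#' @param track named list of numeric vectors (NA = absent).
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_score_track <- function(track, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (chrom in names(track)) {
    v <- track[[chrom]]
    r <- rle(ifelse(is.na(v), NA_real_, v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- !is.na(r$values)
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", chrom, starts[keep] - 1L,
                         ends[keep], r$values[keep]), con)
  }
  invisible(file)
}

#' Conservation metaprofile around ligation junctions
#'
#' Averages a per-base conservation score over windows of width \code{W}
#' centred at each ligation junction (relative positions \code{-W/2} to
#' \code{W/2 - 1}), against a control of the same number of random genomic
#' windows of the same width. Positions absent from the track, or falling
#' off a chromosome end, are excluded from the means and counted.
#'
#' @param junctions data.frame with columns \code{chrom}, \code{pos}
#'   (0-based genomic junction positions).
#' @param track score track from [read_score_track()] (named list of
#'   per-chromosome numeric vectors, NA = absent).
#' @param W window width (default 1000, even).
#' @param n_controls number of random control windows (default: one per
#'   junction).
#' @param seed RNG seed for control placement.
#' @return list with \code{position} (relative coordinates),
#'   \code{observed}, \code{control} (mean score per relative position),
#'   \code{n_junctions}, \code{n_missing} (score values unavailable across
#'   all observed windows).
#' @export
conservation_profile <- function(junctions, track, W = 1000L,
                                 n_controls = NULL, seed = NULL) {
  stopifnot(all(c("chrom", "pos") %in% names(junctions)))
  if (nrow(junctions) == 0) stop("no junctions supplied")
  W <- as.integer(W)
  stopifnot(W >= 2, W %% 2 == 0)
  half <- W %/% 2L
  rel <- seq.int(-half, half - 1L)

  window_scores <- function(chrom, pos) {
    v <- track[[chrom]]
    if (is.null(v)) return(rep(NA_real_, W))
    idx <- pos + rel + 1L   # 1-based vector indices
    ok <- idx >= 1L & idx <= length(v)
    out <- rep(NA_real_, W)
    out[ok] <- v[idx[ok]]
    out
  }

  obs <- mapply(window_scores, junctions$chrom, junctions$pos)
  n_controls <- n_controls %||% nrow(junctions)
  ctl <- with_seed(seed, {
    chroms <- names(track)
    lens <- vapply(track, length, integer(1))
    ci <- sample(seq_along(chroms), n_controls, replace = TRUE,
                 prob = lens / sum(lens))
    cpos <- vapply(ci, function(i) {
      as.integer(sample.int(max(lens[i] - W, 1L), 1L)) + half
    }, integer(1))
    mapply(window_scores, chroms[ci], cpos)
  })
  list(position = rel,
       observed = rowMeans(obs, na.rm = TRUE),
       control = rowMeans(ctl, na.rm = TRUE),
       n_junctions = nrow(junctions),
       n_missing = sum(is.na(obs)))
}
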