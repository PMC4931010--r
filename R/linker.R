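#' The published biotinylated RNA linker used in proximity ligation, DNA form
#'
#' 24-nt linker oligo ligated between interacting RNA fragments; its DNA
#' spelling is the sequence observed in sequencing reads.
#' @export
PROXIMITY_LINKER <- "CTAGTAGCCCATGCAATGCGAGGA"

#' Locate the linker inside a read sequence
#'
#' Ungapped scan for the best-scoring occurrence of the full linker inside
#' \code{seq}, or of a linker prefix at the 3' end of \code{seq} / linker
#' suffix at its 5' end (the read running off the linker), with overlap at
#' least \code{min_overlap}. A candidate is admissible when its mismatch
#' count is at most \code{floor(max_mismatch_rate * matched_length)}; the
#' best candidate maximises matched length minus mismatches, ties broken by
#' longer match then smaller start.
#'
#' @param seq DNA string to scan.
#' @param linker linker sequence (default [PROXIMITY_LINKER]).
#' @param min_overlap minimum matched length for partial (prefix/suffix)
#'   matches; default 6.
#' @param max_mismatch_rate mismatch budget per matched base; default 0.1.
#' @param ends which partial matches to consider: \code{"both"},
#'   \code{"prefix"} (linker prefix at read 3' end), \code{"suffix"}, or
#'   \code{"none"} (full-linker occurrences only).
#' @return \code{NULL} when no admissible match exists, else a list with
#'   \code{start}, \code{end} (0-based half-open offsets in \code{seq}),
#'   \code{mismatches}, \code{kind} (\code{"internal"}, \code{"prefix"},
#'   \code{"suffix"} or \code{"full"}) and \code{n_disjoint} (number of
#'   disjoint full-linker occurrences; >= 2 marks a multi-linker read).
#' @examples
#' find_linker(paste0(strrep("A", 20), PROXIMITY_LINKER, strrep("G", 20)))
#' @export
find_linker <- function(seq, linker = PROXIMITY_LINKER, min_overlap = 6L,
                        max_mismatch_rate = 0.1, ends = "both") {
  stopifnot(nchar(linker) > 0, min_overlap >= 4)
  ends <- match.arg(ends, c("both", "prefix", "suffix", "none"))
  hit <- cpp_find_linker(seq, linker, as.integer(min_overlap), max_mismatch_rate,
                         ends %in% c("both", "prefix"),
                         ends %in% c("both", "suffix"))
  if (!hit$found) return(NULL)
  hit$kind <- c("internal", "prefix", "suffix", "full")[hit$kind]
  hit$found <- NULL
  hit
}

#' Split demultiplexed read pairs at the linker into chimeric fragments
#'
#' Reconstructs each insert from the read-1 payload (insert sense strand)
#' and the reverse-complemented read 2. Mates overlapping by at least
#' \code{merge_min} bases (mismatch fraction <= \code{merge_max_mismatch_rate})
#' are merged into the complete insert, in which only full-linker
#' occurrences are searched; unmerged mates are scanned separately, allowing
#' a partial linker at the gap-facing ends. Bases 5' of the linker become
#' RNA1, bases 3' of it RNA2; fragments shorter than \code{min_frag} are set
#' empty (counted in the attribute \code{n_short_dropped}). Reads with two
#' disjoint full-linker occurrences are categorised \code{ambiguous}.
#'
#' @param payload1 character vector: read-1 sequence after the barcode
#'   layout (insert sense strand).
#' @param read2 character vector: raw read-2 sequences (reverse strand).
#' @param linker linker sequence.
#' @param min_overlap,max_mismatch_rate linker matching parameters, see
#'   [find_linker()].
#' @param merge_min minimum mate overlap for merging (default 10).
#' @param merge_max_mismatch_rate mismatch tolerance in the mate overlap.
#' @param min_frag minimum fragment length to keep (default 15).
#' @return data.frame with columns \code{category} (\code{chimeric},
#'   \code{linker_rna2}, \code{rna1_linker}, \code{linker_only},
#'   \code{no_linker}, \code{ambiguous}), \code{rna1}, \code{rna2},
#'   \code{merged}, \code{linker_start}, \code{linker_end}; the number of
#'   sub-minimum fragments blanked is in \code{attr(, "n_short_dropped")}.
#' @export
split_read_pairs <- function(payload1, read2, linker = PROXIMITY_LINKER,
                             min_overlap = 6L, max_mismatch_rate = 0.1,
                             merge_min = 10L, merge_max_mismatch_rate = 0.1,
                             min_frag = 15L) {
  stopifnot(length(payload1) == length(read2))
  if (length(payload1) == 0) {
    return(data.frame(category = character(), rna1 = character(),
                      rna2 = character(), merged = logical(),
                      linker_start = integer(), linker_end = integer(),
                      stringsAsFactors = FALSE))
  }
  read2rc <- revcomp(read2)
  res <- cpp_parse_pairs(payload1, read2rc, linker, as.integer(min_overlap),
                         max_mismatch_rate, as.integer(merge_min),
                         merge_max_mismatch_rate, as.integer(min_frag))
  # count fragments blanked for being shorter than min_frag
  res0 <- cpp_parse_pairs(payload1, read2rc, linker, as.integer(min_overlap),
                          max_mismatch_rate, as.integer(merge_min),
                          merge_max_mismatch_rate, 1L)
  n_short <- sum(nzchar(res0$rna1) & !nzchar(res$rna1)) +
    sum(nzchar(res0$rna2) & !nzchar(res$rna2))
  attr(res, "n_short_dropped") <- n_short
  res
}

#' Parse a raw paired-end chimeric library
#'
#' Full read-level parsing: PCR-duplicate removal (exact read-pair
#' identity), sample demultiplexing and UMI extraction per the barcode
#' layout, and linker splitting of each surviving pair. This is pipeline
#' front half "removing PCR duplicates" through "parsing the chimeric
#' cDNAs".
#'
#' @param read1,read2 character vectors of raw mate sequences.
#' @param ids read identifiers (default \code{read_1..n}).
#' @param layout a [barcode_layout()].
#' @param linker linker sequence.
#' @param max_mismatch barcode mismatch budget for [demultiplex()].
#' @param dedup drop exact PCR duplicates first (default TRUE).
#' @param ... linker/merge/fragment options passed to [split_read_pairs()].
#' @return list with \code{chimeras} (data.frame: read_id, sample_id, umi,
#'   category, rna1, rna2, merged), \code{counts} (category counts by
#'   sample) and \code{report} (read-accounting list: input, duplicates,
#'   undetermined, short fragments dropped).
#' @export
parse_chimeras <- function(read1, read2, ids = NULL, layout = barcode_layout(),
                           linker = PROXIMITY_LINKER, max_mismatch = 1L,
                           dedup = TRUE, ...) {
  stopifnot(length(read1) == length(read2))
  n_input <- length(read1)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_len(n_input))
  dd <- if (dedup) dedup_read_pairs(read1, read2) else
    list(keep = rep(TRUE, n_input), n_duplicates = 0L)
  read1 <- read1[dd$keep]; read2 <- read2[dd$keep]; ids <- ids[dd$keep]
  dm <- demultiplex(read1, layout, max_mismatch = max_mismatch)
  det <- dm$sample_id != "undetermined"
  payload <- substr(read1[det], layout$width + 1L, nchar(read1[det]))
  sp <- split_read_pairs(payload, read2[det], linker = linker, ...)
  chim <- data.frame(read_id = ids[det], sample_id = dm$sample_id[det],
                     umi = dm$umi[det], category = sp$category,
                     rna1 = sp$rna1, rna2 = sp$rna2, merged = sp$merged,
                     stringsAsFactors = FALSE)
  counts <- as.data.frame(table(sample = chim$sample_id,
                                category = chim$category),
                          stringsAsFactors = FALSE)
  list(chimeras = chim, counts = counts,
       report = list(n_input = n_input,
                     n_duplicates = dd$n_duplicates,
                     n_unique = sum(dd$keep),
                     n_undetermined = sum(!det),
                     n_parsed = nrow(chim),
                     n_short_dropped = attr(sp, "n_short_dropped")))
}
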