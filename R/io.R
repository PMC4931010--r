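#' Read a FASTQ file
#'
#' @param file path (plain or gzip).
#' @return list with \code{ids} and \code{seqs} (character vectors).
#' @export
read_fastq <- function(file) {
  x <- Biostrings::readDNAStringSet(file, format = "fastq")
  list(ids = sub("\\s.*$", "", names(x)), seqs = unname(as.character(x)))
}

#' Write a FASTQ file (constant qualities)
#'
#' @param seqs,ids character vectors.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_fastq <- function(seqs, ids, file) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, file, format = "fastq", qualities = q)
  invisible(file)
}

#' Read/write a FASTA reference
#' @param file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, file) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' Write gene models as GTF
#'
#' One \code{gene} record per gene with \code{gene_id} and
#' \code{gene_biotype} attributes; GTF's 1-based inclusive coordinates come
#' straight from the \code{GRanges} representation.
#'
#' @param genes \code{GRanges} with \code{gene_id} and \code{biotype}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_gtf <- function(genes, file) {
  gr <- genes
  S4Vectors::mcols(gr) <- NULL
  gr$source <- "chimeramap"
  gr$type <- "gene"
  gr$gene_id <- genes$gene_id
  gr$gene_biotype <- genes$biotype
  rtracklayer::export(gr, file, format = "gtf")
  invisible(file)
}

#' Read gene models from GTF
#'
#' @param file GTF path; \code{gene} records (or all records when none are
#'   typed \code{gene}) with \code{gene_id} and \code{gene_biotype}
#'   attributes.
#' @return \code{GRanges} with metadata columns \code{gene_id},
#'   \code{biotype}.
#' @export
read_gtf <- function(file) {
  gr <- rtracklayer::import(file, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr)) && any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                GenomicRanges::ranges(gr),
                                strand = GenomicRanges::strand(gr))
  out$gene_id <- gr$gene_id
  out$biotype <- if ("gene_biotype" %in% names(S4Vectors::mcols(gr)))
    gr$gene_biotype else NA_character_
  out
}

#' Write chimera fragment loci as BEDPE
#'
#' One record per chimera: both fragment loci (0-based half-open), read id,
#' score 0, both strands, then sample and UMI as extra columns.
#'
#' @param df data.frame with columns \code{chrom1}, \code{start1},
#'   \code{end1}, \code{chrom2}, \code{start2}, \code{end2}, \code{name},
#'   \code{strand1}, \code{strand2}, \code{sample}, \code{umi}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_bedpe <- function(df, file) {
  out <- data.frame(df$chrom1, df$start1, df$end1, df$chrom2, df$start2,
                    df$end2, df$name, 0L, df$strand1, df$strand2,
                    df$sample, df$umi)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_bedpe
#' @export
read_bedpe <- function(file) {
  df <- utils::read.table(file, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                 "name", "score", "strand1", "strand2", "sample", "umi")[seq_along(df)]
  df
}

# TSV convenience writers used by the pipeline
write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

read_tsv <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
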