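# transcript-coordinate projection of genomic fragment intervals
# (single-exon gene models; genomic and transcript coords 0-based half-open)
.project_tx <- function(gstart, gend, gene_start0, gene_end0, gene_strand) {
  ts <- ifelse(gene_strand == "+", gstart - gene_start0, gene_end0 - gend)
  te <- ifelse(gene_strand == "+", gend - gene_start0, gene_end0 - gstart)
  list(start = as.integer(ts), end = as.integer(te))
}

#' Run the full chimera analysis pipeline
#'
#' End-to-end orchestration in the published stage order: (1) PCR-duplicate
#' removal, (2) sample demultiplexing, (3-4) insert reconstruction and
#' chimeric cDNA parsing, (5) fragment mapping (built-in seed aligner),
#' (6) gene assignment and interaction calling, (7) interaction sites, plus
#' the intramolecular structure branch (filters, junction pairs, proximal
#' site pairs, cut-density tracks). Every read dropped at any stage is
#' attributed to exactly one documented reason in the run report.
#'
#' @param fastq1,fastq2 paths to the paired FASTQ files.
#' @param genome_fasta reference FASTA path.
#' @param annotation_gtf gene-model GTF path (gene_id, gene_biotype).
#' @param out_dir output directory (created if absent).
#' @param layout a [barcode_layout()].
#' @param linker linker sequence.
#' @param opts named list overriding stage defaults: \code{max_mismatch}
#'   (demultiplex, 1), \code{min_overlap} (6), \code{max_mismatch_rate}
#'   (0.1), \code{merge_min} (10), \code{min_frag} (15), \code{align_k}
#'   (15), \code{align_max_mismatch} (2), \code{min_overlap_frac} (0.5),
#'   \code{min_pair_count} (2), \code{fdr} (0.05), \code{min_site_support}
#'   (5), \code{site_max_gap} (10), \code{min_site_width} (10),
#'   \code{intra_max_span} (2000), \code{proximal_min_support} (3),
#'   \code{proximal_tol} (10), \code{contact_bin} (10).
#' @param seed RNG seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return Invisibly, a list with the stage outputs (\code{chimeras},
#'   \code{assignments}, \code{interactions}, \code{sites},
#'   \code{intra}, \code{proximal}, \code{report}); TSV/BEDPE/JSON files
#'   are written under \code{out_dir}.
#' @export
run_pipeline <- function(fastq1, fastq2, genome_fasta, annotation_gtf,
                         out_dir, layout = barcode_layout(),
                         linker = PROXIMITY_LINKER, opts = list(), seed = 1L) {
  defaults <- list(max_mismatch = 1L, min_overlap = 6L, max_mismatch_rate = 0.1,
                   merge_min = 10L, min_frag = 15L, align_k = 15L,
                   align_max_mismatch = 2L, min_overlap_frac = 0.5,
                   min_pair_count = 2L, fdr = 0.05, min_site_support = 5L,
                   site_max_gap = 10L, min_site_width = 10L,
                   intra_max_span = 2000L, proximal_min_support = 3L,
                   proximal_tol = 10L, contact_bin = 10L)
  unknown <- setdiff(names(opts), names(defaults))
  if (length(unknown)) stop("unknown options: ", paste(unknown, collapse = ", "))
  o <- modifyList(defaults, opts)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fq1 <- read_fastq(fastq1); fq2 <- read_fastq(fastq2)
  parsed <- parse_chimeras(fq1$seqs, fq2$seqs, ids = fq1$ids, layout = layout,
                           linker = linker, max_mismatch = o$max_mismatch,
                           min_overlap = o$min_overlap,
                           max_mismatch_rate = o$max_mismatch_rate,
                           merge_min = o$merge_min, min_frag = o$min_frag)
  chim <- parsed$chimeras

  genome <- read_fasta(genome_fasta)
  genes <- read_gtf(annotation_gtf)
  idx <- genome_index(genome, k = o$align_k)

  # map both fragments of the chimeric reads
  cc <- chim[chim$category == "chimeric", , drop = FALSE]
  aln1 <- toy_align(cc$rna1, idx, max_mismatch = o$align_max_mismatch)
  aln2 <- toy_align(cc$rna2, idx, max_mismatch = o$align_max_mismatch)
  both_unique <- aln1$unique & aln2$unique
  mapped <- cbind(cc[both_unique, c("read_id", "sample_id", "umi")],
                  setNames(aln1[both_unique, c("chrom", "start", "end", "strand")],
                           c("chrom1", "start1", "end1", "strand1")),
                  setNames(aln2[both_unique, c("chrom", "start", "end", "strand")],
                           c("chrom2", "start2", "end2", "strand2")))

  gr1 <- GenomicRanges::GRanges(mapped$chrom1,
                                IRanges::IRanges(mapped$start1 + 1L, mapped$end1),
                                strand = mapped$strand1)
  gr2 <- GenomicRanges::GRanges(mapped$chrom2,
                                IRanges::IRanges(mapped$start2 + 1L, mapped$end2),
                                strand = mapped$strand2)
  as1 <- assign_genes(gr1, genes, min_overlap_frac = o$min_overlap_frac)
  as2 <- assign_genes(gr2, genes, min_overlap_frac = o$min_overlap_frac)
  mapped$gene1 <- as1$unit; mapped$gene2 <- as2$unit
  mapped$biotype1 <- as1$biotype; mapped$biotype2 <- as2$biotype
  n_ambiguous_assign <- sum((as1$ambiguous | as2$ambiguous))

  write_bedpe(data.frame(chrom1 = mapped$chrom1, start1 = mapped$start1,
                         end1 = mapped$end1, chrom2 = mapped$chrom2,
                         start2 = mapped$start2, end2 = mapped$end2,
                         name = mapped$read_id, strand1 = mapped$strand1,
                         strand2 = mapped$strand2, sample = mapped$sample_id,
                         umi = mapped$umi, stringsAsFactors = FALSE),
              file.path(out_dir, "chimeras.bedpe"))

  # interaction calling over inter-gene chimeras
  pc <- count_pairs(mapped$gene1, mapped$gene2)
  biotypes <- setNames(genes$biotype, genes$gene_id)
  extra <- unique(c(mapped$gene1, mapped$gene2))
  extra <- setdiff(extra[!is.na(extra)], names(biotypes))
  if (length(extra)) {
    bt <- ifelse(startsWith(extra, "repeat:"), "transposonRNA", "novel")
    biotypes <- c(biotypes, setNames(bt, extra))
  }
  interactions <- call_interactions(pc, biotypes,
                                    min_pair_count = o$min_pair_count,
                                    fdr = o$fdr)
  write_tsv(interactions, file.path(out_dir, "interactions.tsv"))

  # interaction sites per gene, in transcript coordinates
  gene_tab <- data.frame(gene_id = genes$gene_id,
                         start0 = GenomicRanges::start(genes) - 1L,
                         end0 = GenomicRanges::end(genes),
                         strand = as.character(GenomicRanges::strand(genes)),
                         stringsAsFactors = FALSE)
  rownames(gene_tab) <- gene_tab$gene_id
  frag_long <- rbind(
    data.frame(gene = mapped$gene1, gstart = mapped$start1, gend = mapped$end1,
               stringsAsFactors = FALSE),
    data.frame(gene = mapped$gene2, gstart = mapped$start2, gend = mapped$end2,
               stringsAsFactors = FALSE))
  frag_long <- frag_long[!is.na(frag_long$gene) &
                           frag_long$gene %in% gene_tab$gene_id, ]
  sites <- NULL
  if (nrow(frag_long)) {
    gt <- gene_tab[frag_long$gene, ]
    tx <- .project_tx(frag_long$gstart, frag_long$gend, gt$start0, gt$end0,
                      gt$strand)
    keep <- tx$start >= 0 & tx$end <= gt$end0 - gt$start0
    sites <- do.call(rbind, lapply(split(which(keep), frag_long$gene[keep]),
      function(ii) {
        s <- call_sites(tx$start[ii], tx$end[ii],
                        min_site_support = o$min_site_support,
                        max_gap = o$site_max_gap,
                        min_site_width = o$min_site_width)
        if (nrow(s)) cbind(gene_id = frag_long$gene[ii[1]], s) else NULL
      }))
  }
  if (is.null(sites))
    sites <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), support = integer())
  rownames(sites) <- NULL
  write_tsv(sites, file.path(out_dir, "sites.tsv"))

  # intramolecular structure branch
  same <- !is.na(mapped$gene1) & !is.na(mapped$gene2) &
    mapped$gene1 == mapped$gene2 & mapped$gene1 %in% gene_tab$gene_id
  intra <- data.frame(); proximal <- data.frame()
  if (any(same)) {
    sm <- mapped[same, ]
    cand <- data.frame(gene1 = sm$gene1, gene2 = sm$gene2, has_linker = TRUE,
                       strand1 = sm$strand1, strand2 = sm$strand2,
                       start1 = sm$start1, end1 = sm$end1,
                       start2 = sm$start2, end2 = sm$end2,
                       stringsAsFactors = FALSE)
    cand$gene_strand <- gene_tab[cand$gene1, "strand"]
    filt <- filter_intramolecular(cand, max_span = o$intra_max_span)
    if (nrow(filt)) {
      gt <- gene_tab[filt$gene1, ]
      intra <- intra_pairs(filt, gt$start0, gt$end0)
      proximal <- do.call(rbind, lapply(split(seq_len(nrow(intra)), intra$gene_id),
        function(ii) {
          pp <- call_proximal_pairs(intra$junction1[ii], intra$junction2[ii],
                                    min_support = o$proximal_min_support,
                                    tol = o$proximal_tol)
          if (nrow(pp)) cbind(gene_id = intra$gene_id[ii[1]], pp) else NULL
        }))
      if (is.null(proximal)) proximal <- data.frame()
      rownames(proximal) <- NULL
      # cut-density bedGraph per structured gene (transcript coordinates)
      cd_lines <- character(0)
      for (g in unique(intra$gene_id)) {
        ii <- intra$gene_id == g
        L <- gene_tab[g, "end0"] - gene_tab[g, "start0"]
        cd <- cut_density(c(intra$frag1_start[ii], intra$frag2_start[ii]),
                          c(intra$frag1_end[ii], intra$frag2_end[ii]), L)
        nz <- which(cd$counts > 0)
        if (length(nz))
          cd_lines <- c(cd_lines, sprintf("%s\t%d\t%d\t%d", g, nz - 1L, nz,
                                          cd$counts[nz]))
      }
      writeLines(cd_lines, file.path(out_dir, "cut_density.bedgraph"))
    }
  }
  if (nrow(intra)) write_tsv(intra, file.path(out_dir, "intra_pairs.tsv"))
  if (nrow(proximal)) write_tsv(proximal, file.path(out_dir, "proximal_pairs.tsv"))

  pc_drops <- attr(pc, "drops")
  report <- list(
    seed = seed,
    options = o,
    n_input = parsed$report$n_input,
    n_duplicates = parsed$report$n_duplicates,
    n_unique = parsed$report$n_unique,
    n_undetermined = parsed$report$n_undetermined,
    n_parsed = parsed$report$n_parsed,
    n_short_dropped = parsed$report$n_short_dropped,
    category_counts = as.list(table(chim$category)),
    n_chimeric = nrow(cc),
    n_both_unique = nrow(mapped),
    n_not_uniquely_mapped = nrow(cc) - nrow(mapped),
    n_ambiguous_assignment = n_ambiguous_assign,
    n_unassigned_or_samegene =
      pc_drops$n_unassigned + pc_drops$n_same_gene,
    n_same_gene = pc_drops$n_same_gene,
    n_pairs_tested = nrow(interactions),
    n_significant = sum(interactions$significant),
    n_intra_pairs = nrow(intra),
    n_proximal_pairs = nrow(proximal))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(chimeras = chim, assignments = mapped,
                 interactions = interactions, sites = sites, intra = intra,
                 proximal = proximal, report = report))
}
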