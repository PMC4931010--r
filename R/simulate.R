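#' Simulation configuration
#'
#' Study conditions for the synthetic chimeric library: a random toy
#' genome with single-exon genes over six biotypes, a planted
#' preferential-attachment interactome, per-read construct categories
#' matching the library chemistry (chimeric / linker-RNA2 / no-linker /
#' linker-only), random-ligation contamination, PCR duplicates, sequencing
#' errors, and planted intramolecular structure (proximal junction pairs
#' whose termini mark RNase cut hotspots). Defaults emulate a desk-scale
#' version of the real library: 20 genes per biotype, a 200-edge
#' interactome, 50,000 read pairs of length 100, 0.5% base error, 20%
#' duplicates and 7% random ligation.
#'
#' @param seed master RNG seed.
#' @param n_chromosomes,chrom_length genome shape (per species).
#' @param genes_per_biotype genes of each biotype.
#' @param biotypes biotype vocabulary used by the generator.
#' @param n_edges planted interactome size (edges).
#' @param n_read_pairs total unique read pairs (before duplication),
#'   including the planted intramolecular reads.
#' @param read_length sequenced length of each mate.
#' @param random_ligation_rate fraction of chimeric reads joining two
#'   random molecules instead of a planted edge.
#' @param duplicate_rate PCR duplicates re-emitted verbatim, as a fraction
#'   of unique pairs.
#' @param error_rate per-base substitution probability.
#' @param category_mix named fractions over
#'   \code{chimeric}/\code{linker_rna2}/\code{no_linker}/\code{linker_only}
#'   (must sum to 1).
#' @param layout [barcode_layout()] shared with the parser.
#' @param samples sample ids to multiplex (must exist in the layout).
#' @param linker linker sequence.
#' @param frag_len clamped log-normal fragment length model
#'   (list: meanlog, sdlog, min, max).
#' @param n_structure_genes genes carrying a planted proximal junction
#'   pair.
#' @param structure_reads_per_pair planted cut-and-ligated reads per
#'   proximal pair.
#' @param junction_jitter max +/- displacement of planted junctions (nt).
#' @param two_species add a second species' genome (cross-species
#'   random-ligation control).
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L, chrom_length = 120000L,
                       genes_per_biotype = 20L,
                       biotypes = c("mRNA", "lincRNA", "snoRNA", "snRNA",
                                    "miRNA", "pseudogene"),
                       n_edges = 200L,
                       n_read_pairs = 50000L, read_length = 100L,
                       random_ligation_rate = 0.07,
                       duplicate_rate = 0.2, error_rate = 0.005,
                       category_mix = c(chimeric = 0.70, linker_rna2 = 0.15,
                                        no_linker = 0.10, linker_only = 0.05),
                       layout = barcode_layout(),
                       samples = c("ES-1", "ES-2"),
                       linker = PROXIMITY_LINKER,
                       frag_len = list(meanlog = log(80), sdlog = 0.5,
                                       min = 15L, max = 300L),
                       n_structure_genes = 5L,
                       structure_reads_per_pair = 10L,
                       junction_jitter = 3L,
                       two_species = FALSE) {
  rates <- c(random_ligation_rate, duplicate_rate, error_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (abs(sum(category_mix) - 1) > 1e-8) stop("category mix must sum to 1")
  need <- c("chimeric", "linker_rna2", "no_linker", "linker_only")
  if (!all(need %in% names(category_mix))) stop("category mix incomplete")
  if (!all(samples %in% names(layout$barcodes)))
    stop("samples must have barcodes in the layout")
  structure(as.list(environment()), class = "sim_config")
}

# biotype-specific gene length ranges (nt)
.gene_len_ranges <- list(mRNA = c(800L, 2000L), lincRNA = c(500L, 1500L),
                         snoRNA = c(100L, 250L), snRNA = c(100L, 200L),
                         miRNA = c(60L, 100L), pseudogene = c(300L, 900L))

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate the synthetic reference: genome, genes, interactome, structure
#'
#' Deterministic under the config seed: i.i.d.-uniform-base chromosomes,
#' non-overlapping single-exon genes with random strands, a planted
#' preferential-attachment interactome over species-A genes with per-edge
#' read weights, and planted proximal junction pairs on the longest mRNA
#' genes.
#'
#' @param cfg a [sim_config()].
#' @return list with \code{genome} (named character), \code{genes}
#'   (\code{GRanges} with \code{gene_id}, \code{biotype}), \code{species}
#'   (data.frame reference -> species), \code{edges} (data.frame
#'   \code{gene_a}, \code{gene_b}, \code{weight}), \code{structure}
#'   (data.frame \code{gene_id}, \code{pos1}, \code{pos2},
#'   \code{tx_length}).
#' @export
make_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    species_tags <- if (cfg$two_species) c("speciesA", "speciesB") else "speciesA"
    genome <- character(0); species <- character(0)
    gene_rows <- list()
    for (sp in species_tags) {
      prefix <- if (sp == "speciesA") "" else "spB_"
      chroms <- setNames(
        vapply(seq_len(cfg$n_chromosomes), function(i) .random_dna(cfg$chrom_length),
               character(1)),
        sprintf("%schrom%d", prefix, seq_len(cfg$n_chromosomes)))
      genome <- c(genome, chroms)
      species <- c(species, setNames(rep(sp, length(chroms)), names(chroms)))
      # draw gene lengths, shuffle, place sequentially with random gaps
      lens <- unlist(lapply(cfg$biotypes, function(b) {
        r <- .gene_len_ranges[[b]] %||% c(300L, 1000L)
        sample(r[1]:r[2], cfg$genes_per_biotype, replace = TRUE)
      }))
      bts <- rep(cfg$biotypes, each = cfg$genes_per_biotype)
      ids <- sprintf("%s%s_%02d", prefix, bts,
                     sequence(rep(cfg$genes_per_biotype, length(cfg$biotypes))))
      o <- sample.int(length(lens))
      lens <- lens[o]; bts <- bts[o]; ids <- ids[o]
      ci <- 1L; pos <- 1L
      for (g in seq_along(lens)) {
        pos <- pos + sample(50:300, 1L)
        while (pos + lens[g] > cfg$chrom_length) {
          ci <- ci + 1L
          if (ci > cfg$n_chromosomes)
            stop("genes cannot be placed without overlap; ",
                 "increase chromosome length or count")
          pos <- 1L + sample(50:300, 1L)
        }
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          chrom = names(chroms)[ci], start = pos, end = pos + lens[g] - 1L,
          strand = sample(c("+", "-"), 1L), gene_id = ids[g], biotype = bts[g],
          species = sp, stringsAsFactors = FALSE)
        pos <- pos + lens[g]
      }
    }
    gdf <- do.call(rbind, gene_rows)
    genes <- GenomicRanges::GRanges(gdf$chrom,
                                    IRanges::IRanges(gdf$start, gdf$end),
                                    strand = gdf$strand)
    genes$gene_id <- gdf$gene_id
    genes$biotype <- gdf$biotype
    genes$species <- gdf$species

    # planted interactome: preferential-attachment edges within each species
    # (a mixed-lysate library carries both species' genuine complexes)
    edges <- do.call(rbind, lapply(species_tags, function(sp) {
      ga <- gdf$gene_id[gdf$species == sp]
      g <- igraph::sample_pa(length(ga),
                             m = max(2L, ceiling(cfg$n_edges / length(ga))),
                             directed = FALSE)
      el <- igraph::as_edgelist(g)
      el <- unique(el[el[, 1] != el[, 2], , drop = FALSE])
      if (nrow(el) > cfg$n_edges)
        el <- el[sort(sample.int(nrow(el), cfg$n_edges)), , drop = FALSE]
      perm <- sample(ga)   # detach PA node index from gene placement order
      e1 <- perm[as.integer(el[, 1])]; e2 <- perm[as.integer(el[, 2])]
      data.frame(gene_a = pmin(e1, e2), gene_b = pmax(e1, e2),
                 weight = stats::runif(nrow(el), 0.2, 1.8),
                 stringsAsFactors = FALSE)
    }))

    # planted structure: proximal junction pairs on the longest mRNAs
    structure_df <- NULL
    if (cfg$n_structure_genes > 0) {
      mr <- gdf[gdf$species == "speciesA" & gdf$biotype == "mRNA", ]
      mr <- mr[order(-(mr$end - mr$start + 1L)), ]
      mr <- utils::head(mr, cfg$n_structure_genes)
      L <- mr$end - mr$start + 1L
      structure_df <- data.frame(gene_id = mr$gene_id,
                                 pos1 = as.integer(round(0.25 * L)),
                                 pos2 = as.integer(round(0.70 * L)),
                                 tx_length = L, stringsAsFactors = FALSE)
    }
    list(genome = genome, genes = genes,
         species = data.frame(reference = names(genome),
                              species = unname(species),
                              stringsAsFactors = FALSE),
         edges = edges, structure = structure_df)
  })
}

# transcript-sense sequence of every gene
.tx_seqs <- function(reference) {
  gdf <- as.data.frame(reference$genes)
  seqs <- substring(reference$genome[as.character(gdf$seqnames)],
                    gdf$start, gdf$end)
  minus <- gdf$strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  setNames(seqs, gdf$gene_id)
}

.draw_frag_len <- function(n, model, cap) {
  len <- as.integer(round(stats::rlnorm(n, model$meanlog, model$sdlog)))
  pmin(pmax(len, model$min), pmin(model$max, cap))
}

.apply_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  nerr <- stats::rbinom(length(reads), nchar(reads), rate)
  idx <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(nchar(reads[i]), nerr[i])
    ch <- strsplit(reads[i], "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate a chimeric sequencing library with full ground truth
#'
#' Builds each insert per its category (RNA1+linker+RNA2 for chimeric
#' reads, with the gene pair drawn from the planted interactome or, at the
#' random-ligation rate, from random molecules; linker+RNA2; a bare
#' fragment; or the bare linker), plants the configured intramolecular
#' cut-and-ligated reads on the structure genes, prefixes read 1 with the
#' barcode layout (UMI + sample barcode) and the insert sense strand,
#' takes read 2 as the reverse complement of the insert 3' end, applies
#' per-base substitution errors, injects verbatim PCR duplicates, and
#' shuffles emission order. Every emitted read has exactly one truth
#' record.
#'
#' @param cfg a [sim_config()].
#' @param reference output of [make_reference()].
#' @return list with \code{read1}, \code{read2}, \code{ids} and
#'   \code{truth} (data.frame keyed by read id: category, sample, umi,
#'   gene/fragment loci per side in 0-based half-open genomic coordinates,
#'   species per side, \code{is_random_ligation}, \code{is_intra},
#'   transcript junctions, \code{is_duplicate}, \code{duplicate_of}).
#' @export
simulate_library <- function(cfg, reference) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1L, {
    gdf <- as.data.frame(reference$genes)
    gdf$gene_id <- reference$genes$gene_id
    rownames(gdf) <- gdf$gene_id
    txs <- .tx_seqs(reference)
    sp_of <- setNames(reference$species$species, reference$species$reference)
    gene_sp <- setNames(sp_of[as.character(gdf$seqnames)], gdf$gene_id)

    n_intra <- if (is.null(reference$structure)) 0L else
      nrow(reference$structure) * cfg$structure_reads_per_pair
    n_main <- cfg$n_read_pairs - n_intra
    if (n_main < 0) stop("n_read_pairs smaller than planted structure reads")

    categories <- sample(names(cfg$category_mix), n_main, replace = TRUE,
                         prob = cfg$category_mix)

    # pick a random sub-fragment of a gene; returns tx coords + sequence
    cut_fragment <- function(gene_id, len = NULL) {
      L <- nchar(txs[[gene_id]])
      fl <- if (is.null(len)) .draw_frag_len(1L, cfg$frag_len, L) else min(len, L)
      s <- sample.int(L - fl + 1L, 1L) - 1L
      list(start = s, end = s + fl, seq = substr(txs[[gene_id]], s + 1L, s + fl))
    }

    n_total <- n_main + n_intra
    gene1 <- gene2 <- rep(NA_character_, n_total)
    f1s <- f1e <- f2s <- f2e <- rep(NA_integer_, n_total)
    j1 <- j2 <- rep(NA_integer_, n_total)
    is_random <- is_intra <- rep(FALSE, n_total)
    inserts <- character(n_total)
    cat_all <- c(categories, rep("chimeric", n_intra))

    all_genes <- gdf$gene_id
    for (i in seq_len(n_main)) {
      cat_i <- categories[i]
      if (cat_i == "chimeric") {
        if (stats::runif(1) < cfg$random_ligation_rate) {
          pair <- sample(all_genes, 2L)
          is_random[i] <- TRUE
        } else {
          e <- sample.int(nrow(reference$edges), 1L,
                          prob = reference$edges$weight)
          pair <- c(reference$edges$gene_a[e], reference$edges$gene_b[e])
        }
        fa <- cut_fragment(pair[1]); fb <- cut_fragment(pair[2])
        gene1[i] <- pair[1]; gene2[i] <- pair[2]
        f1s[i] <- fa$start; f1e[i] <- fa$end
        f2s[i] <- fb$start; f2e[i] <- fb$end
        inserts[i] <- paste0(fa$seq, cfg$linker, fb$seq)
      } else if (cat_i == "linker_rna2") {
        g <- sample(all_genes, 1L); fb <- cut_fragment(g)
        gene2[i] <- g; f2s[i] <- fb$start; f2e[i] <- fb$end
        inserts[i] <- paste0(cfg$linker, fb$seq)
      } else if (cat_i == "no_linker") {
        g <- sample(all_genes, 1L); fa <- cut_fragment(g)
        gene1[i] <- g; f1s[i] <- fa$start; f1e[i] <- fa$end
        inserts[i] <- fa$seq
      } else {
        inserts[i] <- cfg$linker
      }
    }

    if (n_intra > 0) {
      row <- n_main
      for (s in seq_len(nrow(reference$structure))) {
        st <- reference$structure[s, ]
        L <- st$tx_length
        for (r in seq_len(cfg$structure_reads_per_pair)) {
          row <- row + 1L
          jj1 <- st$pos1 + sample(-cfg$junction_jitter:cfg$junction_jitter, 1L)
          jj2 <- st$pos2 + sample(-cfg$junction_jitter:cfg$junction_jitter, 1L)
          len1 <- sample(20:60, 1L); len2 <- sample(20:60, 1L)
          a1 <- max(0L, jj1 + 1L - len1)
          b2 <- min(L, jj2 + len2)
          gene1[row] <- gene2[row] <- st$gene_id
          f1s[row] <- a1; f1e[row] <- jj1 + 1L
          f2s[row] <- jj2; f2e[row] <- b2
          j1[row] <- jj1; j2[row] <- jj2
          is_intra[row] <- TRUE
          inserts[row] <- paste0(substr(txs[[st$gene_id]], a1 + 1L, jj1 + 1L),
                                 cfg$linker,
                                 substr(txs[[st$gene_id]], jj2 + 1L, b2))
        }
      }
    }

    # barcode region: N positions from a random UMI, X from the sample barcode
    samples <- sample(cfg$samples, n_total, replace = TRUE)
    n_umi <- length(cfg$layout$n_pos)
    umi <- vapply(seq_len(n_total), function(i)
      paste(sample(c("A", "C", "G", "T"), n_umi, replace = TRUE), collapse = ""),
      character(1))
    bc_region <- vapply(seq_len(n_total), function(i) {
      ch <- character(cfg$layout$width)
      ch[cfg$layout$n_pos] <- strsplit(umi[i], "")[[1]]
      ch[cfg$layout$x_pos] <- strsplit(unname(cfg$layout$barcodes[samples[i]]), "")[[1]]
      paste(ch, collapse = "")
    }, character(1))

    read1 <- substr(paste0(bc_region, inserts), 1L,
                    cfg$layout$width + cfg$read_length)
    read2 <- substr(revcomp(inserts), 1L, cfg$read_length)
    read1 <- .apply_errors(read1, cfg$error_rate)
    read2 <- .apply_errors(read2, cfg$error_rate)

    # genomic fragment loci (0-based half-open) from transcript coords
    tx_to_genome <- function(gid, ts, te) {
      if (is.na(gid)) return(c(NA_integer_, NA_integer_))
      g <- gdf[gid, ]
      if (g$strand == "+") c(g$start - 1L + ts, g$start - 1L + te)
      else c(g$end - te, g$end - ts)
    }
    gloc1 <- t(mapply(tx_to_genome, gene1, f1s, f1e))
    gloc2 <- t(mapply(tx_to_genome, gene2, f2s, f2e))

    truth <- data.frame(
      category = cat_all, sample = samples, umi = umi,
      gene1 = gene1, gene2 = gene2,
      chrom1 = ifelse(is.na(gene1), NA, as.character(gdf[gene1, "seqnames"])),
      frag1_gstart = gloc1[, 1], frag1_gend = gloc1[, 2],
      chrom2 = ifelse(is.na(gene2), NA, as.character(gdf[gene2, "seqnames"])),
      frag2_gstart = gloc2[, 1], frag2_gend = gloc2[, 2],
      frag1_tstart = f1s, frag1_tend = f1e,
      frag2_tstart = f2s, frag2_tend = f2e,
      species1 = ifelse(is.na(gene1), NA, unname(gene_sp[gene1])),
      species2 = ifelse(is.na(gene2), NA, unname(gene_sp[gene2])),
      is_random_ligation = is_random, is_intra = is_intra,
      junction1 = j1, junction2 = j2,
      stringsAsFactors = FALSE)

    # PCR duplicates: verbatim re-emission, then shuffle emission order
    n_dup <- round(n_total * cfg$duplicate_rate)
    src <- if (n_dup > 0) sample.int(n_total, n_dup, replace = TRUE) else integer(0)
    group <- c(seq_len(n_total), src)
    read1 <- c(read1, read1[src]); read2 <- c(read2, read2[src])
    truth <- truth[group, ]
    perm <- sample.int(length(group))
    read1 <- read1[perm]; read2 <- read2[perm]
    truth <- truth[perm, ]; group <- group[perm]
    first_of_group <- !duplicated(group)
    ids <- sprintf("sim_%06d", seq_along(group))
    truth$read_id <- ids
    truth$is_duplicate <- !first_of_group
    truth$duplicate_of <- ifelse(first_of_group, NA_character_,
                                 ids[match(group, group)])
    rownames(truth) <- NULL
    truth <- truth[, c("read_id", setdiff(names(truth), "read_id"))]

    list(read1 = read1, read2 = read2, ids = ids, truth = truth)
  })
}

#' Score interaction calls against planted truth
#'
#' Sensitivity is the fraction of planted edges with at least one emitted
#' (non-random) read that were called significant; specificity is one
#' minus the fraction of tested non-planted pairs called significant.
#'
#' @param calls data.frame with \code{gene_a}, \code{gene_b},
#'   \code{significant} (the tested pairs, e.g. from
#'   [call_interactions()]).
#' @param truth simulator truth data.frame.
#' @param edges planted edge list from [make_reference()].
#' @return list with \code{sensitivity}, \code{specificity},
#'   \code{n_planted_with_reads}, \code{n_called}, \code{confusion}
#'   (2x2 planted x called table over tested pairs).
#' @export
evaluate_calls <- function(calls, truth, edges) {
  key <- function(a, b) paste0(pmin(a, b), "\x01", pmax(a, b))
  planted <- key(edges$gene_a, edges$gene_b)
  emitted <- truth[!truth$is_duplicate & truth$category == "chimeric" &
                     !truth$is_random_ligation & !truth$is_intra, ]
  planted_seen <- intersect(planted, unique(key(emitted$gene1, emitted$gene2)))
  called <- key(calls$gene_a, calls$gene_b)[calls$significant]
  tested <- key(calls$gene_a, calls$gene_b)
  sens <- if (length(planted_seen)) mean(planted_seen %in% called) else NA_real_
  tested_nonplanted <- setdiff(tested, planted)
  spc <- if (length(tested_nonplanted))
    1 - mean(tested_nonplanted %in% called) else NA_real_
  confusion <- table(planted = tested %in% planted,
                     called = tested %in% called)
  list(sensitivity = sens, specificity = spc,
       n_planted_with_reads = length(planted_seen),
       n_called = length(called), confusion = confusion)
}
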