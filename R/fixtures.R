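#' Configuration for the synthetic test fixture
#'
#' The generator emulates the post-alignment inputs of a small bulk
#' RNA-seq study: a toy genome, an ENSEMBL-style reference annotation,
#' per-sample ab initio assemblies containing exact reference copies plus
#' planted novel loci and single-exon noise, adapter-contaminated reads,
#' HTSeq-style counts and DE result tables. Defaults mirror a small
#' validation study: four samples, a handful of annotated genes, a few
#' planted lincRNA and antisense loci, one planted coding candidate, and
#' single-exon noise present in a minority of samples.
#'
#' Planted noncoding features are kept under 303 spliced bases so that no
#' 100-codon ORF can occur in them by construction; the planted coding
#' locus carries an ORF of exactly `orf_codons` codons built by sampling
#' non-stop codons.
#'
#' @param seed integer PRNG seed governing every random draw.
#' @param n_chroms,chrom_len genome shape (contigs x bp).
#' @param n_ref_genes annotated multi-exon genes (every second gene gets a
#'   second isoform sharing its first junction).
#' @param n_novel_linc planted intergenic multi-exon noncoding loci.
#' @param n_novel_antisense planted multi-exon loci exonically overlapping
#'   a reference gene on the opposite strand.
#' @param n_noise_single_exon planted intergenic single-exon transcripts
#'   present only in the first `noise_presence` samples.
#' @param n_orf_loci planted intergenic loci carrying a significant ORF.
#' @param orf_codons length of the planted ORF (codons, excluding stop).
#' @param n_samples number of assembled samples.
#' @param noise_presence number of samples containing each noise
#'   transcript (default 1, a strict minority of 4).
#' @param adapter_seq,adapter_fraction,n_reads,read_len FASTQ generation:
#'   adapter appended to the 3' end of a known fraction of reads.
#' @return a `FixtureConfig` list.
#' @export
fixture_config <- function(seed = 1L, n_chroms = 2L, chrom_len = 60000L,
                           n_ref_genes = 8L, n_novel_linc = 3L,
                           n_novel_antisense = 5L,
                           n_noise_single_exon = 5L, n_orf_loci = 1L,
                           orf_codons = 120L, n_samples = 4L,
                           noise_presence = 1L,
                           adapter_seq = "AGATCGGAAGAGC",
                           adapter_fraction = 0.3, n_reads = 200L,
                           read_len = 50L) {
  stopifnot(n_chroms >= 1, chrom_len >= 10000, n_ref_genes >= 0,
            n_novel_linc >= 0, n_novel_antisense >= 0,
            n_noise_single_exon >= 0, n_orf_loci >= 0,
            n_samples >= 1, noise_presence >= 0,
            noise_presence <= n_samples, orf_codons >= 1,
            nchar(adapter_seq) >= 1)
  if (n_novel_antisense > n_ref_genes)
    stop("each antisense locus overlays a distinct reference gene; ",
         "n_novel_antisense must not exceed n_ref_genes")
  structure(as.list(environment()), class = "FixtureConfig")
}

SLOT_WIDTH <- 4000L

#' Generate a self-contained synthetic fixture
#'
#' Writes, under `outdir`: `genome.fa`, `reference.gtf`,
#' `samples/<sample>.gtf`, `counts/<sample>.counts.tsv`,
#' `reads/sample_1.fastq`, `de/{cuffdiff_gene_exp.diff,edger.tsv,
#' deseq2.tsv}` and `truth_manifest.tsv`. All draws come from one PRNG
#' stream keyed by `cfg$seed`, so a given configuration always produces
#' byte-identical files.
#'
#' @param cfg a [fixture_config()].
#' @param outdir writable output directory (created if needed).
#' @return invisible manifest list: file paths, the truth data.frame and
#'   the configuration.
#' @export
make_fixture <- function(cfg = fixture_config(), outdir) {
  stopifnot(inherits(cfg, "FixtureConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("samples", "counts", "reads", "de"))
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  set.seed(cfg$seed)

  # --- slot layout: features never collide by construction -----------------
  slots_per_chrom <- (cfg$chrom_len - 2000L) %/% SLOT_WIDTH
  n_features <- cfg$n_ref_genes + cfg$n_novel_linc + cfg$n_orf_loci +
    cfg$n_noise_single_exon
  if (n_features > slots_per_chrom * cfg$n_chroms)
    stop("cannot place ", n_features, " features in ",
         slots_per_chrom * cfg$n_chroms, " slots; increase chrom_len")
  slot_base <- function(i) {  # i is 1-based global slot index
    chrom_i <- (i - 1L) %/% slots_per_chrom
    offset <- (i - 1L) %% slots_per_chrom
    list(chrom = paste0("chrT", chrom_i + 1L),
         base = 1000L + offset * SLOT_WIDTH)
  }

  # --- genome --------------------------------------------------------------
  genome_chars <- lapply(seq_len(cfg$n_chroms), function(i)
    sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE))
  names(genome_chars) <- paste0("chrT", seq_len(cfg$n_chroms))

  slot_i <- 0L
  truth <- list()
  ref_txs <- list()      # reference transcripts
  planted_txs <- list()  # novel/noise transcripts with presence rule

  biotypes <- c("protein_coding", "lincRNA", "processed_transcript",
                "protein_coding")
  for (g in seq_len(cfg$n_ref_genes)) {
    slot_i <- slot_i + 1L
    sb <- slot_base(slot_i)
    strand <- if (g %% 2L == 1L) "+" else "-"
    gid <- sprintf("REFG_%03d", g)
    gname <- sprintf("Gene%03d", g)
    bt <- biotypes[(g - 1L) %% length(biotypes) + 1L]
    e <- data.frame(start = sb$base + c(200L, 800L, 1500L),
                    end = sb$base + c(200L + 299L, 800L + 249L,
                                      1500L + 399L))
    attrs <- c(gene_name = gname, gene_biotype = bt)
    iso1 <- transcript_model(paste0(gid, ".1"), gid, sb$chrom, strand,
                             e$start, e$end, attributes = attrs)
    ref_txs[[length(ref_txs) + 1L]] <- iso1
    if (g %% 2L == 0L) {
      iso2 <- transcript_model(paste0(gid, ".2"), gid, sb$chrom, strand,
                               e$start[1:2], e$end[1:2], attributes = attrs)
      ref_txs[[length(ref_txs) + 1L]] <- iso2
    }
    truth[[length(truth) + 1L]] <- data.frame(
      feature_id = gid, feature = "reference", expected_class = "annotated",
      chrom = sb$chrom, start = min(e$start), end = max(e$end),
      strand = strand, key = tx_structure_key(iso1),
      stringsAsFactors = FALSE)

    if (g <= cfg$n_novel_antisense) {
      # antisense RNA over exons 1-2 of this gene, opposite strand,
      # 101+101 = 202 spliced bases (no room for a significant ORF)
      as_strand <- if (strand == "+") "-" else "+"
      aid <- sprintf("PLANT_AS_%03d", g)
      as_tx <- transcript_model(aid, aid, sb$chrom, as_strand,
                                c(e$start[1L] + 20L, e$start[2L] + 20L),
                                c(e$start[1L] + 120L, e$start[2L] + 120L))
      planted_txs[[length(planted_txs) + 1L]] <-
        list(tx = as_tx, in_all = TRUE)
      truth[[length(truth) + 1L]] <- data.frame(
        feature_id = aid, feature = "novel_antisense",
        expected_class = "novel_antisense", chrom = sb$chrom,
        start = e$start[1L] + 20L, end = e$start[2L] + 120L,
        strand = as_strand, key = tx_structure_key(as_tx),
        stringsAsFactors = FALSE)
    }
  }

  for (k in seq_len(cfg$n_novel_linc)) {
    slot_i <- slot_i + 1L
    sb <- slot_base(slot_i)
    strand <- if (k %% 2L == 1L) "+" else "-"
    lid <- sprintf("PLANT_LINC_%03d", k)
    # 150 + 140 = 290 spliced bases: below any significant ORF
    tx <- transcript_model(lid, lid, sb$chrom, strand,
                           sb$base + c(100L, 600L),
                           sb$base + c(100L + 149L, 600L + 139L))
    planted_txs[[length(planted_txs) + 1L]] <- list(tx = tx, in_all = TRUE)
    truth[[length(truth) + 1L]] <- data.frame(
      feature_id = lid, feature = "novel_lincRNA",
      expected_class = "novel_lincRNA", chrom = sb$chrom,
      start = sb$base + 100L, end = sb$base + 739L, strand = strand,
      key = tx_structure_key(tx), stringsAsFactors = FALSE)
  }

  for (k in seq_len(cfg$n_orf_loci)) {
    slot_i <- slot_i + 1L
    sb <- slot_base(slot_i)
    oid <- sprintf("PLANT_ORF_%03d", k)
    # spliced sequence: 10 nt pad, ATG, (orf_codons-1) non-stop codons,
    # TAA, 10 nt pad; split across two exons
    body <- paste(sample(setdiff(all_codons(), c(STOP_CODONS, "ATG")),
                         cfg$orf_codons - 1L, replace = TRUE),
                  collapse = "")
    spliced <- paste0(rand_bases(10L), "ATG", body, "TAA", rand_bases(10L))
    sl <- nchar(spliced)
    e1_len <- 200L
    ex <- data.frame(start = sb$base + c(100L, 600L),
                     end = sb$base + c(100L + e1_len - 1L,
                                       600L + (sl - e1_len) - 1L))
    tx <- transcript_model(oid, oid, sb$chrom, "+", ex$start, ex$end)
    # write the spliced sequence into the (+ strand) genome
    ch <- strsplit(spliced, "")[[1L]]
    genome_chars[[sb$chrom]][ex$start[1L]:ex$end[1L]] <- ch[1:e1_len]
    genome_chars[[sb$chrom]][ex$start[2L]:ex$end[2L]] <- ch[(e1_len + 1L):sl]
    planted_txs[[length(planted_txs) + 1L]] <- list(tx = tx, in_all = TRUE)
    truth[[length(truth) + 1L]] <- data.frame(
      feature_id = oid, feature = "novel_coding_candidate",
      expected_class = "novel_coding_candidate", chrom = sb$chrom,
      start = ex$start[1L], end = ex$end[2L], strand = "+",
      key = tx_structure_key(tx), stringsAsFactors = FALSE)
  }

  for (k in seq_len(cfg$n_noise_single_exon)) {
    slot_i <- slot_i + 1L
    sb <- slot_base(slot_i)
    nid <- sprintf("PLANT_NOISE_%03d", k)
    tx <- transcript_model(nid, nid, sb$chrom, "+",
                           sb$base + 100L, sb$base + 349L)
    planted_txs[[length(planted_txs) + 1L]] <-
      list(tx = tx, in_all = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      feature_id = nid, feature = "noise_single_exon",
      expected_class = "filtered", chrom = sb$chrom,
      start = sb$base + 100L, end = sb$base + 349L, strand = "+",
      key = tx_structure_key(tx), stringsAsFactors = FALSE)
  }

  # --- write genome --------------------------------------------------------
  genome_path <- file.path(outdir, "genome.fa")
  gset <- Biostrings::DNAStringSet(vapply(genome_chars, paste,
                                          character(1), collapse = ""))
  Biostrings::writeXStringSet(gset, genome_path, width = 70L)

  # --- reference GTF -------------------------------------------------------
  reference_path <- file.path(outdir, "reference.gtf")
  ref_loci <- group_ref_loci(ref_txs)
  write_gtf(ref_loci, reference_path)

  # --- per-sample assemblies ----------------------------------------------
  sample_ids <- sprintf("sample_%d", seq_len(cfg$n_samples))
  sample_paths <- file.path(outdir, "samples",
                            paste0(sample_ids, ".gtf"))
  for (s in seq_len(cfg$n_samples)) {
    txs <- list()
    cuff_i <- 0L
    for (tx in ref_txs) txs[[length(txs) + 1L]] <- tx
    for (pl in planted_txs)
      if (pl$in_all || s <= cfg$noise_presence)
        txs[[length(txs) + 1L]] <- pl$tx
    out_txs <- lapply(seq_along(txs), function(i) {
      t <- txs[[i]]
      t2 <- transcript_model(sprintf("CUFF.%d.1", i), sprintf("CUFF.%d", i),
                             t$chrom, t$strand, t$exons$start, t$exons$end,
                             attributes = c(
                               FPKM = sprintf("%.4f", stats::rlnorm(1, 3, 1)),
                               source_id = t$transcript_id))
      t2
    })
    loci <- lapply(out_txs, function(t) gene_locus(t$gene_id, list(t)))
    write_gtf(loci, sample_paths[s])
  }

  # --- HTSeq-style counts --------------------------------------------------
  count_paths <- file.path(outdir, "counts",
                           paste0(sample_ids, ".counts.tsv"))
  ref_ids <- sort(unique(vapply(ref_txs, `[[`, character(1), "gene_id")))
  for (s in seq_len(cfg$n_samples)) {
    cnt <- stats::rpois(length(ref_ids), lambda = 50)
    writeLines(c(paste(ref_ids, cnt, sep = "\t"),
                 paste("__no_feature", stats::rpois(1, 100), sep = "\t")),
               count_paths[s])
  }

  # --- reads with planted adapter ------------------------------------------
  reads_path <- file.path(outdir, "reads", "sample_1.fastq")
  chrom1 <- genome_chars[[1L]]
  with_adapter <- seq_len(cfg$n_reads) <=
    round(cfg$adapter_fraction * cfg$n_reads)
  adapter <- toupper(cfg$adapter_seq)
  a_len <- nchar(adapter)
  fq <- character(0)
  for (i in seq_len(cfg$n_reads)) {
    pos <- sample.int(cfg$chrom_len - cfg$read_len, 1L)
    rd <- paste(chrom1[pos:(pos + cfg$read_len - 1L)], collapse = "")
    if (with_adapter[i])
      rd <- paste0(substr(rd, 1L, cfg$read_len - a_len), adapter)
    fq <- c(fq, sprintf("@read_%04d%s", i,
                        if (with_adapter[i]) " adapter=1" else " adapter=0"),
            rd, "+", strrep("I", cfg$read_len))
  }
  writeLines(fq, reads_path)

  # --- DE result tables over the reference genes ---------------------------
  de_dir <- file.path(outdir, "de")
  lfc <- stats::rnorm(length(ref_ids), 0, 2)
  pv <- stats::runif(length(ref_ids))^2
  qv <- stats::p.adjust(pv, "BH")
  val1 <- stats::rlnorm(length(ref_ids), 3, 1)
  cuff <- data.frame(
    test_id = ref_ids, gene_id = ref_ids,
    gene = sprintf("Gene%03d", seq_along(ref_ids)),
    locus = "chrT1:1-1000", sample_1 = "ctrl", sample_2 = "case",
    status = "OK", value_1 = round(val1, 4),
    value_2 = round(val1 * 2^lfc, 4),
    check.names = FALSE, stringsAsFactors = FALSE)
  cuff[["log2(fold_change)"]] <- round(lfc, 4)
  cuff$test_stat <- round(lfc / 0.5, 4)
  cuff$p_value <- signif(pv, 4)
  cuff$q_value <- signif(qv, 4)
  cuff$significant <- ifelse(qv < 0.05, "yes", "no")
  utils::write.table(cuff, file.path(de_dir, "cuffdiff_gene_exp.diff"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  edger <- data.frame(gene_id = ref_ids, logFC = round(lfc, 4),
                      logCPM = round(stats::runif(length(ref_ids), 1, 10), 4),
                      PValue = signif(pv, 4), FDR = signif(qv, 4),
                      stringsAsFactors = FALSE)
  utils::write.table(edger, file.path(de_dir, "edger.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  deseq2 <- data.frame(gene_id = ref_ids, baseMean = round(val1, 4),
                       log2FoldChange = round(lfc, 4),
                       lfcSE = 0.3, stat = round(lfc / 0.3, 4),
                       pvalue = signif(pv, 4), padj = signif(qv, 4),
                       stringsAsFactors = FALSE)
  deseq2$padj[length(ref_ids)] <- NA  # one NA padj, as DESeq2 emits
  utils::write.table(deseq2, file.path(de_dir, "deseq2.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")

  # --- truth manifest ------------------------------------------------------
  truth_df <- do.call(rbind, truth)
  truth_path <- file.path(outdir, "truth_manifest.tsv")
  utils::write.table(truth_df, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(
    genome = genome_path, reference = reference_path,
    samples = stats::setNames(sample_paths, sample_ids),
    counts = stats::setNames(count_paths, sample_ids),
    reads = reads_path,
    de = list(cuffdiff = file.path(de_dir, "cuffdiff_gene_exp.diff"),
              edger = file.path(de_dir, "edger.tsv"),
              deseq2 = file.path(de_dir, "deseq2.tsv")),
    truth = truth_df, truth_path = truth_path, config = cfg))
}

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

group_ref_loci <- function(ref_txs) {
  gids <- vapply(ref_txs, `[[`, character(1), "gene_id")
  lapply(split(seq_along(ref_txs), factor(gids, levels = unique(gids))),
         function(idx) {
    a <- ref_txs[[idx[1L]]]$attributes
    gene_locus(gids[idx[1L]], ref_txs[idx],
               gene_name = unname(a["gene_name"] %||% gids[idx[1L]]),
               biotype = unname(a["gene_biotype"] %||% "unknown"),
               locus_class = "annotated")
  })
}

#' Run the merge/classify/filter/discovery pipeline on a fixture
#'
#' Reads a fixture directory produced by [make_fixture()] (or any
#' directory with the same layout), merges the per-sample assemblies,
#' classifies transcripts against the reference, applies the single-exon
#' filter and annotates biotypes and locus classes.
#'
#' @param fixture_dir fixture directory.
#' @param cfg a [filter_config()].
#' @param coding_cfg a [coding_config()].
#' @return list: `annotated` (final locus list), `codes`, `presence`,
#'   `filter_report`, `reference`.
#' @export
run_discovery_pipeline <- function(fixture_dir, cfg = filter_config(),
                                   coding_cfg = coding_config()) {
  ref <- read_gtf(file.path(fixture_dir, "reference.gtf"), "reference")
  sample_files <- sort(list.files(file.path(fixture_dir, "samples"),
                                  pattern = "\\.gtf$", full.names = TRUE))
  per_sample <- stats::setNames(
    lapply(sample_files, read_gtf, dialect = "assembled"),
    sub("\\.gtf$", "", basename(sample_files)))
  merged <- merge_samples(per_sample)
  idx <- reference_index(ref)
  codes <- classify_transcripts(merged, idx)
  pres <- sample_presence(merged)
  filt <- filter_single_exon(merged, pres, cfg, codes)
  codes_f <- codes[codes$transcript_id %in%
                     sample_presence(filt)$transcript_id, , drop = FALSE]
  genome <- load_genome(file.path(fixture_dir, "genome.fa"))
  annotated <- annotate_biotypes(filt, ref, genome, codes = codes_f,
                                 cfg = coding_cfg)
  list(annotated = annotated, codes = codes, presence = pres,
       filter_report = attr(filt, "report"), reference = ref)
}

#' Compare pipeline output against a fixture's truth manifest
#'
#' A planted feature is recovered when the final locus set contains a
#' locus of the expected class whose span overlaps the planted span on
#' the same strand; `filtered` features (minority single-exon noise) are
#' recovered when no retained transcript has their exon structure.
#'
#' @param result list from [run_discovery_pipeline()].
#' @param truth truth data.frame (or path to `truth_manifest.tsv`).
#' @return data.frame: `feature_id`, `expected_class`, `recovered`.
#' @export
evaluate_recovery <- function(result, truth) {
  if (is.character(truth))
    truth <- utils::read.delim(truth, stringsAsFactors = FALSE)
  loci <- result$annotated
  keys <- vapply(loci_transcripts(loci), tx_structure_key, character(1))
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    recovered <- if (tr$expected_class == "filtered") {
      !tr$key %in% keys
    } else {
      any(vapply(loci, function(l)
        l$locus_class == tr$expected_class && l$chrom == tr$chrom &&
          l$strand == tr$strand && l$start <= tr$end && l$end >= tr$start,
        logical(1)))
    }
    data.frame(feature_id = tr$feature_id,
               expected_class = tr$expected_class,
               recovered = recovered, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
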