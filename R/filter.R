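#' Filtering thresholds for assembled transcript sets
#'
#' @param majority_fraction fraction of samples a single-exon transcript
#'   must exceed (strictly) to be retained; default 0.5, i.e. a strict
#'   majority — a transcript seen in exactly half the samples is removed.
#' @param min_locus_reads minimum total read count (summed over samples)
#'   for a locus to be considered for differential expression; default 10.
#' @param min_fpkm minimum of the per-sample FPKM maximum; default 0.
#' @return a `FilterConfig` list.
#' @export
filter_config <- function(majority_fraction = 0.5, min_locus_reads = 10L,
                          min_fpkm = 0) {
  stopifnot(majority_fraction > 0, majority_fraction <= 1,
            min_locus_reads >= 0, min_fpkm >= 0)
  structure(list(majority_fraction = majority_fraction,
                 min_locus_reads = as.integer(min_locus_reads),
                 min_fpkm = min_fpkm),
            class = "FilterConfig")
}

#' Remove spurious single-exon transcripts
#'
#' Multi-exon transcripts (anything containing a splice junction) are
#' always retained. A single-exon transcript is retained only when it was
#' observed in a strict majority of samples
#' (`n_present > majority_fraction * n_samples`); in addition, single-exon
#' transcripts classified `intronic` against the reference are removed
#' regardless of presence, as likely pre-mRNA fragments. Loci left with no
#' transcripts are dropped.
#'
#' @param loci list of `GeneLocus` from [merge_samples()].
#' @param presence data.frame from [sample_presence()] covering every
#'   transcript.
#' @param cfg a [filter_config()].
#' @param codes optional data.frame from [classify_transcripts()]; when
#'   supplied, enables the intronic single-exon rule.
#' @return filtered locus list; attribute `report` holds a data.frame
#'   (`transcript_id`, `action`, `reason`) describing every decision.
#' @export
filter_single_exon <- function(loci, presence, cfg = filter_config(),
                               codes = NULL) {
  stopifnot(inherits(cfg, "FilterConfig"))
  pres_n <- stats::setNames(presence$n_present, presence$transcript_id)
  n_samples <- unique(presence$n_samples)
  stopifnot(length(n_samples) == 1L)
  code_of <- if (!is.null(codes))
    stats::setNames(codes$code, codes$transcript_id) else character(0)

  report <- list()
  out <- list()
  for (loc in loci) {
    keep <- logical(length(loc$transcripts))
    for (i in seq_along(loc$transcripts)) {
      t <- loc$transcripts[[i]]
      tid <- t$transcript_id
      if (nrow(t$exons) > 1L) {
        keep[i] <- TRUE
        report[[tid]] <- c(tid, "kept", "multi_exon")
        next
      }
      if (!tid %in% names(pres_n))
        stop("no presence information for transcript '", tid, "'")
      if (length(code_of) && !is.na(code_of[tid] %||% NA) &&
          code_of[[tid]] == "intronic") {
        keep[i] <- FALSE
        report[[tid]] <- c(tid, "removed", "single_exon_intronic")
        next
      }
      thresh <- cfg$majority_fraction * n_samples
      if (pres_n[[tid]] > thresh) {
        keep[i] <- TRUE
        report[[tid]] <- c(tid, "kept", "single_exon_majority")
      } else {
        keep[i] <- FALSE
        report[[tid]] <- c(tid, "removed",
                           if (pres_n[[tid]] == thresh)
                             "single_exon_tie_minority" else
                             "single_exon_minority")
      }
    }
    if (any(keep)) {
      loc2 <- gene_locus(loc$gene_id, loc$transcripts[keep],
                         gene_name = loc$gene_name, biotype = loc$biotype,
                         locus_class = loc$locus_class)
      out[[length(out) + 1L]] <- loc2
    }
  }
  rep_df <- if (length(report)) {
    d <- as.data.frame(do.call(rbind, unname(report)),
                       stringsAsFactors = FALSE)
    names(d) <- c("transcript_id", "action", "reason")
    d
  } else data.frame(transcript_id = character(0), action = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  attr(out, "report") <- rep_df
  attr(out, "n_samples") <- n_samples
  attr(out, "samples") <- attr(loci, "samples")
  out
}

#' Remove loci with insufficient read coverage
#'
#' A locus is retained only when its total read count across samples meets
#' `min_locus_reads` (inclusive) and the maximum per-sample FPKM over its
#' transcripts meets `min_fpkm`. Loci absent from the count table are
#' treated as zero-count.
#'
#' @param loci list of `GeneLocus`.
#' @param counts numeric matrix (gene_id x sample) or data.frame of
#'   per-sample read counts; see [read_htseq_counts()].
#' @param cfg a [filter_config()].
#' @return filtered locus list; attribute `report` records removed loci
#'   with the reason (`low_reads` / `low_fpkm`).
#' @export
filter_low_coverage <- function(loci, counts, cfg = filter_config()) {
  stopifnot(inherits(cfg, "FilterConfig"))
  counts <- as.matrix(counts)
  if (length(counts) && any(counts < 0))
    stop("negative read count in counts table")
  report <- list()
  keep <- vapply(loci, function(loc) {
    total <- if (loc$gene_id %in% rownames(counts))
      sum(counts[loc$gene_id, ]) else 0
    max_fpkm <- suppressWarnings(
      max(0, unlist(lapply(loc$transcripts, `[[`, "fpkm_by_sample"))))
    if (total < cfg$min_locus_reads) {
      report[[loc$gene_id]] <<- c(loc$gene_id, "removed", "low_reads")
      FALSE
    } else if (max_fpkm < cfg$min_fpkm) {
      report[[loc$gene_id]] <<- c(loc$gene_id, "removed", "low_fpkm")
      FALSE
    } else TRUE
  }, logical(1))
  out <- loci[keep]
  rep_df <- if (length(report)) {
    d <- as.data.frame(do.call(rbind, unname(report)),
                       stringsAsFactors = FALSE)
    names(d) <- c("gene_id", "action", "reason")
    d
  } else data.frame(gene_id = character(0), action = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  attr(out, "report") <- rep_df
  attr(out, "n_samples") <- attr(loci, "n_samples")
  attr(out, "samples") <- attr(loci, "samples")
  out
}

#' Read HTSeq-style count files into a matrix
#'
#' Each file is a two-column tab-delimited table (`gene_id`, `count`);
#' summary rows beginning with `__` are dropped.
#'
#' @param paths character vector of file paths.
#' @param sample_ids column names; default the file base names.
#' @return integer matrix, genes x samples (union of gene ids, absent
#'   entries 0).
#' @export
read_htseq_counts <- function(paths, sample_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- sub("\\.(txt|tsv|counts)(\\.gz)?$", "", basename(paths))
  stopifnot(length(paths) == length(sample_ids))
  tabs <- lapply(paths, function(p) {
    d <- utils::read.delim(p, header = FALSE, stringsAsFactors = FALSE)
    d <- d[!grepl("^__", d[[1L]]), , drop = FALSE]
    stats::setNames(as.integer(d[[2L]]), d[[1L]])
  })
  genes <- sort(unique(unlist(lapply(tabs, names))))
  m <- matrix(0L, nrow = length(genes), ncol = length(paths),
              dimnames = list(genes, sample_ids))
  for (i in seq_along(tabs)) m[names(tabs[[i]]), i] <- tabs[[i]]
  m
}

#' Write a filtering report
#'
#' @param filtered result of [filter_single_exon()] or
#'   [filter_low_coverage()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(filtered, path) {
  rep_df <- attr(filtered, "report")
  if (is.null(rep_df)) stop("object carries no filtering report")
  utils::write.table(rep_df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
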