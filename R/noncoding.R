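#' Classify a novel locus as coding candidate, lincRNA or antisense RNA
#'
#' Applies the discovery rule for unannotated loci: a locus containing at
#' least one isoform with a significant open reading frame is a potential
#' novel protein-coding gene and is not considered noncoding; otherwise
#' the locus is a novel antisense RNA when any isoform exonically overlaps
#' an annotated gene on the opposite strand, and a long intergenic
#' noncoding RNA (lincRNA) when not.
#'
#' An external per-transcript coding call (e.g. from a sequence-intrinsic
#' classifier run outside this package) may be supplied via
#' `coding_calls`; where present it overrides the ORF rule for that
#' isoform.
#'
#' @param locus a novel `GeneLocus` (no transcript may be classified
#'   `equal`).
#' @param codes data.frame from [classify_transcripts()] covering the
#'   locus's transcripts.
#' @param genome FASTA path or [load_genome()] object.
#' @param cfg a [coding_config()].
#' @param coding_calls optional named character vector transcript_id ->
#'   `"coding"` / `"noncoding"`; see [read_coding_calls()].
#' @return list with `locus_class` (one of `novel_coding_candidate`,
#'   `novel_antisense`, `novel_lincRNA`) and `best_orf_codons`.
#' @export
classify_novel_locus <- function(locus, codes, genome,
                                 cfg = coding_config(),
                                 coding_calls = NULL) {
  code_of <- stats::setNames(codes$code, codes$transcript_id)
  tids <- vapply(locus$transcripts, `[[`, character(1), "transcript_id")
  missing <- setdiff(tids, names(code_of))
  if (length(missing))
    stop("no class code for transcript(s): ", paste(missing, collapse = ", "))
  if (any(code_of[tids] == "equal"))
    stop("locus '", locus$gene_id,
         "' contains an 'equal' transcript; it is not novel")
  if (is.character(genome)) genome <- load_genome(genome)

  best_orf <- 0L
  any_coding <- FALSE
  for (tx in locus$transcripts) {
    if (!is.null(coding_calls) && tx$transcript_id %in% names(coding_calls)) {
      if (coding_calls[[tx$transcript_id]] == "coding") any_coding <- TRUE
      next
    }
    orf <- find_longest_orf(extract_sequence(genome, tx), cfg)
    best_orf <- max(best_orf, orf$best_orf_length_codons)
    if (orf$has_significant_orf) any_coding <- TRUE
  }
  cls <- if (any_coding) "novel_coding_candidate"
         else if (any(code_of[tids] == "antisense")) "novel_antisense"
         else "novel_lincRNA"
  list(locus_class = cls, best_orf_codons = best_orf)
}

#' Read an external coding-potential call file
#'
#' Two tab-delimited columns: transcript_id, label (`coding` /
#' `noncoding`).
#'
#' @param path file path.
#' @return named character vector for `coding_calls` arguments.
#' @export
read_coding_calls <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L || !all(d[[2L]] %in% c("coding", "noncoding")))
    stop("coding call file must have columns transcript_id, ",
         "label in {coding, noncoding}")
  stats::setNames(d[[2L]], d[[1L]])
}

#' Annotate loci with biotypes and locus classes against the reference
#'
#' Loci whose transcripts matched an annotated gene (`equal` or
#' `novel_isoform`) inherit that gene's id, name and `gene_biotype`
#' (biotype `"unknown"` with a warning when the reference carries none).
#' Remaining loci are novel: they are classified with
#' [classify_novel_locus()], receive their class as biotype, and are given
#' identifiers `NOVEL_LOC_%06d` in (chromosome, start) order.
#'
#' @param loci list of `GeneLocus` (merged, filtered assembly).
#' @param reference reference loci carrying `gene_biotype` attributes.
#' @param genome FASTA path or [load_genome()] object.
#' @param codes optional precomputed [classify_transcripts()] table;
#'   computed when absent.
#' @param cfg a [coding_config()].
#' @param coding_calls optional external calls, see
#'   [classify_novel_locus()].
#' @return annotated locus list, genomic order; attribute `classification`
#'   holds a per-locus summary data.frame.
#' @export
annotate_biotypes <- function(loci, reference, genome, codes = NULL,
                              cfg = coding_config(), coding_calls = NULL) {
  idx <- if (inherits(reference, "reference_index")) reference
         else reference_index(reference)
  if (is.null(codes)) codes <- classify_transcripts(loci, idx)
  if (is.character(genome)) genome <- load_genome(genome)
  ref_by_id <- stats::setNames(reference, vapply(reference, `[[`,
                                                 character(1), "gene_id"))
  code_of <- stats::setNames(codes$code, codes$transcript_id)
  match_of <- stats::setNames(codes$matched_gene_id, codes$transcript_id)

  is_novel <- logical(length(loci))
  out <- vector("list", length(loci))
  summary_rows <- vector("list", length(loci))
  for (i in seq_along(loci)) {
    loc <- loci[[i]]
    tids <- vapply(loc$transcripts, `[[`, character(1), "transcript_id")
    lc <- code_of[tids]
    if (any(lc %in% c("equal", "novel_isoform"))) {
      # annotated: inherit from the matched gene (prefer an 'equal' match)
      pick <- tids[order(match(lc, c("equal", "novel_isoform")))][1L]
      mg <- match_of[[pick]]
      ref_gene <- ref_by_id[[mg]]
      biotype <- ref_gene$biotype
      if (is.null(biotype) || is.na(biotype) || biotype == "unknown") {
        warning("reference gene '", mg, "' has no biotype; using 'unknown'")
        biotype <- "unknown"
      }
      loc$gene_id <- ref_gene$gene_id
      loc$gene_name <- ref_gene$gene_name
      loc$biotype <- biotype
      loc$locus_class <- "annotated"
      loc$transcripts <- lapply(loc$transcripts, function(t) {
        t$gene_id <- ref_gene$gene_id
        t
      })
      best_orf <- NA_integer_
    } else {
      is_novel[i] <- TRUE
      cl <- classify_novel_locus(loc, codes, genome, cfg, coding_calls)
      loc$locus_class <- cl$locus_class
      loc$biotype <- cl$locus_class
      best_orf <- cl$best_orf_codons
    }
    out[[i]] <- loc
    summary_rows[[i]] <- data.frame(
      gene_id = loc$gene_id, class = loc$locus_class, biotype = loc$biotype,
      best_orf_codons = best_orf, n_isoforms = length(loc$transcripts),
      coords = sprintf("%s:%d-%d(%s)", loc$chrom, loc$start, loc$end,
                       loc$strand),
      stringsAsFactors = FALSE)
  }

  # deterministic novel ids in (chrom, start) order
  if (any(is_novel)) {
    nv <- which(is_novel)
    ord <- nv[order(vapply(out[nv], `[[`, character(1), "chrom"),
                    vapply(out[nv], `[[`, integer(1), "start"))]
    for (k in seq_along(ord)) {
      i <- ord[k]
      nid <- sprintf("NOVEL_LOC_%06d", k)
      out[[i]]$gene_id <- nid
      out[[i]]$gene_name <- nid
      out[[i]]$transcripts <- lapply(out[[i]]$transcripts, function(t) {
        t$gene_id <- nid
        t
      })
      summary_rows[[i]]$gene_id <- nid
    }
  }
  ord_all <- order(vapply(out, `[[`, character(1), "chrom"),
                   vapply(out, `[[`, integer(1), "start"),
                   vapply(out, `[[`, character(1), "gene_id"))
  out <- out[ord_all]
  attr(out, "classification") <- do.call(rbind, summary_rows[ord_all])
  out
}

#' Write the per-locus classification report
#'
#' @param annotated result of [annotate_biotypes()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_classification_report <- function(annotated, path) {
  cls <- attr(annotated, "classification")
  if (is.null(cls)) stop("object carries no classification table")
  utils::write.table(cls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
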