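#' Parse a differential-expression result table
#'
#' Understands three column dialects:
#' \describe{
#'   \item{cuffdiff}{`gene_exp.diff`: `test_id, gene_id, gene, locus,
#'     sample_1, sample_2, status, value_1, value_2, log2(fold_change),
#'     test_stat, p_value, q_value, ...`; group abundances are kept.}
#'   \item{edger}{topTags-style: a gene id column plus `logFC, PValue,
#'     FDR`.}
#'   \item{deseq2}{results-style: a gene id column plus `log2FoldChange,
#'     pvalue, padj`.}
#' }
#' All fold changes are log2 in these dialects and are passed through
#' unchanged. A missing adjusted p value (`NA`) is set to 1.0 and flagged
#' in `fdr_imputed`.
#'
#' @param path tab-delimited file path.
#' @param dialect `"cuffdiff"`, `"edger"` or `"deseq2"`.
#' @param method method label recorded on each row; defaults to the
#'   dialect (`"edgeR_glm"` for edger — pass `"edgeR_exact"` for
#'   exact-test output).
#' @return data.frame of unified DE records: `gene_id`, `gene_name`,
#'   `log2fc`, `p_value`, `fdr`, `fdr_imputed`, `method`, plus
#'   `value_1`/`value_2`/`sample_1`/`sample_2` for cuffdiff.
#' @export
parse_de_output <- function(path, dialect = c("cuffdiff", "edger", "deseq2"),
                            method = NULL) {
  dialect <- match.arg(dialect)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- switch(dialect,
    cuffdiff = c("gene_id", "gene", "locus", "value_1", "value_2",
                 "log2(fold_change)", "p_value", "q_value"),
    edger = c("logFC", "PValue", "FDR"),
    deseq2 = c("log2FoldChange", "pvalue", "padj"))
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("file does not match dialect '", dialect,
         "': missing column '", miss[1L], "'")
  gene_col <- function() {
    for (cand in c("gene_id", "gene", "id"))
      if (cand %in% names(d)) return(d[[cand]])
    d[[1L]]
  }
  out <- switch(dialect,
    cuffdiff = data.frame(
      gene_id = d$gene_id, gene_name = d$gene,
      chrom_location = d$locus,
      log2fc = as.numeric(d[["log2(fold_change)"]]),
      p_value = as.numeric(d$p_value), fdr = as.numeric(d$q_value),
      sample_1 = d$sample_1 %||% NA_character_,
      sample_2 = d$sample_2 %||% NA_character_,
      value_1 = as.numeric(d$value_1), value_2 = as.numeric(d$value_2),
      stringsAsFactors = FALSE),
    edger = data.frame(
      gene_id = gene_col(), gene_name = NA_character_,
      chrom_location = NA_character_,
      log2fc = as.numeric(d$logFC),
      p_value = as.numeric(d$PValue), fdr = as.numeric(d$FDR),
      stringsAsFactors = FALSE),
    deseq2 = data.frame(
      gene_id = gene_col(), gene_name = NA_character_,
      chrom_location = NA_character_,
      log2fc = as.numeric(d$log2FoldChange),
      p_value = as.numeric(d$pvalue), fdr = as.numeric(d$padj),
      stringsAsFactors = FALSE))
  out$fdr_imputed <- is.na(out$fdr)
  out$fdr[out$fdr_imputed] <- 1.0
  out$method <- method %||% switch(dialect, cuffdiff = "cuffdiff",
                                   edger = "edgeR_glm", deseq2 = "deseq2")
  if (!out$method[1L] %in% c("cuffdiff", "edgeR_glm", "edgeR_exact",
                             "deseq2"))
    stop("method must be one of cuffdiff, edgeR_glm, edgeR_exact, deseq2")
  out
}

#' Build the unified annotated DE table and the DE-only locus set
#'
#' Joins DE records with the annotated locus set (gene name, biotype,
#' chromosomal location) and the read-count matrix, sorts by FDR then
#' gene id, and selects the differentially expressed loci
#' (`fdr < alpha`) whose models can be written as a GTF via
#' [write_gtf()].
#'
#' @param records data.frame from [parse_de_output()].
#' @param loci list of annotated `GeneLocus` (e.g. from
#'   [annotate_biotypes()]).
#' @param counts optional gene x sample count matrix; columns are appended
#'   as `count.<sample>`.
#' @param alpha FDR threshold for the DE-only set; default 0.05.
#' @return list with `table` (the unified data.frame) and `de_loci` (list
#'   of `GeneLocus` with `fdr < alpha`). Gene ids absent from `loci` get
#'   biotype `"unknown"` and are listed in attribute `unresolved`.
#' @export
build_unified_table <- function(records, loci, counts = NULL, alpha = 0.05) {
  loci_ids <- vapply(loci, `[[`, character(1), "gene_id")
  by_id <- stats::setNames(loci, loci_ids)
  tab <- records
  n <- nrow(tab)
  tab$biotype <- rep("unknown", length.out = n)
  tab$locus_class <- rep(NA_character_, length.out = n)
  unresolved <- character(0)
  for (i in seq_len(nrow(tab))) {
    loc <- by_id[[tab$gene_id[i]]]
    if (is.null(loc)) {
      unresolved <- c(unresolved, tab$gene_id[i])
      next
    }
    tab$biotype[i] <- loc$biotype
    tab$locus_class[i] <- loc$locus_class
    if (is.na(tab$gene_name[i]) || tab$gene_name[i] == "-")
      tab$gene_name[i] <- loc$gene_name
    tab$chrom_location[i] <- sprintf("%s:%d-%d(%s)", loc$chrom, loc$start,
                                     loc$end, loc$strand)
  }
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    for (s in colnames(counts)) {
      v <- rep(NA_integer_, nrow(tab))
      hit <- tab$gene_id %in% rownames(counts)
      v[hit] <- counts[tab$gene_id[hit], s]
      tab[[paste0("count.", s)]] <- v
    }
  }
  if (nrow(tab))
    tab <- tab[order(tab$fdr, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  de_ids <- tab$gene_id[tab$fdr < alpha]
  de_loci <- unname(by_id[intersect(names(by_id), de_ids)])
  structure(list(table = tab, de_loci = de_loci),
            unresolved = unique(unresolved))
}

#' Fold-change concordance between two measurement series
#'
#' Pearson correlation between paired fold changes (e.g. an RNA-seq
#' method versus qRT-PCR for the same genes), its square (the coefficient
#' of determination R^2), and the fraction of pairs whose fold-change
#' signs agree (zero counted as positive). Non-finite pairs (e.g.
#' infinite fold changes from zero-count genes) are dropped with a
#' warning.
#'
#' @param x,y numeric vectors of equal length; at least 3 finite pairs.
#' @return list of class `ConcordanceResult`: `n`, `r`, `r_squared`,
#'   `sign_agreement`.
#' @export
concordance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  fin <- is.finite(x) & is.finite(y)
  if (!all(fin)) {
    warning(sum(!fin), " non-finite pair(s) excluded from concordance")
    x <- x[fin]
    y <- y[fin]
  }
  if (length(x) < 3L) stop("need at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in one input")
  r <- stats::cor(x, y)
  sgn <- function(v) ifelse(v >= 0, 1L, -1L)
  structure(list(n = length(x), r = r, r_squared = r^2,
                 sign_agreement = mean(sgn(x) == sgn(y))),
            class = "ConcordanceResult")
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat(sprintf("Concordance over %d pairs: r = %.3f, R^2 = %.3f, sign agreement = %.3f\n",
              x$n, x$r, x$r_squared, x$sign_agreement))
  invisible(x)
}

#' Bundled RNA-seq vs qRT-PCR fold-change validation table
#'
#' Log2 (RNA-seq) and qRT-PCR fold changes for genes validated in three
#' published bulk RNA-seq experiments (human Alzheimer's-disease
#' hippocampus, embryonic vs adult mouse cortex, and a rat liver
#' toxicology study), each quantified with four differential-expression
#' workflows (Cuffdiff, edgeR GLM, edgeR exact test, DESeq2). The rat
#' qRT-PCR column is on a different fold-change scale than its RNA-seq
#' columns and is unsuitable for R^2 comparison across methods.
#'
#' @return data.frame with columns `dataset`, `gene`, `cuffdiff`,
#'   `edger_glm`, `edger_exact`, `deseq2`, `qpcr`.
#' @export
qpcr_validation_data <- function() {
  path <- system.file("extdata", "qpcr_fold_changes.tsv",
                      package = "rnaseqtk", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
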