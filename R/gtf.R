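#' Read a GTF file into gene loci
#'
#' Parses exon records of a tab-delimited GTF (2.2) file and groups them
#' into transcripts and gene loci. Two dialects are understood:
#' `"reference"` for an ENSEMBL-style annotation carrying `gene_biotype`
#' and `gene_name` attributes, and `"assembled"` for Cufflinks-style
#' per-sample assemblies carrying an `FPKM` attribute. Unknown attributes
#' are preserved verbatim and written back by [write_gtf()].
#'
#' Gzip- and bzip2-compressed files are decompressed transparently based on
#' the `.gz` / `.bz2` extension.
#'
#' @param path GTF file path.
#' @param dialect `"reference"` or `"assembled"`.
#' @param sample_id for assembled dialect: the sample whose FPKM the file's
#'   `FPKM` attribute represents. Defaults to the file's base name.
#' @return list of [gene_locus()] objects; transcripts grouped by
#'   `gene_id`, exons sorted ascending by start.
#' @export
read_gtf <- function(path, dialect = c("reference", "assembled"),
                     sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.(gtf|gff)(\\.(gz|bz2))?$", "", basename(path))
  lines <- readLines(open_maybe_compressed(path))
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(list())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop("malformed GTF line ", lineno[which(nf < 9L)[1L]],
         ": expected 9 tab-delimited fields, got ", nf[which(nf < 9L)[1L]])
  m <- do.call(rbind, fields)
  feature <- m[, 3L]
  ex <- feature == "exon"
  if (!any(ex)) return(list())
  m <- m[ex, , drop = FALSE]
  lineno <- lineno[ex]

  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed GTF line ", lineno[bad[1L]], ": non-numeric coordinates")
  bad <- which(start > end)
  if (length(bad))
    stop("validation error at GTF line ", lineno[bad[1L]],
         ": exon start > end (", start[bad[1L]], " > ", end[bad[1L]], ")")
  strand <- m[, 7L]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop("malformed GTF line ", lineno[bad[1L]],
         ": strand must be '+' or '-'")

  attrs <- lapply(seq_len(nrow(m)), function(i)
    parse_gtf_attributes(m[i, 9L], lineno[i]))
  tid <- vapply(attrs, function(a)
    unname(a["transcript_id"] %||% NA_character_), character(1))
  gid <- vapply(attrs, function(a)
    unname(a["gene_id"] %||% NA_character_), character(1))
  if (anyNA(tid))
    stop("parse error at GTF line ", lineno[which(is.na(tid))[1L]],
         ": record missing transcript_id")
  if (anyNA(gid))
    stop("parse error at GTF line ", lineno[which(is.na(gid))[1L]],
         ": record missing gene_id")

  fpkm_missing <- FALSE
  txs <- lapply(split(seq_along(tid), factor(tid, levels = unique(tid))),
                function(idx) {
    a <- attrs[[idx[1L]]]
    extra <- a[setdiff(names(a), c("gene_id", "transcript_id"))]
    fpkm <- numeric(0)
    if (dialect == "assembled") {
      if ("FPKM" %in% names(a)) {
        fpkm <- stats::setNames(as.numeric(a[["FPKM"]]), sample_id)
      } else {
        fpkm_missing <<- TRUE
        fpkm <- stats::setNames(0.0, sample_id)
      }
    }
    transcript_model(tid[idx[1L]], gid[idx[1L]],
                     chrom = m[idx[1L], 1L], strand = strand[idx[1L]],
                     starts = start[idx], ends = end[idx],
                     fpkm_by_sample = fpkm, attributes = extra)
  })
  if (fpkm_missing)
    warning("assembled GTF '", basename(path),
            "': transcripts without FPKM attribute; abundance set to 0")

  loci <- lapply(split(txs, factor(gid[!duplicated(tid)],
                                   levels = unique(gid))),
                 function(member_txs) {
    a1 <- member_txs[[1L]]$attributes
    gene_locus(member_txs[[1L]]$gene_id, unname(member_txs),
               gene_name = unname(a1["gene_name"] %||%
                                    member_txs[[1L]]$gene_id),
               biotype = unname(a1["gene_biotype"] %||%
                                  if (dialect == "reference") "unknown"
                                  else "novel"),
               locus_class = if (dialect == "reference") "annotated"
                             else NA_character_)
  })
  unname(loci)
}

#' Write gene loci as a GTF file
#'
#' Emits one `exon` row per exon with attributes serialized in the order
#' `gene_id`, `transcript_id`, then remaining keys alphabetically, so that
#' output is deterministic and write/read/write is a fixed point. Records
#' are ordered by (chromosome, transcript start, transcript_id); exons
#' ascend within each transcript.
#'
#' @param loci list of [gene_locus()] objects (may be empty).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(loci, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  writeLines("##format: gtf", con)
  txs <- loci_transcripts(loci)
  if (length(txs) == 0L) return(invisible(path))
  ord <- order(vapply(txs, `[[`, character(1), "chrom"),
               vapply(txs, function(t) min(t$exons$start), integer(1)),
               vapply(txs, `[[`, character(1), "transcript_id"))
  for (t in txs[ord]) {
    extra <- t$attributes
    if (length(extra)) extra <- extra[order(names(extra))]
    attr_str <- paste0(
      'gene_id "', t$gene_id, '"; transcript_id "', t$transcript_id, '";',
      if (length(extra))
        paste0(" ", paste0(names(extra), ' "', extra, '";', collapse = " "))
      else "")
    writeLines(sprintf("%s\trnaseqtk\texon\t%d\t%d\t.\t%s\t.\t%s",
                       t$chrom, t$exons$start, t$exons$end, t$strand,
                       attr_str), con)
  }
  invisible(path)
}

# `key "value";` pairs; unquoted values tolerated
parse_gtf_attributes <- function(s, lineno) {
  s <- trimws(s)
  if (s == "")
    stop("parse error at GTF line ", lineno, ": empty attribute field")
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  parts <- trimws(parts)
  parts <- parts[parts != ""]
  mm <- regmatches(parts, regexec('^(\\S+)\\s+"?([^"]*)"?$', parts))
  bad <- which(lengths(mm) != 3L)
  if (length(bad))
    stop("parse error at GTF line ", lineno, ": cannot parse attribute '",
         parts[bad[1L]], "'")
  stats::setNames(vapply(mm, `[`, character(1), 3L),
                  vapply(mm, `[`, character(1), 2L))
}

open_maybe_compressed <- function(path) {
  if (grepl("\\.bz2$", path)) bzfile(path) else gzfile(path)
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || (length(a) == 1L && is.na(a))) b else a
}
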