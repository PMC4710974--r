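#' Merge assembled transcripts across samples
#'
#' Collapses per-sample ab initio assemblies into one non-redundant
#' transcript set, recording which samples each structure was observed in.
#' Multi-exon transcripts collapse when their intron chains (the ordered
#' set of donor/acceptor pairs) are identical on the same chromosome and
#' strand; terminal exon ends are merged to the union. Single-exon
#' transcripts collapse transitively when their exons overlap by at least
#' 1 bp on the same strand, the merged exon spanning the union.
#'
#' Merged transcripts are regrouped into loci by same-strand span overlap
#' and assigned deterministic `XLOC_nnnnnn` / `TMERGE_nnnnnn` identifiers
#' in genomic order; contributing transcript ids are kept in the
#' `contributors` attribute. Per-sample FPKM maps are combined (maximum on
#' collision within a sample).
#'
#' @param per_sample named list: sample_id -> list of [gene_locus()]
#'   objects, as returned by [read_gtf()] with `dialect = "assembled"`.
#' @return list of `GeneLocus`. Each transcript carries `present_in`
#'   (character vector of contributing samples) and the result carries
#'   attribute `n_samples`. See [sample_presence()].
#' @export
merge_samples <- function(per_sample) {
  if (!is.list(per_sample) || length(per_sample) == 0L ||
      is.null(names(per_sample)) || any(names(per_sample) == ""))
    stop("per_sample must be a non-empty named list of loci lists")
  samples <- sort(names(per_sample))
  n_samples <- length(samples)

  entries <- list()
  for (s in samples) {
    for (tx in loci_transcripts(per_sample[[s]])) {
      tx$present_in <- s
      entries[[length(entries) + 1L]] <- tx
    }
  }
  if (length(entries) == 0L) stop("no transcripts in any sample")

  multi <- entries[vapply(entries, function(t) nrow(t$exons) > 1L, logical(1))]
  single <- entries[vapply(entries, function(t) nrow(t$exons) == 1L, logical(1))]

  merged <- list()
  # multi-exon: exact intron-chain identity
  if (length(multi)) {
    keys <- vapply(multi, tx_structure_key, character(1))
    for (idx in split(seq_along(multi), factor(keys, levels = unique(keys)))) {
      grp <- multi[idx]
      rep_tx <- grp[[1L]]
      rep_tx$exons$start[1L] <-
        min(vapply(grp, function(t) t$exons$start[1L], integer(1)))
      n <- nrow(rep_tx$exons)
      rep_tx$exons$end[n] <-
        max(vapply(grp, function(t) t$exons$end[nrow(t$exons)], integer(1)))
      merged[[length(merged) + 1L]] <- merge_group_metadata(rep_tx, grp)
    }
  }
  # single-exon: transitive >=1 bp same-strand overlap
  if (length(single)) {
    gr <- GenomicRanges::GRanges(
      seqnames = vapply(single, `[[`, character(1), "chrom"),
      ranges = IRanges::IRanges(
        start = vapply(single, function(t) t$exons$start[1L], integer(1)),
        end = vapply(single, function(t) t$exons$end[1L], integer(1))),
      strand = vapply(single, `[[`, character(1), "strand"))
    red <- GenomicRanges::reduce(gr)
    hit <- GenomicRanges::findOverlaps(gr, red)
    cl <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    for (k in sort(unique(cl))) {
      grp <- single[cl == k]
      rep_tx <- grp[[1L]]
      rep_tx$exons <- data.frame(
        start = GenomicRanges::start(red)[k],
        end = GenomicRanges::end(red)[k])
      merged[[length(merged) + 1L]] <- merge_group_metadata(rep_tx, grp)
    }
  }

  # deterministic transcript ids in genomic order
  ord <- order(vapply(merged, `[[`, character(1), "chrom"),
               vapply(merged, function(t) t$exons$start[1L], integer(1)),
               vapply(merged, function(t) t$exons$end[nrow(t$exons)],
                      integer(1)),
               vapply(merged, tx_structure_key, character(1)))
  merged <- merged[ord]
  for (i in seq_along(merged))
    merged[[i]]$transcript_id <- sprintf("TMERGE_%06d", i)

  out <- group_transcripts_into_loci(merged, id_prefix = "XLOC")
  attr(out, "n_samples") <- n_samples
  attr(out, "samples") <- samples
  out
}

merge_group_metadata <- function(rep_tx, grp) {
  pres <- sort(unique(unlist(lapply(grp, `[[`, "present_in"))))
  fpkm <- numeric(0)
  for (t in grp) for (s in names(t$fpkm_by_sample))
    fpkm[s] <- max(fpkm[s] %||% 0, t$fpkm_by_sample[[s]], na.rm = TRUE)
  rep_tx$present_in <- pres
  rep_tx$fpkm_by_sample <- if (length(fpkm)) fpkm[order(names(fpkm))]
                           else fpkm
  contributors <- sort(unique(vapply(grp, `[[`, character(1),
                                     "transcript_id")))
  rep_tx$attributes <- c(rep_tx$attributes[setdiff(names(rep_tx$attributes),
                                                   c("contributors", "FPKM"))],
                         contributors = paste(contributors, collapse = ","))
  rep_tx
}

#' Sample-presence table of a merged transcript set
#'
#' @param loci result of [merge_samples()].
#' @return data.frame with columns `transcript_id`, `present_in`
#'   (comma-separated sample ids), `n_present`, `n_samples`.
#' @export
sample_presence <- function(loci) {
  txs <- loci_transcripts(loci)
  n_samples <- attr(loci, "n_samples") %||%
    length(unique(unlist(lapply(txs, `[[`, "present_in"))))
  data.frame(
    transcript_id = vapply(txs, `[[`, character(1), "transcript_id"),
    present_in = vapply(txs, function(t)
      paste(sort(t$present_in %||% character(0)), collapse = ","),
      character(1)),
    n_present = vapply(txs, function(t)
      length(t$present_in %||% character(0)), integer(1)),
    n_samples = n_samples,
    stringsAsFactors = FALSE)
}
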