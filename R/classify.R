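#' Classify an assembled transcript against the reference annotation
#'
#' Assigns one of five class codes describing how a transcript relates to
#' the reference, with fixed precedence:
#'
#' 1. `equal` — intron chain identical to a reference transcript on the
#'    same strand (single-exon transcripts: same-strand exonic overlap
#'    with a single-exon reference transcript);
#' 2. `novel_isoform` — shares at least one intron (donor/acceptor pair)
#'    with a same-strand reference transcript;
#' 3. `intronic` — falls entirely inside one intron of a same-strand
#'    reference transcript;
#' 4. `novel_isoform` (overlap form) — exonic overlap with a same-strand
#'    reference gene without any shared intron (the five-code alphabet
#'    must partition, and such transcripts are isoform-like fragments of
#'    an annotated gene);
#' 5. `antisense` — exonic overlap only with opposite-strand reference
#'    genes;
#' 6. `intergenic` — no exonic overlap with any reference gene.
#'
#' `matched_gene_id` is the reference gene supporting the call (largest
#' exonic overlap, ties to the lexicographically smallest id) and is `NA`
#' exactly for `intergenic` transcripts.
#'
#' @param tx a `TranscriptModel`.
#' @param reference list of reference [gene_locus()] objects, or a
#'   prebuilt index from [reference_index()].
#' @return list with elements `code` and `matched_gene_id`.
#' @seealso [classify_transcripts()] for the vectorized form.
#' @export
classify_vs_reference <- function(tx, reference) {
  idx <- if (inherits(reference, "reference_index")) reference
         else reference_index(reference)
  classify_one(tx, idx)
}

#' Build a reusable classification index over a reference annotation
#'
#' @param reference list of reference `GeneLocus` objects.
#' @return opaque index object for [classify_vs_reference()].
#' @export
reference_index <- function(reference) {
  txs <- loci_transcripts(reference)
  exons <- loci_exon_granges(reference)
  introns <- list(gr = GenomicRanges::GRanges())
  jn <- character(0)
  if (length(txs)) {
    jdf <- do.call(rbind, lapply(txs, function(t) {
      j <- junctions(t)
      if (nrow(j)) j$gene_id <- t$gene_id
      j
    }))
    if (!is.null(jdf) && nrow(jdf)) {
      jn <- paste(jdf$chrom, jdf$strand, jdf$donor, jdf$acceptor, sep = "|")
      introns$gr <- GenomicRanges::GRanges(
        seqnames = jdf$chrom,
        ranges = IRanges::IRanges(jdf$donor + 1L, jdf$acceptor - 1L),
        strand = jdf$strand, gene_id = jdf$gene_id)
      introns$key_gene <- stats::setNames(jdf$gene_id, jn)
    }
  }
  chains <- stats::setNames(
    vapply(txs, `[[`, character(1), "gene_id"),
    vapply(txs, tx_structure_key, character(1)))
  single_exon_ref <- txs[vapply(txs, function(t) nrow(t$exons) == 1L,
                                logical(1))]
  structure(list(exons = exons, junction_keys = unique(jn),
                 junction_gene = if (length(jn)) introns$key_gene else
                   stats::setNames(character(0), character(0)),
                 introns = introns$gr, chains = chains,
                 single_exon = single_exon_ref),
            class = "reference_index")
}

classify_one <- function(tx, idx) {
  tx_gr <- GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(tx$exons$start, tx$exons$end),
    strand = tx$strand)
  # exonic overlaps, same and opposite strand
  same_hit <- suppressWarnings(
    GenomicRanges::findOverlaps(tx_gr, idx$exons, ignore.strand = FALSE))
  any_hit <- suppressWarnings(
    GenomicRanges::findOverlaps(tx_gr, idx$exons, ignore.strand = TRUE))
  same_genes <- unique(idx$exons$gene_id[S4Vectors::subjectHits(same_hit)])
  anti_idx <- setdiff(S4Vectors::subjectHits(any_hit),
                      S4Vectors::subjectHits(same_hit))
  anti_genes <- unique(idx$exons$gene_id[anti_idx])

  overlap_bp <- function(sub_hits) {
    if (length(sub_hits) == 0L) return(stats::setNames(numeric(0), character(0)))
    ov <- suppressWarnings(GenomicRanges::pintersect(
      tx_gr[S4Vectors::queryHits(sub_hits)],
      idx$exons[S4Vectors::subjectHits(sub_hits)]))
    tapply(GenomicRanges::width(ov),
           idx$exons$gene_id[S4Vectors::subjectHits(sub_hits)], sum)
  }
  best_gene <- function(genes, hits) {
    if (length(genes) == 0L) return(NA_character_)
    bp <- overlap_bp(hits)
    bp <- bp[names(bp) %in% genes]
    cand <- names(bp)[bp == max(bp)]
    sort(cand)[1L]
  }

  key <- tx_structure_key(tx)
  n_ex <- nrow(tx$exons)

  # 1. equal
  if (n_ex > 1L) {
    if (key %in% names(idx$chains))
      return(list(code = "equal",
                  matched_gene_id = unname(idx$chains[[key]])))
  } else if (length(idx$single_exon)) {
    for (rt in idx$single_exon) {
      if (rt$chrom == tx$chrom && rt$strand == tx$strand &&
          rt$exons$start[1L] <= tx$exons$end[1L] &&
          rt$exons$end[1L] >= tx$exons$start[1L])
        return(list(code = "equal", matched_gene_id = rt$gene_id))
    }
  }
  # 2. novel_isoform via shared intron
  j <- junctions(tx)
  if (nrow(j)) {
    jk <- paste(j$chrom, j$strand, j$donor, j$acceptor, sep = "|")
    shared <- jk[jk %in% idx$junction_keys]
    if (length(shared))
      return(list(code = "novel_isoform",
                  matched_gene_id = unname(sort(
                    idx$junction_gene[shared])[1L])))
  }
  # 3. intronic: whole span inside one intron, same strand
  if (length(idx$introns)) {
    span_gr <- GenomicRanges::GRanges(
      tx$chrom, IRanges::IRanges(min(tx$exons$start), max(tx$exons$end)),
      strand = tx$strand)
    within <- suppressWarnings(
      GenomicRanges::findOverlaps(span_gr, idx$introns, type = "within",
                                  ignore.strand = FALSE))
    if (length(within) > 0L)
      return(list(code = "intronic",
                  matched_gene_id = sort(unique(
                    idx$introns$gene_id[S4Vectors::subjectHits(within)]))[1L]))
  }
  # 4. same-strand exonic overlap without shared intron -> isoform-like
  if (length(same_genes))
    return(list(code = "novel_isoform",
                matched_gene_id = best_gene(same_genes, same_hit)))
  # 5. antisense
  if (length(anti_genes)) {
    anti_hits <- any_hit[S4Vectors::subjectHits(any_hit) %in% anti_idx]
    return(list(code = "antisense",
                matched_gene_id = best_gene(anti_genes, anti_hits)))
  }
  # 6. intergenic
  list(code = "intergenic", matched_gene_id = NA_character_)
}

#' Classify every transcript of a locus set against the reference
#'
#' @param loci list of `GeneLocus` (e.g. from [merge_samples()]).
#' @param reference reference loci or a [reference_index()].
#' @return data.frame with columns `transcript_id`, `gene_id` (the query
#'   locus), `code`, `matched_gene_id`.
#' @export
classify_transcripts <- function(loci, reference) {
  idx <- if (inherits(reference, "reference_index")) reference
         else reference_index(reference)
  txs <- loci_transcripts(loci)
  res <- lapply(txs, classify_one, idx = idx)
  data.frame(
    transcript_id = vapply(txs, `[[`, character(1), "transcript_id"),
    gene_id = vapply(txs, `[[`, character(1), "gene_id"),
    code = vapply(res, `[[`, character(1), "code"),
    matched_gene_id = vapply(res, function(r)
      r$matched_gene_id %||% NA_character_, character(1)),
    stringsAsFactors = FALSE)
}
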