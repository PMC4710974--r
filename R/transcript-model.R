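#' Construct a transcript model
#'
#' A transcript model is the unit every other tool in the package operates
#' on: an ordered exon chain on one strand of one chromosome, linked to a
#' gene, optionally carrying per-sample abundance (FPKM) and arbitrary GTF
#' attributes.
#'
#' Coordinates are GTF-native: 1-based, inclusive at both ends. Exons are
#' stored sorted by start and must not overlap; the gap between consecutive
#' exons (the intron) must be at least 1 bp.
#'
#' @param transcript_id character scalar.
#' @param gene_id character scalar.
#' @param chrom chromosome/contig name.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends integer vectors of equal length: exon coordinates,
#'   1-based inclusive.
#' @param fpkm_by_sample named numeric vector of non-negative abundances,
#'   one entry per sample (may be empty).
#' @param attributes named character vector of extra GTF attributes,
#'   preserved verbatim on round-trip.
#' @return an object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             starts, ends,
                             fpkm_by_sample = numeric(0),
                             attributes = character(0)) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(gene_id), length(gene_id) == 1L,
            length(chrom) == 1L, length(strand) == 1L)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got '", strand, "'")
  starts <- as.integer(starts)
  ends <- as.integer(ends)
  if (length(starts) == 0L)
    stop("transcript '", transcript_id, "' must have at least one exon")
  if (length(starts) != length(ends))
    stop("starts and ends differ in length")
  if (any(starts > ends))
    stop("exon with start > end in transcript '", transcript_id, "'")
  ord <- order(starts)
  starts <- starts[ord]
  ends <- ends[ord]
  if (length(starts) > 1L && any(starts[-1L] - ends[-length(ends)] < 2L))
    stop("overlapping or abutting exons (intron length < 1) in transcript '",
         transcript_id, "'")
  if (length(fpkm_by_sample) && any(fpkm_by_sample < 0))
    stop("negative FPKM in transcript '", transcript_id, "'")
  structure(list(
    transcript_id = transcript_id,
    gene_id = gene_id,
    chrom = as.character(chrom),
    strand = strand,
    exons = data.frame(start = starts, end = ends),
    fpkm_by_sample = fpkm_by_sample,
    attributes = attributes
  ), class = "TranscriptModel")
}

#' Construct a gene locus
#'
#' A gene locus groups transcripts sharing a chromosome and strand, carries
#' the gene's biotype (ENSEMBL vocabulary, or a `novel_*` class for loci
#' discovered from assembly) and, once classified, a locus class.
#'
#' @param gene_id,gene_name character scalars.
#' @param transcripts list of [transcript_model()] objects, all on the same
#'   chromosome and strand.
#' @param biotype gene biotype string; `"unknown"` when the reference does
#'   not supply one.
#' @param locus_class one of `"annotated"`, `"novel_coding_candidate"`,
#'   `"novel_lincRNA"`, `"novel_antisense"`, or `NA` before classification.
#' @return an object of class `GeneLocus` with a `span` covering all exons.
#' @export
gene_locus <- function(gene_id, transcripts, gene_name = gene_id,
                       biotype = "unknown", locus_class = NA_character_) {
  stopifnot(is.list(transcripts), length(transcripts) >= 1L)
  if (!all(vapply(transcripts, inherits, logical(1), "TranscriptModel")))
    stop("all transcripts must be TranscriptModel objects")
  chrom <- unique(vapply(transcripts, `[[`, character(1), "chrom"))
  strand <- unique(vapply(transcripts, `[[`, character(1), "strand"))
  if (length(chrom) != 1L || length(strand) != 1L)
    stop("locus '", gene_id, "': transcripts must share chromosome and strand")
  ok_classes <- c("annotated", "novel_coding_candidate",
                  "novel_lincRNA", "novel_antisense")
  if (!is.na(locus_class) && !locus_class %in% ok_classes)
    stop("invalid locus_class '", locus_class, "'")
  starts <- vapply(transcripts, function(t) min(t$exons$start), integer(1))
  ends <- vapply(transcripts, function(t) max(t$exons$end), integer(1))
  structure(list(
    gene_id = gene_id,
    gene_name = gene_name,
    biotype = biotype,
    transcripts = transcripts,
    locus_class = locus_class,
    chrom = chrom,
    start = min(starts),
    end = max(ends),
    strand = strand
  ), class = "GeneLocus")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (gene %s) %s:%d-%d(%s), %d exon(s)\n",
              x$transcript_id, x$gene_id, x$chrom,
              min(x$exons$start), max(x$exons$end), x$strand,
              nrow(x$exons)))
  invisible(x)
}

#' @export
print.GeneLocus <- function(x, ...) {
  cat(sprintf("GeneLocus %s [%s/%s] %s:%d-%d(%s), %d transcript(s)\n",
              x$gene_id, x$biotype,
              ifelse(is.na(x$locus_class), "unclassified", x$locus_class),
              x$chrom, x$start, x$end, x$strand, length(x$transcripts)))
  invisible(x)
}

# ---- internal helpers over the model ---------------------------------------

#' Exon-exon junctions of a transcript
#'
#' @param tx a `TranscriptModel`.
#' @return data.frame with columns chrom, donor (last base of the upstream
#'   exon, genomic orientation), acceptor (first base of the downstream
#'   exon) and strand; zero rows for a single-exon transcript.
#' @export
junctions <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L)
    return(data.frame(chrom = character(0), donor = integer(0),
                      acceptor = integer(0), strand = character(0)))
  data.frame(chrom = tx$chrom,
             donor = tx$exons$end[-n],
             acceptor = tx$exons$start[-1L],
             strand = tx$strand,
             stringsAsFactors = FALSE)
}

# canonical structure key: identical keys <=> identical intron chain on the
# same chrom/strand (multi-exon), or placeholder for single-exon
tx_structure_key <- function(tx) {
  j <- junctions(tx)
  if (nrow(j) == 0L)
    return(paste0(tx$chrom, "|", tx$strand, "|SE"))
  paste0(tx$chrom, "|", tx$strand, "|",
         paste(j$donor, j$acceptor, sep = "-", collapse = ","))
}

tx_span <- function(tx) c(min(tx$exons$start), max(tx$exons$end))

#' Flatten loci to a list of transcripts
#' @param loci list of `GeneLocus`.
#' @return flat list of `TranscriptModel` objects.
#' @export
loci_transcripts <- function(loci) {
  unlist(lapply(loci, `[[`, "transcripts"), recursive = FALSE)
}

# exon-level GRanges for a list of loci, with transcript/gene metadata
loci_exon_granges <- function(loci) {
  txs <- loci_transcripts(loci)
  gene_of <- rep(vapply(loci, `[[`, character(1), "gene_id"),
                 vapply(loci, function(l) length(l$transcripts), integer(1)))
  n_ex <- vapply(txs, function(t) nrow(t$exons), integer(1))
  if (length(txs) == 0L || sum(n_ex) == 0L)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = rep(vapply(txs, `[[`, character(1), "chrom"), n_ex),
    ranges = IRanges::IRanges(
      start = unlist(lapply(txs, function(t) t$exons$start)),
      end = unlist(lapply(txs, function(t) t$exons$end))),
    strand = rep(vapply(txs, `[[`, character(1), "strand"), n_ex),
    transcript_id = rep(vapply(txs, `[[`, character(1), "transcript_id"), n_ex),
    gene_id = rep(gene_of, n_ex))
}

# group a flat transcript list into loci by same-strand span overlap
# (transitive closure via reduce); gene ids assigned in genomic order
group_transcripts_into_loci <- function(txs, id_prefix = "XLOC") {
  if (length(txs) == 0L) return(list())
  spans <- GenomicRanges::GRanges(
    seqnames = vapply(txs, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(txs, function(t) min(t$exons$start), integer(1)),
      end = vapply(txs, function(t) max(t$exons$end), integer(1))),
    strand = vapply(txs, `[[`, character(1), "strand"))
  clusters <- GenomicRanges::reduce(spans)
  hit <- GenomicRanges::findOverlaps(spans, clusters)
  cl <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  # order clusters genomically for deterministic ids
  cl_ord <- order(as.character(GenomicRanges::seqnames(clusters)),
                  GenomicRanges::start(clusters),
                  as.character(GenomicRanges::strand(clusters)))
  rank_of <- integer(length(clusters))
  rank_of[cl_ord] <- seq_along(cl_ord)
  lapply(split(seq_along(txs), rank_of[cl]), function(idx) {
    gid <- sprintf("%s_%06d", id_prefix, rank_of[cl[idx[1L]]])
    members <- lapply(txs[idx], function(t) { t$gene_id <- gid; t })
    gene_locus(gid, members, biotype = "unknown")
  })
}
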