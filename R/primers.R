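#' Splice junctions shared by every isoform of a gene
#'
#' Returns the intersection of the isoforms' junction sets (same
#' chromosome, strand, donor and acceptor), sorted by genomic position.
#' Any single-exon isoform has an empty junction set, which forces an
#' empty intersection.
#'
#' @param isoforms list of `TranscriptModel`, all on one chromosome and
#'   strand.
#' @return data.frame with columns `chrom`, `donor`, `acceptor`, `strand`
#'   (possibly zero rows).
#' @export
common_junctions <- function(isoforms) {
  stopifnot(length(isoforms) >= 1L)
  strands <- unique(vapply(isoforms, `[[`, character(1), "strand"))
  chroms <- unique(vapply(isoforms, `[[`, character(1), "chrom"))
  if (length(strands) != 1L || length(chroms) != 1L)
    stop("isoforms must share one chromosome and strand")
  jsets <- lapply(isoforms, function(t) {
    j <- junctions(t)
    paste(j$donor, j$acceptor, sep = "-")
  })
  common <- Reduce(intersect, jsets)
  if (length(common) == 0L)
    return(data.frame(chrom = character(0), donor = integer(0),
                      acceptor = integer(0), strand = character(0)))
  parts <- do.call(rbind, strsplit(common, "-", fixed = TRUE))
  out <- data.frame(chrom = chroms, donor = as.integer(parts[, 1L]),
                    acceptor = as.integer(parts[, 2L]), strand = strands,
                    stringsAsFactors = FALSE)
  out[order(out$donor, out$acceptor), , drop = FALSE]
}

#' Longest exonic region shared by every isoform
#'
#' Intersects the exonic interval sets of all isoforms and returns the
#' longest resulting interval (ties to the smaller start), or `NULL` when
#' the intersection is empty.
#'
#' @inheritParams common_junctions
#' @return one-row data.frame (`chrom`, `start`, `end`, `strand`) or
#'   `NULL`.
#' @export
common_exonic_region <- function(isoforms) {
  stopifnot(length(isoforms) >= 1L)
  strands <- unique(vapply(isoforms, `[[`, character(1), "strand"))
  chroms <- unique(vapply(isoforms, `[[`, character(1), "chrom"))
  if (length(strands) != 1L || length(chroms) != 1L)
    stop("isoforms must share one chromosome and strand")
  ir <- Reduce(IRanges::intersect, lapply(isoforms, function(t)
    IRanges::reduce(IRanges::IRanges(t$exons$start, t$exons$end))))
  if (length(ir) == 0L) return(NULL)
  w <- IRanges::width(ir)
  best <- which(w == max(w))
  best <- best[which.min(IRanges::start(ir)[best])]
  data.frame(chrom = chroms, start = IRanges::start(ir)[best],
             end = IRanges::end(ir)[best], strand = strands,
             stringsAsFactors = FALSE)
}

#' Build the qPCR primer template for a gene
#'
#' Prefers a splice junction present in all isoforms: among common
#' junctions, the one maximizing the minimum exonic flank available in
#' every isoform is chosen (both primers must sit in sequence present in
#' every isoform), and up to `flank` spliced bases are extracted on each
#' side. When no common junction exists, the longest common exonic region
#' is used instead, provided it is at least 40 bp (two ~20-mers must fit).
#' The template is reported in transcript orientation.
#'
#' @param gene a `GeneLocus`.
#' @param genome FASTA path or [load_genome()] object.
#' @param flank maximum spliced bases per side of the junction; default
#'   150 (comfortably fits typical 60-200 bp qPCR amplicons).
#' @return a `PrimerTarget` list: `gene_id`, `kind`
#'   (`junction_spanning` / `common_exonic` / `failure`), `template_seq`,
#'   `junction_pos` (0-based offset of the first base after the junction,
#'   or `NA`), `flank`, and `reason` for failures.
#' @export
build_primer_target <- function(gene, genome, flank = 150L) {
  stopifnot(inherits(gene, "GeneLocus"), length(gene$transcripts) >= 1L,
            flank >= 1L)
  if (is.character(genome)) genome <- load_genome(genome)
  isoforms <- gene$transcripts
  strand <- gene$strand
  cj <- common_junctions(isoforms)

  if (nrow(cj) > 0L) {
    # flank available on each genomic side: length of the exon ending at
    # the donor / starting at the acceptor, minimized over isoforms
    avail <- t(vapply(seq_len(nrow(cj)), function(k) {
      up <- vapply(isoforms, function(t) {
        i <- match(cj$donor[k], t$exons$end)
        t$exons$end[i] - t$exons$start[i] + 1L
      }, integer(1))
      dn <- vapply(isoforms, function(t) {
        i <- match(cj$acceptor[k], t$exons$start)
        t$exons$end[i] - t$exons$start[i] + 1L
      }, integer(1))
      c(min(up), min(dn))
    }, integer(2)))
    score <- pmin(avail[, 1L], avail[, 2L])
    k <- which.max(score)  # ties: first by genomic position
    up <- min(avail[k, 1L], flank)
    dn <- min(avail[k, 2L], flank)
    exons <- data.frame(
      chrom = gene$chrom,
      start = c(cj$donor[k] - up + 1L, cj$acceptor[k]),
      end = c(cj$donor[k], cj$acceptor[k] + dn - 1L),
      strand = strand, stringsAsFactors = FALSE)
    template <- extract_sequence(genome, exons)
    junction_pos <- if (strand == "+") up else dn
    return(structure(list(gene_id = gene$gene_id, kind = "junction_spanning",
                          template_seq = template,
                          junction_pos = junction_pos,
                          flank = as.integer(flank), reason = NA_character_),
                     class = "PrimerTarget"))
  }

  cer <- common_exonic_region(isoforms)
  if (!is.null(cer) && cer$end - cer$start + 1L >= 40L) {
    exons <- data.frame(chrom = cer$chrom, start = cer$start, end = cer$end,
                        strand = strand, stringsAsFactors = FALSE)
    template <- extract_sequence(genome, exons)
    return(structure(list(gene_id = gene$gene_id, kind = "common_exonic",
                          template_seq = template,
                          junction_pos = NA_integer_,
                          flank = as.integer(flank), reason = NA_character_),
                     class = "PrimerTarget"))
  }
  structure(list(gene_id = gene$gene_id, kind = "failure",
                 template_seq = NA_character_, junction_pos = NA_integer_,
                 flank = as.integer(flank),
                 reason = "no common junction and no common exonic region >= 40 bp"),
            class = "PrimerTarget")
}

#' Pick a primer pair on a template
#'
#' A small deterministic primer-picking engine: candidate primers of
#' length 18-24 are scored on melting temperature (consensus formula
#' `64.9 + 41 * (GC - 16.4) / length`), GC fraction, homopolymer runs and
#' 3' clamp, and pairs are scored on Tm balance and product size. For
#' `junction_spanning` targets the left primer must lie entirely before
#' the junction and the right primer entirely after it, so the amplicon
#' necessarily contains `junction_pos`.
#'
#' @param target a `PrimerTarget` from [build_primer_target()].
#' @param params named list overriding engine defaults: `min_len`,
#'   `max_len`, `min_tm`, `max_tm`, `opt_tm`, `min_gc`, `max_gc`,
#'   `product_min`, `product_max`, `product_opt`, `max_homopolymer`.
#' @return list with `success`; on success `left_seq`, `right_seq`,
#'   `left_start`, `right_start` (0-based on the template, right primer
#'   given 5'->3' on the reverse strand), `product_size`; on failure
#'   `reason`.
#' @export
pick_primers <- function(target, params = list()) {
  if (target$kind == "failure")
    return(list(success = FALSE, reason = target$reason))
  if (is.na(target$template_seq) || nchar(target$template_seq) < 60L)
    stop("template must be at least 60 bp")
  p <- utils::modifyList(list(
    min_len = 18L, max_len = 24L, min_tm = 55, max_tm = 65, opt_tm = 60,
    min_gc = 0.35, max_gc = 0.65, product_min = 70L, product_max = 200L,
    product_opt = 120L, max_homopolymer = 4L), params)
  template <- toupper(target$template_seq)
  L <- nchar(template)
  jp <- target$junction_pos

  cand <- primer_candidates(template, p)
  if (nrow(cand) == 0L)
    return(list(success = FALSE, reason = "no acceptable primer candidates"))

  # left candidates on the forward strand; right on reverse complement
  left <- cand
  if (!is.na(jp)) left <- left[left$end0 < jp, , drop = FALSE]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(template)))
  rcand <- primer_candidates(rc, p)
  # map reverse-strand candidate to template coordinates
  rcand$t_start0 <- L - 1L - rcand$end0
  rcand$t_end0 <- L - 1L - rcand$start0
  right <- rcand
  if (!is.na(jp)) right <- right[right$t_start0 > jp, , drop = FALSE]
  if (nrow(left) == 0L || nrow(right) == 0L)
    return(list(success = FALSE, reason = "no primer on one side"))

  best <- NULL
  for (i in seq_len(nrow(left))) {
    prod <- right$t_end0 - left$start0[i] + 1L
    ok <- which(prod >= p$product_min & prod <= p$product_max)
    for (j in ok) {
      sc <- abs(left$tm[i] - p$opt_tm) + abs(right$tm[j] - p$opt_tm) +
        abs(left$tm[i] - right$tm[j]) +
        0.02 * abs(prod[j] - p$product_opt)
      if (is.null(best) || sc < best$score - 1e-9) {
        best <- list(score = sc, i = i, j = j, product = prod[j])
      }
    }
  }
  if (is.null(best))
    return(list(success = FALSE, reason = "no pair with acceptable product size"))
  list(success = TRUE,
       left_seq = left$seq[best$i],
       right_seq = right$seq[best$j],
       left_start = left$start0[best$i],
       right_start = right$t_start0[best$j],
       product_size = best$product,
       left_tm = left$tm[best$i],
       right_tm = right$tm[best$j])
}

# enumerate acceptable primers on one strand of a template
primer_candidates <- function(seq, p) {
  L <- nchar(seq)
  rows <- list()
  for (len in p$min_len:p$max_len) {
    if (len > L) next
    starts0 <- 0:(L - len)
    subs <- substring(seq, starts0 + 1L, starts0 + len)
    gc <- vapply(strsplit(subs, ""), function(ch)
      sum(ch %in% c("G", "C")) / length(ch), numeric(1))
    tm <- 64.9 + 41 * (gc * len - 16.4) / len
    run <- grepl(sprintf("A{%d}|C{%d}|G{%d}|T{%d}",
                         p$max_homopolymer + 1L, p$max_homopolymer + 1L,
                         p$max_homopolymer + 1L, p$max_homopolymer + 1L),
                 subs)
    clamp <- substring(subs, len, len) %in% c("G", "C")
    has_n <- grepl("N", subs, fixed = TRUE)
    ok <- gc >= p$min_gc & gc <= p$max_gc & tm >= p$min_tm & tm <= p$max_tm &
      !run & clamp & !has_n
    if (any(ok))
      rows[[length(rows) + 1L]] <- data.frame(
        seq = subs[ok], start0 = starts0[ok], end0 = starts0[ok] + len - 1L,
        tm = tm[ok], gc = gc[ok], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(seq = character(0), start0 = integer(0),
                      end0 = integer(0), tm = numeric(0), gc = numeric(0)))
  do.call(rbind, rows)
}

#' Design primers for a set of genes
#'
#' Convenience wrapper running [build_primer_target()] and
#' [pick_primers()] over each locus and collecting a primer table
#' (left/right layout).
#'
#' @param loci list of `GeneLocus`.
#' @param genome FASTA path or [load_genome()] object.
#' @param flank see [build_primer_target()].
#' @param params see [pick_primers()].
#' @return data.frame: `gene_id`, `kind`, `left_seq`, `right_seq`,
#'   `product_size`, `template_length`, `junction_pos`, `status`.
#' @export
design_primers <- function(loci, genome, flank = 150L, params = list()) {
  if (is.character(genome)) genome <- load_genome(genome)
  rows <- lapply(loci, function(loc) {
    tgt <- build_primer_target(loc, genome, flank)
    res <- if (tgt$kind == "failure") list(success = FALSE,
                                           reason = tgt$reason)
           else if (nchar(tgt$template_seq) < 60L)
             list(success = FALSE, reason = "template shorter than 60 bp")
           else pick_primers(tgt, params)
    data.frame(
      gene_id = loc$gene_id, kind = tgt$kind,
      left_seq = if (isTRUE(res$success)) res$left_seq else NA_character_,
      right_seq = if (isTRUE(res$success)) res$right_seq else NA_character_,
      product_size = if (isTRUE(res$success)) res$product_size else NA_integer_,
      template_length = if (tgt$kind == "failure") NA_integer_
                        else nchar(tgt$template_seq),
      junction_pos = tgt$junction_pos,
      status = if (isTRUE(res$success)) "ok" else res$reason,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
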