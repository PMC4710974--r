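# Independent brute-force oracles and tiny-fixture builders used across the
# suite. These deliberately avoid the package's own code paths (no IRanges,
# no shared helpers) so agreement is meaningful.

mk_tx <- function(id, chrom, strand, starts, ends, gene = id, ...) {
  transcript_model(id, gene, chrom, strand, starts, ends, ...)
}

mk_locus <- function(id, txs, ...) gene_locus(id, txs, ...)

write_tiny_genome <- function(seqs, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]])))
  writeLines(lines, path)
  path
}

# exhaustive ATG..stop enumeration over the three sense frames
oracle_longest_orf <- function(seq, require_stop = TRUE) {
  seq <- toupper(seq)
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(seq)
  best <- 0L
  for (start in seq_len(max(0L, L - 2L))) {
    if (substr(seq, start, start + 2L) != "ATG") next
    len <- 0L
    p <- start
    terminated <- FALSE
    while (p + 2L <= L) {
      codon <- substr(seq, p, p + 2L)
      if (grepl("N", codon, fixed = TRUE)) break
      if (codon %in% stops) { terminated <- TRUE; break }
      len <- len + 1L
      p <- p + 3L
    }
    if ((terminated || !require_stop) && len > best) best <- len
  }
  best
}

# naive exact 3'-adapter search at error rate 0
oracle_trim_pos <- function(seq, adapter, min_overlap) {
  L <- nchar(seq)
  A <- nchar(adapter)
  for (p in seq_len(L)) {
    k <- min(A, L - p + 1L)
    if (k < A && k < min_overlap) next
    if (substr(seq, p, p + k - 1L) == substr(adapter, 1L, k)) return(p)
  }
  NA_integer_
}

# brute-force re-statement of the five-code classification rule, using only
# nested loops over exons and plain arithmetic
oracle_classify <- function(tx, ref_loci) {
  ref_txs <- list()
  for (loc in ref_loci) for (t in loc$transcripts)
    ref_txs[[length(ref_txs) + 1L]] <- t
  exon_overlap <- function(a, b) {
    for (i in seq_len(nrow(a$exons))) for (j in seq_len(nrow(b$exons)))
      if (a$chrom == b$chrom &&
          a$exons$start[i] <= b$exons$end[j] &&
          a$exons$end[i] >= b$exons$start[j]) return(TRUE)
    FALSE
  }
  chain <- function(t) {
    n <- nrow(t$exons)
    if (n < 2L) return(character(0))
    paste(t$exons$end[-n], t$exons$start[-1L], sep = "-")
  }
  tx_chain <- chain(tx)
  # equal
  for (rt in ref_txs) {
    if (rt$chrom != tx$chrom || rt$strand != tx$strand) next
    if (nrow(tx$exons) > 1L) {
      if (length(tx_chain) == length(chain(rt)) &&
          all(tx_chain == chain(rt)))
        return("equal")
    } else if (nrow(rt$exons) == 1L && exon_overlap(tx, rt)) {
      return("equal")
    }
  }
  # shared intron
  for (rt in ref_txs)
    if (rt$chrom == tx$chrom && rt$strand == tx$strand &&
        length(intersect(tx_chain, chain(rt))))
      return("novel_isoform")
  # intronic: span inside one intron of a same-strand transcript
  span <- c(min(tx$exons$start), max(tx$exons$end))
  for (rt in ref_txs) {
    if (rt$chrom != tx$chrom || rt$strand != tx$strand) next
    n <- nrow(rt$exons)
    if (n < 2L) next
    for (i in seq_len(n - 1L))
      if (span[1L] >= rt$exons$end[i] + 1L &&
          span[2L] <= rt$exons$start[i + 1L] - 1L)
        return("intronic")
  }
  same <- FALSE
  anti <- FALSE
  for (rt in ref_txs) {
    if (rt$chrom != tx$chrom || !exon_overlap(tx, rt)) next
    if (rt$strand == tx$strand) same <- TRUE else anti <- TRUE
  }
  if (same) return("novel_isoform")
  if (anti) return("antisense")
  "intergenic"
}

# brute-force common junction intersection
oracle_common_junctions <- function(isoforms) {
  per <- lapply(isoforms, function(t) {
    n <- nrow(t$exons)
    if (n < 2L) return(character(0))
    paste(t$exons$end[-n], t$exons$start[-1L], sep = "-")
  })
  out <- per[[1L]]
  for (p in per[-1L]) out <- out[out %in% p]
  sort(out)
}

# random multi/single-exon transcript inside [lo, hi]
random_tx <- function(id, chrom, strand, lo, hi, max_exons = 4L) {
  n <- sample.int(max_exons, 1L)
  width <- hi - lo
  repeat {
    bounds <- sort(sample(seq.int(lo, hi), 2L * n))
    starts <- bounds[seq(1L, 2L * n, 2L)]
    ends <- bounds[seq(2L, 2L * n, 2L)]
    if (n == 1L || all(starts[-1L] - ends[-n] >= 2L)) break
  }
  mk_tx(id, chrom, strand, starts, ends)
}

# random reference annotation: a few genes in disjoint windows
random_reference <- function(n_genes, chrom = "c1", window = 2000L) {
  lapply(seq_len(n_genes), function(g) {
    lo <- (g - 1L) * window + 1L
    strand <- sample(c("+", "-"), 1L)
    tx <- random_tx(sprintf("rt%d", g), chrom, strand, lo,
                    lo + window - 200L)
    mk_locus(sprintf("rg%d", g), list(tx), biotype = "protein_coding",
             locus_class = "annotated")
  })
}
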