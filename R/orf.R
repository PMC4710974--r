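#' Coding-potential configuration
#'
#' The package's coding-potential rule is the classical longest-ORF proxy:
#' a locus is a protein-coding candidate when any isoform carries an open
#' reading frame of at least `min_orf_codons` codons (ATG through stop,
#' stop excluded from the count). 100 codons (~300 nt) is the conventional
#' cutoff separating long noncoding RNAs from plausible coding sequences.
#'
#' @param min_orf_codons ORF length threshold in codons; default 100.
#' @param require_start_codon must the ORF begin with ATG? Default TRUE.
#' @param require_stop_codon must the ORF end at an in-frame stop codon
#'   (TAA/TAG/TGA) rather than running off the sequence end? Default TRUE.
#' @return a `CodingConfig` list.
#' @export
coding_config <- function(min_orf_codons = 100L, require_start_codon = TRUE,
                          require_stop_codon = TRUE) {
  stopifnot(min_orf_codons >= 1)
  structure(list(min_orf_codons = as.integer(min_orf_codons),
                 require_start_codon = isTRUE(require_start_codon),
                 require_stop_codon = isTRUE(require_stop_codon)),
            class = "CodingConfig")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find the longest open reading frame in a spliced transcript sequence
#'
#' Scans the three sense-strand frames only (assembled transcripts are
#' stranded, so the antisense frames belong to a different transcript).
#' Codons containing `N` break a codon run without acting as a stop.
#' Length is counted in codons from the start codon up to, and excluding,
#' the terminating stop. Ties are broken by the smaller start offset, then
#' the lower frame.
#'
#' @param seq nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @param cfg a [coding_config()].
#' @return list with `best_orf_length_codons`, `frame` (0/1/2),
#'   `start_offset` (0-based in the spliced sequence; `NA` when no ORF),
#'   and `has_significant_orf`
#'   (`best_orf_length_codons >= cfg$min_orf_codons`).
#' @export
find_longest_orf <- function(seq, cfg = coding_config()) {
  stopifnot(inherits(cfg, "CodingConfig"), is.character(seq),
            length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains characters outside {A,C,G,T,N}")
  best <- list(best_orf_length_codons = 0L, frame = NA_integer_,
               start_offset = NA_integer_, has_significant_orf = FALSE)
  L <- nchar(seq)
  for (frame in 0:2) {
    n_codons <- (L - frame) %/% 3L
    if (n_codons < 1L) next
    pos <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(seq, pos, pos + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_break <- grepl("N", codons, fixed = TRUE)
    is_start <- codons == "ATG"

    open_from <- NA_integer_   # codon index opening the current candidate
    i <- 1L
    while (i <= n_codons) {
      if (is_stop[i] || is_break[i]) {
        if (!is.na(open_from) && is_stop[i]) {
          len <- i - open_from
          best <- orf_better(best, len, frame, pos[open_from] - 1L)
        }
        open_from <- NA_integer_
      } else if (is.na(open_from)) {
        if (is_start[i] || !cfg$require_start_codon) open_from <- i
      }
      i <- i + 1L
    }
    if (!is.na(open_from) && !cfg$require_stop_codon) {
      len <- n_codons + 1L - open_from
      best <- orf_better(best, len, frame, pos[open_from] - 1L)
    }
  }
  best$has_significant_orf <- best$best_orf_length_codons >= cfg$min_orf_codons
  best
}

orf_better <- function(best, len, frame, offset0) {
  if (len > best$best_orf_length_codons ||
      (len == best$best_orf_length_codons && len > 0L &&
       (is.na(best$start_offset) || offset0 < best$start_offset ||
        (offset0 == best$start_offset && frame < best$frame)))) {
    best$best_orf_length_codons <- len
    best$frame <- frame
    best$start_offset <- offset0
  }
  best
}
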