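#' Adapter-trimming configuration
#'
#' 3'-adapter semantics: the read is truncated at the leftmost position
#' where the full adapter occurs, or where a prefix of the adapter (at
#' least `min_overlap` bases) matches the read's 3' end, allowing a
#' mismatch fraction of up to `max_mismatch_rate` of the aligned length.
#'
#' @param adapter_seq adapter nucleotide string (non-empty).
#' @param min_overlap minimum adapter prefix length considered at the 3'
#'   end; default 3.
#' @param max_mismatch_rate allowed mismatch fraction in `[0, 1)`;
#'   default 0.1.
#' @return a `TrimConfig` list.
#' @export
trim_config <- function(adapter_seq, min_overlap = 3L,
                        max_mismatch_rate = 0.1) {
  stopifnot(is.character(adapter_seq), nchar(adapter_seq) >= 1L,
            min_overlap >= 1L, min_overlap <= nchar(adapter_seq),
            max_mismatch_rate >= 0, max_mismatch_rate < 1)
  structure(list(adapter_seq = toupper(adapter_seq),
                 min_overlap = as.integer(min_overlap),
                 max_mismatch_rate = max_mismatch_rate),
            class = "TrimConfig")
}

#' Trim a 3' adapter from one read
#'
#' @param seq read sequence.
#' @param qual quality string of the same length.
#' @param cfg a [trim_config()].
#' @return list with `seq` and `qual` truncated at the adapter start (the
#'   read is returned unchanged when no acceptable match exists) and
#'   `trimmed`, the number of bases removed.
#' @export
trim_read <- function(seq, qual, cfg) {
  stopifnot(inherits(cfg, "TrimConfig"))
  if (nchar(seq) != nchar(qual))
    stop("sequence and quality strings differ in length")
  pos <- adapter_match_pos(toupper(seq), cfg)
  if (is.na(pos))
    return(list(seq = seq, qual = qual, trimmed = 0L))
  list(seq = substr(seq, 1L, pos - 1L),
       qual = substr(qual, 1L, pos - 1L),
       trimmed = nchar(seq) - pos + 1L)
}

# 1-based start of the leftmost acceptable adapter occurrence, or NA
adapter_match_pos <- function(seq, cfg) {
  L <- nchar(seq)
  A <- nchar(cfg$adapter_seq)
  if (L == 0L) return(NA_integer_)
  s <- strsplit(seq, "")[[1L]]
  a <- strsplit(cfg$adapter_seq, "")[[1L]]
  for (p in seq_len(L)) {
    k <- min(A, L - p + 1L)
    # partial matches (adapter running off the 3' end) need min_overlap
    if (k < A && k < cfg$min_overlap) next
    mism <- sum(s[p:(p + k - 1L)] != a[seq_len(k)])
    if (mism <= floor(cfg$max_mismatch_rate * k)) return(p)
  }
  NA_integer_
}

#' Trim adapters from a FASTQ file
#'
#' Streams 4-line FASTQ records (plain, `.gz` or `.bz2` transparently
#' decompressed), applies [trim_read()] to each, and writes the result.
#'
#' @param input,output FASTQ paths; output compressed when it ends in
#'   `.gz`.
#' @param cfg a [trim_config()].
#' @return summary list: `reads`, `reads_trimmed`, `mean_trimmed_bases`.
#' @export
trim_fastq <- function(input, output, cfg) {
  con_in <- open_maybe_compressed(input)
  open(con_in, "r")
  on.exit(close(con_in), add = TRUE)
  con_out <- if (grepl("\\.gz$", output)) gzfile(output, "w")
             else file(output, "w")
  on.exit(close(con_out), add = TRUE)
  n <- 0L
  n_trimmed <- 0L
  total_trimmed <- 0
  repeat {
    rec <- readLines(con_in, n = 4L)
    if (length(rec) == 0L) break
    if (length(rec) < 4L)
      stop("truncated FASTQ record at read ", n + 1L)
    res <- trim_read(rec[2L], rec[4L], cfg)
    n <- n + 1L
    if (res$trimmed > 0L) {
      n_trimmed <- n_trimmed + 1L
      total_trimmed <- total_trimmed + res$trimmed
    }
    writeLines(c(rec[1L], res$seq, rec[3L], res$qual), con_out)
  }
  list(reads = n, reads_trimmed = n_trimmed,
       mean_trimmed_bases = if (n > 0L) total_trimmed / n else 0)
}

#' Insert-size statistics from library metadata
#'
#' The insert (the adapter-free portion of a library fragment) has mean
#' `fragment_mean - 2 * adapter_len`; the adapter length is treated as a
#' constant, so the standard deviation passes through unchanged. The mate
#' inner distance (insert minus both reads), used to configure spliced
#' aligners, is also reported and may legitimately be negative for
#' overlapping mates.
#'
#' @param fragment_mean,fragment_sd fragment-length mean and standard
#'   deviation in bp (`fragment_mean > 2 * adapter_len`).
#' @param adapter_len adapter length in bp (per end).
#' @param read_len read length in bp.
#' @return list with `insert_mean`, `insert_sd`, `mate_inner_distance`.
#' @export
insert_stats <- function(fragment_mean, fragment_sd, adapter_len, read_len) {
  stopifnot(fragment_mean > 0, fragment_sd >= 0, adapter_len >= 0,
            read_len >= 1)
  insert_mean <- fragment_mean - 2 * adapter_len
  if (insert_mean <= 0)
    stop("non-positive insert size (", insert_mean,
         "): fragment_mean must exceed 2 * adapter_len")
  list(insert_mean = insert_mean, insert_sd = fragment_sd,
       mate_inner_distance = insert_mean - 2 * read_len)
}
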