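#' Load a genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that trims FASTA
#' description lines to the first word, so `extract_sequence()` can look
#' contigs up by name. Pass the returned object to repeated extraction
#' calls to avoid re-reading the file.
#'
#' @param path FASTA file path (plain or gzip).
#' @return a [Biostrings::DNAStringSet] keyed by contig name.
#' @export
load_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract the spliced sequence of an exon chain
#'
#' Concatenates the genomic sequence of each exon (1-based inclusive
#' coordinates) in genomic order and, for the minus strand, reverse
#' complements the concatenation as a whole — i.e. returns the transcript
#' sequence in transcript orientation.
#'
#' @param genome FASTA path or a [Biostrings::DNAStringSet] from
#'   [load_genome()].
#' @param exons a `TranscriptModel`, or a data.frame with columns
#'   `chrom`, `start`, `end`, `strand` (one strand/chrom throughout).
#' @return upper-case nucleotide string.
#' @export
extract_sequence <- function(genome, exons) {
  if (is.character(genome)) genome <- load_genome(genome)
  if (inherits(exons, "TranscriptModel"))
    exons <- data.frame(chrom = exons$chrom, start = exons$exons$start,
                        end = exons$exons$end, strand = exons$strand,
                        stringsAsFactors = FALSE)
  chrom <- unique(exons$chrom)
  strand <- unique(exons$strand)
  stopifnot(length(chrom) == 1L, length(strand) == 1L)
  if (!chrom %in% names(genome))
    stop("contig '", chrom, "' not found in genome")
  contig <- genome[[chrom]]
  if (any(exons$start < 1L) || any(exons$end > length(contig)))
    stop("exon coordinates outside contig '", chrom, "' (length ",
         length(contig), ")")
  exons <- exons[order(exons$start), , drop = FALSE]
  pieces <- Biostrings::extractAt(
    contig, IRanges::IRanges(exons$start, exons$end))
  spliced <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  if (strand == "-")
    spliced <- Biostrings::reverseComplement(spliced)
  toupper(as.character(spliced))
}
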