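test_that("common junctions are the intersection of isoform junction sets", {
  iso1 <- mk_tx("i1", "c1", "+", c(100L, 300L, 600L), c(200L, 400L, 700L))
  iso2 <- mk_tx("i2", "c1", "+", c(100L, 300L), c(200L, 400L))
  cj <- common_junctions(list(iso1, iso2))
  expect_equal(nrow(cj), 1L)
  expect_equal(cj$donor, 200L)
  expect_equal(cj$acceptor, 300L)
  # identical isoforms keep all junctions
  cj2 <- common_junctions(list(iso1, iso1))
  expect_equal(nrow(cj2), 2L)
  expect_equal(cj2$donor, c(200L, 400L))
  # a single-exon isoform forces an empty intersection
  se <- mk_tx("se", "c1", "+", 150L, 350L)
  expect_equal(nrow(common_junctions(list(iso1, se))), 0L)
  expect_error(common_junctions(list(iso1, mk_tx("x", "c1", "-", 1L, 5L))),
               "strand")
})

test_that("common junctions equal brute-force set intersection and are
           order-invariant", {
  set.seed(55)
  for (rep in 1:40) {
    n_iso <- sample(2:5, 1)
    isoforms <- lapply(seq_len(n_iso), function(i)
      random_tx(sprintf("i%d", i), "c1", "+", 1L, 2000L, max_exons = 5L))
    got <- common_junctions(isoforms)
    got_keys <- sort(paste(got$donor, got$acceptor, sep = "-"))
    expect_equal(got_keys, oracle_common_junctions(isoforms))
    shuffled <- common_junctions(rev(isoforms))
    expect_equal(got, shuffled)
    # result is a subset of every isoform's junctions
    for (iso in isoforms) {
      jk <- paste(junctions(iso)$donor, junctions(iso)$acceptor, sep = "-")
      expect_true(all(got_keys %in% jk))
    }
  }
})

test_that("common exonic region is the longest shared interval", {
  a <- mk_tx("a", "c1", "+", 100L, 300L)
  b <- mk_tx("b", "c1", "+", 200L, 400L)
  cer <- common_exonic_region(list(a, b))
  expect_equal(c(cer$start, cer$end), c(200L, 300L))
  # disjoint isoforms share nothing
  c_ <- mk_tx("c", "c1", "+", 500L, 600L)
  expect_null(common_exonic_region(list(a, c_)))
  # identical single-exon isoforms return themselves
  s <- mk_tx("s", "c1", "+", 50L, 150L)
  cer3 <- common_exonic_region(list(s, s, s))
  expect_equal(c(cer3$start, cer3$end), c(50L, 150L))
})

flank_gene <- function(genome_len = 2000L) {
  # two isoforms sharing one junction with 200 bp of exon on each side
  set.seed(9)
  g <- write_tiny_genome(list(
    cp = paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
               collapse = "")))
  iso1 <- mk_tx("f1", "cp", "+", c(101L, 501L), c(300L, 700L), gene = "GF")
  iso2 <- mk_tx("f2", "cp", "+", c(101L, 501L, 901L), c(300L, 700L, 1000L),
                gene = "GF")
  list(genome = g, locus = mk_locus("GF", list(iso1, iso2)))
}

test_that("junction templates have the stated length and junction offset", {
  fx <- flank_gene()
  tgt <- build_primer_target(fx$locus, fx$genome, flank = 150L)
  expect_equal(tgt$kind, "junction_spanning")
  expect_equal(nchar(tgt$template_seq), 300L)
  expect_equal(tgt$junction_pos, 150L)
  # template is the spliced sequence around the junction
  expected <- extract_sequence(fx$genome, data.frame(
    chrom = "cp", start = c(151L, 501L), end = c(300L, 650L), strand = "+"))
  expect_equal(tgt$template_seq, expected)
})

test_that("minus-strand junction templates are reported in transcript
           orientation", {
  set.seed(10)
  g <- write_tiny_genome(list(
    cm = paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
               collapse = "")))
  iso <- mk_tx("m1", "cm", "-", c(101L, 501L), c(300L, 700L), gene = "GM")
  tgt <- build_primer_target(mk_locus("GM", list(iso)), g, flank = 150L)
  expect_equal(tgt$kind, "junction_spanning")
  # 5' flank comes from the genomic-right exon on the minus strand
  expect_equal(nchar(tgt$template_seq), 300L)
  expect_equal(tgt$junction_pos, 150L)
  expect_equal(tgt$template_seq, extract_sequence(g, data.frame(
    chrom = "cm", start = c(151L, 501L), end = c(300L, 650L),
    strand = "-")))
})

test_that("fallback to a common exonic region happens iff no junction is
           shared", {
  set.seed(12)
  g <- write_tiny_genome(list(
    cf = paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
               collapse = "")))
  # no shared junction, 500 bp common exon
  iso1 <- mk_tx("e1", "cf", "+", 101L, 700L, gene = "GE")
  iso2 <- mk_tx("e2", "cf", "+", c(101L, 801L), c(600L, 900L), gene = "GE")
  tgt <- build_primer_target(mk_locus("GE", list(iso1, iso2)), g)
  expect_equal(tgt$kind, "common_exonic")
  expect_equal(nchar(tgt$template_seq), 500L)
  expect_true(is.na(tgt$junction_pos))
  # no overlap at all: reported failure, not an error
  iso3 <- mk_tx("e3", "cf", "+", 1001L, 1100L, gene = "GE")
  tgt2 <- build_primer_target(mk_locus("GE", list(iso1, iso3)), g)
  expect_equal(tgt2$kind, "failure")
  expect_match(tgt2$reason, "no common junction")
  # a common region under 40 bp is unusable
  iso4 <- mk_tx("e4", "cf", "+", 671L, 800L, gene = "GE")
  tgt3 <- build_primer_target(mk_locus("GE", list(iso1, iso4)), g)
  expect_equal(tgt3$kind, "failure")
})

test_that("picked primers flank the junction and sit inside the template", {
  fx <- flank_gene()
  tgt <- build_primer_target(fx$locus, fx$genome, flank = 150L)
  res <- pick_primers(tgt)
  expect_true(res$success)
  left_end <- res$left_start + nchar(res$left_seq) - 1L
  expect_lt(left_end, tgt$junction_pos)
  expect_gt(res$right_start, tgt$junction_pos)
  expect_equal(res$product_size,
               res$right_start + nchar(res$right_seq) - res$left_start)
  # left primer is a substring of the template; right matches the reverse
  # complement
  expect_equal(substr(tgt$template_seq, res$left_start + 1L,
                      left_end + 1L), res$left_seq)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(res$right_seq)))
  expect_equal(substr(tgt$template_seq, res$right_start + 1L,
                      res$right_start + nchar(res$right_seq)), rc)
})

test_that("common-exonic primers lie fully inside the template and short
           templates are rejected", {
  set.seed(13)
  g <- write_tiny_genome(list(
    cg = paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE),
               collapse = "")))
  iso <- mk_tx("x1", "cg", "+", 101L, 600L, gene = "GX")
  iso2 <- mk_tx("x2", "cg", "+", 101L, 600L, gene = "GX")
  # single-exon isoforms: no junction, fall back to the shared exon
  tgt <- build_primer_target(mk_locus("GX", list(iso, iso2)), g)
  expect_equal(tgt$kind, "common_exonic")
  res <- pick_primers(tgt)
  expect_true(res$success)
  L <- nchar(tgt$template_seq)
  expect_gte(res$left_start, 0L)
  expect_lte(res$right_start + nchar(res$right_seq), L)
  short <- tgt
  short$template_seq <- substr(tgt$template_seq, 1, 59)
  expect_error(pick_primers(short), "at least 60")
})

test_that("the primer table reports a usable pair for every fixture gene", {
  d <- tempfile()
  m <- make_fixture(fixture_config(seed = 31), d)
  ref <- read_gtf(m$reference, "reference")
  tab <- design_primers(ref, m$genome)
  expect_equal(nrow(tab), length(ref))
  expect_true(all(tab$kind == "junction_spanning"))
  expect_true(all(tab$status == "ok"))
  expect_true(all(tab$product_size >= 70 & tab$product_size <= 200))
})
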