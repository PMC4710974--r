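two_sample_input <- function(txA, txB) {
  list(A = list(mk_locus("gA", txA)), B = list(mk_locus("gB", txB)))
}

test_that("identical intron chains across samples collapse to one
           transcript with combined presence", {
  txA <- mk_tx("a1", "c1", "+", c(100L, 300L), c(200L, 400L))
  txB <- mk_tx("b1", "c1", "+", c(90L, 300L), c(200L, 420L))
  merged <- merge_samples(two_sample_input(list(txA), list(txB)))
  txs <- loci_transcripts(merged)
  expect_length(txs, 1L)
  expect_equal(sort(txs[[1]]$present_in), c("A", "B"))
  # merged span is the union of the contributors
  expect_equal(txs[[1]]$exons$start[1], 90L)
  expect_equal(txs[[1]]$exons$end[2], 420L)
  # internal junction untouched
  expect_equal(junctions(txs[[1]])$donor, 200L)
  expect_equal(junctions(txs[[1]])$acceptor, 300L)
})

test_that("overlapping single-exon transcripts merge to the union span", {
  txA <- mk_tx("a1", "c1", "+", 100L, 200L)
  txB <- mk_tx("b1", "c1", "+", 150L, 250L)
  merged <- merge_samples(two_sample_input(list(txA), list(txB)))
  txs <- loci_transcripts(merged)
  expect_length(txs, 1L)
  expect_equal(txs[[1]]$exons$start, 100L)
  expect_equal(txs[[1]]$exons$end, 250L)
  expect_equal(sort(txs[[1]]$present_in), c("A", "B"))
})

test_that("opposite strands and disjoint single-exon transcripts stay
           separate", {
  txA <- mk_tx("a1", "c1", "+", 100L, 200L)
  txB <- mk_tx("b1", "c1", "-", 150L, 250L)
  txC <- mk_tx("b2", "c1", "+", 500L, 600L, gene = "gC")
  merged <- merge_samples(list(A = list(mk_locus("gA", list(txA))),
                               B = list(mk_locus("gB", list(txB)),
                                        mk_locus("gC", list(txC)))))
  expect_length(loci_transcripts(merged), 3L)
})

test_that("one sample returns its own structures with singleton presence", {
  txs <- list(mk_tx("a1", "c1", "+", c(10L, 50L), c(20L, 90L)),
              mk_tx("a2", "c2", "-", 5L, 80L, gene = "g2"))
  merged <- merge_samples(list(only = list(mk_locus("g1", txs[1]),
                                           mk_locus("g2", txs[2]))))
  out <- loci_transcripts(merged)
  expect_length(out, 2L)
  for (t in out) expect_equal(t$present_in, "only")
  pres <- sample_presence(merged)
  expect_true(all(pres$n_present == 1L))
  expect_true(all(pres$n_samples == 1L))
})

test_that("merging is invariant to sample order and never grows the set", {
  set.seed(42)
  for (rep in 1:10) {
    mk_sample <- function(s) {
      n <- sample.int(5, 1)
      lapply(seq_len(n), function(i) {
        tx <- random_tx(sprintf("%s_t%d", s, i), "c1",
                        sample(c("+", "-"), 1), 1L, 3000L)
        mk_locus(sprintf("%s_g%d", s, i), list(tx))
      })
    }
    samples <- list(s1 = mk_sample("s1"), s2 = mk_sample("s2"),
                    s3 = mk_sample("s3"))
    m1 <- merge_samples(samples)
    m2 <- merge_samples(samples[c(3, 1, 2)])
    key_pres <- function(m) {
      txs <- loci_transcripts(m)
      o <- order(vapply(txs, rnaseqtk:::tx_structure_key, character(1)))
      lapply(txs[o], function(t)
        list(exons = t$exons, strand = t$strand, pres = sort(t$present_in)))
    }
    expect_equal(key_pres(m1), key_pres(m2))
    n_in <- sum(lengths(lapply(samples, function(s)
      loci_transcripts(s))))
    expect_lte(length(loci_transcripts(m1)), n_in)
  }
})

test_that("merge rejects empty or unnamed input", {
  expect_error(merge_samples(list()), "named list")
  expect_error(merge_samples(list(list())), "named list")
})

# ---- classification ---------------------------------------------------------

ref_two_genes <- function() {
  # plus-strand 2-exon gene and minus-strand gene downstream
  list(mk_locus("G1", list(mk_tx("G1.1", "c1", "+", c(1000L, 2000L),
                                 c(1500L, 2600L), gene = "G1")),
                biotype = "protein_coding", locus_class = "annotated"),
       mk_locus("G2", list(mk_tx("G2.1", "c1", "-", c(5000L, 5800L),
                                 c(5400L, 6200L), gene = "G2")),
                biotype = "lincRNA", locus_class = "annotated"))
}

test_that("classification examples follow the five-code precedence", {
  ref <- ref_two_genes()
  # identical chain -> equal
  same <- mk_tx("q1", "c1", "+", c(900L, 2000L), c(1500L, 2700L))
  expect_equal(classify_vs_reference(same, ref)$code, "equal")
  # shares the intron -> novel isoform
  iso <- mk_tx("q2", "c1", "+", c(1200L, 2000L, 2800L),
               c(1500L, 2650L, 3000L))
  res <- classify_vs_reference(iso, ref)
  expect_equal(res$code, "novel_isoform")
  expect_equal(res$matched_gene_id, "G1")
  # single exon inside the intron, same strand -> intronic
  intr <- mk_tx("q3", "c1", "+", 1600L, 1900L)
  expect_equal(classify_vs_reference(intr, ref)$code, "intronic")
  # opposite strand over G1 exons, no same-strand overlap -> antisense
  anti <- mk_tx("q4", "c1", "-", c(1100L, 2100L), c(1400L, 2300L))
  res <- classify_vs_reference(anti, ref)
  expect_equal(res$code, "antisense")
  expect_equal(res$matched_gene_id, "G1")
  # 10 kb away -> intergenic with no matched gene
  far <- mk_tx("q5", "c1", "+", c(16000L, 16500L), c(16200L, 16800L))
  res <- classify_vs_reference(far, ref)
  expect_equal(res$code, "intergenic")
  expect_true(is.na(res$matched_gene_id))
})

test_that("classification agrees with the brute-force oracle on random
           instances", {
  set.seed(101)
  for (rep in 1:12) {
    ref <- random_reference(sample(2:5, 1))
    idx <- reference_index(ref)
    n_q <- sample(10:50, 1)
    lim <- length(ref) * 2000L
    for (q in seq_len(n_q)) {
      tx <- random_tx(sprintf("q%d", q), "c1", sample(c("+", "-"), 1),
                      1L, lim)
      expect_equal(classify_vs_reference(tx, idx)$code,
                   oracle_classify(tx, ref),
                   info = sprintf("rep %d query %d", rep, q))
    }
  }
})

# ---- filtering --------------------------------------------------------------

presence_fixture <- function(n_present_by_tx, n_samples, exon_counts) {
  txs <- mapply(function(id, nex) {
    starts <- seq(100L, by = 300L, length.out = nex)
    tx <- mk_tx(id, "c1", "+", starts, starts + 100L)
    tx$present_in <- paste0("s", seq_len(n_present_by_tx[[id]]))
    tx
  }, names(n_present_by_tx), exon_counts, SIMPLIFY = FALSE)
  loci <- lapply(txs, function(t) mk_locus(paste0("g_", t$transcript_id),
                                           list(t)))
  pres <- data.frame(transcript_id = names(n_present_by_tx),
                     present_in = "", n_present = unlist(n_present_by_tx),
                     n_samples = n_samples)
  list(loci = loci, pres = pres)
}

test_that("single-exon majority rule is strict and spares multi-exon
           transcripts", {
  fx <- presence_fixture(list(se_3of5 = 3L, se_2of4 = 2L, me_1of8 = 1L),
                         n_samples = 5L, exon_counts = c(1L, 1L, 2L))
  # 3 of 5 beats the strict majority
  kept <- filter_single_exon(fx$loci, transform(fx$pres, n_samples = 5L))
  ids <- vapply(loci_transcripts(kept), `[[`, character(1), "transcript_id")
  expect_true("se_3of5" %in% ids)
  # 2 of 4 is a tie: removed
  fx4 <- presence_fixture(list(se_2of4 = 2L), 4L, 1L)
  kept4 <- filter_single_exon(fx4$loci, fx4$pres)
  expect_length(loci_transcripts(kept4), 0L)
  expect_equal(attr(kept4, "report")$reason, "single_exon_tie_minority")
  # splice junction always preserved, even at 1 of 8
  fx8 <- presence_fixture(list(me_1of8 = 1L), 8L, 2L)
  kept8 <- filter_single_exon(fx8$loci, fx8$pres)
  expect_length(loci_transcripts(kept8), 1L)
})

test_that("intronic single-exon transcripts are removed regardless of
           presence", {
  ref <- ref_two_genes()
  intr <- mk_tx("se_intronic", "c1", "+", 1600L, 1900L)
  intr$present_in <- paste0("s", 1:4)
  loci <- list(mk_locus("gi", list(intr)))
  pres <- data.frame(transcript_id = "se_intronic", present_in = "",
                     n_present = 4L, n_samples = 4L)
  codes <- classify_transcripts(loci, ref)
  expect_equal(codes$code, "intronic")
  kept <- filter_single_exon(loci, pres, codes = codes)
  expect_length(loci_transcripts(kept), 0L)
  expect_equal(attr(kept, "report")$reason, "single_exon_intronic")
  # without codes the same transcript survives on presence alone
  kept2 <- filter_single_exon(loci, pres)
  expect_length(loci_transcripts(kept2), 1L)
})

test_that("low-coverage loci are removed by total reads and FPKM floors", {
  loci <- list(mk_locus("gz", list(mk_tx("tz", "c1", "+", 1L, 100L))),
               mk_locus("gs", list(mk_tx("ts", "c1", "+", 200L, 300L))))
  counts <- rbind(gz = c(0L, 0L, 0L), gs = c(4L, 3L, 3L))
  colnames(counts) <- paste0("s", 1:3)
  kept <- filter_low_coverage(loci, counts, filter_config())
  expect_equal(vapply(kept, `[[`, character(1), "gene_id"), "gs")
  expect_equal(attr(kept, "report")$reason, "low_reads")
  # sum = 10 meets the inclusive threshold
  expect_true("gs" %in% vapply(kept, `[[`, character(1), "gene_id"))
  # no-op configuration returns the input set
  all_kept <- filter_low_coverage(loci, counts,
                                  filter_config(min_locus_reads = 0L))
  expect_length(all_kept, 2L)
  expect_error(filter_low_coverage(loci, rbind(gz = -1L), filter_config()),
               "negative")
})

test_that("filtering is idempotent and a subset operation on random
           merged sets", {
  set.seed(77)
  for (rep in 1:200) {
    n_samples <- sample(2:6, 1)
    n_tx <- sample(1:6, 1)
    txs <- lapply(seq_len(n_tx), function(i) {
      tx <- random_tx(sprintf("t%d", i), "c1", "+",
                      (i - 1L) * 1000L + 1L, i * 1000L - 100L)
      tx$present_in <- paste0("s", sample.int(n_samples,
                                              sample.int(n_samples, 1)))
      tx
    })
    loci <- lapply(txs, function(t) mk_locus(paste0("g", t$transcript_id),
                                             list(t)))
    pres <- data.frame(
      transcript_id = vapply(txs, `[[`, character(1), "transcript_id"),
      present_in = "",
      n_present = vapply(txs, function(t) length(t$present_in), integer(1)),
      n_samples = n_samples)
    once <- filter_single_exon(loci, pres)
    ids_in <- vapply(txs, `[[`, character(1), "transcript_id")
    ids_once <- vapply(loci_transcripts(once), `[[`, character(1),
                       "transcript_id")
    expect_true(all(ids_once %in% ids_in))
    twice <- filter_single_exon(once, pres)
    expect_equal(vapply(loci_transcripts(twice), `[[`, character(1),
                        "transcript_id"), ids_once)
    # multi-exon transcripts are never removed
    me <- ids_in[vapply(txs, function(t) nrow(t$exons) > 1L, logical(1))]
    expect_true(all(me %in% ids_once))
  }
})

test_that("HTSeq-style count files combine into a matrix", {
  p1 <- tempfile()
  p2 <- tempfile()
  writeLines(c("gA\t5", "gB\t7", "__no_feature\t100"), p1)
  writeLines(c("gA\t2", "gC\t9"), p2)
  m <- read_htseq_counts(c(p1, p2), c("s1", "s2"))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m["gA", ], c(s1 = 5L, s2 = 2L))
  expect_equal(m["gC", ], c(s1 = 0L, s2 = 9L))
  expect_false("__no_feature" %in% rownames(m))
})
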