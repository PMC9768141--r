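# Locus fixture: gA CDS ends 1000, gB CDS starts 1500 (plus strand).
is_fixture <- function(strand = "+", rt_exons = NULL, extra_tx = list(),
                       extra_counts = NULL) {
  df <- data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(1, 1100), end = c(1090, 2200), strand = strand,
    cds_start = c(101, 1500), cds_end = c(1000, 2100),
    stringsAsFactors = FALSE)
  genes <- make_gene_set(df)
  rt_exons <- rt_exons %||% list(rbind(c(1, 1049), c(1401, 2200)))
  txs <- make_txs(c(rt_exons, extra_tx), strand = strand,
                  read_count = extra_counts %||% rep(1L, length(rt_exons) + length(extra_tx)))
  asg <- suppressMessages(call_rt_transcripts(txs, genes, 30))
  loci <- suppressMessages(group_rt_loci(asg, genes))
  list(genes = genes, txs = txs, loci = loci)
}

test_that("find_is_introns keeps only inter-CDS introns and merges support", {
  fx <- is_fixture(rt_exons = list(
    rbind(c(1, 1049), c(1401, 2200)),   # IS intron 1050-1400
    rbind(c(1, 1049), c(1401, 2200)),   # identical -> merged, support 2
    rbind(c(1, 400), c(600, 2200))))    # intron 401-599 inside gA CDS -> not IS
  isdf <- find_is_introns(fx$loci[1, ], fx$txs, fx$genes)
  expect_equal(nrow(isdf), 1L)
  expect_equal(isdf$start, 1050)
  expect_equal(isdf$end, 1400)
  expect_equal(isdf$support, 2L)
  expect_equal(isdf$donor_pos, 1050)
  expect_equal(isdf$acceptor_pos, 1400)
  expect_true(isdf$major)
})

test_that("IS boundary anchors are exclusive at the CDS ends", {
  # donor right at the first base after gA's CDS (1001) and acceptor right
  # before gB's CDS (1499) still qualify; touching a CDS base does not
  fx <- is_fixture(rt_exons = list(
    rbind(c(1, 1000), c(1500, 2200)),    # intron 1001-1499: qualifies
    rbind(c(1, 999), c(1500, 2200))))    # intron 1000-1499 covers CDS base 1000
  isdf <- find_is_introns(fx$loci[1, ], fx$txs, fx$genes)
  expect_equal(nrow(isdf), 1L)
  expect_equal(c(isdf$start, isdf$end), c(1001, 1499))
})

test_that("major flag goes to the most-supported intron, ties to the 5'-most donor", {
  fx <- is_fixture(rt_exons = list(rbind(c(1, 1049), c(1401, 2200))),
                   extra_tx = list(rbind(c(1, 1099), c(1401, 2200))),
                   extra_counts = c(9L, 1L))
  isdf <- find_is_introns(fx$loci[1, ], fx$txs, fx$genes)
  expect_equal(nrow(isdf), 2L)
  expect_equal(isdf$major[order(-isdf$support)], c(TRUE, FALSE))

  # tie: equal support -> 5'-most donor wins
  fx2 <- is_fixture(rt_exons = list(rbind(c(1, 1049), c(1401, 2200))),
                    extra_tx = list(rbind(c(1, 1099), c(1401, 2200))),
                    extra_counts = c(3L, 3L))
  isdf2 <- find_is_introns(fx2$loci[1, ], fx2$txs, fx2$genes)
  expect_true(isdf2$major[isdf2$donor_pos == 1050])
  expect_false(isdf2$major[isdf2$donor_pos == 1100])
})

test_that("IS introns stay disjoint from every locus gene's CDS", {
  for (seed in 1:20) {
    set.seed(seed)
    gap_end <- sample(1200:1450, 1L)
    fx <- is_fixture(rt_exons = list(rbind(c(1, sample(1001:1190, 1L)),
                                           c(gap_end + 50L, 2200))))
    isdf <- find_is_introns(fx$loci[1, ], fx$txs, fx$genes)
    if (nrow(isdf) == 0L) next
    cds_all <- unlist(fx$genes$cds)
    iv <- IRanges(isdf$start, isdf$end)
    expect_equal(sum(countOverlaps(iv, ranges(cds_all))), 0L)
  }
})

test_that("classify_termination follows the polyA-in-intron dichotomy", {
  fx <- is_fixture()
  isdf <- find_is_introns(fx$loci[1, ], fx$txs, fx$genes)

  # polyA at 1200: strictly inside the 1050-1400 intron
  mono_in <- make_txs(list(cbind(1, 1200)), strand = "+", ids = "m1")
  cls <- classify_termination(fx$loci[1, ], isdf, mono_in, 10)
  expect_equal(cls$class_label, "IS_with_internal_polyA")
  expect_equal(cls$internal_polya_pos, 1200)

  # no first monocistronic transcripts at all
  cls2 <- classify_termination(fx$loci[1, ], isdf,
                               make_txs(list(), ids = character()), 10)
  expect_equal(cls2$class_label, "IS_without_internal_polyA")

  # polyA at the donor base is not "inside"
  mono_donor <- make_txs(list(cbind(1, 1050)), strand = "+", ids = "m2")
  cls3 <- classify_termination(fx$loci[1, ], isdf, mono_donor, 10)
  expect_equal(cls3$class_label, "IS_without_internal_polyA")

  # no IS introns
  cls4 <- classify_termination(fx$loci[1, ], isdf[0, ], mono_in, 10)
  expect_equal(cls4$class_label, "no_IS")
})

test_that("classification labels are exhaustive and mutually exclusive", {
  labels <- c("IS_with_internal_polyA", "IS_without_internal_polyA", "no_IS")
  fx <- is_fixture()
  isdf <- find_is_introns(fx$loci[1, ], fx$txs, fx$genes)
  for (mono in list(make_txs(list(cbind(1, 1200))),
                    make_txs(list(cbind(1, 980))),
                    make_txs(list(), ids = character()))) {
    for (is_in in list(isdf, isdf[0, ])) {
      cls <- classify_termination(fx$loci[1, ], is_in, mono, 10)
      expect_length(cls$class_label, 1L)
      expect_true(cls$class_label %in% labels)
    }
  }
})

test_that("polyA sites within the cluster radius collapse to one representative", {
  fx <- is_fixture()
  isdf <- find_is_introns(fx$loci[1, ], fx$txs, fx$genes)
  mono <- make_txs(list(cbind(1, 1198), cbind(1, 1203)), strand = "+")
  cls <- classify_termination(fx$loci[1, ], isdf, mono, 10)
  expect_equal(cls$n_polya_clusters,
               oracle_cluster_count(c(1198, 1203), 10))
  expect_equal(cls$n_polya_clusters, 1L)
  # radius 2 splits them
  cls2 <- classify_termination(fx$loci[1, ], isdf, mono, 2)
  expect_equal(cls2$n_polya_clusters, oracle_cluster_count(c(1198, 1203), 2))
})

test_that("splice_site_dinucleotides is strand-aware and flags non-canonical ends", {
  # intron bases 4..15 of a 20-nt chromosome: GTAAGT...TACAG
  seqs <- make_genome(chr1 = "AAAGTAAGTCCTACAGAAAA")
  intron <- list(chrom = "chr1", strand = "+", start = 4, end = 16)
  ss <- splice_site_dinucleotides(intron, seqs)
  expect_equal(ss$donor_seq, "GTA")
  expect_equal(ss$acceptor_seq, "CAG")
  expect_true(ss$canonical)

  bad <- splice_site_dinucleotides(list(chrom = "chr1", strand = "+",
                                        start = 3, end = 16), seqs)
  expect_false(bad$canonical)
  expect_equal(bad$donor_seq, "AGT")

  # minus strand: reverse-complement before extraction
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    "GTAAGTCCTACAG")))
  seqs2 <- make_genome(chr1 = paste0("AAA", rc, "AAAA"))
  ssm <- splice_site_dinucleotides(list(chrom = "chr1", strand = "-",
                                        start = 4, end = 16), seqs2)
  expect_equal(ssm$donor_seq, "GTA")
  expect_equal(ssm$acceptor_seq, "CAG")
  expect_true(ssm$canonical)

  expect_error(splice_site_dinucleotides(list(chrom = "chr1", strand = "+",
                                              start = 10, end = 30), seqs),
               "bounds")
})
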