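# Tandem pair used throughout: gA at 101-550 (CDS 151-450), gB at 801-1250
# (CDS 851-1150), plus strand, 250 nt intergenic gap.
tandem_pair <- function(extra = NULL) {
  df <- data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(101, 801), end = c(550, 1250), strand = "+",
    cds_start = c(151, 851), cds_end = c(450, 1150),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- rbind(df, extra)
  make_gene_set(df)
}

test_that("call_rt_transcripts calls tandem-spanning reads and orders the chain", {
  genes <- tandem_pair()
  txs <- make_txs(list(
    cbind(101, 1250),          # spans both CDS -> RT, chain gA,gB
    cbind(101, 550),           # first gene only
    cbind(101, 870)),          # second-gene CDS overlap 20 bp < 30 -> not RT
    strand = "+")
  res <- suppressMessages(call_rt_transcripts(txs, genes, 30))
  expect_equal(res$transcript_id, "tx1")
  expect_equal(res$gene_chain, "gA,gB")
  expect_equal(res$n_genes, 2L)
})

test_that("minus-strand chains are ordered in transcription direction", {
  df <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                   start = c(101, 801), end = c(550, 1250), strand = "-",
                   cds_start = c(151, 851), cds_end = c(450, 1150),
                   stringsAsFactors = FALSE)
  genes <- make_gene_set(df)
  txs <- make_txs(list(cbind(101, 1250)), strand = "-")
  res <- suppressMessages(call_rt_transcripts(txs, genes, 30))
  # transcription runs right to left: 5'-most gene is gB
  expect_equal(res$gene_chain, "gB,gA")
})

test_that("antisense and UTR-only overlaps are rejected; overlapping-span genes excluded", {
  antisense <- data.frame(
    gene_id = "gAS", chrom = "chr1", start = 601, end = 760, strand = "-",
    cds_start = 621, cds_end = 740, stringsAsFactors = FALSE)
  genes <- tandem_pair(extra = antisense)
  txs <- make_txs(list(
    cbind(101, 770),           # gA CDS + antisense gene region -> strand filter
    cbind(101, 820)),          # gA CDS + gB 5'UTR only -> CDS requirement
    strand = "+")
  res <- suppressMessages(call_rt_transcripts(txs, genes, 30))
  expect_equal(nrow(res), 0L)

  # a gene whose span overlaps gB disqualifies both as a trivially co-spanned
  # pair, but gA-gB remains callable through a spanning read
  nested <- data.frame(
    gene_id = "gOv", chrom = "chr1", start = 1100, end = 1400, strand = "+",
    cds_start = 1120, cds_end = 1380, stringsAsFactors = FALSE)
  genes2 <- tandem_pair(extra = nested)
  txs2 <- make_txs(list(cbind(801, 1400)), strand = "+")  # covers gB + gOv only
  res2 <- suppressMessages(call_rt_transcripts(txs2, genes2, 30))
  expect_equal(nrow(res2), 0L)
})

test_that("call_rt_transcripts errors without protein-coding genes and skips foreign chromosomes", {
  genes <- tandem_pair()
  genes$span$biotype <- "other"
  txs <- make_txs(list(cbind(101, 1250)))
  expect_error(suppressMessages(call_rt_transcripts(txs, genes, 30)),
               "protein-coding")
  txs2 <- make_txs(list(cbind(101, 1250)), chrom = "chrX")
  # seqlevel-mismatch warning from findOverlaps is expected here
  res <- suppressWarnings(suppressMessages(call_rt_transcripts(txs2, tandem_pair(), 30)))
  expect_equal(nrow(res), 0L)
})

test_that("call_rt_transcripts agrees with the per-base oracle on random scenes", {
  for (seed in 1:60) {
    sc <- random_scene(seed)
    res <- suppressMessages(call_rt_transcripts(sc$txs, sc$genes, 30))
    got <- setNames(as.list(res$gene_chain), res$transcript_id)
    want <- oracle_rt_call(sc$txs, sc$gene_df, 30)
    expect_equal(length(got), length(want), info = paste("seed", seed))
    if (length(want))
      expect_identical(got[sort(names(got))], want[sort(names(want))],
                       info = paste("seed", seed))
  }
})

test_that("raising min_cds_overlap_bp never increases RT calls", {
  for (seed in 1:10) {
    sc <- random_scene(seed + 100)
    n_prev <- Inf
    for (thr in c(1, 30, 80, 200)) {
      n <- nrow(suppressMessages(call_rt_transcripts(sc$txs, sc$genes, thr)))
      expect_lte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("group_rt_loci groups by ordered gene tuple and partitions by sample", {
  genes <- tandem_pair()
  txs <- make_txs(list(cbind(101, 1250),
                       rbind(c(101, 700), c(790, 1250)),
                       cbind(101, 1250)),
                  strand = "+", sample_id = c("s1", "s1", "s2"))
  asg <- suppressMessages(call_rt_transcripts(txs, genes, 30))
  loci <- suppressMessages(group_rt_loci(asg, genes))
  expect_equal(nrow(loci), 1L)  # same gene pair, different exon chains
  expect_length(loci$transcript_ids[[1]], 3L)
  expect_equal(sort(unique(loci$sample_ids[[1]])), c("s1", "s2"))
  expect_equal(as.vector(table(loci$sample_ids[[1]])), c(2L, 1L))
})

test_that("distinct gene tuples give distinct loci", {
  extra <- data.frame(gene_id = "gC", chrom = "chr1", start = 1501, end = 1950,
                      strand = "+", cds_start = 1551, cds_end = 1850,
                      stringsAsFactors = FALSE)
  genes <- tandem_pair(extra = extra)
  txs <- make_txs(list(cbind(101, 1250), cbind(101, 1950)), strand = "+")
  asg <- suppressMessages(call_rt_transcripts(txs, genes, 30))
  loci <- suppressMessages(group_rt_loci(asg, genes))
  expect_equal(nrow(loci), 2L)
  expect_setequal(loci$gene_chain, c("gA,gB", "gA,gB,gC"))
})

test_that("summarize_counts reproduces the three-level counting", {
  genes <- tandem_pair()
  txs <- make_txs(list(cbind(101, 1250),
                       cbind(101, 1250),
                       rbind(c(101, 700), c(790, 1250))),
                  strand = "+", sample_id = "s1")
  asg <- suppressMessages(call_rt_transcripts(txs, genes, 30))
  loci <- suppressMessages(group_rt_loci(asg, genes))
  s <- summarize_counts(loci, c(s1 = 1000))
  expect_equal(s$n_rts, 3L)
  expect_equal(s$n_rt_variants, 2L)  # two distinct intron chains
  expect_equal(s$n_rt_loci, 1L)
  expect_equal(s$proportion_pct, 0.3)
  expect_error(summarize_counts(loci, c(s1 = 0)), "> 0")
  # sample with no RTs: all-zero row
  s2 <- summarize_counts(loci, c(s1 = 1000, sX = 500))
  expect_equal(s2$n_rts[s2$sample_id == "sX"], 0L)
  expect_equal(s2$proportion_pct[s2$sample_id == "sX"], 0)
})

test_that("detect_monocistronic_counterparts separates roles and flags", {
  genes <- tandem_pair()
  txs <- make_txs(list(cbind(101, 1250),    # RT
                       cbind(101, 550),     # first mono
                       cbind(101, 580),     # first mono: ends 30 nt into gap
                       cbind(801, 1250)),   # second mono
                  strand = "+")
  asg <- suppressMessages(call_rt_transcripts(txs, genes, 30))
  loci <- suppressMessages(group_rt_loci(asg, genes))
  mono <- detect_monocistronic_counterparts(loci[1, ], txs, genes, 30)
  expect_setequal(mono$first_monos, c("tx2", "tx3"))
  expect_equal(mono$second_monos, "tx4")
  expect_true(mono$has_first_monocistronic)
  expect_true(mono$has_second_monocistronic)
  # partition: every transcript lands in exactly one class
  classes <- c(RT = 1L, mono = length(mono$first_monos) + length(mono$second_monos))
  expect_equal(sum(classes), 4L)
})
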