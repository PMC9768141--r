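cage_track <- function(df) {
  gr <- GRanges(df$chrom, IRanges(df$position, width = 1), strand = df$strand)
  gr$tpm <- df$tpm
  gr
}

test_that("tss_supported uses a strict TPM threshold and strand-aware window", {
  gene <- GRanges("chr1", IRanges(1000, 1500), strand = "+")
  at <- function(pos, tpm, strand = "+")
    cage_track(data.frame(chrom = "chr1", strand = strand, position = pos, tpm = tpm))
  expect_true(tss_supported(gene, at(1000, 0.3)))
  expect_false(tss_supported(gene, at(1000, 0.2)))  # boundary: strictly > 0.2
  expect_false(tss_supported(gene, at(1000, 5, strand = "-")))
  expect_true(tss_supported(gene, at(1099, 0.3), window_nt = 100))
  expect_false(tss_supported(gene, at(1101, 0.3), window_nt = 100))
  # minus-strand gene: 5' end is the span end
  gene_m <- GRanges("chr1", IRanges(1000, 1500), strand = "-")
  expect_true(tss_supported(gene_m, at(1510, 0.3, strand = "-"), window_nt = 20))
  expect_false(tss_supported(gene_m, at(1000, 0.3, strand = "-"), window_nt = 20))
})

test_that("translation_efficiency is the footprint:RNA ratio with a zero guard", {
  expect_equal(translation_efficiency(30, 10), 3)
  expect_equal(translation_efficiency(0, 10), 0)
  te <- translation_efficiency(30, 0)
  expect_true(is.na(te))
  expect_equal(attr(te, "undefined"), 1L)
  expect_error(translation_efficiency(-1, 10), "non-negative")
})

test_that("TE is scale-invariant under common library rescaling", {
  te1 <- translation_efficiency(30, 10, fp_libsize = 1e6, rna_libsize = 2e6,
                                normalize = TRUE)
  te2 <- translation_efficiency(30, 10, fp_libsize = 3e6, rna_libsize = 6e6,
                                normalize = TRUE)
  expect_equal(te1, te2)
})

test_that("compare_orf_te emits all pairwise Tukey comparisons deterministically", {
  mk <- function(construct, role, fp, rna) data.frame(
    orf_id = paste0(construct, "_", role), role = role, construct = construct,
    replicate = seq_along(fp), footprint_count = fp, rna_count = rna,
    fp_libsize = 1e6, rna_libsize = 1e6, stringsAsFactors = FALSE)

  # identical replicate TEs in both groups -> adjusted p = 1
  same <- rbind(mk("c1", "first", c(10, 20, 30), c(10, 10, 10)),
                mk("c1", "second", c(10, 20, 30), c(10, 10, 10)))
  res <- compare_orf_te(same)
  expect_equal(res$comparisons$p_adj, 1)

  # three groups -> 3 pairwise comparisons, ordered by label
  three <- rbind(mk("c1", "first", c(10, 12, 14), c(10, 10, 10)),
                 mk("c1", "second", c(9, 11, 13), c(10, 10, 10)),
                 mk("c2", "first", c(8, 10, 12), c(10, 10, 10)))
  res3 <- compare_orf_te(three)
  expect_equal(nrow(res3$comparisons), 3L)
  expect_equal(res3$comparisons, res3$comparisons[order(res3$comparisons$group1,
                                                        res3$comparisons$group2), ],
               ignore_attr = TRUE)

  # a group with all-undefined TE is dropped with a warning
  undef <- rbind(mk("c1", "first", c(10, 12, 14), c(10, 10, 10)),
                 mk("c1", "second", c(5, 6, 7), c(0, 0, 0)),
                 mk("c2", "first", c(9, 11, 13), c(10, 10, 10)))
  expect_warning(resu <- compare_orf_te(undef), "excluded")
  expect_equal(nrow(resu$groups), 2L)
})

test_that("a planted 50-fold TE difference is detected, consistent with a permutation oracle", {
  set.seed(202)
  fp_first <- rpois(3, 200); rna_first <- rpois(3, 200)
  fp_second <- rpois(3, 4); rna_second <- rpois(3, 200)
  df <- data.frame(
    orf_id = rep(c("o1", "o2"), each = 3),
    role = rep(c("first", "second"), each = 3),
    construct = "c1", replicate = rep(1:3, 2),
    footprint_count = c(fp_first, fp_second),
    rna_count = c(rna_first, rna_second),
    fp_libsize = 1e6, rna_libsize = 1e6, stringsAsFactors = FALSE)
  res <- compare_orf_te(df)
  expect_equal(nrow(res$comparisons), 1L)
  expect_lt(res$comparisons$p_adj, 0.01)
  # direction: first > second on the log scale
  d <- if (grepl(":first$", res$comparisons$group1))
    res$comparisons$diff_log_te else -res$comparisons$diff_log_te
  expect_gt(d, 0)
  # permutation oracle agrees the difference is extreme at matched alpha:
  # with 3+3 observations the smallest achievable two-sided permutation p is
  # 2/C(6,3) = 0.1 (a split and its mirror), so check p at that floor plus
  # Monte-Carlo slack
  p_perm <- oracle_permutation_p(log(fp_first / rna_first),
                                 log(fp_second / rna_second))
  expect_lte(p_perm, 0.12)
})

test_that("hypergeom_enrichment matches exhaustive enumeration", {
  # the worked small case: population 10 with 4 successes, draw 5, observe >= 3
  expect_equal(hypergeom_enrichment(10, 4, 5, 3), 11 / 42, tolerance = 1e-12)
  expect_equal(oracle_hypergeom(10, 4, 5, 3), 11 / 42, tolerance = 1e-12)
  # trivial bounds
  expect_equal(hypergeom_enrichment(20, 5, 7, 0), 1)
  expect_equal(hypergeom_enrichment(10, 3, 3, 3), 1 / choose(10, 3),
               tolerance = 1e-12)
  expect_error(hypergeom_enrichment(10, 12, 5, 3), "impossible")
  expect_error(hypergeom_enrichment(10, 4, 5, 6), "impossible")
})

test_that("localization_distribution tallies roles with unknown fallback", {
  df <- data.frame(
    gene_id = c("a1", "a2", "b1", "b2"), chrom = "chr1",
    start = c(1, 501, 1001, 1501), end = c(400, 900, 1400, 1900),
    strand = "+", cds_start = c(51, 551, 1051, 1551),
    cds_end = c(350, 850, 1350, 1850),
    localization = c("mitochondrion", "other", "chloroplast", "unknown"),
    stringsAsFactors = FALSE)
  genes <- make_gene_set(df)
  loci <- data.frame(gene_chain = c("a1,a2", "b1,b2"), stringsAsFactors = FALSE)
  dist <- localization_distribution(loci, genes)
  first <- dist[dist$role == "first", ]
  expect_equal(first$count[first$localization == "mitochondrion"], 1L)
  expect_equal(first$count[first$localization == "chloroplast"], 1L)
  expect_equal(sum(first$count), 2L)
  expect_equal(sum(first$fraction), 1)
  all_bg <- dist[dist$role == "all_genes", ]
  expect_equal(sum(all_bg$count), 4L)

  # empty locus list
  dist0 <- localization_distribution(loci[0, , drop = FALSE], genes)
  expect_equal(sum(dist0$count[dist0$role == "first"]), 0L)
})

test_that("set_localization labels genes and defaults absentees to unknown", {
  df <- data.frame(gene_id = c("a1", "a2"), chrom = "chr1",
                   start = c(1, 501), end = c(400, 900), strand = "+",
                   cds_start = c(51, 551), cds_end = c(350, 850),
                   stringsAsFactors = FALSE)
  genes <- make_gene_set(df)
  genes <- set_localization(genes, data.frame(gene_id = "a1",
                                              localization = "chloroplast"))
  expect_equal(genes$span$localization, c("chloroplast", "unknown"))
  expect_error(set_localization(genes, data.frame(gene_id = "a1",
                                                  localization = "nucleus")),
               "unknown localization")
})
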