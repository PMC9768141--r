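## CAGE TSS support, ribosome-profiling translation efficiency (TE), and
## organelle-localization enrichment.

# 5' end of a gene span in transcription direction (1-based).
gene_5p_end <- function(span) {
  ifelse(as.character(strand(span)) == "-", end(span), start(span))
}

#' CAGE support of a gene's transcription start site
#'
#' `TRUE` iff any same-strand CAGE position within `window_nt` of the gene's
#' annotated 5' end has TPM strictly greater than `tpm_threshold`.
#'
#' @param gene A length-1 GRanges gene span (e.g. one element of
#'   `gene_set$span`).
#' @param cage CAGE track from [read_cage()].
#' @param tpm_threshold Strict lower TPM bound (default 0.2).
#' @param window_nt Half-width of the search window around the annotated 5'
#'   end (default 100).
#' @return Logical scalar.
#' @export
tss_supported <- function(gene, cage, tpm_threshold = 0.2, window_nt = 100L) {
  stopifnot(length(gene) == 1L)
  if (window_nt < 0L) stop("window_nt must be >= 0")
  tss <- gene_5p_end(gene)
  win <- GRanges(seqnames(gene),
                 IRanges::IRanges(max(1L, tss - window_nt), tss + window_nt),
                 strand = strand(gene))
  hit <- cage[S4Vectors::queryHits(findOverlaps(cage, win, ignore.strand = FALSE))]
  any(hit$tpm > tpm_threshold)
}

#' Read a per-ORF count table
#'
#' TSV with columns `orf_id`, `role` (`first`/`second`), `construct`,
#' `replicate`, `footprint_count`, `rna_count`, `fp_libsize`, `rna_libsize`.
#' Footprint counts are expected to be pre-filtered to 27-29 nt footprints
#' (this package takes count tables, not alignments).
#'
#' @param path TSV path.
#' @return The validated data.frame.
#' @export
read_orf_counts <- function(path) {
  df <- read_tsv(path)
  need <- c("orf_id", "role", "construct", "replicate",
            "footprint_count", "rna_count", "fp_libsize", "rna_libsize")
  if (!all(need %in% names(df)))
    stop("ORF count TSV needs columns: ", paste(need, collapse = ", "))
  if (any(df$footprint_count < 0) || any(df$rna_count < 0))
    stop("negative counts in ORF table")
  if (!all(df$role %in% c("first", "second")))
    stop("role must be 'first' or 'second'")
  df
}

#' Translation efficiency of an ORF
#'
#' TE = footprint count / RNA count. With `normalize = TRUE` both counts are
#' scaled to per-million of their library sizes first (which leaves the TE
#' ratio structure intact). Zero RNA counts yield `NA` with attribute
#' `undefined = TRUE`; such values are excluded from group statistics.
#'
#' @param footprint_count,rna_count Non-negative counts.
#' @param fp_libsize,rna_libsize Library sizes (required when normalizing).
#' @param normalize Scale to counts per million before the ratio.
#' @return Numeric vector of TE values (`NA` where RNA count is zero).
#' @export
translation_efficiency <- function(footprint_count, rna_count,
                                   fp_libsize = NULL, rna_libsize = NULL,
                                   normalize = FALSE) {
  if (any(footprint_count < 0) || any(rna_count < 0))
    stop("counts must be non-negative")
  fp <- footprint_count
  rna <- rna_count
  if (normalize) {
    if (is.null(fp_libsize) || is.null(rna_libsize))
      stop("library sizes required when normalize = TRUE")
    fp <- 1e6 * fp / fp_libsize
    rna <- 1e6 * rna / rna_libsize
  }
  te <- ifelse(rna_count == 0, NA_real_, fp / rna)
  if (anyNA(te)) attr(te, "undefined") <- which(is.na(te))
  te
}

#' Compare translation efficiency across ORF groups
#'
#' Groups are `construct x role` cells. TE is computed per replicate,
#' log-transformed (ratios are multiplicative), and all pairwise group
#' differences are tested with Tukey's HSD on a one-way ANOVA. Groups whose
#' TE is undefined in every replicate are dropped with a warning.
#'
#' @param orf_counts A data.frame as returned by [read_orf_counts()].
#' @param normalize Per-million library scaling before the ratio (default
#'   TRUE).
#' @return A list with `groups` (per-group n, mean TE, sd TE, mean log TE)
#'   and `comparisons` (pairwise `group1`, `group2`, `diff_log_te`,
#'   `p_adj`), both ordered by group label.
#' @export
compare_orf_te <- function(orf_counts, normalize = TRUE) {
  df <- orf_counts
  df$te <- translation_efficiency(df$footprint_count, df$rna_count,
                                  df$fp_libsize, df$rna_libsize,
                                  normalize = normalize)
  df$group <- paste(df$construct, df$role, sep = ":")
  defined <- !is.na(df$te) & df$te > 0
  all_undef <- tapply(defined, df$group, sum) == 0L
  if (any(all_undef)) {
    rt_warn("group(s) with no defined positive TE excluded: ",
            paste(names(all_undef)[all_undef], collapse = ", "))
    df <- df[!(df$group %in% names(all_undef)[all_undef]), , drop = FALSE]
  }
  df <- df[!is.na(df$te) & df$te > 0, , drop = FALSE]
  groups <- sort(unique(df$group))
  if (length(groups) < 2L) stop("need >= 2 groups with defined TE")
  if (any(tapply(df$te, df$group, length) < 2L))
    stop("need >= 2 replicates with defined TE per group")
  df$log_te <- log(df$te)
  df$group <- factor(df$group, levels = groups)
  fit <- aov(log_te ~ group, data = df)
  tk <- TukeyHSD(fit)$group
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  comparisons <- data.frame(
    group1 = vapply(pair, `[`, character(1), 1L),
    group2 = vapply(pair, `[`, character(1), 2L),
    diff_log_te = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"]),
    stringsAsFactors = FALSE)
  comparisons <- comparisons[order(comparisons$group1, comparisons$group2), ,
                             drop = FALSE]
  rownames(comparisons) <- NULL
  group_stats <- data.frame(
    group = groups,
    n = as.integer(tapply(df$te, df$group, length)),
    mean_te = as.numeric(tapply(df$te, df$group, mean)),
    sd_te = as.numeric(tapply(df$te, df$group, sd)),
    mean_log_te = as.numeric(tapply(df$log_te, df$group, mean)),
    stringsAsFactors = FALSE)
  rownames(group_stats) <- NULL
  list(groups = group_stats, comparisons = comparisons)
}

#' Upper-tail hypergeometric enrichment test
#'
#' P(X >= sample_successes) when drawing `sample_size` genes without
#' replacement from a population of `population_size` genes of which
#' `population_successes` carry the label. Computed in log space with
#' [lchoose()] for numerical stability.
#'
#' @param population_size,population_successes,sample_size,sample_successes
#'   Non-negative integers; successes cannot exceed the corresponding sizes.
#' @return The upper-tail p-value in (0, 1].
#' @export
hypergeom_enrichment <- function(population_size, population_successes,
                                 sample_size, sample_successes) {
  N <- population_size; K <- population_successes
  n <- sample_size; k <- sample_successes
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > n || k > K)
    stop("impossible hypergeometric configuration")
  jmax <- min(n, K)
  j <- k:jmax
  # need n - j <= N - K
  j <- j[n - j <= N - K]
  if (length(j) == 0L) stop("impossible hypergeometric configuration")
  logp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  p <- sum(exp(logp))
  min(p, 1)
}

#' Localization distribution of RT-locus genes
#'
#' Counts and fractions of subcellular-localization categories for the first
#' genes, last ("second") genes, and the whole-annotation background.
#'
#' @param loci An `rt_loci` data.frame.
#' @param genes A [gene_set] whose `localization` column is filled (see
#'   [set_localization()]).
#' @return A data.frame with `role` (`first`, `second`, `all_genes`),
#'   `localization`, `count`, `total`, `fraction`.
#' @export
localization_distribution <- function(loci, genes) {
  loc <- setNames(genes$span$localization, genes$span$gene_id)
  cats <- c("mitochondrion", "chloroplast", "other", "unknown")
  chain <- strsplit(loci$gene_chain, ",", fixed = TRUE)
  first <- vapply(chain, `[`, character(1), 1L)
  second <- vapply(chain, function(x) x[length(x)], character(1))
  one <- function(ids, role) {
    l <- unname(loc[ids]); l[is.na(l)] <- "unknown"
    cnt <- table(factor(l, levels = cats))
    data.frame(role = role, localization = cats, count = as.integer(cnt),
               total = length(ids),
               fraction = if (length(ids)) as.numeric(cnt) / length(ids) else 0,
               stringsAsFactors = FALSE)
  }
  rbind(one(first, "first"), one(second, "second"),
        one(genes$span$gene_id, "all_genes"))
}

#' Enrichment of organelle-localized first genes
#'
#' Convenience wrapper: builds the hypergeometric input from a locus table
#' and gene set (successes = genes labelled mitochondrion or chloroplast)
#' and returns the upper-tail p-value for the first genes.
#'
#' @inheritParams localization_distribution
#' @return A list: `p_value` plus the four hypergeometric inputs.
#' @export
first_gene_organelle_enrichment <- function(loci, genes) {
  loc <- setNames(genes$span$localization, genes$span$gene_id)
  organelle <- c("mitochondrion", "chloroplast")
  first <- vapply(strsplit(loci$gene_chain, ",", fixed = TRUE), `[`, character(1), 1L)
  first <- unique(first)
  inp <- list(population_size = length(loc),
              population_successes = sum(loc %in% organelle),
              sample_size = length(first),
              sample_successes = sum(loc[first] %in% organelle))
  c(list(p_value = do.call(hypergeom_enrichment, inp)), inp)
}
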