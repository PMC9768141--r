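# Independent oracles. Each re-derives an expected result by brute force and
# stays deliberately naive: per-base set arithmetic, substring loops,
# exhaustive subset enumeration. None of them call the code paths they check.

# Per-base RT calling oracle: exonic base set vs CDS base set per gene,
# same-strand, >= min_bp each for >= 2 genes; genes whose spans share any
# base with another qualifying gene's span are excluded; chain ordered by
# span start, reversed on minus.
oracle_rt_call <- function(txs, gene_df, min_bp) {
  res <- list()
  for (i in seq_along(txs)) {
    ex <- txs[[i]]
    tx_strand <- as.character(BiocGenerics::strand(ex))[1]
    bases <- unlist(lapply(seq_along(ex), function(j)
      seq(BiocGenerics::start(ex)[j], BiocGenerics::end(ex)[j])))
    qual <- character()
    for (g in seq_len(nrow(gene_df))) {
      if (gene_df$strand[g] != tx_strand) next
      cds_bases <- seq(gene_df$cds_start[g], gene_df$cds_end[g])
      if (!is.na(match("cds2_start", names(gene_df))) &&
          !is.na(gene_df$cds2_start[g]))
        cds_bases <- c(cds_bases, seq(gene_df$cds2_start[g], gene_df$cds2_end[g]))
      if (length(intersect(bases, cds_bases)) >= min_bp)
        qual <- c(qual, gene_df$gene_id[g])
    }
    if (length(qual) >= 2L) {
      keep <- vapply(qual, function(a) {
        sa <- seq(gene_df$start[match(a, gene_df$gene_id)],
                  gene_df$end[match(a, gene_df$gene_id)])
        !any(vapply(setdiff(qual, a), function(b) {
          sb <- seq(gene_df$start[match(b, gene_df$gene_id)],
                    gene_df$end[match(b, gene_df$gene_id)])
          length(intersect(sa, sb)) > 0L
        }, logical(1)))
      }, logical(1))
      qual <- qual[keep]
    }
    if (length(qual) < 2L) next
    ord <- order(gene_df$start[match(qual, gene_df$gene_id)])
    if (tx_strand == "-") ord <- rev(ord)
    res[[names(txs)[i]]] <- paste(qual[ord], collapse = ",")
  }
  res
}

# Sliding-window hexamer scan oracle on a plain character string
# (transcription-direction sequence); returns 1-based offsets.
oracle_hexamer_scan <- function(seq_str, set) {
  hits <- data.frame(hexamer = character(), offset = integer(),
                     stringsAsFactors = FALSE)
  n <- nchar(seq_str)
  if (n < 6L) return(hits)
  for (o in 1:(n - 5L)) {
    w <- substr(seq_str, o, o + 5L)
    if (w %in% set)
      hits <- rbind(hits, data.frame(hexamer = w, offset = o,
                                     stringsAsFactors = FALSE))
  }
  hits
}

# Exhaustive hypergeometric upper tail: enumerate all C(N, n) draws from a
# population whose first K members are successes.
oracle_hypergeom <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)
  mean(succ >= k)
}

# Sweep-line interval union oracle over 1-based closed intervals.
oracle_union <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  rs <- starts[1]; re <- ends[1]; out <- NULL
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= re + 1L) re <- max(re, ends[i])
    else { out <- rbind(out, c(rs, re)); rs <- starts[i]; re <- ends[i] }
  }
  rbind(out, c(rs, re))
}

# Two-group permutation test on log TE (first vs second), two-sided on the
# mean difference.
oracle_permutation_p <- function(log_te_first, log_te_second, n_perm = 2000,
                                 seed = 1) {
  set.seed(seed)
  obs <- abs(mean(log_te_first) - mean(log_te_second))
  pool <- c(log_te_first, log_te_second)
  n1 <- length(log_te_first)
  stat <- replicate(n_perm, {
    idx <- sample.int(length(pool), n1)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  (sum(stat >= obs) + 1) / (n_perm + 1)
}

# single-linkage position clustering oracle on sorted positions
oracle_cluster_count <- function(pos, radius) {
  pos <- sort(pos)
  sum(diff(pos) > radius) + 1L
}
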