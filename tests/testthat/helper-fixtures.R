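# Fixture builders shared across the suite. Everything is generated in code;
# no stored data files.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# gene_set from a plain table: one row per gene, single CDS interval unless
# cds2_start/cds2_end are given.
make_gene_set <- function(df) {
  span <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  span$gene_id <- df$gene_id
  span$biotype <- df$biotype %||% rep("protein_coding", nrow(df))
  span$localization <- df$localization %||% rep("unknown", nrow(df))
  cds <- lapply(seq_len(nrow(df)), function(i) {
    s <- c(df$cds_start[i], df$cds2_start[i])
    e <- c(df$cds_end[i], df$cds2_end[i])
    keep <- !is.na(s)
    GRanges(df$chrom[i], IRanges(s[keep], e[keep]), strand = df$strand[i])
  })
  cds <- GRangesList(cds)
  names(cds) <- df$gene_id
  gene_set(span, cds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# transcripts GRangesList from a list of exon matrices (2 cols: start, end)
make_txs <- function(exon_list, chrom = "chr1", strand = "+",
                     sample_id = "s1", read_count = NULL, ids = NULL) {
  n <- length(exon_list)
  if (length(strand) == 1L) strand <- rep(strand, n)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  ids <- ids %||% paste0("tx", seq_len(n))
  gl <- GRangesList(lapply(seq_len(n), function(i) {
    m <- exon_list[[i]]
    sort(GRanges(chrom[i], IRanges(m[, 1], m[, 2]), strand = strand[i]))
  }))
  names(gl) <- ids
  mcols(gl) <- S4Vectors::DataFrame(
    transcript_id = ids,
    sample_id = if (length(sample_id) == 1L) rep(sample_id, n) else sample_id,
    read_count = as.integer(read_count %||% rep(1L, n)))
  gl
}

# Random small annotation + transcripts for oracle-equivalence testing.
# Genes may overlap in span (exercises the span-overlap exclusion) and sit
# on both strands; transcripts get 1-3 exons.
random_scene <- function(seed, n_genes_max = 20L, n_tx = 15L) {
  set.seed(seed)
  n_genes <- sample(2:n_genes_max, 1L)
  starts <- sort(sample.int(5000, n_genes))
  widths <- sample(80:400, n_genes, replace = TRUE)
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  df <- data.frame(
    gene_id = sprintf("g%02d", seq_len(n_genes)), chrom = "chr1",
    start = starts, end = starts + widths, strand = strands,
    cds_start = starts + 10L, cds_end = starts + widths - 10L,
    stringsAsFactors = FALSE)
  genes <- make_gene_set(df)
  exon_list <- list(); tx_strand <- character()
  for (i in seq_len(n_tx)) {
    s <- sample.int(5200, 1L)
    len <- sample(100:1500, 1L)
    n_ex <- sample(1:3, 1L)
    if (n_ex == 1L) {
      m <- cbind(s, s + len)
    } else {
      cuts <- sort(sample(seq(s + 20L, s + len - 20L), 2L * (n_ex - 1L)))
      bounds <- c(s, cuts, s + len)
      m <- cbind(bounds[seq(1L, length(bounds), 2L)],
                 bounds[seq(2L, length(bounds), 2L)])
    }
    exon_list[[i]] <- m
    tx_strand[i] <- sample(c("+", "-"), 1L)
  }
  list(genes = genes, gene_df = df,
       txs = make_txs(exon_list, strand = tx_strand))
}

# toy genome: DNAStringSet from explicit strings
make_genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}
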