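## RT (readthrough transcript) calling.
##
## A transcript is a readthrough candidate iff its exonic bases overlap the
## merged CDS of >= 2 distinct same-strand protein-coding genes by at least
## `min_cds_overlap_bp` each. CDS overlap (not gene-span overlap) is the
## criterion so that a 3'UTR overhang into a neighbour's UTR never calls an
## RT. Genes whose annotated spans overlap another qualifying gene's span are
## dropped as partners: overlapping annotations co-span trivially and are not
## readthrough.

# Sum of exonic overlap (bp) between one transcript's exons and one gene's
# merged CDS. Both already same chrom/strand when called.
exonic_cds_overlap <- function(exons, cds) {
  sum(width(GenomicRanges::intersect(exons, cds, ignore.strand = TRUE)))
}

# Sparse transcript x gene exonic-CDS overlap in bp, strand-matched, in one
# findOverlaps pass. Exact because exons within a transcript and merged CDS
# within a gene are each non-overlapping.
overlap_bp_table <- function(transcripts, cds_list) {
  ex <- unlist(transcripts, use.names = FALSE)
  tx_of_ex <- rep(seq_along(transcripts), lengths(transcripts))
  cd <- unlist(cds_list, use.names = FALSE)
  gene_of_cd <- rep(seq_along(cds_list), lengths(cds_list))
  h <- findOverlaps(ex, cd, ignore.strand = FALSE)
  if (length(h) == 0L)
    return(data.frame(tx = integer(), gene = integer(), bp = integer()))
  q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
  bp <- pmin(end(ex)[q], end(cd)[s]) - pmax(start(ex)[q], start(cd)[s]) + 1L
  agg <- rowsum(bp, group = paste(tx_of_ex[q], gene_of_cd[s]))
  key <- strsplit(rownames(agg), " ", fixed = TRUE)
  data.frame(tx = as.integer(vapply(key, `[`, character(1), 1L)),
             gene = as.integer(vapply(key, `[`, character(1), 2L)),
             bp = as.integer(agg[, 1L]))
}

#' Call readthrough transcripts
#'
#' @param transcripts GRangesList of exons from [read_transcripts()].
#' @param genes A [gene_set]. Only protein-coding genes participate.
#' @param min_cds_overlap_bp Minimum exonic overlap with each gene's CDS
#'   (default 30 bp).
#' @return A data.frame with one row per RT transcript: `transcript_id`,
#'   `sample_id`, `read_count`, `chrom`, `strand`, `gene_chain` (comma-joined
#'   gene ids, 5' to 3' in transcription direction), `n_genes`,
#'   `intron_signature`.
#' @export
call_rt_transcripts <- function(transcripts, genes, min_cds_overlap_bp = 30L) {
  stopifnot(is(genes, "gene_set"))
  stopifnot_scalar_count(min_cds_overlap_bp, "min_cds_overlap_bp")
  pc <- genes$span[genes$span$biotype == "protein_coding"]
  if (length(pc) == 0L) stop("empty protein-coding gene set")
  cds <- genes$cds[pc$gene_id]

  rng <- unlist(range(transcripts), use.names = FALSE)
  missing_chrom <- !(as.character(seqnames(rng)) %in%
                       unique(as.character(seqnames(pc))))
  if (any(missing_chrom))
    rt_log(sum(missing_chrom), " transcript(s) on sequences absent from the ",
           "annotation: not RT")

  ov <- overlap_bp_table(transcripts, cds)
  ov <- ov[ov$bp >= min_cds_overlap_bp, , drop = FALSE]
  tx_strand <- as.character(strand(rng))
  tx_chrom <- as.character(seqnames(rng))
  out <- vector("list", length(transcripts))
  for (i in unique(ov$tx)) {
    qual <- ov$gene[ov$tx == i]
    if (length(qual) < 2L) next
    # drop genes whose span overlaps another qualifying gene's span
    qspan <- pc[qual]
    co <- countOverlaps(qspan, qspan, ignore.strand = FALSE)
    qual <- qual[co == 1L]
    if (length(qual) < 2L) next
    ord <- order(start(pc)[qual])
    if (tx_strand[i] == "-") ord <- rev(ord)
    out[[i]] <- data.frame(
      transcript_id = mcols(transcripts)$transcript_id[i],
      sample_id = mcols(transcripts)$sample_id[i] %||% NA_character_,
      read_count = mcols(transcripts)$read_count[i] %||% 1L,
      chrom = tx_chrom[i],
      strand = tx_strand[i],
      gene_chain = paste(pc$gene_id[qual][ord], collapse = ","),
      n_genes = length(qual),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(transcript_id = character(), sample_id = character(),
                      read_count = integer(), chrom = character(),
                      strand = character(), gene_chain = character(),
                      n_genes = integer(), stringsAsFactors = FALSE)
  res$intron_signature <- intron_signature(transcripts[res$transcript_id])
  rt_log("call_rt_transcripts: ", nrow(res), " RT transcript(s) of ",
         length(transcripts))
  res
}

#' Group RT transcript assignments into loci
#'
#' One locus per distinct ordered gene tuple, supporting transcripts
#' partitioned by sample; loci sorted by chromosome then start.
#'
#' @param assignments Row-bound output of [call_rt_transcripts()] over all
#'   samples.
#' @param genes The [gene_set] used for calling (locates loci for sorting).
#' @return A data.frame of class `rt_loci`: `locus_id`, `chrom`, `strand`,
#'   `gene_chain`, `n_genes`, plus list-columns `transcript_ids`,
#'   `sample_ids`, `read_counts`, `intron_signatures` (parallel per
#'   supporting transcript).
#' @export
group_rt_loci <- function(assignments, genes) {
  if (nrow(assignments) == 0L) {
    res <- data.frame(locus_id = character(), chrom = character(),
                      strand = character(), gene_chain = character(),
                      n_genes = integer(), stringsAsFactors = FALSE)
    res$transcript_ids <- list(); res$sample_ids <- list()
    res$read_counts <- list(); res$intron_signatures <- list()
    class(res) <- c("rt_loci", "data.frame")
    return(res)
  }
  sp <- split(seq_len(nrow(assignments)), assignments$gene_chain)
  first_gene <- vapply(strsplit(names(sp), ",", fixed = TRUE), `[`, character(1), 1L)
  locus_start <- start(genes$span)[match(first_gene, genes$span$gene_id)]
  rows <- vapply(sp, `[`, integer(1), 1L)
  res <- data.frame(
    chrom = assignments$chrom[rows],
    strand = assignments$strand[rows],
    gene_chain = names(sp),
    n_genes = assignments$n_genes[rows],
    stringsAsFactors = FALSE)
  res$transcript_ids <- lapply(sp, function(j) assignments$transcript_id[j])
  res$sample_ids <- lapply(sp, function(j) assignments$sample_id[j])
  res$read_counts <- lapply(sp, function(j) assignments$read_count[j])
  res$intron_signatures <- lapply(sp, function(j) assignments$intron_signature[j])
  ord <- order(res$chrom, locus_start)
  res <- res[ord, , drop = FALSE]
  res <- cbind(locus_id = sprintf("RTL%04d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("rt_loci", "data.frame")
  rt_log("group_rt_loci: ", nrow(res), " locus/loci")
  res
}

#' Per-sample RT counting (three-level summary)
#'
#' Counts per sample: distinct RT exon-chain structures ("variants", keyed by
#' the intron-chain signature), supporting reads ("RTs"), and loci with at
#' least one supporting transcript, plus the proportion of RT reads among all
#' transcripts.
#'
#' @param loci An `rt_loci` data.frame from [group_rt_loci()].
#' @param total_transcripts_per_sample Named numeric vector: total number of
#'   transcripts identified per sample (> 0).
#' @return A data.frame with columns `sample_id`, `n_rt_variants`, `n_rts`,
#'   `n_rt_loci`, `n_total_transcripts`, `proportion_pct` (rounded to 3
#'   decimals).
#' @export
summarize_counts <- function(loci, total_transcripts_per_sample) {
  if (any(total_transcripts_per_sample <= 0))
    stop("total transcripts per sample must be > 0")
  samples <- names(total_transcripts_per_sample)
  if (is.null(samples)) stop("total_transcripts_per_sample must be named by sample")
  out <- lapply(samples, function(s) {
    n_rts <- 0L; n_loci <- 0L; sigs <- character()
    for (i in seq_len(nrow(loci))) {
      sel <- loci$sample_ids[[i]] == s
      if (!any(sel)) next
      n_loci <- n_loci + 1L
      n_rts <- n_rts + sum(loci$read_counts[[i]][sel])
      # variant key is per-locus: identical intron chains at different loci
      # are different structures
      sigs <- c(sigs, paste0(loci$locus_id[i], "|", loci$intron_signatures[[i]][sel]))
    }
    data.frame(sample_id = s,
               n_rt_variants = length(unique(sigs)),
               n_rts = n_rts,
               n_rt_loci = n_loci,
               n_total_transcripts = unname(total_transcripts_per_sample[s]),
               proportion_pct = round(100 * n_rts / total_transcripts_per_sample[s], 3),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Monocistronic counterparts at an RT locus
#'
#' Transcripts overlapping the first gene's CDS by at least the threshold and
#' no other locus gene's CDS are first-gene monocistronic counterparts;
#' symmetric for the last ("second") gene. RT transcripts themselves fall in
#' neither list.
#'
#' @param locus One row of an `rt_loci` data.frame.
#' @param transcripts GRangesList of all transcript models in the region.
#' @param genes The [gene_set].
#' @param min_cds_overlap_bp Overlap threshold, as in [call_rt_transcripts()].
#' @return A list with `first_monos` and `second_monos` (character vectors of
#'   transcript ids) and logical flags `has_first_monocistronic`,
#'   `has_second_monocistronic`.
#' @export
detect_monocistronic_counterparts <- function(locus, transcripts, genes,
                                              min_cds_overlap_bp = 30L) {
  chain <- strsplit(locus$gene_chain, ",", fixed = TRUE)[[1]]
  stopifnot(length(chain) >= 2L)
  ov <- overlap_bp_table(transcripts, genes$cds[chain])
  ov <- ov[ov$bp >= min_cds_overlap_bp, , drop = FALSE]
  hit <- matrix(FALSE, nrow = length(chain), ncol = length(transcripts))
  hit[cbind(ov$gene, ov$tx)] <- TRUE
  only <- function(g) which(hit[g, ] & colSums(hit[-g, , drop = FALSE]) == 0L)
  ids <- mcols(transcripts)$transcript_id %||% names(transcripts)
  first_monos <- ids[only(1L)]
  second_monos <- ids[only(length(chain))]
  list(first_monos = first_monos, second_monos = second_monos,
       has_first_monocistronic = length(first_monos) > 0L,
       has_second_monocistronic = length(second_monos) > 0L)
}
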