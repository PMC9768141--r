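## Intergenic splicing (IS): introns of an RT that join the 3' region of one
## gene to the 5' region of the next gene in the chain. The inter-CDS region
## is anchored at CDS ends (not annotated transcript ends) so the rule stays
## robust to UTR annotation quality: an intron qualifies iff, in transcription
## direction, its donor lies after the upstream gene's CDS 3' end and its
## acceptor before the downstream gene's CDS 5' start.

# 3'-most CDS coordinate of a gene in transcription direction (1-based).
cds_3p_end <- function(cds, strand) if (strand == "+") max(end(cds)) else min(start(cds))
cds_5p_start <- function(cds, strand) if (strand == "+") min(start(cds)) else max(end(cds))

#' Find IS introns at an RT locus
#'
#' Collects the introns of every supporting RT transcript, keeps those lying
#' entirely between the CDS 3' end of one chain gene and the CDS 5' start of
#' the next (exclusive at both anchors), merges identical introns across
#' reads with summed read support, and flags the most-supported intron of
#' each adjacent gene pair as `major` (ties broken by the 5'-most donor).
#'
#' @param locus One row of an `rt_loci` data.frame.
#' @param transcripts GRangesList of exons holding the locus's supporting
#'   transcripts (by `transcript_id`).
#' @param genes The [gene_set].
#' @return A data.frame with one row per distinct IS intron: `locus_id`,
#'   `pair_index` (1 = between first and second chain gene), `chrom`,
#'   `strand`, `start`, `end` (1-based closed), `donor_pos`, `acceptor_pos`,
#'   `support`, `major`.
#' @export
find_is_introns <- function(locus, transcripts, genes) {
  chain <- strsplit(locus$gene_chain, ",", fixed = TRUE)[[1]]
  strand <- locus$strand
  minus <- strand == "-"
  txids <- locus$transcript_ids[[1]] %||% locus$transcript_ids
  if (is.list(txids)) txids <- txids[[1]]
  support <- locus$read_counts[[1]] %||% locus$read_counts
  if (is.list(support)) support <- support[[1]]
  intr <- tx_introns(transcripts[txids])

  rows <- list()
  for (p in seq_len(length(chain) - 1L)) {
    up <- genes$cds[[chain[p]]]
    dn <- genes$cds[[chain[p + 1L]]]
    up3 <- cds_3p_end(up, strand)
    dn5 <- cds_5p_start(dn, strand)
    # exclusive inter-CDS region in genomic coordinates
    lo <- if (minus) dn5 + 1L else up3 + 1L
    hi <- if (minus) up3 - 1L else dn5 - 1L
    if (lo > hi) next
    for (t in seq_along(intr)) {
      x <- intr[[t]]
      keep <- start(x) >= lo & end(x) <= hi
      if (!any(keep)) next
      x <- x[keep]
      rows[[length(rows) + 1L]] <- data.frame(
        pair_index = p, start = start(x), end = end(x),
        support = support[t], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(locus_id = character(), pair_index = integer(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      donor_pos = integer(), acceptor_pos = integer(),
                      support = integer(), major = logical(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(support ~ pair_index + start + end, data = df, FUN = sum)
  agg$chrom <- locus$chrom
  agg$strand <- strand
  agg$locus_id <- locus$locus_id
  agg$donor_pos <- if (minus) agg$end else agg$start
  agg$acceptor_pos <- if (minus) agg$start else agg$end
  # major per adjacent pair: highest support, then 5'-most donor
  donor_rank <- if (minus) -agg$donor_pos else agg$donor_pos
  agg$major <- FALSE
  for (p in unique(agg$pair_index)) {
    sel <- which(agg$pair_index == p)
    best <- sel[order(-agg$support[sel], donor_rank[sel])][1L]
    agg$major[best] <- TRUE
  }
  ord <- order(agg$pair_index, agg$start)
  agg <- agg[ord, c("locus_id", "pair_index", "chrom", "strand", "start", "end",
                    "donor_pos", "acceptor_pos", "support", "major")]
  rownames(agg) <- NULL
  agg
}

# Single-linkage clustering of 1-based positions: positions whose sorted
# neighbours are <= radius apart share a cluster. One representative per
# cluster: the position with the highest summed support, ties broken 5'-most
# in transcription direction.
cluster_polya_table <- function(pos, support, radius, strand) {
  if (length(pos) == 0L)
    return(data.frame(rep_pos = integer(), total_support = numeric()))
  o <- order(pos)
  pos <- pos[o]; support <- support[o]
  cl <- cumsum(c(1L, as.integer(diff(pos) > radius)))
  out <- lapply(split(seq_along(pos), cl), function(j) {
    tab <- tapply(support[j], pos[j], sum)
    cand <- as.integer(names(tab)[tab == max(tab)])
    data.frame(rep_pos = if (strand == "-") max(cand) else min(cand),
               total_support = sum(support[j]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

cluster_polya_sites <- function(pos, support, radius, strand) {
  cluster_polya_table(pos, support, radius, strand)$rep_pos
}

#' Classify first-gene transcription termination at an RT locus
#'
#' PolyA sites of the locus's first-gene monocistronic transcripts are
#' clustered (single linkage, `cluster_radius_nt`); the locus is
#' `IS_with_internal_polyA` when any cluster representative falls strictly
#' inside an IS intron (on intron bases, excluding the donor base),
#' `IS_without_internal_polyA` when IS introns exist but no representative
#' does, and `no_IS` otherwise.
#'
#' @param locus One row of an `rt_loci` data.frame.
#' @param is_introns Output of [find_is_introns()] for this locus.
#' @param first_monos GRangesList of the first-gene monocistronic transcripts
#'   (may be empty).
#' @param cluster_radius_nt Single-linkage radius for 3'-end wobble
#'   (default 10 nt).
#' @return A data.frame row: `locus_id`, `class_label`, `n_polya_clusters`,
#'   `internal_polya_pos` (NA when none).
#' @export
classify_termination <- function(locus, is_introns, first_monos,
                                 cluster_radius_nt = 10L) {
  stopifnot_scalar_count(cluster_radius_nt, "cluster_radius_nt", min = 0L)
  label <- "no_IS"; internal <- NA_integer_; reps <- integer()
  if (nrow(is_introns) > 0L) {
    label <- "IS_without_internal_polyA"
    if (length(first_monos) > 0L) {
      pa <- polya_site(first_monos)
      support <- mcols(first_monos)$read_count %||% rep(1L, length(first_monos))
      reps <- cluster_polya_sites(pa$pos, support, cluster_radius_nt, locus$strand)
      for (r in reps) {
        inside <- r >= is_introns$start & r <= is_introns$end & r != is_introns$donor_pos
        if (any(inside)) { label <- "IS_with_internal_polyA"; internal <- r; break }
      }
    }
  }
  data.frame(locus_id = locus$locus_id, class_label = label,
             n_polya_clusters = length(reps), internal_polya_pos = internal,
             stringsAsFactors = FALSE)
}

#' Splice-site trinucleotides of an intron
#'
#' First three and last three intron bases in transcription direction
#' (reverse-complemented on the minus strand), with a canonical GT..AG flag.
#'
#' @param intron One row of a [find_is_introns()] data.frame (or any row-like
#'   list with `chrom`, `strand`, `start`, `end`).
#' @param genome A [Biostrings::DNAStringSet] keyed by chromosome.
#' @return A list: `donor_seq`, `acceptor_seq` (3 nt each), `canonical`.
#' @export
splice_site_dinucleotides <- function(intron, genome) {
  chrom <- as.character(intron$chrom)
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  if (intron$start < 1L || intron$end > length(genome[[chrom]]))
    stop("intron outside sequence bounds: ", chrom, ":", intron$start, "-", intron$end)
  s <- Biostrings::subseq(genome[[chrom]], intron$start, intron$end)
  if (intron$strand == "-") s <- Biostrings::reverseComplement(s)
  s <- as.character(s)
  n <- nchar(s)
  if (n < 6L) stop("intron shorter than 6 nt")
  donor <- substr(s, 1L, 3L)
  acceptor <- substr(s, n - 2L, n)
  list(donor_seq = donor, acceptor_seq = acceptor,
       canonical = substr(s, 1L, 2L) == "GT" && substr(s, n - 1L, n) == "AG")
}
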