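#' Construct a gene set
#'
#' A `gene_set` bundles annotated protein-coding gene models: one span per
#' gene plus the union of its CDS intervals across annotated isoforms.
#' Coordinates follow the Bioconductor convention (1-based, closed) on both
#' components.
#'
#' @param span A [GenomicRanges::GRanges] with one range per gene and
#'   metadata columns `gene_id`, `biotype` and `localization`
#'   (one of `"mitochondrion"`, `"chloroplast"`, `"other"`, `"unknown"`).
#' @param cds A [GenomicRanges::GRangesList] named by `gene_id`, each element
#'   the sorted, non-overlapping CDS intervals of that gene (merged across
#'   isoforms). Protein-coding genes must have at least one CDS interval.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(span, cds) {
  stopifnot(is(span, "GRanges"), is(cds, "GRangesList"))
  if (is.null(span$gene_id)) stop("span must carry a gene_id metadata column")
  if (anyDuplicated(span$gene_id)) stop("duplicated gene_id in span")
  if (is.null(span$biotype)) span$biotype <- "protein_coding"
  if (is.null(span$localization)) span$localization <- "unknown"
  if (!all(span$gene_id %in% names(cds)))
    stop("every gene needs a (possibly empty) cds element")
  cds <- cds[span$gene_id]
  names(span) <- span$gene_id
  # invariants: CDS within span, non-overlapping, sorted
  for (i in seq_along(span)) {
    ci <- cds[[i]]
    if (span$biotype[i] == "protein_coding" && length(ci) == 0L)
      stop("protein-coding gene without CDS: ", span$gene_id[i])
    if (length(ci)) {
      if (!all(start(ci) >= start(span)[i] & end(ci) <= end(span)[i]))
        stop("CDS outside gene span: ", span$gene_id[i])
      if (is.unsorted(start(ci)) || any(start(ci)[-1] <= end(ci)[-length(ci)]))
        stop("CDS intervals must be sorted and non-overlapping: ", span$gene_id[i])
    }
  }
  structure(list(span = span, cds = cds), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set: %d genes (%d protein-coding) on %d sequence(s)\n",
              length(x$span), sum(x$span$biotype == "protein_coding"),
              length(unique(as.character(seqnames(x$span))))))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$span)

#' Attach subcellular-localization labels to a gene set
#'
#' @param genes A [gene_set].
#' @param table A data.frame with columns `gene_id` and `localization`, or a
#'   named character vector. Genes absent from the table are labelled
#'   `"unknown"`.
#' @return The `gene_set` with its `localization` column replaced.
#' @export
set_localization <- function(genes, table) {
  if (is.data.frame(table)) table <- setNames(table$localization, table$gene_id)
  loc <- unname(table[genes$span$gene_id])
  loc[is.na(loc)] <- "unknown"
  bad <- setdiff(unique(loc), c("mitochondrion", "chloroplast", "other", "unknown"))
  if (length(bad)) stop("unknown localization label(s): ", paste(bad, collapse = ","))
  genes$span$localization <- loc
  genes
}

# Light structural pre-scan so a malformed GFF3 line is reported with its
# line number (rtracklayer's own errors do not carry one).
check_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^(#|\\s*$)", lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1L]]
    stop("malformed GFF3 at line ", bad, ": expected 9 tab-separated fields, got ",
         nf[which(nf != 9L)[1L]])
  }
  invisible(TRUE)
}

#' Read gene models from GFF3
#'
#' Parses a `gene`/`mRNA`/`CDS` hierarchy. CDS intervals of all annotated
#' isoforms of a gene are merged by union, and only genes whose biotype
#' matches `biotype_filter` are returned. GFF3's 1-based closed coordinates
#' are kept as-is (the package-wide convention).
#'
#' @param path Path to a GFF3 file.
#' @param biotype_filter Biotype to keep, or `NULL` for all genes. A gene's
#'   biotype is taken from a `biotype`/`gene_biotype` attribute when present,
#'   otherwise inferred: genes with CDS are `protein_coding`, others `other`.
#' @return A [gene_set].
#' @export
read_gff3_genes <- function(path, biotype_filter = "protein_coding") {
  check_gff3_lines(path)
  gff <- rtracklayer::import.gff3(path)
  genes <- gff[gff$type == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  gid <- genes$ID %||% genes$Name
  if (is.null(gid)) stop("gene features need ID attributes")

  tx <- gff[gff$type %in% c("mRNA", "transcript")]
  tx_parent <- as.character(unlist(tx$Parent, use.names = FALSE))
  tx2gene <- setNames(tx_parent, tx$ID)

  cds <- gff[gff$type == "CDS"]
  cds_parent <- vapply(cds$Parent, function(p)
    if (length(p)) as.character(p[1L]) else NA_character_, character(1))
  # CDS may hang off an mRNA (usual) or directly off a gene
  cds_gene <- ifelse(cds_parent %in% names(tx2gene),
                     tx2gene[cds_parent],
                     ifelse(cds_parent %in% gid, cds_parent, NA_character_))
  orphan <- is.na(cds_gene)
  if (any(orphan)) {
    rt_warn(sum(orphan), " CDS feature(s) without resolvable parent skipped")
    cds <- cds[!orphan]
    cds_gene <- cds_gene[!orphan]
  }
  cds_by_gene <- GenomicRanges::reduce(
    S4Vectors::split(granges(cds), factor(cds_gene, levels = gid)))

  biotype <- genes$biotype %||% genes$gene_biotype
  if (is.null(biotype)) {
    biotype <- ifelse(lengths(cds_by_gene)[gid] > 0L, "protein_coding", "other")
  }
  span <- granges(genes)
  mcols(span) <- S4Vectors::DataFrame(gene_id = gid, biotype = as.character(biotype),
                                      localization = "unknown")
  if (!is.null(biotype_filter)) {
    keep <- span$biotype == biotype_filter
    span <- span[keep]
    cds_by_gene <- cds_by_gene[gid[keep]]
  }
  rt_log("read_gff3_genes: ", length(span), " gene(s) kept from ", path)
  if (length(span) == 0L)
    return(structure(list(span = span, cds = cds_by_gene), class = "gene_set"))
  gene_set(span, cds_by_gene)
}

validate_bed12_blocks <- function(gr) {
  blk <- gr$blocks
  for (i in seq_along(gr)) {
    b <- blk[[i]]
    ok <- length(b) >= 1L && min(start(b)) == 1L && max(end(b)) == width(gr)[i] &&
      !is.unsorted(start(b)) &&
      (length(b) < 2L || all(start(b)[-1] > end(b)[-length(b)]))
    if (!ok)
      stop("inconsistent BED12 blocks in record '", gr$name[i] %||% i, "'")
  }
  invisible(TRUE)
}

#' Read transcript models
#'
#' One record per full-length read or per collapsed isoform. BED12 input uses
#' the `score` column as the supporting read count when it is >= 1 (collapsed
#' isoforms); otherwise each record counts as a single read. GFF3 input uses
#' `exon` features grouped by `Parent`.
#'
#' @param path Input file.
#' @param format `"bed12"` or `"gff3"`.
#' @param sample_id Sample label attached to every transcript.
#' @return A [GenomicRanges::GRangesList] of exons (sorted by genomic
#'   coordinate) with metadata columns `transcript_id`, `sample_id`,
#'   `read_count`.
#' @export
read_transcripts <- function(path, format = c("bed12", "gff3"), sample_id = "sample1") {
  format <- match.arg(format)
  if (format == "bed12") {
    gr <- rtracklayer::import.bed(path)
    if (is.null(gr$blocks)) gr$blocks <- as(IRanges::IRanges(1L, width(gr)), "IRangesList")
    validate_bed12_blocks(gr)
    exons <- rtracklayer::blocks(gr)
    ids <- gr$name %||% paste0("tx", seq_along(gr))
    counts <- gr$score %||% rep(1, length(gr))
    counts <- ifelse(is.na(counts) | counts < 1, 1L, as.integer(counts))
  } else {
    check_gff3_lines(path)
    gff <- rtracklayer::import.gff3(path)
    ex <- gff[gff$type == "exon"]
    if (length(ex) == 0L) stop("no exon features in ", path)
    parent <- as.character(unlist(ex$Parent, use.names = FALSE))
    exons <- S4Vectors::split(granges(ex), parent)
    exons <- exons[order(match(names(exons), unique(parent)))]
    ids <- names(exons)
    txf <- gff[gff$type %in% c("mRNA", "transcript")]
    counts <- rep(1L, length(exons))
    if (!is.null(txf$read_count)) {
      rc <- setNames(as.integer(txf$read_count), txf$ID)[ids]
      counts <- ifelse(is.na(rc), 1L, rc)
    }
  }
  exons <- GenomicRanges::sort(exons)  # genomic order within each transcript
  ids <- make.unique(as.character(ids))
  names(exons) <- ids
  mcols(exons) <- S4Vectors::DataFrame(transcript_id = ids,
                                       sample_id = sample_id,
                                       read_count = as.integer(counts))
  rt_log("read_transcripts: ", length(exons), " transcript model(s) from ", path)
  exons
}

#' Write transcript models as BED12
#'
#' Exact inverse of [read_transcripts()] for BED12: exon block structures
#' round-trip unchanged. The `score` column carries `read_count`.
#'
#' @param txs GRangesList of exons with the metadata of [read_transcripts()].
#' @param path Output path.
#' @export
write_transcripts_bed12 <- function(txs, path) {
  gr <- range(txs)
  gr <- unlist(gr, use.names = FALSE)
  gr$name <- mcols(txs)$transcript_id %||% names(txs)
  gr$score <- mcols(txs)$read_count %||% rep(0L, length(txs))
  gr$blocks <- IRanges::IRangesList(lapply(seq_along(txs), function(i) {
    e <- txs[[i]]
    IRanges::IRanges(start(e) - start(gr)[i] + 1L, end(e) - start(gr)[i] + 1L)
  }))
  gr$thick <- ranges(gr)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Polyadenylation site of transcript models
#'
#' The 3' terminal transcribed base in genomic coordinates: the maximum exon
#' end on the plus strand, the minimum exon start on the minus strand.
#'
#' @param txs A GRangesList of exons, or a single GRanges of exons.
#' @return A data.frame with columns `transcript_id`, `chrom`, `strand`,
#'   `pos` (1-based).
#' @export
polya_site <- function(txs) {
  if (is(txs, "GRanges")) txs <- GenomicRanges::GRangesList(tx = txs)
  rng <- unlist(range(txs), use.names = FALSE)
  minus <- is_minus(strand(rng))
  data.frame(
    transcript_id = mcols(txs)$transcript_id %||% names(txs) %||% as.character(seq_along(txs)),
    chrom = as.character(seqnames(rng)),
    strand = as.character(strand(rng)),
    pos = ifelse(minus, start(rng), end(rng)),
    stringsAsFactors = FALSE)
}

# Introns of each transcript: gaps between consecutive exons, genomic order.
tx_introns <- function(txs) {
  GenomicRanges::psetdiff(unlist(range(txs), use.names = FALSE), txs)
}

# Canonical string signature of a transcript's intron chain (grouping key for
# "RT variant" counting). Single-exon chains sign as "".
intron_signature <- function(txs) {
  intr <- tx_introns(txs)
  vapply(seq_along(intr), function(i) {
    x <- intr[[i]]
    if (length(x) == 0L) return("")
    paste(paste0(start(x), "-", end(x)), collapse = ";")
  }, character(1))
}

#' Read a CAGE track
#'
#' TSV with columns `chrom`, `strand`, `position` (1-based) and `tpm`.
#'
#' @param path TSV path.
#' @return A width-1 [GenomicRanges::GRanges] with metadata column `tpm`.
#' @export
read_cage <- function(path) {
  df <- read_tsv(path)
  need <- c("chrom", "strand", "position", "tpm")
  if (!all(need %in% names(df)))
    stop("CAGE TSV needs columns: ", paste(need, collapse = ", "))
  if (any(df$tpm < 0)) stop("negative TPM in CAGE track")
  if (anyDuplicated(df[c("chrom", "strand", "position")]))
    stop("duplicate (chrom, strand, position) in CAGE track")
  gr <- GRanges(df$chrom, IRanges::IRanges(df$position, width = 1L), strand = df$strand)
  gr$tpm <- df$tpm
  rt_log("read_cage: ", length(gr), " position(s) from ", path)
  gr
}
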