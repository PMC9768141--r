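## End-to-end driver: RT calling -> IS classification -> polyA signal scan ->
## expression support, with TSV outputs and a JSON run manifest.

#' Build and validate a pipeline configuration
#'
#' @param gff3 Gene annotation (GFF3).
#' @param transcripts Named character vector of BED12 paths, one per sample.
#' @param genome Optional genome FASTA (needed for hexamer scanning and
#'   splice-site sequences).
#' @param cage Optional CAGE TSV.
#' @param orf_counts Optional per-ORF count TSV.
#' @param localization Optional gene localization TSV.
#' @param nue_hexamers,ce_hexamers Optional dictionary files (one hexamer per
#'   line); both default to the shipped literature-flavored sets.
#' @param outdir Output directory.
#' @param min_cds_overlap_bp,cluster_radius_nt,window_max_len_nt,
#'   tpm_threshold,tss_window_nt Stage thresholds (validated before any I/O).
#' @param total_transcripts_per_sample Optional named vector; defaults to the
#'   number of reads in each sample's input.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(gff3, transcripts, genome = NULL, cage = NULL,
                            orf_counts = NULL, localization = NULL,
                            nue_hexamers = NULL, ce_hexamers = NULL,
                            outdir = "rt_out",
                            min_cds_overlap_bp = 30L,
                            cluster_radius_nt = 10L,
                            window_max_len_nt = 150L,
                            tpm_threshold = 0.2,
                            tss_window_nt = 100L,
                            total_transcripts_per_sample = NULL) {
  # threshold validation happens before any file is touched
  stopifnot_scalar_count(min_cds_overlap_bp, "min_cds_overlap_bp")
  stopifnot_scalar_count(cluster_radius_nt, "cluster_radius_nt", min = 0L)
  stopifnot_scalar_count(window_max_len_nt, "window_max_len_nt")
  if (!is.numeric(tpm_threshold) || tpm_threshold <= 0)
    stop("tpm_threshold must be > 0")
  stopifnot_scalar_count(tss_window_nt, "tss_window_nt", min = 0L)
  if (is.null(names(transcripts)))
    stop("transcripts must be a named vector (names = sample ids)")
  for (p in c(gff3, unname(transcripts), genome, cage, orf_counts, localization,
              nue_hexamers, ce_hexamers))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  structure(list(gff3 = gff3, transcripts = transcripts, genome = genome,
                 cage = cage, orf_counts = orf_counts,
                 localization = localization,
                 nue_hexamers = nue_hexamers, ce_hexamers = ce_hexamers,
                 outdir = outdir,
                 min_cds_overlap_bp = as.integer(min_cds_overlap_bp),
                 cluster_radius_nt = as.integer(cluster_radius_nt),
                 window_max_len_nt = as.integer(window_max_len_nt),
                 tpm_threshold = tpm_threshold,
                 tss_window_nt = as.integer(tss_window_nt),
                 total_transcripts_per_sample = total_transcripts_per_sample),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path JSON file.
#' @param ... Overrides applied on top of the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  over <- list(...)
  vals[names(over)] <- over
  do.call(pipeline_config, vals)
}

#' Run the full readthrough analysis pipeline
#'
#' Stages: RT calling and locus grouping; monocistronic counterparts; IS
#' introns and termination classification; polyA-signal window scan (genome
#' required); CAGE TSS support of second genes (`NA` with a warning when no
#' CAGE track is given); TE comparison; localization distribution and
#' first-gene organelle enrichment. Writes per-stage TSVs, a per-sample
#' summary, a locus master table and a JSON run manifest to
#' `config$outdir`.
#'
#' @param config A [pipeline_config()].
#' @return A list with elements `loci`, `master`, `summary`, `is_introns`,
#'   `termination`, `scans`, `te`, `enrichment`, `localization`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  genes <- read_gff3_genes(cfg$gff3)
  if (!is.null(cfg$localization))
    genes <- set_localization(genes, read_tsv(cfg$localization))

  samples <- names(cfg$transcripts)
  tx_list <- lapply(samples, function(s)
    read_transcripts(cfg$transcripts[[s]], "bed12", sample_id = s))
  all_tx <- suppressWarnings(do.call(c, tx_list))
  names(all_tx) <- mcols(all_tx)$transcript_id <-
    make.unique(as.character(mcols(all_tx)$transcript_id))

  assignments <- call_rt_transcripts(all_tx, genes, cfg$min_cds_overlap_bp)
  loci <- group_rt_loci(assignments, genes)

  totals <- cfg$total_transcripts_per_sample %||%
    vapply(tx_list, function(x) sum(mcols(x)$read_count), numeric(1))
  if (is.null(names(totals))) names(totals) <- samples
  summary_df <- summarize_counts(loci, totals)

  genome <- if (!is.null(cfg$genome)) Biostrings::readDNAStringSet(cfg$genome)
  if (!is.null(genome)) names(genome) <- sub("\\s.*$", "", names(genome))
  dict <- if (!is.null(cfg$nue_hexamers) || !is.null(cfg$ce_hexamers)) {
    hexamer_dictionary(
      nue = if (is.null(cfg$nue_hexamers)) character() else read_hexamer_file(cfg$nue_hexamers),
      ce = if (is.null(cfg$ce_hexamers)) character() else read_hexamer_file(cfg$ce_hexamers))
  } else default_hexamer_dictionary()
  cage <- if (!is.null(cfg$cage)) read_cage(cfg$cage)
  if (is.null(cage))
    rt_warn("no CAGE input: TSS support columns will be NA")

  is_all <- list(); term_all <- list(); scans <- list(); master_rows <- list()
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, , drop = FALSE]
    mono <- detect_monocistronic_counterparts(locus, all_tx, genes,
                                              cfg$min_cds_overlap_bp)
    isdf <- find_is_introns(locus, all_tx, genes)
    is_all[[i]] <- isdf
    first_monos <- all_tx[mono$first_monos]
    term <- classify_termination(locus, isdf, first_monos, cfg$cluster_radius_nt)
    term_all[[i]] <- term

    has_nue <- NA; has_ce <- NA
    if (!is.null(genome) && length(first_monos) > 0L) {
      support <- mcols(first_monos)$read_count %||% rep(1L, length(first_monos))
      pa <- polya_site(first_monos)
      ct <- cluster_polya_table(pa$pos, support, cfg$cluster_radius_nt,
                                locus$strand)
      # scan at the most-supported representative; donor-capped when the
      # polyA lies inside an IS intron
      p0 <- if (!is.na(term$internal_polya_pos)) term$internal_polya_pos else
        ct$rep_pos[which.max(ct$total_support)]
      donor <- NA_integer_
      if (!is.na(term$internal_polya_pos) && nrow(isdf)) {
        inside <- p0 >= isdf$start & p0 <= isdf$end
        if (any(inside)) donor <- isdf$donor_pos[inside][1L]
      }
      win <- build_scan_window(locus$chrom, p0, locus$strand,
                               donor_pos = if (is.na(donor)) NULL else donor,
                               max_len_nt = cfg$window_max_len_nt)
      sc <- scan_hexamers(win, genome, dict, locus_id = locus$locus_id)
      scans[[length(scans) + 1L]] <- sc
      has_nue <- sc$has_nue; has_ce <- sc$has_ce
    }

    chain <- strsplit(locus$gene_chain, ",", fixed = TRUE)[[1]]
    second_gene <- chain[length(chain)]
    tss <- if (is.null(cage)) NA else
      tss_supported(genes$span[second_gene], cage, cfg$tpm_threshold,
                    cfg$tss_window_nt)

    per_sample <- vapply(samples, function(s)
      sum(locus$read_counts[[1]][locus$sample_ids[[1]] == s]), numeric(1))
    row <- data.frame(locus_id = locus$locus_id, chrom = locus$chrom,
                      strand = locus$strand, gene_chain = locus$gene_chain,
                      n_genes = locus$n_genes, stringsAsFactors = FALSE)
    for (s in samples) row[[paste0("reads_", s)]] <- per_sample[[s]]
    row$has_first_monocistronic <- mono$has_first_monocistronic
    row$has_second_monocistronic <- mono$has_second_monocistronic
    row$n_is_introns <- nrow(isdf)
    row$class_label <- term$class_label
    row$second_gene_tss_supported <- tss
    row$has_nue <- has_nue
    row$has_ce <- has_ce
    row$first_gene_localization <-
      genes$span$localization[match(chain[1L], genes$span$gene_id)]
    master_rows[[i]] <- row
  }

  master <- if (length(master_rows)) do.call(rbind, master_rows) else
    data.frame(locus_id = character())
  is_df <- if (length(is_all)) do.call(rbind, is_all) else data.frame()
  term_df <- if (length(term_all)) do.call(rbind, term_all) else data.frame()
  scan_df <- if (length(scans)) do.call(rbind, lapply(scans, function(s)
    data.frame(locus_id = s$locus_id, win_start = start(s$window),
               win_end = end(s$window), has_nue = s$has_nue, has_ce = s$has_ce,
               n_nue_hits = nrow(s$nue_hits), n_ce_hits = nrow(s$ce_hits),
               stringsAsFactors = FALSE))) else data.frame()

  te <- NULL
  if (!is.null(cfg$orf_counts)) {
    orf <- read_orf_counts(cfg$orf_counts)
    if (nrow(orf) > 0L) te <- compare_orf_te(orf)
  }
  enrichment <- NULL; locdist <- NULL
  if (!is.null(cfg$localization) && nrow(master) > 0L) {
    enrichment <- first_gene_organelle_enrichment(loci, genes)
    locdist <- localization_distribution(loci, genes)
  }

  # outputs
  write_tsv(master, file.path(cfg$outdir, "rt_loci_master.tsv"))
  write_tsv(summary_df, file.path(cfg$outdir, "rt_summary.tsv"))
  if (nrow(is_df)) write_tsv(is_df, file.path(cfg$outdir, "is_introns.tsv"))
  if (nrow(term_df)) write_tsv(term_df, file.path(cfg$outdir, "termination_classes.tsv"))
  if (length(scan_df) && nrow(scan_df))
    write_tsv(scan_df, file.path(cfg$outdir, "polya_signal_scans.tsv"))
  if (!is.null(te)) {
    write_tsv(te$groups, file.path(cfg$outdir, "te_groups.tsv"))
    write_tsv(te$comparisons, file.path(cfg$outdir, "te_comparisons.tsv"))
  }
  inputs <- c(gff3 = cfg$gff3, cfg$transcripts, genome = cfg$genome,
              cage = cfg$cage, orf_counts = cfg$orf_counts,
              localization = cfg$localization)
  manifest <- list(
    package = "readthroughr",
    version = as.character(packageVersion("readthroughr")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = cfg[c("min_cds_overlap_bp", "cluster_radius_nt",
                       "window_max_len_nt", "tpm_threshold", "tss_window_nt")],
    inputs = as.list(tools::md5sum(unname(inputs[!vapply(inputs, is.null, TRUE)]))))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  rt_log("run_pipeline: ", nrow(master), " RT locus/loci -> ", cfg$outdir)
  invisible(list(loci = loci, master = master, summary = summary_df,
                 is_introns = is_df, termination = term_df, scans = scans,
                 te = te, enrichment = enrichment, localization = locdist,
                 manifest = manifest))
}

#' Score pipeline output against planted ground truth
#'
#' Per stage, sensitivity (= recovered / planted) and precision (= correct /
#' reported) against the simulator's ground truth: RT loci (gene pairs), IS
#' introns (exact coordinates), termination classes, hexamer presence flags,
#' TSS support, and the sign of the first-vs-second TE contrast.
#'
#' @param truth Ground-truth list from [simulate_dataset()] (or its JSON
#'   re-read with `jsonlite::read_json(..., simplifyVector = TRUE)`).
#' @param result Return value of [run_pipeline()] on the simulated files.
#' @return A data.frame with `stage`, `sensitivity`, `precision`, `n_true`,
#'   `n_called`.
#' @export
evaluate_recovery <- function(truth, result) {
  td <- truth$truth
  master <- result$master
  sp <- function(n_tp, n_true, n_called) c(
    sensitivity = if (n_true == 0) 1 else n_tp / n_true,
    precision = if (n_called == 0) 1 else n_tp / n_called)

  true_pairs <- paste(td$gene1[td$is_rt], td$gene2[td$is_rt], sep = ",")
  called_pairs <- if (nrow(master)) master$gene_chain else character()
  rt <- sp(length(intersect(true_pairs, called_pairs)),
           length(true_pairs), length(called_pairs))

  key <- function(l, s, e) paste(l, s, e, sep = ":")
  tis <- td[td$has_is, , drop = FALSE]
  truth_is <- c(key(paste(tis$gene1, tis$gene2, sep = ","),
                    tis$major_intron_start, tis$major_intron_end),
                key(paste(tis$gene1[tis$has_minor_is], tis$gene2[tis$has_minor_is], sep = ","),
                    tis$minor_intron_start[tis$has_minor_is],
                    tis$minor_intron_end[tis$has_minor_is]))
  isdf <- result$is_introns
  called_is <- if (nrow(isdf))
    key(master$gene_chain[match(isdf$locus_id, master$locus_id)],
        isdf$start, isdf$end) else character()
  isr <- sp(length(intersect(truth_is, called_is)), length(truth_is),
            length(called_is))

  tc <- td[td$is_rt, , drop = FALSE]
  cls_truth <- setNames(tc$class_label, paste(tc$gene1, tc$gene2, sep = ","))
  cls_called <- if (nrow(master))
    setNames(master$class_label, master$gene_chain) else character()
  common <- intersect(names(cls_truth), names(cls_called))
  n_ok <- sum(cls_truth[common] == cls_called[common])
  cls <- sp(n_ok, length(cls_truth), length(cls_called))

  hx_true <- td[td$window_defined & td$is_rt, , drop = FALSE]
  hx_key <- paste(hx_true$gene1, hx_true$gene2, sep = ",")
  hx_called <- if (nrow(master))
    master[!is.na(master$has_nue), , drop = FALSE] else master
  hx_common <- intersect(hx_key, hx_called$gene_chain)
  m1 <- match(hx_common, hx_key); m2 <- match(hx_common, hx_called$gene_chain)
  hx_ok <- sum(hx_true$has_nue[m1] == hx_called$has_nue[m2] &
               hx_true$has_ce[m1] == hx_called$has_ce[m2])
  hx <- sp(hx_ok, length(hx_key), nrow(hx_called))

  tss_ok <- NA_real_
  if (nrow(master) && !all(is.na(master$second_gene_tss_supported))) {
    m <- match(master$gene_chain, paste(td$gene1, td$gene2, sep = ","))
    tss_ok <- mean(master$second_gene_tss_supported == td$tss_supported[m],
                   na.rm = TRUE)
  }

  te_sign <- NA_real_
  if (!is.null(result$te)) {
    cmp <- result$te$comparisons
    fs <- cmp[grepl(":first$", cmp$group1) & grepl(":second$", cmp$group2) |
              grepl(":second$", cmp$group1) & grepl(":first$", cmp$group2), ,
              drop = FALSE]
    d <- ifelse(grepl(":first$", fs$group1), fs$diff_log_te, -fs$diff_log_te)
    planted_sign <- sign(log(truth$config$te_first / truth$config$te_second))
    te_sign <- mean(sign(d) == planted_sign)
  }

  data.frame(
    stage = c("rt_loci", "is_introns", "termination_class", "hexamer_flags",
              "tss_support", "te_contrast_sign"),
    sensitivity = c(rt["sensitivity"], isr["sensitivity"], cls["sensitivity"],
                    hx["sensitivity"], tss_ok, te_sign),
    precision = c(rt["precision"], isr["precision"], cls["precision"],
                  hx["precision"], tss_ok, te_sign),
    n_true = c(length(true_pairs), length(truth_is), length(cls_truth),
               length(hx_key), sum(!is.na(td$tss_supported)), NA),
    n_called = c(length(called_pairs), length(called_is), length(cls_called),
                 nrow(hx_called), NA, NA),
    stringsAsFactors = FALSE)
}
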