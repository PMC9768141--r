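## Seeded synthetic-data generator. Emits a complete toy dataset — genome
## FASTA, GFF3 annotation, per-sample BED12 transcript models, CAGE TSV, ORF
## count TSV, localization TSV, ground_truth.json — with planted ground
## truth for every pipeline stage. The layout mirrors the canonical tandem
## gene-pair geometry at toy scale: fixed-size genes (CDS 300 nt, 50 nt
## 5'UTR, 100 nt 3'UTR), seeded-uniform intergenic gaps of 200-600 nt, and
## IS introns spanning from 40 nt past the first CDS stop to 40 nt before
## the second CDS start, with canonical GT..AG ends.

#' Simulation configuration
#'
#' Defaults restate the study system's observed composition where one is
#' reported: 58% of RT loci with an IS intron (158/271), 67% of IS loci with
#' first-gene polyadenylation inside the intron (106/158), 81% of scanned
#' loci carrying NUE and CE hexamers (86/106 each), 72% of second genes with
#' CAGE TSS support (194/271), 33% organelle-localized first genes (89/271),
#' a 50-fold first:second ORF translation-efficiency ratio, and roughly
#' 3-fold more RT reads in the NMD-deficient sample than wild type.
#'
#' @param seed Integer seed fixing every draw.
#' @param n_gene_pairs Number of tandem same-strand gene pairs.
#' @param fraction_rt_loci Fraction of pairs producing readthrough reads.
#' @param fraction_is Fraction of RT loci with an IS intron.
#' @param fraction_polya_in_intron Fraction of IS loci whose first-gene polyA
#'   lies inside the IS intron (these also emit first monocistronic reads;
#'   IS loci without internal polyA emit none, the "only RTs" type).
#' @param fraction_minor_is Fraction of IS loci that additionally carry a
#'   weakly supported minor IS intron.
#' @param fraction_nue,fraction_ce Fractions of scan-window loci with a
#'   planted NUE / CE hexamer.
#' @param fraction_tss_supported Fraction of second genes given a CAGE peak
#'   above the TPM threshold.
#' @param fraction_organelle_first Fraction of RT first genes labelled
#'   organelle-localized; `fraction_organelle_background` applies to all
#'   other genes.
#' @param reads_rt_per_sample Named integer vector: RT read support per
#'   sample (also defines the sample set).
#' @param reads_first_mono,reads_second_mono,reads_minor_is Read support per
#'   isoform class per sample.
#' @param planted_nue,planted_ce The hexamers planted (also the dictionary a
#'   recovery analysis should scan with).
#' @param te_first,te_second Planted translation efficiencies.
#' @param n_te_replicates,rna_mean Ribo/RNA count model: replicates and mean
#'   RNA count per ORF.
#' @param noise_model `"poisson"` or `"nb"`; `nb_dispersion` is the
#'   negative-binomial dispersion (1/size).
#' @param tss_tpm_range TPM range for supported TSS peaks; unsupported ones
#'   draw from (0.01, 0.2].
#' @param antisense_decoys,utr_overlap_decoys Plant decoy features that a
#'   correct caller must reject.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_gene_pairs = 30L,
                              fraction_rt_loci = 0.5,
                              fraction_is = 0.58,
                              fraction_polya_in_intron = 0.67,
                              fraction_minor_is = 0.3,
                              fraction_nue = 0.81,
                              fraction_ce = 0.81,
                              fraction_tss_supported = 0.72,
                              fraction_organelle_first = 0.33,
                              fraction_organelle_background = 0.15,
                              reads_rt_per_sample = c(WT = 2L, upf1 = 6L),
                              reads_first_mono = 5L,
                              reads_second_mono = 5L,
                              reads_minor_is = 1L,
                              planted_nue = "AATAAA",
                              planted_ce = "TTCATT",
                              te_first = 1.0,
                              te_second = 0.02,
                              n_te_replicates = 3L,
                              rna_mean = 200,
                              noise_model = c("poisson", "nb"),
                              nb_dispersion = 0.1,
                              tss_tpm_range = c(0.5, 5),
                              antisense_decoys = FALSE,
                              utr_overlap_decoys = FALSE) {
  cfg <- list(seed = stopifnot_scalar_count(seed, "seed", min = 0L),
              n_gene_pairs = stopifnot_scalar_count(n_gene_pairs, "n_gene_pairs"),
              fraction_rt_loci = fraction_rt_loci,
              fraction_is = fraction_is,
              fraction_polya_in_intron = fraction_polya_in_intron,
              fraction_minor_is = fraction_minor_is,
              fraction_nue = fraction_nue, fraction_ce = fraction_ce,
              fraction_tss_supported = fraction_tss_supported,
              fraction_organelle_first = fraction_organelle_first,
              fraction_organelle_background = fraction_organelle_background,
              reads_rt_per_sample = reads_rt_per_sample,
              reads_first_mono = as.integer(reads_first_mono),
              reads_second_mono = as.integer(reads_second_mono),
              reads_minor_is = as.integer(reads_minor_is),
              planted_nue = toupper(planted_nue), planted_ce = toupper(planted_ce),
              te_first = te_first, te_second = te_second,
              n_te_replicates = as.integer(n_te_replicates),
              rna_mean = rna_mean,
              noise_model = match.arg(noise_model),
              nb_dispersion = nb_dispersion,
              tss_tpm_range = tss_tpm_range,
              antisense_decoys = isTRUE(antisense_decoys),
              utr_overlap_decoys = isTRUE(utr_overlap_decoys))
  fr <- c("fraction_rt_loci", "fraction_is", "fraction_polya_in_intron",
          "fraction_minor_is", "fraction_nue", "fraction_ce",
          "fraction_tss_supported", "fraction_organelle_first",
          "fraction_organelle_background")
  for (f in fr) if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0,1]")
  if (is.null(names(cfg$reads_rt_per_sample)))
    stop("reads_rt_per_sample must be named by sample")
  n_rt <- round(cfg$n_gene_pairs * cfg$fraction_rt_loci)
  if (cfg$fraction_is > 0 && n_rt == 0)
    stop("config error: fraction_is > 0 but zero RT loci")
  if (any(nchar(c(cfg$planted_nue, cfg$planted_ce)) != 6L))
    stop("planted hexamers must be 6-mers")
  if (cfg$te_first <= 0 || cfg$te_second <= 0) stop("planted TE must be positive")
  structure(cfg, class = "simulation_config")
}

# geometry constants (nt)
SIM_UTR5 <- 50L; SIM_CDS <- 300L; SIM_UTR3 <- 100L
SIM_GENE <- SIM_UTR5 + SIM_CDS + SIM_UTR3  # 450
SIM_SPACER <- 500L
SIM_INTRON_PAD <- 40L

# Per-pair geometry in transcription ("tx") coordinates, 1-based within the
# pair region. Gap g is the intergenic distance between gene spans.
pair_geometry <- function(g) {
  list(
    gene1 = c(1L, SIM_GENE),
    cds1 = c(SIM_UTR5 + 1L, SIM_UTR5 + SIM_CDS),               # 51..350
    gene2 = c(SIM_GENE + g + 1L, 2L * SIM_GENE + g),           # 451+g..900+g
    cds2 = c(SIM_GENE + g + SIM_UTR5 + 1L,
             SIM_GENE + g + SIM_UTR5 + SIM_CDS),               # 501+g..800+g
    intron = c(SIM_UTR5 + SIM_CDS + SIM_INTRON_PAD + 1L,       # 391
               SIM_GENE + g + SIM_UTR5 - SIM_INTRON_PAD),      # 460+g
    minor_donor = SIM_UTR5 + SIM_CDS + SIM_INTRON_PAD + 11L,   # 401
    region_len = 2L * SIM_GENE + g)
}

# tx offset -> genomic position given the region's genomic 5' origin and
# direction d (+1 / -1)
tx2gen <- function(origin, d, t) origin + d * (t - 1L)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Write a transcription-direction sequence into the plus-strand genome
# character vector.
put_seq <- function(chars, origin, d, t_start, seq_str) {
  b <- strsplit(seq_str, "")[[1]]
  pos <- tx2gen(origin, d, t_start + seq_along(b) - 1L)
  if (d < 0) b <- unname(COMPLEMENT[b])
  chars[pos] <- b
  chars
}

get_tx_seq <- function(chars, origin, d, t_start, len) {
  pos <- tx2gen(origin, d, t_start + 0:(len - 1L))
  b <- chars[pos]
  if (d < 0) b <- unname(COMPLEMENT[b])
  paste(b, collapse = "")
}

# Redraw non-reserved window bases until the window holds no hit of `dict`
# hexamers other than those starting at `allowed_tx` offsets.
scrub_window <- function(chars, origin, d, win, dict, reserved_tx, allowed_tx) {
  len <- win[2] - win[1] + 1L
  for (iter in 1:100) {
    s <- get_tx_seq(chars, origin, d, win[1], len)
    bad <- integer()
    for (h in dict) {
      m <- gregexpr(h, s, fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      bad <- c(bad, win[1] - 1L + as.integer(m))
    }
    bad <- setdiff(unique(bad), allowed_tx)
    if (length(bad) == 0L) return(chars)
    for (o in bad) {
      cand <- setdiff(o:(o + 5L), reserved_tx)
      cand <- cand[cand >= win[1] & cand <= win[2]]
      if (length(cand) == 0L) next
      t <- cand[1L]
      cur <- get_tx_seq(chars, origin, d, t, 1L)
      chars <- put_seq(chars, origin, d, t,
                       sample(setdiff(c("A", "C", "G", "T"), cur), 1L))
    }
  }
  stop("scrub_window failed to converge")
}

# sample() without the length-1 surprise, and tolerant of k = 0
sample_exact <- function(x, k) {
  if (k == 0L || length(x) == 0L) return(x[0])
  x[sample.int(length(x), k)]
}

draw_counts <- function(n, mu, cfg) {
  if (cfg$noise_model == "poisson") rpois(n, mu)
  else rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Writes `genome.fasta`, `genes.gff3`, `transcripts_<sample>.bed` (BED12,
#' one record per read), `cage.tsv`, `orf_counts.tsv`, `localization.tsv`
#' and `ground_truth.json` under `outdir`. Identical configs (including
#' seed) produce byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if absent).
#' @return The ground-truth list (invisibly identical to what
#'   `ground_truth.json` serializes): per-pair truth table, planted hexamer
#'   dictionary, per-sample read totals, and file paths.
#' @export
simulate_dataset <- function(config, outdir) {
  stopifnot(is(config, "simulation_config"))
  cfg <- config
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  n <- cfg$n_gene_pairs
  samples <- names(cfg$reads_rt_per_sample)

  gaps <- as.integer(floor(runif(n, 200, 601)))
  strands <- rep(c("+", "-"), length.out = n)

  n_rt <- round(n * cfg$fraction_rt_loci)
  rt_idx <- sort(sample_exact(seq_len(n), n_rt))
  n_is <- round(n_rt * cfg$fraction_is)
  is_idx <- sort(sample_exact(rt_idx, n_is))
  n_int <- round(n_is * cfg$fraction_polya_in_intron)
  int_idx <- sort(sample_exact(is_idx, n_int))
  minor_idx <- sort(sample_exact(is_idx, round(n_is * cfg$fraction_minor_is)))

  # region origins on one chromosome
  region_len <- 2L * SIM_GENE + gaps
  region_start <- cumsum(c(1L, head(region_len + SIM_SPACER, -1L)))
  genome_len <- sum(region_len + SIM_SPACER)
  chars <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)
  chrom <- "chr1"

  truth <- vector("list", n)
  gff <- character()
  bed <- setNames(rep(list(character()), length(samples)), samples)
  cage <- list()
  loc_rows <- list()
  orf_rows <- list()

  gff <- c(gff, "##gff-version 3")

  add_bed <- function(name, exons_tx, origin, d, strand) {
    # exons_tx: list of c(t1, t2) in transcription order; emits 0-based BED12
    gen <- lapply(exons_tx, function(e) sort(as.integer(tx2gen(origin, d, e))))
    gen <- gen[order(vapply(gen, `[`, integer(1), 1L))]
    starts <- vapply(gen, `[`, integer(1), 1L)
    ends <- vapply(gen, `[`, integer(1), 2L)
    cs <- min(starts) - 1L; ce <- max(ends)
    sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            chrom, cs, ce, name, 1L, strand, cs, ce, length(gen),
            paste0(paste(ends - starts + 1L, collapse = ","), ","),
            paste0(paste(starts - 1L - cs, collapse = ","), ","))
  }

  for (i in seq_len(n)) {
    g <- gaps[i]
    geo <- pair_geometry(g)
    strand <- strands[i]
    d <- if (strand == "-") -1L else 1L
    origin <- if (strand == "-") region_start[i] + geo$region_len - 1L else region_start[i]
    gen_iv <- function(tt) sort(tx2gen(origin, d, tt))  # tx interval -> genomic
    id1 <- sprintf("G%03da", i); id2 <- sprintf("G%03db", i)

    is_rt <- i %in% rt_idx
    has_is <- i %in% is_idx
    internal <- i %in% int_idx
    has_minor <- i %in% minor_idx

    # annotation
    for (gg in list(list(id = id1, span = geo$gene1, cds = geo$cds1),
                    list(id = id2, span = geo$gene2, cds = geo$cds2))) {
      sp <- gen_iv(gg$span); cd <- gen_iv(gg$cds)
      gff <- c(gff,
        sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=protein_coding",
                chrom, sp[1], sp[2], strand, gg$id),
        sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
                chrom, sp[1], sp[2], strand, gg$id, gg$id),
        sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s.1",
                chrom, sp[1], sp[2], strand, gg$id),
        sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tID=cds-%s;Parent=%s.1",
                chrom, cd[1], cd[2], strand, gg$id, gg$id))
    }

    # splice sites for IS loci (major + optional minor share the acceptor)
    reserved <- integer()
    if (has_is) {
      chars <- put_seq(chars, origin, d, geo$intron[1], "GTAAGT")
      chars <- put_seq(chars, origin, d, geo$intron[2] - 5L, "TTACAG")
      reserved <- c(reserved, geo$intron[1]:(geo$intron[1] + 5L),
                    (geo$intron[2] - 5L):geo$intron[2])
      if (has_minor) {
        chars <- put_seq(chars, origin, d, geo$minor_donor, "GTAAGT")
        reserved <- c(reserved, geo$minor_donor:(geo$minor_donor + 5L))
      }
    }

    # first-gene polyA and hexamer window
    polya_tx <- NA_integer_; win <- NULL; donor_tx <- NA_integer_
    emit_first_mono <- TRUE
    if (is_rt && has_is && !internal) emit_first_mono <- FALSE  # "only RTs" type
    if (emit_first_mono) {
      polya_tx <- if (is_rt && has_is && internal) geo$intron[1] + 99L
                  else SIM_UTR5 + SIM_CDS + 30L                 # 3'UTR, before donor
      if (is_rt && has_is && internal) donor_tx <- geo$intron[1]
      lo <- if (!is.na(donor_tx)) max(polya_tx - 150L, donor_tx) else polya_tx - 150L
      win <- c(lo, polya_tx - 1L)
    }

    plant_nue <- FALSE; plant_ce <- FALSE
    nue_tx <- NA_integer_; ce_tx <- NA_integer_
    if (!is.null(win)) {
      plant_nue <- runif(1) < cfg$fraction_nue
      plant_ce <- runif(1) < cfg$fraction_ce
      allowed <- integer()
      if (plant_nue) {
        nue_tx <- polya_tx - 36L
        chars <- put_seq(chars, origin, d, nue_tx, cfg$planted_nue)
        reserved <- c(reserved, nue_tx:(nue_tx + 5L)); allowed <- c(allowed, nue_tx)
      }
      if (plant_ce) {
        ce_tx <- polya_tx - 15L
        chars <- put_seq(chars, origin, d, ce_tx, cfg$planted_ce)
        reserved <- c(reserved, ce_tx:(ce_tx + 5L)); allowed <- c(allowed, ce_tx)
      }
      chars <- scrub_window(chars, origin, d, win,
                            unique(c(cfg$planted_nue, cfg$planted_ce)),
                            reserved, allowed)
      # negative control: same hexamer just upstream of the window
      out_tx <- win[1] - 10L
      if (out_tx >= 1L)
        chars <- put_seq(chars, origin, d, out_tx, cfg$planted_nue)
    }

    # decoy annotation/transcripts
    if (cfg$antisense_decoys) {
      as_strand <- if (strand == "+") "-" else "+"
      sp <- gen_iv(c(SIM_GENE + 21L, SIM_GENE + 170L))
      cd <- gen_iv(c(SIM_GENE + 51L, SIM_GENE + 140L))
      as_id <- sprintf("G%03das", i)
      gff <- c(gff,
        sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=protein_coding",
                chrom, sp[1], sp[2], as_strand, as_id),
        sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
                chrom, sp[1], sp[2], as_strand, as_id, as_id),
        sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tID=cds-%s;Parent=%s.1",
                chrom, cd[1], cd[2], as_strand, as_id, as_id))
    }

    # reads per sample
    for (s in samples) {
      rid <- function(cls, k) sprintf("%s_p%03d_%s_r%d", s, i, cls, k)
      if (is_rt) {
        n_rt_reads <- cfg$reads_rt_per_sample[[s]]
        exons <- if (has_is)
          list(c(1L, geo$intron[1] - 1L), c(geo$intron[2] + 1L, geo$gene2[2]))
        else list(c(1L, geo$gene2[2]))
        for (k in seq_len(n_rt_reads))
          bed[[s]] <- c(bed[[s]], add_bed(rid("rt", k), exons, origin, d, strand))
        if (has_is && has_minor) {
          exons_m <- list(c(1L, geo$minor_donor - 1L),
                          c(geo$intron[2] + 1L, geo$gene2[2]))
          for (k in seq_len(cfg$reads_minor_is))
            bed[[s]] <- c(bed[[s]], add_bed(rid("rtminor", k), exons_m, origin, d, strand))
        }
      }
      if (emit_first_mono) {
        for (k in seq_len(cfg$reads_first_mono))
          bed[[s]] <- c(bed[[s]], add_bed(rid("mono1", k),
                                          list(c(1L, polya_tx)), origin, d, strand))
      }
      for (k in seq_len(cfg$reads_second_mono))
        bed[[s]] <- c(bed[[s]], add_bed(rid("mono2", k),
                                        list(c(geo$gene2[1], geo$gene2[2])),
                                        origin, d, strand))
      if (cfg$antisense_decoys) {
        as_strand <- if (strand == "+") "-" else "+"
        bed[[s]] <- c(bed[[s]],
          add_bed(rid("decoyas", 1L), list(c(1L, geo$region_len)),
                  if (strand == "-") region_start[i] else region_start[i] + geo$region_len - 1L,
                  -d, as_strand))
      }
      if (cfg$utr_overlap_decoys) {
        bed[[s]] <- c(bed[[s]],
          add_bed(rid("decoyutr", 1L),
                  list(c(1L, geo$cds2[1] + 19L)), origin, d, strand))
      }
    }

    # CAGE: gene1 TSS always strong; gene2 TSS per fraction
    tss_ok <- runif(1) < cfg$fraction_tss_supported
    tpm2 <- if (tss_ok) runif(1, cfg$tss_tpm_range[1], cfg$tss_tpm_range[2])
            else runif(1, 0.01, 0.19)
    cage[[length(cage) + 1L]] <- data.frame(
      chrom = chrom, strand = strand,
      position = c(tx2gen(origin, d, 1L), tx2gen(origin, d, geo$gene2[1])),
      tpm = round(c(runif(1, 1, 10), tpm2), 4), stringsAsFactors = FALSE)

    # localization
    org <- c("mitochondrion", "chloroplast")
    loc1 <- if (is_rt && runif(1) < cfg$fraction_organelle_first) sample(org, 1L)
            else if (!is_rt && runif(1) < cfg$fraction_organelle_background) sample(org, 1L)
            else "other"
    loc2 <- if (runif(1) < cfg$fraction_organelle_background) sample(org, 1L) else "other"
    loc_rows[[length(loc_rows) + 1L]] <- data.frame(
      gene_id = c(id1, id2), localization = c(loc1, loc2), stringsAsFactors = FALSE)

    # ORF counts for RT loci (transient-assay style constructs)
    if (is_rt) {
      for (r in seq_len(cfg$n_te_replicates)) {
        rna1 <- draw_counts(1, cfg$rna_mean, cfg)
        rna2 <- draw_counts(1, cfg$rna_mean, cfg)
        orf_rows[[length(orf_rows) + 1L]] <- data.frame(
          orf_id = c(paste0(id1, "_orf"), paste0(id2, "_orf")),
          role = c("first", "second"),
          construct = sprintf("RTC%03d", i),
          replicate = r,
          footprint_count = c(draw_counts(1, cfg$te_first * cfg$rna_mean, cfg),
                              draw_counts(1, cfg$te_second * cfg$rna_mean, cfg)),
          rna_count = c(rna1, rna2),
          fp_libsize = 1e6, rna_libsize = 1e6,
          stringsAsFactors = FALSE)
      }
    }

    major_iv <- if (has_is) gen_iv(geo$intron) else c(NA_integer_, NA_integer_)
    minor_iv <- if (has_is && has_minor) gen_iv(c(geo$minor_donor, geo$intron[2]))
                else c(NA_integer_, NA_integer_)
    truth[[i]] <- data.frame(
      pair_id = i, gene1 = id1, gene2 = id2, chrom = chrom, strand = strand,
      region_start = region_start[i], gap = g,
      is_rt = is_rt, has_is = has_is, polya_in_intron = is_rt && has_is && internal,
      has_minor_is = has_is && has_minor,
      class_label = if (!is_rt) NA_character_
                    else if (!has_is) "no_IS"
                    else if (internal) "IS_with_internal_polyA"
                    else "IS_without_internal_polyA",
      major_intron_start = major_iv[1], major_intron_end = major_iv[2],
      minor_intron_start = minor_iv[1], minor_intron_end = minor_iv[2],
      first_polya_pos = if (emit_first_mono) tx2gen(origin, d, polya_tx) else NA_integer_,
      window_defined = !is.null(win),
      has_nue = plant_nue, has_ce = plant_ce,
      nue_pos = if (!is.na(nue_tx)) tx2gen(origin, d, nue_tx) else NA_integer_,
      ce_pos = if (!is.na(ce_tx)) tx2gen(origin, d, ce_tx) else NA_integer_,
      tss_supported = tss_ok, tss_tpm = tpm2,
      loc_first = loc1, loc_second = loc2,
      stringsAsFactors = FALSE)
  }

  truth_df <- do.call(rbind, truth)

  # write files
  paths <- list(
    genome = file.path(outdir, "genome.fasta"),
    gff3 = file.path(outdir, "genes.gff3"),
    cage = file.path(outdir, "cage.tsv"),
    orf_counts = file.path(outdir, "orf_counts.tsv"),
    localization = file.path(outdir, "localization.tsv"),
    ground_truth = file.path(outdir, "ground_truth.json"))
  paths$transcripts <- setNames(
    file.path(outdir, sprintf("transcripts_%s.bed", samples)), samples)

  genome <- Biostrings::DNAStringSet(setNames(paste(chars, collapse = ""), chrom))
  Biostrings::writeXStringSet(genome, paths$genome, width = 80L)
  writeLines(gff, paths$gff3)
  for (s in samples) writeLines(bed[[s]], paths$transcripts[[s]])
  write_tsv(do.call(rbind, cage), paths$cage)
  orf_df <- if (length(orf_rows)) do.call(rbind, orf_rows) else
    data.frame(orf_id = character(), role = character(), construct = character(),
               replicate = integer(), footprint_count = integer(),
               rna_count = integer(), fp_libsize = numeric(), rna_libsize = numeric())
  write_tsv(orf_df, paths$orf_counts)
  write_tsv(do.call(rbind, loc_rows), paths$localization)

  totals <- vapply(bed, length, integer(1))
  gt <- list(config = unclass(cfg), truth = truth_df,
             dictionary = list(nue = cfg$planted_nue, ce = cfg$planted_ce),
             total_transcripts_per_sample = as.list(totals),
             paths = c(lapply(paths[names(paths) != "transcripts"], unname),
                       list(transcripts = as.list(paths$transcripts))))
  jsonlite::write_json(gt, paths$ground_truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  rt_log("simulate_dataset: ", n, " pair(s), ", sum(truth_df$is_rt),
         " RT, ", sum(truth_df$has_is), " IS, genome ", genome_len, " nt -> ", outdir)
  invisible(gt)
}
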