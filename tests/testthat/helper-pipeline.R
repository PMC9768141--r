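# Simulate a dataset and run the full pipeline on it with the planted
# hexamer dictionary as the explicit scan dictionary. Shared by the pipeline
# and acceptance tests.
run_sim_pipeline <- function(seed = 7, n = 10, dir = NULL, ...) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  gt <- suppressMessages(simulate_dataset(
    simulation_config(seed = seed, n_gene_pairs = n, ...),
    file.path(dir, "sim")))
  nf <- file.path(dir, "nue.txt"); writeLines(gt$dictionary$nue, nf)
  cf <- file.path(dir, "ce.txt"); writeLines(gt$dictionary$ce, cf)
  cfg <- pipeline_config(
    gff3 = gt$paths$gff3, transcripts = unlist(gt$paths$transcripts),
    genome = gt$paths$genome, cage = gt$paths$cage,
    orf_counts = gt$paths$orf_counts, localization = gt$paths$localization,
    nue_hexamers = nf, ce_hexamers = cf,
    outdir = file.path(dir, "out"))
  res <- suppressWarnings(suppressMessages(run_pipeline(cfg)))
  list(gt = gt, res = res, cfg = cfg, dir = dir)
}
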