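# readthroughr

Detection and characterization of readthrough (polycistronic) transcripts
from long-read transcript models.

## The problem

In plants, RNA polymerase II occasionally fails to terminate at a gene's
polyadenylation site and continues into one or more downstream same-strand
genes, producing a *readthrough transcript* (RT) — effectively a eukaryotic
polycistronic mRNA. Full-length isoform sequencing (PacBio ISO-seq, Nanopore
cDNA) makes these directly observable as single reads spanning two or more
annotated genes. Their biology hinges on a handful of measurable features:

- whether an *intergenic splicing* (IS) intron joins the 3′ region of the
  first gene to the 5′ region of the second, removing the first gene's
  polyadenylation site and signals from the mature RT;
- whether the first gene's monocistronic mRNAs terminate *inside* that IS
  intron (so splicing and termination compete for the same pre-mRNA);
- whether polyadenylation-signal-like (NUE) and cleavage-element-like (CE)
  hexamers occur in the window from −150 nt (or the IS donor, if closer) up
  to the first-gene polyA site;
- whether the second gene has its own CAGE-supported transcription start
  site (TPM strictly > 0.2);
- how translation efficiency TE = footprints / RNA reads per ORF compares
  between first and second ORFs (second ORFs of bicistronic mRNAs are
  rarely re-initiated);
- whether organelle-targeted first genes are enriched, tested with an
  upper-tail hypergeometric test
  P(X ≥ k) = Σ<sub>j≥k</sub> C(K,j)·C(N−K,n−j)/C(N,n).

`readthroughr` implements this analysis as a reusable pipeline for anyone
with a GFF3 annotation and BED12 transcript models (one record per read, or
collapsed isoforms carrying read counts), plus a seeded synthetic-data
generator that emits a complete toy dataset — genome FASTA, GFF3, per-sample
BED12, CAGE TSV, ORF count TSV, localization TSV — with planted ground
truth for every stage, so every claim the pipeline makes is testable against
a known answer.

## Worked example

Simulate a 6-pair dataset and run the full pipeline (equivalently via the
CLI in `inst/scripts/rtpipe.R`: `rtpipe.R simulate ...` then
`rtpipe.R all ...`):

```r
library(readthroughr)
gt <- simulate_dataset(simulation_config(seed = 9, n_gene_pairs = 6), "cli_sim")
writeLines(gt$dictionary$nue, "nue.txt"); writeLines(gt$dictionary$ce, "ce.txt")
cfg <- pipeline_config(
  gff3 = gt$paths$gff3, transcripts = unlist(gt$paths$transcripts),
  genome = gt$paths$genome, cage = gt$paths$cage,
  orf_counts = gt$paths$orf_counts, localization = gt$paths$localization,
  nue_hexamers = "nue.txt", ce_hexamers = "ce.txt", outdir = "cli_out")
res <- run_pipeline(cfg)
res$summary
```

The per-sample summary (`cli_out/rt_summary.tsv`) printed by this run:

```
sample_id  n_rt_variants  n_rts  n_rt_loci  n_total_transcripts  proportion_pct
WT                     4      7          3                   62          11.290
upf1                   4     19          3                   74          25.676
```

`n_rt_variants` counts distinct intron-chain structures, `n_rts` supporting
reads, `n_rt_loci` distinct gene sets; the proportion is RT reads over all
transcripts (the simulated NMD-deficient sample, `upf1`, is built to carry
~3× the RT reads of `WT`). The locus master table
(`cli_out/rt_loci_master.tsv`) from the same run:

```
locus_id  gene_chain    n_is_introns  class_label                second_gene_tss_supported  has_nue  has_ce  first_gene_localization
RTL0001   G003a,G003b   0             no_IS                      FALSE                      TRUE     TRUE    mitochondrion
RTL0002   G004a,G004b   2             IS_without_internal_polyA  TRUE                       NA       NA      other
RTL0003   G005a,G005b   1             IS_with_internal_polyA     FALSE                      TRUE     FALSE   chloroplast
```

RTL0002 is the "only RTs" locus type: no first-gene monocistronic mRNA is
produced, so there is no polyA site to scan (`has_nue`/`has_ce` are `NA`).
RTL0003 terminates its first monocistronic mRNA inside the IS intron. The TE
comparison (`cli_out/te_comparisons.tsv`) reports Tukey-adjusted p-values on
log TE for every construct × ORF-role pair; in this run each construct's
second ORF sits ~e<sup>−3.9</sup> ≈ 50-fold below its first ORF with
p_adj < 10⁻⁶, matching the planted contrast:

```
group1         group2         diff_log_te  p_adj
RTC003:second  RTC003:first   -3.910       3.7e-07
...
```

`evaluate_recovery(gt, res)` scores the whole run against the planted truth
(sensitivity and precision per stage, all 1.0 on decoy-free simulations).

## Layout

- `R/` — genome model & I/O, RT detection, IS classification, polyA-signal
  scanning, expression support (TSS/TE/enrichment), synthetic-data
  generator, pipeline driver
- `inst/scripts/rtpipe.R` — CLI (`simulate`, `call`, `is-classify`,
  `polya-scan`, `tss`, `te`, `enrich`, `all`)
- `inst/extdata/` — editable default NUE/CE hexamer dictionaries
- `vignettes/readthrough-methods.Rmd` — models, parameters, design choices,
  limitations
- `tests/testthat/` — unit, property and oracle tests; `test-acceptance.R`
  holds the acceptance criteria
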