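# histodiff

Paired-sample differential analysis of promoter histone-mark
(H3K4me3) ChIP-seq: one case library (e.g. a tumour) against one
matched control (e.g. its surrounding tissue), with no replicates.
The package is aimed at analysts who have two mapped-read BED files, a
gene annotation and (optionally) peak calls and an expression table,
and want the standard battery of paired comparisons with full
provenance — plus a seeded synthetic-data generator with known ground
truth so every stage can be validated end to end.

## What it computes

* **Normalized coverage.** Reads are shifted 50 bp toward the
  fragment midpoint (`+` strand: downstream; `-` strand: upstream),
  piled up per base, and normalized by the genome-average count, so a
  track value of *v* means *v*-fold the genome mean.
* **Meta-profiles.** Average normalized signal at offsets
  *d ∈ [−W, W)* around TSSs, TTSs or CpG-island midpoints,
  strand-oriented (negative offsets are 5′ of the anchor).
* **Gained / lost genes.** With per-gene peak counts in three
  categories — distal promoter (−5 kb/+1 kb of the TSS), exon, gene
  body — a gene is *gained* when it has no peak in any category in
  the control and at least one in the case, *lost* in the reverse
  situation.
* **Copy-number amplification.** A region is reported when
  (1) width > 1 kb, (2) case density ≥ 5× the case genome mean,
  (3) case count ≥ 5× the control count in the region, (4) ≥ 2× the
  control genome mean, and (5) duplicate reads were removed by
  sequence; significance is the upper Poisson tail
  *P(X ≥ k)*, *X* ~ Poisson(λ), with λ the (library-size-scaled)
  control region read count and *k* the case count.
* **Expression linkage.** Pearson *r* between TSS-vicinity
  (−0.5 kb/+1 kb) counts and mean expression; Wilcoxon rank-sum
  comparison between two gene sets; Welch t-test of the two samples
  over 500-bp windows at CpG-island midpoints.

See `vignettes/histodiff-methods.Rmd` for the model, parameter
rationale and the generator's design.

## Worked example

Simulate the default synthetic study (two 500-kb chromosomes, 60
genes, 6 gained and 6 lost, one 2-kb fold-6 amplified region) and run
the stages:

```r
library(histodiff)

sim <- simulate_chipseq(sim_config(seed = 1))
track_control <- normalize_track(pileup(sim$reads_control, shift_params(), sim$sizes))
track_case    <- normalize_track(pileup(sim$reads_case,    shift_params(), sim$sizes))
track_case
#> CoverageTrack: 2 chromosome(s), 1,000,000 bp, 31097 reads, normalized (genome mean 1.119)

peaks_control <- standin_call_peaks(track_control, sample_label = "control")
peaks_case    <- standin_call_peaks(track_case,    sample_label = "case")
overlap_summary(peaks_control, peaks_case)
#> Peaks: control 54 (48 shared, 6 only), case 58 (48 shared, 10 only)

gl <- classify_gain_loss(assign_peaks(peaks_control, sim$genes),
                         assign_peaks(peaks_case,    sim$genes))
table(gl$status)
#>            gained              lost unchanged_present
#>                 6                 6                48
setequal(gl$gene_id[gl$status == "gained"], sim$truth$gained)
#> [1] TRUE

corr <- signal_expression_correlation(tss_vicinity_counts(track_case, sim$genes),
                                      sim$expression, log_transform = FALSE)
corr$r
#> [1] 0.991033

cpg_window_ttest(track_control, track_case, sim$cpg)
#> CpG-window t-test (welch): mean_a = 11.09, mean_b = 10.72, t = 0.190, p = 0.85 (n = 70 islands)
```

The 54 control / 58 case peaks are the 54 enriched promoters per
sample plus a few split calls; the six called gained and lost genes
are exactly the implanted ones; *r* ≈ 0.99 reflects the generator's
linear coupling of expression to true promoter intensity; and the CpG
t-test is non-significant because gains and losses are balanced by
construction.

The whole analysis can equally be driven by one orchestrated call with
a manifest and stage caching:

```r
res <- run_pipeline(pipeline_config(simulate = sim_config(seed = 1)), "out/")
unlist(res$status)
```

or from a shell via the thin wrapper `inst/scripts/histodiff`
(`histodiff run --config pipeline.yaml --outdir out/`).

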