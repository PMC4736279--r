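# tssbreadth

Classification of **H3K4me3 peak breadth at transcription start sites
(TSSs)** from ChIP-seq coverage, and of its association with differential
gene transcription between a control and a disease condition (the
motivating setting is primary monocytes in systemic lupus erythematosus).

H3K4me3 marks active promoters, but its *shape* varies: some promoters
carry a narrow peak confined to ±250 bp around the TSS, others extend the
mark upstream, downstream (typically to ~650 bp, where the elongation mark
H3K36me3 takes over), or both ways. This package provides, for whoever
needs to reproduce or extend this kind of analysis:

* **Profiles** — stranded reads are extended to 200 bp fragments, binned
  into a TSS × 41 matrix (50 bp bins over −1025..+1025 bp, oriented in the
  direction of transcription) and normalized against matched input
  controls onto a log2-vs-background scale where ±1.0 is exactly two-fold
  above/below background.
* **Classification** — two-component Gaussian mixtures fit by EM separate
  marked from unmarked TSSs (on the TSS-region mean *m*) and, on each
  breadth axis *d*<sub>up</sub> = up − tss and
  *d*<sub>down</sub> = down − tss, "extended" from "not extended";
  the joint axis calls give the four patterns *narrow peak*,
  *upstream extended*, *downstream extended*, *broad symmetric*, with
  posterior-threshold confidence control and Cohen's κ for
  between-condition agreement.
* **Association** — Wilcoxon comparisons of expression by pattern, loess
  detrending of the variance–mean relation, Fisher's exact odds ratios of
  pattern membership × differential expression, and hypergeometric
  gene-set overrepresentation with Benjamini–Hochberg FDR.
* **Dose-response** — per-gene percent H3K4me3 change at upstream/TSS/
  downstream regions (100·(2^Δ − 1)), OLS residualization of each region
  on the other two, binned response curves with the least-squares slope
  over the 1–10 % range, fraction-increased summaries, and zero-centered
  summaries for external gene lists.
* **Motifs** — log2-odds PWM scanning of promoter windows on both strands
  (MEME-format collections) and positional enrichment by pattern group.
* **Synthetic data** — a generator producing read-level ChIP-seq cohorts,
  expression tables, and promoter sequences with planted motifs, whose
  defaults encode the effect sizes the workflow is designed to detect, so
  every stage is testable without patient data.

## Worked example

Simulate a cohort of 1000 TSSs (six ChIP + six input samples per
condition), build the normalized profile matrix, and classify:

```r
library(tssbreadth)

cfg <- generator_config(n_tss = 1000, seed = 1)
sim <- simulate_chipseq(cfg)

mats  <- lapply(lapply(sim$chip_control,  extend_reads), bin_depth, tss = sim$tss)
inps  <- lapply(lapply(sim$input_control, extend_reads), bin_depth, tss = sim$tss)
mat   <- normalize_and_subtract(mats, inps)   # 1000 x 41, log2 vs background
s     <- summarize_regions(mat)

fit    <- fit_gmm2(s$tss, seed = 1)
marked <- select_marked(fit, s$tss)           # posterior >= 0.95
calls  <- classify_patterns(s, marked, seed = 1)
table(calls$label)
#>         narrow_peak   upstream_extended downstream_extended     broad_symmetric
#>                  67                 212                 193                 118
#>        unclassified            unmarked
#>                   5                 405
mean(as.character(calls$label) == sim$truth$pattern_control)
#> [1] 0.995
```

99.5 % of the generative labels are recovered. Label-level cohorts then
reproduce the association statistics the defaults encode — e.g. the odds
of being transcriptionally up-regulated in the disease condition by
baseline pattern (narrow-peak genes strongly depleted, downstream-extended
genes enriched):

```r
tr <- generate_truth(cfg, n = 8399, classified_only = TRUE)
de <- data.frame(gene_id = tr$gene_id, de = tr$de)
pattern_de_fisher(truth_calls(tr), de, directions = "increased")
#>                 label   a    b    or  p_value
#> 1         narrow_peak  18  859 0.105 4.96e-42
#> 2   upstream_extended 391 2655 0.750 9.09e-06
#> 3 downstream_extended 638 2086 2.440 1.71e-46
#> 4     broad_symmetric 223 1529 0.780 1.63e-03

tab <- residualize(region_change_table(
  generate_truth(generator_config(n_tss = 5000, seed = 1))))
response_curve(tab, "downstream", residualized = TRUE)
#> Dose-response at downstream region: slope 1.489 %/% (SE 0.035) over bins -10..10

agreement(truth_calls(tr, "control"), truth_calls(tr, "disease"))
#> Pattern agreement on 8399 TSSs: 95.0% (kappa = 0.929, p = 0)
```

So on this cohort every 1 % gain of downstream H3K4me3 buys ~1.5 % of
transcription on average, and the breadth patterns are highly stable
between conditions.

## The analysis workflow

The numbered scripts under `analysis/` run the whole study on the
synthetic cohort and narrate what they find, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R        # cohort: reads, truth, expression, promoters
Rscript analysis/02_profile.R        # profile matrices + region summaries
Rscript analysis/03_classify.R       # patterns per condition + agreement
Rscript analysis/04_transcription.R  # expression/variance/Fisher/gene sets
Rscript analysis/05_dose_response.R  # region changes, slope, fractions
Rscript analysis/06_motifs.R         # PWM scan + positional enrichment
```

`run_breadth_pipeline()` performs the same profile → classify → associate
→ dose-response chain in one call from a single configuration list (or
YAML file) and writes a JSON report.

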