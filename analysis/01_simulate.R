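#!/usr/bin/env Rscript
# Stage 1: generate the synthetic monocyte-like cohort.
#
# Builds a ChIP-seq cohort (six control + six disease samples with matched
# input controls), the gene-level ground truth (breadth patterns in both
# conditions, DE states, region-specific H3K4me3 changes), per-sample
# expression, promoter sequences with planted motifs, and a few synthetic
# gene sets. Everything downstream (02..06) reads only these files.

suppressPackageStartupMessages(library(tssbreadth))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(n_tss = 1000L, seed = 1L)
print(cfg)

sim <- simulate_chipseq(cfg)
print(sim)

write_tss_bed(sim$tss, file.path(out, "tss.bed"))
for (grp in c("chip_control", "chip_disease", "input_control", "input_disease")) {
  for (s in names(sim[[grp]])) {
    write_bed(sim[[grp]][[s]], file.path(out, sprintf("%s_%s.bed", grp, s)))
  }
}
write_tsv(sim$truth, file.path(out, "truth.tsv"))
yaml::write_yaml(unclass(cfg), file.path(out, "config.yaml"))

ex <- generate_expression(sim$truth, cfg)
write_tsv(data.frame(gene_id = rownames(ex$expression_control),
                     ex$expression_control),
          file.path(out, "expression_control.tsv"))
write_tsv(data.frame(gene_id = rownames(ex$expression_disease),
                     ex$expression_disease),
          file.path(out, "expression_disease.tsv"))
write_tsv(ex$differential, file.path(out, "differential.tsv"))

md <- generate_motif_data(cfg, sim$truth)
Biostrings::writeXStringSet(md$sequences, file.path(out, "promoters.fa"))
write_meme(md$pwms, file.path(out, "motifs.meme"))
write_tsv(md$planted, file.path(out, "planted_motifs.tsv"))

# synthetic gene sets: one enriched in downstream-extended genes (an
# "immune-response-like" set), one in narrow-peak genes (a
# "housekeeping-like" set), plus random sets
set.seed(2)
tr <- sim$truth
pick <- function(pool, frac_in, n = 60) {
  inside <- sample(pool, round(n * frac_in))
  outside <- sample(setdiff(tr$gene_id, pool), n - length(inside))
  c(inside, outside)
}
sets <- list(
  immune_like = pick(tr$gene_id[tr$pattern_control == "downstream_extended"], 0.7),
  housekeeping_like = pick(tr$gene_id[tr$pattern_control == "narrow_peak"], 0.5),
  random_a = sample(tr$gene_id, 60),
  random_b = sample(tr$gene_id, 60)
)
writeLines(
  vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1)),
  file.path(out, "gene_sets.gmt")
)

cat(sprintf(
  "Wrote cohort: %d TSSs, DE-up %d, DE-down %d; %d planted motif occurrences\n",
  nrow(tr), sum(tr$de == "increased"), sum(tr$de == "decreased"),
  nrow(md$planted)
))
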