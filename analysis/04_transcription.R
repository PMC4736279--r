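#!/usr/bin/env Rscript
# Stage 4: breadth patterns vs transcription.
#
# Expression level and detrended between-sample variance by pattern,
# Fisher odds ratios of pattern membership against differential
# transcription, and gene-set overrepresentation per pattern on the
# marked-TSS background.

suppressPackageStartupMessages(library(tssbreadth))

out <- "results/transcription"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

calls <- read_tsv("results/classify/patterns_control.tsv")
calls$label <- factor(calls$label, levels = all_labels())
expr <- read_tsv("results/sim/expression_control.tsv")
de <- read_tsv("results/sim/differential.tsv")

baseline <- if (sum(calls$label == "unclassified") >= 30) "unclassified" else "unmarked"
ep <- expression_by_pattern(expr, calls, baseline = baseline)
write_tsv(ep, file.path(out, "expression_by_pattern.tsv"))
cat(sprintf("Expression vs %s baseline:\n", baseline))
print(ep, digits = 3)

em <- as.matrix(expr[, -1]); rownames(em) <- expr$gene_id
dv <- detrended_variance(em)
write_tsv(dv, file.path(out, "detrended_variance.tsv"))
merged <- merge(dv, calls[, c("gene_id", "label")], by = "gene_id")
cat("Mean level-detrended log2 variance by pattern:\n")
print(round(tapply(merged$residual, merged$label, mean), 3))

fres <- pattern_de_fisher(calls, de)
write_tsv(fres, file.path(out, "pattern_de_fisher.tsv"))
up <- fres[fres$direction == "increased", ]
cat("Odds of increased transcription by pattern:\n")
print(up[, c("label", "or", "p_value")], digits = 3)

sets <- read_gmt("results/sim/gene_sets.gmt")
background <- calls$gene_id[calls$label != "unmarked"]
enr <- do.call(rbind, lapply(pattern_labels(), function(p) {
  r <- overrepresentation(calls$gene_id[calls$label == p], sets, background)
  cbind(pattern = p, r)
}))
write_tsv(enr, file.path(out, "overrepresentation.tsv"))
cat("Top gene-set enrichments (FDR < 0.05):\n")
print(enr[enr$fdr < 0.05, ], digits = 3)
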