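#!/usr/bin/env Rscript

## Generate the synthetic paired methylation/expression study used by the
## downstream analyses: two arms (AR/HC) of 8 patients sampled in the pollen
## and non-pollen seasons on both assays, with 30 planted promoter DMPs
## (delta beta 0.3), 30 planted DEGs (log2FC 1.5), 15 negatively correlated
## CpG-gene driver pairs (Spearman -0.8), and three 120-gene co-expression
## modules, the first of which carries the symptom-score trait (cor 0.8).

suppressMessages(library(methdriver))

cfg <- sim_config(seed = 20240101)
d <- generate_dataset(cfg)

dir.create("results", showWarnings = FALSE)
paths <- write_dataset(d, "results/dataset")

cat(sprintf("wrote %d files under results/dataset\n", length(paths)))
cat(sprintf("methylation: %d probes x %d samples (%.1f%% missing)\n",
            nrow(d$meth$beta), ncol(d$meth$beta), 100 * mean(is.na(d$meth$beta))))
cat(sprintf("expression:  %d probes x %d samples -> %d genes\n",
            nrow(d$expr$expr), ncol(d$expr$expr),
            length(unique(d$expr$probe_to_gene))))
cat(sprintf("planted: %d promoter DMPs (+%d body-annotated decoys), %d DEGs, %d driver pairs, %d modules\n",
            length(d$truth$dmp_ids), length(d$truth$decoy_dmp_ids),
            length(d$truth$deg_ids), nrow(d$truth$driver_pairs), cfg$n_modules))
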