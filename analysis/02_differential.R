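#!/usr/bin/env Rscript

## Per-season differential screens: methylation QC (missing-rate filter,
## probe-type normalization) and DMP calling with the adaptive
## mean + 2 sd delta-beta threshold and the promoter restriction;
## expression background correction, detection filtering with group-mean
## replacement, gene collapse, and DEG calling with the adaptive log2FC
## threshold.

suppressMessages(library(methdriver))

d <- read_dataset("results/dataset")
dir.create("results/differential", recursive = TRUE, showWarnings = FALSE)

## methylation preprocessing
fm <- filter_missing(d$meth$beta, 0.10)
cat(sprintf("missing-rate filter: %d -> %d probes (%d samples kept)\n",
            nrow(d$meth$beta), nrow(fm$matrix), ncol(fm$matrix)))
dt <- setNames(d$meth$annotation$design_type, d$meth$annotation$probe)
beta <- normalize_probe_types(fm$matrix, dt)
write_matrix_tsv(beta, "results/differential/beta_normalized.tsv", "probe")

## expression preprocessing (shared); detection filter runs per season below
log_expr <- suppressWarnings(background_correct(d$expr$expr, d$expr$detection_p))

for (season in c("pollen", "non-pollen")) {
  tag <- gsub("-", "_", season)
  ms <- d$meth$sample_sheet[d$meth$sample_sheet$season == season, ]
  es <- d$expr$sample_sheet[d$expr$sample_sheet$season == season, ]

  mres <- moderated_ttest(beta[, intersect(colnames(beta), ms$sample_id)],
                          setNames(ms$group, ms$sample_id))
  dmps <- suppressWarnings(call_dmps(mres, d$meth$annotation))
  thr_m <- attr(dmps, "threshold")

  dfi <- detection_filter_impute(log_expr[, es$sample_id],
                                 d$expr$detection_p[, es$sample_id],
                                 setNames(es$group, es$sample_id))
  genes <- collapse_to_genes(dfi$expr, d$expr$probe_to_gene)
  eres <- moderated_ttest(genes, setNames(es$group, es$sample_id))
  degs <- call_degs(eres)
  thr_e <- attr(degs, "threshold")

  write_table_tsv(mres, sprintf("results/differential/meth_results_%s.tsv", tag))
  write_table_tsv(dmps, sprintf("results/differential/dmps_%s.tsv", tag))
  write_table_tsv(eres, sprintf("results/differential/expr_results_%s.tsv", tag))
  write_table_tsv(degs, sprintf("results/differential/degs_%s.tsv", tag))
  write_matrix_tsv(genes, sprintf("results/differential/genes_%s.tsv", tag), "gene")

  cat(sprintf("[%s] delta-beta threshold %.3f -> %d promoter DMPs (%d hyper / %d hypo)\n",
              season, thr_m$tau, nrow(dmps),
              sum(dmps$direction == "hyper"), sum(dmps$direction == "hypo")))
  cat(sprintf("[%s] log2FC threshold %.3f -> %d DEGs (%d up / %d down)\n",
              season, thr_e$tau, nrow(degs),
              sum(degs$direction == "up"), sum(degs$direction == "down")))
}
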