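#!/usr/bin/env Rscript

## Functional enrichment of the methylation-driven genes: hypergeometric
## over-representation against the gene-set collection, per season, and a
## single-CpG GSEA around the most negatively correlated pollen-season
## driver CpG (genes ranked by their Spearman correlation with its beta
## values across matched samples).

suppressMessages(library(methdriver))

d <- read_dataset("results/dataset")
beta <- read_matrix_tsv("results/differential/beta_normalized.tsv")
dir.create("results/enrichment", recursive = TRUE, showWarnings = FALSE)

for (season in c("pollen", "non-pollen")) {
  tag <- gsub("-", "_", season)
  pairs <- read_table_tsv(sprintf("results/integration/driver_pairs_%s.tsv", tag))
  genes <- read_matrix_tsv(sprintf("results/differential/genes_%s.tsv", tag))
  if (nrow(pairs) == 0) { cat(sprintf("[%s] no driver genes to enrich\n", season)); next }
  ora <- ora_hypergeometric(unique(pairs$gene), d$gene_sets, rownames(genes))
  write_table_tsv(ora, sprintf("results/enrichment/ora_%s.tsv", tag))
  top <- ora[1, ]
  cat(sprintf("[%s] ORA over %d sets; top: %s (k=%d/K=%d, p=%.3g, BH q=%.3g)\n",
              season, nrow(ora), top$set, top$k, top$K, top$p, top$p_adj))
}

## single-CpG GSEA on the strongest pollen-season pair
pairs <- read_table_tsv("results/integration/driver_pairs_pollen.tsv")
if (nrow(pairs)) {
  genes <- read_matrix_tsv("results/differential/genes_pollen.tsv")
  ms <- d$meth$sample_sheet[d$meth$sample_sheet$season == "pollen", ]
  es <- d$expr$sample_sheet[d$expr$sample_sheet$season == "pollen", ]
  matched <- match_samples(ms, es)
  top_probe <- pairs$probe[which.min(pairs$rho)]
  ranked <- suppressWarnings(rank_by_cpg(beta[top_probe, ], genes, matched))
  gsea <- gsea_run(ranked, d$gene_sets, n_perm = 1000,
                   seed = stream_seed(20240101, "gsea"))
  write_table_tsv(gsea[, setdiff(colnames(gsea), "leading_edge")],
                  "results/enrichment/gsea_top_probe.tsv")
  cat(sprintf("GSEA around %s (rho=%.2f with %s): top set %s (ES=%.2f, NES=%.2f, p=%.3g)\n",
              top_probe, min(pairs$rho), pairs$gene[which.min(pairs$rho)],
              gsea$set[1], gsea$es[1], gsea$nes[1], gsea$p[1]))
}
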