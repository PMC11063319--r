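#!/usr/bin/env Rscript

## Methylation-expression integration: match samples by patient within each
## season, correlate each annotated CpG with its gene across matched samples
## (Spearman), and call methylation-driven pairs (Cor < -0.4, p < 0.05,
## probe a DMP, gene a DEG, direction-consistent). Compare the driver gene
## sets of the two seasons.

suppressMessages(library(methdriver))

d <- read_dataset("results/dataset")
beta <- read_matrix_tsv("results/differential/beta_normalized.tsv")
dir.create("results/integration", recursive = TRUE, showWarnings = FALSE)

pair_tables <- list()
for (season in c("pollen", "non-pollen")) {
  tag <- gsub("-", "_", season)
  ms <- d$meth$sample_sheet[d$meth$sample_sheet$season == season, ]
  es <- d$expr$sample_sheet[d$expr$sample_sheet$season == season, ]
  genes <- read_matrix_tsv(sprintf("results/differential/genes_%s.tsv", tag))
  dmps <- read_table_tsv(sprintf("results/differential/dmps_%s.tsv", tag))
  degs <- read_table_tsv(sprintf("results/differential/degs_%s.tsv", tag))

  matched <- match_samples(ms, es)
  bmat <- beta[, intersect(colnames(beta), ms$sample_id)]
  cand <- d$meth$annotation[d$meth$annotation$probe %in% rownames(bmat),
                            c("probe", "gene")]
  scored <- suppressWarnings(correlate_pairs(bmat, genes, cand, matched))
  pairs <- suppressWarnings(call_driver_pairs(scored, dmps, degs, season = season))
  pair_tables[[season]] <- pairs

  write_table_tsv(scored, sprintf("results/integration/scored_pairs_%s.tsv", tag))
  write_table_tsv(pairs, sprintf("results/integration/driver_pairs_%s.tsv", tag))
  cat(sprintf("[%s] %d matched samples; %d scored pairs pass Cor < -0.4 & p < 0.05; %d driver pairs (%d hyper-low / %d hypo-high)\n",
              season, nrow(matched),
              sum(scored$rho < -0.4 & scored$p < 0.05, na.rm = TRUE),
              nrow(pairs), sum(pairs$regulation_class == "hyper_low"),
              sum(pairs$regulation_class == "hypo_high")))
}

venn <- compare_gene_sets(pair_tables[["pollen"]]$gene,
                          pair_tables[["non-pollen"]]$gene,
                          c("pollen", "non-pollen"))
write_table_tsv(venn$counts, "results/integration/season_venn.tsv")
cat(sprintf("season comparison: %d genes unique to pollen, %d unique to non-pollen, %d shared\n",
            length(venn$unique_a), length(venn$unique_b),
            length(venn$intersection)))

## sanity against the planted truth
truth_keys <- paste(d$truth$driver_pairs$probe, d$truth$driver_pairs$gene)
called_keys <- paste(pair_tables[["pollen"]]$probe, pair_tables[["pollen"]]$gene)
cat(sprintf("pollen-season recovery of planted pairs: %d/%d (precision %.2f)\n",
            sum(truth_keys %in% called_keys), length(truth_keys),
            if (length(called_keys)) mean(called_keys %in% truth_keys) else NA))
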