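#!/usr/bin/env Rscript

## Evaluate the whole analysis against the planted ground truth of the
## simulated study: DMP / DEG / driver-pair recovery per season and module
## recovery for the co-expression stage.

suppressMessages(library(methdriver))

d <- read_dataset("results/dataset")
dir.create("results", showWarnings = FALSE)

rows <- list()
for (season in c("pollen", "non-pollen")) {
  tag <- gsub("-", "_", season)
  dmps <- read_table_tsv(sprintf("results/differential/dmps_%s.tsv", tag))
  degs <- read_table_tsv(sprintf("results/differential/degs_%s.tsv", tag))
  pairs <- read_table_tsv(sprintf("results/integration/driver_pairs_%s.tsv", tag))
  tk <- paste(d$truth$driver_pairs$probe, d$truth$driver_pairs$gene)
  ck <- paste(pairs$probe, pairs$gene)
  rows[[season]] <- data.frame(
    season = season,
    dmp_sensitivity = mean(d$truth$dmp_ids %in% dmps$feature),
    decoy_dmps_called = sum(d$truth$decoy_dmp_ids %in% dmps$feature),
    deg_sensitivity = mean(d$truth$deg_ids %in% degs$feature),
    pair_sensitivity = mean(tk %in% ck),
    pair_precision = if (length(ck)) mean(ck %in% tk) else NA)
}
rec <- do.call(rbind, rows)

mods <- read_table_tsv("results/coexpression/module_assignment.tsv")
truth_mod <- d$truth$module_membership
inmat <- mods$gene[mods$gene %in% names(truth_mod) & mods$module != "grey"]
purity <- if (length(inmat)) {
  agree <- vapply(split(truth_mod[inmat], mods$module[match(inmat, mods$gene)]),
                  function(tl) max(table(tl)) / length(tl), 0)
  stats::weighted.mean(agree, vapply(split(inmat, mods$module[match(inmat, mods$gene)]),
                                     length, 0))
} else NA

write_table_tsv(rec, "results/recovery.tsv")
print(rec, row.names = FALSE)
cat(sprintf("module label purity (non-grey planted genes): %.3f; %d of %d planted module genes assigned\n",
            purity, length(inmat), length(truth_mod)))
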