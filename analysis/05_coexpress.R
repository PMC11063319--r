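#!/usr/bin/env Rscript

## Weighted co-expression analysis of the pollen-season expression matrix:
## MAD top-25% gene filter, outlier-sample check, soft-threshold selection
## (scale-free R^2 target 0.85), TOM, static-cut module detection
## (minModuleSize 100), module eigengenes, and module-trait correlation
## (group, sex, symptom score; key modules at Cor > 0.4, p < 0.05).

suppressMessages(library(methdriver))

d <- read_dataset("results/dataset")
genes <- read_matrix_tsv("results/differential/genes_pollen.tsv")
es <- d$expr$sample_sheet[d$expr$sample_sheet$season == "pollen", ]
dir.create("results/coexpression", recursive = TRUE, showWarnings = FALSE)

mat <- mad_filter(genes, 0.25)
outl <- tryCatch(remove_outlier_samples(mat), error = function(e) {
  cat("outlier removal skipped:", conditionMessage(e), "\n")
  list(retained = colnames(mat), dropped = character(0))
})
mat <- mat[, outl$retained]
cat(sprintf("network input: %d genes x %d samples (%d outlier samples removed)\n",
            nrow(mat), ncol(mat), length(outl$dropped)))

pick <- pick_soft_threshold(mat)
write_table_tsv(pick$fit_table, "results/coexpression/soft_threshold.tsv")
cat(sprintf("soft threshold: power %d (fit target %s)\n", pick$power,
            if (pick$reached_target) "reached" else "not reached; sample-size default"))

adj <- abs(cor(t(mat)))^pick$power
diag(adj) <- 0
colors <- suppressWarnings(detect_modules(tom_similarity(adj), 100))
write_table_tsv(data.frame(gene = names(colors), module = unname(colors)),
                "results/coexpression/module_assignment.tsv")
sizes <- sort(table(colors[colors != "grey"]), decreasing = TRUE)
cat(sprintf("detected %d modules: %s\n", length(sizes),
            paste(sprintf("%s (%d)", names(sizes), sizes), collapse = ", ")))

if (length(sizes)) {
  me <- module_eigengenes(mat, colors)
  write_matrix_tsv(me$eigengenes, "results/coexpression/eigengenes.tsv", "module")
  es2 <- es[match(colnames(mat), es$sample_id), ]
  traits <- data.frame(group = as.numeric(es2$group == "AR"),
                       sex = as.numeric(es2$sex == "F"),
                       symptom_score = es2$symptom_score)
  tc <- suppressWarnings(module_trait_correlation(me$eigengenes, traits))
  write_table_tsv(tc, "results/coexpression/module_trait.tsv")
  key <- tc[tc$key, ]
  if (nrow(key)) {
    cat("key module-trait relations:\n")
    for (i in seq_len(nrow(key)))
      cat(sprintf("  %s ~ %s: cor %.2f (p=%.3g)\n",
                  key$module[i], key$trait[i], key$cor[i], key$p[i]))
  } else cat("no key module at Cor > 0.4 & p < 0.05\n")

  ## key-gene neighborhood: strongest driver gene inside a key module
  pairs <- read_table_tsv("results/integration/driver_pairs_pollen.tsv")
  key_mods <- unique(key$module)
  cand <- pairs[order(pairs$rho), ]
  cand <- cand[!is.na(colors[cand$gene]) & colors[cand$gene] %in% key_mods, ]
  if (nrow(cand)) {
    kg <- cand$gene[1]
    sub <- mat[names(colors)[colors == colors[kg]], , drop = FALSE]
    nb <- key_gene_neighbors(sub, kg)
    write_table_tsv(nb, "results/coexpression/key_gene_neighbors.tsv")
    cat(sprintf("key gene %s (%s module): %d significantly correlated neighbors\n",
                kg, colors[kg], nrow(nb)))
  } else cat("no driver gene inside a key module; neighborhood step skipped\n")
}
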