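small_cfg <- function(seed = 1, ...) {
  args <- list(n_probes_meth = 120, n_genes = 80, n_per_group = 4,
               n_planted_dmps = 10, n_planted_degs = 10, n_driver_pairs = 5,
               n_modules = 0, missing_rate = 0.02, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

test_that("configuration invariants are enforced with the field named", {
  expect_error(sim_config(n_driver_pairs = 50, n_planted_dmps = 10),
               "n_driver_pairs")
  expect_error(sim_config(driver_cor = 0.3), "driver_cor")
  expect_error(sim_config(driver_cor = -1), "driver_cor")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(n_genes = 10), "n_genes")
  expect_error(sim_config(delta_beta = -0.1), "delta_beta")
})

test_that("truth table matches the construction", {
  d <- generate_dataset(sim_config(seed = 1))
  expect_equal(nrow(d$truth$driver_pairs), 15)
  expect_true(all(d$truth$driver_pairs$probe %in% d$truth$dmp_ids))
  expect_true(all(d$truth$driver_pairs$gene %in% d$truth$deg_ids))
  ## module indices contiguous from 0
  expect_equal(sort(unique(d$truth$module_membership)), 0:2)
  ## planted DMPs promoter-annotated, decoys body-annotated
  ann <- d$meth$annotation
  expect_true(all(ann$feature[ann$probe %in% d$truth$dmp_ids] %in%
                    c("TSS1500", "TSS200", "5'UTR", "1stExon")))
  expect_true(all(ann$feature[ann$probe %in% d$truth$decoy_dmp_ids] == "Body"))
  ## driver probes annotated to their paired genes
  idx <- match(d$truth$driver_pairs$probe, ann$probe)
  expect_equal(ann$gene[idx], d$truth$driver_pairs$gene)
})

test_that("beta values live in [0,1] with the requested missingness", {
  d <- generate_dataset(small_cfg())
  b <- d$meth$beta
  expect_true(all(b >= 0 & b <= 1, na.rm = TRUE))
  expect_equal(mean(is.na(b)), 0.02, tolerance = 0.05)
  expect_true(all(is.finite(d$expr$expr)))
  expect_true(all(d$expr$detection_p >= 0 & d$expr$detection_p <= 1))
  ## no missingness requested: none produced
  d0 <- generate_dataset(small_cfg(missing_rate = 0))
  expect_false(anyNA(d0$meth$beta))
})

test_that("generation is deterministic given the seed", {
  d1 <- generate_dataset(small_cfg(seed = 5))
  d2 <- generate_dataset(small_cfg(seed = 5))
  expect_identical(d1, d2)
  d3 <- generate_dataset(small_cfg(seed = 6))
  expect_false(identical(d1$meth$beta, d3$meth$beta))
})

test_that("planted group shifts land near the configured effect sizes", {
  d <- generate_dataset(sim_config(seed = 2, missing_rate = 0))
  sheet <- d$meth$sample_sheet
  ar <- sheet$sample_id[sheet$group == "AR"]
  hc <- sheet$sample_id[sheet$group == "HC"]
  db <- rowMeans(d$meth$beta[d$truth$dmp_ids, ar]) -
    rowMeans(d$meth$beta[d$truth$dmp_ids, hc])
  expect_equal(mean(abs(db)), 0.3, tolerance = 0.05)
  esh <- d$expr$sample_sheet
  lfc <- rowMeans(log2(d$expr$expr[paste0("ep", sprintf("%06d", 1:30)),
                                   esh$sample_id[esh$group == "AR"]])) -
    rowMeans(log2(d$expr$expr[paste0("ep", sprintf("%06d", 1:30)),
                              esh$sample_id[esh$group == "HC"]]))
  expect_equal(mean(abs(lfc)), 1.5, tolerance = 0.15)
})

test_that("driver-pair sample correlation converges to the target", {
  d <- generate_dataset(sim_config(n_probes_meth = 60, n_genes = 40,
                                   n_per_group = 200, n_planted_dmps = 10,
                                   n_planted_degs = 10, n_driver_pairs = 6,
                                   n_modules = 0, missing_rate = 0, seed = 3))
  m <- match_samples(d$meth$sample_sheet, d$expr$sample_sheet)
  g <- collapse_to_genes(log2(d$expr$expr), d$expr$probe_to_gene)
  for (i in seq_len(6)) {
    rho <- cor(d$meth$beta[d$truth$driver_pairs$probe[i], m$meth_sample],
               g[d$truth$driver_pairs$gene[i], m$expr_sample],
               method = "spearman")
    expect_equal(rho, -0.8, tolerance = 0.05)
  }
})

test_that("datasets round-trip through the TSV/GMT writers", {
  d <- generate_dataset(small_cfg(n_modules = 2, module_size = 20,
                                  n_genes = 80))
  dir <- withr::local_tempdir()
  paths <- write_dataset(d, dir)
  expect_true(all(file.exists(paths)))
  back <- read_dataset(dir)
  expect_equal(back$meth$beta, d$meth$beta)
  expect_equal(back$expr$expr, d$expr$expr, tolerance = 1e-12)
  expect_equal(back$expr$probe_to_gene, d$expr$probe_to_gene)
  expect_equal(back$truth$driver_pairs$probe, d$truth$driver_pairs$probe)
  expect_equal(back$truth$trait_values, d$truth$trait_values, tolerance = 1e-12)
  expect_equal(back$gene_sets[["planted_module_1"]],
               d$gene_sets[["planted_module_1"]])
  ## GMT line format: name, description, members
  gmt <- readLines(file.path(dir, "gene_sets.gmt"))
  first <- strsplit(gmt[1], "\t")[[1]]
  expect_equal(first[1], "planted_module_1")
  expect_gte(length(first), 3)
})

test_that("empty matrices survive the TSV round trip as header-only files", {
  dir <- withr::local_tempdir()
  m <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("a", "b", "c")))
  f <- file.path(dir, "empty.tsv")
  write_matrix_tsv(m, f)
  expect_equal(length(readLines(f)), 1L)
  back <- read_matrix_tsv(f)
  expect_equal(dim(back), c(0L, 3L))
  expect_equal(colnames(back), c("a", "b", "c"))
})
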