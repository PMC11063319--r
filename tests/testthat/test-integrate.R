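make_sheet <- function(ids, patients, season = "pollen") {
  data.frame(sample_id = ids, patient_id = patients, season = season,
             stringsAsFactors = FALSE)
}

test_that("sample matching pairs by patient and season", {
  ## 16 methylation + 19 expression samples sharing 15 patients -> 15 pairs
  ms <- make_sheet(paste0("M", 1:16), paste0("P", 1:16))
  es <- make_sheet(paste0("E", 1:19), paste0("P", c(1:15, 20:23)))
  m <- suppressWarnings(match_samples(ms, es))
  expect_equal(nrow(m), 15)
  expect_setequal(m$patient_id, paste0("P", 1:15))
  expect_setequal(attr(m, "unmatched"), c("M16", paste0("E", 16:19)))

  ## disjoint patients -> empty with warning
  expect_warning(m0 <- match_samples(make_sheet("M1", "PA"),
                                     make_sheet("E1", "PB")), "unmatched")
  expect_equal(nrow(m0), 0)

  ## identical sheets -> identity pairing
  s <- make_sheet(paste0("S", 1:4), paste0("P", 1:4))
  mi <- match_samples(s, s)
  expect_equal(mi$meth_sample, mi$expr_sample)

  ## duplicated (patient, season) is an error
  expect_error(match_samples(make_sheet(c("M1", "M2"), c("PA", "PA")), s),
               "duplicate")
})

test_that("spearman statistics match the explicit rank-formula oracle under ties", {
  set.seed(77)
  for (i in 1:20) {
    x <- sample(1:5, 15, replace = TRUE)   # heavy ties
    y <- x * -1 + sample(0:3, 15, replace = TRUE)
    st <- spearman_test(x, y)
    expect_equal(st$rho, oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("small-sample exact p equals full permutation enumeration", {
  ## independent enumeration for n = 5 (120 permutations)
  perms5 <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms5 <- perms5[apply(perms5, 1, function(r) length(unique(r)) == 5), ]
  x <- c(2.3, -1.1, 0.4, 5.5, 3.2)
  y <- c(0.5, 2.2, 1.0, -3.3, 0.1)
  st <- spearman_test(x, y)
  expect_equal(st$method, "exact")
  null_rho <- apply(perms5, 1, function(pr) oracle_spearman(x, y[pr]))
  expect_equal(st$p, mean(abs(null_rho) >= abs(st$rho) - 1e-12))
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(13)
  x <- rnorm(25); y <- rnorm(25)
  base <- spearman_test(x, y)
  expect_equal(spearman_test(exp(x), y)$rho, base$rho)
  expect_equal(spearman_test(x, y^3 + 2 * y)$rho, base$rho)
  expect_equal(spearman_test(qlogis(plogis(x)), y)$p, base$p)
})

test_that("perfect monotone relationships give rho of -1 and +1", {
  b <- seq(0.1, 0.9, length.out = 8)
  expect_equal(spearman_test(b, rev(seq_len(8)))$rho, -1)
  expect_equal(spearman_test(b, b)$rho, 1)
})

test_that("pair scoring uses matched samples and complete cases", {
  set.seed(31)
  beta <- named_matrix(runif(40), 4, 10, rp = "cg", cp = "M")
  expr <- named_matrix(rnorm(30, 8), 3, 10, rp = "G", cp = "E")
  expr["G001", ] <- 10 - 9 * beta["cg001", ]   # perfect negative
  matched <- data.frame(meth_sample = colnames(beta),
                        expr_sample = colnames(expr))
  cand <- data.frame(probe = c("cg001", "cg002", "cg004"),
                     gene = c("G001", "G002", "G003"))
  sc <- correlate_pairs(beta, expr, cand, matched)
  expect_equal(nrow(sc), 3)
  expect_equal(sc$rho[sc$probe == "cg001"], -1)
  ## missing values: complete cases only, pairs under 4 cases skipped
  beta["cg002", 1:8] <- NA
  expect_warning(sc2 <- correlate_pairs(beta, expr, cand, matched), "skipped")
  expect_false("cg002" %in% sc2$probe)
})

test_that("driver-pair calling applies thresholds, set restriction and class logic", {
  dmps <- data.frame(feature = c("cg1", "cg2"), direction = c("hyper", "hypo"))
  degs <- data.frame(feature = c("gA", "gB"), direction = c("down", "down"))
  scored <- data.frame(
    probe = c("cg1", "cg1", "cg2", "cg9"),
    gene = c("gA", "gB", "gB", "gA"),
    rho = c(-0.5, -0.39, -0.8, -0.9),
    p = c(0.03, 0.01, 0.001, 0.001), n = 15)
  out <- suppressWarnings(call_driver_pairs(scored, dmps, degs))
  ## cg1-gA called hyper_low; cg1-gB excluded at the strict -0.4 boundary;
  ## cg2-gB dropped as inconsistent (hypo + down); cg9 not a DMP
  expect_equal(out$probe, "cg1")
  expect_equal(out$regulation_class, "hyper_low")
  expect_warning(call_driver_pairs(scored, dmps, degs), "not opposite")
  ## with the consistency check disabled, cg2-gB comes back
  out2 <- call_driver_pairs(scored, dmps, degs, check_consistency = FALSE)
  expect_setequal(paste(out2$probe, out2$gene), c("cg1 gA", "cg2 gB"))
})

test_that("called pairs are a subset of scored pairs and of DMP x DEG", {
  set.seed(19)
  d <- generate_dataset(sim_config(seed = 19, n_genes = 200,
                                   n_planted_degs = 15, n_driver_pairs = 8,
                                   n_modules = 0))
  res <- suppressWarnings(run_pipeline(d$meth, d$expr,
                                       config = pipeline_config(seasons = "pollen")))
  st <- res$seasons$pollen
  key <- function(df) paste(df$probe, df$gene)
  expect_true(all(key(st$pairs) %in% key(st$scored)))
  expect_true(all(st$pairs$probe %in% st$dmps$feature))
  expect_true(all(st$pairs$gene %in% st$degs$feature))
  expect_true(all(st$pairs$rho < 0))
})

test_that("gene-set comparison produces a consistent Venn partition", {
  shared <- paste0("s", 1:4)
  a <- c(paste0("a", 1:3), shared)
  b <- c(paste0("b", 1:5), shared)
  cmp <- compare_gene_sets(a, b)
  expect_equal(length(cmp$intersection), 4)
  expect_setequal(cmp$unique_a, paste0("a", 1:3))
  expect_equal(cmp$counts$n, c(3, 5, 4))
  expect_length(compare_gene_sets(a, a)$unique_a, 0)
  empty <- compare_gene_sets(character(0), b)
  expect_setequal(empty$unique_b, unique(b))
})
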