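test_that("moderated t with zero prior df equals the ordinary pooled t", {
  set.seed(42)
  m <- named_matrix(rnorm(50 * 12, 5), 50, 12)
  grp <- two_groups(6, 6, colnames(m))
  res <- moderated_ttest(m, grp, d0 = 0)
  for (i in c(1, 17, 50)) {
    t_ref <- oracle_pooled_t(m[i, 1:6], m[i, 7:12])
    expect_equal(res$t[i], t_ref, tolerance = 1e-10)
    expect_equal(res$p[i], 2 * pt(-abs(t_ref), df = 10), tolerance = 1e-10)
  }
})

test_that("identical groups give zero effects and p = 1", {
  m0 <- named_matrix(rnorm(20 * 4), 20, 8)
  m0[, 5:8] <- m0[, 1:4]
  res <- moderated_ttest(m0, two_groups(4, 4, colnames(m0)))
  expect_true(all(res$effect == 0))
  expect_true(all(res$p >= 0.99))
})

test_that("variance shrinkage is monotone in the prior df", {
  set.seed(9)
  m <- named_matrix(rnorm(200 * 10, sd = rep(c(0.2, 2), 100)), 200, 10)
  grp <- two_groups(5, 5, colnames(m))
  r_small <- moderated_ttest(m, grp, d0 = 1)
  r_large <- moderated_ttest(m, grp, d0 = 1e6)
  s2 <- r_small$s2
  ## large prior df pulls all posterior variances to (nearly) one value
  expect_lt(diff(range(r_large$s2_post)), diff(range(r_small$s2_post)))
  ## shrinkage moves each variance toward the prior, never past the data side
  prior_fit <- attr(moderated_ttest(m, grp), "prior")
  expect_gt(prior_fit$d0, 0)
})

test_that("moderated t agrees with the established empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(123)
  m <- named_matrix(rnorm(500 * 16, 7, sd = rep(runif(500, 0.3, 2), 16)), 500, 16)
  grp <- two_groups(8, 8, colnames(m))
  res <- moderated_ttest(m, grp)
  design <- cbind(1, as.numeric(grp == "AR"))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(res$effect, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(attr(res, "prior")$d0, fit$df.prior, tolerance = 0.05)
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 0.01)
  expect_gt(cor(res$p, fit$p.value[, 2]), 0.9999)
})

test_that("adaptive threshold is mean + 2 sd of absolute effects", {
  expect_equal(adaptive_threshold(c(1, 1, 1, 1))$tau, 1)
  th <- adaptive_threshold(c(0, 2))
  expect_equal(th$mean_abs, 1)
  expect_equal(th$sd_abs, sqrt(2))
  expect_equal(th$tau, 1 + 2 * sqrt(2))
  ## homogeneity: scaling effects by c scales tau by c
  set.seed(3)
  e <- rnorm(100)
  expect_equal(adaptive_threshold(3.7 * e)$tau, 3.7 * adaptive_threshold(e)$tau)
  ## permutation invariance
  expect_equal(adaptive_threshold(rev(e))$tau, adaptive_threshold(e)$tau)
  expect_error(adaptive_threshold(1), "at least 2")
})

test_that("DMP calls respect p, effect and promoter criteria", {
  res <- data.frame(feature = c("cg1", "cg2", "cg3", "cg4"),
                    effect = c(0.3, 0.5, 0.01, -0.4),
                    t = 0, p = c(0.01, 0.001, 0.5, 0.02),
                    stringsAsFactors = FALSE)
  ann <- data.frame(probe = c("cg1", "cg2", "cg3", "cg4"),
                    gene = c("A", "B", "C", "D"),
                    feature = c("TSS200", "Body", "TSS1500", "5'UTR"),
                    stringsAsFactors = FALSE)
  thr <- adaptive_threshold(c(0.05, 0.15))  # tau = 0.2414
  out <- call_dmps(res, ann, threshold = thr)
  expect_setequal(out$feature, c("cg1", "cg4"))   # cg2 excluded: Body
  expect_equal(out$direction[out$feature == "cg1"], "hyper")
  expect_equal(out$direction[out$feature == "cg4"], "hypo")
  ## missing annotation -> warning, probe excluded
  out2 <- expect_warning(
    call_dmps(res, ann[-1, ], threshold = thr), "without annotation")
  expect_false("cg1" %in% out2$feature)
})

test_that("DEG calls use a strict effect inequality and partition up/down", {
  thr <- structure(list(tau = 1, mean_abs = NA, sd_abs = NA, n_features = NA),
                   class = "adaptive_threshold")
  res <- data.frame(feature = c("g1", "g2", "g3"),
                    effect = c(1.01, 1.0, -1.2), t = 0,
                    p = c(0.04, 0.04, 0.04), stringsAsFactors = FALSE)
  out <- call_degs(res, threshold = thr)
  expect_setequal(out$feature, c("g1", "g3"))     # |effect| = tau excluded
  expect_equal(sort(unique(out$direction)), c("down", "up"))
  expect_length(intersect(out$feature[out$direction == "up"],
                          out$feature[out$direction == "down"]), 0)
})

test_that("planted promoter DMPs are recovered by the adaptive screen", {
  hits <- numeric(0)
  for (seed in 1:15) {
    d <- generate_dataset(sim_config(seed = seed, n_genes = 100,
                                     n_planted_degs = 10, n_driver_pairs = 5,
                                     n_modules = 0, missing_rate = 0))
    sheet <- d$meth$sample_sheet
    ms <- sheet[sheet$season == "pollen", ]
    res <- moderated_ttest(d$meth$beta[, ms$sample_id],
                           setNames(ms$group, ms$sample_id))
    dmps <- call_dmps(res, d$meth$annotation)
    hits <- c(hits, sum(d$truth$dmp_ids %in% dmps$feature))
    ## decoy body-annotated probes must never be called
    expect_length(intersect(d$truth$decoy_dmp_ids, dmps$feature), 0)
  }
  expect_gte(mean(hits), 24)  # >= 24 of 30 planted on average
})
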