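block_data <- function(n_blocks = 2, block_size = 120, n_bg = 60, n = 18,
                       noise_sd = sqrt(3 / 7)) {
  f <- matrix(rnorm(n_blocks * n), n_blocks)
  y <- rbind(
    do.call(rbind, lapply(seq_len(n_blocks), function(m)
      f[rep(m, block_size), ] + matrix(rnorm(block_size * n, sd = noise_sd),
                                       block_size))),
    matrix(rnorm(n_bg * n), n_bg))
  rownames(y) <- sprintf("g%04d", seq_len(nrow(y)))
  colnames(y) <- sprintf("s%02d", seq_len(n))
  list(y = y, truth = rep(c(seq_len(n_blocks), 0), c(rep(block_size, n_blocks), n_bg)))
}

test_that("MAD filter keeps the requested top fraction deterministically", {
  set.seed(2)
  e <- named_matrix(rnorm(400, sd = rep(1:4, each = 4)), 100, 4, rp = "g")
  out <- mad_filter(e, 0.25)
  expect_equal(nrow(out), 25)
  ## constant genes never kept when enough variable genes exist
  e2 <- e; e2[1:10, ] <- 5
  expect_false(any(rownames(mad_filter(e2, 0.25)) %in% rownames(e2)[1:10]))
  ## scaling a gene raises it into the kept set
  e3 <- e; e3["g001", ] <- e3["g001", ] * 50
  expect_true("g001" %in% rownames(mad_filter(e3, 0.25)))
})

test_that("outlier-sample removal drops a planted outlier and spares clean data", {
  set.seed(14)
  ## homogeneous samples: none dropped
  e <- named_matrix(rnorm(2000), 100, 20, rp = "g")
  r <- remove_outlier_samples(e)
  expect_length(r$dropped, 0)
  ## identical samples: zero heights, none dropped
  e2 <- named_matrix(rep(rnorm(100), 6), 100, 6, rp = "g")
  expect_length(remove_outlier_samples(e2)$dropped, 0)
  ## one sample replaced by an alien profile on structured data
  bd <- block_data(n_blocks = 3, block_size = 40, n_bg = 20, n = 20)
  e3 <- bd$y
  e3[, 5] <- rnorm(nrow(e3), sd = 4)
  r3 <- remove_outlier_samples(e3)
  expect_true("s05" %in% r3$dropped)
})

test_that("soft-threshold fit index matches a from-definition recomputation", {
  set.seed(23)
  bd <- block_data(n_blocks = 2, block_size = 25, n_bg = 10, n = 15)
  ps <- pick_soft_threshold(bd$y, powers = 1:8)
  for (p in c(2, 5)) {
    a <- abs(cor(t(bd$y)))^p
    diag(a) <- 0
    k <- rowSums(a)
    ## independent recomputation of the binned log-log regression
    bins <- cut(k[k > 0], breaks = 10)
    lf <- log10(as.numeric(table(bins)[table(bins) > 0]))
    lk <- log10(tapply(k[k > 0], bins, mean)[table(bins) > 0])
    sl <- coef(lm(lf ~ lk))[2]
    r2 <- summary(lm(lf ~ lk))$r.squared
    expect_equal(ps$fit_table$fit_index[ps$fit_table$power == p],
                 unname(r2 * sign(-sl)), tolerance = 1e-10)
  }
  ## mean connectivity is non-increasing in the power
  expect_true(all(diff(ps$fit_table$mean_k) <= 0))
  expect_error(suppressWarnings(pick_soft_threshold(named_matrix(rep(1, 300), 60, 5))),
               "constant|undefined")
})

test_that("soft-threshold choice stays moderate on block-structured data", {
  set.seed(37)
  bd <- block_data(n_blocks = 4, block_size = 60, n_bg = 560, n = 18)
  ps <- pick_soft_threshold(bd$y)
  expect_lte(ps$power, 10)
  expect_true(is.finite(ps$fit_table$fit_index[ps$power]))
})

test_that("TOM matches the hand-computed 3-node value and the O(n^3) oracle", {
  a <- matrix(0.5, 3, 3); diag(a) <- 0
  dimnames(a) <- list(paste0("g", 1:3), paste0("g", 1:3))
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], 0.5)       # (0.25 + 0.5) / (1 + 1 - 0.5)
  expect_equal(diag(tom), setNames(rep(1, 3), rownames(a)))

  ## zero adjacency -> identity
  z <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  expect_equal(unname(tom_similarity(z)), diag(4))

  set.seed(41)
  for (i in 1:5) {
    a20 <- matrix(runif(400), 20, 20)
    a20 <- (a20 + t(a20)) / 2
    diag(a20) <- 0
    dimnames(a20) <- list(paste0("g", 1:20), paste0("g", 1:20))
    tom20 <- tom_similarity(a20)
    expect_equal(unname(tom20), oracle_tom(a20), tolerance = 1e-12)
    expect_lt(max(abs(tom20 - t(tom20))), 1e-10)
    expect_true(all(tom20 >= 0 & tom20 <= 1))
  }
  bad <- matrix(runif(9), 3, 3); diag(bad) <- 0
  expect_error(tom_similarity(bad), "asymmetric")
})

test_that("planted blocks are detected as modules invariant to gene order", {
  set.seed(52)
  bd <- block_data()
  adj <- abs(cor(t(bd$y)))^6; diag(adj) <- 0
  cols <- detect_modules(tom_similarity(adj), min_module_size = 100)
  mods <- setdiff(unique(cols), "grey")
  expect_equal(length(mods), 2)
  ## permuting gene order changes nothing up to labels
  pm <- sample(nrow(bd$y))
  adj2 <- abs(cor(t(bd$y[pm, ])))^6; diag(adj2) <- 0
  cols2 <- detect_modules(tom_similarity(adj2), min_module_size = 100)
  expect_equal(unname(cols2[names(cols)]), unname(cols))
  ## min size above gene count: everything grey
  expect_warning(all_grey <- detect_modules(tom_similarity(adj), 10000),
                 "grey")
  expect_true(all(all_grey == "grey"))
})

test_that("module eigengenes are unit-norm first PCs with aligned sign", {
  set.seed(61)
  ## module of identical genes: eigengene proportional to the profile
  prof <- rnorm(10)
  e <- named_matrix(rep(prof, each = 5), 5, 10, rp = "g")
  cols <- setNames(rep("blue", 5), rownames(e))
  me <- module_eigengenes(e, cols)
  expect_equal(me$var_explained[["blue"]], 1)
  expect_equal(abs(cor(me$eigengenes["blue", ], prof)), 1)
  expect_gt(cor(me$eigengenes["blue", ], prof), 0)   # sign alignment
  expect_equal(sum(me$eigengenes["blue", ]^2), 1)    # unit norm

  ## agreement with a power-iteration PCA oracle on 10-gene fixtures
  for (i in 1:5) {
    x <- named_matrix(rnorm(120), 10, 12, rp = "g")
    cols2 <- setNames(rep("red", 10), rownames(x))
    me2 <- module_eigengenes(x, cols2)
    z <- t(scale(t(x)))
    or <- oracle_pc1(z)
    expect_equal(abs(cor(me2$eigengenes["red", ], or$vector)), 1,
                 tolerance = 1e-6)
    expect_equal(me2$var_explained[["red"]], or$value / or$total,
                 tolerance = 1e-6)
  }

  ## flipping the sign of all genes leaves the aligned eigengene usable
  me3 <- module_eigengenes(-e, cols)
  expect_equal(abs(cor(me3$eigengenes["blue", ], me$eigengenes["blue", ])), 1)
})

test_that("module-trait correlation flags planted relations and skips constants", {
  set.seed(71)
  eg <- matrix(rnorm(36), 2, 18, dimnames = list(c("blue", "red"), NULL))
  traits <- data.frame(t1 = eg["blue", ], t2 = rnorm(18), t3 = rep(1, 18))
  expect_warning(module_trait_correlation(eg, traits), "constant")
  out <- suppressWarnings(module_trait_correlation(eg, traits))
  expect_true(out$key[out$module == "blue" & out$trait == "t1"])
  expect_equal(out$cor[out$module == "blue" & out$trait == "t1"], 1)
  expect_false(any(out$trait == "t3"))
  ## signed default: strong negative correlation is not "key"
  traits2 <- data.frame(t4 = -eg["blue", ])
  out2 <- module_trait_correlation(eg, traits2)
  expect_false(out2$key[out2$module == "blue"])
  expect_true(module_trait_correlation(eg, traits2, use_abs = TRUE)$key[1])
})

test_that("key-gene neighborhoods recover planted co-regulated genes", {
  set.seed(81)
  n <- 18
  f <- rnorm(n)
  e <- rbind(key = f + rnorm(n, sd = 0.2),
             do.call(rbind, lapply(1:50, function(i) f + rnorm(n, sd = 0.85))),
             matrix(rnorm(30 * n), 30))
  rownames(e) <- c("key", paste0("nb", 1:50), paste0("bg", 1:30))
  colnames(e) <- paste0("s", 1:n)
  out <- key_gene_neighbors(e, "key")
  expect_false("key" %in% out$gene)
  expect_gte(mean(paste0("nb", 1:50) %in% out$gene), 0.8)
  ## identical gene always included; anti-correlated excluded under signed rule
  e2 <- rbind(e, twin = e["key", ], anti = -e["key", ])
  out2 <- key_gene_neighbors(e2, "key")
  expect_true("twin" %in% out2$gene)
  expect_false("anti" %in% out2$gene)
  expect_error(key_gene_neighbors(e, "nope"), "not found")
})
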