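## Two-group differential testing with an empirical-Bayes moderated t, the
## adaptive mean+2sd effect-size threshold, and promoter-restricted DMP /
## DEG calling.

## Invert the trigamma function by Newton iteration (tolerance 1e-8).
trigamma_inverse <- function(x) {
  assert_that(is_number(x) && x > 0, "trigamma_inverse needs a positive value")
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

## Method-of-moments fit of the scaled inverse-chi-square variance prior:
## log s^2 is matched to its theoretical mean/variance under d residual df,
## giving prior df d0 (via trigamma inversion) and prior variance s0^2.
fit_variance_prior <- function(s2, df, d0_cap = 1e6) {
  ok <- is.finite(s2) & s2 > 0
  assert_that(sum(ok) >= 2, "need at least two positive variances to fit the prior")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- min(2 * trigamma_inverse(evar), d0_cap)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- d0_cap
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Per feature, the pooled two-sample variance is shrunk toward a prior
#' fitted across features by method of moments on `log(s^2)` (prior df via
#' trigamma inversion, capped at 1e6 to represent an effectively infinite
#' prior). The moderated statistic is
#' `t = effect / sqrt(s2_post * (1/n1 + 1/n2))` with
#' `s2_post = (d0*s0^2 + d*s^2) / (d0 + d)` and two-sided p-values on
#' `d0 + d` degrees of freedom. Effects are `mean(group1) - mean(group2)`.
#'
#' @param mat features x samples matrix (beta values or log2 expression).
#' @param groups named vector mapping sample ID to group; exactly two groups.
#' @param group1 label of the group whose mean comes first in the effect
#'   (default `"AR"` if present, else the first level).
#' @param d0 optional prior df override; `d0 = 0` reduces to the ordinary
#'   pooled-variance t-test.
#' @return data.frame with columns `feature`, `effect`, `t`, `p`,
#'   `p_adj` (Benjamini-Hochberg), `s2`, `s2_post`; prior in
#'   `attr(, "prior")`.
#' @export
moderated_ttest <- function(mat, groups, group1 = NULL, d0 = NULL) {
  check_matrix(mat)
  groups <- as.character(groups[colnames(mat)])
  assert_that(!anyNA(groups), "groups must cover every sample column")
  lev <- unique(groups)
  assert_that(length(lev) == 2L, "exactly two groups are required")
  if (is.null(group1)) group1 <- if ("AR" %in% lev) "AR" else lev[1L]
  assert_that(group1 %in% lev, "group1 '%s' not found in groups", group1)
  g2 <- setdiff(lev, group1)
  i1 <- which(groups == group1); i2 <- which(groups == g2)
  n1 <- length(i1); n2 <- length(i2)
  assert_that(n1 >= 2 && n2 >= 2, "need at least 2 samples per group")

  m1 <- rowMeans(mat[, i1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(mat[, i2, drop = FALSE], na.rm = TRUE)
  v1 <- apply(mat[, i1, drop = FALSE], 1L, stats::var, na.rm = TRUE)
  v2 <- apply(mat[, i2, drop = FALSE], 1L, stats::var, na.rm = TRUE)
  df_resid <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df_resid
  effect <- m1 - m2

  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, df_resid)
  } else {
    assert_that(is_number(d0) && d0 >= 0, "d0 must be >= 0")
    prior <- list(d0 = d0, s02 = if (d0 > 0) mean(s2, na.rm = TRUE) else 0)
  }
  s2_post <- (prior$d0 * prior$s02 + df_resid * s2) / (prior$d0 + df_resid)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, effect / se, ifelse(effect == 0, 0, sign(effect) * Inf))
  df_total <- prior$d0 + df_resid
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[t_mod == 0] <- 1
  res <- data.frame(feature = rownames(mat), effect = effect, t = t_mod,
                    p = p, p_adj = stats::p.adjust(p, "BH"),
                    s2 = s2, s2_post = s2_post,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "prior") <- c(prior, list(df_resid = df_resid, df_total = df_total,
                                      group1 = group1, group2 = g2))
  res
}

#' Adaptive effect-size threshold: mean + 2 sd of absolute effects
#'
#' tau = mean(|effect|) + 2 * sd(|effect|), with the sample (n-1) standard
#' deviation, computed over all tested features.
#'
#' @param effects numeric vector of effects (signed; absolute values used).
#' @return object of class `adaptive_threshold` with fields `tau`,
#'   `mean_abs`, `sd_abs`, `n_features`.
#' @export
adaptive_threshold <- function(effects) {
  effects <- effects[is.finite(effects)]
  assert_that(length(effects) >= 2, "need at least 2 finite effects")
  a <- abs(effects)
  out <- list(mean_abs = mean(a), sd_abs = stats::sd(a),
              n_features = length(a))
  out$tau <- out$mean_abs + 2 * out$sd_abs
  structure(out, class = "adaptive_threshold")
}

#' @export
print.adaptive_threshold <- function(x, ...) {
  cat(sprintf("adaptive threshold: tau = %.4g (mean |effect| %.4g + 2 x sd %.4g, %d features)\n",
              x$tau, x$mean_abs, x$sd_abs, x$n_features))
  invisible(x)
}

#' Call differentially methylated positions
#'
#' A probe is a DMP when (1) `|delta beta| > tau` (adaptive threshold over
#' all tested probes), (2) raw `p < alpha`, and (3) its annotated genomic
#' feature is a promoter feature. Direction `hyper`/`hypo` follows the sign
#' of the effect (group1 minus group2).
#'
#' @param results data.frame from [moderated_ttest()].
#' @param annotation data.frame with columns `probe`, `gene`, `feature`.
#' @param threshold optional [adaptive_threshold()]; computed from
#'   `results$effect` when `NULL`.
#' @param alpha raw p-value cutoff.
#' @param promoter_features feature labels counting as promoter.
#' @return data.frame of called probes with `gene`, `feature`, `direction`.
#' @export
call_dmps <- function(results, annotation, threshold = NULL, alpha = 0.05,
                      promoter_features = c("TSS1500", "TSS200", "5'UTR", "1stExon")) {
  if (is.null(threshold)) threshold <- adaptive_threshold(results$effect)
  pass <- results$p < alpha & abs(results$effect) > threshold$tau
  hit <- results[pass, , drop = FALSE]
  idx <- match(hit$feature, annotation$probe)
  if (anyNA(idx)) {
    warning(sprintf("%d significant probe(s) without annotation excluded",
                    sum(is.na(idx))))
    hit <- hit[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  hit$gene <- annotation$gene[idx]
  hit$feature_label <- annotation$feature[idx]
  hit <- hit[hit$feature_label %in% promoter_features, , drop = FALSE]
  hit$direction <- ifelse(hit$effect > 0, "hyper", "hypo")
  attr(hit, "threshold") <- threshold
  hit
}

#' Call differentially expressed genes
#'
#' As [call_dmps()] without the promoter restriction: `|log2FC| > tau`
#' (strict) and raw `p < alpha`; direction `up`/`down` from the effect sign.
#'
#' @inheritParams call_dmps
#' @return data.frame of called genes with `direction`.
#' @export
call_degs <- function(results, threshold = NULL, alpha = 0.05) {
  if (is.null(threshold)) threshold <- adaptive_threshold(results$effect)
  pass <- results$p < alpha & abs(results$effect) > threshold$tau
  hit <- results[pass, , drop = FALSE]
  hit$direction <- ifelse(hit$effect > 0, "up", "down")
  attr(hit, "threshold") <- threshold
  hit
}

#' Convert beta values to M-values
#'
#' `M = log2(beta / (1 - beta))` with beta clipped away from 0/1.
#' @param beta matrix of beta values.
#' @param eps clipping margin.
#' @export
beta_to_mvalue <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}
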