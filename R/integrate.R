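## Methylation-expression integration: patient-level sample matching,
## Spearman correlation of CpG beta against gene expression over matched
## samples, and the negative-correlation driver-pair call restricted to
## DMPs and DEGs.

#' Match methylation and expression samples by patient and season
#'
#' @param meth_sheet,expr_sheet sample sheets with columns `sample_id`,
#'   `patient_id`, `season`.
#' @return data.frame with one row per (patient, season) present in both
#'   assays: `meth_sample`, `expr_sample`, `patient_id`, `season`; unmatched
#'   sample IDs are reported in `attr(, "unmatched")`.
#' @export
match_samples <- function(meth_sheet, expr_sheet) {
  key_m <- paste(meth_sheet$patient_id, meth_sheet$season, sep = "\r")
  key_e <- paste(expr_sheet$patient_id, expr_sheet$season, sep = "\r")
  assert_that(!anyDuplicated(key_m), "duplicate (patient, season) in methylation sheet")
  assert_that(!anyDuplicated(key_e), "duplicate (patient, season) in expression sheet")
  shared <- intersect(key_m, key_e)
  im <- match(shared, key_m); ie <- match(shared, key_e)
  out <- data.frame(meth_sample = meth_sheet$sample_id[im],
                    expr_sample = expr_sheet$sample_id[ie],
                    patient_id = meth_sheet$patient_id[im],
                    season = meth_sheet$season[im],
                    stringsAsFactors = FALSE)
  unmatched <- c(meth_sheet$sample_id[!(key_m %in% shared)],
                 expr_sheet$sample_id[!(key_e %in% shared)])
  if (length(unmatched)) warning(sprintf("%d unmatched sample(s)", length(unmatched)))
  attr(out, "unmatched") <- unmatched
  out
}

## Exact Spearman permutation null distributions, cached per n (tie-free).
.spearman_null_env <- new.env(parent = emptyenv())

spearman_exact_null <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearman_null_env[[key]])) return(.spearman_null_env[[key]])
  pm <- matrix(1L, 1L, 1L)
  if (n > 1L) for (k in 2:n) {
    npm <- nrow(pm)
    out <- matrix(0L, npm * k, k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1L) * npm + seq_len(npm)
      left <- if (pos > 1L) pm[, seq_len(pos - 1L), drop = FALSE] else NULL
      right <- if (pos < k) pm[, pos:(k - 1L), drop = FALSE] else NULL
      out[rows, ] <- cbind(left, k, right)
    }
    pm <- out
  }
  d2 <- rowSums((pm - rep(seq_len(n), each = nrow(pm)))^2)
  rho <- 1 - 6 * d2 / (n * (n^2 - 1))
  .spearman_null_env[[key]] <- rho
  rho
}

#' Spearman correlation with a small-sample exact p-value
#'
#' rho uses average ranks for ties. For `n <= 9` with no ties in either
#' variable the two-sided p-value is exact over all `n!` rank permutations;
#' otherwise it uses the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df.
#'
#' @param x,y numeric vectors of equal length (complete cases used).
#' @return list with `rho`, `p`, `n`, `method`.
#' @export
spearman_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert_that(n >= 4, "need at least 4 complete observations")
  rho <- stats::cor(x, y, method = "spearman")
  if (is.na(rho)) return(list(rho = NA_real_, p = NA_real_, n = n, method = "degenerate"))
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 9 && !ties) {
    null <- spearman_exact_null(n)
    p <- mean(abs(null) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    r <- min(max(rho, -1 + 1e-15), 1 - 1e-15)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

#' Correlate CpG beta values with candidate gene expression
#'
#' For each annotated (probe, gene) candidate, the Spearman correlation is
#' computed across matched samples (complete cases only); pairs with fewer
#' than 4 complete cases are skipped with a warning.
#'
#' @param beta probes x samples beta matrix (methylation sample IDs).
#' @param expr genes x samples expression matrix (expression sample IDs).
#' @param candidate_map data.frame with columns `probe`, `gene` from the
#'   array annotation.
#' @param matched data.frame from [match_samples()].
#' @return data.frame (one row per scored pair): `probe`, `gene`, `rho`,
#'   `p`, `n`.
#' @export
correlate_pairs <- function(beta, expr, candidate_map, matched) {
  assert_that(nrow(matched) >= 4, "need at least 4 matched samples")
  cand <- candidate_map[candidate_map$probe %in% rownames(beta) &
                          candidate_map$gene %in% rownames(expr), , drop = FALSE]
  bm <- beta[, matched$meth_sample, drop = FALSE]
  em <- expr[, matched$expr_sample, drop = FALSE]
  n_skip <- 0L
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    x <- bm[cand$probe[i], ]
    y <- em[cand$gene[i], ]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 4L) { n_skip <- n_skip + 1L; next }
    st <- spearman_test(x, y)
    rows[[i]] <- data.frame(probe = cand$probe[i], gene = cand$gene[i],
                            rho = st$rho, p = st$p, n = st$n,
                            stringsAsFactors = FALSE)
  }
  if (n_skip > 0L) warning(sprintf("%d pair(s) skipped (< 4 complete cases)", n_skip))
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) out <- data.frame(probe = character(), gene = character(),
                                      rho = numeric(), p = numeric(), n = integer())
  rownames(out) <- NULL
  out
}

#' Call methylation-driven CpG-gene pairs
#'
#' Retains scored pairs with `rho < rho_max` (strict) and `p < alpha` whose
#' probe is a called DMP and gene a called DEG. The regulation class follows
#' the DMP direction (`hyper` -> `hyper_low`, `hypo` -> `hypo_high`); pairs
#' whose DEG direction does not oppose the DMP direction are dropped with a
#' warning (negative regulation consistency).
#'
#' @param scored data.frame from [correlate_pairs()].
#' @param dmps data.frame from [call_dmps()] (needs `feature`, `direction`).
#' @param degs data.frame from [call_degs()] (needs `feature`, `direction`).
#' @param rho_max correlation ceiling (default -0.4).
#' @param alpha p-value cutoff.
#' @param season optional label attached to the result.
#' @param check_consistency drop pairs whose DEG direction does not oppose
#'   the DMP direction (default `TRUE`; disable to obtain the raw
#'   threshold-filtered DMP x DEG pairs).
#' @return data.frame of called pairs with `regulation_class` and `season`.
#' @export
call_driver_pairs <- function(scored, dmps, degs, rho_max = -0.4,
                              alpha = 0.05, season = NA_character_,
                              check_consistency = TRUE) {
  keep <- scored$rho < rho_max & scored$p < alpha &
    scored$probe %in% dmps$feature & scored$gene %in% degs$feature
  out <- scored[keep, , drop = FALSE]
  if (nrow(out)) {
    pd <- dmps$direction[match(out$probe, dmps$feature)]
    gd <- degs$direction[match(out$gene, degs$feature)]
    consistent <- (pd == "hyper" & gd == "down") | (pd == "hypo" & gd == "up")
    if (!check_consistency) consistent <- rep(TRUE, nrow(out))
    if (any(!consistent))
      warning(sprintf("%d pair(s) dropped: DEG direction not opposite to DMP",
                      sum(!consistent)))
    out <- out[consistent, , drop = FALSE]
    out$regulation_class <- ifelse(
      dmps$direction[match(out$probe, dmps$feature)] == "hyper",
      "hyper_low", "hypo_high")
  } else {
    out$regulation_class <- character(0)
  }
  out$season <- rep(season, nrow(out))
  rownames(out) <- NULL
  out
}

#' Compare two gene sets (Venn-style overlap report)
#'
#' @param set_a,set_b character vectors of gene IDs.
#' @param labels length-2 character vector naming the sets.
#' @return list with `unique_a`, `unique_b`, `intersection`, and a `counts`
#'   data.frame ready for a Venn table.
#' @export
compare_gene_sets <- function(set_a, set_b, labels = c("A", "B")) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  inter <- intersect(set_a, set_b)
  ua <- setdiff(set_a, set_b); ub <- setdiff(set_b, set_a)
  list(unique_a = ua, unique_b = ub, intersection = inter,
       counts = data.frame(
         part = c(paste0("unique_", labels[1]), paste0("unique_", labels[2]),
                  "intersection"),
         n = c(length(ua), length(ub), length(inter)),
         stringsAsFactors = FALSE))
}
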