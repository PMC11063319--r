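## Gene-set enrichment: hypergeometric over-representation analysis on gene
## lists, and single-CpG GSEA (weighted Kolmogorov-Smirnov running sum with
## a gene-label permutation null) on a correlation-ranked transcriptome.

#' Hypergeometric over-representation analysis
#'
#' Per gene set, the upper-tail probability `P(X >= k)` for
#' `X ~ Hypergeom(N, K, n)`: universe size `N`, set size in universe `K`,
#' query size `n`, overlap `k`. Query genes outside the universe are
#' intersected away (and counted in `attr(, "dropped_query")`). p-values are
#' Benjamini-Hochberg adjusted across the collection; rows sorted by p.
#'
#' @param query character vector of gene IDs.
#' @param collection named list of gene-set member vectors (e.g. [read_gmt()]).
#' @param universe character vector of background gene IDs.
#' @return data.frame with `set`, `k`, `K`, `n`, `N`, `p`, `p_adj`.
#' @export
ora_hypergeometric <- function(query, collection, universe) {
  universe <- unique(universe)
  assert_that(length(universe) > 0, "universe must be non-empty")
  query0 <- unique(query)
  assert_that(length(query0) > 0, "query must be non-empty")
  query <- intersect(query0, universe)
  assert_that(length(query) > 0, "no query gene is in the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(unique(collection[[nm]]), universe)
    K <- length(members)
    k <- length(intersect(members, query))
    p <- if (k == 0L) {
      ## P(X >= 0) = 1 always; phyper(-1, ...) returns 1
      stats::phyper(-1, K, N - K, n, lower.tail = FALSE)
    } else {
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    }
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, "BH")
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_query") <- setdiff(query0, universe)
  out
}

#' Rank genes by their Spearman correlation with one CpG's beta values
#'
#' @param cpg_beta named numeric vector of beta values (sample IDs).
#' @param expr genes x samples expression matrix.
#' @param samples data.frame with columns `meth_sample`, `expr_sample`
#'   pairing the two assays (e.g. from [match_samples()]), or `NULL` when
#'   the names of `cpg_beta` already match `colnames(expr)`.
#' @return numeric vector of correlations, named by gene, sorted decreasing
#'   (ties broken by gene ID).
#' @export
rank_by_cpg <- function(cpg_beta, expr, samples = NULL) {
  if (!is.null(samples)) {
    b <- cpg_beta[samples$meth_sample]
    e <- expr[, samples$expr_sample, drop = FALSE]
  } else {
    shared <- intersect(names(cpg_beta), colnames(expr))
    b <- cpg_beta[shared]
    e <- expr[, shared, drop = FALSE]
  }
  ok <- !is.na(b)
  b <- b[ok]; e <- e[, ok, drop = FALSE]
  assert_that(length(b) >= 4, "need at least 4 shared samples")
  assert_that(stats::sd(b) > 0, "CpG beta values are constant across samples")
  rho <- apply(e, 1L, function(y) stats::cor(b, y, method = "spearman"))
  if (anyNA(rho)) {
    warning(sprintf("%d gene(s) with undefined correlation dropped from ranking",
                    sum(is.na(rho))))
    rho <- rho[!is.na(rho)]
  }
  rho <- rho[order(-rho, names(rho))]
  rho
}

## Fast ES from sorted hit positions: the running sum between hits is
## linear, so its extrema occur immediately before or after a hit.
es_from_hits <- function(hit_pos, weights, L) {
  m <- length(hit_pos)
  wsum <- sum(weights)
  if (wsum <= 0) weights <- rep(1 / m, m) else weights <- weights / wsum
  miss_step <- 1 / (L - m)
  cw <- cumsum(weights)
  after <- cw - (hit_pos - seq_len(m)) * miss_step
  before <- c(0, cw[-m]) - (hit_pos - seq_len(m)) * miss_step
  hi <- max(after); lo <- min(before)
  if (abs(hi) >= abs(lo)) hi else lo
}

#' GSEA enrichment score (weighted Kolmogorov-Smirnov running sum)
#'
#' Walking down the ranked list, the running sum gains
#' `|score|^w / sum_set |score|^w` at each set member and loses
#' `1 / (L - |set|)` at each non-member; the enrichment score is the
#' extremum of largest absolute value. The full running-sum profile is
#' returned for plotting.
#'
#' @param scores named numeric vector sorted in the desired ranking order
#'   (typically decreasing correlation).
#' @param gene_set character vector of member gene IDs.
#' @param weight_exponent the exponent `w` (default 1, the classic
#'   weighted scheme; `w = 0` gives the unweighted KS statistic).
#' @return list with `es`, `running` (length-L profile), `hit_positions`,
#'   `leading_edge` (member genes up to the extremum).
#' @export
gsea_es <- function(scores, gene_set, weight_exponent = 1) {
  L <- length(scores)
  hits <- names(scores) %in% gene_set
  m <- sum(hits)
  assert_that(m > 0, "gene set does not intersect the ranked list")
  assert_that(m < L, "gene set covers the entire ranked list")
  w <- abs(scores)^weight_exponent
  wh <- w * hits
  tot <- sum(wh)
  inc <- if (tot > 0) wh / tot else hits / m
  dec <- (!hits) / (L - m)
  running <- unname(cumsum(inc - dec))
  i_max <- which.max(running); i_min <- which.min(running)
  es <- unname(if (abs(running[i_max]) >= abs(running[i_min])) running[i_max] else running[i_min])
  extremum <- if (es >= 0) i_max else i_min
  leading <- if (es >= 0) names(scores)[seq_len(extremum)][hits[seq_len(extremum)]]
  else names(scores)[extremum:L][hits[extremum:L]]
  list(es = es, running = running, hit_positions = which(hits),
       leading_edge = leading)
}

#' Run GSEA over a gene-set collection with a gene-label permutation null
#'
#' The null distribution reassigns scores to genes uniformly at random
#' (`n_perm` times); each set's null ES shares the permutation stream.
#' `NES = ES / mean(|null ES| of the same sign)`; empirical p-values are
#' `(r + 1) / (n_same + 1)` against the same-sign null; FDR q-values follow
#' the positive/negative NES pooling convention.
#'
#' @param scores named numeric vector sorted decreasing.
#' @param collection named list of gene sets.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed (the only stochastic step of the analysis path).
#' @param weight_exponent passed to the ES computation.
#' @return data.frame with `set`, `size`, `es`, `nes`, `p`, `fdr_q`,
#'   `leading_edge` (comma-separated); deterministic given `seed`.
#' @export
gsea_run <- function(scores, collection, n_perm = 1000, seed = 1,
                     weight_exponent = 1) {
  assert_that(n_perm >= 100, "n_perm must be >= 100")
  L <- length(scores)
  w_all <- abs(scores)^weight_exponent
  gene_pos <- stats::setNames(seq_len(L), names(scores))
  sets <- lapply(collection, function(g) unname(gene_pos[intersect(g, names(scores))]))
  keep <- vapply(sets, function(p) length(p) > 0 && length(p) < L, TRUE)
  sets <- sets[keep]
  assert_that(length(sets) > 0, "no usable gene set (empty or full overlap)")

  obs <- vapply(names(sets), function(nm) {
    hp <- sort(sets[[nm]])
    es_from_hits(hp, w_all[hp], L)
  }, 0)

  set.seed(seed)
  null_es <- matrix(0, n_perm, length(sets))
  sizes <- vapply(sets, length, 1L)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(L)  # position of each gene after relabelling
    for (j in seq_along(sets)) {
      hp <- sort(perm[sets[[j]]])
      null_es[b, j] <- es_from_hits(hp, w_all[hp], L)
    }
  }

  nes <- numeric(length(sets)); pval <- numeric(length(sets))
  null_nes <- null_es
  for (j in seq_along(sets)) {
    nj <- null_es[, j]
    pos_mean <- mean(nj[nj >= 0]); neg_mean <- mean(abs(nj[nj < 0]))
    denom <- if (obs[j] >= 0) pos_mean else neg_mean
    if (!is.finite(denom) || denom == 0) denom <- mean(abs(nj))
    nes[j] <- obs[j] / denom
    same <- if (obs[j] >= 0) nj[nj >= 0] else nj[nj < 0]
    pval[j] <- (sum(abs(same) >= abs(obs[j])) + 1) / (length(same) + 1)
    null_nes[, j] <- ifelse(nj >= 0,
                            nj / ifelse(is.finite(pos_mean) && pos_mean > 0, pos_mean, 1),
                            nj / ifelse(is.finite(neg_mean) && neg_mean > 0, neg_mean, 1))
  }

  ## FDR: compare each observed NES against the pooled null NES of its sign
  all_null <- as.numeric(null_nes)
  fdr <- vapply(seq_along(sets), function(j) {
    if (nes[j] >= 0) {
      num <- sum(all_null >= nes[j]) / max(1, sum(all_null >= 0))
      den <- sum(nes >= nes[j]) / max(1, sum(nes >= 0))
    } else {
      num <- sum(all_null <= nes[j]) / max(1, sum(all_null < 0))
      den <- sum(nes <= nes[j]) / max(1, sum(nes < 0))
    }
    min(1, num / max(den, 1e-12))
  }, 0)

  leading <- vapply(names(sets), function(nm) {
    res <- gsea_es(scores, collection[[nm]], weight_exponent)
    paste(res$leading_edge, collapse = ",")
  }, "")

  out <- data.frame(set = names(sets), size = sizes, es = unname(obs),
                    nes = nes, p = pval, fdr_q = fdr,
                    leading_edge = unname(leading),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$set), , drop = FALSE]
}
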