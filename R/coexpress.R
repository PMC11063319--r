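## Weighted co-expression network stage: MAD variance filter, outlier-sample
## removal by clustering height, scale-free soft-threshold selection,
## topological overlap, static-cut module detection, eigengenes, and
## module-trait / key-gene correlation screens.

#' Keep the most variable genes by median absolute deviation
#'
#' Retains the `ceiling(top_fraction * G)` genes with largest MAD across
#' samples; ties are broken deterministically by gene ID.
#'
#' @param expr genes x samples matrix.
#' @param top_fraction fraction of genes to keep (default 0.25).
#' @return filtered matrix.
#' @export
mad_filter <- function(expr, top_fraction = 0.25) {
  check_matrix(expr)
  assert_that(nrow(expr) >= 4, "need at least 4 genes")
  assert_that(is_number(top_fraction) && top_fraction > 0 && top_fraction <= 1,
              "top_fraction must lie in (0, 1]")
  m <- apply(expr, 1L, stats::mad, na.rm = TRUE)
  keep_n <- ceiling(top_fraction * nrow(expr))
  ord <- order(-m, rownames(expr))
  expr[sort(ord[seq_len(keep_n)]), , drop = FALSE]
}

#' Remove outlier samples by average-linkage clustering height
#'
#' Samples are clustered (average linkage, Euclidean distance on gene-wise
#' standardized profiles); a sample is an outlier when the height at which
#' it first merges exceeds `median + 3 * MAD` of all first-merge heights.
#'
#' @param expr genes x samples matrix.
#' @param max_drop_frac abort when more than this fraction would be dropped.
#' @return list with `retained` and `dropped` sample IDs and the height
#'   table.
#' @export
remove_outlier_samples <- function(expr, max_drop_frac = 0.25) {
  check_matrix(expr)
  n <- ncol(expr)
  assert_that(n >= 4, "need at least 4 samples")
  z <- t(scale(t(expr)))
  z <- z[stats::complete.cases(z), , drop = FALSE]
  if (nrow(z) == 0L) {
    ## every gene constant across samples: no basis for outlier calls
    return(list(retained = colnames(expr), dropped = character(0),
                heights = data.frame(sample = colnames(expr), height = 0,
                                     cutoff = 0, stringsAsFactors = FALSE)))
  }
  hc <- stats::hclust(stats::dist(t(z)), method = "average")
  ## first-merge height per leaf
  h <- rep(NA_real_, n)
  for (i in seq_len(nrow(hc$merge))) {
    for (side in hc$merge[i, ]) {
      if (side < 0 && is.na(h[-side])) h[-side] <- hc$height[i]
    }
  }
  cut <- stats::median(h) + 3 * stats::mad(h)
  drop <- h > cut & cut > 0
  assert_that(mean(drop) <= max_drop_frac,
              "outlier rule would drop %d of %d samples; aborting", sum(drop), n)
  list(retained = colnames(expr)[!drop], dropped = colnames(expr)[drop],
       heights = data.frame(sample = colnames(expr), height = h,
                            cutoff = cut, stringsAsFactors = FALSE))
}

#' Pick the soft-threshold power for an approximately scale-free network
#'
#' For each candidate power the adjacency is `|cor|^power`, connectivity
#' `k_i = sum_{j != i} a_ij`; `log10(k)` is binned, `log10(frequency)` is
#' regressed on `log10(mean k)` per bin, and the signed fit index is
#' `R^2 * sign(-slope)`. The smallest power whose index reaches `r2_target`
#' is chosen (else the argmax).
#'
#' When no candidate power reaches the fit target, the sample-size default
#' for unsigned networks is used instead (9 below 20 samples, 8 below 30,
#' 7 below 40, else 6), since maximizing a poor fit index tends to select
#' extreme powers that disconnect the network.
#'
#' @param expr genes x samples matrix.
#' @param powers candidate integer powers (default 1:20).
#' @param r2_target scale-free fit target (default 0.85).
#' @param n_bins histogram bins for the degree distribution.
#' @return list with `power` (chosen), `fit_table`
#'   (power, fit_index, mean_k), and `reached_target` flag.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_target = 0.85,
                                n_bins = 10) {
  check_matrix(expr)
  assert_that(nrow(expr) >= 50, "need at least 50 genes for a degree distribution")
  cm <- abs(stats::cor(t(expr)))
  diag(cm) <- 0
  assert_that(!anyNA(cm), "correlation undefined (constant gene?)")
  fit <- lapply(powers, function(p) {
    a <- cm^p
    k <- rowSums(a)
    data.frame(power = p, fit_index = scale_free_fit_index(k, n_bins),
               mean_k = mean(k))
  })
  tab <- do.call(rbind, fit)
  rownames(tab) <- NULL
  ## powers whose mean connectivity falls below 1 give an essentially
  ## disconnected network; a high fit index there is a binning artifact
  reach <- which(!is.na(tab$fit_index) & tab$fit_index >= r2_target &
                   tab$mean_k >= 1)
  reached <- length(reach) > 0
  chosen <- if (reached) tab$power[reach[1L]] else default_power(ncol(expr))
  list(power = chosen, fit_table = tab, reached_target = reached)
}

## unsigned-network default soft power by sample size
default_power <- function(n_samples) {
  if (n_samples < 20) 9L else if (n_samples < 30) 8L else if (n_samples < 40) 7L else 6L
}

#' Scale-free topology fit index of a connectivity vector
#'
#' Connectivities are binned into `n_bins` equal-width intervals; the signed
#' index is `R^2 * sign(-slope)` of the regression of `log10(frequency)` on
#' `log10(mean k)` across occupied bins.
#'
#' @param k numeric vector of node connectivities.
#' @param n_bins number of equal-width bins (default 10).
#' @return signed fit index in `[-1, 1]`, or `NA` with too few occupied bins.
#' @export
scale_free_fit_index <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  mk <- tapply(k, bins, mean)
  ok <- !is.na(freq) & freq > 0
  lf <- log10(freq[ok]); lk <- log10(mk[ok])
  if (length(lf) < 3) return(NA_real_)
  fitlm <- stats::lm(lf ~ lk)
  unname(summary(fitlm)$r.squared * sign(-stats::coef(fitlm)[2]))
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with a
#' unit diagonal; rewards gene pairs that share network neighbors.
#'
#' @param adjacency symmetric matrix in `[0, 1]` with zero diagonal.
#' @return symmetric TOM matrix in `[0, 1]` with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  assert_that(is.matrix(adjacency) && nrow(adjacency) == ncol(adjacency),
              "adjacency must be square")
  assert_that(max(abs(adjacency - t(adjacency))) <= 1e-10,
              "adjacency asymmetric beyond 1e-10")
  assert_that(all(adjacency >= 0 & adjacency <= 1),
              "adjacency values must lie in [0, 1]")
  assert_that(all(diag(adjacency) == 0), "adjacency diagonal must be zero")
  shared <- adjacency %*% adjacency
  k <- rowSums(adjacency)
  kmin <- outer(k, k, pmin)
  tom <- (shared + adjacency) / (kmin + 1 - adjacency)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

## conventional module color sequence (largest module first)
module_colors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue",
                   "darkred", "darkgreen", "darkturquoise", "darkgrey",
                   "orange", "darkorange", "white", "skyblue", "saddlebrown",
                   "steelblue", "paleturquoise", "violet", "darkolivegreen",
                   "darkmagenta")

#' Detect co-expression modules from a TOM by static tree cut
#'
#' Average-linkage clustering on `1 - TOM`, cut at a fixed height (default
#' 0.99 of the largest merge height); branches smaller than
#' `min_module_size` are assigned `"grey"`; the rest are labelled with the
#' conventional color sequence in decreasing size order.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param min_module_size smallest branch kept as a module (default 100).
#' @param cut_height absolute cut height; `NULL` uses 0.99 of the max merge.
#' @return named character vector gene -> module color.
#' @export
detect_modules <- function(tom, min_module_size = 100, cut_height = NULL) {
  assert_that(!is.null(rownames(tom)), "TOM must carry gene names")
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  if (is.null(cut_height)) cut_height <- 0.99 * max(hc$height)
  branch <- stats::cutree(hc, h = cut_height)
  sizes <- sort(table(branch), decreasing = TRUE)
  big <- names(sizes)[sizes >= min_module_size]
  colors <- rep("grey", nrow(tom))
  names(colors) <- rownames(tom)
  if (length(big) > length(module_colors))
    big <- big[seq_along(module_colors)]
  for (i in seq_along(big)) {
    colors[branch == as.integer(big[i])] <- module_colors[i]
  }
  if (all(colors == "grey")) warning("no module reached min_module_size; all genes grey")
  colors
}

#' Module eigengenes (first principal component per module)
#'
#' Genes are standardized across samples; the eigengene is the first right
#' singular vector (unit norm over samples), sign-aligned so it correlates
#' positively with the module's average standardized expression. A
#' single-gene module's eigengene is that standardized gene, unit-scaled.
#'
#' @param expr genes x samples matrix.
#' @param colors named gene -> module color vector ("grey" skipped).
#' @return list with `eigengenes` (module x sample matrix) and
#'   `var_explained` (named numeric).
#' @export
module_eigengenes <- function(expr, colors) {
  colors <- colors[rownames(expr)]
  mods <- setdiff(unique(colors), "grey")
  assert_that(length(mods) > 0, "no non-grey module")
  eg <- matrix(NA_real_, length(mods), ncol(expr),
               dimnames = list(mods, colnames(expr)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    x <- expr[names(colors)[colors == m], , drop = FALSE]
    z <- t(scale(t(x)))
    z <- z[stats::complete.cases(z), , drop = FALSE]
    if (nrow(z) == 1L) {
      v <- z[1L, ] / sqrt(sum(z[1L, ]^2))
      eg[m, ] <- v; ve[m] <- 1
      next
    }
    sv <- svd(z, nu = 0, nv = 1)
    v <- sv$v[, 1L]
    if (stats::cor(v, colMeans(z)) < 0) v <- -v
    eg[m, ] <- v
    ve[m] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  list(eigengenes = eg, var_explained = ve)
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation and two-sided p-value per (module, trait); a module
#' is flagged key for a trait when the correlation exceeds `cor_min`
#' (signed by default, absolute with `use_abs = TRUE`) at `p < alpha`.
#' Constant traits are skipped with a warning.
#'
#' @param eigengenes module x sample matrix.
#' @param traits data.frame of numeric traits, rows = samples in eigengene
#'   column order (e.g. group AR=1/HC=0, sex F=1/M=0, symptom score).
#' @param cor_min correlation threshold (default 0.4).
#' @param alpha p-value threshold.
#' @param use_abs flag modules on `|cor|` instead of signed `cor`.
#' @return data.frame with `module`, `trait`, `cor`, `p`, `key`.
#' @export
module_trait_correlation <- function(eigengenes, traits, cor_min = 0.4,
                                     alpha = 0.05, use_abs = FALSE) {
  assert_that(nrow(traits) == ncol(eigengenes),
              "traits rows must match eigengene samples")
  rows <- list()
  for (tr in colnames(traits)) {
    v <- traits[[tr]]
    if (stats::sd(v, na.rm = TRUE) == 0 || all(is.na(v))) {
      warning(sprintf("trait '%s' constant; skipped", tr))
      next
    }
    for (m in rownames(eigengenes)) {
      ct <- stats::cor.test(eigengenes[m, ], v)
      cval <- unname(ct$estimate)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, trait = tr, cor = cval, p = ct$p.value,
        key = (if (use_abs) abs(cval) else cval) > cor_min & ct$p.value < alpha,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(module = character(), trait = character(),
                                      cor = numeric(), p = numeric(), key = logical())
  rownames(out) <- NULL
  out
}

#' Genes in a module significantly correlated with a key gene
#'
#' Pearson correlation of every module gene with the key gene; genes with
#' `cor > cor_min` (signed by default) and `p < alpha` are returned, the key
#' gene itself excluded.
#'
#' @param expr_module genes x samples matrix restricted to one module.
#' @param key_gene gene ID present in `expr_module`.
#' @param cor_min,alpha thresholds as elsewhere (0.4 / 0.05).
#' @param use_abs use `|cor|` instead of signed correlation.
#' @return data.frame with `gene`, `cor`, `p`, sorted by decreasing cor.
#' @export
key_gene_neighbors <- function(expr_module, key_gene, cor_min = 0.4,
                               alpha = 0.05, use_abs = FALSE) {
  check_matrix(expr_module)
  assert_that(key_gene %in% rownames(expr_module),
              "key gene '%s' not found in the module submatrix", key_gene)
  ref <- expr_module[key_gene, ]
  others <- setdiff(rownames(expr_module), key_gene)
  rows <- lapply(others, function(g) {
    ct <- stats::cor.test(ref, expr_module[g, ])
    data.frame(gene = g, cor = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  sel <- if (use_abs) abs(out$cor) > cor_min else out$cor > cor_min
  out <- out[sel & out$p < alpha, , drop = FALSE]
  out <- out[order(-out$cor, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
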