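## Independent brute-force oracles used to validate the package's own
## implementations. These are written from the definitions, not the package
## code paths.

## Spearman rho via the explicit rank formula (Pearson on average ranks).
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## Hypergeometric upper tail P(X >= k) by direct combinatorial enumeration.
oracle_hyper_tail <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## Weighted-KS enrichment score by a literal element-by-element walk.
oracle_gsea_es <- function(scores, gene_set, w = 1) {
  L <- length(scores)
  hits <- names(scores) %in% gene_set
  denom_hit <- sum(abs(scores[hits])^w)
  run <- numeric(L); acc <- 0
  miss_step <- 1 / (L - sum(hits))
  for (i in seq_len(L)) {
    acc <- acc + if (hits[i]) abs(scores[i])^w / denom_hit else -miss_step
    run[i] <- acc
  }
  hi <- max(run); lo <- min(run)
  if (abs(hi) >= abs(lo)) hi else lo
}

## TOM by the direct O(n^3) triple loop.
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l_ij <- sum(a[i, ] * a[, j])
    out[i, j] <- (l_ij + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

## Ordinary pooled-variance two-sample t statistic.
oracle_pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

## First principal component by power iteration on the gene-gene covariance.
oracle_pc1 <- function(z, iters = 2000) {
  cc <- crossprod(z) / (nrow(z))   # samples x samples inner products
  v <- rep(1, ncol(z)); v <- v / sqrt(sum(v^2))
  for (i in seq_len(iters)) {
    v2 <- cc %*% v
    v <- as.numeric(v2) / sqrt(sum(v2^2))
  }
  list(vector = v, value = as.numeric(t(v) %*% cc %*% v),
       total = sum(diag(cc)))
}

## small labelled matrix fixture
named_matrix <- function(vals, nr, nc, rp = "f", cp = "s") {
  matrix(vals, nr, nc, dimnames = list(sprintf("%s%03d", rp, seq_len(nr)),
                                       sprintf("%s%03d", cp, seq_len(nc))))
}

## two-group label helper
two_groups <- function(n1, n2, cols) {
  stats::setNames(rep(c("AR", "HC"), c(n1, n2)), cols)
}
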