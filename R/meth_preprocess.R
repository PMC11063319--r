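## Methylation quality control and normalization: beta computation from
## intensities, missing-rate filtering (probes first, then samples),
## blacklist removal, and a per-sample quantile mapping that places Type-II
## probe beta values on the Type-I empirical distribution.

#' Compute beta values from methylated/unmethylated intensities
#'
#' beta = M / (M + U + offset), elementwise; missing values propagate.
#'
#' @param M methylated intensity matrix (nonnegative).
#' @param U unmethylated intensity matrix, same shape as `M`.
#' @param offset stabilizing constant added to the denominator (default 100).
#' @return beta matrix in `[0, 1]`.
#' @export
compute_beta <- function(M, U, offset = 100) {
  assert_that(identical(dim(M), dim(U)), "M and U must have identical dimensions")
  assert_that(all(M >= 0, na.rm = TRUE) && all(U >= 0, na.rm = TRUE),
              "intensities must be nonnegative")
  assert_that(is_number(offset) && offset >= 0, "offset must be >= 0")
  M / (M + U + offset)
}

#' Filter features and samples by missing rate
#'
#' Rows (probes) with missing fraction strictly above `max_rate` are dropped
#' first; columns (samples) are then re-evaluated on the retained rows and
#' dropped by the same rule. Features/samples at exactly the threshold are
#' kept. The operation is idempotent.
#'
#' @param mat numeric matrix, `NA` marking missing entries.
#' @param max_rate maximum tolerated missing fraction in `[0, 1)`.
#' @return list with `matrix` (filtered), `dropped_probes` and
#'   `dropped_samples` (data frames of IDs with their missing rates).
#' @export
filter_missing <- function(mat, max_rate = 0.10) {
  check_matrix(mat)
  assert_that(is_number(max_rate) && max_rate >= 0 && max_rate < 1,
              "max_rate must lie in [0, 1)")
  row_rate <- rowMeans(is.na(mat))
  keep_r <- row_rate <= max_rate
  assert_that(any(keep_r), "all probes exceed the missing-rate threshold")
  m2 <- mat[keep_r, , drop = FALSE]
  col_rate <- colMeans(is.na(m2))
  keep_c <- col_rate <= max_rate
  assert_that(any(keep_c), "all samples exceed the missing-rate threshold")
  list(matrix = m2[, keep_c, drop = FALSE],
       dropped_probes = data.frame(id = rownames(mat)[!keep_r],
                                   missing_rate = row_rate[!keep_r],
                                   row.names = NULL),
       dropped_samples = data.frame(id = colnames(mat)[!keep_c],
                                    missing_rate = col_rate[!keep_c],
                                    row.names = NULL))
}

#' Remove blacklisted probes from a beta matrix
#'
#' Cross-reactive, non-specific and multi-mapped probes are consumed as an
#' externally curated ID list; unknown IDs are ignored.
#'
#' @param beta probes x samples matrix.
#' @param blacklist character vector of probe IDs to drop.
#' @return list with `matrix` and `n_removed` (= size of the intersection).
#' @export
apply_probe_blacklist <- function(beta, blacklist) {
  check_matrix(beta)
  assert_that(is.character(blacklist) || length(blacklist) == 0,
              "blacklist must be a character vector")
  hit <- rownames(beta) %in% blacklist
  assert_that(!all(hit), "blacklist removes every probe")
  list(matrix = beta[!hit, , drop = FALSE], n_removed = sum(hit))
}

#' Map Type-II probe beta values onto the Type-I distribution per sample
#'
#' A simplified probe-design correction: within each sample, Type-II values
#' are replaced by the Type-I empirical quantile at their own Type-II rank,
#' leaving Type-I values untouched. The mapping is monotone in the Type-II
#' values and keeps the output in `[0, 1]`.
#'
#' @param beta probes x samples matrix.
#' @param design_type named character vector (`"I"`/`"II"`) covering all probes.
#' @return normalized beta matrix, same shape.
#' @export
normalize_probe_types <- function(beta, design_type) {
  check_matrix(beta)
  dt <- design_type[rownames(beta)]
  assert_that(!anyNA(dt) && all(dt %in% c("I", "II")),
              "every probe needs design type 'I' or 'II'")
  type2 <- which(dt == "II")
  if (length(type2) == 0L || length(type2) == nrow(beta)) return(beta)
  out <- beta
  for (s in seq_len(ncol(beta))) {
    x1 <- beta[dt == "I", s]
    x1 <- x1[!is.na(x1)]
    if (length(x1) < 2L) {
      warning(sprintf("sample '%s': fewer than 2 Type-I probes, normalization skipped",
                      colnames(beta)[s]))
      next
    }
    x2 <- beta[type2, s]
    ok <- !is.na(x2)
    if (!any(ok)) next
    pr <- (rank(x2[ok], ties.method = "average") - 0.5) / sum(ok)
    out[type2[ok], s] <- stats::quantile(x1, probs = pr, names = FALSE, type = 7)
  }
  out
}
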