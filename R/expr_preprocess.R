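## Expression preprocessing: background correction against undetected
## probes, per-group detection filtering with group-mean replacement, and
## collapse of probes to unique genes.

#' Background-correct and log-transform an expression matrix
#'
#' Per sample, the background level is the mean intensity of probes whose
#' detection p-value exceeds `p_undetected`; that level is subtracted, the
#' result floored at `floor` intensity units, and log2-transformed. The
#' transform is monotone in the input intensities within each sample.
#'
#' @param expr raw intensity matrix, probes x samples.
#' @param detection_p matching matrix of detection p-values.
#' @param p_undetected detection p above which a probe defines background.
#' @param floor minimum intensity before log2 (default 1).
#' @return log2-scale matrix, same shape.
#' @export
background_correct <- function(expr, detection_p, p_undetected = 0.5, floor = 1) {
  check_matrix(expr)
  assert_that(identical(dim(expr), dim(detection_p)),
              "expr and detection_p must have identical dimensions")
  out <- expr
  no_bg <- character(0)
  for (s in seq_len(ncol(expr))) {
    undet <- detection_p[, s] > p_undetected
    b <- if (any(undet, na.rm = TRUE)) {
      mean(expr[which(undet), s], na.rm = TRUE)
    } else {
      no_bg <- c(no_bg, colnames(expr)[s])
      0
    }
    out[, s] <- log2(pmax(expr[, s] - b, floor))
  }
  if (length(no_bg))
    warning(sprintf("%d sample(s) with no undetected probes, background set to 0: %s",
                    length(no_bg), paste(no_bg, collapse = ", ")))
  out
}

#' Detection-significance filter with group-mean replacement
#'
#' Within each group, a probe is significant when its detection p-value is
#' below `alpha` in at least `min_frac` of that group's samples (inclusive).
#' Entries of non-significant probes are replaced by the probe's mean over
#' that group's samples, so imputed rows are constant within the group.
#' Probes significant in no group can optionally be dropped.
#'
#' @param expr expression matrix (any scale), probes x samples.
#' @param detection_p matching detection p-value matrix.
#' @param groups named character/factor vector mapping sample ID to group;
#'   must cover all columns.
#' @param alpha detection p-value cutoff (default 0.05).
#' @param min_frac minimum detected fraction per group (default 0.5).
#' @param drop_undetected drop probes significant in no group.
#' @return list with `expr` (imputed), `significant` (list of probe ID
#'   vectors per group), `dropped` (probe IDs removed).
#' @export
detection_filter_impute <- function(expr, detection_p, groups, alpha = 0.05,
                                    min_frac = 0.5, drop_undetected = FALSE) {
  check_matrix(expr)
  assert_that(identical(dim(expr), dim(detection_p)),
              "expr and detection_p must have identical dimensions")
  groups <- groups[colnames(expr)]
  assert_that(!anyNA(groups), "groups must cover every sample")
  lev <- unique(as.character(groups))
  sig <- list()
  out <- expr
  for (g in lev) {
    cols <- which(groups == g)
    assert_that(length(cols) > 0L, "group '%s' has no samples", g)
    frac <- rowMeans(detection_p[, cols, drop = FALSE] < alpha)
    s <- frac >= min_frac
    sig[[g]] <- rownames(expr)[s]
    if (any(!s)) {
      grp_mean <- rowMeans(expr[!s, cols, drop = FALSE])
      out[!s, cols] <- matrix(grp_mean, sum(!s), length(cols))
    }
  }
  dropped <- character(0)
  if (drop_undetected) {
    keep <- rownames(expr) %in% unique(unlist(sig))
    dropped <- rownames(expr)[!keep]
    out <- out[keep, , drop = FALSE]
  }
  list(expr = out, significant = sig, dropped = dropped)
}

#' Collapse probes to unique genes by highest mean expression
#'
#' For each gene the single probe with the highest mean expression across
#' samples is retained (ties broken by lexicographically smallest probe ID);
#' probes without a gene annotation are dropped.
#'
#' @param expr probes x samples matrix.
#' @param probe_to_gene named character vector, probe ID -> gene symbol.
#' @return genes x samples matrix with unique gene rownames.
#' @export
collapse_to_genes <- function(expr, probe_to_gene) {
  check_matrix(expr)
  gene <- probe_to_gene[rownames(expr)]
  keep <- !is.na(gene) & nzchar(gene)
  expr <- expr[keep, , drop = FALSE]
  gene <- gene[keep]
  mu <- rowMeans(expr)
  ord <- order(gene, -mu, rownames(expr))
  pick <- ord[!duplicated(gene[ord])]
  out <- expr[pick, , drop = FALSE]
  rownames(out) <- unname(gene[pick])
  out
}
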