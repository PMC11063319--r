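## Plain-text interchange: TSV matrices (first column = feature ID, header
## row = sample IDs), TSV tables, and Broad-dialect GMT gene sets.

#' Write a numeric matrix as TSV
#'
#' First column holds the feature (row) IDs under `id_col`; remaining columns
#' are samples. Round-trips losslessly through [read_matrix_tsv()] at full
#' double precision.
#'
#' @param mat numeric matrix with row and column names.
#' @param path output file path.
#' @param id_col name for the ID column.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature_id") {
  if (nrow(mat) == 0L) {
    writeLines(paste(c(id_col, colnames(mat)), collapse = "\t"), path)
    return(invisible(path))
  }
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(mat))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#' @param path input file path.
#' @return numeric matrix with feature IDs as rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    m <- matrix(numeric(0), nrow = 0, ncol = ncol(df) - 1L,
                dimnames = list(NULL, colnames(df)[-1L]))
    return(m)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

#' Write/read a data frame as TSV
#' @param df data frame.
#' @param path file path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a gene-set collection from a GMT file
#'
#' Broad dialect: one set per line, `name<TAB>description<TAB>gene1<TAB>...`;
#' the description field may be empty. Member lists are deduplicated.
#'
#' @param path GMT file path.
#' @return named list of character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  assert_that(!any(bad), "GMT line(s) with fewer than 3 fields: %s",
              paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' Write a gene-set collection to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector parallel to `sets`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  assert_that(length(sets) == 0L || !is.null(names(sets)),
              "gene sets must be named")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe blacklist (one probe ID per line)
#' @param path text file path; blank lines and `#` comments ignored.
#' @export
read_blacklist <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a flat key:value configuration file (YAML subset)
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
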