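#' @keywords internal
"_PACKAGE"

## Validation errors carry a condition class so the orchestrator can map
## them to a stage and exit cleanly.
stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("mdg_validation_error", "error")))
}

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop_validation(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

is_number <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x)

#' Derive a named random stream seed from a master seed
#'
#' One master seed is expanded into independent per-component seeds so that
#' the draws of one simulation component do not shift when another component
#' grows. The mapping is a small deterministic hash of the component name
#' folded into the master seed, kept below 2^31.
#'
#' @param seed master integer seed.
#' @param component character scalar naming the stream.
#' @return an integer seed usable with [set.seed()].
#' @export
stream_seed <- function(seed, component) {
  assert_that(is_count(abs(seed)), "seed must be an integer")
  assert_that(is.character(component) && length(component) == 1L,
              "component must be a single string")
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)) * 131)
  as.integer((abs(seed) %% 1000003L * 1009L + h) %% 2147483629)
}

## matrix sanity helper used by several stages
check_matrix <- function(x, name = "matrix") {
  assert_that(is.matrix(x), "%s must be a matrix", name)
  assert_that(!is.null(rownames(x)) && !is.null(colnames(x)),
              "%s must carry row and column names", name)
  invisible(TRUE)
}
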