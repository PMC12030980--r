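# Internal helpers: condition classes, seeded evaluation, numeric utilities.

abort_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("roiboost_invalid_input", "roiboost_error")))
}

abort_config <- function(msg) {
  stop(errorCondition(msg, class = c("roiboost_config_error", "roiboost_error")))
}

abort_empty_region <- function(msg) {
  stop(errorCondition(msg, class = c("roiboost_empty_region", "roiboost_error")))
}

warn_metric <- function(msg) {
  warning(warningCondition(msg, class = "roiboost_metric_warning"))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded operations are pure functions
#' of their inputs and never perturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-item child seed from a base seed; stays within 32-bit range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483587)
}

# round() uses banker's rounding; per-class split counts use round-half-up.
round_half_up <- function(x) floor(x + 0.5)

# Row-wise softmax with max subtraction for numerical stability.
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

relu <- function(x) pmax(x, 0)

clip01 <- function(x) pmin(pmax(x, 0), 1)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

stopifnot_count <- function(x, name, min = 1L) {
  if (!is_count(x) || x < min) {
    abort_invalid(sprintf("`%s` must be an integer >= %d, got %s",
                          name, min, deparse(substitute(x))))
  }
}
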