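# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# All stochastic entry points funnel through here so that a user-supplied seed
# fully determines the result without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

abort_config <- function(msg) abort(msg, class = "rapidprog_config_error")
abort_input  <- function(msg) abort(msg, class = "rapidprog_input_error")
abort_state  <- function(msg) abort(msg, class = "rapidprog_state_error")

assert_fraction <- function(x, name, allow_one = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 &&
    (x < 1 || (allow_one && x <= 1))
  if (!ok) {
    abort_config(sprintf("`%s` must be a fraction in [0,%s), got %s",
                         name, if (allow_one) "1]" else "1", format(x)))
  }
  invisible(x)
}

assert_count <- function(x, name, positive = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x) &&
    x >= if (positive) 1 else 0
  if (!ok) abort_config(sprintf("`%s` must be a non-negative integer", name))
  invisible(as.integer(x))
}

# Coerce a features tibble / data.frame / matrix to a plain numeric matrix,
# dropping a patient_id column when present.
as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  x <- as.data.frame(x)
  if ("patient_id" %in% names(x)) {
    rn <- as.character(x$patient_id)
    x <- x[setdiff(names(x), "patient_id")]
    m <- as.matrix(x)
    rownames(m) <- rn
  } else {
    m <- as.matrix(x)
  }
  if (!is.numeric(m)) abort_input("feature values must be numeric")
  storage.mode(m) <- "double"
  m
}
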