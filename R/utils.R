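# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ezloc <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "ezloc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

warn_ezloc <- function(msg, class) {
  warning(structure(
    class = c(class, "ezloc_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @noRd
assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ezloc(sprintf("'%s' must be a finite numeric scalar", name),
               "ezloc_parameter_error")
  if (positive && x <= 0)
    stop_ezloc(sprintf("'%s' must be > 0 (got %g)", name, x),
               "ezloc_parameter_error")
  invisible(x)
}

# Deterministic RNG scoping: run `expr` under a local seed without
# disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Row-wise euclidean norms of an n x 3 matrix.
row_norms <- function(x) sqrt(rowSums(x * x))

normalize_rows <- function(x) {
  n <- row_norms(x)
  n[n == 0] <- 1
  x / n
}
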