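## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message (no call in output)
#' @noRd
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Check a scalar condition, abort with message otherwise
#' @noRd
stopifnot_msg <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) abort(fmt, ...)
  invisible(TRUE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a child seed from a base seed and a stream index.
#' Keeps results < 2^31 so they remain valid R integers.
#' @noRd
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * stream) %% 2147483629)
}

#' Run an expression with a local RNG state (does not disturb the caller's)
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
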