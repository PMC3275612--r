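# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == round(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

#' Evaluate code under a fixed random seed
#'
#' Runs `code` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so seeded simulations never disturb the global random
#' stream. A `NULL` seed runs the code against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is_scalar_number(seed))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Linear interpolation that extends flat beyond the data range; duplicate
# x values (paired boundary points at a jump) collapse to their mean.
interp_profile <- function(x, y, xout) {
  approx(x, y, xout = xout, method = "linear", rule = 2, ties = mean)$y
}
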