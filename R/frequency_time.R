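# Cumulative cell frequency vs. cell-cycle time under exponential growth.
#
# In an exponentially expanding population the density of cells over
# cell-cycle age a (normalized to [0,1)) is 2*ln(2)*2^(-a): newborns are
# twice as frequent as dividing cells. The cumulative frequency up to age t
# is F(t) = 2*(1 - 2^(-t)), and inverting F maps a cumulative-frequency
# coordinate back to normalized cell-cycle time.

#' Exponential-growth age distribution
#'
#' `age_density` is the probability density of normalized cell-cycle age,
#' `age_cdf` its cumulative distribution, and `age_quantile` the inverse CDF.
#'
#' @param u normalized age(s) in `[0, 1]`.
#' @param p cumulative probabilities in `[0, 1]`.
#' @return numeric vector.
#' @export
age_density <- function(u) 2 * log(2) * 2^(-u)

#' @rdname age_density
#' @export
age_cdf <- function(u) 2 * (1 - 2^(-u))

#' @rdname age_density
#' @export
age_quantile <- function(p) -log2(1 - p / 2)

#' Map cumulative cell frequency to normalized cell-cycle time
#'
#' Cumulative frequency is directly proportional to residence time only
#' after correcting for the age distribution that binary division imposes on
#' an exponentially growing population. `mode = "identity"` returns the
#' frequency unchanged (the convention used for plotted profiles);
#' `mode = "age_corrected"` returns `t = -log2(1 - x/2)`, the inverse of
#' `F(t) = 2*(1 - 2^(-t))`. Both endpoints map to themselves.
#'
#' @param x cumulative frequency values in `[0, 1]`.
#' @param mode `"identity"` or `"age_corrected"`.
#' @return normalized time values in `[0, 1]`.
#' @examples
#' frequency_to_time(c(0, 0.5, 1), "age_corrected")
#' @export
frequency_to_time <- function(x, mode = c("identity", "age_corrected")) {
  mode <- match.arg(mode)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("x must lie in [0, 1]")
  }
  if (mode == "identity") x else age_quantile(x)
}
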