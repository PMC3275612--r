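# Piecewise functional fits of cyclin accumulation on the frequency axis:
# a second-order polynomial y = c + b*x + a*x^2 and/or exponential
# y = c*e^(k*x) segments over user-stated breakpoint domains.

#' Fit piecewise functional forms to a profile channel
#'
#' Least-squares fit of each requested form on the profile points falling
#' in its domain (synthetic boundary points are excluded). Polynomials are
#' fitted linearly; exponentials by nonlinear least squares initialized
#' from a log-linear fit.
#'
#' @param profile an [expression_profile].
#' @param channel channel to fit.
#' @param segments list of `list(form =, domain = c(x0, x1))` entries with
#'   `form` either `"poly2"` or `"exponential"` and `0 <= x0 < x1 <= 1`.
#' @return list of `fit_segment` objects: `form`, `domain`,
#'   `coefficients` (`c, b, a` for poly2; `c, k` for exponential),
#'   `r_squared`, `n_points`, and `predict` (the fitted function).
#' @export
fit_piecewise <- function(profile, channel, segments) {
  stopifnot(inherits(profile, "expression_profile"))
  pts <- profile_real_points(profile)
  x_all <- pts$x; y_all <- pts[[channel]]
  lapply(segments, function(seg) {
    form <- match.arg(seg$form, c("poly2", "exponential"))
    dom <- seg$domain
    stopifnot(length(dom) == 2, dom[1] < dom[2])
    sel <- x_all >= dom[1] & x_all <= dom[2]
    if (sum(sel) < 3) {
      stop(sprintf("fewer than 3 profile points in domain [%.3g, %.3g]",
                   dom[1], dom[2]))
    }
    x <- x_all[sel]; y <- y_all[sel]
    if (form == "poly2") {
      fit <- lm(y ~ x + I(x^2))
      cf <- setNames(unname(coef(fit)), c("c", "b", "a"))
      pred <- function(x0) cf["c"] + cf["b"] * x0 + cf["a"] * x0^2
      resid <- y - pred(x)
    } else {
      if (all(y > 0)) {
        lf <- lm(log(y) ~ x)
        start <- list(c = exp(unname(coef(lf)[1])), k = unname(coef(lf)[2]))
      } else {
        start <- list(c = max(abs(y)), k = 1)
      }
      fit <- minpack.lm::nlsLM(y ~ c * exp(k * x), start = start,
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      cf <- setNames(unname(coef(fit)), c("c", "k"))
      pred <- function(x0) cf["c"] * exp(cf["k"] * x0)
      resid <- y - pred(x)
    }
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum(resid^2) / sst else 1
    structure(list(form = form, domain = dom, coefficients = cf,
                   r_squared = max(min(r2, 1), 0), n_points = length(x),
                   predict = pred),
              class = "fit_segment")
  })
}

#' @export
print.fit_segment <- function(x, ...) {
  cat(sprintf("fit_segment %s on [%.3g, %.3g]: %s; R^2 = %.4f (n = %d)\n",
              x$form, x$domain[1], x$domain[2],
              paste(sprintf("%s = %.5g", names(x$coefficients), x$coefficients),
                    collapse = ", "),
              x$r_squared, x$n_points))
  invisible(x)
}

# Average relative growth rate of a fitted segment over its domain:
# (log y(x1) - log y(x0)) / (x1 - x0), guarded against non-positive fitted
# values. For an exponential segment this equals the fitted k.
segment_rate <- function(fit) {
  y0 <- fit$predict(fit$domain[1])
  y1 <- fit$predict(fit$domain[2])
  eps <- 1e-3 * max(abs(y0), abs(y1), 1)
  (log(max(y1, eps)) - log(max(y0, eps))) / (fit$domain[2] - fit$domain[1])
}

# First x (over the fitted domains) where the piecewise fit exceeds
# `fraction` of its maximum.
fit_onset <- function(fits, fraction) {
  grid <- sort(unique(unlist(lapply(fits, function(f) {
    seq(f$domain[1], f$domain[2], length.out = 200)
  }))))
  y <- rep(NA_real_, length(grid))
  for (f in fits) {
    in_dom <- grid >= f$domain[1] & grid <= f$domain[2]
    y[in_dom] <- f$predict(grid[in_dom])
  }
  thr <- fraction * max(y, na.rm = TRUE)
  grid[which(y >= thr)[1]]
}

#' Compare accumulation rates of two cyclins
#'
#' From piecewise fits of two cyclin profiles (ordered early then late
#' segment), reports each cyclin's late/early average-relative-rate ratio,
#' which cyclin's ratio is larger (the "more exponential character"), and
#' the onset order: the first x at which each fitted curve exceeds a stated
#' fraction of its own maximum.
#'
#' @param fits_a,fits_b lists of `fit_segment`s from [fit_piecewise()],
#'   fitted on the same axis mode.
#' @param labels names for the two cyclins in the report.
#' @param onset_fraction onset threshold as a fraction of each fit's
#'   maximum.
#' @return a list of class `rate_comparison`: per-cyclin `early_rate`,
#'   `late_rate`, `ratio`; `larger_ratio`; `equal_ratios`; `onset` (named
#'   x positions) and `onset_order`.
#' @export
compare_rates <- function(fits_a, fits_b,
                          labels = c("cyclin_a2", "cyclin_b1"),
                          onset_fraction = 0.10) {
  stopifnot(length(fits_a) >= 2, length(fits_b) >= 2)
  summarize <- function(fits) {
    early <- segment_rate(fits[[1]])
    late <- segment_rate(fits[[length(fits)]])
    list(early_rate = early, late_rate = late, ratio = late / early)
  }
  sa <- summarize(fits_a)
  sb <- summarize(fits_b)
  equal <- isTRUE(all.equal(sa$ratio, sb$ratio, tolerance = 1e-9))
  onset <- setNames(c(fit_onset(fits_a, onset_fraction),
                      fit_onset(fits_b, onset_fraction)), labels)
  out <- setNames(list(sa, sb), labels)
  out$larger_ratio <- if (equal) NA_character_ else
    labels[which.max(c(sa$ratio, sb$ratio))]
  out$equal_ratios <- equal
  out$onset <- onset
  out$onset_order <- labels[order(onset)]
  class(out) <- "rate_comparison"
  out
}

#' @export
print.rate_comparison <- function(x, ...) {
  labs <- setdiff(names(x), c("larger_ratio", "equal_ratios", "onset", "onset_order"))
  for (l in labs) {
    cat(sprintf("%s: early rate %.3f, late rate %.3f, late/early = %.3f\n",
                l, x[[l]]$early_rate, x[[l]]$late_rate, x[[l]]$ratio))
  }
  if (x$equal_ratios) cat("late/early ratios are equal\n") else
    cat("larger late/early ratio:", x$larger_ratio, "\n")
  cat("onset order:", paste(x$onset_order, collapse = " before "),
      sprintf("(x = %s)", paste(sprintf("%.3f", x$onset), collapse = ", ")), "\n")
  invisible(x)
}
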