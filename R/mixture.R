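# One-dimensional multi-Gaussian models of DNA-content histograms.
#
# A DNA histogram of an asynchronous 2C stemline is modeled as a sum of
# normal components: one bounding component for G1 (2C), one for G2+M (4C),
# and a grid of S-phase components spanning the 2C-4C interval. Component
# areas are cell-frequency fractions and sum to 1.

#' Gaussian mixture component
#'
#' @param mean component mean (linear fluorescence units).
#' @param sd component standard deviation; must be positive.
#' @param area unitless cell fraction in (0, 1].
#' @param label phase tag: one of `"G1"`, `"S"`, `"G2M"`.
#' @return an object of class `gaussian_component`.
#' @export
gaussian_component <- function(mean, sd, area, label = "S") {
  stopifnot(is_scalar_number(mean), is_scalar_number(sd), is_scalar_number(area))
  if (sd <= 0) stop("component sd must be > 0")
  if (area <= 0 || area > 1) stop("component area must be in (0, 1]")
  label <- match.arg(label, c("G1", "S", "G2M"))
  structure(list(mean = mean, sd = sd, area = area, label = label),
            class = "gaussian_component")
}

#' One-dimensional Gaussian mixture for a DNA histogram
#'
#' @param components list of [gaussian_component()] objects, ordered by mean.
#' @return an object of class `gaussian_mixture`, a list with numeric vectors
#'   `mean`, `sd`, `area` and character `label`.
#' @export
gaussian_mixture <- function(components) {
  stopifnot(length(components) >= 1)
  m <- vapply(components, `[[`, numeric(1), "mean")
  s <- vapply(components, `[[`, numeric(1), "sd")
  a <- vapply(components, `[[`, numeric(1), "area")
  lab <- vapply(components, `[[`, character(1), "label")
  ord <- order(m)
  mix <- structure(list(mean = m[ord], sd = s[ord], area = a[ord],
                        label = lab[ord]),
                   class = "gaussian_mixture")
  validate_mixture(mix)
  mix
}

validate_mixture <- function(mix) {
  if (abs(sum(mix$area) - 1) > 1e-9) {
    stop("component areas must sum to 1 (got ", format(sum(mix$area)), ")")
  }
  if (any(mix$sd <= 0)) stop("component sds must be positive")
  if (is.unsorted(mix$mean, strictly = FALSE)) stop("components must be ordered by mean")
  g1 <- which(mix$label == "G1"); g2m <- which(mix$label == "G2M")
  if (length(g1) == 1 && length(g2m) == 1) {
    smeans <- mix$mean[mix$label == "S"]
    if (length(smeans) &&
        (any(smeans <= mix$mean[g1]) || any(smeans >= mix$mean[g2m]))) {
      stop("S component means must lie strictly between the G1 and G2M means")
    }
  }
  invisible(mix)
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat("gaussian_mixture with", length(x$mean), "components\n")
  print(data.frame(label = x$label, mean = x$mean, sd = x$sd, area = x$area),
        row.names = FALSE)
  invisible(x)
}

#' Build the synthetic DNA-content mixture
#'
#' Constructs the standard multi-Gaussian model of a DNA histogram: single
#' bounding components for G1 (at `g1_mean`) and G2+M (at `2 * g1_mean`,
#' the 4C = 2 x 2C constraint), and `n_s_components` S-phase components with
#' means evenly spaced strictly between the bounding means, equal areas
#' summing to `s_fraction`, and standard deviations interpolated linearly
#' between the bounding sds. With fractions 60/30/10 and six S components
#' this reproduces the classic eight-component proof-of-principle histogram.
#'
#' @param g1_fraction,s_fraction,g2m_fraction cell fractions; must sum to 1,
#'   all strictly positive.
#' @param g1_mean G1 (2C) mean in linear fluorescence units.
#' @param cv coefficient of variation of the bounding components
#'   (sd = cv * mean), in (0, 0.2].
#' @param n_s_components number of S-phase components (>= 1).
#' @return a [gaussian_mixture()].
#' @examples
#' mix <- make_dna_mixture(0.60, 0.30, 0.10)
#' length(mix$mean)  # 8
#' @export
make_dna_mixture <- function(g1_fraction, s_fraction, g2m_fraction,
                             g1_mean = 100, cv = 0.03, n_s_components = 6) {
  fr <- c(g1_fraction, s_fraction, g2m_fraction)
  stopifnot(all(vapply(fr, is_scalar_number, logical(1))))
  if (abs(sum(fr) - 1) > 1e-9) stop("phase fractions must sum to 1")
  if (any(fr <= 0)) stop("all phase fractions must be strictly positive")
  if (!is_count(n_s_components)) stop("n_s_components must be a positive integer")
  if (!is_scalar_number(cv) || cv <= 0 || cv > 0.2) stop("cv must be in (0, 0.2]")
  if (!is_scalar_number(g1_mean) || g1_mean <= 0) stop("g1_mean must be positive")

  g2m_mean <- 2 * g1_mean
  sd_lo <- cv * g1_mean
  sd_hi <- cv * g2m_mean
  k <- seq_len(n_s_components)
  s_means <- g1_mean + k / (n_s_components + 1) * g1_mean
  s_sds <- sd_lo + (s_means - g1_mean) / (g2m_mean - g1_mean) * (sd_hi - sd_lo)

  comps <- c(
    list(gaussian_component(g1_mean, sd_lo, g1_fraction, "G1")),
    lapply(k, function(i) {
      gaussian_component(s_means[i], s_sds[i], s_fraction / n_s_components, "S")
    }),
    list(gaussian_component(g2m_mean, sd_hi, g2m_fraction, "G2M"))
  )
  gaussian_mixture(comps)
}

#' Mixture density and CDF
#'
#' @param x numeric vector of DNA values.
#' @param mixture a [gaussian_mixture()].
#' @return numeric vector of densities (`dmixture`) or cumulative
#'   probabilities (`pmixture`).
#' @export
dmixture <- function(x, mixture) {
  rowSums(vapply(seq_along(mixture$mean), function(k) {
    mixture$area[k] * dnorm(x, mixture$mean[k], mixture$sd[k])
  }, numeric(length(x))))
}

#' @rdname dmixture
#' @export
pmixture <- function(x, mixture) {
  rowSums(vapply(seq_along(mixture$mean), function(k) {
    mixture$area[k] * stats::pnorm(x, mixture$mean[k], mixture$sd[k])
  }, numeric(length(x))))
}

#' Sample a DNA histogram from a mixture
#'
#' Draws `n` events (component chosen with probability equal to its area,
#' value from that component's normal), bins them, and retains both the raw
#' values and the generating component index of each event so that recovery
#' tests can use the component-choice indicator as a truth label.
#'
#' @param mixture a [gaussian_mixture()].
#' @param n number of events; values below 1000 void the recovery guarantees
#'   and raise a warning.
#' @param seed integer seed; the sample is reproducible under a fixed seed.
#' @param bins number of histogram bins.
#' @return a list of class `dna_histogram`: `values`, `component` (index into
#'   the mixture), `breaks`, `counts`, `mids`, and the generating `mixture`.
#' @export
sample_histogram <- function(mixture, n, seed = NULL, bins = 256) {
  validate_mixture(mixture)
  if (!is_count(n)) stop("n must be a positive integer")
  if (n < 1000) warning("n < 1000: recovery guarantees are void at this size")
  if (!is_count(bins)) stop("bins must be a positive integer")
  with_seed(seed, {
    comp <- sample.int(length(mixture$mean), n, replace = TRUE,
                       prob = mixture$area)
    values <- rnorm(n, mixture$mean[comp], mixture$sd[comp])
    breaks <- seq(min(values), max(values), length.out = bins + 1)
    counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                       nbins = bins)
    structure(list(values = values, component = comp, breaks = breaks,
                   counts = counts, mids = (head(breaks, -1) + tail(breaks, -1)) / 2,
                   mixture = mixture),
              class = "dna_histogram")
  })
}

# Equal-density crossing point between two neighboring components, found by
# root-finding on the log-density difference over (mean1, mean2).
component_crossing <- function(m1, s1, a1, m2, s2, a2) {
  f <- function(b) {
    (log(a1) + dnorm(b, m1, s1, log = TRUE)) -
      (log(a2) + dnorm(b, m2, s2, log = TRUE))
  }
  lo <- m1 + 1e-9 * (m2 - m1)
  hi <- m2 - 1e-9 * (m2 - m1)
  if (f(lo) <= 0) return(lo)
  if (f(hi) >= 0) return(hi)
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Region boundaries for segmenting a mixture-generated DNA histogram
#'
#' Returns the ordered thresholds that split a DNA histogram into one G1
#' region, `n interior` S-spanning regions, and one G2+M region, with the
#' terminal regions sized to enclose the measurement variation of the
#' bounding Gaussian clusters. Two placement rules are offered for the
#' terminal boundaries: `"crossing"` puts them at the equal-density point
#' between the bounding component and its nearest S component (the
#' misclassification-balancing choice), `"sd"` puts them at
#' bounding mean +/- `k` sd. Interior boundaries are evenly spaced.
#'
#' @param mixture a [gaussian_mixture()] with G1 and G2M bounding components.
#' @param n_regions total region count (>= 3); the default 9 gives the
#'   single-G1 + seven S-spanning + single-G2M layout.
#' @param rule terminal boundary rule, `"crossing"` or `"sd"`.
#' @param k sd multiplier for `rule = "sd"`.
#' @return numeric vector of `n_regions - 1` strictly increasing boundaries.
#' @export
mixture_boundaries <- function(mixture, n_regions = 9,
                               rule = c("crossing", "sd"), k = 3) {
  validate_mixture(mixture)
  rule <- match.arg(rule)
  if (!is_count(n_regions) || n_regions < 3) stop("n_regions must be >= 3")
  i_g1 <- which(mixture$label == "G1")
  i_g2m <- which(mixture$label == "G2M")
  if (length(i_g1) != 1 || length(i_g2m) != 1) {
    stop("mixture must contain exactly one G1 and one G2M component")
  }
  i_s <- which(mixture$label == "S")
  if (rule == "sd") {
    b_lo <- mixture$mean[i_g1] + k * mixture$sd[i_g1]
    b_hi <- mixture$mean[i_g2m] - k * mixture$sd[i_g2m]
  } else {
    s_first <- i_s[which.min(mixture$mean[i_s])]
    s_last <- i_s[which.max(mixture$mean[i_s])]
    b_lo <- component_crossing(mixture$mean[i_g1], mixture$sd[i_g1], mixture$area[i_g1],
                               mixture$mean[s_first], mixture$sd[s_first], mixture$area[s_first])
    b_hi <- component_crossing(mixture$mean[s_last], mixture$sd[s_last], mixture$area[s_last],
                               mixture$mean[i_g2m], mixture$sd[i_g2m], mixture$area[i_g2m])
  }
  if (b_hi <= b_lo) stop("terminal boundaries collapsed; mixture too narrow")
  seq(b_lo, b_hi, length.out = n_regions - 1)
}
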