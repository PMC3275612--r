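# 1-D segmentation of DNA histograms by contiguous regions.

#' Segment a DNA histogram by contiguous regions
#'
#' Splits the value range at the supplied strictly increasing boundaries
#' into contiguous intervals (the first and last open-ended, so they can be
#' sized to enclose the full measurement variation of the bounding G1 and
#' G2+M clusters) and reports the event count and median per interval, as
#' an [expression_profile] on the cumulative-frequency axis. Empty
#' intervals are flagged, excluded from the profile, and carry no frequency
#' mass.
#'
#' @param values numeric DNA values.
#' @param boundaries strictly increasing interval thresholds (e.g. from
#'   [mixture_boundaries()]).
#' @param channel channel name used for the profile column.
#' @return an [expression_profile]; the full interval table (including
#'   empty intervals) is attached as attribute `"segments"`.
#' @export
segment_histogram_1d <- function(values, boundaries, channel = "dna") {
  stopifnot(is.numeric(values), length(values) >= 1, is.numeric(boundaries))
  if (length(boundaries) < 1 || is.unsorted(boundaries, strictly = TRUE)) {
    stop("boundaries must be strictly increasing")
  }
  k <- findInterval(values, boundaries) + 1L
  nreg <- length(boundaries) + 1L
  counts <- tabulate(k, nbins = nreg)
  lower <- c(-Inf, boundaries)
  upper <- c(boundaries, Inf)
  med <- rep(NA_real_, nreg)
  se <- rep(NA_real_, nreg)
  for (i in which(counts > 0)) {
    vi <- values[k == i]
    med[i] <- median(vi)
    se[i] <- if (length(vi) > 1) 1.2533 * sd(vi) / sqrt(length(vi)) else NA_real_
  }
  seg <- data.frame(region = seq_len(nreg), lower = lower, upper = upper,
                    count = counts, fraction = counts / length(values),
                    center = med)
  if (any(counts == 0)) {
    warning("empty interval(s): ", paste(which(counts == 0), collapse = ", "),
            " (center undefined; excluded from the profile)")
  }
  keep <- counts > 0
  f <- counts[keep] / sum(counts[keep])
  pts <- data.frame(x = cumsum(f) - f / 2, count = counts[keep],
                    synthetic = FALSE)
  pts[[channel]] <- med[keep]
  pts[[paste0(channel, "_se")]] <- se[keep]
  prof <- new_expression_profile(pts, channels = channel)
  attr(prof, "segments") <- seg
  prof
}

#' Direct DNA-segmentation boundaries for a synthetic population
#'
#' The standard nine-region layout for a 2C/4C DNA histogram: terminal
#' boundaries at `2C * (1 + k * cv)` and `4C * (1 - k * cv)` (enclosing the
#' bounding clusters' measurement variation), interior boundaries evenly
#' spaced.
#'
#' @param model a [phase_model()] supplying the DNA levels and CV.
#' @param n_regions region count (default 9).
#' @param k sd multiplier for the terminal boundaries.
#' @return numeric vector of `n_regions - 1` boundaries.
#' @export
dna_boundaries <- function(model, n_regions = 9, k = 3) {
  stopifnot(inherits(model, "phase_model"))
  cv <- model$noise_cv[["dna"]]
  lo <- model$dna_levels[1] * (1 + k * cv)
  hi <- model$dna_levels[2] * (1 - k * cv)
  seq(lo, hi, length.out = n_regions - 1)
}
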