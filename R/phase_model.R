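# Ground-truth generator model: phase fractions, programmed per-marker
# expression curves over normalized cell-cycle position u in [0,1), and a
# multiplicative log-normal measurement-noise model.
#
# u = 0 is defined at mitotic exit / birth; one cell-cycle time Tc maps to
# the whole interval, with no inheritance across the division (a single
# generation snapshot).

default_curve_params <- function() {
  list(
    dna_width_mean = 50,
    ssc_base = 150,
    a2 = list(quad_level = 15, quad_frac = 0.8, peak = 100, dip = 70,
              floor = 0, decay_eps = 0.5),
    b1 = list(base = 5, onset_u = 0.25, mid = 20, peak = 100, dip = 75,
              floor = 2),
    phh3 = list(base = 2, peak = 100, ramp_start_g2_frac = 0.08,
                ramp_end_m_frac = 0.25),
    # landmark positions inside mitosis, as fractions of the M interval
    m_dip_end = 0.32, m_a2_plateau_end = 0.5, m_a2_floor = 0.68,
    m_b1_floor = 0.82, m_phh3_floor = 0.96
  )
}

# Build the default programmed marker curves. Each curve is a vectorized
# function of u in [0,1) carrying a "floor_u" attribute (the position where
# a degrading marker reaches its floor; NA for monotone channels). The
# shapes encode: constant G1, two-phase rise of the cyclins through S/G2
# (polynomial then exponential for A2, two exponentials for B1), a brief
# early-mitotic dip then a prophase plateau, and the ordered degradations
# A2 -> B1 -> PHH3 dephosphorylation at the end of mitosis.
build_marker_curves <- function(phase_fractions, dna_levels,
                                params = default_curve_params()) {
  g1 <- phase_fractions[["G1"]]; s <- phase_fractions[["S"]]
  g2 <- phase_fractions[["G2"]]; m <- phase_fractions[["M"]]
  t1 <- g1; t2 <- g1 + s; t3 <- g1 + s + g2
  c2 <- dna_levels[1]; c4 <- dna_levels[2]
  p <- params

  dna <- function(u) {
    ifelse(u < t1, c2, ifelse(u < t2, c2 + (c4 - c2) * (u - t1) / (t2 - t1), c4))
  }
  attr(dna, "floor_u") <- NA_real_

  ssc <- function(u) p$ssc_base * 2^u
  attr(ssc, "floor_u") <- NA_real_

  dna_width <- function(u) rep(p$dna_width_mean, length(u))
  attr(dna_width, "floor_u") <- NA_real_

  # cyclin A2
  qe <- t1 + p$a2$quad_frac * s           # end of the polynomial phase
  peak_u <- t3 + p$phh3$ramp_end_m_frac * m
  dip_end <- t3 + p$m_dip_end * m
  plat_end <- t3 + p$m_a2_plateau_end * m
  a2_floor_u <- t3 + p$m_a2_floor * m
  kA <- log(p$a2$peak / p$a2$quad_level) / (peak_u - qe)
  kAd <- log(p$a2$dip / p$a2$decay_eps) / (a2_floor_u - plat_end)
  a2 <- function(u) {
    y <- rep(p$a2$floor, length(u))
    i <- u < t1; y[i] <- 0
    i <- u >= t1 & u < qe
    y[i] <- p$a2$quad_level * ((u[i] - t1) / (qe - t1))^2
    i <- u >= qe & u < peak_u
    y[i] <- p$a2$quad_level * exp(kA * (u[i] - qe))
    i <- u >= peak_u & u < dip_end
    y[i] <- p$a2$peak + (p$a2$dip - p$a2$peak) * (u[i] - peak_u) / (dip_end - peak_u)
    i <- u >= dip_end & u < plat_end; y[i] <- p$a2$dip
    i <- u >= plat_end & u < a2_floor_u
    y[i] <- p$a2$dip * exp(-kAd * (u[i] - plat_end))
    y
  }
  attr(a2, "floor_u") <- a2_floor_u

  # cyclin B1
  b1_plat_end <- t3 + p$m_a2_floor * m    # B1 holds its plateau until A2 is gone
  b1_floor_u <- t3 + p$m_b1_floor * m
  kB1 <- log(p$b1$mid / p$b1$base) / (t2 - p$b1$onset_u)
  kB2 <- log(p$b1$peak / p$b1$mid) / (peak_u - t2)
  kBd <- log(p$b1$dip / p$b1$floor) / (b1_floor_u - b1_plat_end)
  b1 <- function(u) {
    y <- rep(p$b1$floor, length(u))
    i <- u < p$b1$onset_u; y[i] <- p$b1$base
    i <- u >= p$b1$onset_u & u < t2
    y[i] <- p$b1$base * exp(kB1 * (u[i] - p$b1$onset_u))
    i <- u >= t2 & u < peak_u
    y[i] <- p$b1$mid * exp(kB2 * (u[i] - t2))
    i <- u >= peak_u & u < dip_end
    y[i] <- p$b1$peak + (p$b1$dip - p$b1$peak) * (u[i] - peak_u) / (dip_end - peak_u)
    i <- u >= dip_end & u < b1_plat_end; y[i] <- p$b1$dip
    i <- u >= b1_plat_end & u < b1_floor_u
    y[i] <- p$b1$dip * exp(-kBd * (u[i] - b1_plat_end))
    y
  }
  attr(b1, "floor_u") <- b1_floor_u

  # PHH3: ramp starts in late G2, saturates early in M, decays last
  ramp0 <- t3 - p$phh3$ramp_start_g2_frac * g2
  ramp1 <- peak_u
  fall0 <- b1_floor_u
  phh3_floor_u <- t3 + p$m_phh3_floor * m
  kPd <- log(p$phh3$peak / p$phh3$base) / (phh3_floor_u - fall0)
  phh3 <- function(u) {
    y <- rep(p$phh3$base, length(u))
    i <- u >= ramp0 & u < ramp1
    y[i] <- p$phh3$base + (p$phh3$peak - p$phh3$base) * (u[i] - ramp0) / (ramp1 - ramp0)
    i <- u >= ramp1 & u < fall0; y[i] <- p$phh3$peak
    i <- u >= fall0 & u < phh3_floor_u
    y[i] <- p$phh3$peak * exp(-kPd * (u[i] - fall0))
    y
  }
  attr(phh3, "floor_u") <- phh3_floor_u

  list(dna = dna, dna_width = dna_width, cyclin_a2 = a2, cyclin_b1 = b1,
       phh3 = phh3, ssc = ssc)
}

#' Ground-truth phase model for synthetic cytometry populations
#'
#' Defines the study conditions for the synthetic simulator: the fractions
#' of cell-cycle time spent in G1/S/G2/M, the 2C and 4C DNA levels, the
#' programmed per-marker expression curves over normalized cell-cycle
#' position `u` in `[0, 1)`, and the coefficient of variation of the
#' multiplicative log-normal measurement noise per channel. Optional
#' `background_slope` adds a scatter-proportional background
#' (`slope * ssc`) to a channel, emulating size-dependent non-specific
#' staining for preprocessing tests.
#'
#' The default curves encode: DNA constant at 2C in G1, linear 2C to 4C
#' across S, constant 4C in G2+M; cyclin A2 zero through G1 with a
#' second-order polynomial rise in early/mid S and an exponential rise
#' through late S/G2; cyclin B1 low but nonzero in G1 with a slow-then-fast
#' two-exponential rise; PHH3 at baseline until a steep late-G2/M-entry
#' ramp; both cyclins dip briefly at mitotic entry then plateau; and the
#' ordered degradations A2 before B1 before PHH3 dephosphorylation, whose
#' floor positions satisfy `u_A2 < u_B1 < u_PHH3`.
#'
#' @param phase_fractions named fractions of cell-cycle time,
#'   `c(G1=, S=, G2=, M=)`, summing to 1.
#' @param dna_levels `c(2C value, 4C value)`; the 4C value must be twice the
#'   2C value.
#' @param noise_cv named per-channel CV of the log-normal noise.
#' @param background_slope named per-channel scatter-background slope.
#' @param curve_params parameter list as from `default_curve_params()`;
#'   levels and landmark fractions for the default curve shapes.
#' @param marker_curves optional named list of custom vectorized curve
#'   functions of `u`; overrides the default construction (such models
#'   cannot be serialized to JSON).
#' @return an object of class `phase_model`.
#' @export
phase_model <- function(phase_fractions = c(G1 = 0.30, S = 0.40, G2 = 0.244, M = 0.056),
                        dna_levels = c(200, 400),
                        noise_cv = c(dna = 0.03, dna_width = 0.05,
                                     cyclin_a2 = 0.10, cyclin_b1 = 0.10,
                                     phh3 = 0.10, ssc = 0.15),
                        background_slope = NULL,
                        curve_params = default_curve_params(),
                        marker_curves = NULL) {
  stopifnot(length(phase_fractions) == 4)
  if (is.null(names(phase_fractions))) names(phase_fractions) <- c("G1", "S", "G2", "M")
  if (!setequal(names(phase_fractions), c("G1", "S", "G2", "M"))) {
    stop("phase_fractions must be named G1, S, G2, M")
  }
  phase_fractions <- phase_fractions[c("G1", "S", "G2", "M")]
  if (abs(sum(phase_fractions) - 1) > 1e-9) stop("phase fractions must sum to 1")
  if (any(phase_fractions <= 0)) stop("phase fractions must be positive")
  stopifnot(length(dna_levels) == 2)
  if (abs(dna_levels[2] - 2 * dna_levels[1]) > 1e-9 * dna_levels[1]) {
    stop("the 4C DNA level must be exactly twice the 2C level")
  }
  custom <- !is.null(marker_curves)
  curves <- if (custom) marker_curves else {
    build_marker_curves(phase_fractions, dna_levels, curve_params)
  }
  missing_cv <- setdiff(names(curves), names(noise_cv))
  if (length(missing_cv)) {
    noise_cv[missing_cv] <- 0
  }
  if (is.null(background_slope)) {
    background_slope <- setNames(rep(0, length(curves)), names(curves))
  } else {
    bs <- setNames(rep(0, length(curves)), names(curves))
    bs[names(background_slope)] <- background_slope
    background_slope <- bs
  }
  model <- structure(list(phase_fractions = phase_fractions,
                          dna_levels = dna_levels,
                          marker_curves = curves,
                          noise_cv = noise_cv,
                          background_slope = background_slope,
                          curve_params = curve_params,
                          custom_curves = custom),
                     class = "phase_model")
  flo <- marker_floors(model)
  if (all(c("cyclin_a2", "cyclin_b1", "phh3") %in% names(flo))) {
    fo <- flo[c("cyclin_a2", "cyclin_b1", "phh3")]
    if (!any(is.na(fo)) && is.unsorted(fo, strictly = TRUE)) {
      stop("degradation order violated: require u_A2 < u_B1 < u_PHH3")
    }
  }
  model
}

#' @export
print.phase_model <- function(x, ...) {
  cat("phase_model\n  time fractions:",
      paste(sprintf("%s=%.3f", names(x$phase_fractions), x$phase_fractions),
            collapse = " "), "\n")
  cat("  channels:", paste(names(x$marker_curves), collapse = ", "), "\n")
  invisible(x)
}

#' Positions where degrading markers reach their floors
#'
#' @param model a [phase_model()].
#' @return named numeric vector of floor positions (`NA` for monotone
#'   channels).
#' @export
marker_floors <- function(model) {
  vapply(model$marker_curves, function(f) {
    attr(f, "floor_u") %||% NA_real_
  }, numeric(1))
}

# Cumulative phase boundaries on the u axis: G1/S, S/G2, G2/M.
phase_boundaries <- function(model) {
  cumsum(model$phase_fractions)[c("G1", "S", "G2")]
}

# Phase label for normalized positions.
phase_of <- function(u, model) {
  b <- phase_boundaries(model)
  cut(u, breaks = c(0, b, 1), labels = c("G1", "S", "G2", "M"),
      right = FALSE, include.lowest = TRUE)
}

#' Noiseless ground-truth expression profile
#'
#' Evaluates a model's programmed curve at `n_points` positions and places
#' the values on the same cumulative-frequency axis convention that profile
#' extraction uses, so extracted profiles can be compared directly against
#' the generating truth.
#'
#' @param model a [phase_model()].
#' @param channel channel name present in the model.
#' @param n_points number of evaluation positions.
#' @param age_weighted if `TRUE` (default) the frequency axis is the
#'   exponential-growth age CDF of `u`; if `FALSE`, `x = u`.
#' @return an [expression_profile] with one column for `channel`.
#' @export
ground_truth_profile <- function(model, channel, n_points = 200,
                                 age_weighted = TRUE) {
  stopifnot(inherits(model, "phase_model"))
  if (!channel %in% names(model$marker_curves)) {
    stop("channel '", channel, "' not in model (have: ",
         paste(names(model$marker_curves), collapse = ", "), ")")
  }
  if (!is_count(n_points)) stop("n_points must be a positive integer")
  u <- (seq_len(n_points) - 0.5) / n_points
  x <- if (age_weighted) age_cdf(u) else u
  y <- model$marker_curves[[channel]](u)
  pts <- data.frame(x = x, count = NA_integer_, synthetic = FALSE)
  pts[[channel]] <- y
  new_expression_profile(pts, channels = channel, axis_mode = "frequency")
}

#' Read and write phase models as JSON
#'
#' Serializes the model parameters (fractions, DNA levels, noise CVs,
#' background slopes, curve parameters). Models with user-supplied curve
#' closures cannot be serialized.
#'
#' @param model a [phase_model()].
#' @param path file path.
#' @return `read_phase_model` returns a [phase_model()];
#'   `write_phase_model` returns `path` invisibly.
#' @export
write_phase_model <- function(model, path) {
  stopifnot(inherits(model, "phase_model"))
  if (isTRUE(model$custom_curves)) {
    stop("models with custom curve functions cannot be serialized to JSON")
  }
  obj <- list(phase_fractions = as.list(model$phase_fractions),
              dna_levels = model$dna_levels,
              noise_cv = as.list(model$noise_cv),
              background_slope = as.list(model$background_slope),
              curve_params = model$curve_params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_phase_model
#' @export
read_phase_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cp <- obj$curve_params
  # nested lists come back as lists of scalars; coerce leaf vectors
  phase_model(phase_fractions = unlist(obj$phase_fractions),
              dna_levels = unlist(obj$dna_levels),
              noise_cv = unlist(obj$noise_cv),
              background_slope = unlist(obj$background_slope),
              curve_params = cp)
}
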