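# A rule-built full-cycle segmentation scheme for the synthetic model:
# the computational counterpart of the manually placed region sets used on
# real data. Interphase is segmented as contiguous cyclin slabs in the
# cyclin-vs-PHH3 view (PHH3 is flat there, so the backbone is horizontal
# and slab boundaries are already perpendicular to it); mitosis is
# segmented in the same channel pair under the mitotic gate context,
# following the trajectory PHH3 rise -> entry dip/prophase plateau ->
# cyclin fall -> post-cyclin cluster -> PHH3 fall.

#' Build the full-cycle reference scheme for a synthetic panel
#'
#' Constructs a globally ordered region scheme over two views of the same
#' channel pair - cyclin vs. PHH3 under the interphase gate context
#' (`NOT <gate>`) and under the mitotic context (`<gate>`) - whose
#' landmarks (slab boundaries, mitotic box edges) are derived from the
#' model's programmed curves. Region 1 is the irreducible G1 cluster (the
#' cyclin-low slab), regions 2..n+2 are geometric cyclin slabs spanning the
#' S/G2 rise, and seven mitotic boxes follow the mitotic trajectory in
#' temporal order.
#'
#' @param model a [phase_model()] with default (parameterized) curves.
#' @param cyclin `"cyclin_a2"` or `"cyclin_b1"`: the panel's private
#'   cyclin.
#' @param phh3_channel PHH3 channel name.
#' @param n_strips number of interphase cyclin slabs above the G1 cluster.
#' @param mitotic_threshold PHH3 threshold of the mitotic gate context
#'   (linear scale); must match the threshold used to build the gate mask.
#' @param gate mitotic gate mask name referenced by the contexts.
#' @return a [region_scheme()].
#' @export
build_reference_scheme <- function(model, cyclin = c("cyclin_a2", "cyclin_b1"),
                                   phh3_channel = "phh3", n_strips = 12,
                                   mitotic_threshold = 20, gate = "R3") {
  stopifnot(inherits(model, "phase_model"))
  if (isTRUE(model$custom_curves)) {
    stop("reference scheme construction requires the parameterized default curves")
  }
  cyclin <- match.arg(cyclin)
  cy_curve <- model$marker_curves[[cyclin]]
  p3_curve <- model$marker_curves[[phh3_channel]]
  fr <- model$phase_fractions
  t1 <- fr[["G1"]]; t3 <- t1 + fr[["S"]] + fr[["G2"]]; m <- fr[["M"]]
  cp <- model$curve_params
  peak_u <- t3 + cp$phh3$ramp_end_m_frac * m
  ramp0 <- t3 - cp$phh3$ramp_start_g2_frac * fr[["G2"]]
  if (mitotic_threshold <= cp$phh3$base || mitotic_threshold >= cp$phh3$peak) {
    stop("mitotic_threshold must lie between the PHH3 baseline and peak")
  }
  u_thr <- uniroot(function(u) p3_curve(u) - mitotic_threshold,
                   c(ramp0, peak_u), tol = 1e-12)$root

  top <- cy_curve(u_thr)                       # cyclin level when PHH3 crosses the gate
  g1_level <- cy_curve(t1 / 2)
  c0 <- max(1.8 * g1_level, 0.012 * top)       # upper edge of the G1 cluster slab
  dip <- cy_curve(t3 + (cp$m_dip_end + cp$m_a2_plateau_end) / 2 * m)
  floor_level <- cy_curve(1 - 1e-9)
  cy_hi <- 0.57 * dip                          # plateau / falling boundary
  cy_lo <- max(3 * floor_level, 0.03 * dip)    # falling / fallen boundary
  p_peak <- cp$phh3$peak
  p35 <- 0.35 * p_peak
  p45 <- 0.45 * p_peak
  p55 <- 0.55 * p_peak
  p80 <- 0.80 * p_peak                         # ~2 sd below the PHH3 plateau
  BIG <- 1e6

  vi <- make_view(cyclin, phh3_channel, name = paste0(cyclin, ":interphase"))
  vm <- make_view(cyclin, phh3_channel, name = paste0(cyclin, ":mitosis"))
  # cyclin-low cells split by DNA content: separating the 2C stemline from
  # post-mitotic (still 4C) cells needs the third parameter, so the G1
  # cluster and the terminal late-telophase cluster live in a cyclin-vs-DNA
  # view; without this, cycle-end cells wrap into G1 and shift every
  # downstream frequency
  vc <- make_view(cyclin, "dna", name = paste0(cyclin, ":cluster"))
  ctx_i <- paste("NOT", gate)
  ctx_m <- gate
  dna_mid <- mean(model$dna_levels)
  # the terminal cluster takes only the 4C mode (bounding-cluster variation,
  # as in 1-D segmentation); cyclin-low events with mid-range DNA are
  # aberrant S-phase cells without cyclin signal and stay unassigned, as an
  # outlier gate would drop them
  dna_4c_lo <- model$dna_levels[2] * (1 - 3 * model$noise_cv[["dna"]])

  bnd <- exp(seq(log(c0), log(top), length.out = n_strips + 1))
  regions <- list(rect_region(1, vc, c(-BIG, c0), c(-BIG, dna_mid), ctx_i))
  for (k in seq_len(n_strips)) {
    regions[[k + 1]] <- rect_region(k + 1, vi, c(bnd[k], bnd[k + 1]),
                                    c(-BIG, BIG), ctx_i)
  }
  regions[[n_strips + 2]] <- rect_region(n_strips + 2, vi, c(top, BIG),
                                         c(-BIG, BIG), ctx_i)
  i0 <- n_strips + 2
  mboxes <- list(
    list(c(cy_hi, BIG), c(mitotic_threshold, p45)),  # PHH3 rising, cyclin high
    list(c(cy_hi, BIG), c(p45, p80)),
    list(c(cy_hi, BIG), c(p80, BIG)),                # entry dip + prophase plateau
    list(c(cy_lo, cy_hi), c(p80, BIG)),              # cyclin degradation
    list(c(-BIG, cy_lo), c(p80, BIG)),               # post-cyclin cluster
    list(c(-BIG, cy_lo), c(p55, p80)),               # PHH3 falling
    list(c(-BIG, cy_lo), c(p35, p55)),
    list(c(-BIG, cy_lo), c(mitotic_threshold, p35))
  )
  for (k in seq_along(mboxes)) {
    regions[[i0 + k]] <- rect_region(i0 + k, vm, mboxes[[k]][[1]],
                                     mboxes[[k]][[2]], ctx_m)
  }
  n_m <- length(mboxes)
  regions[[i0 + n_m + 1]] <- rect_region(i0 + n_m + 1, vc, c(-BIG, c0),
                                         c(dna_4c_lo, BIG), ctx_i)
  scheme <- region_scheme(regions,
                          description = sprintf("full-cycle reference scheme: %s vs %s",
                                                cyclin, phh3_channel))
  # expression-regime transitions (region indices after which the regime
  # changes): end of interphase, top of the PHH3 ramp, end of the plateau,
  # end of the PHH3 fall
  attr(scheme, "transition_regions") <- c(n_strips + 2L, n_strips + 4L,
                                          n_strips + 7L, n_strips + 10L)
  scheme
}

#' Segment and extract a full panel in one call
#'
#' Convenience wrapper used throughout examples and tests: builds the
#' mitotic gate mask at the scheme's threshold, assigns events to the
#' reference scheme, and extracts the requested channels.
#'
#' @param population a [sample_population()] result (or an [event_table()]).
#' @param model the generating [phase_model()].
#' @param cyclin panel cyclin channel.
#' @param channels channels to extract; defaults to DNA, the panel cyclin
#'   and PHH3.
#' @param n_strips,mitotic_threshold passed to [build_reference_scheme()].
#' @return list: `profile` ([expression_profile]), `labels`, `scheme`,
#'   `events` (with the mitotic mask attached).
#' @export
extract_panel <- function(population, model, cyclin = "cyclin_a2",
                          channels = c("dna", cyclin, "phh3"),
                          n_strips = 12, mitotic_threshold = 20) {
  events <- as_event_table(population)
  scheme <- build_reference_scheme(model, cyclin, n_strips = n_strips,
                                   mitotic_threshold = mitotic_threshold)
  events <- attach_mask(events, mitotic_gate(events, "phh3",
                                             threshold = mitotic_threshold))
  labels <- assign_events(events, scheme)
  idx <- vapply(scheme$regions, `[[`, integer(1), "global_index")
  prof <- extract_profile(events, labels, channels, expected_regions = idx)
  transitions <- match(attr(scheme, "transition_regions"),
                       attr(prof$points, "region_index"))
  list(profile = prof, labels = labels, scheme = scheme, events = events,
       transitions = transitions[!is.na(transitions)])
}
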