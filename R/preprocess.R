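# Preprocessing gates: aggregate/debris removal by 2-D density contour,
# mitotic gating on PHH3, scatter-dependent background subtraction, outlier
# contour gates, and the boolean gate algebra that rejoins cytokinetic
# cells to the 2C stemline, e.g. ((R2 AND R4 AND R5) OR R3).

#' Boolean gate mask
#'
#' @param name gate id (conventionally R2, R3, R4, R5, ...).
#' @param mask per-event logical vector.
#' @param definition free-text description of how the gate was built.
#' @return an object of class `gate_mask`.
#' @export
gate_mask <- function(name, mask, definition = "") {
  stopifnot(is.character(name), length(name) == 1L, is.logical(mask))
  if (anyNA(mask)) stop("gate mask must not contain NA")
  structure(list(name = name, mask = mask, definition = definition),
            class = "gate_mask")
}

#' @export
print.gate_mask <- function(x, ...) {
  cat(sprintf("gate_mask %s: %d / %d events (%s)\n", x$name, sum(x$mask),
              length(x$mask), x$definition))
  invisible(x)
}

# Smoothed 2-D density (128 x 128 grid, Silverman bandwidths) and the
# smallest level set containing `level` percent of the probability mass of
# the contiguous population around the main mode. The population is the
# connected component of cells above a small density floor (a fraction of
# the peak), so diffuse background - debris clouds, doublet modes detached
# from the singlet mode - is not part of the mass the contour must enclose.
# Returns a per-event logical over all events; events outside `subset` are
# FALSE.
density_contour_mask <- function(events, x_channel, y_channel, level,
                                 subset = NULL, grid = 128,
                                 floor_frac = 0.002) {
  events <- as_event_table(events)
  if (!is_scalar_number(level) || level <= 0 || level >= 100) {
    stop("contour level must lie strictly between 0 and 100 percent")
  }
  x <- channel_values(events, x_channel)
  y <- channel_values(events, y_channel)
  keep <- subset %||% rep(TRUE, length(x))
  xs <- x[keep]; ys <- y[keep]
  if (length(xs) == 0) stop("no events to gate")
  if (length(xs) < 500) stop("too few events (", length(xs),
                             ") for density estimation; need >= 500")
  bw <- c(MASS::bandwidth.nrd(xs), MASS::bandwidth.nrd(ys))
  if (any(bw <= 0)) stop("density estimation failed: degenerate bandwidth")
  kd <- MASS::kde2d(xs, ys, h = bw, n = grid,
                    lims = c(range(xs) + c(-1, 1) * bw[1],
                             range(ys) + c(-1, 1) * bw[2]))
  cell_p <- kd$z / sum(kd$z)
  mode_ij <- arrayInd(which.max(kd$z), dim(kd$z))
  pop_comp <- flood_component(kd$z >= floor_frac * max(kd$z), mode_ij)
  pop_mass <- sum(cell_p[pop_comp])
  in_pop <- which(pop_comp)
  ord <- in_pop[order(kd$z[in_pop], decreasing = TRUE)]
  thr <- kd$z[ord[which(cumsum(cell_p[ord]) >= level / 100 * pop_mass)[1]]]
  comp <- flood_component(pop_comp & kd$z >= thr, mode_ij)
  ix <- findInterval(x, kd$x, all.inside = TRUE)
  iy <- findInterval(y, kd$y, all.inside = TRUE)
  # snap each event to its nearest grid node
  ix <- ix + (x - kd$x[ix] > diff(kd$x[1:2]) / 2)
  iy <- iy + (y - kd$y[iy] > diff(kd$y[1:2]) / 2)
  ix <- pmin(pmax(ix, 1L), grid); iy <- pmin(pmax(iy, 1L), grid)
  keep & comp[cbind(ix, iy)]
}

# 4-neighborhood flood fill from a start cell over TRUE cells.
flood_component <- function(mask, start) {
  comp <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!mask[start[1], start[2]]) return(comp)
  stack <- matrix(start, ncol = 2)
  comp[start[1], start[2]] <- TRUE
  nr <- nrow(mask); nc <- ncol(mask)
  while (nrow(stack)) {
    cur <- stack[nrow(stack), , drop = FALSE]
    stack <- stack[-nrow(stack), , drop = FALSE]
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      i <- cur[1] + d[1]; j <- cur[2] + d[2]
      if (i >= 1 && i <= nr && j >= 1 && j <= nc && mask[i, j] && !comp[i, j]) {
        comp[i, j] <- TRUE
        stack <- rbind(stack, c(i, j))
      }
    }
  }
  comp
}

#' Singlet gate: aggregate and debris removal
#'
#' Builds a contour gate on the pulse-width vs. integrated-DNA plane: the
#' smallest region of a smoothed 2-D density containing `level` percent of
#' probability around the singlet mode. Aggregates (greater width at equal
#' integrated signal) and debris fall outside. Late mitotic/cytokinetic
#' events may also be excluded here; they are restored downstream via the
#' mitotic gate in the combined gate expression.
#'
#' @param events an [event_table()].
#' @param width_channel DNA pulse-width channel name.
#' @param dna_channel integrated DNA channel name.
#' @param level percent of density enclosed, in (0, 100); default 99.
#' @param name gate id for the returned mask (default `"R2"`).
#' @return a [gate_mask()].
#' @export
singlet_gate <- function(events, width_channel, dna_channel, level = 99,
                         name = "R2") {
  m <- density_contour_mask(events, width_channel, dna_channel, level)
  gate_mask(name, m, sprintf("%g%% density contour on %s vs %s (singlet mode)",
                             level, width_channel, dna_channel))
}

#' Mitotic gate on PHH3 fluorescence
#'
#' Flags events above a PHH3 threshold separating the high-PHH3 mitotic
#' mode from interphase. By default the threshold sits at the density
#' minimum between the two largest modes of the asinh-transformed PHH3
#' distribution (computed within `gated_on` when given); it can be
#' overridden, mirroring visually placed gates.
#'
#' @param events an [event_table()].
#' @param phh3_channel PHH3 channel name.
#' @param gated_on optional [gate_mask()]: the gate the PHH3 distribution
#'   is taken from (typically the singlet gate); both the threshold
#'   estimation and the returned mask are restricted to it, so debris with
#'   spuriously high PHH3-channel signal cannot enter through the mitotic
#'   rejoin.
#' @param threshold optional manual threshold on the linear PHH3 scale.
#' @param name gate id (default `"R3"`).
#' @param cofactor asinh cofactor for the working transform.
#' @return a [gate_mask()]; empty with a warning when no mitotic mode exists.
#' @export
mitotic_gate <- function(events, phh3_channel, gated_on = NULL,
                         threshold = NULL, name = "R3", cofactor = 5) {
  events <- as_event_table(events)
  v <- channel_values(events, phh3_channel)
  sub <- if (is.null(gated_on)) rep(TRUE, length(v)) else gated_on$mask
  if (is.null(threshold)) {
    z <- asinh(v[sub] / cofactor)
    d <- density(z, n = 512)
    pk <- which(diff(sign(diff(d$y))) == -2) + 1L
    pk <- pk[d$y[pk] > 1e-4 * max(d$y)]
    main <- pk[which.max(d$y[pk])]
    # the mitotic mode sits well above interphase (typically 10-30x); look
    # for the strongest peak at least ~4.5-fold above the main mode
    cand <- pk[d$x[pk] > d$x[main] + 1.5]
    if (!length(cand)) {
      warning("PHH3 distribution is unimodal: no mitotic mode found; empty gate")
      return(gate_mask(name, rep(FALSE, length(v)),
                       sprintf("PHH3 mitotic gate on %s: no mitotic mode", phh3_channel)))
    }
    mito <- cand[which.max(d$y[cand])]
    valley <- main + which.min(d$y[main:mito]) - 1L
    threshold <- cofactor * sinh(d$x[valley])
  }
  gate_mask(name, sub & v > threshold,
            sprintf("%s > %.4g (inter-mode density minimum or override)%s",
                    phh3_channel, threshold,
                    if (is.null(gated_on)) "" else paste0(" within ", gated_on$name)))
}

# Theil-Sen slope: median of pairwise slopes. For large n the full pair set
# is replaced by the deterministic offset pairing (i, i + n/2) on x-sorted
# data, which keeps the estimator robust and reproducible.
theil_sen <- function(x, y, max_exact = 3000) {
  n <- length(x)
  stopifnot(n >= 2, length(y) == n)
  if (n <= max_exact) {
    ij <- utils::combn(n, 2)
    dx <- x[ij[2, ]] - x[ij[1, ]]
    dy <- y[ij[2, ]] - y[ij[1, ]]
  } else {
    o <- order(x)
    x <- x[o]; y <- y[o]
    h <- n %/% 2
    i <- seq_len(n - h)
    dx <- x[i + h] - x[i]
    dy <- y[i + h] - y[i]
  }
  ok <- dx != 0
  slope <- median(dy[ok] / dx[ok])
  intercept <- median(y - slope * x)
  c(intercept = intercept, slope = slope)
}

#' Scatter-dependent background subtraction
#'
#' Estimates the size-dependent non-specific staining of a cyclin channel
#' as a linear function of side scatter within a reference population of
#' cyclin-negative cells (typically G1), and subtracts `beta * SSC` from
#' all events, in the spirit of a spillover-style linear compensation. On
#' success the median corrected cyclin signal of the reference cells lies
#' within `epsilon` of zero, where `epsilon` is 1 percent of the channel's
#' 90th percentile.
#'
#' @param events an [event_table()].
#' @param cyclin_channel channel to correct.
#' @param ssc_channel side-scatter channel.
#' @param negative_mask [gate_mask()] of reference (cyclin-negative) cells.
#' @return the corrected [event_table()], with attributes `beta` (the
#'   subtracted slope) and `reference_median` (post-correction reference
#'   median) on the corrected channel recorded in `metadata$corrections`.
#' @export
background_subtract <- function(events, cyclin_channel, ssc_channel,
                                negative_mask) {
  events <- as_event_table(events)
  stopifnot(inherits(negative_mask, "gate_mask"))
  sel <- negative_mask$mask
  if (!any(sel)) stop("negative_mask selects no events")
  cy <- channel_values(events, cyclin_channel)
  ssc <- channel_values(events, ssc_channel)
  fit <- theil_sen(ssc[sel], cy[sel])
  beta <- unname(fit["slope"])
  clamped <- beta < 0
  if (clamped) {
    warning("estimated background slope is negative; clamped to 0")
    beta <- 0
  }
  corrected <- cy - beta * ssc
  out <- events
  out$data[[cyclin_channel]] <- corrected
  eps <- 0.01 * abs(quantile(cy, 0.9, names = FALSE))
  ref_med <- median(corrected[sel])
  if (!clamped && abs(ref_med) > max(eps, .Machine$double.eps^0.5)) {
    warning(sprintf("reference median %.4g exceeds epsilon %.4g after correction",
                    ref_med, eps))
  }
  out$metadata$corrections[[cyclin_channel]] <- list(beta = beta,
                                                     reference_median = ref_med)
  out
}

#' Outlier contour gate on interphase cells
#'
#' Contour gate (as in [singlet_gate()]) on a cyclin vs. DNA plot of
#' interphase events, removing doublets, aberrant cyclin-negative S-phase
#' cells and outliers while keeping `level` percent of the interphase
#' density.
#'
#' @param events an [event_table()].
#' @param cyclin_channel,dna_channel plot channels.
#' @param interphase_mask [gate_mask()] selecting interphase events
#'   (e.g. R2 AND NOT R3).
#' @param level percent of density enclosed; default 99.
#' @param name gate id (default `"R5"`).
#' @return a [gate_mask()] (FALSE outside `interphase_mask`).
#' @export
outlier_gates <- function(events, cyclin_channel, dna_channel,
                          interphase_mask, level = 99, name = "R5") {
  stopifnot(inherits(interphase_mask, "gate_mask"))
  m <- density_contour_mask(events, cyclin_channel, dna_channel, level,
                            subset = interphase_mask$mask)
  gate_mask(name, m, sprintf("%g%% density contour on %s vs %s within %s",
                             level, cyclin_channel, dna_channel,
                             interphase_mask$name))
}

# Parse and evaluate a boolean gate formula over named masks.
eval_gate_expression <- function(expression, masks, n) {
  if (is.null(expression) || !nzchar(trimws(expression)) ||
      identical(toupper(trimws(expression)), "TRUE")) {
    return(rep(TRUE, n))
  }
  tokens <- gsub("\\b(AND)\\b", "&", expression, ignore.case = TRUE)
  tokens <- gsub("\\b(OR)\\b", "|", tokens, ignore.case = TRUE)
  tokens <- gsub("\\b(NOT)\\b", "!", tokens, ignore.case = TRUE)
  ids <- unlist(regmatches(tokens, gregexpr("[A-Za-z_][A-Za-z0-9_.]*", tokens)))
  missing <- setdiff(ids, names(masks))
  if (length(missing)) {
    stop("gate expression references unknown masks: ",
         paste(missing, collapse = ", "))
  }
  residue <- gsub("[A-Za-z_][A-Za-z0-9_.]*|[()!&|[:space:]]", "", tokens)
  if (nzchar(residue)) stop("invalid characters in gate expression: ", residue)
  env <- new.env(parent = baseenv())  # tokens are whitelisted above
  for (nm in names(masks)) {
    v <- if (inherits(masks[[nm]], "gate_mask")) masks[[nm]]$mask else masks[[nm]]
    assign(nm, v, envir = env)
  }
  out <- eval(parse(text = tokens)[[1]], envir = env)
  if (!is.logical(out) || length(out) != n) stop("gate expression did not evaluate to a mask")
  out
}

#' Combine gate masks with a boolean formula
#'
#' Evaluates an AND/OR/NOT formula over named masks element-wise, e.g.
#' `"((R2 AND R4 AND R5) OR R3)"` - the final gating strategy that keeps
#' clean interphase cells while rejoining the mitotic/cytokinetic events
#' that the singlet gate excluded.
#'
#' @param masks named list of [gate_mask()] objects (or an [event_table()]
#'   whose attached masks are used).
#' @param expression boolean formula string over the mask names.
#' @param name gate id for the result.
#' @return a [gate_mask()].
#' @export
combine_gates <- function(masks, expression, name = "combined") {
  if (inherits(masks, "event_table")) masks <- masks$masks
  if (!length(masks)) stop("no masks supplied")
  if (is.null(names(masks)) || any(!nzchar(names(masks)))) {
    names(masks) <- vapply(masks, `[[`, character(1), "name")
  }
  n <- length(if (inherits(masks[[1]], "gate_mask")) masks[[1]]$mask else masks[[1]])
  gate_mask(name, eval_gate_expression(expression, masks, n), expression)
}
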