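# Expression-vs-cumulative-frequency profiles.
#
# A segment holding fraction f_i of the gated events (in global order) is
# plotted at x_i = sum_{j<i} f_j + f_i/2 on a 0-1 axis equal to one
# cell-cycle time; the y value is the median of each requested channel
# within the segment. Channels not used to define the segmentation may be
# read out through the same regions (indirect derivation).

#' Expression profile
#'
#' Ordered records of (cumulative-frequency center, per-channel center
#' statistic, dispersion, count), plus flagged synthetic boundary points.
#'
#' @param points data frame with columns `x`, `count`, `synthetic`, one
#'   column per channel, and optional `<channel>_se` / `<channel>_sem` /
#'   `<channel>_ci95` dispersion columns.
#' @param channels channel names.
#' @param axis_mode `"frequency"` (raw cumulative frequency, the default
#'   plotting convention) or `"age_corrected_time"`.
#' @return an object of class `expression_profile`.
#' @export
new_expression_profile <- function(points, channels,
                                   axis_mode = c("frequency", "age_corrected_time")) {
  axis_mode <- match.arg(axis_mode)
  stopifnot(is.data.frame(points),
            all(c("x", "count", "synthetic") %in% names(points)),
            all(channels %in% names(points)))
  if (any(points$x < -1e-9 | points$x > 1 + 1e-9)) {
    stop("profile x values must lie in [0, 1]")
  }
  real_x <- points$x[!points$synthetic]
  if (length(real_x) > 1 && is.unsorted(real_x, strictly = TRUE)) {
    stop("x must be strictly increasing over non-synthetic points")
  }
  structure(list(points = points, channels = channels, axis_mode = axis_mode),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("expression_profile:", nrow(x$points), "points (",
      sum(x$points$synthetic), "synthetic );",
      "channels:", paste(x$channels, collapse = ", "),
      "; axis:", x$axis_mode, "\n")
  invisible(x)
}

profile_real_points <- function(profile) {
  profile$points[!profile$points$synthetic, , drop = FALSE]
}

#' Extract an expression profile from segment labels
#'
#' For segment i holding fraction `f_i` of all assigned events, the profile
#' point sits at `x_i = sum_{j<i} f_j + f_i/2`, with the per-channel median
#' of the segment's events as the center value and a median standard error
#' (`1.2533 * sd / sqrt(n)`) as the within-segment dispersion. Channels
#' that did not define the segmentation are extracted the same way
#' (indirect derivation). Segments listed in `expected_regions` but holding
#' no events are skipped with a warning.
#'
#' @param events an [event_table()].
#' @param labels per-event integer segment labels in global order (`NA` =
#'   unassigned), as from [assign_events()].
#' @param channels channel names to extract.
#' @param expected_regions optional full vector of region indices, used to
#'   detect empty segments.
#' @return an [expression_profile].
#' @export
extract_profile <- function(events, labels, channels,
                            expected_regions = NULL) {
  events <- as_event_table(events)
  stopifnot(length(labels) == n_events(events))
  for (ch in channels) channel_values(events, ch)  # validates presence
  present <- sort(unique(labels[!is.na(labels)]))
  if (!length(present)) stop("no assigned events")
  if (!is.null(expected_regions)) {
    empty <- setdiff(expected_regions, present)
    if (length(empty)) {
      warning("empty segment(s) skipped: ", paste(sort(empty), collapse = ", "))
    }
  }
  counts <- vapply(present, function(k) sum(labels == k, na.rm = TRUE), numeric(1))
  total <- sum(counts)
  f <- counts / total
  x <- cumsum(f) - f / 2
  pts <- data.frame(x = x, count = as.integer(counts), synthetic = FALSE)
  for (ch in channels) {
    v <- channel_values(events, ch)
    med <- numeric(length(present)); se <- numeric(length(present))
    for (i in seq_along(present)) {
      vi <- v[which(labels == present[i])]
      med[i] <- median(vi)
      se[i] <- 1.2533 * sd(vi) / sqrt(length(vi))
    }
    pts[[ch]] <- med
    pts[[paste0(ch, "_se")]] <- se
  }
  attr(pts, "region_index") <- present
  new_expression_profile(pts, channels = channels, axis_mode = "frequency")
}

# Linear extrapolation from two support points.
extrapolate2 <- function(x1, y1, x2, y2, x0) {
  if (x2 == x1) return(y2)
  y1 + (y2 - y1) * (x0 - x1) / (x2 - x1)
}

#' Insert synthetic boundary points into a profile
#'
#' Completes a profile by adding flagged synthetic points: Y intercepts at
#' x = 0 and x = 1 extrapolated linearly from the two nearest real points
#' of the first and last stretch, and, at each stated transition (a change
#' of expression regime between point `i` and `i + 1`), one point at the
#' shared frequency boundary per adjoining stretch, extrapolated from that
#' stretch's side. Stretches with fewer than two real points fall back to
#' constant extension with a warning.
#'
#' @param profile an [expression_profile] with real (counted) points.
#' @param transition_indices integer positions `i` (into the non-synthetic
#'   points) marking a transition between points `i` and `i + 1`.
#' @return the augmented [expression_profile]; synthetic points carry
#'   `count = 0` and `synthetic = TRUE`.
#' @export
insert_boundary_points <- function(profile, transition_indices = integer()) {
  stopifnot(inherits(profile, "expression_profile"))
  real <- profile_real_points(profile)
  n <- nrow(real)
  if (any(transition_indices < 1 | transition_indices >= n)) {
    stop("transition indices must lie between 1 and ", n - 1)
  }
  transition_indices <- sort(unique(as.integer(transition_indices)))
  total <- sum(real$count)
  f <- real$count / total
  bounds <- c(0, sort(unique(c(transition_indices, n))))
  stretches <- lapply(seq_len(length(bounds) - 1), function(k) {
    (bounds[k] + 1):bounds[k + 1]
  })
  chans <- profile$channels
  ex <- function(idx, pick, x0) {
    # extrapolate all channels from the two stretch points nearest x0
    row <- real[1, , drop = FALSE]
    row$x <- x0; row$count <- 0L; row$synthetic <- TRUE
    for (ch in chans) {
      if (length(idx) < 2) {
        warning("stretch with < 2 points: constant extension used at x = ", x0)
        row[[ch]] <- real[[ch]][idx[1]]
      } else {
        two <- if (pick == "head") idx[1:2] else idx[(length(idx) - 1):length(idx)]
        row[[ch]] <- extrapolate2(real$x[two[1]], real[[ch]][two[1]],
                                  real$x[two[2]], real[[ch]][two[2]], x0)
      }
      sec <- paste0(ch, "_se")
      if (sec %in% names(row)) row[[sec]] <- NA_real_
    }
    row
  }
  out <- real
  key <- real$x  # secondary ordering key for coincident boundary points
  add <- function(row, k) {
    out <<- rbind(out, row)
    key <<- c(key, k)
  }
  add(ex(stretches[[1]], "head", 0), -Inf)
  add(ex(stretches[[length(stretches)]], "tail", 1), Inf)
  for (i in transition_indices) {
    xb <- real$x[i] + f[i] / 2
    left <- stretches[[which(vapply(stretches, function(s) i %in% s, logical(1)))]]
    right <- stretches[[which(vapply(stretches, function(s) (i + 1) %in% s, logical(1)))]]
    add(ex(left, "tail", xb), xb - 1e-12)
    add(ex(right, "head", xb), xb + 1e-12)
  }
  out <- out[order(key, out$synthetic), , drop = FALSE]
  rownames(out) <- NULL
  new_expression_profile(out, channels = chans, axis_mode = profile$axis_mode)
}

#' Combine replicate profiles
#'
#' Point-wise mean of x and of the channel medians across identically
#' structured replicates (equal region counts), with the standard error of
#' the mean and the t-based 95 percent confidence half-width per point.
#'
#' @param profiles list of [expression_profile]s with equal point counts
#'   and channel sets.
#' @return an [expression_profile] with `<channel>_sem` and
#'   `<channel>_ci95` columns.
#' @export
combine_replicates <- function(profiles) {
  stopifnot(length(profiles) >= 2)
  lapply(profiles, function(p) stopifnot(inherits(p, "expression_profile")))
  npts <- vapply(profiles, function(p) nrow(p$points), integer(1))
  if (length(unique(npts)) != 1) {
    stop("replicate profiles must have matching point counts (got ",
         paste(npts, collapse = ", "), ")")
  }
  chans <- profiles[[1]]$channels
  for (p in profiles) stopifnot(identical(p$channels, chans),
                                identical(p$axis_mode, profiles[[1]]$axis_mode))
  r <- length(profiles)
  xs <- sapply(profiles, function(p) p$points$x)
  pts <- data.frame(x = rowMeans(xs),
                    count = as.integer(rowSums(sapply(profiles, function(p) p$points$count))),
                    synthetic = profiles[[1]]$points$synthetic)
  tcrit <- qt(0.975, df = r - 1)
  for (ch in chans) {
    ys <- sapply(profiles, function(p) p$points[[ch]])
    m <- rowMeans(ys)
    sem <- apply(ys, 1, sd) / sqrt(r)
    pts[[ch]] <- m
    pts[[paste0(ch, "_sem")]] <- sem
    pts[[paste0(ch, "_ci95")]] <- tcrit * sem
  }
  new_expression_profile(pts, channels = chans,
                         axis_mode = profiles[[1]]$axis_mode)
}

#' Merge independently measured panels through the frequency domain
#'
#' Places two profiles that share a channel (typically PHH3) on the common
#' cumulative-frequency axis unchanged - no warping - and reports the
#' maximum absolute difference of the shared channel after linear
#' interpolation of both profiles onto a common grid. Agreement below a
#' chosen threshold licenses co-plotting of the panels' private channels.
#'
#' @param profile_a,profile_b [expression_profile]s containing
#'   `shared_channel`; axis modes must match.
#' @param shared_channel the channel measured in both panels.
#' Interpolation uses the complete profiles - synthetic boundary points
#' included, since they anchor the steep transitions that plain
#' interval-center points cut across.
#'
#' @param grid optional common x grid; defaults to the union of both
#'   profiles' x values restricted to their shared range.
#' @return list with `profiles` (the two inputs, unchanged) and `report`,
#'   a `merge_report` containing `shared_channel`, `max_abs_deviation`,
#'   `grid`, and the per-grid-point `deviation`.
#' @export
merge_panels <- function(profile_a, profile_b, shared_channel, grid = NULL) {
  stopifnot(inherits(profile_a, "expression_profile"),
            inherits(profile_b, "expression_profile"))
  if (!identical(profile_a$axis_mode, profile_b$axis_mode)) {
    stop("axis modes differ between panels")
  }
  for (p in list(profile_a, profile_b)) {
    if (!shared_channel %in% p$channels) {
      stop("shared channel '", shared_channel, "' missing from a panel")
    }
  }
  ra <- profile_a$points
  rb <- profile_b$points
  if (is.null(grid)) {
    lo <- max(min(ra$x), min(rb$x))
    hi <- min(max(ra$x), max(rb$x))
    grid <- sort(unique(c(ra$x, rb$x)))
    grid <- grid[grid >= lo & grid <= hi]
  }
  ya <- interp_profile(ra$x, ra[[shared_channel]], grid)
  yb <- interp_profile(rb$x, rb[[shared_channel]], grid)
  dev <- abs(ya - yb)
  report <- structure(list(shared_channel = shared_channel,
                           max_abs_deviation = max(dev),
                           grid = grid, deviation = dev),
                      class = "merge_report")
  list(profiles = list(a = profile_a, b = profile_b), report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf("merge_report: shared channel %s, max |deviation| = %.4g over %d grid points\n",
              x$shared_channel, x$max_abs_deviation, length(x$grid)))
  invisible(x)
}

#' Join profiles into one denser profile
#'
#' Union of the profiles' points sorted by x; the data density along the
#' shared trajectory is enhanced. Only channels common to all inputs are
#' kept.
#'
#' @param profiles list of [expression_profile]s with a common axis mode.
#' @return an [expression_profile].
#' @export
join_profiles <- function(profiles) {
  profiles <- Filter(function(p) !is.null(p), profiles)
  stopifnot(length(profiles) >= 1)
  if (length(profiles) == 1) return(profiles[[1]])
  chans <- Reduce(intersect, lapply(profiles, `[[`, "channels"))
  if (!length(chans)) stop("profiles share no channels")
  modes <- unique(vapply(profiles, `[[`, character(1), "axis_mode"))
  if (length(modes) != 1) stop("axis modes differ")
  cols <- c("x", "count", "synthetic", chans)
  pts <- do.call(rbind, lapply(profiles, function(p) p$points[, cols]))
  pts <- pts[order(pts$x), , drop = FALSE]
  rownames(pts) <- NULL
  # exact x ties among real points (possible across replicates) are nudged
  # apart by 1e-12 to keep the strict-ordering invariant
  real_idx <- which(!pts$synthetic)
  if (anyDuplicated(pts$x[real_idx])) {
    pts$x[real_idx] <- pts$x[real_idx] +
      (ave(seq_along(real_idx), pts$x[real_idx], FUN = seq_along) - 1) * 1e-12
  }
  new_expression_profile(pts, channels = chans, axis_mode = modes)
}

#' Interpolated crossing position of a profile
#'
#' First x (at or after `after`) where the piecewise-linear profile of
#' `channel` crosses `level` in the stated direction; used e.g. to locate
#' degradation floors on the frequency axis.
#'
#' @param profile an [expression_profile].
#' @param channel channel name.
#' @param level threshold value.
#' @param direction `"down"` (falling through) or `"up"`.
#' @param after ignore crossings before this x.
#' @return the interpolated x, or `NA` if no crossing exists.
#' @export
profile_crossing <- function(profile, channel, level,
                             direction = c("down", "up"), after = 0) {
  direction <- match.arg(direction)
  pts <- profile_real_points(profile)
  x <- pts$x; y <- pts[[channel]]
  for (i in seq_len(length(x) - 1)) {
    if (x[i + 1] < after) next
    hit <- if (direction == "down") y[i] > level && y[i + 1] <= level else
      y[i] < level && y[i + 1] >= level
    if (hit) {
      return(x[i] + (level - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i]))
    }
  }
  NA_real_
}

#' Recovery error of a profile against a reference
#'
#' Root-mean-square deviation between a profile's channel values and a
#' reference profile (typically [ground_truth_profile()]) interpolated at
#' matched x. Because the x axis is cumulative cell frequency, each point
#' represents an interval of cells equal to its event fraction; the default
#' frequency weighting therefore computes the L2 error over the frequency
#' axis (a point carrying 40 percent of the cells counts accordingly),
#' which is the natural metric on this axis. `weights = "uniform"` treats
#' every point equally instead.
#'
#' @param profile an [expression_profile] with counted points.
#' @param reference an [expression_profile] holding the same channel.
#' @param channel channel name.
#' @param weights `"frequency"` or `"uniform"`.
#' @param relative divide by the reference channel's dynamic range.
#' @return a single numeric RMSE (relative to range when `relative`).
#' @export
profile_rmse <- function(profile, reference, channel,
                         weights = c("frequency", "uniform"),
                         relative = TRUE) {
  weights <- match.arg(weights)
  pts <- profile_real_points(profile)
  ref <- profile_real_points(reference)
  yref <- interp_profile(ref$x, ref[[channel]], pts$x)
  dev2 <- (pts[[channel]] - yref)^2
  w <- if (weights == "frequency") pts$count / sum(pts$count) else
    rep(1 / nrow(pts), nrow(pts))
  out <- sqrt(sum(w * dev2))
  if (relative) out / diff(range(ref[[channel]])) else out
}

#' Convert a profile's frequency axis to age-corrected time
#'
#' Applies [frequency_to_time()] with `mode = "age_corrected"` to every
#' point; the result is flagged by `axis_mode = "age_corrected_time"`.
#'
#' @param profile an [expression_profile] on the raw frequency axis.
#' @return an [expression_profile] on normalized time.
#' @export
profile_to_time <- function(profile) {
  stopifnot(inherits(profile, "expression_profile"))
  if (profile$axis_mode != "frequency") stop("profile is not on the frequency axis")
  pts <- profile$points
  pts$x <- frequency_to_time(pmin(pmax(pts$x, 0), 1), "age_corrected")
  new_expression_profile(pts, channels = profile$channels,
                         axis_mode = "age_corrected_time")
}

#' Write a profile to CSV or JSON
#'
#' @param profile an [expression_profile].
#' @param path output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "expression_profile"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(axis_mode = profile$axis_mode,
                              channels = profile$channels,
                              points = profile$points),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    write.csv(profile$points, path, row.names = FALSE)
  }
  invisible(path)
}
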