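# 2-D geometry primitives for region gating. Point-in-polygon uses the
# even-odd rule with boundary points counted as inside (downstream
# assignment then tie-breaks shared edges toward the earlier region).

#' Point-in-polygon test (even-odd rule, boundary-inclusive)
#'
#' @param px,py point coordinates (vectors).
#' @param vx,vy polygon vertex coordinates (closed implicitly).
#' @param boundary `"inside"` counts boundary points as inside (default);
#'   `"outside"` excludes them (strict interior).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, vx, vy, boundary = c("inside", "outside")) {
  boundary <- match.arg(boundary)
  n <- length(vx)
  stopifnot(n >= 3, length(vy) == n, length(px) == length(py))
  span <- max(diff(range(vx)), diff(range(vy)))
  eps <- 1e-9 * max(span, 1e-300)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      inside <- xor(inside, crosses & (px < xint))
    }
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    seg_len <- abs(xj - xi) + abs(yj - yi)
    near <- abs(cross) <= eps * (seg_len + 1) &
      px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
      py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
    on_edge <- on_edge | near
    j <- i
  }
  if (boundary == "inside") inside | on_edge else inside & !on_edge
}

orient2d <- function(ax, ay, bx, by, cx, cy) {
  sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
}

# Proper (interior) crossing of segments a-b and c-d; shared endpoints and
# collinear touching do not count.
segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  o1 <- orient2d(ax, ay, bx, by, cx, cy)
  o2 <- orient2d(ax, ay, bx, by, dx, dy)
  o3 <- orient2d(cx, cy, dx, dy, ax, ay)
  o4 <- orient2d(cx, cy, dx, dy, bx, by)
  (o1 * o2 < 0) && (o3 * o4 < 0)
}

polygon_is_simple <- function(vx, vy) {
  n <- length(vx)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (they share a vertex)
      if (abs(i - j) <= 1 || (i == 1 && j == n)) next
      if (segments_cross(vx[idx[i, 1]], vy[idx[i, 1]], vx[idx[i, 2]], vy[idx[i, 2]],
                         vx[idx[j, 1]], vy[idx[j, 1]], vx[idx[j, 2]], vy[idx[j, 2]])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Signed polygon area (shoelace formula)
#'
#' @param vx,vy vertex coordinates.
#' @return signed area; positive for counter-clockwise vertex order.
#' @export
polygon_area <- function(vx, vy) {
  n <- length(vx)
  j <- c(seq_len(n)[-1], 1L)
  sum(vx * vy[j] - vx[j] * vy) / 2
}

# TRUE if two simple polygons share interior area (shared edges/vertices
# alone do not count): proper edge crossing, a vertex strictly inside the
# other polygon, or full containment (centroid strictly inside).
polygons_overlap <- function(ax, ay, bx, by) {
  na <- length(ax); nb <- length(bx)
  ia <- cbind(seq_len(na), c(seq_len(na)[-1], 1L))
  ib <- cbind(seq_len(nb), c(seq_len(nb)[-1], 1L))
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (segments_cross(ax[ia[i, 1]], ay[ia[i, 1]], ax[ia[i, 2]], ay[ia[i, 2]],
                         bx[ib[j, 1]], by[ib[j, 1]], bx[ib[j, 2]], by[ib[j, 2]])) {
        return(TRUE)
      }
    }
  }
  if (any(point_in_polygon(ax, ay, bx, by, boundary = "outside"))) return(TRUE)
  if (any(point_in_polygon(bx, by, ax, ay, boundary = "outside"))) return(TRUE)
  if (point_in_polygon(mean(ax), mean(ay), bx, by, boundary = "outside")) return(TRUE)
  if (point_in_polygon(mean(bx), mean(by), ax, ay, boundary = "outside")) return(TRUE)
  FALSE
}

#' Bivariate view specification
#'
#' Names the two channels of a bivariate plot and the display transform of
#' each axis. Segmentation geometry operates in display coordinates:
#' polygons are defined there and events are transformed before
#' point-in-polygon tests.
#'
#' @param x_channel,y_channel channel names.
#' @param trans_x,trans_y axis transforms: `"linear"`, `"log10"`
#'   (clamped at `1e-3`), or `"asinh"`.
#' @param cofactor asinh cofactor.
#' @param name view label; defaults to `"x~y"`.
#' @return an object of class `cyto_view`.
#' @export
make_view <- function(x_channel, y_channel, trans_x = "linear",
                      trans_y = "linear", cofactor = 5, name = NULL) {
  structure(list(x_channel = x_channel, y_channel = y_channel,
                 trans_x = trans_x, trans_y = trans_y, cofactor = cofactor,
                 name = name %||% paste0(x_channel, "~", y_channel)),
            class = "cyto_view")
}

apply_axis_transform <- function(v, trans, cofactor = 5) {
  switch(trans,
         linear = v,
         log10 = log10(pmax(v, 1e-3)),
         asinh = asinh(v / cofactor),
         stop("unknown axis transform '", trans, "'"))
}

# Event coordinates of a view in display space.
view_coords <- function(events, view) {
  list(x = apply_axis_transform(channel_values(events, view$x_channel),
                                view$trans_x, view$cofactor),
       y = apply_axis_transform(channel_values(events, view$y_channel),
                                view$trans_y, view$cofactor))
}
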