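# The "backbone": an ordered polyline tracing the modal path of the data
# through a bivariate view. Regions are later built perpendicular to it.

#' Backbone of a bivariate data trajectory
#'
#' @param view a [make_view()] specification.
#' @param anchors two-column matrix of ordered anchor points in display
#'   coordinates; at least two, with consecutive anchors distinct.
#' @return an object of class `backbone`.
#' @export
backbone <- function(view, anchors) {
  anchors <- as.matrix(anchors)
  stopifnot(ncol(anchors) == 2, nrow(anchors) >= 2)
  step <- sqrt(rowSums((anchors[-1, , drop = FALSE] -
                          anchors[-nrow(anchors), , drop = FALSE])^2))
  if (any(step == 0)) stop("consecutive backbone anchors must be distinct")
  structure(list(view = view, anchors = unname(anchors)), class = "backbone")
}

#' Trace the backbone of a bivariate view
#'
#' In manual mode (`anchors` supplied) the anchors are returned verbatim,
#' mirroring the usual cursor-driven workflow. Otherwise the ridge of a
#' smoothed 2-D histogram (128 x 128 kernel density, Silverman bandwidths)
#' is walked greedily from the global mode in both directions over cells
#' above `min_density_frac` of the peak, and ordered along increasing arc
#' length from the end nearest `start` (when given).
#'
#' @param events an [event_table()].
#' @param view a [make_view()].
#' @param anchors optional matrix of manual anchors (display coordinates).
#' @param start optional length-2 display-coordinate point marking the
#'   desired start end of the ridge.
#' @param grid density grid size.
#' @param min_density_frac ridge floor, as a fraction of the peak density.
#' @return a [backbone()].
#' @export
trace_backbone <- function(events, view, anchors = NULL, start = NULL,
                           grid = 128, min_density_frac = 0.05) {
  if (!is.null(anchors)) return(backbone(view, anchors))
  events <- as_event_table(events)
  if (n_events(events) < 1000) stop("need >= 1000 events in view to trace a backbone")
  co <- view_coords(events, view)
  bw <- c(MASS::bandwidth.nrd(co$x), MASS::bandwidth.nrd(co$y))
  if (any(bw <= 0)) stop("degenerate density; supply manual anchors")
  kd <- MASS::kde2d(co$x, co$y, h = bw, n = grid)
  ok <- kd$z >= min_density_frac * max(kd$z)
  mode_ij <- arrayInd(which.max(kd$z), dim(kd$z))

  walk <- function(from, visited) {
    path <- NULL
    cur <- from
    repeat {
      nbrs <- expand.grid(i = cur[1] + (-1):1, j = cur[2] + (-1):1)
      nbrs <- nbrs[nbrs$i >= 1 & nbrs$i <= grid & nbrs$j >= 1 & nbrs$j <= grid, ]
      nbrs <- nbrs[!(nbrs$i == cur[1] & nbrs$j == cur[2]), ]
      cand <- nbrs[ok[cbind(nbrs$i, nbrs$j)] & !visited[cbind(nbrs$i, nbrs$j)], ]
      if (!nrow(cand)) break
      pick <- cand[which.max(kd$z[cbind(cand$i, cand$j)]), ]
      cur <- c(pick$i, pick$j)
      visited[cur[1], cur[2]] <- TRUE
      # also block the immediate neighborhood behind us to avoid zig-zags
      path <- rbind(path, cur)
    }
    list(path = path, visited = visited)
  }

  visited <- matrix(FALSE, grid, grid)
  visited[mode_ij[1], mode_ij[2]] <- TRUE
  w1 <- walk(c(mode_ij), visited)
  w2 <- walk(c(mode_ij), w1$visited)
  idx <- rbind(if (!is.null(w1$path)) w1$path[rev(seq_len(nrow(w1$path))), , drop = FALSE],
               mode_ij,
               w2$path)
  if (nrow(idx) < 2) {
    stop("ridge tracing failed (disconnected or degenerate density); ",
         "supply manual anchors")
  }
  pts <- cbind(kd$x[idx[, 1]], kd$y[idx[, 2]])
  # mean-shift refinement: pull each grid-resolution ridge cell onto the
  # local density center (flat kernel, one bandwidth radius)
  h2 <- mean(bw)^2
  for (it in 1:3) {
    pts <- t(apply(pts, 1, function(p) {
      sel <- (co$x - p[1])^2 + (co$y - p[2])^2 <= h2
      if (sum(sel) >= 20) c(mean(co$x[sel]), mean(co$y[sel])) else p
    }))
  }
  # collapse anchors that converged onto the same center
  step <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  pts <- pts[c(TRUE, step > 1e-8 * (1 + mean(bw))), , drop = FALSE]
  if (nrow(pts) < 2) stop("ridge collapsed to a point; supply manual anchors")
  if (!is.null(start)) {
    d_head <- sum((pts[1, ] - start)^2)
    d_tail <- sum((pts[nrow(pts), ] - start)^2)
    if (d_tail < d_head) pts <- pts[rev(seq_len(nrow(pts))), ]
  }
  backbone(view, pts)
}

# Arc-length positions of backbone anchors and interpolation of cut points
# with unit tangents.
backbone_cuts <- function(bb, n_cuts) {
  a <- bb$anchors
  seg <- diff(a)
  len <- sqrt(rowSums(seg^2))
  s <- c(0, cumsum(len))
  target <- seq(0, s[length(s)], length.out = n_cuts)
  k <- findInterval(target, s, rightmost.closed = TRUE, all.inside = TRUE)
  frac <- (target - s[k]) / len[k]
  pts <- a[k, , drop = FALSE] + seg[k, , drop = FALSE] * frac
  tangents <- seg[k, , drop = FALSE] / len[k]
  # at interior anchor hits, average the two adjacent segment directions
  at_anchor <- which(abs(frac) < 1e-12 & k > 1)
  for (i in at_anchor) {
    t2 <- seg[k[i] - 1, ] / len[k[i] - 1] + seg[k[i], ] / len[k[i]]
    tangents[i, ] <- t2 / sqrt(sum(t2^2))
  }
  list(points = pts, tangents = tangents, arc = target)
}
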