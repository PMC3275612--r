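# Region schemes: globally ordered sequences of polygon regions, each bound
# to a bivariate view and a boolean gate context - the discretized "worm"
# through multiparameter space.

#' Polygon region of a segmentation scheme
#'
#' @param global_index order position within the scheme (unique).
#' @param view a [make_view()].
#' @param vertices two-column matrix of >= 3 ordered vertices in display
#'   coordinates; the polygon must be simple.
#' @param gate_context boolean formula over named gate masks selecting the
#'   events this region may claim (empty string = all events).
#' @return an object of class `polygon_region`.
#' @export
polygon_region <- function(global_index, view, vertices, gate_context = "") {
  vertices <- as.matrix(vertices)
  stopifnot(is_count(global_index), inherits(view, "cyto_view"),
            ncol(vertices) == 2, nrow(vertices) >= 3)
  if (!polygon_is_simple(vertices[, 1], vertices[, 2])) {
    stop("region ", global_index, ": polygon is self-intersecting")
  }
  structure(list(global_index = as.integer(global_index), view = view,
                 vertices = unname(vertices), gate_context = gate_context),
            class = "polygon_region")
}

rect_region <- function(global_index, view, xlim, ylim, gate_context = "") {
  polygon_region(global_index, view,
                 cbind(c(xlim[1], xlim[2], xlim[2], xlim[1]),
                       c(ylim[1], ylim[1], ylim[2], ylim[2])),
                 gate_context)
}

#' Region scheme: the ordered discretized trajectory
#'
#' @param regions list of [polygon_region()] ordered (or orderable) by
#'   `global_index`; indices must form a unique sequence.
#' @param description free text.
#' @return an object of class `region_scheme`.
#' @export
region_scheme <- function(regions, description = "") {
  stopifnot(length(regions) >= 1)
  idx <- vapply(regions, `[[`, integer(1), "global_index")
  if (anyDuplicated(idx)) stop("global_index values must be unique")
  regions <- regions[order(idx)]
  views <- list()
  for (r in regions) views[[r$view$name]] <- r$view
  structure(list(regions = regions, views = views, description = description),
            class = "region_scheme")
}

#' @export
print.region_scheme <- function(x, ...) {
  cat("region_scheme:", length(x$regions), "regions across",
      length(x$views), "view(s)\n")
  for (v in x$views) {
    n <- sum(vapply(x$regions, function(r) r$view$name == v$name, logical(1)))
    cat(sprintf("  %s [%s/%s]: %d regions\n", v$name, v$trans_x, v$trans_y, n))
  }
  invisible(x)
}

#' Build contiguous orthogonal regions along a backbone
#'
#' Divides a backbone into `n_regions` consecutive quadrilaterals whose
#' dividing sides are perpendicular to the local backbone tangent. Each
#' dividing side's two vertices are computed once and reused by both
#' neighboring regions, so shared edges coincide exactly and the band has
#' zero overlap and zero gap by construction.
#'
#' @param bb a [backbone()].
#' @param n_regions number of regions (>= 1).
#' @param half_width distance from the backbone to the band edge; a scalar
#'   or a vector of `n_regions + 1` per-cut values.
#' @param gate_context boolean gate formula applied to every region.
#' @param first_index global index of the first region.
#' @return list of [polygon_region()].
#' @export
build_orthogonal_regions <- function(bb, n_regions, half_width,
                                     gate_context = "", first_index = 1) {
  stopifnot(inherits(bb, "backbone"), is_count(n_regions))
  n_cuts <- n_regions + 1
  hw <- if (length(half_width) == 1) rep(half_width, n_cuts) else half_width
  if (length(hw) != n_cuts) {
    stop("half_width must be scalar or length n_regions + 1")
  }
  if (any(hw <= 0)) stop("half_width must be positive everywhere")
  cuts <- backbone_cuts(bb, n_cuts)
  normals <- cbind(-cuts$tangents[, 2], cuts$tangents[, 1])
  lo <- cuts$points - normals * hw
  hi <- cuts$points + normals * hw
  regions <- vector("list", n_regions)
  for (i in seq_len(n_regions)) {
    verts <- rbind(lo[i, ], hi[i, ], hi[i + 1, ], lo[i + 1, ])
    if (!polygon_is_simple(verts[, 1], verts[, 2])) {
      stop("regions ", i, " and ", i + 1, ": dividing sides cross at a ",
           "high-curvature point; use fewer regions or a narrower half_width")
    }
    regions[[i]] <- polygon_region(first_index + i - 1, bb$view, verts,
                                   gate_context)
  }
  regions
}

region_context_mask <- function(region, events) {
  eval_gate_expression(region$gate_context, events$masks, n_events(events))
}

#' Assign events to scheme regions
#'
#' Regions are tested in global order within each event's passing gate
#' context; the first containing polygon wins, which resolves shared-edge
#' ties deterministically toward the earlier region. Events contained by no
#' region are labeled `NA`.
#'
#' @param events an [event_table()] (with any masks referenced by region
#'   gate contexts attached).
#' @param scheme a [region_scheme()].
#' @return integer vector of per-event global region indices (`NA` =
#'   unassigned).
#' @export
assign_events <- function(events, scheme) {
  events <- as_event_table(events)
  stopifnot(inherits(scheme, "region_scheme"))
  n <- n_events(events)
  labels <- rep(NA_integer_, n)
  coords <- lapply(scheme$views, function(v) view_coords(events, v))
  for (r in scheme$regions) {
    open <- which(is.na(labels))
    if (!length(open)) break
    ctx <- region_context_mask(r, events)
    cand <- open[ctx[open]]
    if (!length(cand)) next
    co <- coords[[r$view$name]]
    inside <- point_in_polygon(co$x[cand], co$y[cand],
                               r$vertices[, 1], r$vertices[, 2])
    labels[cand[inside]] <- r$global_index
  }
  labels
}

#' Validate a region scheme against its construction rules
#'
#' Checks, per view, that no two regions share interior area (shared edges
#' are allowed); and, when events are supplied, reports the fraction of
#' gated events left unassigned and the per-region event counts. When a
#' per-event truth position `u` is supplied, the report also states whether
#' the median true position increases strictly with global index - the
#' computational analogue of verifying trajectory unidirectionality with a
#' pulse label.
#'
#' @param scheme a [region_scheme()].
#' @param events optional [event_table()].
#' @param truth optional numeric vector of per-event true normalized
#'   positions.
#' @param min_events warn threshold for events per region.
#' @return a list of class `scheme_validation`: `overlaps` (data frame of
#'   offending index pairs), `unassigned_fraction`, `region_counts`,
#'   `min_events_ok`, `monotone_u` (`NA` when truth not given), `ok`.
#' @export
validate_scheme <- function(scheme, events = NULL, truth = NULL,
                            min_events = 50) {
  stopifnot(inherits(scheme, "region_scheme"))
  overlaps <- data.frame(a = integer(), b = integer(), view = character())
  for (vname in names(scheme$views)) {
    rs <- Filter(function(r) r$view$name == vname, scheme$regions)
    if (length(rs) < 2) next
    for (i in seq_len(length(rs) - 1)) {
      for (j in (i + 1):length(rs)) {
        if (polygons_overlap(rs[[i]]$vertices[, 1], rs[[i]]$vertices[, 2],
                             rs[[j]]$vertices[, 1], rs[[j]]$vertices[, 2])) {
          overlaps <- rbind(overlaps,
                            data.frame(a = rs[[i]]$global_index,
                                       b = rs[[j]]$global_index,
                                       view = vname))
        }
      }
    }
  }
  unassigned_fraction <- NA_real_
  region_counts <- NULL
  monotone_u <- NA
  min_events_ok <- NA
  if (!is.null(events)) {
    events <- as_event_table(events)
    labels <- assign_events(events, scheme)
    gated <- Reduce(`|`, lapply(scheme$regions, region_context_mask,
                                events = events))
    unassigned_fraction <- sum(is.na(labels) & gated) / max(sum(gated), 1)
    idx <- vapply(scheme$regions, `[[`, integer(1), "global_index")
    region_counts <- setNames(vapply(idx, function(k) sum(labels == k, na.rm = TRUE),
                                     numeric(1)), idx)
    min_events_ok <- all(region_counts >= min_events)
    if (!min_events_ok) {
      warning("regions below ", min_events, " events: ",
              paste(names(region_counts)[region_counts < min_events],
                    collapse = ", "))
    }
    if (!is.null(truth)) {
      med_u <- vapply(idx, function(k) {
        median(truth[which(labels == k)])
      }, numeric(1))
      monotone_u <- !is.unsorted(med_u, strictly = TRUE) && !anyNA(med_u)
      attr(monotone_u, "median_u") <- setNames(med_u, idx)
    }
  }
  structure(list(overlaps = overlaps,
                 unassigned_fraction = unassigned_fraction,
                 region_counts = region_counts,
                 min_events_ok = min_events_ok,
                 monotone_u = monotone_u,
                 ok = nrow(overlaps) == 0),
            class = "scheme_validation")
}

#' @export
print.scheme_validation <- function(x, ...) {
  cat("scheme validation:", if (x$ok) "no overlaps" else
    paste(nrow(x$overlaps), "overlapping pair(s)"), "\n")
  if (!is.na(x$unassigned_fraction)) {
    cat(sprintf("  unassigned fraction: %.4f\n", x$unassigned_fraction))
  }
  if (!is.na(x$min_events_ok)) cat("  min events ok:", x$min_events_ok, "\n")
  if (!is.na(x$monotone_u)) cat("  median u strictly increasing:", x$monotone_u, "\n")
  invisible(x)
}

#' Read and write region schemes as JSON
#'
#' Serializes views (channel names and transforms), per-region vertex
#' arrays, gate-context formulas and the global order; the format is plain
#' JSON so vertex tables can be edited externally and re-imported.
#'
#' @param scheme a [region_scheme()].
#' @param path file path.
#' @return `read_scheme` returns a [region_scheme()]; `write_scheme`
#'   returns `path` invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "region_scheme"))
  obj <- list(
    description = scheme$description,
    views = lapply(scheme$views, function(v) {
      v[c("x_channel", "y_channel", "trans_x", "trans_y", "cofactor", "name")]
    }),
    regions = lapply(scheme$regions, function(r) {
      list(global_index = r$global_index, view = r$view$name,
           gate_context = r$gate_context,
           vertices = unname(apply(r$vertices, 1, as.numeric, simplify = FALSE)))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  obj <- jsonlite::read_json(path)
  views <- lapply(obj$views, function(v) {
    make_view(v$x_channel, v$y_channel, v$trans_x, v$trans_y, v$cofactor, v$name)
  })
  names(views) <- vapply(views, `[[`, character(1), "name")
  regions <- lapply(obj$regions, function(r) {
    verts <- do.call(rbind, lapply(r$vertices, unlist))
    polygon_region(r$global_index, views[[r$view]], verts,
                   r$gate_context %||% "")
  })
  region_scheme(regions, description = obj$description %||% "")
}
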