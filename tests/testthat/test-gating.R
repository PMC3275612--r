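# Polygon gating: geometry primitives, backbone tracing, orthogonal region
# construction, scheme validation and event assignment.

test_that("point-in-polygon follows the even-odd rule with inclusive boundary", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_true(point_in_polygon(0.5, 0.5, sq[, 1], sq[, 2]))
  expect_false(point_in_polygon(1.5, 0.5, sq[, 1], sq[, 2]))
  expect_true(point_in_polygon(1, 0.5, sq[, 1], sq[, 2]))    # on an edge
  expect_true(point_in_polygon(0, 0, sq[, 1], sq[, 2]))      # on a vertex
  expect_false(point_in_polygon(1, 0.5, sq[, 1], sq[, 2], boundary = "outside"))
  # concave L-shape: the notch is outside, both arms inside
  cc <- cbind(c(0, 4, 4, 2, 2, 0), c(0, 0, 4, 4, 2, 2))
  expect_true(point_in_polygon(3, 3.9, cc[, 1], cc[, 2]))
  expect_false(point_in_polygon(1, 3, cc[, 1], cc[, 2]))
  expect_true(point_in_polygon(1, 1, cc[, 1], cc[, 2]))
})

test_that("manual anchors are returned verbatim and lines trace straight", {
  v <- make_view("a", "b")
  anchors <- cbind(c(0, 1, 2), c(0, 1.5, 2))
  ev <- event_table(data.frame(a = runif(1500), b = runif(1500)))
  bb <- trace_backbone(ev, v, anchors = anchors)
  expect_equal(bb$anchors, unname(anchors))

  xy <- data.frame(a = seq(0, 10, length.out = 5000),
                   b = seq(0, 10, length.out = 5000))
  bb2 <- trace_backbone(event_table(xy), v)
  expect_lt(max(abs(bb2$anchors[, 2] - bb2$anchors[, 1])), 0.05)
})

test_that("the traced ridge of a synthetic worm stays within one local sd", {
  m <- default_model()
  pop <- pop50k()
  keep <- pop$truth$u < 0.92   # interphase arm: PHH3 flat, cyclin rising
  ev <- event_table(pop$events$data[keep, ])
  bb <- trace_backbone(ev, make_view("cyclin_a2", "phh3"), start = c(0, 2))
  # true noiseless curve: phh3 = 2 along the whole arm; local sd = cv * 2
  expect_lt(max(abs(bb$anchors[, 2] - 2)), 1 * default_model()$noise_cv[["phh3"]] * 2)
})

test_that("orthogonal regions have perpendicular dividing sides", {
  v <- make_view("a", "b")
  horiz <- backbone(v, cbind(c(0, 10), c(0, 0)))
  regs <- build_orthogonal_regions(horiz, 5, half_width = 1)
  for (r in regs) {
    # dividing sides are vertical: first and second vertex share x
    expect_equal(r$vertices[1, 1], r$vertices[2, 1])
    expect_equal(r$vertices[3, 1], r$vertices[4, 1])
  }
  diag45 <- backbone(v, cbind(c(0, 10), c(0, 10)))
  regs45 <- build_orthogonal_regions(diag45, 4, half_width = 1)
  areas <- vapply(regs45, function(r) abs(polygon_area(r$vertices[, 1], r$vertices[, 2])),
                  numeric(1))
  expect_true(all(abs(areas - areas[1]) < 1e-9))  # congruent regions
  # dividing sides at -45 degrees: direction (1, -1) up to scale
  d <- regs45[[2]]$vertices[2, ] - regs45[[2]]$vertices[1, ]
  expect_equal(d[1] / d[2], -1)
})

test_that("orthogonal bands on a semicircle have zero overlap and zero gap", {
  th <- seq(0, pi, length.out = 81)
  bb <- backbone(make_view("a", "b"), cbind(cos(th), sin(th)))
  regs <- build_orthogonal_regions(bb, 10, half_width = 0.2)
  polys <- lapply(regs, `[[`, "vertices")
  # independent clipping oracle: pairwise intersection areas are zero
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_lt(clip_area(polys[[i]], polys[[j]]), 1e-10)
    }
  }
  # zero gap: region areas tile the band (sum of areas = area of the hull
  # swept by the cuts, computed independently from the cut vertices)
  areas <- vapply(polys, shoelace, numeric(1))
  # build the band outline: inner edge forward, outer edge backward
  inner <- do.call(rbind, lapply(polys, function(p) p[1, , drop = FALSE]))
  outer <- do.call(rbind, lapply(polys, function(p) p[2, , drop = FALSE]))
  inner <- rbind(inner, polys[[10]][4, , drop = FALSE])
  outer <- rbind(outer, polys[[10]][3, , drop = FALSE])
  outline <- rbind(inner, outer[nrow(outer):1, , drop = FALSE])
  expect_equal(sum(areas), shoelace(outline), tolerance = 1e-9)
  # half-width beyond the curvature radius makes dividing sides cross
  expect_error(build_orthogonal_regions(bb, 20, half_width = 1.2), "narrower")
})

test_that("validate_scheme flags overlaps and certifies shared edges", {
  th <- seq(0, pi / 2, length.out = 41)
  bb <- backbone(make_view("a", "b"), cbind(cos(th), sin(th)))
  regs <- build_orthogonal_regions(bb, 6, half_width = 0.15)
  val <- validate_scheme(region_scheme(regs))
  expect_true(val$ok)
  expect_equal(nrow(val$overlaps), 0)
  # deliberately shift one region: overlap flagged
  regs[[3]]$vertices <- regs[[3]]$vertices + 0.02
  val2 <- validate_scheme(region_scheme(regs))
  expect_gte(nrow(val2$overlaps), 1)
})

test_that("assignment is first-match in global order with edge tie-breaks", {
  v <- make_view("a", "b")
  r1 <- polygon_region(1, v, cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  r2 <- polygon_region(2, v, cbind(c(1, 2, 2, 1), c(0, 0, 1, 1)))
  ev <- event_table(data.frame(a = c(0.5, 1.0, 1.5, 3.0), b = rep(0.5, 4)))
  lab <- assign_events(ev, region_scheme(list(r1, r2)))
  expect_identical(lab, c(1L, 1L, 2L, NA_integer_))   # shared edge -> earlier
  # conservation: assigned counts + unassigned = total
  expect_equal(sum(!is.na(lab)) + sum(is.na(lab)), n_events(ev))
})

test_that("reference scheme orders regions along true cell-cycle time", {
  res <- panel50k()
  pop <- pop50k()
  val <- suppressWarnings(validate_scheme(res$scheme, res$events,
                                          truth = pop$truth$u))
  expect_true(val$ok)
  expect_true(val$monotone_u)
  expect_lt(val$unassigned_fraction, 0.01)
  med <- attr(val$monotone_u, "median_u")
  expect_false(is.unsorted(med, strictly = TRUE))
  # gate contexts split the views: every region belongs to a known view
  expect_setequal(unique(vapply(res$scheme$regions, function(r) r$view$name,
                                character(1))),
                  names(res$scheme$views))
})

test_that("schemes survive a JSON round trip", {
  scheme <- build_reference_scheme(default_model(), "cyclin_a2")
  path <- tempfile(fileext = ".json")
  write_scheme(scheme, path)
  back <- read_scheme(path)
  expect_equal(length(back$regions), length(scheme$regions))
  for (i in seq_along(scheme$regions)) {
    expect_equal(back$regions[[i]]$vertices, scheme$regions[[i]]$vertices)
    expect_equal(back$regions[[i]]$gate_context, scheme$regions[[i]]$gate_context)
    expect_equal(back$regions[[i]]$view$name, scheme$regions[[i]]$view$name)
  }
})
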