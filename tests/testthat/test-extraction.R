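# Profile extraction, boundary points, replicates, panel merging, and the
# frequency/time axis.

test_that("extract_profile centers each segment in its frequency interval", {
  ev <- event_table(data.frame(y = c(rep(1, 60), rep(5, 40))))
  one <- extract_profile(ev, rep(1L, 100), "y")
  expect_equal(one$points$x, 0.5)
  expect_equal(one$points$y, median(ev$data$y))

  two <- extract_profile(ev, rep(c(1L, 2L), each = 50), "y")
  expect_equal(two$points$x, c(0.25, 0.75))

  lab <- c(rep(1L, 60), rep(2L, 25), rep(3L, 15))
  ev2 <- event_table(data.frame(y = c(rep(2, 60), rep(4, 25), rep(8, 15))))
  prof <- extract_profile(ev2, lab, "y")
  # first segment holds 60%: plotted at x = 0.30; centering rule holds
  expect_equal(prof$points$x, c(0.30, 0.725, 0.925))
  expect_equal(prof$points$y, c(2, 4, 8))
  # frequency conservation
  f <- prof$points$count / sum(prof$points$count)
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_equal(prof$points$x, cumsum(f) - f / 2, tolerance = 1e-12)

  expect_warning(extract_profile(ev2, lab, "y", expected_regions = 1:4),
                 "empty segment")
  # unassigned events are excluded from frequency bookkeeping
  lab_na <- lab; lab_na[1:10] <- NA
  prof_na <- extract_profile(ev2, lab_na, "y")
  expect_equal(sum(prof_na$points$count), 90)
})

test_that("early-region boundary perturbations propagate as bookkeeping says", {
  n <- 1000
  ev <- event_table(data.frame(y = rnorm(n)))
  lab <- rep(1:5, times = c(400, 200, 150, 150, 100))
  base <- extract_profile(ev, lab, "y")
  # move the segment-1/2 boundary so delta of mass changes hands: the two
  # adjoining points shift by exactly delta/2, later points are untouched
  delta <- 50 / n
  lab2 <- lab; lab2[351:400] <- 2L
  pert <- extract_profile(ev, lab2, "y")
  expect_equal(pert$points$x[1] - base$points$x[1], -delta / 2)
  expect_equal(pert$points$x[2] - base$points$x[2], -delta / 2)
  expect_equal(pert$points$x[3:5], base$points$x[3:5])
  # dropping mass from the first segment shifts every downstream point by
  # the same exact bookkeeping factor delta * (1 - x) / (1 - delta)
  lab3 <- lab; lab3[1:50] <- NA
  drop <- extract_profile(ev, lab3, "y")
  shift <- drop$points$x[2:5] - base$points$x[2:5]
  expect_equal(shift, -delta * (1 - base$points$x[2:5]) / (1 - delta),
               tolerance = 1e-12)
})

test_that("boundary points extend stretches by linear extrapolation", {
  # flat profile: boundary points equal the plateau value
  pts <- data.frame(x = c(0.2, 0.5, 0.8), count = c(200L, 300L, 300L),
                    synthetic = FALSE, y = c(3, 3, 3))
  flat <- insert_boundary_points(new_expression_profile(pts, "y"))
  expect_true(all(flat$points$y == 3))
  expect_setequal(flat$points$x[flat$points$synthetic], c(0, 1))

  # exact linear stretch: the extrapolated endpoints lie on the line
  xs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  lin <- new_expression_profile(
    data.frame(x = xs, count = 200L, synthetic = FALSE, y = 2 + 10 * xs), "y")
  ext <- insert_boundary_points(lin)
  expect_equal(ext$points$y[ext$points$x == 0], 2)
  expect_equal(ext$points$y[ext$points$x == 1], 12)

  # plateau/ramp/plateau from the eight-component DNA mixture: the inserted
  # G1/S boundary point stays within 1% of the true 2C value
  h <- fig2_sample()
  seg <- segment_histogram_1d(h$values, mixture_boundaries(h$mixture))
  aug <- suppressWarnings(insert_boundary_points(seg, c(1, 8)))
  xb <- seg$points$x[1] + seg$points$count[1] / sum(seg$points$count) / 2
  yb <- aug$points$dna[aug$points$synthetic & abs(aug$points$x - xb) < 1e-9]
  expect_true(all(abs(yb[1] - 100) / 100 < 0.01))

  expect_error(insert_boundary_points(lin, transition_indices = 9), "between")
})

test_that("frequency_to_time inverts the exponential-growth age CDF", {
  expect_identical(frequency_to_time(c(0, 0.5, 1), "identity"), c(0, 0.5, 1))
  expect_equal(frequency_to_time(0, "age_corrected"), 0)
  expect_equal(frequency_to_time(1, "age_corrected"), 1)
  # numeric-inversion oracle: solve integral(2 ln2 2^-a) da = x for t
  oracle <- function(x) {
    uniroot(function(t) {
      stats::integrate(function(a) 2 * log(2) * 2^(-a), 0, t)$value - x
    }, c(0, 1), tol = 1e-12)$root
  }
  for (x in c(0.1, 0.5, 0.9)) {
    expect_equal(frequency_to_time(x, "age_corrected"), oracle(x),
                 tolerance = 1e-9)
  }
  expect_equal(frequency_to_time(0.5, "age_corrected"), 0.41504,
               tolerance = 1e-5)
  expect_error(frequency_to_time(1.2, "age_corrected"), "0, 1")
})

test_that("replicate combination averages points and propagates dispersion", {
  mk <- function(y) new_expression_profile(
    data.frame(x = c(0.25, 0.75), count = 500L, synthetic = FALSE, y = y), "y")
  same <- combine_replicates(list(mk(c(1, 2)), mk(c(1, 2)), mk(c(1, 2))))
  expect_equal(same$points$y_sem, c(0, 0))
  d <- 0.6
  three <- combine_replicates(list(mk(c(5, 1)), mk(c(5 + d, 1)), mk(c(5 - d, 1))))
  expect_equal(three$points$y[1], 5)
  expect_equal(three$points$y_sem[1], d / sqrt(3))
  expect_equal(three$points$y_ci95[1], qt(0.975, 2) * d / sqrt(3))
  expect_error(combine_replicates(list(mk(c(1, 2)),
    new_expression_profile(data.frame(x = 0.5, count = 10L, synthetic = FALSE,
                                      y = 1), "y"))),
    "matching point counts")

  # three independent syntheses of the eight-component histogram: the
  # combined G1 plateau CI covers the true 2C value
  profs <- lapply(1:3, function(k) {
    h <- sample_histogram(fig2_mixture(), 50000, seed = 400 + k)
    segment_histogram_1d(h$values, mixture_boundaries(h$mixture))
  })
  comb <- combine_replicates(profs)
  expect_lte(abs(comb$points$dna[1] - 100), comb$points$dna_ci95[1] + 0.05)
})

test_that("panel merging reports shared-channel deviation without warping", {
  res <- panel50k()
  self <- merge_panels(res$profile, res$profile, "phh3")
  expect_equal(self$report$max_abs_deviation, 0)
  shifted <- res$profile
  shifted$points$phh3 <- shifted$points$phh3 + 2.5
  shift <- merge_panels(res$profile, shifted, "phh3")
  expect_equal(shift$report$max_abs_deviation, 2.5)
  # x axes are returned unchanged (no warping)
  expect_identical(shift$profiles$a$points$x, res$profile$points$x)
  timep <- profile_to_time(res$profile)
  expect_error(merge_panels(res$profile, timep, "phh3"), "axis modes")
  expect_error(merge_panels(res$profile, res$profile, "nope"), "missing")
})

test_that("joining profiles increases data density in sorted order", {
  res <- panel50k()
  p <- res$profile
  expect_identical(join_profiles(list(p)), p)
  q <- p
  q$points$x <- pmin(q$points$x + 0.013, 1)
  j <- join_profiles(list(p, q))
  expect_equal(nrow(j$points), 2 * nrow(p$points))
  expect_false(is.unsorted(j$points$x))
  # more points in the mitotic window than either input
  win <- function(pr) sum(pr$points$x > 0.96)
  expect_gt(win(j), max(win(p), win(q)))
})

test_that("profiles convert to age-corrected time and export to disk", {
  res <- panel50k()
  tp <- profile_to_time(res$profile)
  expect_equal(tp$axis_mode, "age_corrected_time")
  expect_true(all(tp$points$x <= res$profile$points$x + 1e-12))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_profile(res$profile, csv)
  write_profile(res$profile, js)
  back <- read.csv(csv)
  expect_equal(back$x, res$profile$points$x)
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE)$axis_mode,
               "frequency")
})
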