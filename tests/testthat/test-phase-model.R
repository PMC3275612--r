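# Phase model, programmed curves, and population sampling.

test_that("phase_model enforces its invariants", {
  expect_error(phase_model(phase_fractions = c(G1 = 0.5, S = 0.3, G2 = 0.3, M = 0.1)),
               "sum to 1")
  expect_error(phase_model(dna_levels = c(200, 300)), "twice")
  m <- default_model()
  expect_equal(sum(m$phase_fractions), 1)
  expect_equal(m$dna_levels[2], 2 * m$dna_levels[1])
})

test_that("default curves encode the degradation order A2 < B1 < PHH3", {
  flo <- marker_floors(default_model())
  expect_true(flo[["cyclin_a2"]] < flo[["cyclin_b1"]])
  expect_true(flo[["cyclin_b1"]] < flo[["phh3"]])
  expect_true(all(flo[c("cyclin_a2", "cyclin_b1", "phh3")] < 1))
})

test_that("ground_truth_profile follows the extraction axis convention", {
  m <- default_model()
  # DNA: plateau, linear rise, plateau with plateau ratio exactly 2
  g <- ground_truth_profile(m, "dna", 500)
  expect_equal(max(g$points$dna) / min(g$points$dna), 2)
  b <- cumsum(m$phase_fractions)
  in_g1 <- g$points$x < age_cdf(b[["G1"]] - 1e-6)
  in_g2 <- g$points$x > age_cdf(b[["S"]]) & g$points$x < age_cdf(b[["G2"]])
  expect_true(all(g$points$dna[in_g1] == m$dna_levels[1]))
  expect_true(all(g$points$dna[in_g2] == m$dna_levels[2]))
  # cyclin A2 is zero through G1 and rises from the G1/S boundary on
  a2 <- ground_truth_profile(m, "cyclin_a2", 500)
  expect_true(all(a2$points$cyclin_a2[in_g1] == 0))
  after <- a2$points$x > age_cdf(b[["G1"]] + 0.02) & a2$points$x < age_cdf(0.9)
  expect_true(all(diff(a2$points$cyclin_a2[after]) > 0))
  # a constant curve gives a flat profile at that constant
  flat <- phase_model(marker_curves = list(k = {
    f <- function(u) rep(7, length(u)); attr(f, "floor_u") <- NA_real_; f
  }))
  expect_true(all(ground_truth_profile(flat, "k", 50)$points$k == 7))
  # uniform axis mode returns u itself
  gu <- ground_truth_profile(m, "dna", 100, age_weighted = FALSE)
  expect_equal(gu$points$x, ((1:100) - 0.5) / 100)
})

test_that("zero-noise populations lie exactly on the marker curves", {
  m0 <- phase_model(noise_cv = c(dna = 0, dna_width = 0, cyclin_a2 = 0,
                                 cyclin_b1 = 0, phh3 = 0, ssc = 0))
  pop <- sample_population(m0, 2000, seed = 3)
  for (ch in channels(pop$events)) {
    expect_equal(pop$events$data[[ch]], m0$marker_curves[[ch]](pop$truth$u))
  }
})

test_that("sampled age distribution matches the analytic density", {
  pop <- sample_population(default_model(), 100000, seed = 11)
  # age-weighted: P(u < 0.5) = 2(1 - 2^(-1/2)) ~ 0.5858
  expect_lt(abs(mean(pop$truth$u < 0.5) - 2 * (1 - 2^-0.5)), 0.005)
  unif <- sample_population(default_model(), 100000, seed = 12,
                            age_weighted = FALSE)
  expect_lt(abs(mean(unif$truth$u < 0.5) - 0.5), 0.005)
})

test_that("phase occupancies match the age-density integrals within 3 binomial sd", {
  m <- default_model()
  pop <- pop50k()
  b <- c(0, cumsum(m$phase_fractions))
  n <- nrow(pop$truth)
  for (i in seq_len(4)) {
    p_exp <- age_cdf(b[i + 1]) - age_cdf(b[i])
    p_obs <- mean(pop$truth$phase == names(m$phase_fractions)[i])
    expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
  }
})

test_that("phase model serializes to JSON and back", {
  m <- phase_model(phase_fractions = c(G1 = 0.4, S = 0.35, G2 = 0.19, M = 0.06),
                   dna_levels = c(100, 200),
                   background_slope = c(cyclin_a2 = 0.02))
  path <- withr::local_tempfile(fileext = ".json")
  write_phase_model(m, path)
  m2 <- read_phase_model(path)
  expect_equal(m2$phase_fractions, m$phase_fractions)
  expect_equal(m2$dna_levels, m$dna_levels)
  expect_equal(m2$background_slope, m$background_slope)
  u <- seq(0, 0.999, length.out = 200)
  for (ch in names(m$marker_curves)) {
    expect_equal(m2$marker_curves[[ch]](u), m$marker_curves[[ch]](u))
  }
  expect_error(write_phase_model(
    phase_model(marker_curves = list(k = function(u) u)), path),
    "custom")
})

test_that("contaminant events are labeled and interleaved", {
  pop <- sample_population(default_model(), 5000, seed = 9,
                           contaminant_fraction = 0.1)
  expect_equal(sum(pop$truth$contaminant), 500)
  expect_equal(nrow(pop$truth), n_events(pop$events))
  expect_true(all(is.na(pop$truth$u[pop$truth$contaminant])))
  expect_false(anyNA(pop$events$data))
})
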