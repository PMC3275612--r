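# DNA-histogram mixture synthesis and sampling.

test_that("make_dna_mixture builds the eight-component histogram model", {
  mix <- fig2_mixture()
  expect_length(mix$mean, 8)
  expect_equal(sum(mix$area), 1)
  expect_equal(mix$area[mix$label == "G1"], 0.60)
  expect_equal(sum(mix$area[mix$label == "S"]), 0.30)
  expect_equal(mix$area[mix$label == "G2M"], 0.10)
  expect_equal(mix$mean[mix$label == "G1"], 100)
  expect_equal(mix$mean[mix$label == "G2M"], 200)
  # S components evenly spaced strictly inside, equal areas, interpolated sd
  s <- which(mix$label == "S")
  expect_equal(mix$mean[s], 100 + (1:6) / 7 * 100)
  expect_true(all(abs(mix$area[s] - 0.05) < 1e-12))
  expect_equal(mix$sd[s], 3 + (mix$mean[s] - 100) / 100 * 3)
})

test_that("the 4C/2C mean ratio is 2 for any valid input", {
  for (g1 in c(50, 100, 250)) {
    mix <- make_dna_mixture(0.5, 0.4, 0.1, g1_mean = g1, cv = 0.05,
                            n_s_components = 3)
    expect_equal(mix$mean[mix$label == "G2M"] / mix$mean[mix$label == "G1"], 2)
  }
})

test_that("make_dna_mixture validates its contract", {
  expect_error(make_dna_mixture(0.7, 0.2, 0.2), "sum to 1")
  expect_error(make_dna_mixture(1.0, 0.0, 0.0), "strictly positive")
  expect_error(make_dna_mixture(0.6, 0.3, 0.1, n_s_components = 0), "positive integer")
  expect_error(make_dna_mixture(0.6, 0.3, 0.1, cv = 0.5), "cv")
})

test_that("sample_histogram draws from the mixture reproducibly", {
  one <- gaussian_mixture(list(gaussian_component(100, 3, 1, "G1")))
  h <- sample_histogram(one, 10000, seed = 7)
  # CLT bound on the sample mean
  expect_lt(abs(mean(h$values) - 100), 3 * 3 / sqrt(10000))

  h2 <- fig2_sample()
  # binomial oracle on the component-choice indicator: the fraction of
  # events drawn from the G1 component is 0.60 +/- 3 binomial sd (~0.0066)
  g1_frac <- mean(h2$component == which(h2$mixture$label == "G1"))
  expect_lt(abs(g1_frac - 0.60), 0.01)

  h3 <- sample_histogram(fig2_mixture(), 50000, seed = 1)
  expect_identical(h3$counts, h2$counts)
  expect_identical(h3$values, h2$values)

  expect_warning(sample_histogram(one, 999, seed = 1), "recovery")
})

test_that("mixture_boundaries places terminal boundaries by either rule", {
  mix <- fig2_mixture()
  b_sd <- mixture_boundaries(mix, 9, rule = "sd", k = 3)
  expect_length(b_sd, 8)
  expect_equal(b_sd[1], 100 + 3 * 3)
  expect_equal(b_sd[8], 200 - 3 * 6)
  b_cr <- mixture_boundaries(mix, 9, rule = "crossing")
  # crossing points balance misclassification: the mixture density of the
  # bounding component equals that of its nearest S neighbor there
  d_g1 <- 0.60 * dnorm(b_cr[1], 100, 3)
  d_s1 <- 0.05 * dnorm(b_cr[1], 100 + 100 / 7, 3 + 3 / 7)
  expect_equal(d_g1, d_s1, tolerance = 1e-6)
  expect_true(all(diff(b_cr) > 0))
})

test_that("mixture density and CDF are coherent", {
  mix <- fig2_mixture()
  xs <- seq(50, 260, length.out = 11)
  num_cdf <- vapply(xs, function(q) {
    stats::integrate(dmixture, -Inf, q, mixture = mix, rel.tol = 1e-9)$value
  }, numeric(1))
  expect_equal(pmixture(xs, mix), num_cdf, tolerance = 1e-6)
})
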