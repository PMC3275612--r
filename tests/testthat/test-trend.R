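# Piecewise polynomial/exponential fits of cyclin accumulation.

profile_of <- function(x, y) {
  new_expression_profile(data.frame(x = x, count = 100L, synthetic = FALSE,
                                    y = y), "y")
}

test_that("exact functional forms are recovered to numerical precision", {
  x <- seq(0.38, 0.70, length.out = 9)
  fp <- fit_piecewise(profile_of(x, 1 + 2 * x + 3 * x^2), "y",
                      list(list(form = "poly2", domain = c(0.38, 0.70))))[[1]]
  expect_equal(unname(fp$coefficients), c(1, 2, 3), tolerance = 1e-9)
  expect_equal(fp$r_squared, 1)

  x2 <- seq(0.1, 0.9, length.out = 12)
  fe <- fit_piecewise(profile_of(x2, 0.5 * exp(4 * x2)), "y",
                      list(list(form = "exponential", domain = c(0.1, 0.9))))[[1]]
  expect_equal(unname(fe$coefficients), c(0.5, 4), tolerance = 1e-6)
  # on exact data the nonlinear fit matches the log-linear closed form
  ll <- lm(log(0.5 * exp(4 * x2)) ~ x2)
  expect_equal(unname(fe$coefficients),
               c(exp(coef(ll)[[1]]), coef(ll)[[2]]), tolerance = 1e-6)

  expect_error(fit_piecewise(profile_of(x, x), "y",
                             list(list(form = "poly2", domain = c(0.9, 0.95)))),
               "fewer than 3")
})

test_that("poly2 residuals are orthogonal to the design columns", {
  set.seed(5)
  x <- seq(0.2, 0.8, length.out = 25)
  y <- 2 - x + 5 * x^2 + rnorm(25, 0, 0.3)
  f <- fit_piecewise(profile_of(x, y), "y",
                     list(list(form = "poly2", domain = c(0.2, 0.8))))[[1]]
  r <- y - f$predict(x)
  for (col in list(rep(1, 25), x, x^2)) {
    expect_lt(abs(sum(r * col)), 1e-8)
  }
})

test_that("synthetic cyclin profiles show two-phase accumulation", {
  res_a2 <- panel50k()
  res_b1 <- memo("panel_b1_trend", {
    extract_panel(pop50k(), default_model(), "cyclin_b1",
                  channels = c("dna", "cyclin_b1", "phh3"))
  })
  fits_b1 <- fit_piecewise(res_b1$profile, "cyclin_b1",
                           list(list(form = "exponential", domain = c(0.32, 0.79)),
                                list(form = "exponential", domain = c(0.79, 0.95))))
  k1 <- fits_b1[[1]]$coefficients[["k"]]
  k2 <- fits_b1[[2]]$coefficients[["k"]]
  expect_gt(k2, k1)                       # early slow rate, late fast rate

  fits_a2 <- fit_piecewise(res_a2$profile, "cyclin_a2",
                           list(list(form = "poly2", domain = c(0.38, 0.70)),
                                list(form = "exponential", domain = c(0.70, 0.95))))
  cmp <- compare_rates(fits_a2, fits_b1)
  expect_false(cmp$equal_ratios)
  expect_equal(cmp$larger_ratio, "cyclin_b1")   # B1 more exponential
  expect_equal(cmp$onset_order[1], "cyclin_b1") # B1 accumulates earlier
  expect_lt(cmp$onset[["cyclin_b1"]], cmp$onset[["cyclin_a2"]])

  # identical fits are flagged as rate-equal
  same <- compare_rates(fits_a2, fits_a2, labels = c("a", "b"))
  expect_true(same$equal_ratios)
})
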