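# Preprocessing gates and the boolean gate algebra.

make_singlet_fixture <- function(n = 20000, doublet_frac = 0.1, seed = 21) {
  set.seed(seed)
  n_d <- round(n * doublet_frac)
  width <- c(rnorm(n - n_d, 50, 2.5), rnorm(n_d, 100, 5))
  dna <- c(exp(rnorm(n - n_d, log(250), 0.25)), exp(rnorm(n_d, log(500), 0.25)))
  list(events = event_table(data.frame(dna_width = width, dna = dna)),
       doublet = c(rep(FALSE, n - n_d), rep(TRUE, n_d)))
}

test_that("singlet gate keeps singlets and rejects doublets", {
  fx <- make_singlet_fixture(doublet_frac = 0)
  r2 <- singlet_gate(fx$events, "dna_width", "dna", level = 99)
  expect_gte(mean(r2$mask), 0.98)

  fx <- make_singlet_fixture(doublet_frac = 0.1)
  r2 <- singlet_gate(fx$events, "dna_width", "dna", level = 99)
  expect_lt(mean(r2$mask[fx$doublet]), 0.01)
  expect_gte(mean(r2$mask[!fx$doublet]), 0.97)
})

test_that("contour gates validate level and input size", {
  fx <- make_singlet_fixture(n = 1000, doublet_frac = 0)
  expect_error(singlet_gate(fx$events, "dna_width", "dna", level = 100),
               "between 0 and 100")
  expect_error(singlet_gate(fx$events, "dna_width", "dna", level = 0),
               "between 0 and 100")
  small <- event_table(data.frame(dna_width = rnorm(100, 50, 2),
                                  dna = rnorm(100, 250, 10)))
  expect_error(singlet_gate(small, "dna_width", "dna"), "too few events")
})

test_that("mitotic gate finds the inter-mode threshold", {
  set.seed(4)
  n <- 20000; n_m <- 800  # 4% mitotic at 20x baseline
  phh3 <- c(2 * exp(rnorm(n - n_m, 0, 0.15)), 40 * exp(rnorm(n_m, 0, 0.15)))
  ev <- event_table(data.frame(phh3 = phh3))
  r3 <- mitotic_gate(ev, "phh3")
  expect_lt(abs(mean(r3$mask) - 0.04), 0.005)

  # all-interphase input: empty mask with a warning
  ev2 <- event_table(data.frame(phh3 = 2 * exp(rnorm(5000, 0, 0.15))))
  expect_warning(r3b <- mitotic_gate(ev2, "phh3"), "unimodal")
  expect_equal(sum(r3b$mask), 0)

  # manual override: threshold 0 flags everything
  r3c <- mitotic_gate(ev, "phh3", threshold = 0)
  expect_true(all(r3c$mask))
})

test_that("background subtraction recovers the scatter slope", {
  # exact noiseless line: corrected G1 median is exactly zero
  ssc <- seq(100, 400, length.out = 4000)
  ev <- event_table(data.frame(cyclin_a2 = 0.05 * ssc, ssc = ssc))
  g1 <- gate_mask("G1", rep(TRUE, 4000))
  out <- background_subtract(ev, "cyclin_a2", "ssc", g1)
  expect_identical(median(out$data$cyclin_a2), 0)
  expect_equal(out$metadata$corrections$cyclin_a2$beta, 0.05)

  # no size dependence: output equals input
  set.seed(8)
  ev0 <- event_table(data.frame(cyclin_a2 = rnorm(4000, 0, 1), ssc = ssc))
  out0 <- suppressWarnings(background_subtract(ev0, "cyclin_a2", "ssc", g1))
  expect_lt(abs(out0$metadata$corrections$cyclin_a2$beta), 0.005)

  # noisy synthetic: reference median within epsilon = 1% of 90th percentile
  m <- phase_model(background_slope = c(cyclin_a2 = 0.05))
  pop <- sample_population(m, 20000, seed = 13)
  ref <- gate_mask("G1ref", pop$truth$phase == "G1")
  corr <- background_subtract(pop$events, "cyclin_a2", "ssc", ref)
  eps <- 0.01 * quantile(pop$events$data$cyclin_a2, 0.9, names = FALSE)
  expect_lt(abs(median(corr$data$cyclin_a2[ref$mask])), eps)
  # fixed point: re-estimating the slope on corrected data gives ~0
  corr2 <- suppressWarnings(background_subtract(corr, "cyclin_a2", "ssc", ref))
  expect_lt(abs(corr2$metadata$corrections$cyclin_a2$beta), 0.002)

  # negative slope estimates are clamped with a warning
  evn <- event_table(data.frame(cyclin_a2 = -0.05 * ssc, ssc = ssc))
  expect_warning(outn <- background_subtract(evn, "cyclin_a2", "ssc", g1),
                 "clamped")
  expect_equal(outn$data$cyclin_a2, evn$data$cyclin_a2)
})

test_that("outlier gate keeps clean interphase cells and drops contaminants", {
  pop <- sample_population(default_model(), 30000, seed = 9,
                           contaminant_fraction = 0.05)
  ev <- pop$events
  interphase <- gate_mask("interphase", rep(TRUE, n_events(ev)))
  r5 <- outlier_gates(ev, "cyclin_a2", "dna", interphase, level = 99)
  clean <- !pop$truth$contaminant
  expect_gte(mean(r5$mask[clean]), 0.98)
  expect_lt(mean(r5$mask[pop$truth$contaminant]), 0.20)
  expect_error(outlier_gates(ev, "cyclin_a2", "dna", interphase, level = -1),
               "between 0 and 100")
})

test_that("gate formulas combine element-wise with AND/OR/NOT", {
  r2 <- gate_mask("R2", c(TRUE, TRUE, FALSE, FALSE, TRUE))
  r3 <- gate_mask("R3", c(FALSE, FALSE, TRUE, TRUE, FALSE))
  r4 <- gate_mask("R4", c(TRUE, FALSE, TRUE, FALSE, TRUE))
  r5 <- gate_mask("R5", c(TRUE, TRUE, FALSE, TRUE, TRUE))
  masks <- list(R2 = r2, R3 = r3, R4 = r4, R5 = r5)

  expect_equal(sum(combine_gates(masks, "R2 AND R3")$mask), 0)
  # the cytokinetic rejoin: all R3 events are restored even where R3 is
  # disjoint from R2
  final <- combine_gates(masks, "((R2 AND R4 AND R5) OR R3)")
  expect_true(all(final$mask[r3$mask]))
  expect_equal(final$mask, (r2$mask & r4$mask & r5$mask) | r3$mask)
  expect_equal(combine_gates(masks, "NOT (NOT R2)")$mask, r2$mask)
  expect_error(combine_gates(masks, "R2 AND R9"), "unknown masks")
  expect_error(combine_gates(masks, "R2; system('x')"), "unknown|invalid")
  # commutative formulas are order-independent
  expect_equal(combine_gates(masks, "R2 OR (R3 AND R4)")$mask,
               combine_gates(masks, "(R4 AND R3) OR R2")$mask)
})

test_that("the full preprocessing chain separates signal from contaminants", {
  pop <- sample_population(default_model(), 30000, seed = 19,
                           contaminant_fraction = 0.05)
  ev <- pop$events
  r2 <- singlet_gate(ev, "dna_width", "dna", 99)
  ev <- attach_mask(ev, r2)
  r3 <- mitotic_gate(ev, "phh3", gated_on = r2, threshold = 20)
  ev <- attach_mask(ev, r3)
  interphase <- combine_gates(ev, "R2 AND NOT R3", name = "interphase")
  r5 <- outlier_gates(ev, "cyclin_a2", "dna", interphase)
  ev <- attach_mask(ev, r5)
  pre <- combine_gates(ev, "(R2 AND R5) OR R3", name = "pre")
  r4 <- outlier_gates(ev, "cyclin_a2", "dna", pre, name = "R4")
  ev <- attach_mask(ev, r4)
  final <- combine_gates(ev, "((R2 AND R4 AND R5) OR R3)")
  good <- !pop$truth$contaminant
  expect_gte(mean(final$mask[good]), 0.98)            # sensitivity
  expect_lte(mean(final$mask[!good]), 0.20)           # contaminant retention
})
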