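test_that("density calibration reproduces known lines", {
  # slope = 0.020 g/mL per 0.0010 RI units = 20 g/mL per RI unit
  cal <- fit_density_calibration(c(1.3720, 1.3730), c(1.780, 1.800))
  expect_equal(cal$slope, 20)
  expect_equal(predict(cal, 1.3725), 1.790)
  # with exactly two points the line passes through both
  expect_equal(predict(cal, c(1.3720, 1.3730)), c(1.780, 1.800))
  expect_equal(cal$rms, 0, tolerance = 1e-12)
  expect_error(fit_density_calibration(1.37, 1.78), "at least 2")
  expect_error(fit_density_calibration(c(1.37, 1.37), c(1.7, 1.8)),
               "degenerate")
})

test_that("calibration recovers a noisy line within two standard errors", {
  set.seed(101)
  true_slope <- 2100; true_int <- 1.79 - 2100 * 1.3725
  ri <- seq(1.3700, 1.3740, length.out = 5)
  dens <- true_int + true_slope * ri + rnorm(5, sd = 5e-4)
  cal <- fit_density_calibration(ri, dens)
  se <- summary(stats::lm(dens ~ ri))$coefficients["ri", "Std. Error"]
  expect_lt(abs(cal$slope - true_slope), 2 * se)
})

test_that("relative RNA distribution scales to the gradient maximum", {
  g <- as_gradient(data.frame(fraction = 1:4,
                              density = c(1.84, 1.82, 1.80, 1.78),
                              rna_concentration = c(2, 4, 8, 4)))
  g <- relative_rna_distribution(g)
  expect_equal(g$relative_rna, c(25, 50, 100, 50))
  # uniform gradients are all at the maximum
  gu <- as_gradient(data.frame(fraction = 1:4,
                               density = c(1.84, 1.82, 1.80, 1.78),
                               rna_concentration = rep(3, 4)))
  expect_equal(relative_rna_distribution(gu)$relative_rna, rep(100, 4))
  # idempotent
  expect_equal(relative_rna_distribution(g)$relative_rna, g$relative_rna)
  gz <- as_gradient(data.frame(fraction = 1:4,
                               density = c(1.84, 1.82, 1.80, 1.78),
                               rna_concentration = rep(0, 4)))
  expect_error(relative_rna_distribution(gz), "empty gradient")
})

test_that("gradient construction enforces its invariants", {
  expect_error(
    as_gradient(data.frame(fraction = 1:4, density = c(1.8, 1.8, 1.79, 1.78),
                           rna_concentration = 1:4)),
    "strictly")
  expect_error(
    as_gradient(data.frame(fraction = 1:4,
                           density = c(1.84, 1.82, 1.80, 1.78),
                           rna_concentration = 1:4), n_excluded = 1L),
    "at least 4")
})

test_that("fixed and auto window policies agree on a control peaking at 9", {
  wm <- classify_fractions(policy = "fixed")
  expect_equal(which(wm == "heavy"), 5:7, ignore_attr = TRUE)
  expect_equal(which(wm == "light"), 8:10, ignore_attr = TRUE)

  conc <- dnorm(1:13, mean = 9, sd = 1.2)
  g <- as_gradient(data.frame(fraction = 1:15,
                              density = seq(1.854, by = -0.0080833, length.out = 15),
                              rna_concentration = c(conc, 0, 0)),
                   n_excluded = 2L)
  g <- relative_rna_distribution(g)
  expect_equal(peak_fraction(g), 9)
  wa <- classify_fractions(g, policy = "auto")
  expect_equal(attr(wa, "heavy"), 5:7)
  expect_equal(attr(wa, "light"), 8:10)
  # windows are disjoint and inside the analyzed range
  expect_length(intersect(which(wa == "heavy"), which(wa == "light")), 0)
  expect_true(all(c(attr(wa, "heavy"), attr(wa, "light")) <= 13))

  # a peak too close to the dense edge cannot host both windows
  conc_edge <- dnorm(1:13, mean = 3, sd = 1)
  ge <- as_gradient(data.frame(fraction = 1:15,
                               density = seq(1.854, by = -0.0080833, length.out = 15),
                               rna_concentration = c(conc_edge, 0, 0)),
                    n_excluded = 2L)
  expect_error(classify_fractions(relative_rna_distribution(ge),
                                  policy = "auto"), "edge")
})

test_that("auto windows from an unlabeled control capture a labeled community", {
  sc <- fully_labeled_scenario(seed = 31)
  ds <- simulate_experiment(sc)
  ctrl <- relative_rna_distribution(ds$gradients[["0h_r1"]])
  wm <- classify_fractions(ctrl, policy = "auto")
  lab4 <- relative_rna_distribution(ds$gradients[["4h_r1"]])
  expect_true(peak_fraction(lab4) %in% attr(wm, "heavy"))
})

test_that("simulated gradients fractionate linearly in density", {
  for (s in 1:5) {
    ds <- simulate_experiment(default_scenario(seed = s))
    lin <- suppressWarnings(gradient_linearity(ds$gradients[["0h_r1"]]))
    expect_gte(lin$r_squared, 0.99)
    expect_lt(lin$slope, 0)
  }
})
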