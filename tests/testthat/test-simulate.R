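test_that("buoyant density shift is exactly atom_fraction * delta_rho_max", {
  sc <- default_scenario(seed = 11)
  ds <- simulate_experiment(sc)
  expect_equal(ds$truth$buoyant_density_mean,
               ds$truth$unlabeled_density +
                 ds$truth$atom_fraction * sc$delta_rho_max)
  # one taxon at 0.98 with delta 0.035 sits 0.0343 g/mL above its unlabeled
  # density
  laf <- matrix(0, 20, 3); laf[1L, 3L] <- 0.98
  sc2 <- sip_scenario(20, sc$baseline_abundances, laf, taxa = sc$taxa,
                      seed = 1)
  tr <- simulate_experiment(sc2)$truth
  t4 <- tr[tr$timepoint == "4h" & tr$taxon == sc$taxa[1L], ]
  expect_equal(t4$buoyant_density_mean - t4$unlabeled_density, 0.0343)
})

test_that("without label every timepoint shares the same expected profile", {
  sc <- exchangeable_null_scenario(seed = 3)
  ds <- simulate_experiment(sc)
  expect_true(all(!ds$truth$is_labeled))
  expect_equal(ds$truth$buoyant_density_mean, ds$truth$unlabeled_density)
  p0 <- expected_fraction_profile(sc, "0h")
  p4 <- expected_fraction_profile(sc, "4h")
  expect_equal(p0, p4)
  # and the observed modal fractions agree across timepoints up to noise
  pk <- vapply(c("0h", "2h", "4h"), function(tp) {
    peak_fraction(relative_rna_distribution(
      ds$gradients[[paste0(tp, "_r1")]]))
  }, numeric(1))
  expect_lte(diff(range(pk)), 1)
})

test_that("community RNA mass is conserved across fractions", {
  sc <- default_scenario(seed = 5)
  for (tp in sc$timepoints) {
    m <- expected_fraction_profile(sc, tp)
    expect_equal(sum(m) + attr(m, "spillover"), 1, tolerance = 1e-6)
    expect_true(attr(m, "spillover") >= 0)
  }
})

test_that("raising a taxon's atom fraction never lightens its mean density", {
  sc <- default_scenario(seed = 7)
  afs <- seq(0, 0.98, by = 0.14)
  mean_density <- vapply(afs, function(af) {
    laf <- matrix(0, 20, 3); laf[3L, 3L] <- af
    sc2 <- sip_scenario(20, sc$baseline_abundances, laf, taxa = sc$taxa,
                        seed = 1)
    m <- expected_fraction_profile(sc2, "4h")
    grid <- fraction_density_grid(sc2)
    w <- m[3L, ]
    sum(w * grid$density[grid$analyzed]) / sum(w)
  }, numeric(1))
  expect_true(all(diff(mean_density) >= 0))
})

test_that("fraction masses and multinomial sampling match a quadrature oracle", {
  # 20 taxa, 5 labeled at 0.5; the oracle integrates each taxon's Gaussian
  # band over each fraction's density interval with stats::integrate
  sc <- default_scenario(seed = 13, unlabeled_density_sd = 0)
  grid <- fraction_density_grid(sc)
  an <- grid[grid$analyzed, ]
  centers <- sc$unlabeled_density_mean +
    sc$label_atom_fraction[, "4h"] * sc$delta_rho_max
  oracle <- vapply(seq_len(nrow(an)), function(j) {
    vapply(seq_len(sc$n_taxa), function(i) {
      sc$baseline_abundances[i] * stats::integrate(
        stats::dnorm, an$lower[j], an$upper[j],
        mean = centers[i], sd = sc$band_sigma, rel.tol = 1e-10)$value
    }, numeric(1))
  }, numeric(sc$n_taxa))
  m <- expected_fraction_profile(sc, "4h")
  expect_equal(m, oracle, tolerance = 1e-8, ignore_attr = TRUE)
  # multinomial draw means stay within 3 standard errors of the oracle
  set.seed(99)
  for (f in c(5L, 7L, 9L)) {
    p <- oracle[, f] / sum(oracle[, f])
    draws <- stats::rmultinom(200, sc$seq_depth, p) / sc$seq_depth
    se <- sqrt(p * (1 - p) / (sc$seq_depth * 200))
    dev <- abs(rowMeans(draws) - p)
    expect_true(all(dev <= 3 * se + 1e-12))
  }
})

test_that("identical scenario and seed reproduce the dataset bit for bit", {
  sc <- default_scenario(seed = 21)
  d1 <- simulate_experiment(sc)
  d2 <- simulate_experiment(sc)
  expect_identical(d1$feature_table, d2$feature_table)
  expect_identical(d1$gradients, d2$gradients)
  expect_identical(d1$isotopologues, d2$isotopologues)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
})

test_that("scenario validation rejects malformed inputs", {
  ab <- rep(0.05, 20)
  laf <- matrix(0, 20, 3)
  expect_error(sip_scenario(20, ab * 2, laf), "sum to 1")
  expect_error(sip_scenario(20, ab, laf + 0.99), "0.98")
  expect_error(sip_scenario(20, ab, laf, rho_top = 1.9), "rho_bottom")
  expect_error(sip_scenario(20, ab, laf, band_sigma = 0), "band_sigma")
  expect_error(sip_scenario(20, ab, laf, n_excluded = 15), "n_excluded")
  expect_error(sip_scenario(20, ab, laf, delta_rho_max = -1),
               "delta_rho_max")
})

test_that("isotopologue simulation honours its degenerate limits", {
  m0 <- simulate_isotopologues(0.98, 2, 0, 1000, phi = 0, seed = 1)
  expect_identical(m0$i13, 0L)
  expect_equal(atom_percent(m0), 0)
  m1 <- simulate_isotopologues(1, 3, 0.011, 1000, phi = 1, seed = 1)
  expect_identical(m1$i12, 0L)
  expect_equal(atom_percent(m1), 100)
  expect_error(simulate_isotopologues(0.5, 0, 0.01, 100, phi = 0.5),
               "n_carbons")
})

test_that("two-mass peak ratio matches the binomial closed form", {
  phi <- 0.4; a <- 0.98; q <- 0; nC <- 2L; n <- 1e5
  m <- simulate_isotopologues(a, nC, q, n, phi = phi, seed = 42)
  p13 <- phi * a^nC
  p12 <- phi * (1 - a)^nC + (1 - phi)
  ratio_exp <- p13 / p12
  ratio_obs <- m$i13 / m$i12
  # delta-method standard error of the ratio of two multinomial counts
  se <- ratio_exp * sqrt((1 - p13) / (n * p13) + (1 - p12) / (n * p12))
  expect_lt(abs(ratio_obs - ratio_exp), 3 * se)
})

test_that("simulated tree covers the taxa with positive branch lengths", {
  tr <- simulate_tree(20, tip_labels = caecal_taxa(), seed = 2)
  expect_setequal(tr$tip.label, caecal_taxa())
  expect_true(all(tr$edge.length >= 0))
  expect_true(ape::is.rooted(tr))
})
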