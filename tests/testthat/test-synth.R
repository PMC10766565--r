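test_that("unbiased harmonic sampling satisfies equipartition", {
  pot <- harmonic_potential(kappa = 1, box_side = 30)
  tr <- sample_metropolis(pot, list(), 300, n_samples = 8000,
                          step_size = 0.8, seed = 3, thin = 5)
  x <- tr$values$x
  # batch-means standard error accounts for residual autocorrelation
  nb <- 20
  bvar <- tapply(x^2, ceiling(seq_along(x) * nb / length(x)), mean)
  se <- stats::sd(bvar) / sqrt(nb)
  expect_lt(abs(mean(x^2) - rt(300) / 1), 4 * se + 0.01)
  # d is |x| by construction
  expect_equal(tr$values$d,
               sqrt(tr$values$x^2 + tr$values$y^2 + tr$values$z^2))
})

test_that("a flat potential fills its box uniformly", {
  pot <- toy_potential(eps = 0, sigma = 2, box_side = 20)
  tr <- sample_metropolis(pot, list(), 300, n_samples = 4000,
                          step_size = 3, seed = 5, thin = 10)
  # chi-squared on coarse x bins; thinning keeps frames near-independent
  h <- table(cut(tr$values$x, breaks = seq(-10, 10, length.out = 6)))
  expect_gt(stats::chisq.test(h)$p.value, 0.01)
  expect_true(all(abs(tr$values[, c("x", "y", "z")]) <= 10))
})

test_that("a dominant bias pins the sampled CV to its center", {
  pot <- toy_potential(eps = 0, sigma = 2, box_side = 30)
  tr <- sample_metropolis(pot, list(bias_spec("d", 5, 100)), 300,
                          n_samples = 2000, step_size = 0.25, seed = 9,
                          p_rotate = 0.2)
  expect_lt(abs(mean(tr$values$d) - 5), 0.05)
})

test_that("sampling is deterministic given the seed", {
  pot <- toy_potential(eps = 3, sigma = 2, box_side = 25)
  cfg <- umbrella_config("d", 0, 6, n = 4, k = 2, temperature = 300)
  t1 <- sample_windows(pot, cfg, 200, seed = 7)
  t2 <- sample_windows(pot, cfg, 200, seed = 7)
  expect_identical(lapply(t1, function(x) x$values),
                   lapply(t2, function(x) x$values))
  t3 <- sample_windows(pot, cfg, 200, seed = 8)
  expect_false(identical(t1$w01$values, t3$w01$values))
})

test_that("poor step sizes trigger an acceptance warning", {
  pot <- toy_potential(eps = 0, sigma = 2, box_side = 20)
  expect_warning(
    sample_metropolis(pot, list(bias_spec("d", 3, 50)), 300,
                      n_samples = 200, step_size = 40, seed = 1,
                      p_rotate = 0, burn_in = 100),
    "acceptance rate")
})

test_that("toy binding oracle matches independent quadrature", {
  sys <- toy_binding_system(eps = 10, sigma = 2, box_side = 40,
                            kappa_omega = 20)
  orc <- sys$oracle
  # pocket-to-bulk PMF difference: eps + RT ln Z(kappa_omega)
  expect_equal(orc$true_dg_xb, 10 + rt(300) * log(z_orient(20, 300)),
               tolerance = 1e-5)
  # pocket volume against an independent radial quadrature
  rgrid <- seq(0, orc$r_pocket, by = 0.002)
  h <- exp(-rgrid^2 / 8)
  zz <- vapply(h, function(g) z_orient(g * 20, 300, n = 5001), numeric(1))
  lng <- 10 * h / rt(300) + log(zz)
  dg <- rt(300) * (lng[1] - lng)
  vp <- trapz(rgrid, exp(-dg / rt(300)) * 4 * pi * rgrid^2)
  expect_equal(orc$true_v_pocket, vp, tolerance = 1e-3)
  expect_equal(orc$true_dg0,
               -orc$true_dg_xb - rt(300) * log(vp / standard_volume()),
               tolerance = 1e-4)
  expect_lt(orc$refinement_change, 1e-4)
})

test_that("the zero-depth pocket reduces to the pure volume case", {
  sys <- toy_binding_system(eps = 0, sigma = 2, box_side = 40)
  orc <- sys$oracle
  expect_equal(orc$true_dg_xb, 0, tolerance = 1e-12)
  expect_equal(max(abs(orc$true_pmf$dg)), 0, tolerance = 1e-12)
  vp_flat <- 4 / 3 * pi * orc$r_pocket^3
  expect_equal(orc$true_v_pocket, vp_flat, tolerance = 1e-3)
  expect_equal(orc$true_dg0,
               -rt(300) * log(vp_flat / standard_volume()),
               tolerance = 1e-3)
})

test_that("a box without a flat bulk region is rejected", {
  expect_error(toy_potential(eps = 10, sigma = 3, box_side = 20),
               "box_side too small|box_side")
})

test_that("orientation samples in the bulk follow the Haar density", {
  # free ligand (eps 0, coupling on but envelope ~0 away from origin):
  # omega should follow (1 - cos)/pi
  pot <- toy_potential(eps = 0.0, sigma = 1, box_side = 20, kappa_omega = 20)
  tr <- sample_metropolis(pot, list(bias_spec("d", 8, 20)), 300,
                          n_samples = 6000, step_size = 0.5, seed = 13,
                          thin = 8, step_omega = 0.6)
  w <- tr$values$omega
  expect_true(all(w >= 0 & w <= pi))
  # compare mean of cos(omega) with closed form under (1-cos w)/pi: -1/2
  nb <- 20
  bm <- tapply(cos(w), ceiling(seq_along(w) * nb / length(w)), mean)
  se <- stats::sd(bm) / sqrt(nb)
  expect_lt(abs(mean(cos(w)) - (-0.5)), 4 * se + 0.01)
})
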