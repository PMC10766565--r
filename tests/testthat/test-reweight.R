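make_samples <- function(values_by_window, config) {
  trs <- lapply(seq_along(values_by_window), function(i) {
    v <- values_by_window[[i]]
    cv_trajectory(config$windows[[i]]$id, seq_len(nrow(v)), v)
  })
  names(trs) <- vapply(config$windows, function(w) w$id, character(1))
  pool_samples(trs, config)
}

test_that("bias energy matrix evaluates harmonic biases per window", {
  cfg <- window_config(list(
    list(id = "a", biases = list(bias_spec("d", 10, 2))),
    list(id = "b", biases = list(bias_spec("d", 10, 2),
                                 bias_spec("omega", 0.1, 3)))
  ), 300)
  s <- make_samples(list(data.frame(d = 10, omega = 0.1),
                         data.frame(d = 11, omega = 0.3)), cfg)
  u <- bias_energy_matrix(s, cfg)
  expect_equal(unname(u[1, "a"]), 0)               # at the center
  expect_equal(unname(u[2, "a"]), 0.5 * 2 * 1^2)   # 1 kcal/mol
  expect_equal(unname(u[2, "b"]),
               0.5 * 2 * 1^2 + 0.5 * 3 * 0.2^2)    # additivity
  expect_true(all(u >= 0))
})

test_that("zero biases give uniform weights and zero free energies", {
  cfg <- window_config(list(
    list(id = "a", biases = list(bias_spec("x", 0, 0))),
    list(id = "b", biases = list(bias_spec("x", 5, 0)))
  ), 300)
  s <- make_samples(list(data.frame(x = rnorm(40)),
                         data.frame(x = rnorm(60))), cfg)
  fit <- solve_weights(s, cfg)
  expect_equal(fit$weights, rep(1 / 100, 100))
  expect_equal(coef(fit), c(0, 0), tolerance = 1e-12)
  expect_true(fit$converged)
})

test_that("single window recovers the closed-form inverse-Boltzmann weights", {
  cfg <- window_config(list(
    list(id = "a", biases = list(bias_spec("x", 1, 3)))), 300)
  x <- seq(-1, 3, length.out = 25)
  s <- make_samples(list(data.frame(x = x)), cfg)
  fit <- solve_weights(s, cfg)
  u <- 0.5 * 3 * (x - 1)^2
  w_expect <- exp(u / rt(300))
  w_expect <- w_expect / sum(w_expect)
  expect_equal(fit$weights, w_expect, tolerance = 1e-10)
  expect_equal(coef(fit), 0)
})

test_that("solver agrees with a brute-force fixed-point oracle", {
  for (seed in c(3, 17, 99)) {
    withr::with_seed(seed, {
      centers <- sort(runif(3, -1, 3))
      k <- runif(1, 0.5, 3)
      cfg <- window_config(lapply(1:3, function(i) list(
        id = sprintf("w%d", i),
        biases = list(bias_spec("x", centers[i], k)))), 300)
      vals <- lapply(1:3, function(i)
        data.frame(x = rnorm(80, centers[i], 0.8)))
      s <- make_samples(vals, cfg)
      fit <- solve_weights(s, cfg, tol = 1e-12)
      oracle <- bf_reweight(bias_energy_matrix(s, cfg),
                            s$n_per_window, 300)
      expect_equal(coef(fit), oracle$f, tolerance = 1e-8,
                   ignore_attr = TRUE)
      expect_equal(fit$weights, oracle$w, tolerance = 1e-8)
    })
  }
})

test_that("plain fixed-point and Newton modes reach the same solution", {
  g <- make_gauss_samples(kappa = 1, centers = c(0, 2), k = 2,
                          n_per = 150, temperature = 300, seed = 5)
  f1 <- solve_weights(g$samples, g$config, method = "newton")
  f2 <- solve_weights(g$samples, g$config, method = "sc")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-7)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-7)
})

test_that("a constant bias shared by all windows changes nothing (gauge)", {
  g <- make_gauss_samples(kappa = 1, centers = c(0, 2), k = 2,
                          n_per = 100, temperature = 300, seed = 8)
  fit0 <- solve_weights(g$samples, g$config)
  # add the same constant 0.5*k*(c0-0)^2 with c0 = 1 to every window
  cfg2 <- g$config
  cfg2$windows <- lapply(cfg2$windows, function(w) {
    w$biases <- c(w$biases, list(bias_spec("c0", 0, 4)))
    w
  })
  s2 <- g$samples
  s2$frames$c0 <- 1
  fit2 <- solve_weights(s2, cfg2)
  expect_equal(fit2$weights, fit0$weights, tolerance = 1e-9)
  expect_equal(coef(fit2), coef(fit0), tolerance = 1e-9)
})

test_that("equal sample counts recover the equal-n estimator exactly", {
  g <- make_gauss_samples(kappa = 1, centers = c(0, 1.5), k = 1.5,
                          n_per = 120, temperature = 300, seed = 12)
  fit <- solve_weights(g$samples, g$config, tol = 1e-12)
  # equal-n form: w_k = c / sum_i exp(-(U_ik - F_i)/RT), n factored out
  u <- bias_energy_matrix(g$samples, g$config)
  rt_ <- rt(300)
  f <- c(0, 0)
  for (it in 1:20000) {
    w <- 1 / (exp(-(u[, 1] - f[1]) / rt_) + exp(-(u[, 2] - f[2]) / rt_))
    w <- w / sum(w)
    fn <- -rt_ * log(c(sum(w * exp(-u[, 1] / rt_)),
                       sum(w * exp(-u[, 2] / rt_))))
    fn <- fn - fn[1]
    if (max(abs(fn - f)) < 1e-13) break
    f <- fn
  }
  expect_equal(coef(fit), f, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("reweighted averages converge to quadrature truth", {
  # <x^2> under kappa/2 x^2 at 300 K is RT/kappa; windows must cover both
  # tails of the unbiased ensemble for the average to be reachable
  g <- make_gauss_samples(kappa = 1, centers = c(-2, 0, 2), k = 2,
                          n_per = 4000, temperature = 300, seed = 42)
  fit <- solve_weights(g$samples, g$config)
  m2 <- reweighted_mean(fit, g$samples$frames$x^2)
  expect_equal(m2, rt(300) / 1, tolerance = 0.05)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
})

test_that("non-convergence is flagged, not thrown", {
  g <- make_gauss_samples(kappa = 1, centers = c(0, 3), k = 2,
                          n_per = 50, temperature = 300, seed = 2)
  expect_warning(
    fit <- solve_weights(g$samples, g$config, method = "sc", max_iter = 2),
    "did not converge")
  expect_false(fit$converged)
  expect_gt(fit$max_residual, 1e-8)
})

test_that("windows with no effective samples are an error", {
  g <- make_gauss_samples(kappa = 1, centers = c(0, 2), k = 2,
                          n_per = 30, temperature = 300, seed = 4)
  fw <- rep(1, 60)
  fw[31:60] <- 0
  expect_error(solve_weights(g$samples, g$config, frame_weights = fw),
               "zero effective samples")
})

test_that("equilibration discard drops leading frames per window", {
  cfg <- window_config(list(
    list(id = "a", biases = list(bias_spec("x", 0, 1)))), 300)
  tr <- list(a = cv_trajectory("a", 1:10, data.frame(x = 1:10)))
  s <- pool_samples(tr, cfg, discard = 0.25)
  expect_equal(s$frames$x, 3:10)
  expect_equal(unname(s$n_per_window), 8L)
})
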