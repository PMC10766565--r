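# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: plain-loop fixed-point iteration for the
# reweighting estimator, direct trapezoid quadrature for integrals.

R_GAS <- 1.987204e-3

# Brute-force self-consistent reweighting, written from the defining
# equations with naive loops: w_k = c / sum_i n_i exp(-(U_ik - F_i)/RT),
# exp(-F_i/RT) = sum_k w_k exp(-U_ik/RT), F anchored at F_1 = 0.
bf_reweight <- function(u, n_i, temperature, iters = 50000, tol = 1e-13) {
  rt_ <- R_GAS * temperature
  nk <- nrow(u)
  nw <- ncol(u)
  f <- numeric(nw)
  for (it in seq_len(iters)) {
    w <- numeric(nk)
    for (k in seq_len(nk)) {
      den <- 0
      for (i in seq_len(nw)) den <- den + n_i[i] * exp(-(u[k, i] - f[i]) / rt_)
      w[k] <- 1 / den
    }
    w <- w / sum(w)
    fn <- numeric(nw)
    for (i in seq_len(nw)) {
      s <- 0
      for (k in seq_len(nk)) s <- s + w[k] * exp(-u[k, i] / rt_)
      fn[i] <- -rt_ * log(s)
    }
    fn <- fn - fn[1]
    if (max(abs(fn - f)) < tol) {
      f <- fn
      break
    }
    f <- fn
  }
  list(f = f, w = w)
}

# trapezoid quadrature
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# orientation partition factor: integral of (1-cos w)/pi * exp(-a w^2/(2RT))
# over [0, pi], a in kcal/mol/rad^2
z_orient <- function(a, temperature, n = 200001) {
  w <- seq(0, pi, length.out = n)
  trapz(w, (1 - cos(w)) / pi * exp(-a * w^2 / (2 * R_GAS * temperature)))
}

# exact samples from a 1-D harmonic ensemble kappa/2 x^2 biased by
# k/2 (x - c)^2: a Gaussian with precision beta*(kappa + k)
rbiased_gauss <- function(n, kappa, k, center, temperature) {
  rt_ <- R_GAS * temperature
  prec <- (kappa + k) / rt_
  mu <- k * center / (kappa + k)
  stats::rnorm(n, mean = mu, sd = sqrt(1 / prec))
}

# pooled biased_samples for 1-D gaussian umbrella systems on CV "x"
make_gauss_samples <- function(kappa, centers, k, n_per, temperature, seed) {
  withr::with_seed(seed, {
    cfg <- window_config(lapply(seq_along(centers), function(i) list(
      id = sprintf("w%02d", i),
      biases = list(bias_spec("x", centers[i], k)))), temperature)
    trs <- lapply(seq_along(centers), function(i) {
      cv_trajectory(sprintf("w%02d", i), seq_len(n_per),
                    data.frame(x = rbiased_gauss(n_per, kappa, k,
                                                 centers[i], temperature)))
    })
    names(trs) <- vapply(cfg$windows, function(w) w$id, character(1))
    list(config = cfg, samples = pool_samples(trs, cfg))
  })
}
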