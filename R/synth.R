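#' Analytic toy potentials for synthetic benchmarks
#'
#' A `toy_potential` is a closed-form energy surface for a point "ligand" at
#' position x (angstrom, 3-D) with an optional orientation angle omega
#' (radians in [0, pi]); energies in kcal/mol and bounded below. The
#' workhorse is the Gaussian binding pocket
#' U0(x) = -eps * exp(-|x|^2 / (2 sigma^2)),
#' optionally coupled to the orientation through
#' h(x) * kappa_omega/2 * omega^2 with the same Gaussian envelope
#' h(x) = exp(-|x|^2 / (2 sigma^2)), so the orientation is confined in the
#' pocket and free in the bulk. The configuration-space domain is the cube
#' of side `box_side` centered at the origin. Orientation carries the rigid
#' body Haar measure: samplers weight omega by (1 - cos omega)/pi.
#'
#' @param eps Pocket depth, kcal/mol (>= 0).
#' @param sigma Pocket width, angstrom (> 0).
#' @param box_side Cube side L, angstrom; the potential must be flat (within
#'   1e-3 RT at 300 K) at |x| = L/2.
#' @param kappa_omega Orientation coupling, kcal/mol/rad^2 (0 disables the
#'   orientation degree of freedom).
#' @return An object of class `toy_potential` with an `energy(x, omega)`
#'   function vectorised over rows of `x`.
#' @export
toy_potential <- function(eps, sigma, box_side, kappa_omega = 0) {
  stopifnot(eps >= 0, sigma > 0, box_side > 6 * sigma, kappa_omega >= 0)
  flat <- eps * exp(-(box_side / 2)^2 / (2 * sigma^2))
  if (flat > 1e-3 * rt(300))
    stop("box_side too small: potential depth ", format(flat),
         " kcal/mol at |x| = L/2 exceeds 1e-3 RT")
  energy <- function(x, omega = NULL) {
    x <- matrix(x, ncol = 3)
    h <- exp(-rowSums(x^2) / (2 * sigma^2))
    u <- -eps * h
    if (!is.null(omega) && kappa_omega > 0)
      u <- u + h * 0.5 * kappa_omega * omega^2
    u
  }
  structure(list(name = sprintf("gaussian-pocket(eps=%g, sigma=%g)",
                                eps, sigma),
                 eps = eps, sigma = sigma, box_side = box_side,
                 kappa_omega = kappa_omega,
                 has_omega = kappa_omega > 0,
                 energy = energy),
            class = "toy_potential")
}

#' @rdname toy_potential
#' @param kappa Spring constant of an isotropic harmonic well,
#'   kcal/mol/angstrom^2.
#' @export
harmonic_potential <- function(kappa, box_side = 40) {
  stopifnot(kappa >= 0, box_side > 0)
  structure(list(name = sprintf("harmonic(kappa=%g)", kappa),
                 kappa = kappa, box_side = box_side,
                 kappa_omega = 0, has_omega = FALSE,
                 energy = function(x, omega = NULL) {
                   x <- matrix(x, ncol = 3)
                   0.5 * kappa * rowSums(x^2)
                 }),
            class = "toy_potential")
}

#' @export
print.toy_potential <- function(x, ...) {
  cat("Toy potential:", x$name, "\n")
  cat("  box side:", x$box_side, "A;",
      if (x$has_omega) paste("orientation coupling kappa =",
                             x$kappa_omega, "kcal/mol/rad^2")
      else "no orientation degree of freedom", "\n")
  invisible(x)
}

# per-chain harmonic bias energy for the supported toy CVs
# bias_rows: list of list(cv, center = m-vector, k = m-vector)
toy_bias_energy <- function(bias_rows, x, omega) {
  u <- numeric(nrow(x))
  for (b in bias_rows) {
    v <- switch(b$cv,
                d = sqrt(rowSums(x^2)),
                x = x[, 1], y = x[, 2], z = x[, 3],
                omega = omega,
                stop("unsupported CV in toy sampler: '", b$cv, "'"))
    u <- u + 0.5 * b$k * (v - b$center)^2
  }
  u
}

# collect per-window biases plus always-on restraints into vectorised rows
# (one entry per "pass": the j-th bias on a given CV across windows)
collect_bias_rows <- function(config) {
  m <- length(config$windows)
  rows <- list()
  for (i in seq_len(m)) {
    seen <- list()
    for (b in c(config$windows[[i]]$biases, config$restraints)) {
      seen[[b$cv]] <- (if (is.null(seen[[b$cv]])) 0L else seen[[b$cv]]) + 1L
      key <- paste0(b$cv, "#", seen[[b$cv]])
      if (is.null(rows[[key]]))
        rows[[key]] <- list(cv = b$cv, center = numeric(m), k = numeric(m))
      rows[[key]]$center[i] <- b$center
      rows[[key]]$k[i] <- b$k
    }
  }
  unname(rows)
}

#' Metropolis sampling of toy potentials under umbrella biases
#'
#' `sample_windows()` runs one Metropolis chain per window of a
#' [window_config()], all chains stepped together (vectorised across
#' windows), targeting the Boltzmann distribution of the toy potential plus
#' that window's harmonic biases; the orientation angle, when present,
#' additionally carries the (1 - cos omega)/pi Haar factor. Chains start at
#' their distance-bias center, run `burn_in` equilibration steps, and then
#' record every `thin`-th step until `n_samples` frames per window are
#' collected. Recorded CVs: `d` (= |x|), `x`, `y`, `z` and, when the
#' potential has an orientation, `omega`. `sample_metropolis()` is the
#' single-window version.
#'
#' @param potential A [toy_potential()].
#' @param config A [window_config()] whose biases act on the toy CVs.
#' @param n_samples Retained frames per window.
#' @param step_size Standard deviation of Cartesian proposals, angstrom.
#' @param seed Integer RNG seed (chains are deterministic given it).
#' @param thin Record every `thin`-th step.
#' @param burn_in Discarded leading steps.
#' @param step_omega Proposal s.d. for omega, radians.
#' @param p_rotate Probability per step of proposing a uniform random
#'   rotation of the position vector about the origin instead of a Cartesian
#'   displacement. Rotation moves are accepted through the usual Metropolis
#'   criterion; they dramatically speed up mixing over spherical shells,
#'   which Cartesian steps alone traverse diffusively.
#' @return `sample_windows()`: named list of [cv_trajectory()], one per
#'   window. Acceptance rates outside (0.05, 0.95) trigger a warning
#'   suggesting a step-size retune.
#' @export
sample_windows <- function(potential, config, n_samples, step_size = 0.6,
                           seed = 1, thin = 10, burn_in = 2000,
                           step_omega = 0.15, p_rotate = 0.25) {
  stopifnot(inherits(potential, "toy_potential"),
            inherits(config, "window_config"),
            n_samples >= 1, step_size > 0, thin >= 1)
  m <- length(config$windows)
  ids <- vapply(config$windows, function(w) w$id, character(1))
  beta <- 1 / rt(config$temperature)
  rows <- collect_bias_rows(config)
  has_w <- potential$has_omega ||
    any(vapply(rows, function(b) b$cv == "omega", logical(1)))
  half <- potential$box_side / 2

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  # start each chain at its d-bias/restraint center (on the +x axis)
  x <- matrix(0, m, 3)
  for (i in seq_len(m)) {
    for (b in c(config$windows[[i]]$biases, config$restraints))
      if (b$cv == "d") x[i, 1] <- b$center
  }
  w_ang <- if (has_w) rep(0.5, m) else NULL

  log_target <- function(x, w_ang) {
    lt <- -beta * (potential$energy(x, w_ang) +
                     toy_bias_energy(rows, x, w_ang))
    out <- lt
    if (has_w) {
      ok <- w_ang >= 0 & w_ang <= pi
      jac <- rep(-Inf, m)
      jac[ok] <- log1p(-cos(w_ang[ok]))
      out <- out + jac
    }
    oob <- apply(abs(x) > half, 1, any)
    out[oob] <- -Inf
    out
  }

  lt <- log_target(x, w_ang)
  total_steps <- burn_in + n_samples * thin
  acc <- numeric(m)
  store <- array(NA_real_, c(n_samples, m, if (has_w) 4L else 3L))
  rec <- 0L
  rotate_rows <- function(x) {
    # apply an independent uniform random rotation to each row of x
    q <- matrix(stats::rnorm(4 * nrow(x)), ncol = 4)
    q <- q / sqrt(rowSums(q^2))
    q0 <- q[, 1]; qv <- q[, 2:4, drop = FALSE]
    cr1 <- cbind(qv[, 2] * x[, 3] - qv[, 3] * x[, 2],
                 qv[, 3] * x[, 1] - qv[, 1] * x[, 3],
                 qv[, 1] * x[, 2] - qv[, 2] * x[, 1])
    t <- 2 * cr1
    x + q0 * t + cbind(qv[, 2] * t[, 3] - qv[, 3] * t[, 2],
                       qv[, 3] * t[, 1] - qv[, 1] * t[, 3],
                       qv[, 1] * t[, 2] - qv[, 2] * t[, 1])
  }
  for (s in seq_len(total_steps)) {
    if (p_rotate > 0 && stats::runif(1) < p_rotate) {
      xp <- rotate_rows(x)
      wp <- w_ang
    } else {
      xp <- x + matrix(stats::rnorm(3 * m, sd = step_size), m, 3)
      wp <- if (has_w) w_ang + stats::rnorm(m, sd = step_omega) else NULL
    }
    ltp <- log_target(xp, wp)
    take <- log(stats::runif(m)) < (ltp - lt)
    x[take, ] <- xp[take, ]
    if (has_w) w_ang[take] <- wp[take]
    lt[take] <- ltp[take]
    acc <- acc + take
    if (s > burn_in && (s - burn_in) %% thin == 0L) {
      rec <- rec + 1L
      store[rec, , 1:3] <- x
      if (has_w) store[rec, , 4L] <- w_ang
    }
  }
  rate <- acc / total_steps
  bad <- rate < 0.05 | rate > 0.95
  if (any(bad))
    warning("acceptance rate outside (0.05, 0.95) for window(s) ",
            paste(ids[bad], collapse = ", "),
            "; consider retuning step_size")
  out <- vector("list", m)
  names(out) <- ids
  for (i in seq_len(m)) {
    v <- data.frame(d = sqrt(store[, i, 1]^2 + store[, i, 2]^2 +
                               store[, i, 3]^2),
                    x = store[, i, 1], y = store[, i, 2], z = store[, i, 3])
    if (has_w) v$omega <- store[, i, 4L]
    out[[i]] <- cv_trajectory(ids[i], seq_len(n_samples) * thin, v)
  }
  attr(out, "acceptance") <- stats::setNames(rate, ids)
  out
}

#' @rdname sample_windows
#' @param biases List of [bias_spec()] for the single window.
#' @param temperature Temperature in kelvin.
#' @param window_id Identifier for the returned trajectory.
#' @export
sample_metropolis <- function(potential, biases, temperature, n_samples,
                              step_size = 0.6, seed = 1, thin = 10,
                              burn_in = 2000, step_omega = 0.15,
                              p_rotate = 0.25, window_id = "w01") {
  if (length(biases) == 0L) {
    # unbiased run: a zero-strength bias keeps the window machinery happy
    biases <- list(bias_spec("x", 0, 0))
  }
  cfg <- window_config(list(list(id = window_id, biases = biases)),
                       temperature)
  sample_windows(potential, cfg, n_samples, step_size, seed, thin,
                 burn_in, step_omega, p_rotate)[[1]]
}

#' Toy binding system with quadrature ground truth
#'
#' Builds a Gaussian-pocket [toy_potential()] together with its exact
#' reference values computed by 1-D radial quadrature: the radial PMF
#' dG(r) = -RT ln[ e^{beta eps h(r)} Z(h(r)) ] + const (minimum 0 at r = 0),
#' where h(r) is the Gaussian envelope and Z(g) the orientation partition
#' factor integral of (1 - cos w)/pi * exp(-beta g kappa_omega w^2 / 2);
#' the pocket volume V_P = 4 pi int r^2 e^{-dG(r)/RT} dr over the pocket
#' region r <= `r_pocket`; the bulk-vs-pocket PMF difference
#' dG(x_B) = eps + RT ln Z(1); and the resulting standard binding free
#' energy dG0 = -dG(x_B) - RT ln(V_P / V_B). Refining the quadrature by 2x
#' must move dG0 by less than 1e-4 kcal/mol, otherwise an error is raised.
#'
#' @inheritParams toy_potential
#' @param temperature Temperature in kelvin.
#' @param r_pocket Pocket region radius, angstrom (default 5 sigma).
#' @param dr Radial quadrature step, angstrom.
#' @return List with `potential` (a `toy_potential`) and `oracle`, an object
#'   of class `oracle_result`: `true_pmf` (data frame `r`, `dg`),
#'   `true_v_pocket`, `true_dg_xb` (bulk minus pocket, >= 0), `true_dg0`,
#'   `quadrature_resolution`, `refinement_change`.
#' @examples
#' sys <- toy_binding_system(eps = 10, sigma = 2, box_side = 40)
#' sys$oracle$true_dg0
#' @export
toy_binding_system <- function(eps, sigma, box_side, kappa_omega = 0,
                               temperature = 300, r_pocket = 5 * sigma,
                               dr = 0.01) {
  pot <- toy_potential(eps, sigma, box_side, kappa_omega)
  oracle <- function(dr_, nw_) {
    rt_ <- rt(temperature)
    z_omega <- function(g) {
      if (kappa_omega == 0) return(rep(1, length(g)))
      wgrid <- seq(0, pi, length.out = nw_)
      vapply(g, function(gi) {
        f <- (1 - cos(wgrid)) / pi *
          exp(-gi * 0.5 * kappa_omega * wgrid^2 / rt_)
        sum((f[-1] + f[-nw_]) / 2) * (pi / (nw_ - 1))
      }, numeric(1))
    }
    rgrid <- seq(0, r_pocket, by = dr_)
    h <- exp(-rgrid^2 / (2 * sigma^2))
    # -RT ln of the orientation-integrated Boltzmann factor, zeroed at r = 0
    gneg <- eps * h / rt_ + log(z_omega(h))     # = -G(r)/RT up to a constant
    dg <- rt_ * (gneg[1] - gneg)
    dg_xb <- rt_ * (gneg[1] - 0)                # bulk (h = 0) minus pocket
    integrand <- exp(-dg / rt_) * 4 * pi * rgrid^2
    vp <- sum((integrand[-1] + integrand[-length(integrand)]) / 2) * dr_
    dg0 <- -dg_xb - rt_ * log(vp / standard_volume())
    list(pmf = data.frame(r = rgrid, dg = dg), vp = vp,
         dg_xb = dg_xb, dg0 = dg0)
  }
  nw <- 20001L
  coarse <- oracle(dr, nw)
  fine <- oracle(dr / 2, 2L * nw - 1L)
  change <- abs(fine$dg0 - coarse$dg0)
  if (change > 1e-4)
    stop("quadrature not converged: refining by 2x moved dG0 by ",
         format(change), " kcal/mol")
  res <- structure(list(true_pmf = fine$pmf,
                        true_v_pocket = fine$vp,
                        true_dg_xb = fine$dg_xb,
                        true_dg0 = fine$dg0,
                        r_pocket = r_pocket,
                        temperature = temperature,
                        quadrature_resolution = dr / 2,
                        refinement_change = change),
                   class = "oracle_result")
  list(potential = pot, oracle = res)
}

#' @export
print.oracle_result <- function(x, ...) {
  cat("Quadrature oracle at", x$temperature, "K\n")
  cat(sprintf("  dG(x_B) = %.4f kcal/mol, V_P = %.4f A^3\n",
              x$true_dg_xb, x$true_v_pocket))
  cat(sprintf("  dG0 = %.4f kcal/mol (refinement change %.2g)\n",
              x$true_dg0, x$refinement_change))
  invisible(x)
}
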