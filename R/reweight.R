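#' Pool biased trajectories into a single sample set
#'
#' Combines per-window CV trajectories into one pooled set of frames, each
#' tagged with its window of origin. The reweighting estimator operates on
#' this pooled set irrespective of which bias generated each sample. An
#' optional leading fraction of each window can be discarded as
#' equilibration.
#'
#' @param trajectories List of [cv_trajectory()], one per window, in the
#'   order of `config$windows` (or named by window id).
#' @param config A [window_config()].
#' @param discard Leading fraction of each window's frames to drop (0 to <1).
#' @return An object of class `biased_samples` with elements `frames` (data
#'   frame: `window` plus one column per CV), `n_per_window` (named integer)
#'   and `temperature`.
#' @export
pool_samples <- function(trajectories, config, discard = 0) {
  stopifnot(inherits(config, "window_config"),
            is.numeric(discard), discard >= 0, discard < 1)
  ids <- vapply(config$windows, function(w) w$id, character(1))
  if (!is.null(names(trajectories))) {
    missing <- setdiff(ids, names(trajectories))
    if (length(missing) > 0)
      stop("no trajectory supplied for window(s): ",
           paste(missing, collapse = ", "))
    trajectories <- trajectories[ids]
  } else if (length(trajectories) != length(ids)) {
    stop("need one trajectory per window (", length(ids), ")")
  }
  needed <- unique(c(
    unlist(lapply(config$windows, function(w)
      vapply(w$biases, function(b) b$cv, character(1)))),
    vapply(config$restraints, function(b) b$cv, character(1))))
  pieces <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tr <- trajectories[[i]]
    stopifnot(inherits(tr, "cv_trajectory"))
    miss <- setdiff(needed, names(tr$values))
    if (length(miss) > 0)
      stop("window '", ids[i], "': trajectory lacks biased CV(s): ",
           paste(miss, collapse = ", "))
    v <- tr$values
    if (discard > 0) {
      keep <- seq.int(floor(nrow(v) * discard) + 1L, nrow(v))
      v <- v[keep, , drop = FALSE]
    }
    pieces[[i]] <- cbind(window = ids[i], v)
  }
  common <- Reduce(intersect, lapply(pieces, names))
  frames <- do.call(rbind, lapply(pieces, function(p) p[, common, drop = FALSE]))
  rownames(frames) <- NULL
  n_per_window <- vapply(pieces, nrow, integer(1))
  names(n_per_window) <- ids
  structure(list(frames = frames, n_per_window = n_per_window,
                 temperature = config$temperature),
            class = "biased_samples")
}

#' @export
print.biased_samples <- function(x, ...) {
  cat("Pooled biased samples:", nrow(x$frames), "frames from",
      length(x$n_per_window), "windows at", x$temperature, "K\n")
  invisible(x)
}

#' Bias energy matrix
#'
#' Evaluates every window's total bias energy on every pooled frame:
#' entry (k, i) is the sum over window i's harmonic biases of
#' k_b/2 (v_k - center_b)^2, in kcal/mol. Always-on restraints
#' (`config$restraints`) are deliberately excluded: they are common to all
#' windows and remain part of the reweighted ensemble.
#'
#' @param samples A `biased_samples` set from [pool_samples()].
#' @param config A [window_config()].
#' @return Numeric matrix, frames x windows, nonnegative.
#' @export
bias_energy_matrix <- function(samples, config) {
  stopifnot(inherits(samples, "biased_samples"),
            inherits(config, "window_config"))
  n <- nrow(samples$frames)
  k <- length(config$windows)
  u <- matrix(0, n, k)
  colnames(u) <- vapply(config$windows, function(w) w$id, character(1))
  for (i in seq_len(k)) {
    for (b in config$windows[[i]]$biases) {
      v <- samples$frames[[b$cv]]
      if (is.null(v))
        stop("CV '", b$cv, "' (window '", config$windows[[i]]$id,
             "') is not present in the pooled frames")
      u[, i] <- u[, i] + 0.5 * b$k * (v - b$center)^2
    }
  }
  u
}

#' Self-consistent non-parametric reweighting of pooled biased samples
#'
#' Solves the multistate reweighting fixed point for pooled umbrella-sampling
#' frames: each frame k receives an unbiased weight
#' \deqn{w_k = c / \sum_i n_i e^{-(U_i(r_k) - F_i)/RT}}
#' with per-window perturbed free energies F_i satisfying
#' \deqn{e^{-F_i/RT} = \sum_k w_k e^{-U_i(r_k)/RT},}
#' c normalising the weights to 1 and F anchored at F_1 = 0. With equal
#' sample counts n_i the denominator reduces to the classic equal-sample
#' form; unequal counts are supported. All exponentials are evaluated in log
#' space. The default solver first minimises the equivalent convex objective
#' with L-BFGS-B, then polishes with self-consistent sweeps until the
#' fixed-point residual drops below `tol`; `method = "sc"` iterates the fixed
#' point directly.
#'
#' @param samples A `biased_samples` set from [pool_samples()].
#' @param config A [window_config()].
#' @param tol Convergence tolerance on max |F change| per sweep, kcal/mol.
#' @param max_iter Maximum self-consistent sweeps.
#' @param frame_weights Optional nonnegative per-frame multiplicities
#'   (e.g. Bayesian-bootstrap block weights); default 1 for every frame.
#' @param method `"newton"` (default: safeguarded Newton iteration on the
#'   equivalent convex objective, falling back to fixed-point sweeps) or
#'   `"sc"` (plain fixed-point iteration). Both reach the same fixed point.
#' @param f_init Optional initial F values (kcal/mol), e.g. a warm start.
#' @return An object of class `reweight_fit`: `weights` (normalised, one per
#'   frame), `perturbed_free_energies` (kcal/mol, F_1 = 0), `n_iterations`,
#'   `converged`, `max_residual` (kcal/mol), plus the inputs' temperature.
#' @examples
#' cfg <- umbrella_config("x", 0, 2, n = 2, k = 2, temperature = 300)
#' tr <- lapply(cfg$windows, function(w)
#'   cv_trajectory(w$id, 1:50, data.frame(x = rnorm(50, w$biases[[1]]$center))))
#' names(tr) <- c("w01", "w02")
#' fit <- solve_weights(pool_samples(tr, cfg), cfg)
#' sum(fit$weights)  # 1
#' @export
solve_weights <- function(samples, config, tol = 1e-8, max_iter = 10000,
                          frame_weights = NULL, method = c("newton", "sc"),
                          f_init = NULL) {
  method <- match.arg(method)
  stopifnot(tol > 0, max_iter >= 1)
  u <- bias_energy_matrix(samples, config)
  rt_ <- rt(samples$temperature)
  n <- nrow(u)
  kw <- ncol(u)
  if (is.null(frame_weights)) frame_weights <- rep(1, n)
  stopifnot(length(frame_weights) == n, all(frame_weights >= 0),
            all(is.finite(frame_weights)))
  if (sum(frame_weights) <= 0) stop("all frame weights are zero")
  # effective per-window counts follow the (possibly resampled) multiplicities
  wid <- samples$frames$window
  ids <- colnames(u)
  n_eff <- vapply(ids, function(id) sum(frame_weights[wid == id]), numeric(1))
  if (any(n_eff <= 0))
    stop("window(s) with zero effective samples: ",
         paste(ids[n_eff <= 0], collapse = ", "))
  ured <- u / rt_                      # reduced energies
  if (any(!is.finite(ured)))
    stop("non-finite bias energy encountered; check biases and CV values")
  keep <- frame_weights > 0
  lw_s <- log(frame_weights[keep])     # log multiplicities
  negum <- -ured[keep, , drop = FALSE]
  logn <- log(n_eff)
  s_w <- frame_weights[keep]
  stot <- sum(s_w)
  f <- if (is.null(f_init)) numeric(kw) else f_init / rt_
  f <- f - f[1]

  # log denominator D_k = log sum_i n_i exp(f_i - u_ik), two column passes
  log_denom <- function(f) {
    fc <- f + logn
    rm <- negum[, 1] + fc[1]
    if (kw > 1L) for (j in 2:kw) rm <- pmax(rm, negum[, j] + fc[j])
    acc <- exp(negum[, 1] + fc[1] - rm)
    if (kw > 1L) for (j in 2:kw) acc <- acc + exp(negum[, j] + fc[j] - rm)
    rm + log(acc)
  }
  # one fixed-point sweep: f_i <- -log sum_k s_k exp(-u_ik - D_k)
  sweep_f <- function(f) {
    d <- log_denom(f)
    fn <- numeric(kw)
    for (i in seq_len(kw)) fn[i] <- -logsumexp(lw_s + negum[, i] - d)
    fn - fn[1]
  }

  it <- 0L
  resid <- Inf
  if (method == "newton" && kw > 1L) {
    # safeguarded Newton on the convex reweighting objective: the gradient
    # is the fixed-point residual, the Hessian comes from the normalised
    # weight matrix W (rows sum to 1); fall back to a fixed-point sweep
    # whenever a Newton step fails to reduce the residual
    shat <- s_w / stot
    wmat <- matrix(0, length(lw_s), kw)
    while (it < max_iter) {
      d <- log_denom(f)
      fc <- f + logn
      for (i in seq_len(kw)) wmat[, i] <- exp(fc[i] + negum[, i] - d)
      ci <- as.numeric(crossprod(wmat, shat))
      # fixed-point residual, obtained from ci for free
      delta_sc <- logn - log(stot * ci)
      delta_sc <- delta_sc - delta_sc[1]
      resid <- max(abs(delta_sc)) * rt_
      it <- it + 1L
      if (resid <= tol) break
      g <- ci - n_eff / stot
      h <- -crossprod(wmat, shat * wmat)
      diag(h) <- diag(h) + ci
      step <- tryCatch(solve(h[-1, -1, drop = FALSE], -g[-1]),
                       error = function(e) NULL)
      f_new <- if (!is.null(step)) c(0, f[-1] + step) else NULL
      if (!is.null(f_new)) {
        d2 <- log_denom(f_new)
        fn2 <- numeric(kw)
        for (i in seq_len(kw))
          fn2[i] <- -logsumexp(lw_s + negum[, i] - d2)
        r2 <- max(abs((fn2 - fn2[1]) - f_new)) * rt_
        if (r2 < resid) {
          f <- f_new
          next
        }
      }
      f <- f + delta_sc                 # safeguard: plain fixed-point sweep
    }
  } else {
    while (it < max_iter) {
      fn <- sweep_f(f)
      resid <- max(abs(fn - f)) * rt_
      f <- fn
      it <- it + 1L
      if (resid <= tol) break
    }
  }
  converged <- resid <= tol
  if (!converged)
    warning("reweighting did not converge in ", max_iter,
            " sweeps (residual ", format(resid), " kcal/mol)")
  # final weights on all frames (zero-multiplicity frames get weight 0)
  d_all <- {
    fc <- f + logn
    rm <- -ured[, 1] + fc[1]
    if (kw > 1L) for (j in 2:kw) rm <- pmax(rm, -ured[, j] + fc[j])
    acc <- exp(-ured[, 1] + fc[1] - rm)
    if (kw > 1L) for (j in 2:kw) acc <- acc + exp(-ured[, j] + fc[j] - rm)
    rm + log(acc)
  }
  logw <- log(frame_weights) - d_all
  logw[frame_weights == 0] <- -Inf
  logz <- logsumexp(logw[is.finite(logw)])
  w <- exp(logw - logz)
  structure(list(weights = w,
                 perturbed_free_energies = f * rt_,
                 n_iterations = it,
                 converged = converged,
                 max_residual = resid,
                 temperature = samples$temperature,
                 n_per_window = n_eff),
            class = "reweight_fit")
}

#' @export
print.reweight_fit <- function(x, ...) {
  cat("Non-parametric reweighting fit\n")
  cat("  frames:", length(x$weights), " windows:",
      length(x$perturbed_free_energies), "\n")
  cat("  converged:", x$converged, " sweeps:", x$n_iterations,
      " residual:", format(x$max_residual, digits = 3), "kcal/mol\n")
  invisible(x)
}

#' @export
summary.reweight_fit <- function(object, ...) {
  f <- object$perturbed_free_energies
  ess <- 1 / sum(object$weights^2)
  cat("Non-parametric reweighting fit at", object$temperature, "K\n")
  cat(sprintf("  %d frames in %d windows; effective sample size %.0f\n",
              length(object$weights), length(f), ess))
  cat(sprintf("  perturbed free energies F_i (kcal/mol, F_1 = 0): [%.3f, %.3f]\n",
              min(f), max(f)))
  cat("  converged:", object$converged, "after", object$n_iterations,
      "sweeps, residual", format(object$max_residual, digits = 3), "kcal/mol\n")
  invisible(object)
}

#' @export
coef.reweight_fit <- function(object, ...) object$perturbed_free_energies

#' @export
weights.reweight_fit <- function(object, ...) object$weights

#' Reweighted ensemble average
#'
#' Average of a per-frame quantity under the unbiased ensemble implied by a
#' reweighting fit.
#'
#' @param fit A `reweight_fit`.
#' @param x Numeric vector, one value per pooled frame.
#' @return The weighted mean sum(w_k x_k).
#' @export
reweighted_mean <- function(fit, x) {
  stopifnot(inherits(fit, "reweight_fit"), length(x) == length(fit$weights))
  sum(fit$weights * x)
}
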