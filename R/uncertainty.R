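#' Block Bayesian bootstrap plan
#'
#' Settings for the block Bayesian bootstrap: the number of resampled
#' datasets (100 by default), the block granularity within each window
#' (either a number of contiguous blocks or a block length in frames; a last
#' partial block is kept), and the RNG seed making the resample weights
#' reproducible.
#'
#' @param n_resamples Number of resampled datasets (>= 2).
#' @param n_blocks Contiguous blocks per window (ignored if `block_length`
#'   given).
#' @param block_length Frames per block; overrides `n_blocks`.
#' @param seed Integer RNG seed.
#' @return An object of class `bootstrap_plan`.
#' @export
bootstrap_plan <- function(n_resamples = 100, n_blocks = 20,
                           block_length = NULL, seed = 1) {
  stopifnot(n_resamples >= 2)
  if (is.null(block_length)) {
    stopifnot(n_blocks >= 1)
  } else {
    stopifnot(block_length >= 1)
  }
  structure(list(n_resamples = as.integer(n_resamples),
                 n_blocks = as.integer(n_blocks),
                 block_length = if (is.null(block_length)) NULL
                                else as.integer(block_length),
                 seed = as.integer(seed)),
            class = "bootstrap_plan")
}

# contiguous block index per frame for one window of n frames
block_index <- function(n, plan) {
  if (!is.null(plan$block_length)) {
    len <- min(plan$block_length, n)
    idx <- ceiling(seq_len(n) / len)
  } else {
    nb <- min(plan$n_blocks, n)
    idx <- ceiling(seq_len(n) * nb / n)
  }
  as.integer(idx)
}

#' Block Bayesian bootstrap of an estimator over biased samples
#'
#' Estimates the sampling uncertainty of any quantity computed from pooled
#' biased samples by resampling trajectory blocks: per resample and per
#' window, the window's contiguous blocks receive flat-Dirichlet weights,
#' every frame's multiplicity is its block's Dirichlet weight times the
#' block count (so multiplicities average 1 and per-window totals are
#' preserved), and the full estimator -- including re-solving the
#' reweighting fixed point -- is re-run with those multiplicities. Blocks,
#' not frames, are reweighted so that autocorrelation within a block does
#' not deflate the error estimate.
#'
#' @param samples A `biased_samples` set.
#' @param estimator Function `(samples, frame_weights) -> numeric vector`
#'   (named components are preserved).
#' @param plan A [bootstrap_plan()].
#' @return Object of class `boot_summary`: `mean`, `sd` (per component),
#'   `resamples` (matrix, one row per successful resample), `n_failed`.
#'   Identical seeds give identical results. Estimator failures are recorded
#'   and excluded; more than 10% failures is an error.
#' @examples
#' \donttest{
#' cfg <- umbrella_config("x", 0, 0, n = 1, k = 0, temperature = 300)
#' tr <- list(w01 = cv_trajectory("w01", 1:400, data.frame(x = rnorm(400))))
#' s <- pool_samples(tr, cfg)
#' bs <- block_bayesian_bootstrap(s, function(s, fw) {
#'   c(mean_x = sum(fw * s$frames$x) / sum(fw))
#' }, bootstrap_plan(n_resamples = 50, seed = 7))
#' bs$sd
#' }
#' @export
block_bayesian_bootstrap <- function(samples, estimator,
                                     plan = bootstrap_plan()) {
  stopifnot(inherits(samples, "biased_samples"), is.function(estimator),
            inherits(plan, "bootstrap_plan"))
  ids <- names(samples$n_per_window)
  n_i <- samples$n_per_window
  blocks <- lapply(ids, function(id) block_index(n_i[[id]], plan))
  names(blocks) <- ids
  frame_window <- samples$frames$window
  # frame order within pool is per-window contiguous (pool_samples builds it
  # that way); map frames to their block slot
  offsets <- c(0, cumsum(n_i))[seq_along(ids)]
  names(offsets) <- ids

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(plan$seed)

  results <- vector("list", plan$n_resamples)
  failures <- character()
  for (r in seq_len(plan$n_resamples)) {
    fw <- numeric(nrow(samples$frames))
    for (id in ids) {
      bidx <- blocks[[id]]
      nb <- max(bidx)
      g <- stats::rgamma(nb, shape = 1)
      d <- g / sum(g)
      fw[offsets[[id]] + seq_len(n_i[[id]])] <- d[bidx] * nb
    }
    est <- tryCatch(estimator(samples, fw), error = function(e) e)
    if (inherits(est, "error")) {
      failures <- c(failures, conditionMessage(est))
    } else {
      results[[r]] <- est
    }
  }
  ok <- !vapply(results, is.null, logical(1))
  if (length(failures) > 0)
    warning(length(failures), " resample(s) failed and were excluded")
  if (length(failures) > 0.1 * plan$n_resamples)
    stop("more than 10% of bootstrap resamples failed; first error: ",
         failures[1])
  mat <- do.call(rbind, results[ok])
  structure(list(mean = colMeans(mat),
                 sd = apply(mat, 2, stats::sd),
                 resamples = mat,
                 n_failed = length(failures),
                 plan = plan),
            class = "boot_summary")
}

#' @export
print.boot_summary <- function(x, ...) {
  cat("Block Bayesian bootstrap:", nrow(x$resamples), "resamples",
      if (x$n_failed > 0) paste0("(", x$n_failed, " failed)") else "", "\n")
  print(data.frame(mean = x$mean, sd = x$sd))
  invisible(x)
}
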