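#' 1-D PMF from weighted samples
#'
#' Weighted nearest-bin histogram PMF: each frame is assigned to the nearest
#' bin center (ties go to the lower-index bin), the PMF of bin i is
#' -RT ln(sum of assigned weights), and the minimum over occupied bins is
#' shifted to zero. Unoccupied bins are flagged rather than given values.
#'
#' @param weights Normalised per-frame weights (from a [solve_weights()] fit).
#' @param cv_values Per-frame CV values (same length as `weights`).
#' @param bins Strictly increasing bin centers, in the CV's units.
#' @param temperature Temperature in kelvin.
#' @param cv CV name carried in the result.
#' @return An object of class `pmf_profile`: `cv`, `bin_centers`, `pmf`
#'   (kcal/mol, NA where unoccupied), `occupied`, `prob` (bin masses) and
#'   `stderr` (NULL until filled by a bootstrap).
#' @export
weighted_pmf <- function(weights, cv_values, bins, temperature,
                         cv = "cv") {
  stopifnot(length(weights) == length(cv_values),
            all(weights >= 0), length(bins) >= 1)
  if (is.unsorted(bins, strictly = TRUE))
    stop("bin centers must be strictly increasing")
  tot <- sum(weights)
  if (tot <= 0) stop("total weight is zero")
  idx <- nearest_bin(cv_values, bins)
  p <- vapply(seq_along(bins), function(i) sum(weights[idx == i]), numeric(1))
  p <- p / tot
  occupied <- p > 0
  if (!any(occupied)) stop("no occupied bins")
  pmf <- rep(NA_real_, length(bins))
  pmf[occupied] <- -rt(temperature) * log(p[occupied])
  pmf <- pmf - min(pmf, na.rm = TRUE)
  structure(list(cv = cv, bin_centers = bins, pmf = pmf,
                 occupied = occupied, prob = p, stderr = NULL,
                 temperature = temperature),
            class = "pmf_profile")
}

# nearest-center assignment; exact midpoint ties go to the lower index
nearest_bin <- function(v, centers) {
  if (length(centers) == 1L) return(rep(1L, length(v)))
  mids <- (centers[-1] + centers[-length(centers)]) / 2
  findInterval(v, mids, left.open = TRUE) + 1L
}

#' Construct a `pmf_profile` from explicit values
#'
#' For PMFs coming from an external table or a closed form rather than from
#' weighted samples (e.g. a bulk orientation reference).
#'
#' @param bin_centers Strictly increasing grid.
#' @param pmf Free energy values (kcal/mol); NA marks unoccupied bins.
#' @param temperature Temperature in kelvin.
#' @param cv CV name.
#' @param stderr Optional per-bin standard errors.
#' @return A `pmf_profile`.
#' @export
pmf_profile <- function(bin_centers, pmf, temperature, cv = "cv",
                        stderr = NULL) {
  stopifnot(length(bin_centers) == length(pmf))
  if (is.unsorted(bin_centers, strictly = TRUE))
    stop("bin centers must be strictly increasing")
  occupied <- is.finite(pmf)
  if (!any(occupied)) stop("PMF has no finite values")
  pmf <- pmf - min(pmf[occupied])
  structure(list(cv = cv, bin_centers = bin_centers, pmf = pmf,
                 occupied = occupied, prob = NULL, stderr = stderr,
                 temperature = temperature),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat("PMF profile over '", x$cv, "': ", sum(x$occupied), "/",
      length(x$bin_centers), " occupied bins, range [0, ",
      format(max(x$pmf, na.rm = TRUE), digits = 4), "] kcal/mol\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.pmf_profile <- function(x, ...) {
  d <- data.frame(bin_center = x$bin_centers, pmf_kcal_mol = x$pmf,
                  occupied = x$occupied)
  if (!is.null(x$stderr)) d$stderr_kcal_mol <- x$stderr
  d
}

#' @export
plot.pmf_profile <- function(x, ...) {
  graphics::plot(x$bin_centers, x$pmf, type = "l",
                 xlab = x$cv, ylab = "PMF (kcal/mol)", ...)
  if (!is.null(x$stderr)) {
    graphics::arrows(x$bin_centers, x$pmf - x$stderr,
                     x$bin_centers, x$pmf + x$stderr,
                     length = 0.02, angle = 90, code = 3)
  }
  invisible(x)
}

#' Write a PMF profile to CSV
#'
#' Columns: `bin_center`, `pmf_kcal_mol`, `occupied` and, when present,
#' `stderr_kcal_mol`.
#'
#' @param x A `pmf_profile`.
#' @param path Output path.
#' @export
write_pmf_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' 3-D grid PMF of the ligand position
#'
#' Bins per-frame ligand positions on a regular cubic lattice of
#' `voxel_size`-angstrom voxels, sets the PMF of each occupied voxel to
#' -RT ln(weight in voxel), and re-indexes the lattice so that the
#' minimum-PMF voxel sits at the origin with dG = 0. Unoccupied voxels are
#' absent from the result rather than infinite.
#'
#' @param weights Normalised per-frame weights.
#' @param positions Numeric matrix (frames x 3) of ligand positions, angstrom.
#' @param voxel_size Isotropic voxel edge length, angstrom.
#' @param temperature Temperature in kelvin.
#' @return Object of class `grid_pmf`: `voxel_size`, `temperature` and `dg`,
#'   a data frame with integer voxel offsets `ix, iy, iz` from the origin
#'   voxel and `dg` (kcal/mol, >= 0, 0 at the origin).
#' @export
grid_pmf <- function(weights, positions, voxel_size, temperature) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) == length(weights),
            voxel_size > 0, all(is.finite(positions)))
  tot <- sum(weights)
  if (tot <= 0) stop("total weight is zero")
  iv <- floor(positions / voxel_size)
  key <- paste(iv[, 1], iv[, 2], iv[, 3])
  mass <- rowsum(weights / tot, key)
  occ <- mass[, 1] > 0
  mass <- mass[occ, , drop = FALSE]
  ijk <- do.call(rbind, lapply(strsplit(rownames(mass), " "), as.integer))
  dg <- -rt(temperature) * log(mass[, 1])
  o <- which.min(dg)
  dgdf <- data.frame(ix = ijk[, 1] - ijk[o, 1],
                     iy = ijk[, 2] - ijk[o, 2],
                     iz = ijk[, 3] - ijk[o, 3],
                     dg = dg - dg[o])
  dgdf <- dgdf[order(dgdf$dg), ]
  rownames(dgdf) <- NULL
  structure(list(voxel_size = voxel_size, dg = dgdf,
                 origin = ijk[o, ],     # absolute lattice index of origin
                 temperature = temperature),
            class = "grid_pmf")
}

#' @export
print.grid_pmf <- function(x, ...) {
  cat("Grid PMF:", nrow(x$dg), "occupied voxels of",
      x$voxel_size, "A; dG range [0,",
      format(max(x$dg$dg), digits = 4), "] kcal/mol\n")
  invisible(x)
}

#' @export
as.data.frame.grid_pmf <- function(x, ...) x$dg

#' Radial shell average of a grid PMF
#'
#' Groups occupied voxels by the distance |x| of their centers from the
#' origin voxel in shells of `shell_width`, and reports the per-shell mean
#' and population standard deviation of dG(x) together with the voxel count
#' -- the radial profile used to read off the pocket-to-bulk PMF difference.
#'
#' @param grid A [grid_pmf()].
#' @param shell_width Shell thickness in angstrom.
#' @return Object of class `radial_profile`: data frame with `shell_center`
#'   (A), `mean_pmf`, `sd_pmf` (kcal/mol) and `n_voxels`.
#' @export
radial_profile <- function(grid, shell_width = grid$voxel_size) {
  stopifnot(inherits(grid, "grid_pmf"), shell_width > 0)
  d <- grid$dg
  if (nrow(d) == 0) stop("empty grid")
  r <- grid$voxel_size * sqrt(d$ix^2 + d$iy^2 + d$iz^2)
  shell <- floor(r / shell_width)
  agg_mean <- tapply(d$dg, shell, mean)
  agg_n <- tapply(d$dg, shell, length)
  # population sd (sd over all voxels in the shell, no Bessel correction)
  agg_sd <- tapply(d$dg, shell, function(v)
    sqrt(mean((v - mean(v))^2)))
  s <- as.integer(names(agg_mean))
  out <- data.frame(shell_center = (s + 0.5) * shell_width,
                    mean_pmf = as.numeric(agg_mean),
                    sd_pmf = as.numeric(agg_sd),
                    n_voxels = as.integer(agg_n))
  out <- out[order(out$shell_center), ]
  rownames(out) <- NULL
  structure(list(profile = out, shell_width = shell_width,
                 temperature = grid$temperature),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat("Radial PMF profile:", nrow(x$profile), "shells of",
      x$shell_width, "A\n")
  invisible(x)
}

#' @export
as.data.frame.radial_profile <- function(x, ...) x$profile

#' @export
plot.radial_profile <- function(x, ...) {
  p <- x$profile
  graphics::plot(p$shell_center, p$mean_pmf, type = "b", pch = 16,
                 xlab = "|x| (A)", ylab = "mean dG (kcal/mol)", ...)
  graphics::arrows(p$shell_center, p$mean_pmf - p$sd_pmf,
                   p$shell_center, p$mean_pmf + p$sd_pmf,
                   length = 0.02, angle = 90, code = 3)
  invisible(x)
}

#' Pocket-to-bulk PMF difference from a grid PMF
#'
#' The grid PMF difference entering the free-energy budget is the PMF at the
#' pocket center (0 by construction) minus the bulk plateau. The plateau is
#' the per-voxel PMF of the bulk region estimated from its Boltzmann-summed
#' mass: -RT ln( sum over bulk voxels of e^(-dG/RT) / N ), where N is the
#' geometric number of lattice voxels whose centers fall in `bulk_range`
#' (unvisited bulk voxels count as zero mass). Summing masses before taking
#' the log avoids the systematic bias a mean of per-voxel -RT ln(mass)
#' values picks up when individual bulk voxels hold few effective samples.
#'
#' @param grid A [grid_pmf()].
#' @param bulk_range Length-2 numeric, |x| interval (A) treated as bulk;
#'   must lie inside the sampled region.
#' @return List with `difference` (pocket minus bulk, kcal/mol, <= 0),
#'   `bulk_value`, `n_voxels_occupied` and `n_voxels_geometric`.
#' @export
grid_pmf_difference <- function(grid, bulk_range) {
  stopifnot(inherits(grid, "grid_pmf"), length(bulk_range) == 2,
            bulk_range[1] < bulk_range[2])
  h <- grid$voxel_size
  d <- grid$dg
  r <- h * sqrt(d$ix^2 + d$iy^2 + d$iz^2)
  sel <- r >= bulk_range[1] & r <= bulk_range[2]
  if (!any(sel))
    stop("no occupied voxels with centers in [", bulk_range[1], ", ",
         bulk_range[2], "] A")
  # geometric voxel count of the shell on the same lattice
  imax <- ceiling(bulk_range[2] / h) + 1L
  ax <- seq.int(-imax, imax)
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  rr <- h * sqrt(r2)
  n_geom <- sum(rr >= bulk_range[1] & rr <= bulk_range[2])
  rt_ <- rt(grid$temperature)
  bulk <- -rt_ * (logsumexp(-d$dg[sel] / rt_) - log(n_geom))
  list(difference = -bulk, bulk_value = bulk,
       n_voxels_occupied = sum(sel), n_voxels_geometric = n_geom)
}
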