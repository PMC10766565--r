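#' Rotation angle from Euler angles
#'
#' Converts intrinsic z-y-x (yaw-pitch-roll) Euler angles to the single
#' rotation angle Omega separating the rotated frame from the reference: the
#' quaternion scalar is
#' c = cos(phi/2) cos(theta/2) cos(psi/2) + sin(phi/2) sin(theta/2) sin(psi/2)
#' and Omega = 2 arccos(|c|), the absolute value folding the quaternion
#' double cover onto [0, pi]. Under this convention Omega equals the rotation
#' angle arccos((tr R - 1)/2) of R = Rz(phi) Ry(theta) Rx(psi).
#'
#' @param phi,psi Yaw and roll, radians in [0, 2*pi).
#' @param theta Pitch, radians in [-pi/2, pi/2].
#' @return Rotation angle(s) in [0, pi], radians. Vectorised.
#' @examples
#' omega_from_euler(0, 0, 0)    # 0
#' omega_from_euler(pi, 0, 0)   # pi
#' @export
omega_from_euler <- function(phi, theta, psi) {
  cc <- cos(phi / 2) * cos(theta / 2) * cos(psi / 2) +
    sin(phi / 2) * sin(theta / 2) * sin(psi / 2)
  2 * acos(pmin(1, abs(cc)))
}

#' Euler rotation matrix (intrinsic z-y-x)
#'
#' The rotation matrix R = Rz(phi) Ry(theta) Rx(psi) matching
#' [omega_from_euler()]; mainly useful for cross-checks against the
#' matrix-trace rotation angle.
#'
#' @inheritParams omega_from_euler
#' @return A 3x3 rotation matrix.
#' @export
euler_matrix <- function(phi, theta, psi) {
  rz <- matrix(c(cos(phi), sin(phi), 0, -sin(phi), cos(phi), 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cos(theta), 0, -sin(theta), 0, 1, 0,
                 sin(theta), 0, cos(theta)), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(psi), sin(psi), 0, -sin(psi), cos(psi)), 3, 3)
  rz %*% ry %*% rx
}

#' Bulk (unbiased) orientation-angle PMF
#'
#' Numerically accumulates the rotation-angle density p(Omega) of a freely
#' tumbling rigid body (uniform over SO(3)) by discretising the three Euler
#' angles on a regular lattice -- by default 1 degree bins, i.e. 360 x 180 x
#' 360 lattice points in (phi, theta, psi) -- weighting each lattice point by
#' the Haar density cos(theta)/(8 pi^2), computing Omega per point, and
#' depositing the weight linearly between the two nearest Omega bins
#' (nearest-bin deposition leaves lattice aliasing several times larger than
#' the discretisation error). The closed form for this density is
#' (1 - cos Omega)/pi; the lattice route reproduces it to a few 1e-4 at
#' 1-degree resolution. F(Omega) = -RT ln p(Omega), minimum shifted to 0.
#'
#' @param bin_deg Euler lattice spacing in degrees; must divide 90.
#' @param temperature Temperature in kelvin (enters only through RT).
#' @param omega_bin_deg Width of the Omega bins, degrees (default `bin_deg`).
#' @return A [pmf_profile()] over `omega` (radians) with an extra `p`
#'   element: the normalised density on the bin centers.
#' @export
bulk_orientation_pmf <- function(bin_deg = 1, temperature = 300,
                                 omega_bin_deg = bin_deg) {
  stopifnot(bin_deg > 0,
            abs(180 / bin_deg - round(180 / bin_deg)) < 1e-9,
            abs(360 / bin_deg - round(360 / bin_deg)) < 1e-9)
  h <- deg_to_rad(bin_deg)
  nphi <- round(2 * pi / h)
  nth <- round(pi / h)
  phis <- (seq_len(nphi) - 0.5) * h
  thetas <- -pi / 2 + (seq_len(nth) - 0.5) * h
  nb <- round(180 / omega_bin_deg)
  hb <- pi / nb
  acc <- numeric(nb + 1L)
  a_mat <- outer(cos(phis / 2), cos(phis / 2))
  b_mat <- outer(sin(phis / 2), sin(phis / 2))
  for (th in thetas) {
    cc <- abs(cos(th / 2) * a_mat + sin(th / 2) * b_mat)
    w_ang <- 2 * acos(pmin(1, cc))
    u <- w_ang / hb + 0.5
    i0 <- pmax(1L, pmin(nb, as.integer(floor(u))))
    frac <- pmin(1, pmax(0, u - i0))
    wt <- cos(th)
    s1 <- rowsum(1 - frac, i0)
    s2 <- rowsum(frac, i0)
    i1 <- as.integer(rownames(s1))
    i2 <- as.integer(rownames(s2)) + 1L
    acc[i1] <- acc[i1] + wt * s1[, 1]
    acc[i2] <- acc[i2] + wt * s2[, 1]
  }
  acc[nb] <- acc[nb] + acc[nb + 1L]
  acc <- acc[seq_len(nb)]
  p <- acc / sum(acc) / hb
  mids <- (seq_len(nb) - 0.5) * hb
  f <- ifelse(p > 0, -rt(temperature) * log(p), NA_real_)
  out <- pmf_profile(mids, f, temperature, cv = "omega")
  out$p <- p
  attr(out, "provenance") <- "analytic-bulk"
  out
}

#' Closed-form bulk orientation PMF on a fine grid
#'
#' The rotation-angle density of a uniform orientation is
#' p(Omega) = (1 - cos Omega)/pi on [0, pi]. This returns
#' F(Omega) = -RT ln p on a fine regular grid, suitable as the bulk-side
#' input of restraint corrections, where the restrained integrand is much
#' sharper than the 1-degree density-estimation lattice resolves.
#'
#' @param res_deg Grid resolution in degrees (default 0.01).
#' @param temperature Temperature in kelvin.
#' @return A [pmf_profile()] over `omega` with element `p`.
#' @export
bulk_orientation_pmf_analytic <- function(res_deg = 0.01, temperature = 300) {
  h <- deg_to_rad(res_deg)
  grid <- seq(h / 2, pi - h / 2, by = h)
  p <- (1 - cos(grid)) / pi
  f <- -rt(temperature) * log(p)
  out <- pmf_profile(grid, f, temperature, cv = "omega")
  out$p <- p
  attr(out, "provenance") <- "analytic-bulk"
  out
}

#' Restrained-ensemble Boltzmann average from a 1-D PMF
#'
#' The average of the harmonic restraint factor under the unrestrained
#' ensemble described by a 1-D PMF F(zeta):
#' \deqn{\langle e^{-k\zeta^2/2RT}\rangle =
#'   \frac{\int e^{-(F(\zeta)+k\zeta^2/2)/RT} d\zeta}
#'        {\int e^{-F(\zeta)/RT} d\zeta}}
#' evaluated by trapezoidal quadrature on the PMF's own grid, in log space.
#' This is the building block of every restraint correction term. The result
#' lies in (0, 1] and equals 1 exactly at k = 0.
#'
#' @param pmf A `pmf_profile` (orientation angle in radians, or an RMSD in
#'   angstrom) occupied on its grid.
#' @param k Restraint force constant, kcal/mol per (unit of the CV)^2.
#' @param temperature Temperature in kelvin.
#' @param log Return the log of the average instead.
#' @return Dimensionless average in (0, 1] (or its log).
#' @export
restraint_average_from_pmf <- function(pmf, k, temperature, log = FALSE) {
  stopifnot(inherits(pmf, "pmf_profile"), k >= 0)
  occ <- pmf$occupied
  x <- pmf$bin_centers[occ]
  f <- pmf$pmf[occ]
  if (length(x) < 2) stop("PMF has fewer than two occupied bins")
  rt_ <- rt(temperature)
  # truncate where the PMF exceeds min + 25 RT: those points contribute
  # < e^-25 and are typically the noisiest bins
  keep <- f <= min(f) + 25 * rt_
  if (sum(keep) >= 2) {
    x <- x[keep]
    f <- f[keep]
  }
  if (k == 0) return(if (log) 0 else 1)
  lognum <- log_trapz_exp(x, -(f + 0.5 * k * x^2) / rt_)
  logden <- log_trapz_exp(x, -f / rt_)
  lg <- lognum - logden
  if (!is.finite(lg))
    stop("restraint average underflowed; supply the PMF on a finer grid")
  if (log) lg else exp(lg)
}
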