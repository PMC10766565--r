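#' Boltzmann-weighted binding pocket volume
#'
#' Integrates e^(-dG(x)/RT) over the occupied voxels of a grid PMF:
#' V_P = sum over voxels of e^(-dG/RT) * voxel_size^3. Because dG is
#' measured from the pocket minimum, only low-PMF voxels contribute
#' appreciably, so no explicit pocket boundary is needed; an optional radius
#' cutoff is provided for sensitivity analysis. The cumulative series over
#' voxels sorted by ascending dG is returned so convergence of the sum can
#' be inspected (the usual check plots the first ~20 terms).
#'
#' @param grid A [grid_pmf()].
#' @param radius_cutoff Optional |x| cutoff in angstrom; voxels farther from
#'   the origin are excluded.
#' @return List with `v_pocket` (angstrom^3), `cumulative` (data frame:
#'   `rank`, `dg`, `v_cum`) and `voxel_size`.
#' @export
pocket_volume <- function(grid, radius_cutoff = NULL) {
  stopifnot(inherits(grid, "grid_pmf"))
  d <- grid$dg
  if (nrow(d) == 0) stop("empty grid")
  if (!is.null(radius_cutoff)) {
    r <- grid$voxel_size * sqrt(d$ix^2 + d$iy^2 + d$iz^2)
    d <- d[r <= radius_cutoff, , drop = FALSE]
    if (nrow(d) == 0) stop("no voxels within the radius cutoff")
  }
  dg <- sort(d$dg)
  contrib <- exp(-dg / rt(grid$temperature)) * grid$voxel_size^3
  vcum <- cumsum(contrib)
  list(v_pocket = vcum[length(vcum)],
       cumulative = data.frame(rank = seq_along(dg), dg = dg, v_cum = vcum),
       voxel_size = grid$voxel_size)
}

#' Standard-state volume terms
#'
#' Converts pocket and bulk volumes into their free-energy contributions:
#' dG_P = -RT ln(V_P / A^3), dG_B = -RT ln(V_B / A^3) and
#' dG_V = dG_P - dG_B = -RT ln(V_P / V_B). The default bulk volume is the
#' 1 M standard-state volume per molecule, 1e27/N_A ~ 1661 A^3, for which
#' dG_B ~ -7.42 RT.
#'
#' @param v_pocket Pocket volume, angstrom^3.
#' @param temperature Temperature in kelvin.
#' @param v_bulk Bulk volume, angstrom^3 (default [standard_volume()]).
#' @return Object of class `volume_terms`: `v_pocket`, `v_bulk`,
#'   `dg_pocket`, `dg_bulk`, `dg_volume` (kcal/mol), `temperature`.
#' @examples
#' vt <- volume_terms(20, 300)
#' vt$dg_volume   # -RT ln(20/1660.5)
#' @export
volume_terms <- function(v_pocket, temperature, v_bulk = standard_volume()) {
  stopifnot(is.numeric(v_pocket), is.numeric(v_bulk))
  if (v_pocket <= 0) stop("pocket volume must be positive")
  if (v_bulk <= 0) stop("bulk volume must be positive")
  rt_ <- rt(temperature)
  dg_pocket <- -rt_ * log(v_pocket)
  dg_bulk <- -rt_ * log(v_bulk)
  structure(list(v_pocket = v_pocket, v_bulk = v_bulk,
                 dg_pocket = dg_pocket, dg_bulk = dg_bulk,
                 dg_volume = dg_pocket - dg_bulk,
                 temperature = temperature),
            class = "volume_terms")
}

#' @export
print.volume_terms <- function(x, ...) {
  cat(sprintf("V_P = %.4g A^3, V_B = %.4g A^3\n", x$v_pocket, x$v_bulk))
  cat(sprintf("dG_P = %.4f, dG_B = %.4f, dG_V = %.4f kcal/mol\n",
              x$dg_pocket, x$dg_bulk, x$dg_volume))
  invisible(x)
}

#' Assemble the standard binding free energy budget
#'
#' Sums the additive contributions to the standard (absolute) binding free
#' energy:
#' dG0 = grid_pmf_difference + sum of restraint corrections + dG_V,
#' where `grid_pmf_difference` is tabulated in the pocket-minus-bulk
#' convention (a negative number for a binder; it equals minus the
#' bulk-minus-pocket PMF difference). Per-term 1-s.d. uncertainties are
#' propagated as the root sum of squares, and the dissociation constant
#' follows from K_d = exp(dG0/RT) M.
#'
#' @param grid_pmf_difference Pocket-minus-bulk grid PMF difference,
#'   kcal/mol.
#' @param corrections List of [restraint_correction()] (possibly empty).
#' @param dg_volume Volume term dG_V, kcal/mol (never optional).
#' @param temperature Temperature in kelvin.
#' @param grid_err,dg_volume_err Optional 1-s.d. errors of the grid term and
#'   the volume term, kcal/mol.
#' @return Object of class `fe_budget` with the terms, `dg_standard`,
#'   `dg_err` (NA if no errors supplied), `kd` (molar) and `temperature`.
#' @examples
#' b <- assemble_dg0(-13.2, list(), 2.5, 300)   # no corrections
#' b$dg_standard
#' @export
assemble_dg0 <- function(grid_pmf_difference, corrections = list(),
                         dg_volume, temperature,
                         grid_err = NA_real_, dg_volume_err = NA_real_) {
  if (missing(dg_volume) || is.null(dg_volume) || !is.finite(dg_volume))
    stop("the volume term dg_volume is required")
  stopifnot(is.numeric(grid_pmf_difference), is.list(corrections))
  du <- vapply(corrections, function(cc) {
    stopifnot(inherits(cc, "restraint_correction"))
    cc$du
  }, numeric(1))
  du_err <- vapply(corrections, function(cc) cc$du_err, numeric(1))
  dg_standard <- grid_pmf_difference + sum(du) + dg_volume
  errs <- c(grid_err, du_err, dg_volume_err)
  dg_err <- if (all(is.na(errs))) NA_real_ else
    sqrt(sum(errs[!is.na(errs)]^2))
  structure(list(grid_pmf_difference = grid_pmf_difference,
                 grid_err = grid_err,
                 corrections = corrections,
                 dg_volume = dg_volume,
                 dg_volume_err = dg_volume_err,
                 dg_standard = dg_standard,
                 dg_err = dg_err,
                 kd = kd_from_dg(dg_standard, temperature),
                 temperature = temperature),
            class = "fe_budget")
}

#' @export
print.fe_budget <- function(x, ...) {
  fmt <- function(v, e) if (is.na(e)) sprintf("%.2f", v) else
    sprintf("%.2f +/- %.2f", v, e)
  cat("Binding free-energy budget (kcal/mol) at", x$temperature, "K\n")
  cat("  grid PMF difference (pocket - bulk):",
      fmt(x$grid_pmf_difference, x$grid_err), "\n")
  for (cc in x$corrections) {
    cond <- if (length(cc$conditioned_on))
      paste0("^", paste(cc$conditioned_on, collapse = ",")) else ""
    cat(sprintf("  dU_%s%s: %s\n", cc$cv, cond, fmt(cc$du, cc$du_err)))
  }
  cat("  dG_V:", fmt(x$dg_volume, x$dg_volume_err), "\n")
  cat("  dG0 :", fmt(x$dg_standard, x$dg_err), "\n")
  cat(sprintf("  K_d : %.3g M\n", x$kd))
  invisible(x)
}

#' @export
summary.fe_budget <- function(object, ...) {
  print(object)
  if (!is.na(object$dg_err)) {
    lo <- object$dg_standard - object$dg_err
    hi <- object$dg_standard + object$dg_err
    cat(sprintf("  K_d range (+/- 1 s.d.): %.3g - %.3g M\n",
                kd_from_dg(lo, object$temperature),
                kd_from_dg(hi, object$temperature)))
  }
  invisible(object)
}

#' Convert between dissociation constant and binding free energy
#'
#' dG0 = RT ln(K_d / 1 M) and its exact inverse K_d = exp(dG0/RT) M.
#'
#' @param kd Dissociation constant in molar; must be > 0.
#' @param dg Standard binding free energy in kcal/mol.
#' @param temperature Temperature in kelvin.
#' @return Free energy in kcal/mol, or K_d in molar.
#' @examples
#' dg_from_kd(1.68e-6, 298.15)   # ~ -7.88 kcal/mol
#' @export
dg_from_kd <- function(kd, temperature) {
  if (any(kd <= 0)) stop("K_d must be positive")
  rt(temperature) * log(kd)
}

#' @rdname dg_from_kd
#' @export
kd_from_dg <- function(dg, temperature) {
  exp(dg / rt(temperature))
}
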