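#' Physical constants and unit helpers
#'
#' All free energies in this package are in kcal/mol, distances and RMSDs in
#' angstrom, angles in radians internally. `gas_constant()` returns R in
#' kcal mol^-1 K^-1; `rt(temperature)` the thermal energy RT in kcal/mol;
#' `standard_volume()` the 1 M standard-state volume per molecule in
#' angstrom^3 (1e27 / N_A, approximately 1661).
#'
#' @param temperature Temperature in kelvin.
#' @return A numeric scalar.
#' @examples
#' rt(300)              # ~0.596 kcal/mol
#' standard_volume()    # ~1660.5 A^3
#' @export
gas_constant <- function() 1.987204e-3

#' @rdname gas_constant
#' @export
rt <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  gas_constant() * temperature
}

#' @rdname gas_constant
#' @export
standard_volume <- function() 1e27 / 6.02214076e23

# force-constant unit conversion: kcal/(mol deg^2) -> kcal/(mol rad^2)
deg2_to_rad2 <- function(k) k * (180 / pi)^2

deg_to_rad <- function(x) x * pi / 180

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log of trapezoid integral of exp(logf) on grid x (strictly increasing)
log_trapz_exp <- function(x, logf) {
  n <- length(x)
  stopifnot(n >= 2, length(logf) == n)
  # trapezoid weights
  w <- c(diff(x) / 2, 0) + c(0, diff(x) / 2)
  logsumexp(logf + log(w))
}
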