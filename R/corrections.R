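#' Free-energy correction for one always-on harmonic restraint
#'
#' A restraint k/2 zeta^2 held on during the distance umbrella-sampling run
#' shifts the measured pocket-to-bulk PMF difference; the correction removing
#' it is
#' \deqn{\Delta U = -RT \ln \frac{\langle e^{-k\zeta^2/2RT}\rangle_{bulk}}
#'                               {\langle e^{-k\zeta^2/2RT}\rangle_{pocket}}}
#' with both averages computed by quadrature from the unrestrained 1-D PMF of
#' zeta in the bulk and in the pocket ([restraint_average_from_pmf()]).
#' Swapping pocket and bulk flips the sign; identical PMFs give 0.
#'
#' @param pocket_pmf,bulk_pmf `pmf_profile`s of the restrained CV measured in
#'   the binding pocket and in the bulk, with any restraints named in
#'   `conditioned_on` (and only those) applied while they were measured.
#' @param k Restraint force constant, kcal/mol per (CV unit)^2.
#' @param temperature Temperature in kelvin.
#' @param cv CV name recorded in the result.
#' @param conditioned_on Character vector: CVs already restrained when the
#'   two PMFs were measured (provenance bookkeeping for nested restraints).
#' @param du_err Optional 1-s.d. uncertainty to attach (kcal/mol).
#' @return Object of class `restraint_correction` with elements `cv`, `k`,
#'   `du` (kcal/mol), `du_err`, `conditioned_on`.
#' @export
restraint_correction <- function(pocket_pmf, bulk_pmf, k, temperature,
                                 cv = pocket_pmf$cv,
                                 conditioned_on = character(),
                                 du_err = NA_real_) {
  stopifnot(inherits(pocket_pmf, "pmf_profile"),
            inherits(bulk_pmf, "pmf_profile"))
  if (!identical(pocket_pmf$cv, bulk_pmf$cv))
    warning("pocket and bulk PMFs are over different CVs ('",
            pocket_pmf$cv, "' vs '", bulk_pmf$cv, "')")
  lb <- restraint_average_from_pmf(bulk_pmf, k, temperature, log = TRUE)
  lp <- restraint_average_from_pmf(pocket_pmf, k, temperature, log = TRUE)
  du <- -rt(temperature) * (lb - lp)
  structure(list(cv = cv, k = k, du = du, du_err = du_err,
                 conditioned_on = conditioned_on,
                 temperature = temperature),
            class = "restraint_correction")
}

#' @export
print.restraint_correction <- function(x, ...) {
  cond <- if (length(x$conditioned_on))
    paste0(" | ", paste(x$conditioned_on, collapse = ",")) else ""
  cat(sprintf("dU(%s%s) = %.4f kcal/mol (k = %.4g)\n",
              x$cv, cond, x$du, x$k))
  invisible(x)
}

#' Tabulated restraint correction
#'
#' Wraps an externally known correction value (e.g. a published table entry
#' or a value computed elsewhere) as a [restraint_correction()] so it can
#' enter [assemble_dg0()].
#'
#' @param cv CV name.
#' @param du Correction, kcal/mol.
#' @param du_err Optional 1-s.d. uncertainty.
#' @param conditioned_on CVs restrained when the value was measured.
#' @return A `restraint_correction`.
#' @export
manual_correction <- function(cv, du, du_err = NA_real_,
                              conditioned_on = character()) {
  stopifnot(is.finite(du))
  structure(list(cv = cv, k = NA_real_, du = du, du_err = du_err,
                 conditioned_on = conditioned_on, temperature = NA_real_),
            class = "restraint_correction")
}

#' Ordered chain of nested restraints
#'
#' Describes restraints applied together during the distance run and removed
#' one at a time, innermost last: for restraints (alpha, beta, gamma) the
#' corrections are dU_gamma (nothing else restrained when its PMFs were
#' measured), dU_beta^gamma (gamma still on), dU_alpha^{beta,gamma}. Each
#' entry carries the pocket and bulk PMFs of its CV measured under exactly
#' the restraints that follow it in the chain.
#'
#' @param ... Entries created by [chain_restraint()].
#' @return An object of class `restraint_chain`.
#' @export
restraint_chain <- function(...) {
  entries <- list(...)
  if (length(entries) == 0L) stop("a restraint chain needs >= 1 entry")
  for (e in entries)
    if (!inherits(e, "chain_restraint"))
      stop("all entries must be chain_restraint objects")
  structure(entries, class = "restraint_chain")
}

#' @rdname restraint_chain
#' @param cv Restrained CV name.
#' @param k Force constant (kcal/mol per unit^2).
#' @param pocket_pmf,bulk_pmf `pmf_profile`s of the CV in pocket and bulk.
#' @param conditioned_on CVs restrained while these PMFs were measured.
#' @export
chain_restraint <- function(cv, k, pocket_pmf, bulk_pmf,
                            conditioned_on = character()) {
  stopifnot(is.character(cv), k >= 0,
            inherits(pocket_pmf, "pmf_profile"),
            inherits(bulk_pmf, "pmf_profile"))
  structure(list(cv = cv, k = k, pocket_pmf = pocket_pmf,
                 bulk_pmf = bulk_pmf, conditioned_on = conditioned_on),
            class = "chain_restraint")
}

#' Correction terms for a chain of nested restraints
#'
#' Computes the ordered corrections for a [restraint_chain()]: the last
#' restraint in the chain is removed first with no conditioning, the one
#' before it conditioned on the last, and so on. Validates that each entry's
#' `conditioned_on` metadata matches the CVs that follow it in the chain --
#' a silent mix-up between conditioned and unconditioned PMFs is the main
#' failure mode of nested corrections.
#'
#' @param chain A [restraint_chain()].
#' @param temperature Temperature in kelvin.
#' @return List of [restraint_correction()], outermost first, i.e.
#'   `[dU_gamma, dU_beta^gamma, dU_alpha^{beta,gamma}]` for a 3-chain.
#' @export
chain_corrections <- function(chain, temperature) {
  stopifnot(inherits(chain, "restraint_chain"))
  n <- length(chain)
  cvs <- vapply(chain, function(e) e$cv, character(1))
  out <- vector("list", n)
  for (pos in seq.int(n, 1L)) {           # removal order: last entry first
    e <- chain[[pos]]
    expected <- if (pos < n) cvs[seq.int(pos + 1L, n)] else character()
    if (!setequal(e$conditioned_on, expected))
      stop("restraint '", e$cv, "': conditioned_on is {",
           paste(e$conditioned_on, collapse = ","), "} but the chain ",
           "requires {", paste(expected, collapse = ","), "}")
    out[[n - pos + 1L]] <- restraint_correction(
      e$pocket_pmf, e$bulk_pmf, e$k, temperature,
      cv = e$cv, conditioned_on = e$conditioned_on)
  }
  out
}
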