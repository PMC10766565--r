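#' Collective-variable trajectory objects
#'
#' A `cv_trajectory` holds the per-frame values of named collective variables
#' (CVs) for one umbrella-sampling window: an integer `step` per frame and one
#' numeric column per CV. Distances, positions and RMSDs are in angstrom;
#' angular CVs are stored in radians. Steps must be strictly increasing and
#' all values finite.
#'
#' @param window_id Identifier of the window the frames came from.
#' @param step Integer vector of MD step numbers, strictly increasing.
#' @param values Data frame with one numeric column per CV, one row per frame.
#' @return An object of class `cv_trajectory`.
#' @seealso [read_cv_trajectory()], [pool_samples()]
#' @export
cv_trajectory <- function(window_id, step, values) {
  values <- as.data.frame(values)
  step <- as.integer(step)
  if (nrow(values) != length(step))
    stop("`step` and `values` must have one entry per frame")
  if (nrow(values) == 0L) stop("a trajectory must contain at least one frame")
  if (any(diff(step) <= 0L))
    stop("steps must be strictly increasing within a window")
  for (cv in names(values)) {
    v <- values[[cv]]
    if (!is.numeric(v)) stop("CV column '", cv, "' is not numeric")
    if (any(!is.finite(v)))
      stop("CV column '", cv, "' contains non-finite values")
  }
  structure(list(window_id = window_id, step = step, values = values),
            class = "cv_trajectory")
}

#' @export
print.cv_trajectory <- function(x, ...) {
  cat("CV trajectory: window '", x$window_id, "', ",
      nrow(x$values), " frames, CVs: ",
      paste(names(x$values), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a collective-variable trajectory file
#'
#' Parses the whitespace-delimited, `#`-commented trajectory dialect used by
#' collective-variable engines: comment/header lines start with `#`, the last
#' header line before the data names the columns, the first column is `step`.
#' CVs listed in `degrees` are converted to radians on input.
#'
#' @param path Path to the trajectory file.
#' @param declared_cvs Character vector of CV names that must be present.
#' @param degrees CV names whose file values are in degrees.
#' @param window_id Window identifier (defaults to the file name).
#' @return A [cv_trajectory()].
#' @export
read_cv_trajectory <- function(path, declared_cvs, degrees = character(),
                               window_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  blank <- grepl("^\\s*$", lines)
  header <- NULL
  data_rows <- list()
  data_lineno <- integer()
  for (i in seq_along(lines)) {
    if (blank[i]) next
    if (is_comment[i]) {
      tok <- strsplit(sub("^\\s*#\\s*", "", lines[i]), "\\s+")[[1]]
      if (length(tok) > 0 && tok[1] == "step") header <- tok
    } else {
      data_rows[[length(data_rows) + 1L]] <- lines[i]
      data_lineno[length(data_rows)] <- i
    }
  }
  if (is.null(header))
    stop("no '# step ...' header line found in ", path)
  missing <- setdiff(declared_cvs, header)
  if (length(missing) > 0)
    stop("declared CV column(s) missing from ", path, ": ",
         paste(missing, collapse = ", "))
  n <- length(data_rows)
  if (n == 0L) stop("no data rows in ", path)
  mat <- matrix(NA_real_, n, length(header))
  for (r in seq_len(n)) {
    tok <- strsplit(trimws(data_rows[[r]]), "\\s+")[[1]]
    if (length(tok) != length(header))
      stop("line ", data_lineno[r], ": expected ", length(header),
           " columns, found ", length(tok))
    val <- suppressWarnings(as.numeric(tok))
    if (any(is.na(val)))
      stop("line ", data_lineno[r], ": non-numeric token '",
           tok[which(is.na(val))[1]], "'")
    mat[r, ] <- val
  }
  colnames(mat) <- header
  values <- as.data.frame(mat[, declared_cvs, drop = FALSE])
  for (cv in intersect(degrees, declared_cvs))
    values[[cv]] <- deg_to_rad(values[[cv]])
  cv_trajectory(window_id, mat[, "step"], values)
}

#' Write a collective-variable trajectory file
#'
#' Inverse of [read_cv_trajectory()]: writes a `# step ...` header followed by
#' whitespace-delimited rows at full double precision, so a read/write
#' round trip reproduces the values exactly.
#'
#' @param traj A [cv_trajectory()].
#' @param path Output path.
#' @param degrees CV names to be written in degrees.
#' @return `path`, invisibly.
#' @export
write_cv_trajectory <- function(traj, path, degrees = character()) {
  stopifnot(inherits(traj, "cv_trajectory"))
  values <- traj$values
  for (cv in intersect(degrees, names(values)))
    values[[cv]] <- values[[cv]] * 180 / pi
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", paste(c("step", names(values)), collapse = " ")), con)
  body <- cbind(format(traj$step, scientific = FALSE),
                vapply(values, function(v) formatC(v, format = "g", digits = 17),
                       character(nrow(values))))
  writeLines(apply(body, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Harmonic bias specifications and window configurations
#'
#' A `bias_spec` describes one harmonic bias U(v) = k/2 (v - center)^2 on a
#' named CV; `center` in the CV's internal unit (angstrom or radian), `k` in
#' kcal/mol per unit squared. A `window_config` is an ordered set of windows,
#' each with one or more biases, plus the simulation temperature; it defines
#' the N biasing potentials the reweighting estimator removes.
#'
#' @param cv CV name.
#' @param center Harmonic center (internal units).
#' @param k Force constant, kcal/mol per (CV unit)^2; must be >= 0.
#' @param kind Bias functional form; only `"harmonic"` is supported.
#' @return `bias_spec` / `window_config` objects.
#' @export
bias_spec <- function(cv, center, k, kind = "harmonic") {
  stopifnot(is.character(cv), length(cv) == 1L)
  if (!identical(kind, "harmonic")) stop("only harmonic biases are supported")
  if (!is.finite(center)) stop("bias center must be finite")
  if (!is.finite(k) || k < 0) stop("force constant must be finite and >= 0")
  structure(list(cv = cv, center = as.numeric(center), k = as.numeric(k),
                 kind = kind), class = "bias_spec")
}

#' @rdname bias_spec
#' @param windows List of windows; each a list with elements `id` and
#'   `biases` (a list of [bias_spec()]).
#' @param temperature Temperature in kelvin.
#' @param restraints List of [bias_spec()] held on in *every* window
#'   (always-on restraints). These are part of the sampled ensemble, not of
#'   the window-to-window bias differences: the reweighting estimator leaves
#'   them in place (the reconstructed PMF is the restrained one) and they
#'   are removed afterwards with analytic correction terms. Listing a sharp
#'   restraint among a window's `biases` instead would ask the estimator to
#'   reweight to the unrestrained ensemble, which the confined samples
#'   cannot support.
#' @export
window_config <- function(windows, temperature, restraints = list()) {
  if (length(windows) == 0L) stop("a window configuration needs >= 1 window")
  stopifnot(is.numeric(temperature), temperature > 0)
  for (b in restraints)
    if (!inherits(b, "bias_spec")) stop("restraints must be bias_spec objects")
  ids <- character(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (is.null(w$id)) stop("window ", i, " has no id")
    if (length(w$biases) == 0L) stop("window '", w$id, "' declares no biases")
    for (b in w$biases)
      if (!inherits(b, "bias_spec")) stop("window '", w$id,
                                          "': biases must be bias_spec objects")
    ids[i] <- as.character(w$id)
  }
  if (anyDuplicated(ids)) stop("duplicate window ids")
  structure(list(windows = windows, restraints = restraints,
                 temperature = as.numeric(temperature)),
            class = "window_config")
}

#' @export
print.window_config <- function(x, ...) {
  cat("Window configuration:", length(x$windows), "windows at",
      x$temperature, "K\n")
  cvs <- unique(unlist(lapply(x$windows, function(w)
    vapply(w$biases, function(b) b$cv, character(1)))))
  cat("  biased CVs:", paste(cvs, collapse = ", "), "\n")
  if (length(x$restraints) > 0)
    cat("  always-on restraints:",
        paste(vapply(x$restraints, format, character(1)), collapse = "; "),
        "\n")
  invisible(x)
}

#' @export
format.bias_spec <- function(x, ...)
  sprintf("%s: center %.6g, k %.6g", x$cv, x$center, x$k)

#' @export
print.bias_spec <- function(x, ...) {
  cat("harmonic bias on", format(x), "\n")
  invisible(x)
}

#' Read and write window/bias configurations
#'
#' The configuration is a YAML file with a `temperature` (kelvin), a
#' `windows` list -- each window has an `id` and a list of `biases` with
#' fields `cv`, `center`, `k` and optional `unit` (`"A"`, `"rad"` or
#' `"deg"`) -- and an optional top-level `restraints` list of always-on
#' restraints in the same format. Degree-based entries are converted at the
#' boundary: centers by pi/180, force constants by (180/pi)^2, so that all
#' internal angle algebra runs in radians.
#'
#' @param path Path to the YAML configuration.
#' @return [read_window_config()] returns a [window_config()];
#'   [write_window_config()] returns `path` invisibly.
#' @export
read_window_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$temperature)) stop("config is missing 'temperature'")
  if (is.null(raw$windows) || length(raw$windows) == 0L)
    stop("config declares zero windows")
  parse_bias <- function(b, where) {
    if (is.null(b$cv) || is.null(b$center) || is.null(b$k))
      stop(where, ": each bias needs cv, center and k")
    unit <- if (is.null(b$unit)) "A" else b$unit
    center <- as.numeric(b$center)
    k <- as.numeric(b$k)
    if (identical(unit, "deg")) {
      center <- deg_to_rad(center)
      k <- deg2_to_rad2(k)
    } else if (!unit %in% c("A", "rad")) {
      stop(where, ": unknown unit '", unit, "'")
    }
    bias_spec(b$cv, center, k)
  }
  windows <- lapply(seq_along(raw$windows), function(i) {
    w <- raw$windows[[i]]
    id <- if (is.null(w$id)) sprintf("w%02d", i) else as.character(w$id)
    if (is.null(w$biases)) stop("window '", id, "' has no biases")
    biases <- lapply(w$biases, parse_bias,
                     where = paste0("window '", id, "'"))
    list(id = id, biases = biases)
  })
  restraints <- lapply(raw$restraints, parse_bias, where = "restraints")
  window_config(windows, as.numeric(raw$temperature), restraints)
}

#' @rdname read_window_config
#' @param config A [window_config()].
#' @export
write_window_config <- function(config, path) {
  stopifnot(inherits(config, "window_config"))
  # internal units (angstrom/radian) are written unconverted as unit "A"
  ser <- function(b) list(cv = b$cv, center = b$center, k = b$k, unit = "A")
  out <- list(
    temperature = config$temperature,
    windows = lapply(config$windows, function(w)
      list(id = w$id, biases = lapply(w$biases, ser)))
  )
  if (length(config$restraints) > 0)
    out$restraints <- lapply(config$restraints, ser)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Build an evenly spaced distance-window configuration
#'
#' Convenience constructor for the common umbrella-sampling layout: `n`
#' windows with harmonic biases on one CV, centers evenly spaced from `from`
#' to `to`, a shared force constant, and optional always-on restraints added
#' to every window.
#'
#' @param cv Name of the biased CV.
#' @param from,to First and last window centers (internal units).
#' @param n Number of windows.
#' @param k Force constant for the window biases.
#' @param temperature Temperature in kelvin.
#' @param restraints List of [bias_spec()]: always-on restraints (see
#'   [window_config()]).
#' @return A [window_config()].
#' @examples
#' cfg <- umbrella_config("d", 10, 40, n = 31, k = 2, temperature = 300)
#' length(cfg$windows)
#' @export
umbrella_config <- function(cv, from, to, n, k, temperature,
                            restraints = list()) {
  centers <- seq(from, to, length.out = n)
  windows <- lapply(seq_len(n), function(i) list(
    id = sprintf("w%02d", i),
    biases = list(bias_spec(cv, centers[i], k))))
  window_config(windows, temperature, restraints)
}
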