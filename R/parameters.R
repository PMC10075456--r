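#' @useDynLib lileyfit, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Canonical ordering of the decision vector. The deterministic Liley model has
## 22 parameters; the noise amplitude xi makes a 23-entry decision vector, all
## bounded by the physiological ranges in liley_bounds().
.liley_param_names <- c(
  "he_rest", "hi_rest",
  "N_ee", "N_ei", "N_ie", "N_ii",
  "Gamma_e", "Gamma_i",
  "gamma_e", "gamma_i",
  "tau_e", "tau_i",
  "Se_max", "Si_max",
  "mu_e", "mu_i",
  "sigma_e", "sigma_i",
  "he_eq", "hi_eq",
  "p_ee", "p_ei",
  "xi"
)

#' Names of the Liley model parameters in canonical order
#'
#' The fixed ordering used for decision vectors, bounds and all matrix-valued
#' parameter samples: resting potentials, synaptic connection counts, synaptic
#' gains, postsynaptic rate constants, membrane time constants, maximum firing
#' rates, firing thresholds, threshold spreads, reversal potentials, extrinsic
#' input rates, and the noise amplitude `xi`.
#'
#' @return Character vector of length 23.
#' @export
liley_param_names <- function() .liley_param_names

#' Physiological bounds of the Liley model parameter space
#'
#' Lower and upper limits of the search box for every parameter, in the
#' package's internal units (mV, ms, 1/ms). These are the commonly used
#' physiological ranges for the local Liley model: resting potentials
#' -80..-60 mV, excitatory reversal -20..-10 mV, inhibitory reversal
#' -90..-65 mV, synaptic counts 100..5000, gains 0.1..2 mV, rate constants
#' 0.01..1 /ms, membrane time constants 5..150 ms, firing parameters within
#' their sigmoid ranges, extrinsic input 0..10 /ms and noise amplitude 0..10.
#'
#' @return Object of class `liley_bounds`: list with numeric vectors `lower`
#'   and `upper` (length 23, named in canonical order).
#' @export
liley_bounds <- function() {
  lower <- c(
    he_rest = -80, hi_rest = -80,
    N_ee = 2000, N_ei = 2000, N_ie = 100, N_ii = 100,
    Gamma_e = 0.1, Gamma_i = 0.1,
    gamma_e = 0.1, gamma_i = 0.01,
    tau_e = 5, tau_i = 5,
    Se_max = 0.05, Si_max = 0.05,
    mu_e = -55, mu_i = -55,
    sigma_e = 2, sigma_i = 2,
    he_eq = -20, hi_eq = -90,
    p_ee = 0, p_ei = 0,
    xi = 0
  )
  upper <- c(
    he_rest = -60, hi_rest = -60,
    N_ee = 5000, N_ei = 5000, N_ie = 1000, N_ii = 1000,
    Gamma_e = 2, Gamma_i = 2,
    gamma_e = 1, gamma_i = 0.5,
    tau_e = 150, tau_i = 150,
    Se_max = 0.5, Si_max = 0.5,
    mu_e = -40, mu_i = -40,
    sigma_e = 7, sigma_i = 7,
    he_eq = -10, hi_eq = -65,
    p_ee = 10, p_ei = 10,
    xi = 10
  )
  structure(list(lower = lower, upper = upper), class = "liley_bounds")
}

#' Construct a Liley parameter set
#'
#' Builds a validated parameter set for the local (spatially homogeneous)
#' Liley neural mass model. Unspecified parameters take the typical values of
#' [liley_typical()]. Internal units are mV and ms throughout; rates are 1/ms.
#'
#' @param ... Named parameter values overriding the typical set. Names must be
#'   among [liley_param_names()].
#' @param .values Optional full numeric vector (length 23) in canonical order;
#'   if given, `...` must be empty.
#' @param check_bounds If `TRUE`, error when a value falls outside the
#'   physiological bounds of [liley_bounds()].
#' @return Named numeric vector of class `liley_params`.
#' @export
liley_params <- function(..., .values = NULL, check_bounds = FALSE) {
  if (!is.null(.values)) {
    stopifnot(length(list(...)) == 0L)
    v <- as.numeric(.values)
    if (length(v) != 23L)
      stop("'.values' must have length 23 (canonical parameter order)")
    names(v) <- .liley_param_names
  } else {
    v <- unclass(liley_typical())
    dots <- list(...)
    if (length(dots)) {
      nm <- names(dots)
      if (is.null(nm) || any(nm == ""))
        stop("all parameter overrides must be named")
      bad <- setdiff(nm, .liley_param_names)
      if (length(bad))
        stop("unknown parameter(s): ", paste(bad, collapse = ", "))
      v[nm] <- vapply(dots, as.numeric, numeric(1))
    }
  }
  p <- structure(v, class = "liley_params")
  validate_liley_params(p, check_bounds = check_bounds)
  p
}

#' Typical Liley model parameter values
#'
#' The commonly quoted typical operating point of the model (resting
#' potentials -70 mV, connection counts 4000/3034/536/536, gains 0.4/0.8 mV,
#' rate constants 0.3/0.065 per ms, membrane time constants 10 ms, maximum
#' firing rates 0.5 per ms, thresholds -50 mV with 5 mV spread). The reversal
#' potentials, extrinsic input rates and noise amplitude have no single
#' canonical value; the package uses the range midpoints for the reversal
#' potentials and moderate input rates (p_ee = 2/ms, p_ei = 5/ms, at which the
#' deterministic model has a single stable fixed point) with noise amplitude
#' 0.5.
#'
#' @return Object of class `liley_params`.
#' @export
liley_typical <- function() {
  structure(c(
    he_rest = -70, hi_rest = -70,
    N_ee = 4000, N_ei = 3034, N_ie = 536, N_ii = 536,
    Gamma_e = 0.4, Gamma_i = 0.8,
    gamma_e = 0.3, gamma_i = 0.065,
    tau_e = 10, tau_i = 10,
    Se_max = 0.5, Si_max = 0.5,
    mu_e = -50, mu_i = -50,
    sigma_e = 5, sigma_i = 5,
    he_eq = -15, hi_eq = -77.5,
    p_ee = 2, p_ei = 5,
    xi = 0.5
  ), class = "liley_params")
}

#' Validate a Liley parameter set
#'
#' Checks structural validity: positive time constants, rate constants and
#' threshold spreads, and non-degenerate reversal-minus-rest denominators so
#' the membrane weighting terms of the model equations are well defined.
#'
#' @param p A `liley_params` object or named numeric vector.
#' @param check_bounds Also require every value inside [liley_bounds()].
#' @return `p`, invisibly; errors on invalid input.
#' @export
validate_liley_params <- function(p, check_bounds = FALSE) {
  v <- unclass(p)
  if (length(v) != 23L || !all(.liley_param_names %in% names(v)))
    stop("parameter set must contain all 23 canonical parameters")
  v <- v[.liley_param_names]
  if (any(!is.finite(v))) stop("non-finite parameter value")
  if (v[["sigma_e"]] <= 0 || v[["sigma_i"]] <= 0)
    stop("sigma_e and sigma_i must be positive")
  if (v[["tau_e"]] <= 0 || v[["tau_i"]] <= 0)
    stop("tau_e and tau_i must be positive")
  if (v[["gamma_e"]] <= 0 || v[["gamma_i"]] <= 0)
    stop("gamma_e and gamma_i must be positive")
  if (v[["Se_max"]] <= 0 || v[["Si_max"]] <= 0)
    stop("Se_max and Si_max must be positive")
  den <- c(
    abs(v[["he_eq"]] - v[["he_rest"]]), abs(v[["hi_eq"]] - v[["he_rest"]]),
    abs(v[["he_eq"]] - v[["hi_rest"]]), abs(v[["hi_eq"]] - v[["hi_rest"]])
  )
  if (any(den <= 0))
    stop("reversal potentials must differ from both resting potentials")
  if (check_bounds) {
    b <- liley_bounds()
    if (any(v < b$lower - 1e-12) || any(v > b$upper + 1e-12))
      stop("parameter value outside physiological bounds")
  }
  invisible(p)
}

#' @export
print.liley_params <- function(x, digits = 4, ...) {
  cat("Liley neural mass model parameters (mV / ms units):\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Serialise / restore parameter sets as JSON
#'
#' Flat key-to-value JSON using the canonical field names, so parameter sets
#' survive round trips between runs and external tools.
#'
#' @param p A `liley_params` object.
#' @param path File path to write to / read from.
#' @return `write_liley_params` returns `path` invisibly; `read_liley_params`
#'   returns a `liley_params` object.
#' @export
write_liley_params <- function(p, path) {
  validate_liley_params(p)
  jsonlite::write_json(as.list(unclass(p)[.liley_param_names]), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_liley_params
#' @export
read_liley_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  liley_params(.values = unlist(x[.liley_param_names]))
}

## Map a decision vector in [0,1]^23 onto the bounds box, and back.
scale_to_bounds <- function(u, bounds) {
  bounds$lower + u * (bounds$upper - bounds$lower)
}

normalise_to_unit <- function(x, bounds) {
  (x - bounds$lower) / (bounds$upper - bounds$lower)
}
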