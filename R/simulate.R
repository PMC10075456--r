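.liley_state_names <- c("he", "hi", "I_ee", "J_ee", "I_ei", "J_ei",
                        "I_ie", "J_ie", "I_ii", "J_ii")

#' Names of the ten first-order state variables
#'
#' The two membrane potentials, the four synaptic activities and their first
#' time derivatives, in the fixed layout used by [liley_drift()] and the
#' integrator.
#'
#' @return Character vector of length 10.
#' @export
liley_state_names <- function() .liley_state_names

## Evaluate code with a private RNG stream; the caller's RNG state is
## untouched, so seeded simulations are pure functions of their arguments.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Simulation configuration
#'
#' Integration and output settings for [simulate_liley()]. The integration
#' step is 0.0125 ms; an initial transient (5 s by default) is integrated and
#' discarded before the analysed epoch, which is resampled to the EEG rate.
#'
#' @param dt Integration step, ms.
#' @param duration Analysed epoch length, s.
#' @param transient Discarded initial span, s.
#' @param output_rate Output sampling rate, samples/s.
#' @param noise_mode One of `"white_noise"` (Euler-Maruyama diffusion term on
#'   the excitatory-excitatory synaptic drive, output statistics independent
#'   of `dt`), `"per_step_gaussian"` (the extrinsic input rate resampled
#'   independently each step from N(p_ee, xi^2)), or `"off"` (deterministic).
#' @param seed Integer seed; every stochastic simulation is a pure function of
#'   (parameters, config) including this seed.
#' @param c_sig Sigmoid exponent constant; 2 by default (see
#'   [liley_sigmoid()]). Recorded in all simulation metadata.
#' @return Object of class `liley_sim_config`.
#' @export
liley_sim_config <- function(dt = 0.0125, duration = 20, transient = 5,
                             output_rate = 256,
                             noise_mode = c("white_noise", "per_step_gaussian",
                                            "off"),
                             seed = 1L, c_sig = 2) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(dt > 0, duration > 0, transient >= 0, output_rate > 0, c_sig > 0)
  if (1000 / (dt * output_rate) < 1)
    stop("integration step must not be coarser than the output grid")
  structure(list(dt = dt, duration = duration, transient = transient,
                 output_rate = output_rate, noise_mode = noise_mode,
                 seed = as.integer(seed), c_sig = c_sig),
            class = "liley_sim_config")
}

#' Sigmoid firing-rate function
#'
#' Maps a mean membrane potential to a mean population firing rate:
#' `Smax / (1 + exp(-c (h - mu) / sigma))`. The exponent constant `c`
#' defaults to 2; the original Liley formulation uses sqrt(2), which can be
#' requested explicitly.
#'
#' @param h Membrane potential, mV (vectorised).
#' @param Smax Maximum firing rate, 1/ms.
#' @param mu Firing threshold, mV; the rate at `h = mu` is `Smax/2`.
#' @param sigma Threshold standard deviation, mV; must be positive.
#' @param c_sig Exponent constant.
#' @return Firing rate(s) in (0, Smax), 1/ms.
#' @export
liley_sigmoid <- function(h, Smax, mu, sigma, c_sig = 2) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (Smax <= 0) stop("Smax must be positive")
  Smax / (1 + exp(-c_sig * (h - mu) / sigma))
}

#' Drift field of the ten-dimensional Liley system
#'
#' Time derivatives of the state (he, hi, I_lk, J_lk) under the deterministic
#' part of the model, with the second-order synaptic kinetics rewritten as
#' first-order pairs (I' = J, J' = drive - 2 gamma J - gamma^2 I) and the
#' membrane weighting terms (h_eq - h) / |h_eq - h_rest| applied to each
#' synaptic activity.
#'
#' @param state Numeric vector of length 10 in [liley_state_names()] order.
#' @param params A `liley_params` object.
#' @param p_input Instantaneous excitatory-excitatory input rate, 1/ms;
#'   defaults to the parameter `p_ee`. May be negative (noise is not clipped).
#' @param c_sig Sigmoid exponent constant.
#' @return Named numeric vector of the 10 time derivatives (mV/ms, mV/ms^2).
#' @export
liley_drift <- function(state, params, p_input = NULL, c_sig = 2) {
  stopifnot(length(state) == 10L)
  p <- unclass(params)
  if (is.null(p_input)) p_input <- p[["p_ee"]]
  he <- state[1]; hi <- state[2]
  Se <- liley_sigmoid(he, p[["Se_max"]], p[["mu_e"]], p[["sigma_e"]], c_sig)
  Si <- liley_sigmoid(hi, p[["Si_max"]], p[["mu_i"]], p[["sigma_i"]], c_sig)
  Ae <- p[["Gamma_e"]] * p[["gamma_e"]] * exp(1)
  Ai <- p[["Gamma_i"]] * p[["gamma_i"]] * exp(1)
  ge <- p[["gamma_e"]]; gi <- p[["gamma_i"]]
  d <- c(
    (p[["he_rest"]] - he +
       (p[["he_eq"]] - he) / abs(p[["he_eq"]] - p[["he_rest"]]) * state[3] +
       (p[["hi_eq"]] - he) / abs(p[["hi_eq"]] - p[["he_rest"]]) * state[7]) /
      p[["tau_e"]],
    (p[["hi_rest"]] - hi +
       (p[["he_eq"]] - hi) / abs(p[["he_eq"]] - p[["hi_rest"]]) * state[5] +
       (p[["hi_eq"]] - hi) / abs(p[["hi_eq"]] - p[["hi_rest"]]) * state[9]) /
      p[["tau_i"]],
    state[4],
    Ae * (p[["N_ee"]] * Se + p_input) - 2 * ge * state[4] - ge^2 * state[3],
    state[6],
    Ae * (p[["N_ei"]] * Se + p[["p_ei"]]) - 2 * ge * state[6] - ge^2 * state[5],
    state[8],
    Ai * p[["N_ie"]] * Si - 2 * gi * state[8] - gi^2 * state[7],
    state[10],
    Ai * p[["N_ii"]] * Si - 2 * gi * state[10] - gi^2 * state[9]
  )
  names(d) <- .liley_state_names
  d
}

#' Simulate the stochastic Liley model
#'
#' Integrates the ten-dimensional system by the fixed-step Euler-Maruyama
#' method from zero initial conditions, discards the transient, and linearly
#' interpolates the excitatory membrane potential h_e onto the output grid
#' (the model observable, taken as linearly proportional to the EEG). Noise
#' enters only the excitatory-excitatory synaptic drive. A trajectory whose
#' |h_e| exceeds 1e4 mV (or goes non-finite) is returned with the
#' `divergent` flag set rather than raising an error, so optimisers can
#' penalise pathological parameter sets.
#'
#' @param params A `liley_params` object.
#' @param config A `liley_sim_config`.
#' @param init Optional initial state (length 10); zeros by default.
#' @return Object of class `liley_trajectory`: list with `samples` (h_e, mV),
#'   `rate`, `divergent`, and metadata (`params`, `config`).
#' @export
simulate_liley <- function(params, config = liley_sim_config(), init = NULL) {
  raw <- simulate_liley_raw(params, config, init, obs = 0L)
  structure(list(samples = raw$samples, rate = config$output_rate,
                 divergent = raw$divergent, params = params, config = config),
            class = "liley_trajectory")
}

## Shared integration + resampling; obs selects the recorded state component
## (0 = he, 1 = hi).
simulate_liley_raw <- function(params, config, init = NULL, obs = 0L) {
  validate_liley_params(params)
  stopifnot(inherits(config, "liley_sim_config"))
  if (is.null(init)) init <- numeric(10)
  stopifnot(length(init) == 10L)

  dt <- config$dt
  total_ms <- (config$transient + config$duration) * 1000
  n_steps <- as.integer(round(total_ms / dt))
  mode <- switch(config$noise_mode, off = 0L, white_noise = 1L,
                 per_step_gaussian = 2L)

  noise <- if (mode == 0L) numeric(0) else
    with_private_seed(config$seed, stats::rnorm(n_steps))

  h <- liley_integrate_cpp(unclass(params)[.liley_param_names], config$c_sig,
                           dt, n_steps, noise, mode, init, obs)
  divergent <- isTRUE(attr(h, "divergent"))

  n_out <- as.integer(round(config$duration * config$output_rate))
  t_ms <- (config$transient + (seq_len(n_out) - 1) / config$output_rate) * 1000
  idx <- t_ms / dt
  i0 <- pmin(floor(idx), n_steps - 1)
  frac <- idx - i0
  samples <- h[i0 + 1] * (1 - frac) + h[i0 + 2] * frac

  if (!divergent && any(!is.finite(samples))) divergent <- TRUE
  list(samples = samples, divergent = divergent)
}

## Resampled inhibitory membrane potential for the same seeded noise path.
simulate_liley_observable <- function(params, config,
                                      observable = c("he", "hi")) {
  obs <- match(match.arg(observable), c("he", "hi")) - 1L
  simulate_liley_raw(params, config, obs = obs)$samples
}

#' @export
print.liley_trajectory <- function(x, ...) {
  cat(sprintf("Liley model trajectory: %d samples at %g Hz (%s, noise %s)\n",
              length(x$samples), x$rate,
              if (x$divergent) "DIVERGENT" else "finite",
              x$config$noise_mode))
  invisible(x)
}

#' Write a trajectory as CSV
#'
#' Two columns, `time_s` and `he_mV`, with a JSON sidecar (same path plus
#' `.json`) holding the full parameter set and simulation settings.
#'
#' @param traj A `liley_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  n <- length(traj$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / traj$rate, he_mV = traj$samples)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(params = as.list(unclass(traj$params)),
               config = unclass(traj$config), divergent = traj$divergent)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
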