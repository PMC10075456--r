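## Steady-state synaptic activities for given membrane potentials: at
## equilibrium each second-order synaptic equation gives
## I* = Gamma * e * (N * S + input) / gamma.
steady_synaptic <- function(he, hi, p, p_input, c_sig) {
  Se <- liley_sigmoid(he, p[["Se_max"]], p[["mu_e"]], p[["sigma_e"]], c_sig)
  Si <- liley_sigmoid(hi, p[["Si_max"]], p[["mu_i"]], p[["sigma_i"]], c_sig)
  ke <- p[["Gamma_e"]] * exp(1) / p[["gamma_e"]]
  ki <- p[["Gamma_i"]] * exp(1) / p[["gamma_i"]]
  c(I_ee = ke * (p[["N_ee"]] * Se + p_input),
    I_ei = ke * (p[["N_ei"]] * Se + p[["p_ei"]]),
    I_ie = ki * p[["N_ie"]] * Si,
    I_ii = ki * p[["N_ii"]] * Si)
}

## Residual of the reduced 2-D steady-state system in (he, hi): the membrane
## equations with the synaptic activities at their equilibrium values.
reduced_residual <- function(h, p, p_input, c_sig) {
  I <- steady_synaptic(h[1], h[2], p, p_input, c_sig)
  g1 <- p[["he_rest"]] - h[1] +
    (p[["he_eq"]] - h[1]) / abs(p[["he_eq"]] - p[["he_rest"]]) * I[["I_ee"]] +
    (p[["hi_eq"]] - h[1]) / abs(p[["hi_eq"]] - p[["he_rest"]]) * I[["I_ie"]]
  g2 <- p[["hi_rest"]] - h[2] +
    (p[["he_eq"]] - h[2]) / abs(p[["he_eq"]] - p[["hi_rest"]]) * I[["I_ei"]] +
    (p[["hi_eq"]] - h[2]) / abs(p[["hi_eq"]] - p[["hi_rest"]]) * I[["I_ii"]]
  c(g1, g2)
}

## Damped Newton iteration on the reduced system with a finite-difference
## 2x2 Jacobian. Returns the root or NULL.
newton2 <- function(h0, p, p_input, c_sig, tol = 1e-13, maxit = 60) {
  h <- h0
  for (it in seq_len(maxit)) {
    g <- reduced_residual(h, p, p_input, c_sig)
    if (!all(is.finite(g))) return(NULL)
    if (max(abs(g)) < tol) return(h)
    eps <- 1e-7
    J <- cbind(
      (reduced_residual(h + c(eps, 0), p, p_input, c_sig) - g) / eps,
      (reduced_residual(h + c(0, eps), p, p_input, c_sig) - g) / eps
    )
    step <- tryCatch(solve(J, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    lambda <- 1
    repeat {
      h_new <- h - lambda * step
      g_new <- reduced_residual(h_new, p, p_input, c_sig)
      if (all(is.finite(g_new)) &&
          (sum(g_new^2) < sum(g^2) || lambda < 1e-4)) break
      lambda <- lambda / 2
    }
    if (max(abs(h_new - h)) < 1e-14 && max(abs(g_new)) > tol) return(NULL)
    h <- h_new
  }
  g <- reduced_residual(h, p, p_input, c_sig)
  if (max(abs(g)) < tol) h else NULL
}

#' Fixed points of the deterministic Liley model
#'
#' Locates all equilibria of the ten-dimensional deterministic system with
#' the input frozen at `p_input`. The steady state reduces to two equations
#' in the membrane potentials (the synaptic activities follow in closed
#' form); these are solved by damped Newton iteration from a grid of starts
#' over the membrane-potential box, roots are deduplicated, the full
#' ten-dimensional state is reconstituted and the Jacobian eigenvalues
#' computed at each root.
#'
#' @param params A `liley_params` object.
#' @param p_input Input rate held constant, 1/ms; defaults to `p_ee`.
#' @param c_sig Sigmoid exponent constant.
#' @param grid_n Starts per axis of the multi-start grid.
#' @param box Membrane-potential search interval (mV) for both he and hi.
#' @param dedup_tol Roots closer than this (mV, either coordinate) are merged.
#' @return List of objects of class `liley_fixed_point`, sorted by he. Each
#'   has `state` (named length-10 vector), `eigenvalues` (10 complex values,
#'   1/ms), `dominant_real` (max real part), `stable`, and `drift_norm`.
#'   Empty list when no root is found.
#' @export
find_fixed_points <- function(params, p_input = NULL, c_sig = 2,
                              grid_n = 20, box = c(-90, -10),
                              dedup_tol = 1e-6) {
  validate_liley_params(params)
  p <- unclass(params)
  if (is.null(p_input)) p_input <- p[["p_ee"]]

  starts <- seq(box[1], box[2], length.out = grid_n)
  roots <- list()
  for (he0 in starts) for (hi0 in starts) {
    r <- newton2(c(he0, hi0), p, p_input, c_sig)
    if (is.null(r)) next
    dup <- any(vapply(roots, function(x) max(abs(x - r)) < dedup_tol,
                      logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- r
  }
  if (!length(roots)) return(list())
  roots <- roots[order(vapply(roots, `[`, numeric(1), 1))]

  lapply(roots, function(h) {
    I <- steady_synaptic(h[1], h[2], p, p_input, c_sig)
    state <- c(h[1], h[2], I[["I_ee"]], 0, I[["I_ei"]], 0,
               I[["I_ie"]], 0, I[["I_ii"]], 0)
    names(state) <- .liley_state_names
    ev <- eigen(liley_jacobian(params, state, c_sig = c_sig),
                only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    dom <- max(Re(ev))
    structure(list(
      state = state, eigenvalues = ev, dominant_real = dom,
      stable = dom < 0,
      drift_norm = sqrt(sum(liley_drift(state, params, p_input, c_sig)^2))
    ), class = "liley_fixed_point")
  })
}

#' @export
print.liley_fixed_point <- function(x, ...) {
  cat(sprintf(
    "Liley fixed point: he = %.4f mV, hi = %.4f mV (%s, dominant Re = %.5g /ms)\n",
    x$state[["he"]], x$state[["hi"]],
    if (x$stable) "stable" else "unstable", x$dominant_real))
  invisible(x)
}

#' Analytic Jacobian of the drift field
#'
#' The 10 x 10 Jacobian of [liley_drift()] at a state, assembled from the
#' closed-form partial derivatives (sigmoid slope
#' `S'(h) = c/sigma * S * (1 - S/Smax)` and the linear synaptic kinetics).
#'
#' @param params A `liley_params` object.
#' @param state Numeric vector of length 10 in [liley_state_names()] order.
#' @param c_sig Sigmoid exponent constant.
#' @return 10 x 10 numeric matrix (units 1/ms).
#' @export
liley_jacobian <- function(params, state, c_sig = 2) {
  stopifnot(length(state) == 10L)
  p <- unclass(params)
  he <- state[1]; hi <- state[2]
  Dee <- abs(p[["he_eq"]] - p[["he_rest"]])
  Die <- abs(p[["hi_eq"]] - p[["he_rest"]])
  Dei <- abs(p[["he_eq"]] - p[["hi_rest"]])
  Dii <- abs(p[["hi_eq"]] - p[["hi_rest"]])
  Se <- liley_sigmoid(he, p[["Se_max"]], p[["mu_e"]], p[["sigma_e"]], c_sig)
  Si <- liley_sigmoid(hi, p[["Si_max"]], p[["mu_i"]], p[["sigma_i"]], c_sig)
  dSe <- c_sig / p[["sigma_e"]] * Se * (1 - Se / p[["Se_max"]])
  dSi <- c_sig / p[["sigma_i"]] * Si * (1 - Si / p[["Si_max"]])
  Ae <- p[["Gamma_e"]] * p[["gamma_e"]] * exp(1)
  Ai <- p[["Gamma_i"]] * p[["gamma_i"]] * exp(1)
  ge <- p[["gamma_e"]]; gi <- p[["gamma_i"]]
  te <- p[["tau_e"]]; ti <- p[["tau_i"]]

  J <- matrix(0, 10, 10, dimnames = list(.liley_state_names,
                                         .liley_state_names))
  J[1, 1] <- (-1 - state[3] / Dee - state[7] / Die) / te
  J[1, 3] <- (p[["he_eq"]] - he) / Dee / te
  J[1, 7] <- (p[["hi_eq"]] - he) / Die / te
  J[2, 2] <- (-1 - state[5] / Dei - state[9] / Dii) / ti
  J[2, 5] <- (p[["he_eq"]] - hi) / Dei / ti
  J[2, 9] <- (p[["hi_eq"]] - hi) / Dii / ti
  J[3, 4] <- 1
  J[4, 1] <- Ae * p[["N_ee"]] * dSe
  J[4, 3] <- -ge^2; J[4, 4] <- -2 * ge
  J[5, 6] <- 1
  J[6, 1] <- Ae * p[["N_ei"]] * dSe
  J[6, 5] <- -ge^2; J[6, 6] <- -2 * ge
  J[7, 8] <- 1
  J[8, 2] <- Ai * p[["N_ie"]] * dSi
  J[8, 7] <- -gi^2; J[8, 8] <- -2 * gi
  J[9, 10] <- 1
  J[10, 2] <- Ai * p[["N_ii"]] * dSi
  J[10, 9] <- -gi^2; J[10, 10] <- -2 * gi
  J
}

#' Jacobian eigenvalues at a fixed point
#'
#' @param params A `liley_params` object.
#' @param state A fixed-point state (length 10); an error is raised when the
#'   drift norm at `state` exceeds `tol`.
#' @param c_sig Sigmoid exponent constant.
#' @param p_input Input rate for the drift check; defaults to `p_ee`.
#' @param tol Drift-norm tolerance for accepting `state` as a fixed point.
#' @return 10 complex eigenvalues sorted by decreasing real part (1/ms).
#' @export
jacobian_eigenvalues <- function(params, state, c_sig = 2, p_input = NULL,
                                 tol = 1e-8) {
  dn <- sqrt(sum(liley_drift(state, params, p_input, c_sig)^2))
  if (!is.finite(dn) || dn > tol)
    stop(sprintf("state is not a fixed point (drift norm %.3g > %.3g)",
                 dn, tol))
  ev <- eigen(liley_jacobian(params, state, c_sig = c_sig),
              only.values = TRUE)$values
  ev[order(-Re(ev))]
}

#' Classify the attractor type of a parameter set
#'
#' Combines fixed-point stability with a long noise-free simulation:
#' convergence to a point means the stochastic dynamics are noise-driven
#' fluctuations around a stable fixed point; a sustained bounded oscillation
#' (terminal peak-to-peak amplitude of h_e above `threshold` after settling)
#' indicates a noise-driven limit cycle; divergence is flagged as such.
#'
#' @param params A `liley_params` object.
#' @param config A `liley_sim_config`; the noise mode is forced off and the
#'   analysed epoch should be long enough to pass transients (default 10 s).
#' @param threshold Peak-to-peak h_e amplitude (mV) over the terminal 2 s
#'   separating genuine cycles from numerical ringing.
#' @return One of `"noise_driven_fixed_point"`, `"noise_driven_limit_cycle"`,
#'   `"unstable_or_divergent"`.
#' @export
classify_attractor <- function(params,
                               config = liley_sim_config(duration = 10,
                                                         noise_mode = "off"),
                               threshold = 0.1) {
  cfg <- config
  cfg$noise_mode <- "off"
  traj <- simulate_liley(params, cfg)
  if (traj$divergent) return("unstable_or_divergent")
  n_tail <- min(length(traj$samples), as.integer(2 * traj$rate))
  tail_he <- traj$samples[(length(traj$samples) - n_tail + 1):length(traj$samples)]
  ptp <- diff(range(tail_he))
  if (ptp > threshold) "noise_driven_limit_cycle" else "noise_driven_fixed_point"
}
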