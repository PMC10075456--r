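## Discrepancy assigned to divergent (or degenerate, constant-output)
## simulations: orders of magnitude above any achievable objective value, so
## pathological parameter sets are dominated by every viable one.
.divergence_penalty <- 1e6

#' Cached data features for model-data comparison
#'
#' Computes, once per data epoch, everything the objectives need: the
#' normalised 2-20 Hz power spectrum, the pre-whitened log-spectral residual
#' on 2-45 Hz, and the wHVG node-strength sample. The epoch is expected to be
#' preprocessed (z-scored; for real EEG also high-passed).
#'
#' @param x Preprocessed data series.
#' @param rate Sampling rate, samples/s.
#' @param resolution Spectral resolution, Hz. The default 0.125 Hz needs an
#'   epoch of at least 8 s at 256 Hz; shorter epochs need a coarser grid
#'   (e.g. 0.5 Hz for a 2 s epoch).
#' @param band20,band45 The two comparison bands, Hz.
#' @return Object of class `liley_data_features`.
#' @export
data_features <- function(x, rate, resolution = 0.125,
                          band20 = c(2, 20), band45 = c(2, 45)) {
  x <- as.numeric(x)
  psd20 <- compute_psd(x, rate, band = band20, resolution = resolution)
  psd45 <- compute_psd(x, rate, band = band45, resolution = resolution)
  structure(list(
    series = x, rate = rate, resolution = resolution,
    band20 = band20, band45 = band45,
    psd20 = psd20,
    psd45_residual = prewhiten_psd(psd45),
    whvg_strengths = whvg_strengths(x)
  ), class = "liley_data_features")
}

#' @export
print.liley_data_features <- function(x, ...) {
  cat(sprintf(
    "Data features: %d samples at %g Hz; PSD grids %g-%g and %g-%g Hz at %g Hz\n",
    length(x$series), x$rate, x$band20[1], x$band20[2],
    x$band45[1], x$band45[2], x$resolution))
  invisible(x)
}

## Features of one model trajectory, or NULL when the trajectory cannot be
## compared (divergent or constant output).
model_trajectory_features <- function(traj, data, kinds) {
  if (traj$divergent) return(NULL)
  s <- traj$samples
  if (stats::sd(s) < 1e-12) return(NULL)
  z <- zscore(s)
  out <- list()
  if ("psd20" %in% kinds)
    out$psd20 <- compute_psd(z, traj$rate, band = data$band20,
                             resolution = data$resolution)$power
  if ("psd45" %in% kinds)
    out$psd45 <- compute_psd(z, traj$rate, band = data$band45,
                             resolution = data$resolution)
  if ("whvg" %in% kinds)
    out$whvg <- whvg_strengths(z)
  out
}

#' Spectral objective on the 2-20 Hz band
#'
#' Sum of squared differences between the normalised data and model power
#' spectra on the band grid (mean squared error up to the fixed bin count).
#' Invariant to amplitude rescaling of the model output.
#'
#' @param model A `liley_trajectory` at the data rate.
#' @param data A `liley_data_features`.
#' @return Non-negative discrepancy; the divergence penalty (1e6) for
#'   divergent or constant trajectories.
#' @export
objective_psd20 <- function(model, data) {
  ft <- model_trajectory_features(model, data, "psd20")
  if (is.null(ft)) return(.divergence_penalty)
  sum((data$psd20$power - ft$psd20)^2)
}

#' Pre-whitened spectral objective on the 2-45 Hz band
#'
#' Sum of squared differences of the pre-whitened natural-log spectra: each
#' spectrum has its robust log-log linear trend (the 1/f background) removed
#' before differencing, so a pure power-law offset between model and data
#' contributes nothing.
#'
#' @inheritParams objective_psd20
#' @return Non-negative discrepancy; 1e6 for divergent trajectories.
#' @export
objective_psd45 <- function(model, data) {
  ft <- model_trajectory_features(model, data, "psd45")
  if (is.null(ft)) return(.divergence_penalty)
  sum((data$psd45_residual - prewhiten_psd(ft$psd45))^2)
}

#' wHVG node-strength objective
#'
#' Two-sample Kolmogorov-Smirnov statistic between the wHVG node-strength
#' distributions of data and model output, in \[0, 1\].
#'
#' @inheritParams objective_psd20
#' @return D in \[0, 1\]; 1e6 for divergent trajectories.
#' @export
objective_whvg <- function(model, data) {
  ft <- model_trajectory_features(model, data, "whvg")
  if (is.null(ft)) return(.divergence_penalty)
  ks_statistic(data$whvg_strengths, ft$whvg)
}

#' Objective sets of the four fitting algorithms
#'
#' `SOEA20`/`SOEA45` are single-objective fits on the 2-20 Hz spectrum or the
#' pre-whitened 2-45 Hz spectrum; `MOEA20`/`MOEA45` add the wHVG
#' node-strength objective to each.
#'
#' @param algorithm One of `"SOEA20"`, `"SOEA45"`, `"MOEA20"`, `"MOEA45"`.
#' @return Character vector of objective kinds.
#' @export
algorithm_objectives <- function(algorithm = c("MOEA20", "MOEA45",
                                               "SOEA20", "SOEA45")) {
  switch(match.arg(algorithm),
         SOEA20 = "psd20",
         SOEA45 = "psd45",
         MOEA20 = c("psd20", "whvg"),
         MOEA45 = c("psd45", "whvg"))
}

## Deterministic per-evaluation seed stream: a pure function of the master
## seed, the individual's evaluation id and the repeat index, kept within
## 32-bit integer range.
derive_seed <- function(master_seed, id, repeat_idx) {
  s <- (abs(as.double(master_seed)) %% 1e6) * 2038074743 %% 2147483647
  as.integer((s + id * 97003 + repeat_idx * 101) %% 2147483629 + 1)
}

#' Evaluate the objective vector of a parameter set
#'
#' Simulates the model `n_repeats` times with independent, deterministically
#' derived seeds and combines the repeats: the spectral objectives average
#' the model power spectrum across repeats before computing one squared
#' error, while the wHVG objective averages the per-repeat KS statistics.
#' Divergent repeats contribute the 1e6 penalty proportionally. With the
#' noise off all repeats are identical.
#'
#' @param params A `liley_params` object.
#' @param data A `liley_data_features`.
#' @param kinds Objective kinds, subset of `psd20`, `psd45`, `whvg` (see
#'   [algorithm_objectives()]).
#' @param config A `liley_sim_config`; its `duration` and `output_rate`
#'   should match the data epoch.
#' @param n_repeats Simulations per evaluation (5 in the full protocol).
#' @param master_seed Master seed for the evaluation.
#' @param id Evaluation id distinguishing individuals within a run.
#' @return Named numeric vector of objective values (lower is better).
#' @export
evaluate_objectives <- function(params, data, kinds, config,
                                n_repeats = 5, master_seed = 1L, id = 0L) {
  stopifnot(n_repeats >= 1, all(kinds %in% c("psd20", "psd45", "whvg")))
  feats <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    cfg <- config
    cfg$seed <- derive_seed(master_seed, id, r)
    feats[[r]] <- model_trajectory_features(simulate_liley(params, cfg),
                                            data, kinds)
  }
  ok <- !vapply(feats, is.null, logical(1))
  n_ok <- sum(ok)
  pen_weight <- (n_repeats - n_ok) / n_repeats

  vals <- vapply(kinds, function(k) {
    if (n_ok == 0L) return(.divergence_penalty)
    good <- switch(k,
      psd20 = {
        mpsd <- rowMeans(vapply(feats[ok], function(f) f$psd20,
                                numeric(length(data$psd20$power))))
        sum((data$psd20$power - mpsd)^2)
      },
      psd45 = {
        nb <- length(data$psd45_residual)
        mpsd <- rowMeans(vapply(feats[ok], function(f) f$psd45$power,
                                numeric(nb)))
        spec <- feats[ok][[1]]$psd45
        spec$power <- mpsd
        sum((data$psd45_residual - prewhiten_psd(spec))^2)
      },
      whvg = mean(vapply(feats[ok], function(f)
        ks_statistic(data$whvg_strengths, f$whvg), numeric(1)))
    )
    (1 - pen_weight) * good + pen_weight * .divergence_penalty
  }, numeric(1))
  names(vals) <- kinds
  vals
}
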