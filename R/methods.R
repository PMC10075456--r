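#' @export
print.liley_fit <- function(x, ...) {
  cat(sprintf("Liley model fit (%s: %s)\n", x$algorithm,
              paste(x$kinds, collapse = " + ")))
  cat(sprintf("  population %d, %d generations, %d objective repeat(s)\n",
              x$moea$population_size, x$moea$generations, x$moea$n_repeats))
  cat(sprintf("  non-dominated set: %d member(s)\n", nrow(x$pareto_decision)))
  cat("  optimum objectives: ",
      paste(sprintf("%s = %.5g", x$kinds, x$optimum_objectives),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Summarise a Liley model fit
#'
#' Reports the selected optimum's objectives and parameters, the spread of
#' the non-dominated set, and the convergence diagnostics of the last
#' generations.
#'
#' @param object A `liley_fit`.
#' @param ... Unused.
#' @return `object`, invisibly.
#' @export
summary.liley_fit <- function(object, ...) {
  print(object)
  cat("\nOptimal parameters:\n")
  print(object$optimum)
  h <- object$history
  cat(sprintf("\nConvergence: hypervolume %.5g -> %.5g, best distance %.4g -> %.4g over %d generations\n",
              h$hypervolume[1], h$hypervolume[nrow(h)],
              h$best_distance[1], h$best_distance[nrow(h)],
              nrow(h) - 1))
  if (nrow(object$pareto_objectives) > 1) {
    cat("\nNon-dominated objective ranges:\n")
    rng <- apply(object$pareto_objectives, 2, range)
    rownames(rng) <- c("min", "max")
    print(signif(rng, 4))
  }
  invisible(object)
}

#' Optimal parameters of a fit
#'
#' @param object A `liley_fit`.
#' @param ... Unused.
#' @return Named numeric vector of the 23 recovered parameters.
#' @export
coef.liley_fit <- function(object, ...) unclass(object$optimum)

#' Simulate from a fitted model
#'
#' Stochastic model trajectories at the fit's optimal parameters, using the
#' fit's simulation settings.
#'
#' @param object A `liley_fit`.
#' @param nsim Number of trajectories.
#' @param seed Integer seed for the first trajectory; subsequent ones use
#'   consecutive derived seeds.
#' @param ... Unused.
#' @return A list of `liley_trajectory` objects (length `nsim`), or a single
#'   trajectory when `nsim = 1`.
#' @export
simulate.liley_fit <- function(object, nsim = 1, seed = 1L, ...) {
  out <- lapply(seq_len(nsim), function(i) {
    cfg <- object$sim
    cfg$seed <- derive_seed(seed, i, 0L)
    simulate_liley(object$optimum, cfg)
  })
  if (nsim == 1) out[[1]] else out
}

#' Spectral residuals of a fit
#'
#' Difference between the data's normalised 2-20 Hz power spectrum and the
#' mean model spectrum at the optimum (averaged over `nsim` stochastic
#' simulations).
#'
#' @param object A `liley_fit`.
#' @param nsim Simulations averaged.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Data frame with `freq_hz`, `data_power`, `model_power`,
#'   `residual`.
#' @export
residuals.liley_fit <- function(object, nsim = 3, seed = 1L, ...) {
  d <- object$data
  sims <- simulate.liley_fit(object, nsim = nsim, seed = seed)
  if (nsim == 1) sims <- list(sims)
  psds <- vapply(sims, function(tr) {
    compute_psd(zscore(tr$samples), tr$rate, band = d$band20,
                resolution = d$resolution)$power
  }, numeric(length(d$psd20$power)))
  mp <- rowMeans(psds)
  data.frame(freq_hz = d$psd20$freqs, data_power = d$psd20$power,
             model_power = mp, residual = d$psd20$power - mp)
}

#' Diagnostic plots for a Liley model fit
#'
#' Four base-graphics panels: data vs model power spectrum, wHVG
#' node-strength densities, a model trajectory segment against the data, and
#' the per-generation hypervolume convergence curve.
#'
#' @param x A `liley_fit`.
#' @param seed Seed of the illustrative model simulation.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.liley_fit <- function(x, seed = 1L, ...) {
  d <- x$data
  tr <- simulate.liley_fit(x, nsim = 1, seed = seed)
  z <- if (tr$divergent) NULL else zscore(tr$samples)

  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))

  graphics::plot(d$psd20$freqs, d$psd20$power, type = "l",
                 xlab = "frequency (Hz)", ylab = "normalised power",
                 main = "PSD 2-20 Hz")
  if (!is.null(z)) {
    mp <- compute_psd(z, tr$rate, band = d$band20,
                      resolution = d$resolution)$power
    graphics::lines(d$psd20$freqs, mp, col = 2)
  }
  graphics::legend("topright", legend = c("data", "model"), col = 1:2,
                   lty = 1, bty = "n")

  hd <- density_histogram(d$whvg_strengths)
  ctr <- (hd$bin_edges[-1] + hd$bin_edges[-length(hd$bin_edges)]) / 2
  graphics::plot(ctr, hd$density, type = "h", xlab = "wHVG node strength",
                 ylab = "density", main = "wHVG distribution")
  if (!is.null(z)) {
    hm <- density_histogram(whvg_strengths(z))
    cm <- (hm$bin_edges[-1] + hm$bin_edges[-length(hm$bin_edges)]) / 2
    graphics::lines(cm, hm$density, col = 2)
  }

  n_show <- min(length(d$series), as.integer(2 * d$rate))
  tt <- (seq_len(n_show) - 1) / d$rate
  graphics::plot(tt, d$series[seq_len(n_show)], type = "l",
                 xlab = "time (s)", ylab = "z-scored amplitude",
                 main = "Time series (2 s)")
  if (!is.null(z))
    graphics::lines(tt, z[seq_len(n_show)], col = 2)

  graphics::plot(x$history$generation, x$history$hypervolume, type = "b",
                 xlab = "generation", ylab = "hypervolume",
                 main = "Convergence", pch = 20)
  invisible(x)
}

#' Write the non-dominated set as CSV
#'
#' One row per Pareto member: the 23 parameters, the objective values and
#' the rank, plus a JSON sidecar with the run configuration.
#'
#' @param fit A `liley_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pareto_csv <- function(fit, path) {
  df <- as.data.frame(fit$pareto_decision)
  obj <- as.data.frame(fit$pareto_objectives)
  names(obj) <- paste0("objective_", fit$kinds)
  df <- cbind(df, obj, rank = 0L)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(algorithm = fit$algorithm, moea = unclass(fit$moea),
               sim = unclass(fit$sim),
               optimum = as.list(unclass(fit$optimum)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
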