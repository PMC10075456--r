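#' Welch power spectrum, normalised over a band
#'
#' Averaged periodogram with Hann-windowed segments of `rate/resolution`
#' samples and 50% overlap, restricted to `band` and normalised to unit sum
#' over the band so spectra of differently scaled signals are comparable.
#' With a 256 Hz signal and the default 0.125 Hz resolution this uses 8 s
#' segments; a series exactly one segment long degenerates to a single
#' windowed periodogram.
#'
#' @param x Time series (numeric).
#' @param rate Sampling rate, samples/s.
#' @param band Frequency interval `c(f_lo, f_hi)` in Hz, inside (0, rate/2).
#' @param resolution Frequency-bin width, Hz; must give a segment no longer
#'   than the series.
#' @param normalise Divide by the total band power (default).
#' @return Object of class `liley_psd`: list with `freqs` (Hz), `power`,
#'   `band`, `resolution`, `normalised`.
#' @export
compute_psd <- function(x, rate, band = c(2, 20), resolution = 0.125,
                        normalise = TRUE) {
  if (any(!is.finite(x))) stop("time series contains non-finite values")
  nseg <- as.integer(round(rate / resolution))
  if (nseg > length(x))
    stop("series shorter than one averaging segment (", nseg, " samples)")
  if (band[1] <= 0 || band[2] >= rate / 2 || band[1] >= band[2])
    stop("band must lie within (0, rate/2)")

  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / nseg)  # Hann (periodic)
  step <- max(1L, nseg %/% 2L)
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    acc <- acc + Mod(stats::fft(seg))^2
  }
  pw <- acc / length(starts)

  freqs_all <- (seq_len(nseg) - 1) * rate / nseg
  keep <- freqs_all >= band[1] - 1e-9 & freqs_all <= band[2] + 1e-9
  freqs <- freqs_all[keep]
  power <- pw[keep]
  if (normalise) power <- power / sum(power)
  structure(list(freqs = freqs, power = power, band = band,
                 resolution = resolution, normalised = normalise),
            class = "liley_psd")
}

#' Pre-whiten a power spectrum
#'
#' Removes the 1/f background by a robust linear fit (iteratively reweighted
#' least squares with bisquare weights) of log power against log frequency,
#' returning the residuals `ln power - (a + b ln f)`. Robustness keeps sharp
#' spectral peaks from dragging the background estimate. Residuals are
#' invariant to multiplicative rescaling of the input power (absorbed by the
#' intercept). Power is floored at 1e-15 of the spectral maximum before the
#' log so that bins at the numerical leakage floor cannot destabilise the
#' fit.
#'
#' @param spec A `liley_psd` (or list with `freqs`, `power`).
#' @return Numeric vector of log-power residuals, one per frequency bin.
#' @export
prewhiten_psd <- function(spec) {
  f <- spec$freqs
  p <- pmax(spec$power, max(spec$power) * 1e-15)
  if (length(f) < 3L) stop("need at least 3 frequency bins")
  fit <- suppressWarnings(
    MASS::rlm(log(p) ~ log(f), psi = MASS::psi.bisquare, maxit = 100)
  )
  as.numeric(log(p) - stats::fitted(fit))
}

#' Weighted horizontal visibility graph of a time series
#'
#' Maps each time point to a node; two nodes are joined when every
#' intermediate sample lies strictly below both endpoints (so a horizontal
#' line can be traced between them), with equal intermediate values blocking
#' visibility. Each edge carries the signed amplitude difference, later time
#' point minus former; a node's strength is the sum of its incident signed
#' weights. Built by a linear-time monotone-stack sweep.
#'
#' @param x Time series (numeric, length >= 2, finite).
#' @return Object of class `whvg`: list with `n_nodes`, `edges` (data frame
#'   `from`, `to`, `weight`, with `from < to`), and `strength` (per node).
#' @export
build_whvg <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples")
  if (any(!is.finite(x))) stop("time series contains non-finite values")
  g <- whvg_cpp(as.numeric(x))
  edges <- data.frame(from = g$from, to = g$to, weight = g$weight)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(n_nodes = length(x), edges = edges, strength = g$strength),
            class = "whvg")
}

#' @export
print.whvg <- function(x, ...) {
  cat(sprintf("Weighted horizontal visibility graph: %d nodes, %d edges\n",
              x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Node strengths of a series' wHVG
#'
#' Convenience wrapper: the signed node-strength sample used as the
#' graph-based comparison statistic.
#'
#' @param x Time series.
#' @return Numeric vector, one strength per time point.
#' @export
whvg_strengths <- function(x) build_whvg(x)$strength

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum over the pooled sample points of the absolute difference of
#' the two right-continuous empirical CDFs, computed on raw (unbinned)
#' values. Symmetric in its arguments and invariant under any common strictly
#' increasing transform.
#'
#' @param a,b Non-empty numeric samples.
#' @return D in \[0, 1\].
#' @export
ks_statistic <- function(a, b) {
  if (!length(a) || !length(b)) stop("samples must be non-empty")
  y <- sort(unique(c(a, b)))
  Fa <- vapply(y, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(y, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

#' Equal-width density histogram
#'
#' 100 equal bins by default, spanning the sample range (or a caller-supplied
#' range); bins are left-closed/right-open with the final bin right-closed.
#' Densities (bin probabilities) sum to one. A zero-width range degenerates
#' to a single bin of density one.
#'
#' @param sample Non-empty finite numeric sample.
#' @param nbins Number of bins.
#' @param range Optional `c(lo, hi)` histogram range; sample range by default.
#' @return List with `bin_edges` (length nbins + 1) and `density`
#'   (length nbins, sums to 1).
#' @export
density_histogram <- function(sample, nbins = 100, range = NULL) {
  if (!length(sample)) stop("sample must be non-empty")
  if (any(!is.finite(sample))) stop("sample contains non-finite values")
  if (is.null(range)) range <- c(min(sample), max(sample))
  if (range[2] <= range[1]) {
    return(list(bin_edges = c(range[1], range[1]), density = 1))
  }
  edges <- seq(range[1], range[2], length.out = nbins + 1)
  # nudge interior edges down by a relative fuzz so grid points that belong
  # exactly on an edge land in their left-closed bin despite fp rounding
  cut_at <- edges
  cut_at[2:nbins] <- cut_at[2:nbins] - (range[2] - range[1]) * 1e-9
  idx <- findInterval(sample, cut_at, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins)
  list(bin_edges = edges, density = counts / sum(counts))
}

#' Amplitude distribution of a time series
#'
#' The density histogram of the raw sample amplitudes, the companion view to
#' the wHVG node-strength distribution.
#'
#' @inheritParams density_histogram
#' @param x Time series.
#' @return As [density_histogram()].
#' @export
amplitude_distribution <- function(x, nbins = 100, range = NULL) {
  density_histogram(x, nbins = nbins, range = range)
}

#' Hurst exponent by rescaled-range analysis
#'
#' R/S estimate over dyadic window sizes: for each window length the range of
#' the mean-adjusted cumulative sum is divided by the window standard
#' deviation, averaged across windows, and the log-log slope against window
#' length gives H. White noise gives H near 0.5, its cumulative sum H near 1.
#' Deterministic for fixed input.
#'
#' @param x Time series, length >= 256.
#' @return H in (0, 1), or `NA` for (near-)constant input.
#' @export
hurst_exponent <- function(x) {
  n <- length(x)
  if (n < 256L) stop("need at least 256 samples")
  if (stats::sd(x) < .Machine$double.eps * 100) return(NA_real_)
  sizes <- 2^(3:floor(log2(n / 2)))
  rs <- vapply(sizes, function(m) {
    k <- n %/% m
    vals <- vapply(seq_len(k), function(i) {
      seg <- x[((i - 1) * m + 1):(i * m)]
      s <- stats::sd(seg)
      if (s == 0) return(NA_real_)
      z <- cumsum(seg - mean(seg))
      (max(z) - min(z)) / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2L) return(NA_real_)
  unname(stats::coef(stats::lm(log(rs[ok]) ~ log(sizes[ok])))[2])
}

## z-score a series; idempotent (an already standardised series is returned
## unchanged, so repeated normalisation cannot inject rounding noise).
zscore <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant series")
  if (abs(m) < 1e-9 && abs(s - 1) < 1e-9) return(x)
  (x - m) / s
}
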