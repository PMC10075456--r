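#' Jensen-Shannon divergence between two discrete distributions
#'
#' `JSD(P, Q) = H((P+Q)/2) - H(P)/2 - H(Q)/2` with natural-log Shannon
#' entropy and the convention `0 log 0 = 0`. Symmetric, and bounded by
#' `ln 2` (attained on disjoint supports).
#'
#' @param p,q Probability vectors of equal length, each summing to 1
#'   (tolerance 1e-9).
#' @return JSD in \[0, ln 2\] (nats).
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) stop("distributions differ in length")
  if (any(p < 0) || any(q < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("probability vectors must sum to 1")
  H <- function(w) {
    w <- w[w > 0]
    -sum(w * log(w))
  }
  H((p + q) / 2) - H(p) / 2 - H(q) / 2
}

#' Pooled sample of recovered parameter sets
#'
#' Container for the optima pooled across fit replicates (and cohorts): a
#' matrix of decision vectors in canonical order, a label per row and the
#' bounds the optimisation used.
#'
#' @param x Numeric matrix (rows = parameter sets, 23 columns in canonical
#'   order) or a single `liley_params`.
#' @param labels Character labels aligned with rows (algorithm, cohort, ...).
#' @param bounds A `liley_bounds` object.
#' @return Object of class `liley_parameter_sample`.
#' @export
parameter_sample <- function(x, labels = NULL, bounds = liley_bounds()) {
  if (inherits(x, "liley_params")) x <- matrix(unclass(x), nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != 23L) stop("parameter sample must have 23 columns")
  colnames(x) <- names(bounds$lower)
  if (is.null(labels)) labels <- rep("sample", nrow(x))
  if (length(labels) != nrow(x)) stop("one label per row required")
  lo <- matrix(bounds$lower, nrow(x), 23, byrow = TRUE)
  hi <- matrix(bounds$upper, nrow(x), 23, byrow = TRUE)
  if (any(x < lo - 1e-9) || any(x > hi + 1e-9))
    stop("parameter sample contains values outside the bounds")
  structure(list(values = x, labels = as.character(labels), bounds = bounds),
            class = "liley_parameter_sample")
}

#' @export
print.liley_parameter_sample <- function(x, ...) {
  cat(sprintf("Parameter sample: %d sets, labels: %s\n", nrow(x$values),
              paste(unique(x$labels), collapse = ", ")))
  invisible(x)
}

## 100-bin histogram of one parameter column over its full bound range.
param_histogram <- function(sample, param, rows = NULL, nbins = 100) {
  if (is.character(param)) param <- match(param, colnames(sample$values))
  v <- sample$values[, param]
  if (!is.null(rows)) v <- v[rows]
  density_histogram(v, nbins = nbins,
                    range = c(sample$bounds$lower[param],
                              sample$bounds$upper[param]))$density
}

#' Practical identifiability of one parameter
#'
#' JSD between the empirical marginal distribution of a recovered parameter
#' (100 equal bins over its full bound range) and the uniform distribution
#' that approximates the optimisation's starting prior. Values near zero
#' mean the data leave the parameter unconstrained; larger values mean the
#' recovered distribution concentrates, i.e. the parameter is practically
#' identifiable.
#'
#' @param sample A `liley_parameter_sample` with at least 2 rows.
#' @param param Parameter name or column index.
#' @param nbins Number of histogram bins.
#' @return JSD in \[0, ln 2\].
#' @export
identifiability_jsd <- function(sample, param, nbins = 100) {
  stopifnot(nrow(sample$values) >= 2)
  emp <- param_histogram(sample, param, nbins = nbins)
  jsd(emp, rep(1 / nbins, nbins))
}

#' Per-parameter cohort comparison
#'
#' For each parameter, the JSD between the two cohorts' 100-bin marginal
#' histograms (shared grid over the full bound range, so empty-bin handling
#' is common) and Cohen's d, `(mean_a - mean_b) / pooled sd` with the pooled
#' variance weighted by (n - 1). d is `NA` when the pooled sd is zero.
#'
#' @param sample_a,sample_b `liley_parameter_sample` objects over the same
#'   bounds.
#' @param nbins Histogram bins for the JSD.
#' @return Data frame with columns `parameter`, `jsd`, `cohens_d`.
#' @export
cohort_compare <- function(sample_a, sample_b, nbins = 100) {
  stopifnot(nrow(sample_a$values) >= 1, nrow(sample_b$values) >= 1)
  if (max(abs(sample_a$bounds$lower - sample_b$bounds$lower)) > 0 ||
      max(abs(sample_a$bounds$upper - sample_b$bounds$upper)) > 0)
    stop("cohorts must share bounds")
  params <- colnames(sample_a$values)
  res <- lapply(seq_along(params), function(k) {
    ha <- param_histogram(sample_a, k, nbins = nbins)
    hb <- param_histogram(sample_b, k, nbins = nbins)
    a <- sample_a$values[, k]
    b <- sample_b$values[, k]
    na <- length(a); nb <- length(b)
    pooled_var <- if (na + nb > 2)
      ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
    else NA_real_
    d <- if (is.finite(pooled_var) && pooled_var > 0)
      (mean(a) - mean(b)) / sqrt(pooled_var) else NA_real_
    data.frame(parameter = params[k], jsd = jsd(ha, hb), cohens_d = d)
  })
  do.call(rbind, res)
}

#' Classical MDS embedding of a parameter sample
#'
#' Euclidean distances between bound-normalised decision vectors (each
#' parameter mapped to \[0, 1\]) are embedded in 2 dimensions by classical
#' (Torgerson) multidimensional scaling. When the points are intrinsically
#' two-dimensional the embedded distances reproduce the input distances up
#' to rigid motion.
#'
#' @param sample A `liley_parameter_sample` with at least 3 rows.
#' @param k Embedding dimension.
#' @return Numeric matrix (rows aligned with the sample) of coordinates.
#' @export
mds_embed <- function(sample, k = 2) {
  x <- sample$values
  stopifnot(nrow(x) >= 3)
  u <- sweep(sweep(x, 2, sample$bounds$lower, "-"), 2,
             sample$bounds$upper - sample$bounds$lower, "/")
  d <- stats::dist(u)
  if (max(d) == 0) return(matrix(0, nrow(x), k))
  y <- stats::cmdscale(d, k = k)
  if (ncol(y) < k) y <- cbind(y, matrix(0, nrow(y), k - ncol(y)))
  y
}

#' Silhouette score of labelled points
#'
#' Mean over points of `(b - a) / max(a, b)` where `a` is the mean distance
#' to the point's own label and `b` the smallest mean distance to any other
#' label. A point that is its label's only member scores 0 (convention).
#'
#' @param points Numeric matrix (rows = points) or vector.
#' @param labels Grouping labels, at least two distinct values.
#' @return Mean silhouette in \[-1, 1\].
#' @export
silhouette_score <- function(points, labels) {
  pts <- if (is.null(dim(points))) matrix(points, ncol = 1)
         else as.matrix(points)
  labels <- as.character(labels)
  stopifnot(nrow(pts) == length(labels))
  if (length(unique(labels)) < 2) stop("need at least two labels")
  D <- as.matrix(stats::dist(pts))
  s <- vapply(seq_len(nrow(pts)), function(i) {
    own <- which(labels == labels[i])
    own <- own[own != i]
    if (!length(own)) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(D[i, labels == l]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Time-averaged membrane potentials and firing rates
#'
#' Simulates the model and averages, over the post-transient epoch, both
#' membrane potentials and their pointwise sigmoid-transformed firing rates
#' (the average of the instantaneous rate, not the rate at the average
#' potential — the two differ on oscillatory trajectories).
#'
#' @param params A `liley_params` object.
#' @param config A `liley_sim_config`.
#' @return List with `mean_he`, `mean_hi` (mV), `mean_Se`, `mean_Si` (1/ms)
#'   and `divergent`.
#' @export
population_summaries <- function(params, config = liley_sim_config()) {
  traj_e <- simulate_liley(params, config)
  if (traj_e$divergent)
    return(list(mean_he = NA_real_, mean_hi = NA_real_, mean_Se = NA_real_,
                mean_Si = NA_real_, divergent = TRUE))
  # recover hi by re-integrating with the same noise and recording hi:
  # simulate_liley records he only, so integrate the 10-state system in R at
  # the output grid via the same C++ kernel run on the swapped observable.
  hi <- simulate_liley_observable(params, config, observable = "hi")
  p <- unclass(params)
  list(
    mean_he = mean(traj_e$samples),
    mean_hi = mean(hi),
    mean_Se = mean(liley_sigmoid(traj_e$samples, p[["Se_max"]], p[["mu_e"]],
                                 p[["sigma_e"]], config$c_sig)),
    mean_Si = mean(liley_sigmoid(hi, p[["Si_max"]], p[["mu_i"]],
                                 p[["sigma_i"]], config$c_sig)),
    divergent = FALSE
  )
}
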