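# Definition-level oracles, written independently of the package internals.

# O(N^2) wHVG oracle: apply the visibility criterion to every (i, j) pair
# directly, using the maximum of the intermediate samples. For each endpoint
# j, m[i] holds max(x[(i+1):(j-1)]) so the strict criterion x_i, x_j > x_k
# for all intermediates is evaluated verbatim.
oracle_whvg <- function(x) {
  n <- length(x)
  from <- integer(0); to <- integer(0)
  for (j in 2:n) {
    i_seq <- seq_len(j - 1)
    m <- if (j == 2) -Inf else {
      z <- x[2:(j - 1)]
      c(rev(cummax(rev(z))), -Inf)   # m[i] = max over samples between i and j
    }
    vis <- i_seq[i_seq == j - 1 | (x[i_seq] > m & x[j] > m)]
    from <- c(from, vis)
    to <- c(to, rep(j, length(vis)))
  }
  o <- order(from, to)
  edges <- data.frame(from = from[o], to = to[o],
                      weight = as.numeric(x[to[o]] - x[from[o]]))
  strength <- numeric(n)
  for (k in seq_len(nrow(edges))) {
    strength[edges$from[k]] <- strength[edges$from[k]] + edges$weight[k]
    strength[edges$to[k]] <- strength[edges$to[k]] + edges$weight[k]
  }
  list(edges = edges, strength = strength)
}

# KS oracle built on stats::ecdf evaluated at the pooled points.
oracle_ks <- function(a, b) {
  y <- c(a, b)
  max(abs(stats::ecdf(a)(y) - stats::ecdf(b)(y)))
}

# Non-dominated ranks by iterative peeling with a scalar comparator.
oracle_nds <- function(obj) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  rank <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  r <- 0L
  dominated <- function(i, idx) {
    for (j in idx) {
      if (j != i && all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ]))
        return(TRUE)
    }
    FALSE
  }
  while (any(alive)) {
    idx <- which(alive)
    front <- idx[!vapply(idx, dominated, logical(1), idx = idx)]
    rank[front] <- r
    alive[front] <- FALSE
    r <- r + 1L
  }
  rank
}

# Hypervolume by inclusion-exclusion over the union of boxes (small fronts).
oracle_hypervolume <- function(front, ref) {
  front <- as.matrix(front)
  keep <- apply(front, 1, function(p) all(p < ref))
  pts <- front[keep, , drop = FALSE]
  m <- nrow(pts)
  if (m == 0) return(0)
  total <- 0
  for (k in seq_len(m)) {
    for (comb in utils::combn(m, k, simplify = FALSE)) {
      corner <- apply(pts[comb, , drop = FALSE], 2, max)
      total <- total + (-1)^(k + 1) * prod(ref - corner)
    }
  }
  total
}

# Independent re-derivation of the model's vector field, written from the
# second-order synaptic form (I'' + 2 g I' + g^2 I = G g e (N S + input)).
oracle_drift <- function(state, params, p_input = NULL, cc = 2) {
  pv <- unclass(params)
  if (is.null(p_input)) p_input <- pv[["p_ee"]]
  S <- function(h, smax, mu, sg) smax / (1 + exp(-cc * (h - mu) / sg))
  he <- state[1]; hi <- state[2]
  Se <- S(he, pv[["Se_max"]], pv[["mu_e"]], pv[["sigma_e"]])
  Si <- S(hi, pv[["Si_max"]], pv[["mu_i"]], pv[["sigma_i"]])
  second_order <- function(I, J, G, g, drive) {
    c(J, G * g * exp(1) * drive - 2 * g * J - g^2 * I)
  }
  psi <- function(h_eq, h, h_rest) (h_eq - h) / abs(h_eq - h_rest)
  dhe <- (pv[["he_rest"]] - he +
            psi(pv[["he_eq"]], he, pv[["he_rest"]]) * state[3] +
            psi(pv[["hi_eq"]], he, pv[["he_rest"]]) * state[7]) / pv[["tau_e"]]
  dhi <- (pv[["hi_rest"]] - hi +
            psi(pv[["he_eq"]], hi, pv[["hi_rest"]]) * state[5] +
            psi(pv[["hi_eq"]], hi, pv[["hi_rest"]]) * state[9]) / pv[["tau_i"]]
  c(dhe, dhi,
    second_order(state[3], state[4], pv[["Gamma_e"]], pv[["gamma_e"]],
                 pv[["N_ee"]] * Se + p_input),
    second_order(state[5], state[6], pv[["Gamma_e"]], pv[["gamma_e"]],
                 pv[["N_ei"]] * Se + pv[["p_ei"]]),
    second_order(state[7], state[8], pv[["Gamma_i"]], pv[["gamma_i"]],
                 pv[["N_ie"]] * Si),
    second_order(state[9], state[10], pv[["Gamma_i"]], pv[["gamma_i"]],
                 pv[["N_ii"]] * Si))
}

# High-accuracy deterministic reference trajectory on a millisecond grid.
oracle_ode_reference <- function(params, times_ms, init = numeric(10),
                                 p_input = NULL, cc = 2) {
  f <- function(t, y, parms) list(oracle_drift(y, params, p_input, cc))
  deSolve::lsoda(init, times_ms, f, parms = NULL,
                 rtol = 1e-10, atol = 1e-10)
}
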