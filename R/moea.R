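#' Latin hypercube initial population
#'
#' Stratified uniform sample of decision vectors: per parameter, exactly one
#' sample falls in each of the `n` equal-width strata of its bound range.
#'
#' @param bounds A `liley_bounds` object.
#' @param n Population size.
#' @param seed Integer seed.
#' @return `n` x 23 matrix of decision vectors (columns in canonical order).
#' @export
latin_hypercube_init <- function(bounds, n, seed = 1L) {
  stopifnot(n >= 1)
  u <- with_private_seed(seed, lhs::randomLHS(n, length(bounds$lower)))
  x <- sweep(sweep(u, 2, bounds$upper - bounds$lower, "*"), 2, bounds$lower,
             "+")
  colnames(x) <- names(bounds$lower)
  x
}

#' Pareto dominance of objective vectors
#'
#' `a` strictly dominates `b` iff `a` is no worse in every objective and
#' strictly better in at least one (minimisation).
#'
#' @param a,b Numeric objective vectors of equal length.
#' @return Logical.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) stop("objective vectors differ in length")
  all(a <= b) && any(a < b)
}

#' Non-dominated sorting
#'
#' Assigns each row of an objective matrix its non-domination level: rank 0
#' for individuals dominated by none, rank k for those dominated only by
#' individuals of ranks below k (Deb's NSGA-II sort).
#'
#' @param objectives Numeric matrix, one row per individual.
#' @return Integer vector of ranks (0-based).
#' @export
non_dominated_sort <- function(objectives) {
  obj <- as.matrix(objectives)
  n <- nrow(obj)
  if (n == 0L) return(integer(0))
  le <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(obj))) {
    le <- le & outer(obj[, k], obj[, k], "<=")
    lt <- lt | outer(obj[, k], obj[, k], "<")
  }
  dom <- le & lt                       # dom[i, j]: i dominates j
  np <- colSums(dom)                   # how many dominate j
  rank <- rep(NA_integer_, n)
  r <- 0L
  remaining <- rep(TRUE, n)
  while (any(remaining)) {
    front <- remaining & np == 0L
    if (!any(front)) {                 # numerically impossible, but be safe
      front <- remaining & np == min(np[remaining])
    }
    rank[front] <- r
    remaining[front] <- FALSE
    if (any(remaining)) {
      dec <- colSums(dom[front, remaining, drop = FALSE])
      np[remaining] <- np[remaining] - dec
    }
    r <- r + 1L
  }
  rank
}

#' Crowding distance within a front
#'
#' NSGA-II diversity measure: per objective, the front is sorted and the
#' boundary members receive infinity; interior members accumulate the
#' neighbour gap normalised by the objective's range. Fronts of one or two
#' members are all infinite.
#'
#' @param front Numeric matrix of objective vectors (mutually non-dominating).
#' @return Numeric vector of distances (may be `Inf`).
#' @export
crowding_distance <- function(front) {
  front <- as.matrix(front)
  m <- nrow(front)
  if (m <= 2L) return(rep(Inf, m))
  d <- numeric(m)
  for (k in seq_len(ncol(front))) {
    o <- order(front[, k])
    rng <- front[o[m], k] - front[o[1], k]
    d[o[1]] <- Inf
    d[o[m]] <- Inf
    if (rng > 0)
      d[o[2:(m - 1)]] <- d[o[2:(m - 1)]] +
        (front[o[3:m], k] - front[o[1:(m - 2)], k]) / rng
  }
  d
}

#' Hypervolume dominated by a front
#'
#' Lebesgue measure of the union of boxes spanned between each front member
#' and the reference point, for 1-3 objectives (exact sweep). Members that do
#' not dominate the reference point contribute nothing.
#'
#' @param front Numeric matrix (rows = objective vectors) or vector.
#' @param ref Reference point, same dimension.
#' @return Non-negative volume.
#' @export
hypervolume <- function(front, ref) {
  front <- if (is.null(dim(front))) matrix(front, ncol = length(ref))
           else as.matrix(front)
  d <- length(ref)
  stopifnot(ncol(front) == d, d %in% 1:3)
  keep <- apply(front, 1, function(p) all(p < ref))
  front <- front[keep, , drop = FALSE]
  if (nrow(front) == 0L) return(0)
  if (d == 1L) return(ref[1] - min(front[, 1]))
  if (d == 2L) return(hv2(front, ref))
  zs <- sort(unique(front[, 3]))
  vol <- 0
  for (i in seq_along(zs)) {
    z_hi <- if (i < length(zs)) zs[i + 1] else ref[3]
    slab <- z_hi - zs[i]
    area <- hv2(front[front[, 3] <= zs[i], 1:2, drop = FALSE], ref[1:2])
    vol <- vol + slab * area
  }
  vol
}

## 2-D hypervolume by staircase sweep; all points assumed to dominate ref.
hv2 <- function(pts, ref) {
  o <- order(pts[, 1], pts[, 2])
  pts <- pts[o, , drop = FALSE]
  vol <- 0
  y_prev <- ref[2]
  for (i in seq_len(nrow(pts))) {
    if (pts[i, 2] < y_prev) {
      vol <- vol + (ref[1] - pts[i, 1]) * (y_prev - pts[i, 2])
      y_prev <- pts[i, 2]
    }
  }
  vol
}

#' Select the balanced optimum from a Pareto set
#'
#' Each objective is normalised by its mean over the non-dominated set; the
#' member with the smallest Euclidean distance from the origin in the
#' normalised objective space is returned. Ties break to the lowest index.
#'
#' @param objectives Numeric matrix of the non-dominated set's objective
#'   vectors (one row per member).
#' @return Index of the selected member.
#' @export
select_optimal <- function(objectives) {
  obj <- if (is.null(dim(objectives))) matrix(objectives, ncol = 1)
         else as.matrix(objectives)
  if (nrow(obj) == 0L) stop("empty non-dominated set")
  mu <- colMeans(obj)
  mu[mu == 0] <- 1
  which.min(sqrt(rowSums(sweep(obj, 2, mu, "/")^2)))
}

#' MOEA run configuration
#'
#' Settings of the evolutionary search. The defaults are the package's
#' desk-scale protocol (population 100, 20 generations, 3 objective repeats);
#' the full protocol of 100 replicates at population 500 for 50 generations
#' with 5 repeats is one configuration change away.
#'
#' @param population_size Even population size.
#' @param generations Number of generations.
#' @param crossover_fraction Fraction of offspring produced by scattered
#'   (per-gene uniform mask) crossover; the remainder are Gaussian mutants.
#' @param tournament_size Tournament size for parent selection.
#' @param mutation_sd_frac Mutation standard deviation as a fraction of each
#'   gene's bound width; mutants are reflected back into the bounds.
#' @param n_repeats Stochastic simulations averaged per objective evaluation.
#' @param master_seed Master seed; a run is a pure function of it.
#' @return Object of class `liley_moea_config`.
#' @export
liley_moea_config <- function(population_size = 100, generations = 20,
                              crossover_fraction = 0.8, tournament_size = 2,
                              mutation_sd_frac = 0.05, n_repeats = 3,
                              master_seed = 1L) {
  stopifnot(population_size >= 4, population_size %% 2 == 0,
            generations >= 1, crossover_fraction >= 0,
            crossover_fraction <= 1, tournament_size >= 2,
            mutation_sd_frac > 0, n_repeats >= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_fraction = crossover_fraction,
                 tournament_size = as.integer(tournament_size),
                 mutation_sd_frac = mutation_sd_frac,
                 n_repeats = as.integer(n_repeats),
                 master_seed = as.integer(master_seed)),
            class = "liley_moea_config")
}

## Tournament selection on (rank, crowding); returns one index.
tournament_pick <- function(rank, crowd, k) {
  cand <- sample.int(length(rank), k, replace = FALSE)
  best <- cand[1]
  for (i in cand[-1]) {
    if (rank[i] < rank[best] ||
        (rank[i] == rank[best] && crowd[i] > crowd[best])) best <- i
  }
  best
}

## Crowding distances computed front-by-front for a whole population.
population_crowding <- function(objectives, rank) {
  crowd <- numeric(length(rank))
  for (r in unique(rank)) {
    idx <- which(rank == r)
    crowd[idx] <- crowding_distance(objectives[idx, , drop = FALSE])
  }
  crowd
}

## Produce population_size offspring decisions from the current population.
make_offspring <- function(decision, rank, crowd, bounds, cfg) {
  n <- cfg$population_size
  g <- ncol(decision)
  width <- bounds$upper - bounds$lower
  n_cross <- round(cfg$crossover_fraction * n)
  off <- matrix(0, n, g, dimnames = list(NULL, colnames(decision)))
  for (i in seq_len(n)) {
    if (i <= n_cross) {
      p1 <- tournament_pick(rank, crowd, cfg$tournament_size)
      p2 <- tournament_pick(rank, crowd, cfg$tournament_size)
      mask <- stats::runif(g) < 0.5
      off[i, ] <- ifelse(mask, decision[p1, ], decision[p2, ])
    } else {
      p1 <- tournament_pick(rank, crowd, cfg$tournament_size)
      child <- decision[p1, ] +
        stats::rnorm(g, 0, cfg$mutation_sd_frac * width)
      # reflect into the bounds box
      child <- bounds$lower + abs((child - bounds$lower) %% (2 * width))
      child <- ifelse(child > bounds$upper, 2 * bounds$upper - child, child)
      off[i, ] <- pmin(pmax(child, bounds$lower), bounds$upper)
    }
  }
  off
}

## Elitist (rank, crowding) truncation of a pooled population to size n.
truncate_population <- function(objectives, n) {
  rank <- non_dominated_sort(objectives)
  crowd <- population_crowding(objectives, rank)
  ord <- order(rank, -crowd, seq_along(rank))
  sort(ord[seq_len(n)])
}

#' Generic NSGA-II search over a bounded box
#'
#' The evolutionary engine behind [liley_fit()], usable with any objective
#' function: Latin hypercube initialisation, binary tournament selection on
#' (rank, crowding distance), scattered crossover, bounded Gaussian mutation,
#' and elitist (rank, crowding) truncation of the parent+offspring pool.
#' With a single objective it degenerates to an elitist GA. The whole run is
#' a pure function of `seed`.
#'
#' @param fn Objective function `fn(x, id)` mapping a decision vector and an
#'   integer evaluation id to a numeric vector of objectives (minimised).
#'   The id is unique per evaluated individual and lets stochastic objective
#'   functions derive reproducible seeds.
#' @param lower,upper Bound vectors of the decision box.
#' @param population_size Even population size.
#' @param generations Number of generations.
#' @param crossover_fraction Fraction of offspring from scattered crossover.
#' @param tournament_size Tournament size.
#' @param mutation_sd_frac Mutation sd as a fraction of each bound width.
#' @param seed Integer master seed.
#' @param verbose Print per-generation diagnostics.
#' @return List with `decision`, `objectives` (final population), `rank`,
#'   `history` (per-generation hypervolume against a fixed reference point —
#'   1.1 times the component-wise maximum of the initial objectives — and
#'   best normalised distance), and `ref_point`.
#' @export
nsga2 <- function(fn, lower, upper, population_size = 100, generations = 50,
                  crossover_fraction = 0.8, tournament_size = 2,
                  mutation_sd_frac = 0.05, seed = 1L, verbose = FALSE) {
  stopifnot(length(lower) == length(upper), all(lower < upper),
            population_size >= 4, population_size %% 2 == 0)
  bounds <- list(lower = lower, upper = upper)
  n <- as.integer(population_size)
  cfg <- list(population_size = n, crossover_fraction = crossover_fraction,
              tournament_size = as.integer(tournament_size),
              mutation_sd_frac = mutation_sd_frac)

  u <- with_private_seed(seed, lhs::randomLHS(n, length(lower)))
  decision <- sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
  colnames(decision) <- names(lower)
  d_obj <- length(fn(decision[1, ], 1L))
  eval_rows <- function(dec, ids) {
    v <- vapply(seq_along(ids), function(i) fn(dec[i, ], ids[i]),
                numeric(d_obj))
    if (d_obj == 1L) matrix(v, ncol = 1) else t(v)
  }
  objectives <- eval_rows(decision, seq_len(n))
  next_id <- n + 1L

  ref_point <- 1.1 * apply(objectives, 2, max)
  log_gen <- function(gen, objectives) {
    rank <- non_dominated_sort(objectives)
    front <- objectives[rank == 0L, , drop = FALSE]
    mu <- colMeans(front)
    mu[mu == 0] <- 1
    bd <- min(sqrt(rowSums(sweep(front, 2, mu, "/")^2)))
    data.frame(generation = gen,
               hypervolume = unname(hypervolume(front, ref_point)),
               best_distance = unname(bd), row.names = NULL)
  }
  history <- log_gen(0L, objectives)

  ga_seed <- derive_seed(seed, 0L, 0L)
  with_private_seed(ga_seed, {
    for (gen in seq_len(generations)) {
      rank <- non_dominated_sort(objectives)
      crowd <- population_crowding(objectives, rank)
      off <- make_offspring(decision, rank, crowd, bounds, cfg)
      off_obj <- eval_rows(off, next_id + seq_len(n) - 1L)
      next_id <- next_id + n
      pool_dec <- rbind(decision, off)
      pool_obj <- rbind(objectives, off_obj)
      keep <- truncate_population(pool_obj, n)
      decision <- pool_dec[keep, , drop = FALSE]
      objectives <- pool_obj[keep, , drop = FALSE]
      history <- rbind(history, log_gen(gen, objectives))
      if (verbose)
        message(sprintf("generation %d: hv = %.5g, best distance = %.4g",
                        gen, history$hypervolume[gen + 1],
                        history$best_distance[gen + 1]))
    }
  })

  rank <- non_dominated_sort(objectives)
  list(decision = decision, objectives = objectives, rank = rank,
       history = history, ref_point = ref_point)
}

#' Fit the Liley model to a data epoch by evolutionary search
#'
#' The central fitting function: NSGA-II-style multi-objective (or, with a
#' single objective, elitist single-objective) evolutionary search over the
#' bounded 23-dimensional parameter space. The initial population is a Latin
#' hypercube sample of the bounds; each generation applies binary tournament
#' selection on (rank, crowding distance), scattered crossover and bounded
#' Gaussian mutation, evaluates offspring as the repeat-averaged discrepancy
#' between stochastic model simulations and the data features, and truncates
#' parents plus offspring elitistically. Parents keep their cached objective
#' values. Per-generation hypervolume (fixed reference point, 1.1 times the
#' component-wise maximum of the initial objectives) and the best normalised
#' distance are logged as convergence diagnostics.
#'
#' @param data A `liley_data_features` object (see [data_features()]), a
#'   `liley_epoch`, or a numeric series (then supply `rate`).
#' @param algorithm `"MOEA20"`, `"MOEA45"`, `"SOEA20"` or `"SOEA45"`.
#' @param moea A `liley_moea_config`.
#' @param sim A `liley_sim_config`; defaults to the data epoch length at the
#'   data rate, with white noise.
#' @param bounds A `liley_bounds` search box.
#' @param rate Sampling rate when `data` is a bare numeric series.
#' @param resolution Spectral resolution passed to [data_features()] when
#'   `data` is not already a feature object; by default the coarsest of
#'   0.125 Hz and one over the epoch length.
#' @param verbose Print per-generation progress.
#' @return Object of class `liley_fit`; see [coef.liley_fit()],
#'   [summary.liley_fit()], [simulate.liley_fit()], [plot.liley_fit()].
#' @export
liley_fit <- function(data, algorithm = c("MOEA20", "MOEA45", "SOEA20",
                                          "SOEA45"),
                      moea = liley_moea_config(), sim = NULL,
                      bounds = liley_bounds(), rate = NULL,
                      resolution = NULL, verbose = FALSE) {
  algorithm <- match.arg(algorithm)
  kinds <- algorithm_objectives(algorithm)

  if (inherits(data, "liley_epoch")) {
    rate <- data$rate
    data <- data$samples
  }
  if (is.numeric(data)) {
    if (is.null(rate)) stop("supply 'rate' with a bare numeric series")
    epoch_s <- length(data) / rate
    if (is.null(resolution)) resolution <- max(0.125, 1 / epoch_s)
    data <- data_features(data, rate, resolution = resolution)
  }
  stopifnot(inherits(data, "liley_data_features"))

  if (is.null(sim))
    sim <- liley_sim_config(duration = length(data$series) / data$rate,
                            output_rate = data$rate)

  eval_one <- function(x, id)
    evaluate_objectives(liley_params(.values = x), data, kinds, sim,
                        n_repeats = moea$n_repeats,
                        master_seed = moea$master_seed, id = id)
  run <- nsga2(eval_one, bounds$lower, bounds$upper,
               population_size = moea$population_size,
               generations = moea$generations,
               crossover_fraction = moea$crossover_fraction,
               tournament_size = moea$tournament_size,
               mutation_sd_frac = moea$mutation_sd_frac,
               seed = moea$master_seed, verbose = verbose)

  objectives <- run$objectives
  colnames(objectives) <- kinds
  in_front <- run$rank == 0L
  front_dec <- run$decision[in_front, , drop = FALSE]
  front_obj <- objectives[in_front, , drop = FALSE]
  opt <- select_optimal(front_obj)

  structure(list(
    algorithm = algorithm, kinds = kinds,
    optimum = liley_params(.values = front_dec[opt, ]),
    optimum_objectives = front_obj[opt, ],
    pareto_decision = front_dec, pareto_objectives = front_obj,
    population_decision = run$decision, population_objectives = objectives,
    population_rank = run$rank,
    history = run$history, ref_point = run$ref_point,
    data = data, bounds = bounds, moea = moea, sim = sim
  ), class = "liley_fit")
}

#' Run independent fit replicates and pool the optima
#'
#' The evolutionary search is stochastic, so the full protocol repeats it
#' (100 times in the reference setting) and pools each replicate's selected
#' optimum into a parameter sample for distributional analysis. Replicates
#' use independent master seeds derived deterministically from `master_seed`,
#' so serial and parallel execution give identical pooled output.
#'
#' @inheritParams liley_fit
#' @param n_replicates Number of independent runs.
#' @param master_seed Seed from which per-replicate master seeds are derived.
#' @param label Cohort/algorithm label attached to the pooled rows.
#' @return List with `fits` (list of `liley_fit`) and `sample` (a
#'   [parameter_sample()] of the pooled optima).
#' @export
liley_replicates <- function(data, algorithm = "MOEA20",
                             moea = liley_moea_config(), sim = NULL,
                             bounds = liley_bounds(), n_replicates = 3,
                             master_seed = 1L, label = algorithm,
                             verbose = FALSE) {
  stopifnot(n_replicates >= 1)
  fits <- lapply(seq_len(n_replicates), function(i) {
    cfg <- moea
    cfg$master_seed <- derive_seed(master_seed, i, 0L)
    liley_fit(data, algorithm, moea = cfg, sim = sim, bounds = bounds,
              verbose = verbose)
  })
  mat <- t(vapply(fits, function(f) unclass(f$optimum), numeric(23)))
  list(fits = fits,
       sample = parameter_sample(mat, labels = rep(label, n_replicates),
                                 bounds = bounds))
}
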