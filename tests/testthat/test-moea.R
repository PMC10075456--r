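test_that("Latin hypercube initialisation stratifies every dimension", {
  b <- liley_bounds()
  x <- latin_hypercube_init(b, 10, seed = 3)
  expect_identical(dim(x), c(10L, 23L))
  for (k in 1:23) {
    expect_true(all(x[, k] >= b$lower[k] & x[, k] <= b$upper[k]))
    strata <- findInterval(x[, k], seq(b$lower[k], b$upper[k],
                                       length.out = 11),
                           rightmost.closed = TRUE)
    expect_identical(sort(strata), 1:10)
  }
  expect_identical(x, latin_hypercube_init(b, 10, seed = 3))
  expect_false(identical(x, latin_hypercube_init(b, 10, seed = 4)))
})

test_that("dominance follows the strict definition", {
  expect_true(dominates(c(1, 2), c(2, 3)))
  expect_false(dominates(c(1, 3), c(2, 2)))
  expect_false(dominates(c(2, 2), c(1, 3)))
  expect_false(dominates(c(1, 2), c(1, 2)))  # equality is not dominance
  expect_true(dominates(c(1, 2), c(1, 3)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "length")
  # irreflexive and transitive on random vectors
  withr::local_seed(4)
  for (i in 1:200) {
    a <- runif(3); b <- runif(3); cc <- runif(3)
    expect_false(dominates(a, a))
    if (dominates(a, b) && dominates(b, cc)) expect_true(dominates(a, cc))
  }
})

test_that("non-dominated sorting matches hand examples and degenerate cases", {
  expect_identical(non_dominated_sort(rbind(c(1, 2), c(2, 1), c(3, 3))),
                   c(0L, 0L, 1L))
  expect_identical(non_dominated_sort(rbind(c(1, 1), c(1, 1), c(2, 2))),
                   c(0L, 0L, 1L))
  # single objective: ranks reproduce sort order, ties share rank
  v <- c(3, 1, 2, 1)
  expect_identical(non_dominated_sort(matrix(v, ncol = 1)), c(2L, 0L, 1L, 0L))
})

test_that("non-dominated sorting equals the brute-force peeling oracle", {
  withr::local_seed(12)
  for (i in 1:500) {
    n <- if (i <= 490) sample(3:60, 1) else sample(150:200, 1)
    d <- sample(1:3, 1)
    obj <- matrix(runif(n * d), n, d)
    if (i %% 4 == 0) obj <- round(obj, 1)  # force ties and duplicates
    r <- non_dominated_sort(obj)
    expect_identical(r, oracle_nds(obj))
    # rank-0 is an antichain under dominance
    f0 <- which(r == 0L)
    if (length(f0) > 1) {
      for (a in f0[1:min(5, length(f0))]) for (b in f0)
        if (a != b) expect_false(dominates(obj[a, ], obj[b, ]))
    }
  }
})

test_that("crowding distance reproduces the hand example and conventions", {
  expect_identical(crowding_distance(rbind(c(1, 2), c(2, 1))), c(Inf, Inf))
  d <- crowding_distance(rbind(c(0, 2), c(1, 1), c(2, 0)))
  expect_identical(d[c(1, 3)], c(Inf, Inf))
  expect_equal(d[2], 2)
  # permuting the front permutes the distances
  d2 <- crowding_distance(rbind(c(2, 0), c(0, 2), c(1, 1)))
  expect_equal(d2, d[c(3, 1, 2)])
})

test_that("hypervolume matches closed forms and the inclusion-exclusion oracle", {
  expect_equal(hypervolume(rbind(c(1, 2), c(2, 1)), c(3, 3)), 3)
  expect_equal(hypervolume(c(1, 1), c(2, 2)), 1)
  # adding a dominated point changes nothing
  expect_equal(hypervolume(rbind(c(1, 2), c(2, 1), c(2.5, 2.5)), c(3, 3)), 3)
  # a point outside the reference box is ignored
  expect_equal(hypervolume(rbind(c(1, 2), c(4, 0)), c(3, 3)), 2)
  withr::local_seed(21)
  for (i in 1:60) {
    d <- sample(2:3, 1)
    m <- sample(1:7, 1)
    pts <- matrix(runif(m * d), m, d)
    ref <- rep(1.2, d)
    expect_equal(hypervolume(pts, ref), oracle_hypervolume(pts, ref),
                 tolerance = 1e-12)
    # monotone under adding a new point
    extra <- rbind(pts, runif(d))
    expect_gte(hypervolume(extra, ref), hypervolume(pts, ref) - 1e-12)
  }
})

test_that("optimum selection minimises the mean-normalised distance", {
  expect_identical(select_optimal(rbind(c(1, 3), c(3, 1), c(2, 2))), 3L)
  expect_identical(select_optimal(matrix(c(5, 2), ncol = 1)), 2L)
  expect_identical(select_optimal(rbind(c(2, 2))), 1L)
  # ties break to the lowest index
  expect_identical(select_optimal(rbind(c(1, 2), c(2, 1))), 1L)
})

test_that("offspring respect bounds and the scattered-crossover gene pool", {
  b <- list(lower = c(a = 0, b = -1), upper = c(a = 1, b = 1))
  dec <- rbind(c(0.2, -0.5), c(0.9, 0.7))
  cfg <- list(population_size = 40L, crossover_fraction = 1,
              tournament_size = 2L, mutation_sd_frac = 0.05)
  withr::local_seed(31)
  off <- lileyfit:::make_offspring(dec, c(0L, 0L), c(Inf, Inf), b, cfg)
  for (i in seq_len(nrow(off))) for (k in 1:2)
    expect_true(off[i, k] %in% dec[, k])  # child genes come from a parent
  cfg$crossover_fraction <- 0
  mut <- lileyfit:::make_offspring(dec, c(0L, 0L), c(Inf, Inf), b, cfg)
  expect_true(all(mut >= matrix(b$lower, 40, 2, byrow = TRUE) &
                    mut <= matrix(b$upper, 40, 2, byrow = TRUE)))
})

test_that("the engine recovers the analytic front of a convex toy problem", {
  fn <- function(x, id) c(x[1]^2, (x[1] - 2)^2)
  r <- nsga2(fn, lower = c(v = -5), upper = c(v = 5), population_size = 100,
             generations = 50, seed = 3)
  front <- r$objectives[r$rank == 0L, , drop = FALSE]
  dev <- abs(front[, 2] - (2 - sqrt(front[, 1]))^2)
  expect_lt(max(dev), 0.05)
  # hypervolume is non-decreasing up to crowding-truncation exchange
  hv <- r$history$hypervolume
  expect_true(all(diff(hv) > -1e-4 * hv[length(hv)]))
})

test_that("the single-objective degenerate mode is strictly elitist", {
  fn <- function(x, id) sum((x - 0.3)^2)
  r <- nsga2(fn, lower = rep(0, 4), upper = rep(1, 4), population_size = 20,
             generations = 30, seed = 5)
  expect_true(all(diff(r$history$hypervolume) >= 0))
  expect_true(all(diff(r$history$best_distance) <= 1e-12))
  expect_lt(min(r$objectives), 1e-3)
})

test_that("whole fits are reproducible from the master seed", {
  ep <- generate_synthetic_subject(alpha_fixture_params(),
                                   liley_sim_config(duration = 1,
                                                    transient = 2),
                                   seed = 3)
  cfg <- liley_moea_config(population_size = 8, generations = 2,
                           n_repeats = 1, master_seed = 9)
  f1 <- liley_fit(ep, "MOEA20", moea = cfg)
  f2 <- liley_fit(ep, "MOEA20", moea = cfg)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$pareto_objectives, f2$pareto_objectives)
  expect_identical(f1$history, f2$history)
  # the optimum is a member of the non-dominated set, which is an antichain
  expect_true(any(apply(f1$pareto_decision, 1, function(x)
    isTRUE(all.equal(unname(x), unname(coef(f1)))))))
  po <- f1$pareto_objectives
  if (nrow(po) > 1)
    for (a in seq_len(nrow(po))) for (b in seq_len(nrow(po)))
      if (a != b) expect_false(dominates(po[a, ], po[b, ]))
})

test_that("fit methods expose coefficients, simulations and residuals", {
  ep <- generate_synthetic_subject(alpha_fixture_params(),
                                   liley_sim_config(duration = 1,
                                                    transient = 2),
                                   seed = 3)
  fit <- liley_fit(ep, "SOEA20",
                   moea = liley_moea_config(population_size = 8,
                                            generations = 2, n_repeats = 1,
                                            master_seed = 2))
  expect_named(coef(fit), liley_param_names())
  expect_output(print(fit), "SOEA20")
  expect_output(summary(fit), "Convergence")
  tr <- simulate(fit, seed = 4)
  expect_s3_class(tr, "liley_trajectory")
  expect_length(tr$samples, length(ep$samples))
  res <- residuals(fit, nsim = 1)
  expect_identical(names(res),
                   c("freq_hz", "data_power", "model_power", "residual"))
  expect_equal(res$residual, res$data_power - res$model_power)
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pareto_csv(fit, path)
  expect_true(all(c("objective_psd20", "rank") %in% names(read.csv(path))))
})

test_that("replicates pool one optimum per run, reproducibly", {
  ep <- generate_synthetic_subject(alpha_fixture_params(),
                                   liley_sim_config(duration = 1,
                                                    transient = 2),
                                   seed = 3)
  cfg <- liley_moea_config(population_size = 8, generations = 1,
                           n_repeats = 1)
  r1 <- liley_replicates(ep, "SOEA20", moea = cfg, n_replicates = 3,
                         master_seed = 4)
  expect_length(r1$fits, 3)
  expect_identical(nrow(r1$sample$values), 3L)
  expect_identical(r1$sample$labels, rep("SOEA20", 3))
  # distinct seeds give (generically) distinct optima
  expect_gt(max(dist(r1$sample$values)), 0)
  r2 <- liley_replicates(ep, "SOEA20", moea = cfg, n_replicates = 3,
                         master_seed = 4)
  expect_identical(r1$sample$values, r2$sample$values)
})
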