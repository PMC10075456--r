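test_that("JSD matches its closed forms", {
  expect_equal(jsd(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), log(2), tolerance = 1e-12)
  # H(0.75, 0.25) - ln(2)/2, evaluated directly from the definition
  expected <- -(0.75 * log(0.75) + 0.25 * log(0.25)) - log(2) / 2
  expect_equal(jsd(c(1, 0), c(0.5, 0.5)), expected, tolerance = 1e-12)
  expect_lt(abs(expected - 0.215761), 1e-6)
  expect_error(jsd(c(0.5, 0.6), c(0.5, 0.5)), "sum to 1")
  expect_error(jsd(c(1, 0), c(1, 0, 0)), "length")
})

test_that("JSD is symmetric and bounded on random distribution pairs", {
  withr::local_seed(13)
  for (i in 1:1000) {
    k <- sample(2:20, 1)
    p <- runif(k); p <- p / sum(p)
    q <- runif(k); q <- q / sum(q)
    v <- jsd(p, q)
    expect_gte(v, 0)
    expect_lte(v, log(2) + 1e-12)
    expect_equal(v, jsd(q, p), tolerance = 1e-14)
  }
  # zero iff equal (generic continuous draws)
  p <- c(0.2, 0.8)
  expect_gt(jsd(p, c(0.25, 0.75)), 0)
})

test_that("uniform samples over the bounds are judged unidentifiable", {
  b <- liley_bounds()
  withr::local_seed(17)
  u <- matrix(runif(2000 * 23), 2000, 23)
  s <- parameter_sample(sweep(sweep(u, 2, b$upper - b$lower, "*"), 2,
                              b$lower, "+"))
  for (k in c("Gamma_e", "gamma_i", "xi"))
    expect_lt(identifiability_jsd(s, k), 0.05)
})

test_that("a point mass attains the degenerate closed-form JSD", {
  b <- liley_bounds()
  v <- matrix(rep(unclass(liley_typical()), 50), 50, 23, byrow = TRUE)
  s <- parameter_sample(v)
  # all mass in one of 100 bins vs uniform: direct evaluation of the formula
  p <- c(1, rep(0, 99))
  q <- rep(1 / 100, 100)
  m <- (p + q) / 2
  H <- function(w) { w <- w[w > 0]; -sum(w * log(w)) }
  expected <- H(m) - H(p) / 2 - H(q) / 2
  expect_equal(identifiability_jsd(s, "Gamma_e"), expected, tolerance = 1e-12)
})

test_that("identifiability rises as the recovered distribution narrows", {
  b <- liley_bounds()
  k <- match("tau_e", liley_param_names())
  centre <- (b$lower[k] + b$upper[k]) / 2
  withr::local_seed(23)
  base <- sweep(sweep(matrix(runif(1500 * 23), 1500, 23), 2,
                      b$upper - b$lower, "*"), 2, b$lower, "+")
  vals <- vapply(c(0.3, 0.1, 0.03), function(w) {
    x <- base
    raw <- rnorm(1500, centre, w * (b$upper[k] - b$lower[k]))
    x[, k] <- pmin(pmax(raw, b$lower[k]), b$upper[k])
    identifiability_jsd(parameter_sample(x), k)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("identifiability of a true uniform shrinks with sample size", {
  b <- liley_bounds()
  withr::local_seed(29)
  med <- vapply(c(500, 2000, 8000), function(n) {
    median(vapply(1:20, function(r) {
      x <- sweep(sweep(matrix(runif(n * 23), n, 23), 2,
                       b$upper - b$lower, "*"), 2, b$lower, "+")
      identifiability_jsd(parameter_sample(x), "N_ee")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})

test_that("cohort comparison reproduces the hand-computed effect size", {
  b <- liley_bounds()
  mk <- function(vals, param) {
    x <- matrix(rep((b$lower + b$upper) / 2, length(vals)),
                length(vals), 23, byrow = TRUE)
    x[, match(param, liley_param_names())] <- vals
    parameter_sample(x)
  }
  a <- mk(c(0, 2), "p_ee"); bb <- mk(c(3, 5), "p_ee")
  cmp <- cohort_compare(a, bb)
  row <- cmp[cmp$parameter == "p_ee", ]
  expect_equal(row$cohens_d, -3 / sqrt(2), tolerance = 1e-5)
  expect_equal(row$cohens_d, -2.12132, tolerance = 1e-5)
  # swapping cohorts flips d and keeps JSD
  cmp2 <- cohort_compare(bb, a)
  expect_equal(cmp2$cohens_d[cmp2$parameter == "p_ee"], -row$cohens_d)
  expect_equal(cmp2$jsd, cmp$jsd)
  # identical cohorts: everything zero (d undefined where variance is zero)
  same <- cohort_compare(a, a)
  expect_equal(same$jsd, rep(0, 23))
  expect_equal(same$cohens_d[same$parameter == "p_ee"], 0)
  expect_true(is.na(same$cohens_d[same$parameter == "tau_e"]))
})

test_that("Cohen's d recovers a planted standardised effect", {
  b <- liley_bounds()
  k <- match("sigma_e", liley_param_names())
  withr::local_seed(37)
  base <- function(n, shift) {
    x <- matrix(rep((b$lower + b$upper) / 2, n), n, 23, byrow = TRUE)
    x[, k] <- pmin(pmax(rnorm(n, 4.5 + shift, 0.4), b$lower[k]), b$upper[k])
    parameter_sample(x)
  }
  # average over replicate cohort pairs to separate estimator bias from
  # per-draw sampling noise (sd of a single d-hat is ~0.15 at n = 100)
  ds <- vapply(1:20, function(r)
    cohort_compare(base(100, 0.4 * 0.8), base(100, 0))$cohens_d[k],
    numeric(1))
  expect_equal(mean(ds), 0.8, tolerance = 0.1)
})

test_that("classical MDS preserves planar configurations exactly", {
  b <- liley_bounds()
  w <- b$upper - b$lower
  mku <- function(u) b$lower + u * w
  # a 3-4-5 right triangle in the normalised space (scaled by 1/10)
  u1 <- rep(0.2, 23)
  u2 <- u1; u2[1] <- u2[1] + 0.3
  u3 <- u1; u3[2] <- u3[2] + 0.4
  s <- parameter_sample(rbind(mku(u1), mku(u2), mku(u3)))
  y <- mds_embed(s)
  expect_equal(sort(as.numeric(dist(y))), c(0.3, 0.4, 0.5),
               tolerance = 1e-8)
  # points already in a 2-d affine subspace embed isometrically
  withr::local_seed(41)
  uu <- matrix(0.5, 12, 23)
  uu[, 3] <- runif(12, 0.1, 0.9)
  uu[, 7] <- runif(12, 0.1, 0.9)
  s2 <- parameter_sample(t(apply(uu, 1, mku)))
  y2 <- mds_embed(s2)
  unorm <- uu
  expect_equal(as.numeric(dist(y2)), as.numeric(dist(unorm)),
               tolerance = 1e-8)
  # row order only permutes the configuration
  perm <- c(3, 1, 2)
  s3 <- parameter_sample(s$values[perm, ])
  y3 <- mds_embed(s3)
  expect_equal(as.numeric(dist(y3)), as.numeric(dist(y[perm, ])),
               tolerance = 1e-8)
  # degenerate identical rows embed at the origin
  s4 <- parameter_sample(matrix(rep(mku(u1), 3), 3, byrow = TRUE))
  expect_equal(mds_embed(s4), matrix(0, 3, 2))
})

test_that("silhouette scores match the direct formula and cross-check", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  lab <- c("A", "A", "B", "B")
  # by hand: endpoints score 1 - 1/10.5, interior points 1 - 1/9.5
  expected <- mean(c(1 - 1 / 10.5, 1 - 1 / 9.5, 1 - 1 / 9.5, 1 - 1 / 10.5))
  expect_equal(silhouette_score(pts, lab), expected, tolerance = 1e-12)
  expect_equal(expected, 0.8997494, tolerance = 1e-6)
  skip_if_not_installed("cluster")
  cs <- cluster::silhouette(as.integer(factor(lab)), dist(pts))
  expect_equal(silhouette_score(pts, lab), mean(cs[, 3]), tolerance = 1e-12)
})

test_that("silhouette separates tight clusters and ignores coincident ones", {
  withr::local_seed(43)
  a <- matrix(rnorm(100, 0, 0.1), ncol = 2)
  b <- matrix(rnorm(100, 20, 0.1), ncol = 2)
  expect_gt(silhouette_score(rbind(a, b),
                             rep(c("a", "b"), each = 50)), 0.95)
  c1 <- matrix(rnorm(400), ncol = 2)
  c2 <- matrix(rnorm(400), ncol = 2)
  expect_lt(abs(silhouette_score(rbind(c1, c2),
                                 rep(c("a", "b"), each = 200))), 0.05)
  # singleton label scores zero by convention
  expect_equal(silhouette_score(matrix(c(0, 5, 6)), c("x", "y", "y")),
               mean(c(0, (5 - 1) / 5, (6 - 1) / 6)))
})

test_that("population summaries sit at the fixed point when noise is off", {
  p <- params_stable()
  fp <- find_fixed_points(p, grid_n = 8)[[1]]
  cfg <- liley_sim_config(duration = 4, transient = 6, noise_mode = "off")
  s <- population_summaries(p, cfg)
  expect_false(s$divergent)
  expect_equal(s$mean_he, fp$state[["he"]], tolerance = 1e-4)
  expect_equal(s$mean_hi, fp$state[["hi"]], tolerance = 1e-4)
  expect_equal(s$mean_Se,
               liley_sigmoid(fp$state[["he"]], p[["Se_max"]], p[["mu_e"]],
                             p[["sigma_e"]]), tolerance = 1e-6)
  expect_true(s$mean_Se > 0 && s$mean_Se < p[["Se_max"]])
  expect_true(s$mean_Si > 0 && s$mean_Si < p[["Si_max"]])
})

test_that("firing-rate summaries use the pointwise convention on cycles", {
  p <- params_oscillatory()
  cfg <- liley_sim_config(duration = 4, transient = 6, noise_mode = "off")
  s <- population_summaries(p, cfg)
  tr <- simulate_liley(p, cfg)
  rate_pointwise <- mean(liley_sigmoid(tr$samples, p[["Se_max"]],
                                       p[["mu_e"]], p[["sigma_e"]]))
  rate_of_mean <- liley_sigmoid(mean(tr$samples), p[["Se_max"]],
                                p[["mu_e"]], p[["sigma_e"]])
  expect_equal(s$mean_Se, rate_pointwise, tolerance = 1e-12)
  expect_gt(abs(rate_pointwise - rate_of_mean), 1e-4)
  # divergent parameters are flagged, not thrown
  sd_ <- population_summaries(params_divergent(),
                              liley_sim_config(duration = 1, transient = 0.5,
                                               noise_mode = "off"))
  expect_true(sd_$divergent)
  expect_true(is.na(sd_$mean_he))
})
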