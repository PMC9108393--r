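test_that("Latin hypercube designs stratify every dimension and are reproducible", {
  X <- latin_hypercube(4, 2, seed = 10)
  for (j in 1:2)
    expect_identical(sort(findInterval(X[, j], seq(0, 1, by = 0.25))), 1:4)
  expect_identical(latin_hypercube(4, 2, seed = 10), X)
  expect_false(identical(latin_hypercube(4, 2, seed = 11), X))
  X1 <- latin_hypercube(1, 3, seed = 1)
  expect_true(all(X1 > 0 & X1 < 1))
  expect_error(latin_hypercube(0, 2, seed = 1), ">= 1")
})

test_that("the Kriging surrogate interpolates and flags constant data", {
  set.seed(41)
  X <- latin_hypercube(15, 2, seed = 3)
  y <- sin(4 * X[, 1]) + X[, 2]^2
  m <- gp_fit(X, y)
  pr <- gp_predict(m, X)
  expect_lt(max(abs(pr$mean - y)), 1e-6 * diff(range(y)))
  expect_lt(max(pr$sd), 1e-4 * diff(range(y)))
  # constant responses: mean is the constant, sd collapses
  mc <- gp_fit(X, rep(2.5, 15))
  prc <- gp_predict(mc, matrix(stats::runif(10), 5, 2))
  expect_equal(prc$mean, rep(2.5, 5))
  expect_equal(prc$sd, rep(0, 5))
  expect_error(gp_fit(X[1:3, ], y[1:3]), "d \\+ 2")
})

test_that("leave-one-out Kriging predictions are calibrated on a quadratic", {
  set.seed(17)
  X <- latin_hypercube(20, 2, seed = 20)
  y <- (X[, 1] - 0.4)^2 + 2 * (X[, 2] - 0.6)^2
  z <- vapply(1:20, function(i) {
    m <- gp_fit(X[-i, , drop = FALSE], y[-i])
    pr <- gp_predict(m, X[i, , drop = FALSE])
    (y[i] - pr$mean) / max(pr$sd, 1e-12)
  }, 0)
  expect_gte(mean(abs(z) < 3), 0.95)
})

test_that("expected improvement matches its closed form and a Monte-Carlo oracle", {
  # degenerate cases
  expect_equal(expected_improvement(2, 0, 1), 0)
  expect_equal(expected_improvement(0.5, 0, 1), 0.5)
  # at mu = f_min with unit sd, EI is the standard normal density at 0
  expect_equal(expected_improvement(1, 1, 1), stats::dnorm(0),
               tolerance = 1e-12)
  # Monte-Carlo oracle for a generic configuration
  mu <- 1.3; sd <- 0.7; f_min <- 1.0
  set.seed(123)
  draws <- stats::rnorm(1e6, mu, sd)
  imp <- pmax(f_min - draws, 0)
  mc_se <- stats::sd(imp) / sqrt(1e6)
  expect_lt(abs(expected_improvement(mu, sd, f_min) - mean(imp)), 3 * mc_se)
  expect_error(expected_improvement(0, -1, 0), "sd")
})

test_that("batch proposals use distinct criteria and stay separated", {
  set.seed(2)
  X <- latin_hypercube(12, 1, seed = 5)
  y <- (X[, 1] - 0.35)^2
  m <- gp_fit(X, y)
  bounds <- rbind(lower = 0, upper = 1)
  b3 <- propose_batch(m, bounds, 3)
  expect_equal(dim(b3), c(3, 1))
  # first slot is always the EI maximiser; exploitation/exploration slots
  # may be replaced by labelled random points when they collide
  crit <- attr(b3, "criterion")
  expect_identical(crit[1], "max_ei")
  expect_true(all(crit %in% c("max_ei", "min_mean", "max_sd", "random")))
  dists <- as.matrix(stats::dist(b3))
  expect_gte(min(dists[upper.tri(dists)]), 1e-3)
  expect_true(all(b3 >= 0 & b3 <= 1))
  # constant-liar slots appear for larger batches
  b5 <- propose_batch(m, bounds, 5)
  expect_equal(nrow(b5), 5)
  expect_true("liar_ei" %in% attr(b5, "criterion") ||
                "random" %in% attr(b5, "criterion")[4:5])
  # the DE search finds the predictive-sd maximum of the dense-grid
  # oracle on a sparse design with an obvious gap
  Xg <- matrix(c(0.05, 0.1, 0.2, 0.85, 0.95), ncol = 1)
  mg <- gp_fit(Xg, sin(6 * Xg[, 1]), restarts = 3)
  grid <- matrix(seq(0, 1, length.out = 4001), ncol = 1)
  sd_grid <- gp_predict(mg, grid)$sd
  sd_best <- max(sd_grid)
  expect_gt(sd_best, 1e-3)                 # the gap is genuinely uncertain
  de_sd <- de_optimize(function(M) gp_predict(mg, M)$sd, 0, 1,
                       generations = 60, maximize = TRUE)
  expect_lt(abs(de_sd$value - sd_best), 0.01 * sd_best)
  # and it lies inside the unsampled gap
  expect_gt(de_sd$par, 0.2)
  expect_lt(de_sd$par, 0.85)
  # q = 1 returns only the EI maximiser
  b1 <- propose_batch(m, bounds, 1)
  expect_identical(attr(b1, "criterion"), "max_ei")
})

test_that("domain reduction recentres, shrinks and clips", {
  b <- rbind(lower = c(0, 0), upper = c(1, 2))
  r1 <- reduce_domain(b, c(0.5, 1), 0.5)
  expect_equal(unname(r1[1, ]), c(0.25, 0.5))
  expect_equal(unname(r1[2, ]), c(0.75, 1.5))
  # corner incumbent: still inside the original box
  r2 <- reduce_domain(b, c(0, 2), 0.5)
  expect_true(all(r2[1, ] >= b[1, ] & r2[2, ] <= b[2, ]))
  expect_equal(unname(r2[, 1]), c(0, 0.25))
  # four successive halvings leave 1/16 of each width
  r <- b
  for (i in 1:4) r <- reduce_domain(r, c(0.5, 1), 0.5)
  expect_equal(unname(r[2, ] - r[1, ]), c(1, 2) / 16)
  expect_error(reduce_domain(b, c(2, 0), 0.5), "outside")
  expect_error(reduce_domain(b, c(0.5, 1), 1.5), "shrink_factor")
})

test_that("the optimiser respects its budget, seed and incumbent monotonicity", {
  f <- function(x) sum((x - 0.3)^2)
  bounds <- rbind(lower = rep(0, 2), upper = rep(1, 2))
  res <- krig_optimize(f, bounds, budget = 48, seed = 4, n_init = 20)
  expect_lte(res$n_eval, 48)
  expect_equal(res$value, min(res$history$objective))
  # running best is nonincreasing
  expect_true(all(diff(cummin(res$history$objective)) <= 0))
  # exact reproducibility under the seed
  res2 <- krig_optimize(f, bounds, budget = 48, seed = 4, n_init = 20)
  expect_equal(res$history, res2$history)
  # final bounds are a subset of the original box
  expect_true(all(res$bounds_final[1, ] >= 0 & res$bounds_final[2, ] <= 1))
  # budget equal to the design size: pure LHS, no surrogate iterations
  res3 <- krig_optimize(f, bounds, budget = 20, seed = 4, n_init = 20)
  expect_equal(res3$n_eval, 20)
  expect_true(all(res3$history$criterion == "lhs_init"))
  expect_error(krig_optimize(f, bounds, budget = 5, seed = 1, n_init = 20),
               "smaller than the initial design")
})

test_that("the optimiser finds a convex minimum quickly", {
  f <- function(x) sum((x - 0.55)^2) + 0.7
  bounds <- rbind(lower = rep(0, 2), upper = rep(1, 2))
  res <- krig_optimize(f, bounds, budget = 60, seed = 9)
  expect_lt(res$value - 0.7, 1e-3)
})
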