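test_that("fit specifications validate bounds, scales and parameter names", {
  fixed <- default_params("control")
  fs <- fit_spec(free = list(rho_tilde = list(lower = 10, upper = 400,
                                              log10 = TRUE),
                             zeta = list(lower = 0.05, upper = 1)),
                 fixed = fixed, roi_length_um = 1000)
  b <- fit_bounds(fs)
  expect_equal(b["lower", "rho_tilde"], 1)     # log10(10)
  expect_equal(b["upper", "zeta"], 1)
  p <- theta_to_params(c(2, 0.3), fs)
  expect_equal(p$rho_tilde, 100)
  expect_equal(p$zeta, 0.3)
  expect_error(fit_spec(list(bogus = list(lower = 0, upper = 1)), fixed, 1000),
               "unknown free parameter")
  expect_error(fit_spec(list(zeta = list(lower = 1, upper = 0)), fixed, 1000),
               "lower < upper")
  expect_error(fit_spec(list(k = list(lower = -1, upper = 1, log10 = TRUE)),
                        fixed, 1000), "positive bounds")
})

test_that("expected counts integrate the density exactly over bins", {
  # constant density c: every one of 20 equal bins holds c / 20
  sol <- fake_solution(matrix(3, 1, 50), times = 0, n_cells = 50)
  edges <- seq(0, 1000, length.out = 21)
  ec <- expected_counts(sol, edges, 1000)
  expect_equal(as.numeric(ec), rep(3 / 20, 20))
  # partition property: bins sum to the full integral for any density
  set.seed(8)
  rho <- matrix(stats::rexp(60), 2, 30)
  sol2 <- fake_solution(rho, times = c(0, 2), n_cells = 30)
  edges2 <- c(0, sort(stats::runif(7, 0, 1000)), 1000)
  ec2 <- expected_counts(sol2, edges2, 1000)
  expect_equal(rowSums(ec2), rowSums(rho) / 30, ignore_attr = TRUE)
  # brute-force midpoint-quadrature oracle on misaligned bins
  brute <- vapply(seq_len(length(edges2) - 1L), function(b) {
    a <- edges2[b] / 1000; z <- edges2[b + 1L] / 1000
    dx <- (z - a) / 1e6
    xs <- a + (seq_len(1e6) - 0.5) * dx
    cell <- pmin(floor(xs * 30) + 1L, 30L)
    sum(rho[1L, cell]) * dx
  }, 0)
  expect_lt(max(abs(as.numeric(ec2[1L, ]) - brute)), 1e-6)
  expect_error(expected_counts(sol, edges, 1000, times = 5), "absent")
  expect_error(expected_counts(sol, c(-100, 500), 1000), "outside")
})

test_that("the objective is a sum of squared count differences", {
  ds <- small_design(noise = "none")
  exp_c <- design_expected_counts(ds, "DP47")
  spec <- fit_spec(free = list(rho_tilde = list(lower = 10, upper = 400,
                                                log10 = TRUE),
                               zeta = list(lower = 0.05, upper = 1)),
                   fixed = ds$params_control,
                   roi_length_um = ds$roi_length_um,
                   n_cells = ds$n_cells, output_times = ds$times)
  # self-consistency: data equal to the model's own expected counts give
  # an essentially zero objective at the generating parameters
  data <- list(times = exp_c$times, bin_edges_um = exp_c$bin_edges_um,
               counts = exp_c$expected)
  class(data) <- "binned_counts"
  truth <- c(log10(ds$params_control$rho_tilde), ds$params_control$zeta)
  expect_lt(infil_objective(data, spec, truth), 1e-2)
  # a single bin off by 2 adds exactly 4
  data2 <- data
  data2$counts[5, 3] <- data2$counts[5, 3] + 2
  expect_equal(infil_objective(data2, spec, truth) -
                 infil_objective(data, spec, truth), 4, tolerance = 1e-6)
  # order invariance over times and bins
  perm_t <- sample(length(data$times))
  data3 <- data
  data3$times <- data$times[perm_t]
  data3$counts <- data$counts[perm_t, ]
  expect_equal(infil_objective(data3, spec, truth),
               infil_objective(data, spec, truth), tolerance = 1e-9)
  expect_gte(infil_objective(data2, spec, truth), 0)
  expect_error(infil_objective(data, spec, c(10, 0.5)), "outside")
})

test_that("the objective is nearly invariant along the zeta * rho_tilde ridge", {
  ds <- small_design(noise = "none")
  exp_c <- design_expected_counts(ds, "DP47")
  data <- list(times = exp_c$times, bin_edges_um = exp_c$bin_edges_um,
               counts = exp_c$expected)
  class(data) <- "binned_counts"
  spec <- fit_spec(free = list(rho_tilde = list(lower = 1, upper = 1000,
                                                log10 = TRUE),
                               zeta = list(lower = 0.01, upper = 3)),
                   fixed = ds$params_control,
                   roi_length_um = ds$roi_length_um,
                   n_cells = ds$n_cells, output_times = ds$times)
  rt <- ds$params_control$rho_tilde
  zt <- ds$params_control$zeta
  cs <- c(0.5, 0.75, 1.5, 2)
  along <- vapply(cs, function(cc)
    infil_objective(data, spec, c(log10(cc * rt), zt / cc)), 0)
  across <- vapply(cs, function(cc)
    infil_objective(data, spec, c(log10(rt), zt / cc)), 0)
  expect_gt(mean(abs(across)) / mean(abs(along)), 5)
})

test_that("failed simulations yield a finite penalty instead of an error", {
  ds <- small_design(noise = "none")
  exp_c <- design_expected_counts(ds, "DP47")
  data <- list(times = c(exp_c$times, 1e6), bin_edges_um = exp_c$bin_edges_um,
               counts = rbind(round(exp_c$expected), 0))
  class(data) <- "binned_counts"
  # the data demand a time the simulation never reaches: prediction fails,
  # and the optimiser must receive the documented finite penalty
  spec <- fit_spec(free = list(zeta = list(lower = 0.01, upper = 1)),
                   fixed = ds$params_control,
                   roi_length_um = ds$roi_length_um,
                   n_cells = ds$n_cells, output_times = ds$times)
  val <- infil_objective(data, spec, 0.5)
  expect_true(is.finite(val))
  expect_true(isTRUE(attr(val, "failed")))
  expect_equal(as.numeric(val), 1000 * sum(as.numeric(data$counts)^2))
})
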