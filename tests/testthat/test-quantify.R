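make_table <- function(x_um, area_um2, time_h = 48, id = "e1",
                       condition = "DP47") {
  data.frame(experiment_id = id, condition = condition, time_h = time_h,
             x_um = x_um, area_um2 = area_um2)
}

test_that("declumping follows the 50 um^2 threshold rule", {
  # worked boundary cases: below threshold, just under/over the 1.5x
  # boundary, and multi-cell clumps
  expect_identical(declump(c(30, 74, 76, 120, 130)), c(1L, 1L, 2L, 2L, 3L))
  # the exact 75 tie rounds up, making "above 75 is more than one cell" tight
  expect_identical(declump(75), 2L)
  # scale consistency and monotonicity
  expect_identical(declump(50 * (1:8)), 1:8)
  areas <- sort(stats::runif(200, 1, 500))
  expect_true(all(diff(declump(areas)) >= 0))
  expect_error(declump(0), "> 0")
})

test_that("bin counting composes declumping with half-open spatial bins", {
  tb <- make_table(c(10, 20, 30), c(40, 40, 40))
  bc <- bin_counts(tb, roi_length_um = 1000, n_bins = 20)
  expect_equal(bc$counts[1, ], c(3L, rep(0L, 19)), ignore_attr = TRUE)
  # a 120 um^2 clump counts as 2 cells in its bin
  bc2 <- bin_counts(make_table(225, 120), 1000, 20)
  expect_equal(unname(bc2$counts[1, 5]), 2L)
  # edge conventions: a particle exactly on an interior edge goes right,
  # the ROI end stays in the last bin
  bc3 <- bin_counts(make_table(c(50, 1000), c(40, 40)), 1000, 20)
  expect_equal(unname(bc3$counts[1, 2]), 1L)
  expect_equal(unname(bc3$counts[1, 20]), 1L)
  expect_error(bin_counts(make_table(1200, 40), 1000, 20), "outside the ROI")
})

test_that("bin totals conserve declumped counts regardless of binning", {
  set.seed(31)
  tb <- make_table(stats::runif(300, 0, 1000), stats::rlnorm(300, log(60), 0.6),
                   time_h = rep(c(12, 24), each = 150))
  brute <- vapply(c(12, 24), function(t)
    sum(declump(tb$area_um2[tb$time_h == t])), 0L)
  for (nb in c(1, 7, 20, 50)) {
    bc <- bin_counts(tb, 1000, nb)
    expect_identical(unname(rowSums(bc$counts)), as.numeric(brute))
    expect_identical(bc$totals, as.integer(brute))
  }
  # permutation invariance and additivity over concatenation (the split
  # keeps both imaging times in each part so the time grids align)
  perm <- tb[sample(nrow(tb)), ]
  expect_equal(bin_counts(perm, 1000, 20)$counts, bin_counts(tb, 1000, 20)$counts)
  odd <- seq(1, nrow(tb), by = 2)
  c1 <- bin_counts(tb[odd, ], 1000, 20)$counts
  c2 <- bin_counts(tb[-odd, ], 1000, 20)$counts
  expect_equal(c1 + c2, bin_counts(tb, 1000, 20)$counts,
               ignore_attr = TRUE)
})

test_that("binned counts round-trip through the CSV dialect", {
  set.seed(5)
  tb <- make_table(stats::runif(50, 0, 800), stats::runif(50, 20, 200))
  bc <- bin_counts(tb, 800, 16)
  path <- withr::local_tempfile(fileext = ".csv")
  write_binned_counts(bc, path)
  rt <- read_binned_counts(path)
  expect_equal(rt$counts, bc$counts, ignore_attr = TRUE)
  expect_equal(rt$bin_edges_um, bc$bin_edges_um)
  expect_equal(rt$times, bc$times)
})

test_that("infiltration summaries report per-condition totals and distances", {
  # five singleton cells at 100 um: total 5, mean distance 100
  tb <- make_table(rep(100, 5), rep(40, 5))
  sm <- summarize_infiltration(tb, 48)
  expect_equal(sm$mean_total_cells, 5)
  expect_equal(sm$mean_distance_um, 100)
  # two experiments with totals 4 and 6 average to 5
  tb2 <- rbind(make_table(rep(50, 4), rep(40, 4), id = "a"),
               make_table(rep(150, 6), rep(40, 6), id = "b"))
  sm2 <- summarize_infiltration(tb2, 48)
  expect_equal(sm2$mean_total_cells, 5)
  # distances weight clumps by their declumped count
  tb3 <- make_table(c(0, 300), c(40, 120))   # 1 cell at 0, 2 cells at 300
  expect_equal(summarize_infiltration(tb3, 48)$mean_distance_um, 200)
  expect_error(summarize_infiltration(tb, 24), "not present")
  # a condition with no particles at the summary time is flagged, not fatal
  tb4 <- rbind(tb, make_table(10, 40, time_h = 24, condition = "D66-ESK"))
  expect_warning(sm4 <- summarize_infiltration(tb4, 48), "undefined")
  expect_true(is.na(sm4$mean_total_cells[sm4$condition == "D66-ESK"]))
})

test_that("summaries recover the generator's expected totals (Monte Carlo)", {
  ds <- small_design()
  exp_c <- design_expected_counts(ds, "DP47")
  lam_tot <- sum(exp_c$expected[exp_c$times == 24, ])
  # oracle for the clump-declump correction: brute-force expectation of
  # declumped counts under the generator's area/merge model
  set.seed(99)
  n_mc <- 2e4
  a1 <- stats::rlnorm(n_mc, ds$area_meanlog, ds$area_sdlog)
  a2 <- stats::rlnorm(n_mc, ds$area_meanlog, ds$area_sdlog)
  p_m <- ds$clump_prob
  # a cell is merged with a partner with prob ~p_m (ignoring rare chains);
  # a merged pair contributes declump(a1+a2) cells instead of 2
  e_single <- mean(declump(a1))
  e_pair <- mean(declump(a1 + a2))
  factor <- (1 - 2 * p_m) * e_single + p_m * e_pair
  reps <- 200
  seeds <- infilsim:::derive_seeds(7202, reps)
  totals <- vapply(seeds, function(s) {
    tb <- generate_experiment(ds, "DP47", s, expected = exp_c)
    sum(declump(tb$area_um2[tb$time_h == 24]))
  }, 0)
  expected_total <- lam_tot * factor
  se <- stats::sd(totals) / sqrt(reps)
  expect_lt(abs(mean(totals) - expected_total), 3 * se + 0.02 * expected_total)
})
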