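test_that("simulated datasets have the right support and moments", {
  # truth at zero is reproduced exactly
  d0 <- simulate_dataset(0, 0.5, 50, 50, reps = 100, seed = 1)
  expect_true(all(d0$p_x_hat == 0))
  # mean of p_x_hat matches P_x within a 3-sigma CLT band at 1e5 draws
  reps <- 1e5
  d <- simulate_dataset(0.3, 0.6, 40, 25, reps = reps, seed = 2)
  expect_lt(abs(mean(d$p_x_hat) - 0.3), 3 * sqrt(0.3 * 0.7 / (40 * reps)))
  expect_lt(abs(mean(d$p_y_hat) - 0.6), 3 * sqrt(0.6 * 0.4 / (25 * reps)))
  # seeded reproducibility
  expect_identical(simulate_dataset(0.3, 0.6, 40, 25, reps = 10, seed = 9),
                   simulate_dataset(0.3, 0.6, 40, 25, reps = 10, seed = 9))
})

test_that("continuous readiness draws a Beta score with the configured spread", {
  reps <- 2e4
  d <- simulate_dataset(0.4, 0.7, 50, 30, reps = reps,
                        readiness_kind = "continuous", seed = 3)
  expect_true(all(d$p_y_hat > 0 & d$p_y_hat < 1))
  expect_lt(abs(mean(d$p_y_hat) - 0.7), 0.005)
  # per-dataset score variance concentrates near 0.5 * P_y * (1 - P_y)
  expect_equal(mean(d$y_var_hat), 0.5 * 0.7 * 0.3, tolerance = 0.02)
})

test_that("per-setting accounting identities hold and invalid counting is exact-only", {
  res <- run_setting(0.1, 0.1, 50, 50, reps = 2000, B = 300, seed = 4)
  expect_setequal(res$method, c("exact", "delta", "bootstrap"))
  # removed + contributing = total for every method
  expect_true(all(res$n_removed >= 0 & res$n_removed <= res$n_total))
  expect_true(all(res$n_total == 2000))
  expect_true(is.na(res$n_invalid[res$method == "delta"]))
  expect_true(is.na(res$n_invalid[res$method == "bootstrap"]))
  expect_false(is.na(res$n_invalid[res$method == "exact"]))
  # delta removes more than exact here: undefined covers p_rf = 0 and full cells
  expect_gte(res$n_removed[res$method == "delta"],
             res$n_removed[res$method == "exact"])
  expect_true(all(res$coverage_probability >= 0 & res$coverage_probability <= 1))
})

test_that("all methods reach nominal coverage at central parameters and large n", {
  res <- run_setting(0.5, 0.5, 500, 500, reps = 2000, B = 1000, seed = 5)
  # Monte-Carlo 3-sigma at 2000 reps is about 0.015
  expect_true(all(abs(res$coverage_probability - 0.95) < 0.02))
  expect_true(all(res$n_removed == 0))
})

test_that("the boundary setting reproduces conditional overcoverage and invalidity", {
  res <- run_setting(0.02, 0.02, 50, 50, methods = "exact", reps = 4000, seed = 6)
  contributing <- res$n_total - res$n_removed
  # all non-degenerate intervals contain the truth and essentially all are
  # invalid (lower bound below zero)
  expect_equal(res$coverage_probability, 1)
  expect_gt(res$n_invalid / contributing, 0.99)
  # most iterations are degenerate: 1 - (1 - (1-0.02)^50)^2 is about 0.6
  expect_gt(res$n_removed / res$n_total, 0.5)
})

test_that("grid runs are deterministic and their subsets reproduce full-run cells", {
  grid <- simulation_settings(c(0.1, 0.5), c(0.3, 0.9),
                              tibble::tibble(n_x = 50, n_y = 50))
  expect_equal(nrow(grid), 4)
  full1 <- run_grid(grid, methods = c("exact", "delta"), reps = 400, seed = 11)
  full2 <- run_grid(grid, methods = c("exact", "delta"), reps = 400, seed = 11)
  expect_identical(tibble::as_tibble(full1), tibble::as_tibble(full2))
  sub <- run_grid(grid[3, ], methods = c("exact", "delta"), reps = 400, seed = 11)
  expect_identical(
    tibble::as_tibble(sub),
    tibble::as_tibble(full1)[full1$P_x == grid$P_x[3] & full1$P_y == grid$P_y[3], ])
  # a single-setting grid equals run_setting with the derived substream seed
  key <- paste(grid$P_x[3], grid$P_y[3], 50, 50, "binary", sep = "_")
  direct <- run_setting(grid$P_x[3], grid$P_y[3], 50, 50,
                        methods = c("exact", "delta"), reps = 400,
                        seed = effcov:::ec_substream_seed(11, key))
  expect_equal(tibble::as_tibble(sub), tibble::as_tibble(direct))
})

test_that("the default study grid has the published dimensions", {
  expect_length(sim_proportion_grid(), 25)
  expect_equal(nrow(sim_size_pairs()), 11)
  full <- simulation_settings()
  expect_equal(nrow(full), 25 * 25 * 11)
})

test_that("grid summaries expose per-method extrema", {
  grid <- simulation_settings(c(0.05, 0.5), 0.5,
                              tibble::tibble(n_x = 50, n_y = 50))
  res <- run_grid(grid, methods = c("exact", "delta"), reps = 500, seed = 21)
  s <- summarise_grid(res)
  expect_setequal(s$method, c("exact", "delta"))
  expect_true(all(s$max_coverage >= s$min_coverage))
  expect_true(is.na(s$max_invalid_fraction[s$method == "delta"]))
  expect_gte(s$max_invalid_fraction[s$method == "exact"], 0)
})

test_that("continuous-readiness settings run end to end", {
  res <- run_setting(0.3, 0.6, 100, 30, reps = 400, B = 200,
                     readiness_kind = "continuous", seed = 31)
  expect_true(all(res$coverage_probability > 0.8))
  expect_true(all(res$n_removed < 400))
})

test_that("coverage heatmap autoplot builds without error", {
  grid <- simulation_settings(c(0.3, 0.5), 0.5, tibble::tibble(n_x = 50, n_y = 50))
  res <- run_grid(grid, methods = "exact", reps = 200, seed = 41)
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
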