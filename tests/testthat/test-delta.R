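test_that("logit intercept and standard error come straight from the cells", {
  ls <- logit_stat(50, 100)
  expect_equal(ls$b, 0)
  expect_equal(ls$s_b, 0.2)
  ls2 <- logit_stat(1, 2)
  expect_equal(ls2$b, 0)
  expect_equal(ls2$s_b, sqrt(2))
  # antilogit of b recovers the sample proportion
  set.seed(5)
  for (i in 1:25) {
    n <- sample(2:400, 1)
    k <- sample(seq_len(n - 1), 1)
    ls <- logit_stat(k, n)
    expect_equal(antilogit(ls$b), k / n)
    expect_equal(ls$s_b, sqrt(1 / k + 1 / (n - k)))
  }
  # an empty or full cell leaves the logit undefined
  expect_false(logit_stat(0, 50)$defined)
  expect_false(logit_stat(50, 50)$defined)
  expect_true(is.na(logit_stat(0, 50)$b))
  expect_error(logit_stat(5, 3), class = "effcov_validation_error")
})

test_that("stratum gradient matches the chain-rule forms and finite differences", {
  g <- delta_gradient_stratum(0.5, 0.5)
  expect_equal(g$g_x, 2/3)
  expect_equal(g$g_y, 2/3)
  # limit p_y -> 1: gradient w.r.t. b_x tends to 1
  expect_equal(delta_gradient_stratum(0.3, 1 - 1e-9)$g_x, 1, tolerance = 1e-6)
  # symmetry under swapping the two arms
  g_ab <- delta_gradient_stratum(0.22, 0.71)
  g_ba <- delta_gradient_stratum(0.71, 0.22)
  expect_equal(g_ab$g_x, g_ba$g_y)
  expect_equal(g_ab$g_y, g_ba$g_x)
  # central finite differences of logit(antilogit(b_x) antilogit(b_y))
  set.seed(7)
  for (i in 1:100) {
    p <- runif(2, 0.05, 0.95)
    b <- logit(p)
    g <- delta_gradient_stratum(p[1], p[2])
    expect_equal(g$g_x, finite_diff(logit_of_product, b, 1), tolerance = 1e-5)
    expect_equal(g$g_y, finite_diff(logit_of_product, b, 2), tolerance = 1e-5)
  }
  expect_error(delta_gradient_stratum(0, 0.5), class = "effcov_validation_error")
})

test_that("stratum delta variance composes gradients and logit standard errors", {
  # p_x = p_y = 0.5 at n = 100 each: (2/3)^2 * 0.04 * 2
  v <- delta_variance(tibble::tibble(
    region_id = "r", facility_type = "f", x_successes = 50, n_x = 100,
    readiness_kind = "binary", y_successes = 50, n_y = 100,
    y_mean = NA_real_, y_var = NA_real_, region_weight = 1), "stratum")
  expect_equal(v$var_F, 2 * (2/3)^2 * 0.04, tolerance = 1e-12)
  expect_true(v$defined)
  # a full coverage cell makes the interval undefined
  v2 <- delta_variance(tibble::tibble(
    region_id = "r", facility_type = "f", x_successes = 100, n_x = 100,
    readiness_kind = "binary", y_successes = 50, n_y = 100,
    y_mean = NA_real_, y_var = NA_real_, region_weight = 1), "stratum")
  expect_false(v2$defined)
  expect_true(is.na(v2$var_F))
})

test_that("level variances agree with finite-difference gradients on random tables", {
  # For each random table, Var(F) from the analytic per-stratum gradients is
  # compared with sum_i (dF/db_i)^2 s_i^2 where dF/db_i comes from central
  # finite differences of the full level map b -> logit(level estimate).
  set.seed(101)
  for (rep in 1:100) {
    n_r <- sample(1:3, 1); n_f <- sample(1:3, 1)
    grid <- tidyr::crossing(region_id = sprintf("r%d", 1:n_r),
                            facility_type = sprintf("f%d", 1:n_f))
    n_x <- 200; n_y <- 80
    tab <- dplyr::mutate(grid,
      x_successes = sample(5:round(0.9 * n_x / n_f), dplyr::n()),
      n_x = n_x, readiness_kind = "binary",
      y_successes = sample(5:(n_y - 5), dplyr::n(), replace = TRUE), n_y = n_y,
      y_mean = NA_real_, y_var = NA_real_)
    w_r <- runif(n_r, 0.5, 2)
    tab$region_weight <- w_r[as.integer(factor(tab$region_id))]
    w_tab <- dplyr::distinct(tab, region_id, region_weight)
    w <- setNames(w_tab$region_weight / sum(w_tab$region_weight), w_tab$region_id)

    b_x <- logit(tab$x_successes / tab$n_x)
    b_y <- logit(tab$y_successes / tab$n_y)
    s2 <- c(1 / tab$x_successes + 1 / (tab$n_x - tab$x_successes),
            1 / tab$y_successes + 1 / (tab$n_y - tab$y_successes))

    for (lv in c("region", "national")) {
      dv <- delta_variance(tab, lv)
      if (lv == "region") {
        for (r in unique(tab$region_id)) {
          idx <- which(tab$region_id == r)
          f_level <- function(b) {
            m <- length(b) / 2
            logit(sum(antilogit(b[1:m]) * antilogit(b[(m + 1):(2 * m)])))
          }
          b0 <- c(b_x[idx], b_y[idx])
          g_fd <- sapply(seq_along(b0), function(i) finite_diff(f_level, b0, i))
          v_fd <- sum(g_fd^2 * c(s2[idx], s2[nrow(tab) + idx]))
          expect_equal(dv$var_F[dv$region_id == r], v_fd, tolerance = 1e-5)
        }
      } else {
        f_nat <- function(b) {
          m <- length(b) / 2
          logit(sum(w[tab$region_id] * antilogit(b[1:m]) * antilogit(b[(m + 1):(2 * m)])))
        }
        b0 <- c(b_x, b_y)
        g_fd <- sapply(seq_along(b0), function(i) finite_diff(f_nat, b0, i))
        expect_equal(dv$var_F, sum(g_fd^2 * s2), tolerance = 1e-5)
      }
    }
  }
})

test_that("continuous-score delta variance matches arithmetic and finite differences", {
  # (2/3)^2 * 0.04 + (8/3)^2 * 0.01/25
  expect_equal(delta_variance_continuous(50, 100, 0.5, 0.01, 25),
               (2/3)^2 * 0.04 + (8/3)^2 * 4e-4, tolerance = 1e-12)
  # y_var = 0 leaves only the coverage term
  expect_equal(delta_variance_continuous(50, 100, 0.5, 0, 25), (2/3)^2 * 0.04)
  # gradient of ybar -> logit(p_x * ybar) checked at random interior points
  set.seed(33)
  for (i in 1:20) {
    p_x <- runif(1, 0.1, 0.9)
    ybar <- runif(1, 0.1, 0.9)
    y_var <- runif(1, 0.001, 0.04)
    n_x <- 200; x <- round(p_x * n_x); p_x <- x / n_x
    f_y <- function(y) logit(p_x * y[1])
    g_fd <- finite_diff(f_y, ybar, 1)
    p <- p_x * ybar
    expect_equal(p_x / (p * (1 - p)), g_fd, tolerance = 1e-5)
    v_expected <- ((1 - p_x) / (1 - p))^2 * (1 / x + 1 / (n_x - x)) +
      g_fd^2 * y_var / 25
    expect_equal(delta_variance_continuous(x, n_x, ybar, y_var, 25),
                 v_expected, tolerance = 1e-5)
  }
  # boundary inputs are undefined
  expect_true(is.na(delta_variance_continuous(0, 100, 0.5, 0.01, 25)))
  expect_true(is.na(delta_variance_continuous(100, 100, 0.5, 0.01, 25)))
  expect_true(is.na(delta_variance_continuous(50, 100, 1, 0, 25)))
})

test_that("back-transformed interval is inside (0,1), asymmetric, and frozen values hold", {
  ci <- delta_ci(0, 0.04)
  expect_equal(c(ci$lower, ci$upper), antilogit(c(-1, 1) * 1.96 * 0.2))
  expect_equal(round(c(ci$lower, ci$upper), 5), c(0.40324, 0.59676))
  expect_equal(delta_ci(1.2, 0)[, c("lower", "upper")],
               tibble::tibble(lower = antilogit(1.2), upper = antilogit(1.2)))
  set.seed(9)
  Fv <- rnorm(200, 0, 3)
  vv <- runif(200, 0, 4)
  cis <- delta_ci(Fv, vv)
  expect_true(all(cis$lower > 0 & cis$upper < 1))
  expect_true(all(cis$lower <= cis$upper))
  expect_true(all(cis$status == "valid"))
  # undefined upstream logit propagates
  expect_equal(delta_ci(NA_real_, NA_real_)$status, "undefined")
})

test_that("delta and exact endpoints agree at large n away from boundaries", {
  # both are first-order intervals; at n = 1e5 they must agree to 1e-3
  n <- 1e5
  for (p in list(c(0.3, 0.6), c(0.5, 0.5), c(0.7, 0.2))) {
    x <- round(p[1] * n); y <- round(p[2] * n)
    tab <- tibble::tibble(region_id = "r", facility_type = "f",
                          x_successes = x, n_x = n, readiness_kind = "binary",
                          y_successes = y, n_y = n, y_mean = NA_real_,
                          y_var = NA_real_, region_weight = 1)
    dv <- delta_variance(tab, "stratum")
    d_ci <- delta_ci(dv$F, dv$var_F)
    e_ci <- exact_ci(dv$point, exact_variance_stratum(x / n, n, y / n, n))
    expect_equal(d_ci$lower, e_ci$lower, tolerance = 1e-3)
    expect_equal(d_ci$upper, e_ci$upper, tolerance = 1e-3)
  }
})

test_that("design-based standard-error overrides replace the closed form", {
  tab <- tibble::tibble(region_id = "r", facility_type = "f",
                        x_successes = 50, n_x = 100, readiness_kind = "binary",
                        y_successes = 50, n_y = 100, y_mean = NA_real_,
                        y_var = NA_real_, region_weight = 1,
                        s_bx = 0.3, s_by = 0.1)
  v <- delta_variance(tab, "stratum")
  expect_equal(v$var_F, (2/3)^2 * 0.09 + (2/3)^2 * 0.01)
})
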