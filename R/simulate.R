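#' Default simulation grids
#'
#' `sim_proportion_grid()` returns the 25-point grid of true proportions used
#' by the coverage-probability study (0.02 to 0.98, dense near the
#' boundaries); `sim_size_pairs()` returns the 11 (individual, facility)
#' sample-size pairs, covering equal sizes 50-500 and unequal pairs with the
#' facility sample fixed at 50.
#'
#' @return A numeric vector (`sim_proportion_grid`) or a tibble with columns
#'   `n_x`, `n_y` (`sim_size_pairs`).
#' @export
sim_proportion_grid <- function() {
  c(0.02, 0.04, 0.06, 0.08, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35, 0.40, 0.45,
    0.50, 0.55, 0.60, 0.65, 0.70, 0.75, 0.80, 0.85, 0.90, 0.92, 0.94, 0.96,
    0.98)
}

#' @rdname sim_proportion_grid
#' @export
sim_size_pairs <- function() {
  tibble::tibble(
    n_x = c(50, 100, 200, 300, 400, 500, 100, 200, 300, 400, 500),
    n_y = c(50, 100, 200, 300, 400, 500, 50, 50, 50, 50, 50)
  )
}

#' Build a table of simulation settings
#'
#' Crosses grids of true coverage and readiness proportions with sample-size
#' pairs into one row per simulation setting.
#'
#' @param p_x_grid,p_y_grid Numeric vectors of true proportions in \[0, 1\].
#' @param size_pairs A data frame with columns `n_x`, `n_y`.
#' @param readiness_kind `"binary"` or `"continuous"` (continuous draws
#'   readiness scores from a Beta law with mean `P_y`).
#' @return A tibble with columns `P_x`, `P_y`, `n_x`, `n_y`,
#'   `readiness_kind`.
#' @examples
#' simulation_settings(c(0.1, 0.5), c(0.5), tibble::tibble(n_x = 50, n_y = 50))
#' @export
simulation_settings <- function(p_x_grid = sim_proportion_grid(),
                                p_y_grid = sim_proportion_grid(),
                                size_pairs = sim_size_pairs(),
                                readiness_kind = "binary") {
  ec_check_prop(p_x_grid, "p_x_grid"); ec_check_prop(p_y_grid, "p_y_grid")
  stopifnot(readiness_kind %in% c("binary", "continuous"))
  tidyr::crossing(P_x = p_x_grid, P_y = p_y_grid,
                  tibble::as_tibble(size_pairs)) |>
    dplyr::mutate(readiness_kind = readiness_kind) |>
    dplyr::select(P_x, P_y, n_x, n_y, readiness_kind)
}

#' Simulate paired coverage/readiness samples for one setting
#'
#' Draws `reps` independent datasets under simple random sampling: coverage
#' `x ~ Binomial(n_x, P_x)` and, for binary readiness,
#' `y ~ Binomial(n_y, P_y)`. For continuous readiness each dataset is the
#' mean and sample variance of `n_y` scores drawn from `Beta(P_y, 1 - P_y)`,
#' which has mean `P_y` and variance `0.5 * P_y * (1 - P_y)` — a dispersed
#' but boundary-free score law.
#'
#' @param P_x,P_y True coverage and readiness parameters in \[0, 1\].
#' @param n_x,n_y Sample sizes.
#' @param reps Number of datasets to draw.
#' @param readiness_kind `"binary"` or `"continuous"`.
#' @param seed Optional integer seed.
#' @return A tibble with one row per dataset: `x_successes`, `p_x_hat`, and
#'   either `y_successes`, `p_y_hat` (binary) or `p_y_hat`, `y_var_hat`
#'   (continuous).
#' @examples
#' simulate_dataset(0.5, 0.5, 50, 50, reps = 3, seed = 1)
#' @export
simulate_dataset <- function(P_x, P_y, n_x, n_y, reps = 1,
                             readiness_kind = "binary", seed = NULL) {
  ec_check_prop(P_x, "P_x"); ec_check_prop(P_y, "P_y")
  ec_check_count(n_x, "n_x"); ec_check_count(n_y, "n_y")
  ec_check_count(reps, "reps")
  if (!is.null(seed)) set.seed(seed)
  x <- rbinom(reps, n_x, P_x)
  if (readiness_kind == "binary") {
    y <- rbinom(reps, n_y, P_y)
    tibble::tibble(x_successes = x, p_x_hat = x / n_x,
                   y_successes = y, p_y_hat = y / n_y)
  } else {
    if (P_y %in% c(0, 1)) {
      ymat <- matrix(P_y, nrow = reps, ncol = n_y)
    } else {
      ymat <- matrix(rbeta(reps * n_y, P_y, 1 - P_y), nrow = reps)
    }
    tibble::tibble(x_successes = x, p_x_hat = x / n_x,
                   p_y_hat = rowMeans(ymat),
                   y_var_hat = apply(ymat, 1, var))
  }
}

## Row-wise percentile interval of a reps x B matrix (type-7 quantiles).
ec_row_percentiles <- function(m, probs) {
  t(apply(m, 1, quantile, probs = probs, names = FALSE, type = 7))
}

#' Run the coverage-probability simulation for one setting
#'
#' For `reps` simulated datasets, builds the nominally 95% interval for the
#' stratum effective coverage by each requested method and estimates each
#' method's coverage probability — the fraction of intervals containing the
#' true product `P_x * P_y`. Accounting follows the method-specific removal
#' rules: the exact and bootstrap methods drop iterations with a degenerate
#' interval (point estimate exactly 0 or 1); the delta method drops
#' iterations whose interval is undefined (product estimate 0, or either
#' sample proportion equal to 1). Exact-method intervals with a bound
#' outside \[0, 1\] are *invalid* but non-degenerate: they still contribute
#' to the coverage count and are tallied in `n_invalid`.
#'
#' @inheritParams simulate_dataset
#' @param methods Subset of `c("exact", "delta", "bootstrap")`.
#' @param reps Number of simulated datasets (the study default is 10000).
#' @param B Bootstrap resamples per iteration (the study default is 10000;
#'   reduce for exploratory runs).
#' @param conf_level Nominal two-sided level (default 0.95, z = 1.96).
#' @param seed Optional integer seed making the run deterministic.
#' @return A tibble with one row per method: `method`,
#'   `coverage_probability` (over contributing iterations; `NaN` if none),
#'   `n_total`, `n_removed`, `n_invalid` (exact only, else `NA`),
#'   `mean_interval_width`, and `no_information` (`TRUE` when every
#'   iteration was removed).
#' @examples
#' run_setting(0.5, 0.5, 50, 50, methods = "exact", reps = 200, seed = 1)
#' @export
run_setting <- function(P_x, P_y, n_x, n_y,
                        methods = c("exact", "delta", "bootstrap"),
                        reps = 10000, B = 10000,
                        readiness_kind = "binary",
                        conf_level = 0.95, seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  z <- ec_zvalue(conf_level)
  truth <- P_x * P_y
  sims <- simulate_dataset(P_x, P_y, n_x, n_y, reps = reps,
                           readiness_kind = readiness_kind, seed = seed)
  px <- sims$p_x_hat
  py <- sims$p_y_hat
  point <- px * py
  binary <- readiness_kind == "binary"

  res <- list()
  if ("exact" %in% methods) {
    v <- if (binary) {
      exact_variance_stratum(px, n_x, py, n_y)
    } else {
      exact_variance_continuous(px, n_x, py, sims$y_var_hat, n_y)
    }
    lo <- point - z * sqrt(v)
    hi <- point + z * sqrt(v)
    keep <- !(point == 0 | point == 1)
    covered <- keep & lo <= truth & truth <= hi
    res$exact <- tibble::tibble(
      method = "exact",
      coverage_probability = sum(covered) / sum(keep),
      n_total = reps, n_removed = sum(!keep),
      n_invalid = sum(keep & (lo < 0 | hi > 1)),
      mean_interval_width = mean((hi - lo)[keep])
    )
  }
  if ("delta" %in% methods) {
    vF <- if (binary) {
      ec_delta_var_stratum_counts(sims$x_successes, n_x, sims$y_successes, n_y)
    } else {
      delta_variance_continuous(sims$x_successes, n_x, py, sims$y_var_hat, n_y)
    }
    keep <- !is.na(vF)
    Fhat <- logit(pmin(pmax(point, 1e-300), 1 - 1e-16))
    lo <- antilogit(Fhat - z * sqrt(vF))
    hi <- antilogit(Fhat + z * sqrt(vF))
    covered <- keep & !is.na(lo) & lo <= truth & truth <= hi
    res$delta <- tibble::tibble(
      method = "delta",
      coverage_probability = sum(covered) / sum(keep),
      n_total = reps, n_removed = sum(!keep), n_invalid = NA_integer_,
      mean_interval_width = mean((hi - lo)[keep])
    )
  }
  if ("bootstrap" %in% methods) {
    keep <- !(point == 0 | point == 1)
    m <- sum(keep)
    if (m > 0) {
      xb <- matrix(rbinom(m * B, n_x, rep(px[keep], times = B)) / n_x,
                   nrow = m)
      if (binary) {
        yb <- matrix(rbinom(m * B, n_y, rep(py[keep], times = B)) / n_y,
                     nrow = m)
      } else {
        mu <- py[keep]
        vv <- pmin(sims$y_var_hat[keep], 0.999 * mu * (1 - mu))
        nu <- mu * (1 - mu) / vv - 1
        idx <- which(keep)
        yb <- matrix(0, nrow = m, ncol = B)
        for (i in seq_len(m)) {
          yb[i, ] <- colMeans(matrix(rbeta(B * n_y, mu[i] * nu[i],
                                           (1 - mu[i]) * nu[i]), nrow = n_y))
        }
      }
      qs <- ec_row_percentiles(xb * yb, probs = c((1 - conf_level) / 2,
                                                  1 - (1 - conf_level) / 2))
      covered <- qs[, 1] <= truth & truth <= qs[, 2]
      cov_p <- sum(covered) / m
      width <- mean(qs[, 2] - qs[, 1])
    } else {
      cov_p <- NaN
      width <- NaN
    }
    res$bootstrap <- tibble::tibble(
      method = "bootstrap", coverage_probability = cov_p,
      n_total = reps, n_removed = reps - m, n_invalid = NA_integer_,
      mean_interval_width = width
    )
  }
  out <- dplyr::bind_rows(res)
  out$no_information <- out$n_removed == out$n_total
  if (all(out$no_information)) {
    warn("every iteration was removed for every method (no-information setting)")
  }
  dplyr::bind_cols(
    tibble::tibble(P_x = P_x, P_y = P_y, n_x = n_x, n_y = n_y,
                   readiness_kind = readiness_kind)[rep(1, nrow(out)), ],
    out
  )
}

#' Run the simulation over a grid of settings
#'
#' Applies [run_setting()] to every row of a settings table. Each setting
#' gets its own RNG substream derived deterministically from `seed` and the
#' setting's parameters, so any subset of the grid reproduces the
#' corresponding cells of a full run.
#'
#' @param settings A settings tibble from [simulation_settings()].
#' @inheritParams run_setting
#' @param seed Master integer seed.
#' @return A tibble of class `"effcov_simulation"` with one row per
#'   setting x method (columns as in [run_setting()]).
#' @examples
#' grid <- simulation_settings(c(0.3, 0.5), 0.5, tibble::tibble(n_x = 50, n_y = 50))
#' run_grid(grid, methods = "exact", reps = 200, seed = 1)
#' @export
run_grid <- function(settings, methods = c("exact", "delta", "bootstrap"),
                     reps = 10000, B = 10000, conf_level = 0.95, seed = 1) {
  stopifnot(nrow(settings) >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  out <- purrr::pmap(
    settings[, c("P_x", "P_y", "n_x", "n_y", "readiness_kind")],
    function(P_x, P_y, n_x, n_y, readiness_kind) {
      key <- paste(P_x, P_y, n_x, n_y, readiness_kind, sep = "_")
      run_setting(P_x, P_y, n_x, n_y, methods = methods, reps = reps, B = B,
                  readiness_kind = readiness_kind, conf_level = conf_level,
                  seed = ec_substream_seed(seed, key))
    }
  ) |> dplyr::bind_rows()
  class(out) <- c("effcov_simulation", class(out))
  out
}

#' Per-method extrema of a simulation grid
#'
#' Summarises a [run_grid()] result into per-method extrema: the maximum and
#' minimum estimated coverage probability over the grid and, for the exact
#' method, the maximum fraction of invalid intervals among non-degenerate
#' iterations.
#'
#' @param results A tibble from [run_grid()].
#' @return A tibble with columns `method`, `max_coverage`, `min_coverage`,
#'   `max_invalid_fraction`.
#' @export
summarise_grid <- function(results) {
  results |>
    dplyr::group_by(method) |>
    dplyr::summarise(
      max_coverage = max(coverage_probability, na.rm = TRUE),
      min_coverage = min(coverage_probability, na.rm = TRUE),
      max_invalid_fraction = if (all(is.na(n_invalid))) NA_real_ else {
        max(n_invalid / (n_total - n_removed), na.rm = TRUE)
      },
      .groups = "drop"
    )
}

#' Heatmap of estimated coverage probabilities over a simulation grid
#'
#' @param object A `"effcov_simulation"` tibble from [run_grid()].
#' @param ... Unused.
#' @return A ggplot: tiles over the (true coverage, true readiness) grid
#'   filled by estimated coverage probability, faceted by method and sample
#'   sizes.
#' @export
autoplot.effcov_simulation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(P_x), y = factor(P_y),
                                       fill = coverage_probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0.5, 1), oob = scales_squish) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(paste0("n=(", n_x, ",", n_y, ")")),
      cols = ggplot2::vars(method)) +
    ggplot2::labs(x = "true coverage P_x", y = "true readiness P_y",
                  fill = "coverage\nprobability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

## minimal squish so scales is not a hard dependency
scales_squish <- function(x, range = c(0, 1)) pmin(pmax(x, range[1]), range[2])
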