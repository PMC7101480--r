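#' Bootstrap configuration
#'
#' Settings for the parametric percentile bootstrap: number of resamples `B`
#' (default 10000), RNG seed, and the percentile pair. Percentiles are
#' evaluated with the linear-interpolation quantile rule
#' ([stats::quantile()] type 7); at `B = 10000` the choice of rule moves the
#' endpoints by well under 1e-3.
#'
#' @param B Number of bootstrap resamples, at least 100.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param percentiles Lower and upper percentile bounds (default 2.5, 97.5).
#' @param quantile_type Quantile rule passed to [stats::quantile()].
#' @return A list of class `"boot_config"`.
#' @export
boot_config <- function(B = 10000, seed = NULL, percentiles = c(2.5, 97.5),
                        quantile_type = 7) {
  if (B < 100) ec_abort_validation("B must be at least 100")
  if (length(percentiles) != 2 || percentiles[1] <= 0 ||
      percentiles[2] >= 100 || percentiles[1] >= percentiles[2]) {
    ec_abort_validation("percentiles must satisfy 0 < lower < upper < 100")
  }
  structure(list(B = as.integer(B), seed = seed, percentiles = percentiles,
                 quantile_type = quantile_type), class = "boot_config")
}

#' Parametric bootstrap percentile interval for a stratum
#'
#' Resamples the two independent estimators from their fitted binomial laws:
#' `B` draws of `Binomial(n_x, p_x)/n_x` and `Binomial(n_y, p_y)/n_y` are
#' multiplied elementwise and the percentile interval of the products is
#' returned. Bounds are always within \[0, 1\]; when the observed product is
#' exactly 0 or 1 every resample equals it and the interval is flagged
#' `degenerate`. Deterministic given `cfg$seed`.
#'
#' @param p_x,p_y Observed proportions in \[0, 1\].
#' @param n_x,n_y Sample sizes, at least 1.
#' @param cfg A [boot_config()].
#' @param conf_level Unused placeholder for interface symmetry; the interval
#'   level is set by `cfg$percentiles`.
#' @return A one-row tibble with `point`, `variance` (of the bootstrap
#'   products), `lower`, `upper`, `method` (`"bootstrap"`), `status`.
#' @examples
#' parametric_bootstrap_ci(0.5, 100, 0.5, 50, boot_config(B = 1000, seed = 1))
#' @export
parametric_bootstrap_ci <- function(p_x, n_x, p_y, n_y, cfg = boot_config(),
                                    conf_level = 0.95) {
  ec_check_prop(p_x, "p_x"); ec_check_prop(p_y, "p_y")
  ec_check_count(n_x, "n_x"); ec_check_count(n_y, "n_y")
  stopifnot(inherits(cfg, "boot_config"))
  point <- p_x * p_y
  if (point %in% c(0, 1)) {
    return(tibble::tibble(point = point, variance = 0, lower = point,
                          upper = point, method = "bootstrap",
                          status = "degenerate"))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pb <- (rbinom(cfg$B, n_x, p_x) / n_x) * (rbinom(cfg$B, n_y, p_y) / n_y)
  q <- quantile(pb, probs = cfg$percentiles / 100, names = FALSE,
                type = cfg$quantile_type)
  tibble::tibble(point = point, variance = var(pb), lower = q[1],
                 upper = q[2], method = "bootstrap", status = "valid")
}

## Moment-matched Beta parameters for a mean/variance pair on (0,1).
ec_beta_moments <- function(mean, variance) {
  if (variance >= mean * (1 - mean)) {
    ec_abort_validation("y_var must be below y_mean * (1 - y_mean) for a Beta law")
  }
  nu <- mean * (1 - mean) / variance - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Parametric bootstrap interval with a continuous readiness score
#'
#' The readiness arm is resampled from a Beta law with parameters matched to
#' the observed score mean and variance (support on \[0, 1\], the natural
#' choice for a bounded score): each replicate readiness value is the mean of
#' `n_y` independent Beta draws. The coverage arm is binomial as in
#' [parametric_bootstrap_ci()]. With `y_var = 0` the readiness replicates are
#' constant and the interval reflects coverage sampling error alone.
#'
#' @inheritParams parametric_bootstrap_ci
#' @param y_mean Readiness-score mean in \[0, 1\].
#' @param y_var Sample variance of the score; must be below
#'   `y_mean * (1 - y_mean)` for the Beta moment match (0 allowed).
#' @return A one-row tibble in the shared interval schema.
#' @export
parametric_bootstrap_ci_continuous <- function(p_x, n_x, y_mean, y_var, n_y,
                                               cfg = boot_config(),
                                               conf_level = 0.95) {
  ec_check_prop(p_x, "p_x"); ec_check_prop(y_mean, "y_mean")
  ec_check_count(n_x, "n_x"); ec_check_count(n_y, "n_y")
  if (y_var < 0) ec_abort_validation("y_var must be nonnegative")
  stopifnot(inherits(cfg, "boot_config"))
  point <- p_x * y_mean
  if (point %in% c(0, 1)) {
    return(tibble::tibble(point = point, variance = 0, lower = point,
                          upper = point, method = "bootstrap",
                          status = "degenerate"))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  x_boot <- rbinom(cfg$B, n_x, p_x) / n_x
  if (y_var == 0) {
    y_boot <- rep(y_mean, cfg$B)
  } else {
    ab <- ec_beta_moments(y_mean, y_var)
    y_boot <- rowMeans(matrix(rbeta(cfg$B * n_y, ab["alpha"], ab["beta"]),
                              nrow = cfg$B))
  }
  pb <- x_boot * y_boot
  q <- quantile(pb, probs = cfg$percentiles / 100, names = FALSE,
                type = cfg$quantile_type)
  tibble::tibble(point = point, variance = var(pb), lower = q[1],
                 upper = q[2], method = "bootstrap", status = "valid")
}
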