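#' Exact (Goodman) variance of a product of independent proportions
#'
#' For independent estimators the variance of a product satisfies
#' \deqn{Var(ZM) = (Var(Z) + E[Z]^2)(Var(M) + E[M]^2) - (E[Z]E[M])^2,}
#' an identity (not an approximation) due to Goodman. Plugging in the
#' binomial variance `p(1-p)/n` for each sample proportion gives the
#' estimated variance of the stratum effective coverage `p = p_x * p_y`:
#' \deqn{s^2 = [p_x(1-p_x)/n_x + p_x^2][p_y(1-p_y)/n_y + p_y^2] - p^2.}
#' The result is never negative, since each bracket is at least the squared
#' mean it accompanies.
#'
#' @param p_x,p_y Sample proportions in \[0, 1\] (vectorized).
#' @param n_x,n_y Sample sizes (or effective sample sizes) of the individual
#'   and facility samples, at least 1.
#' @return Estimated variance(s) of the product, nonnegative.
#' @examples
#' exact_variance_stratum(0.5, 50, 0.5, 50)  # 0.002525
#' exact_variance_stratum(1, 100, 0.3, 50)   # reduces to 0.3*0.7/50
#' @export
exact_variance_stratum <- function(p_x, n_x, p_y, n_y) {
  ec_check_prop(p_x, "p_x"); ec_check_prop(p_y, "p_y")
  ec_check_count(n_x, "n_x"); ec_check_count(n_y, "n_y")
  bx <- p_x * (1 - p_x) / n_x + p_x^2
  by <- p_y * (1 - p_y) / n_y + p_y^2
  pmax(bx * by - (p_x * p_y)^2, 0)
}

#' Exact variance with a continuous readiness score
#'
#' When readiness is a continuous score on \[0, 1\] summarised by a mean and
#' sample variance over `n_y` facilities, the readiness-mean variance
#' `y_var / n_y` replaces the binomial term in the Goodman identity:
#' \deqn{s^2 = [p_x(1-p_x)/n_x + p_x^2][y_var/n_y + \bar y^2] - (p_x \bar y)^2.}
#'
#' @inheritParams exact_variance_stratum
#' @param y_mean Readiness-score mean(s) in \[0, 1\].
#' @param y_var Sample variance(s) of the score, nonnegative.
#' @return Estimated variance(s), nonnegative.
#' @examples
#' exact_variance_continuous(0.5, 100, 0.8, 0.04, 25)
#' @export
exact_variance_continuous <- function(p_x, n_x, y_mean, y_var, n_y) {
  ec_check_prop(p_x, "p_x"); ec_check_prop(y_mean, "y_mean")
  ec_check_count(n_x, "n_x"); ec_check_count(n_y, "n_y")
  if (any(y_var < 0)) ec_abort_validation("y_var must be nonnegative")
  bx <- p_x * (1 - p_x) / n_x + p_x^2
  by <- y_var / n_y + y_mean^2
  pmax(bx * by - (p_x * y_mean)^2, 0)
}

## Per-stratum exact variance dispatched on readiness_kind; used by the
## region/national aggregators and the high-level estimator.
ec_exact_variance_rows <- function(data) {
  v <- numeric(nrow(data))
  bin <- data$readiness_kind == "binary"
  if (any(bin)) {
    v[bin] <- exact_variance_stratum(data$p_x[bin], data$n_x[bin],
                                     data$p_y[bin], data$n_y[bin])
  }
  if (any(!bin)) {
    v[!bin] <- exact_variance_continuous(data$p_x[!bin], data$n_x[!bin],
                                         data$y_mean[!bin], data$y_var[!bin],
                                         data$n_y[!bin])
  }
  v
}

#' Exact variance at region and national level
#'
#' Under the working assumption of zero covariance between strata, the
#' regional variance is the sum of the per-stratum Goodman variances, and the
#' national variance is the weight-squared sum over regions:
#' \deqn{s_r^2 = \sum_f s_{rf}^2, \qquad s^2 = \sum_r w_r^2 \sum_f s_{rf}^2.}
#'
#' @param data A stratum-summary data frame (see [validate_stratum_table()]);
#'   for `exact_variance_region()` all rows must share one `region_id`.
#' @return A nonnegative variance estimate.
#' @export
exact_variance_region <- function(data) {
  data <- validate_stratum_table(data)
  if (dplyr::n_distinct(data$region_id) != 1L) {
    ec_abort_validation("exact_variance_region() expects strata from a single region")
  }
  sum(ec_exact_variance_rows(data))
}

#' @rdname exact_variance_region
#' @export
exact_variance_national <- function(data) {
  data <- validate_stratum_table(data)
  data$var_rf <- ec_exact_variance_rows(data)
  regional <- dplyr::summarise(
    dplyr::group_by(data, region_id),
    v_r = sum(var_rf), w = region_weight[1], .groups = "drop"
  )
  sum((regional$w / sum(regional$w))^2 * regional$v_r)
}

#' Wald-type interval from a point estimate and exact variance
#'
#' The exact-method interval is the symmetric Wald interval
#' `point +/- z * sqrt(variance)` with `z = 1.96` at the default 95% level.
#' Bounds are reported unclipped: an interval with a bound below 0 or above 1
#' is impossible for a proportion and is flagged `invalid_bounds`, and
#' unclipped bounds are what the invalidity accounting in the simulation
#' engine counts. A zero-width interval at a point estimate of exactly 0 or 1
#' is flagged `degenerate`. Set `clip = TRUE` to truncate bounds to \[0, 1\]
#' for presentation; the status flag is always computed from the unclipped
#' bounds.
#'
#' @param point Point estimate(s) in \[0, 1\].
#' @param variance Nonnegative variance estimate(s).
#' @param conf_level Two-sided confidence level; the default 0.95 uses the
#'   conventional z = 1.96.
#' @param clip If `TRUE`, truncate the reported bounds to \[0, 1\] (display
#'   only; invalidity is still judged on the raw bounds).
#' @return A tibble with columns `point`, `variance`, `lower`, `upper`,
#'   `method` (`"exact"`) and `status` (one of `"valid"`, `"invalid_bounds"`,
#'   `"degenerate"`).
#' @examples
#' exact_ci(0.25, 0.002525)
#' @export
exact_ci <- function(point, variance, conf_level = 0.95, clip = FALSE) {
  ec_check_prop(point, "point")
  if (any(variance < 0)) ec_abort_validation("variance must be nonnegative")
  z <- ec_zvalue(conf_level)
  se <- sqrt(variance)
  lower <- point - z * se
  upper <- point + z * se
  status <- dplyr::case_when(
    point == 0 | point == 1 ~ "degenerate",
    lower < 0 | upper > 1   ~ "invalid_bounds",
    TRUE                    ~ "valid"
  )
  if (clip) {
    lower <- pmax(lower, 0)
    upper <- pmin(upper, 1)
  }
  tibble::tibble(point = point, variance = variance, lower = lower,
                 upper = upper, method = "exact", status = status)
}
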