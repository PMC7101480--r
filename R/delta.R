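#' Logit intercept and its standard error from a binary count cell
#'
#' For a sample with `n1 = successes` and `n0 = trials - successes`, the
#' intercept of a covariate-free logit regression is `b = log(n1/n0)` with
#' standard error `s_b = sqrt(1/n0 + 1/n1)` (the simple-random-sampling
#' closed form; design-based values may be supplied downstream as overrides).
#' The antilogit of `b` recovers the sample proportion. When either cell is
#' empty (`successes` is 0 or equal to `trials`) the logit is undefined and
#' the row is flagged, which propagates to an `undefined` interval status.
#'
#' @param successes,trials Nonnegative integer count(s), `successes <= trials`,
#'   `trials >= 1`.
#' @return A tibble with columns `b`, `s_b`, `n1`, `n0`, and `defined`
#'   (`FALSE` when a cell is empty, with `b`, `s_b` set to `NA`).
#' @examples
#' logit_stat(50, 100)  # b = 0, s_b = 0.2
#' logit_stat(0, 50)    # undefined
#' @export
logit_stat <- function(successes, trials) {
  ec_check_count(trials, "trials")
  ec_check_count(successes, "successes", min = 0)
  if (any(successes > trials)) ec_abort_validation("successes exceeds trials")
  n1 <- successes
  n0 <- trials - successes
  defined <- n1 >= 1 & n0 >= 1
  b <- ifelse(defined, log(n1 / n0), NA_real_)
  s_b <- ifelse(defined, sqrt(1 / n0 + 1 / n1), NA_real_)
  tibble::tibble(b = b, s_b = s_b, n1 = n1, n0 = n0, defined = defined)
}

#' Delta-method gradient of the logit of a stratum product
#'
#' Writing the stratum effective coverage as
#' `F = logit(antilogit(b_x) * antilogit(b_y))`, the chain rule through the
#' logit link (`dp/db = p(1-p)`, `d logit(p)/dp = 1/(p(1-p))`) gives
#' \deqn{\partial F/\partial b_x = \frac{1-p_x}{1-p_x p_y}, \qquad
#'       \partial F/\partial b_y = \frac{1-p_y}{1-p_x p_y}.}
#' These analytic forms are validated against central finite differences in
#' the test suite.
#'
#' @param p_x,p_y Proportions strictly inside (0, 1) with product below 1.
#' @return A tibble with columns `g_x`, `g_y`.
#' @examples
#' delta_gradient_stratum(0.5, 0.5)  # both 2/3
#' @export
delta_gradient_stratum <- function(p_x, p_y) {
  ec_check_prop(p_x, "p_x"); ec_check_prop(p_y, "p_y")
  p <- p_x * p_y
  if (any(p <= 0 | p >= 1)) {
    ec_abort_validation("delta gradient requires the product p_x * p_y strictly inside (0, 1)")
  }
  tibble::tibble(g_x = (1 - p_x) / (1 - p), g_y = (1 - p_y) / (1 - p))
}

## Vectorized delta variance of F = logit(p_x * p_y) for a single binary
## stratum, straight from the four count cells. Fast path for the simulation
## engine: returns var_F with NA where the interval is undefined (any empty
## or full cell).
ec_delta_var_stratum_counts <- function(x, n_x, y, n_y) {
  defined <- x >= 1 & x <= n_x - 1 & y >= 1 & y <= n_y - 1
  p_x <- x / n_x
  p_y <- y / n_y
  p <- p_x * p_y
  s2_bx <- 1 / x + 1 / (n_x - x)
  s2_by <- 1 / y + 1 / (n_y - y)
  g_x <- (1 - p_x) / (1 - p)
  g_y <- (1 - p_y) / (1 - p)
  out <- g_x^2 * s2_bx + g_y^2 * s2_by
  out[!defined] <- NA_real_
  out
}

#' Delta-method variance of logit effective coverage with a continuous score
#'
#' With a continuous readiness score the coverage arm still enters on the
#' logit scale, but the readiness mean enters the expansion on its natural
#' scale (the logit machinery requires binary counts). With `p = p_x * ybar`:
#' \deqn{Var(F) = \left[\frac{1-p_x}{1-p}\right]^2 s_{bx}^2 +
#'   \left[\frac{p_x}{p(1-p)}\right]^2 \frac{s_y^2}{n_y}.}
#'
#' @param x_successes,n_x Coverage count cell (both outcomes must be
#'   observed: `1 <= x_successes <= n_x - 1`).
#' @param y_mean Readiness-score mean(s), strictly inside (0, 1).
#' @param y_var Sample variance(s) of the score, nonnegative.
#' @param n_y Facility sample size(s).
#' @return Variance(s) of `F = logit(p)`; `NA` where undefined.
#' @examples
#' delta_variance_continuous(50, 100, 0.5, 0.01, 25)
#' @export
delta_variance_continuous <- function(x_successes, n_x, y_mean, y_var, n_y) {
  ec_check_count(n_x, "n_x"); ec_check_count(n_y, "n_y")
  ec_check_count(x_successes, "x_successes", min = 0)
  ec_check_prop(y_mean, "y_mean")
  if (any(y_var < 0)) ec_abort_validation("y_var must be nonnegative")
  defined <- x_successes >= 1 & x_successes <= n_x - 1 & y_mean > 0 & y_mean < 1
  p_x <- x_successes / n_x
  p <- p_x * y_mean
  s2_bx <- 1 / x_successes + 1 / (n_x - x_successes)
  out <- ((1 - p_x) / (1 - p))^2 * s2_bx + (p_x / (p * (1 - p)))^2 * y_var / n_y
  out[!defined] <- NA_real_
  out
}

#' Delta-method variance of logit effective coverage from a stratum table
#'
#' Computes `Var(F)` for `F = logit(p)` at the requested aggregation level by
#' the delta method, summing per-stratum contributions under independence.
#' For a level point estimate `p_L` with `D = p_L (1 - p_L)`, a binary
#' stratum contributes
#' \deqn{\left[\frac{w\, p_x(1-p_x)\, p_y}{D}\right]^2 s_{bx}^2 +
#'       \left[\frac{w\, p_x\, p_y(1-p_y)}{D}\right]^2 s_{by}^2,}
#' with `w = 1` at stratum and region level and the normalized region weight
#' at national level; a continuous stratum's readiness term is
#' `[w p_x / D]^2 s_y^2 / n_y`. At stratum level these reduce to the
#' [delta_gradient_stratum()] forms. The `s_b` values use the closed form
#' from [logit_stat()] unless the table carries override columns `s_bx` /
#' `s_by` (design-based standard errors from a survey fit).
#'
#' The variance is undefined (`NA`, `defined = FALSE`) when the level point
#' estimate is 0 or 1, or when any contributing binary cell is empty or full,
#' or a continuous readiness mean sits on the boundary.
#'
#' @param data A stratum-summary data frame (see [validate_stratum_table()]).
#' @param level `"stratum"`, `"region"`, or `"national"`.
#' @return A tibble with one row per unit at the requested level: identifier
#'   columns, `point` (the effective coverage estimate), `F = logit(point)`,
#'   `var_F`, and `defined`.
#' @export
delta_variance <- function(data, level = c("stratum", "region", "national")) {
  level <- match.arg(level)
  data <- validate_stratum_table(data)

  bin <- data$readiness_kind == "binary"
  data$s2_bx <- if ("s_bx" %in% names(data) && !all(is.na(data$s_bx))) {
    dplyr::coalesce(data$s_bx, sqrt(1 / data$x_successes + 1 / (data$n_x - data$x_successes)))^2
  } else {
    1 / data$x_successes + 1 / (data$n_x - data$x_successes)
  }
  s2_by_srs <- ifelse(bin, 1 / data$y_successes + 1 / (data$n_y - data$y_successes), NA_real_)
  data$s2_by <- if ("s_by" %in% names(data) && !all(is.na(data$s_by))) {
    ifelse(bin & !is.na(data$s_by), data$s_by^2, s2_by_srs)
  } else {
    s2_by_srs
  }
  data$cell_defined <- data$x_successes >= 1 & data$x_successes <= data$n_x - 1 &
    ifelse(bin,
           data$y_successes >= 1 & data$y_successes <= data$n_y - 1,
           data$y_mean > 0 & data$y_mean < 1)

  if (level == "stratum") {
    p <- data$p_x * data$p_y
    D <- p * (1 - p)
    term_x <- (data$p_x * (1 - data$p_x) * data$p_y / D)^2 * data$s2_bx
    term_y <- ifelse(bin,
                     (data$p_x * data$p_y * (1 - data$p_y) / D)^2 * data$s2_by,
                     (data$p_x / D)^2 * data$y_var / data$n_y)
    defined <- data$cell_defined & p > 0 & p < 1
    var_F <- ifelse(defined, term_x + term_y, NA_real_)
    return(tibble::tibble(region_id = data$region_id,
                          facility_type = data$facility_type,
                          point = p,
                          F = ifelse(defined, logit(p), NA_real_),
                          var_F = var_F, defined = defined))
  }

  w_tab <- dplyr::distinct(data, region_id, region_weight)
  w_tab$w_norm <- w_tab$region_weight / sum(w_tab$region_weight)
  data <- dplyr::left_join(data, w_tab[, c("region_id", "w_norm")], by = "region_id")
  data$w_eff <- if (level == "national") data$w_norm else 1

  if (level == "region") {
    grouped <- dplyr::group_by(data, region_id)
  } else {
    data$.all <- "national"
    grouped <- dplyr::group_by(data, .data$.all)
  }
  out <- dplyr::summarise(
    grouped,
    point = sum(w_eff * p_x * p_y),
    num_x = list(w_eff * p_x * (1 - p_x) * p_y),
    num_y = list(ifelse(readiness_kind == "binary",
                        w_eff * p_x * p_y * (1 - p_y), w_eff * p_x)),
    s2x = list(s2_bx),
    s2y = list(ifelse(readiness_kind == "binary", s2_by, y_var / n_y)),
    all_defined = all(cell_defined),
    .groups = "drop"
  )
  out$defined <- out$all_defined & out$point > 0 & out$point < 1
  D <- out$point * (1 - out$point)
  out$var_F <- purrr::pmap_dbl(
    list(out$num_x, out$num_y, out$s2x, out$s2y, D, out$defined),
    function(nx, ny, sx, sy, d, ok) {
      if (!ok) return(NA_real_)
      sum((nx / d)^2 * sx + (ny / d)^2 * sy)
    }
  )
  out$F <- ifelse(out$defined, logit(out$point), NA_real_)
  if (level == "region") {
    tibble::tibble(region_id = out$region_id, point = out$point,
                   F = out$F, var_F = out$var_F, defined = out$defined)
  } else {
    tibble::tibble(point = out$point, F = out$F, var_F = out$var_F,
                   defined = out$defined)
  }
}

#' Back-transformed delta-method confidence interval
#'
#' Builds the Wald interval on the logit scale, `F +/- z sqrt(Var(F))`, and
#' maps the endpoints back with the antilogit. The resulting interval is
#' asymmetric about the point estimate and always lies strictly inside
#' (0, 1), so it can never be invalid — the structural advantage of this
#' method over the symmetric exact-method interval near the boundaries.
#'
#' @param F Logit-scale point estimate(s); `NA` marks an undefined upstream
#'   logit and yields an `undefined` row.
#' @param var_F Nonnegative variance(s) of `F` on the logit scale.
#' @param conf_level Two-sided confidence level (default 0.95, z = 1.96).
#' @return A tibble with columns `point` (antilogit of `F`), `variance`
#'   (logit-scale `var_F`), `lower`, `upper`, `method` (`"delta"`), `status`
#'   (`"valid"` or `"undefined"`).
#' @examples
#' delta_ci(0, 0.04)
#' @export
delta_ci <- function(F, var_F, conf_level = 0.95) {
  if (any(var_F < 0, na.rm = TRUE)) ec_abort_validation("var_F must be nonnegative")
  z <- ec_zvalue(conf_level)
  defined <- !is.na(F) & !is.na(var_F)
  se <- sqrt(var_F)
  tibble::tibble(
    point = antilogit(F),
    variance = var_F,
    lower = ifelse(defined, antilogit(F - z * se), NA_real_),
    upper = ifelse(defined, antilogit(F + z * se), NA_real_),
    method = "delta",
    status = ifelse(defined, "valid", "undefined")
  )
}
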