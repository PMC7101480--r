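#' Effective coverage estimates with confidence intervals at all levels
#'
#' The main entry point: takes a stratum-summary table and returns point
#' estimates and 95% confidence intervals for effective coverage at the
#' stratum, region, and national levels, by each requested method. The exact
#' and delta methods are computed at every level; the parametric bootstrap is
#' defined per stratum only. Strata are treated as independent when
#' aggregating variances.
#'
#' @param data A stratum-summary data frame (see [validate_stratum_table()]).
#' @param methods Subset of `c("exact", "delta", "bootstrap")`.
#' @param conf_level Two-sided confidence level (default 0.95, z = 1.96).
#' @param boot A [boot_config()] for the bootstrap method.
#' @param seed Integer seed for the bootstrap; each stratum uses a
#'   deterministic substream so results do not depend on row order.
#' @param clip If `TRUE`, exact-method bounds are truncated to \[0, 1\] for
#'   display (status is still judged on raw bounds).
#' @return An object of class `"effcov_estimate"`: a list with `estimates`
#'   (a tibble with columns `level`, `region_id`, `facility_type`, `method`,
#'   `point`, `variance`, `lower`, `upper`, `status`), the validated `data`,
#'   and the call settings. Use [generics::tidy()] to extract the tibble and
#'   [generics::glance()] for a one-row summary.
#' @examples
#' strata <- tibble::tibble(
#'   region_id = rep(c("north", "south"), each = 2),
#'   facility_type = rep(c("hospital", "clinic"), 2),
#'   x_successes = c(30, 25, 40, 10), n_x = 100,
#'   readiness_kind = "binary", y_successes = c(45, 20, 30, 35), n_y = 50,
#'   y_mean = NA_real_, y_var = NA_real_,
#'   region_weight = rep(c(2, 1), each = 2)
#' )
#' fit <- estimate_effective_coverage(strata, methods = c("exact", "delta"))
#' tidy(fit)
#' glance(fit)
#' @export
estimate_effective_coverage <- function(data,
                                        methods = c("exact", "delta", "bootstrap"),
                                        conf_level = 0.95,
                                        boot = boot_config(),
                                        seed = 1L,
                                        clip = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  data <- validate_stratum_table(data)
  rows <- list()

  id_stratum <- data[, c("region_id", "facility_type")]
  point_stratum <- data$p_x * data$p_y

  if ("exact" %in% methods) {
    v <- ec_exact_variance_rows(data)
    rows$exact_stratum <- dplyr::bind_cols(
      tibble::tibble(level = "stratum"), id_stratum,
      exact_ci(point_stratum, v, conf_level, clip = clip))

    per_region <- data |>
      dplyr::mutate(var_rf = v, p_rf = point_stratum) |>
      dplyr::group_by(region_id) |>
      dplyr::summarise(point = sum(p_rf), variance = sum(var_rf),
                       w = region_weight[1], .groups = "drop")
    rows$exact_region <- dplyr::bind_cols(
      tibble::tibble(level = "region", region_id = per_region$region_id,
                     facility_type = NA_character_),
      exact_ci(per_region$point, per_region$variance, conf_level, clip = clip))

    w_norm <- per_region$w / sum(per_region$w)
    rows$exact_national <- dplyr::bind_cols(
      tibble::tibble(level = "national", region_id = NA_character_,
                     facility_type = NA_character_),
      exact_ci(sum(w_norm * per_region$point),
               sum(w_norm^2 * per_region$variance), conf_level, clip = clip))
  }

  if ("delta" %in% methods) {
    for (lv in c("stratum", "region", "national")) {
      dv <- delta_variance(data, level = lv)
      ci <- delta_ci(dv$F, dv$var_F, conf_level)
      ci$point <- dv$point  # report the point estimate even when undefined
      rows[[paste0("delta_", lv)]] <- dplyr::bind_cols(
        tibble::tibble(
          level = lv,
          region_id = if ("region_id" %in% names(dv)) dv$region_id else NA_character_,
          facility_type = if ("facility_type" %in% names(dv)) dv$facility_type else NA_character_),
        ci)
    }
  }

  if ("bootstrap" %in% methods) {
    rows$bootstrap_stratum <- purrr::pmap(
      dplyr::mutate(data, .row = dplyr::row_number()),
      function(region_id, facility_type, p_x, n_x, p_y, n_y, readiness_kind,
               y_var, ...) {
        cfg <- boot_config(B = boot$B,
                           seed = ec_substream_seed(seed, paste(region_id, facility_type)),
                           percentiles = boot$percentiles,
                           quantile_type = boot$quantile_type)
        ci <- if (readiness_kind == "binary") {
          parametric_bootstrap_ci(p_x, n_x, p_y, n_y, cfg)
        } else {
          parametric_bootstrap_ci_continuous(p_x, n_x, p_y, y_var, n_y, cfg)
        }
        dplyr::bind_cols(tibble::tibble(level = "stratum",
                                        region_id = region_id,
                                        facility_type = facility_type), ci)
      }) |> dplyr::bind_rows()
  }

  estimates <- dplyr::bind_rows(rows) |>
    dplyr::mutate(level = factor(level, levels = c("stratum", "region", "national"))) |>
    dplyr::arrange(level, region_id, facility_type, method) |>
    dplyr::mutate(level = as.character(level))

  structure(list(estimates = estimates, data = data, methods = methods,
                 conf_level = conf_level, boot = boot, seed = seed),
            class = "effcov_estimate")
}

#' @export
print.effcov_estimate <- function(x, ...) {
  cat("Effective coverage estimates (", paste(x$methods, collapse = ", "),
      "; ", format(100 * x$conf_level), "% CI)\n", sep = "")
  cat(dplyr::n_distinct(x$data$region_id), "region(s),",
      nrow(x$data), "strata\n\n")
  print(x$estimates, n = 30)
  invisible(x)
}

#' Tidy an effective-coverage fit
#'
#' @param x An `"effcov_estimate"` object.
#' @param ... Unused.
#' @return The estimates tibble: one row per level x unit x method with
#'   `point`, `variance`, `lower`, `upper`, `status`.
#' @export
tidy.effcov_estimate <- function(x, ...) x$estimates

#' One-row summary of an effective-coverage fit
#'
#' @param x An `"effcov_estimate"` object.
#' @param ... Unused.
#' @return A one-row tibble: counts of strata and regions, the national
#'   point estimate, and tallies of invalid and undefined intervals.
#' @export
glance.effcov_estimate <- function(x, ...) {
  est <- x$estimates
  tibble::tibble(
    n_strata = nrow(x$data),
    n_regions = dplyr::n_distinct(x$data$region_id),
    n_methods = length(x$methods),
    conf_level = x$conf_level,
    national_estimate = est$point[est$level == "national"][1],
    n_invalid = sum(est$status == "invalid_bounds"),
    n_undefined = sum(est$status == "undefined"),
    n_degenerate = sum(est$status == "degenerate")
  )
}

#' Plot effective-coverage intervals by region and method
#'
#' @param object An `"effcov_estimate"` object.
#' @param level Which level to plot (default `"region"`).
#' @param ... Unused.
#' @return A ggplot of point estimates with interval bars, coloured by
#'   method; invalid or undefined intervals are marked by shape.
#' @export
autoplot.effcov_estimate <- function(object, level = "region", ...) {
  est <- dplyr::filter(object$estimates, .data$level == !!level)
  xvar <- if (level == "stratum") "facility_type" else if (level == "region") "region_id" else "level"
  ggplot2::ggplot(est, ggplot2::aes(x = .data[[xvar]], y = point,
                                    colour = method, shape = status)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = lower, ymax = upper),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dotted") +
    ggplot2::labs(y = "effective coverage", x = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
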