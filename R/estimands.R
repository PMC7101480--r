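#' Validate a stratum-summary table
#'
#' A stratum-summary table has one row per (region, facility-type) stratum and
#' carries the observed counts from the two independent samples: the
#' individual-level sample giving crude coverage (`x_successes` of `n_x`
#' individuals using services of this facility type) and the facility-level
#' sample giving readiness. Readiness is either binary (`y_successes` of `n_y`
#' facilities meeting the criterion) or a continuous score on \[0, 1\]
#' summarised by `y_mean` and sample variance `y_var` over `n_y` facilities.
#' `region_weight` is the (possibly unnormalized) population weight of the
#' region, constant within region.
#'
#' Proportions are always derived from counts here, never accepted
#' pre-rounded, so that logit intercepts (which need both count cells) remain
#' computable downstream.
#'
#' @param data A data frame with columns `region_id`, `facility_type`,
#'   `x_successes`, `n_x`, `readiness_kind` (`"binary"` or `"continuous"`),
#'   `y_successes`, `n_y`, `y_mean`, `y_var`, `region_weight`. Binary rows
#'   leave `y_mean`/`y_var` as `NA`; continuous rows leave `y_successes` as
#'   `NA`. Optional columns `s_bx`, `s_by` supply design-based logit-scale
#'   standard errors that override the simple-random-sampling closed form.
#' @return The validated table as a tibble with derived columns `p_x`
#'   (coverage proportion) and `p_y` (readiness proportion or mean).
#' @examples
#' strata <- tibble::tibble(
#'   region_id = "r1", facility_type = c("hospital", "clinic"),
#'   x_successes = c(30, 20), n_x = c(100, 100),
#'   readiness_kind = "binary", y_successes = c(40, 10), n_y = c(50, 50),
#'   y_mean = NA_real_, y_var = NA_real_, region_weight = 1
#' )
#' validate_stratum_table(strata)
#' @export
validate_stratum_table <- function(data) {
  required <- c("region_id", "facility_type", "x_successes", "n_x",
                "readiness_kind", "n_y", "region_weight")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    ec_abort_validation(sprintf("stratum table is missing column(s): %s",
                                paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) ec_abort_validation("stratum table has no rows")
  if (!"y_successes" %in% names(data)) data$y_successes <- NA_real_
  if (!"y_mean" %in% names(data)) data$y_mean <- NA_real_
  if (!"y_var" %in% names(data)) data$y_var <- NA_real_

  bad_kind <- !data$readiness_kind %in% c("binary", "continuous")
  if (any(bad_kind)) {
    ec_abort_validation(sprintf("row %d: unknown readiness_kind '%s'",
                                which(bad_kind)[1],
                                data$readiness_kind[which(bad_kind)[1]]))
  }
  ec_check_count(data$n_x, "n_x")
  ec_check_count(data$n_y, "n_y")
  ec_check_count(data$x_successes, "x_successes", min = 0)
  if (any(data$x_successes > data$n_x)) {
    ec_abort_validation(sprintf("row %d: x_successes exceeds n_x",
                                which(data$x_successes > data$n_x)[1]))
  }

  bin <- data$readiness_kind == "binary"
  if (any(bin & (is.na(data$y_successes)))) {
    ec_abort_validation(sprintf("row %d: binary readiness requires y_successes",
                                which(bin & is.na(data$y_successes))[1]))
  }
  ec_check_count(data$y_successes[bin], "y_successes", min = 0)
  if (any(data$y_successes[bin] > data$n_y[bin])) {
    ec_abort_validation(sprintf("row %d: y_successes exceeds n_y",
                                which(bin & data$y_successes > data$n_y)[1]))
  }
  cont <- !bin
  if (any(cont & (is.na(data$y_mean) | is.na(data$y_var)))) {
    ec_abort_validation(sprintf("row %d: continuous readiness requires y_mean and y_var",
                                which(cont & (is.na(data$y_mean) | is.na(data$y_var)))[1]))
  }
  ec_check_prop(data$y_mean[cont], "y_mean")
  if (any(cont & data$y_var < 0)) {
    ec_abort_validation("y_var must be nonnegative")
  }
  # sample variance of a [0,1]-bounded score cannot exceed the Bernoulli bound
  vmax <- with(data[cont, ], ifelse(n_y >= 2, y_mean * (1 - y_mean) * n_y / (n_y - 1), Inf))
  if (any(data$y_var[cont] > vmax + 1e-12)) {
    ec_abort_validation("y_var exceeds the maximum possible for a score on [0, 1]")
  }

  if (any(!is.finite(data$region_weight) | data$region_weight < 0)) {
    ec_abort_validation("region_weight must be finite and nonnegative")
  }
  w_by_region <- dplyr::distinct(data, region_id, region_weight)
  if (anyDuplicated(w_by_region$region_id) > 0) {
    ec_abort_validation("region_weight must be constant within region_id")
  }
  if (sum(w_by_region$region_weight) <= 0) {
    ec_abort_validation("region weights must not all be zero")
  }
  if (anyDuplicated(data[, c("region_id", "facility_type")]) > 0) {
    ec_abort_validation("duplicated (region_id, facility_type) stratum")
  }

  out <- dplyr::mutate(
    data,
    p_x = x_successes / n_x,
    p_y = dplyr::if_else(readiness_kind == "binary", y_successes / n_y, y_mean)
  )
  # users of all facility types cannot exceed the population of a region
  sums <- dplyr::summarise(dplyr::group_by(out, region_id),
                           total_px = sum(p_x), .groups = "drop")
  if (any(sums$total_px > 1 + 1e-9)) {
    bad <- sums$region_id[sums$total_px > 1 + 1e-9][1]
    ec_abort_validation(sprintf(
      "region '%s': facility-type coverage proportions sum to more than 1", bad))
  }
  out
}

#' Effective coverage of one stratum
#'
#' Effective coverage for a single (region, facility-type) stratum is the
#' product of the crude-coverage proportion and the readiness proportion (or
#' readiness-score mean), `p = p_x * p_y`.
#'
#' @param p_x Crude coverage proportion(s) in \[0, 1\].
#' @param p_y Readiness proportion(s) or score mean(s) in \[0, 1\].
#' @return The elementwise product, in \[0, 1\].
#' @examples
#' effective_coverage_stratum(0.5, 0.5)
#' @export
effective_coverage_stratum <- function(p_x, p_y) {
  ec_check_prop(p_x, "p_x")
  ec_check_prop(p_y, "p_y")
  p_x * p_y
}

#' Effective coverage of one region
#'
#' Regional effective coverage adds the stratum products over the facility
#' types of a single region: `p_r = sum_f p_xf * p_yf`. The facility-type
#' coverage proportions must form a (sub-)partition of the region's
#' population, so their sum may not exceed 1.
#'
#' @param data A stratum-summary data frame (see [validate_stratum_table()])
#'   whose rows all belong to one region.
#' @return The regional effective coverage, a number in \[0, 1\].
#' @examples
#' strata <- tibble::tibble(
#'   region_id = "r1", facility_type = c("a", "b"),
#'   x_successes = c(40, 30), n_x = 100,
#'   readiness_kind = "binary", y_successes = c(25, 50), n_y = 50,
#'   y_mean = NA_real_, y_var = NA_real_, region_weight = 1
#' )
#' effective_coverage_region(strata)  # 0.4*0.5 + 0.3*1 = 0.5
#' @export
effective_coverage_region <- function(data) {
  data <- validate_stratum_table(data)
  if (dplyr::n_distinct(data$region_id) != 1L) {
    ec_abort_validation("effective_coverage_region() expects strata from a single region")
  }
  sum(data$p_x * data$p_y)
}

#' National effective coverage
#'
#' The national estimate is the weighted average of regional effective
#' coverages, `P = sum_r w_r p_r`, with region weights proportional to each
#' region's population denominator. Weights are accepted unnormalized and
#' normalized internally to sum to 1.
#'
#' @inheritParams effective_coverage_region
#' @return The national effective coverage, a number in \[0, 1\].
#' @export
effective_coverage_national <- function(data) {
  data <- validate_stratum_table(data)
  regional <- dplyr::summarise(
    dplyr::group_by(data, region_id),
    p_r = sum(p_x * p_y), w = region_weight[1], .groups = "drop"
  )
  sum(regional$w / sum(regional$w) * regional$p_r)
}
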