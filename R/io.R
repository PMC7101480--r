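#' Read a stratum-summary table from delimited text
#'
#' Reads the comma-separated stratum schema (`region_id`, `facility_type`,
#' `x_successes`, `n_x`, `readiness_kind`, `y_successes`, `n_y`, `y_mean`,
#' `y_var`, `region_weight`; inapplicable cells empty) and validates it with
#' [validate_stratum_table()]. Parse and validation problems raise a
#' descriptive error naming the offending column or row.
#'
#' @param path Path to a CSV file.
#' @return A validated stratum tibble with derived `p_x`, `p_y`.
#' @export
read_stratum_table <- function(path) {
  if (!file.exists(path)) ec_abort_io(sprintf("input file not found: %s", path))
  data <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(
      region_id = readr::col_character(),
      facility_type = readr::col_character(),
      x_successes = readr::col_double(),
      n_x = readr::col_double(),
      readiness_kind = readr::col_character(),
      y_successes = readr::col_double(),
      n_y = readr::col_double(),
      y_mean = readr::col_double(),
      y_var = readr::col_double(),
      region_weight = readr::col_double(),
      .default = readr::col_double()
    ), progress = FALSE),
    error = function(e) ec_abort_io(sprintf("cannot read '%s': %s", path,
                                            conditionMessage(e)))
  )
  if (nrow(data) == 0) ec_abort_validation(sprintf("'%s' contains no data rows", path))
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    ec_abort_validation(sprintf("parse problem in '%s' at line %d: %s",
                                path, probs$row[1] + 1L, probs$expected[1]))
  }
  validate_stratum_table(data)
}

#' Write interval estimates to delimited text
#'
#' Writes the shared results schema (`level`, `region_id`, `facility_type`,
#' `method`, `point`, `variance`, `lower`, `upper`, `status`) as CSV with
#' full double precision (15 significant digits), rows ordered by level
#' (stratum, region, national), region, facility type, and method.
#'
#' @param estimates A tibble in the results schema, e.g. from
#'   [tidy.effcov_estimate()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(estimates, path) {
  if (nrow(estimates) == 0) ec_abort_validation("no estimates to write")
  cols <- c("level", "region_id", "facility_type", "method", "point",
            "variance", "lower", "upper", "status")
  missing_cols <- setdiff(cols, names(estimates))
  if (length(missing_cols) > 0) {
    ec_abort_validation(sprintf("estimates table is missing column(s): %s",
                                paste(missing_cols, collapse = ", ")))
  }
  out <- estimates[, cols] |>
    dplyr::mutate(level = factor(level, levels = c("stratum", "region", "national"))) |>
    dplyr::arrange(level, region_id, facility_type, method) |>
    dplyr::mutate(level = as.character(level))
  tryCatch(readr::write_csv(out, path, na = "", progress = FALSE),
           error = function(e) ec_abort_io(sprintf("cannot write '%s': %s",
                                                   path, conditionMessage(e))))
  invisible(path)
}

#' Generate a synthetic stratum table with known truth
#'
#' Draws a stratum-summary table from known true parameters, emulating the
#' shape of a linked household-survey / facility-assessment application
#' (regions crossed with facility types), together with the truth record.
#' True facility-type coverage proportions within a region are scaled so
#' they sum to 0.9, and each region's individual sample is drawn once as a
#' multinomial over facility types (plus a no-service remainder), so the
#' observed shares always satisfy the partition constraint; readiness is
#' either a binomial proportion or a Beta score summarised per stratum. This supports end-to-end
#' parameter-recovery tests without any external data.
#'
#' @param n_regions,n_facility_types Grid dimensions, at least 1 each.
#' @param seed Integer seed (draws are fully deterministic given it).
#' @param n_x,n_y Per-stratum sample sizes.
#' @param readiness_kind `"binary"` or `"continuous"`.
#' @return A list with `strata` (a valid stratum table) and `truth` (a
#'   tibble of the true `P_x`, `P_y`, weights, and the implied true
#'   stratum/region/national effective coverage, the latter as attributes
#'   `p_region`, `p_national` on the tibble).
#' @examples
#' fx <- generate_fixture(3, 2, seed = 7, n_x = 200, n_y = 50)
#' effective_coverage_national(fx$strata)
#' attr(fx$truth, "p_national")
#' @export
generate_fixture <- function(n_regions, n_facility_types, seed = 1L,
                             n_x = 500, n_y = 100,
                             readiness_kind = "binary") {
  ec_check_count(n_regions, "n_regions"); ec_check_count(n_facility_types, "n_facility_types")
  stopifnot(readiness_kind %in% c("binary", "continuous"))
  set.seed(seed)
  regions <- sprintf("region_%02d", seq_len(n_regions))
  ftypes <- sprintf("ftype_%d", seq_len(n_facility_types))
  truth <- tidyr::crossing(region_id = regions, facility_type = ftypes)
  # raw usage shares scaled within region so facility types sum to 0.9
  raw <- stats::runif(nrow(truth), 0.2, 1)
  truth$P_x <- raw / stats::ave(raw, truth$region_id, FUN = sum) * 0.9
  truth$P_y <- stats::runif(nrow(truth), 0.2, 0.95)
  w <- stats::runif(n_regions, 0.5, 1.5)
  truth$region_weight <- w[match(truth$region_id, regions)]

  # one individual sample per region, partitioned over facility types (plus
  # a no-service remainder) so observed shares can never sum past 1
  x <- unlist(lapply(regions, function(r) {
    px <- truth$P_x[truth$region_id == r]
    stats::rmultinom(1, n_x, c(px, 1 - sum(px)))[seq_along(px)]
  }))
  if (readiness_kind == "binary") {
    y <- rbinom(nrow(truth), n_y, truth$P_y)
    strata <- tibble::tibble(
      region_id = truth$region_id, facility_type = truth$facility_type,
      x_successes = x, n_x = n_x, readiness_kind = "binary",
      y_successes = y, n_y = n_y, y_mean = NA_real_, y_var = NA_real_,
      region_weight = truth$region_weight)
  } else {
    scores <- matrix(rbeta(nrow(truth) * n_y, truth$P_y, 1 - truth$P_y),
                     nrow = nrow(truth))
    strata <- tibble::tibble(
      region_id = truth$region_id, facility_type = truth$facility_type,
      x_successes = x, n_x = n_x, readiness_kind = "continuous",
      y_successes = NA_real_, n_y = n_y, y_mean = rowMeans(scores),
      y_var = apply(scores, 1, var), region_weight = truth$region_weight)
  }
  p_region <- tapply(truth$P_x * truth$P_y, truth$region_id, sum)
  p_national <- sum(w / sum(w) * p_region[regions])
  attr(truth, "p_region") <- p_region
  attr(truth, "p_national") <- p_national
  list(strata = validate_stratum_table(strata), truth = truth)
}
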