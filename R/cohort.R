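#' Donor-level neighborhood-percentage summaries
#'
#' Donors are the replicates for all cohort statistics: per-region
#' neighborhood percentages are first averaged within each donor, yielding
#' one value per donor x neighborhood.
#'
#' @param model A `cellanchor_nbhd` model.
#' @param cells Cells tibble with donor and region columns.
#' @param donor_key,region_key Column names (defaults `"donor_id"`,
#'   `"region"`).
#' @return A tibble: `donor_id` (named by `donor_key`), `neighborhood`,
#'   `percentage` (the donor's mean over its regions).
#' @export
donor_neighborhood_summary <- function(model, cells, donor_key = "donor_id",
                                       region_key = "region") {
  pct <- neighborhood_percentages(model, cells, c(donor_key, region_key))
  pct |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(donor_key, "neighborhood")))) |>
    dplyr::summarise(percentage = mean(.data$percentage), .groups = "drop")
}

check_value_cols <- function(data, cols) {
  bad <- setdiff(cols, names(data))
  if (length(bad) > 0L) {
    stop("schema error: missing column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
}

#' Unpaired two-group comparison of donor-level neighborhood percentages
#'
#' Two-sided unpaired t-test of donor-level percentages between the two
#' levels of a condition (e.g. hypertension vs no hypertension), run per
#' neighborhood.  Welch's unequal-variance form is the default; set
#' `var_equal = TRUE` for the classic pooled-variance test.  No
#' multiple-testing correction is applied; a Benjamini-Hochberg column is
#' appended for transparency when more than one neighborhood is tested.
#'
#' @param summaries Donor-level tibble with columns `neighborhood`,
#'   `percentage` (or `value_col`), and the condition column.
#' @param condition_key Column with exactly two levels.
#' @param neighborhood Optional: restrict to one neighborhood name.
#' @param value_col Value column (default `"percentage"`).
#' @param var_equal Use the pooled-variance t-test (default `FALSE`, Welch).
#' @return A tibble, one row per neighborhood: group means, `n1`, `n2`,
#'   `statistic` (t), `df`, `p_value`, `p_adjusted` (BH).
#' @export
unpaired_condition_test <- function(summaries, condition_key,
                                    neighborhood = NULL,
                                    value_col = "percentage",
                                    var_equal = FALSE) {
  check_value_cols(summaries, c("neighborhood", value_col, condition_key))
  if (!is.null(neighborhood)) {
    summaries <- summaries[summaries$neighborhood %in% neighborhood, ]
  }
  groups <- sort(unique(as.character(summaries[[condition_key]])))
  if (length(groups) != 2L) {
    stop("condition '", condition_key, "' must have exactly 2 levels, found ",
         length(groups), call. = FALSE)
  }
  out <- summaries |>
    dplyr::group_by(.data$neighborhood) |>
    dplyr::group_modify(function(d, key) {
      v1 <- d[[value_col]][d[[condition_key]] == groups[1L]]
      v2 <- d[[value_col]][d[[condition_key]] == groups[2L]]
      if (length(v1) < 2L || length(v2) < 2L) {
        stop("insufficient replicates: each group needs >= 2 donors (",
             key$neighborhood, ": ", length(v1), " vs ", length(v2), ")",
             call. = FALSE)
      }
      if (stats::sd(v1) == 0 && stats::sd(v2) == 0 && mean(v1) == mean(v2)) {
        return(tibble::tibble(group1 = groups[1L], group2 = groups[2L],
                              mean1 = mean(v1), mean2 = mean(v2),
                              n1 = length(v1), n2 = length(v2),
                              statistic = 0, df = length(v1) + length(v2) - 2,
                              p_value = 1))
      }
      tt <- stats::t.test(v1, v2, var.equal = var_equal)
      tibble::tibble(group1 = groups[1L], group2 = groups[2L],
                     mean1 = mean(v1), mean2 = mean(v2),
                     n1 = length(v1), n2 = length(v2),
                     statistic = unname(tt$statistic),
                     df = unname(tt$parameter),
                     p_value = tt$p.value)
    }) |>
    dplyr::ungroup()
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Paired comparison of neighborhood percentages between two tissue classes
#'
#' For each donor, percentages are first averaged within each tissue class
#' (e.g. small bowel vs colon regions), giving one pair per donor; a
#' two-sided paired t-test is then run on the per-donor differences
#' (algebraically the one-sample t-test on differences).  Zero-variance,
#' nonzero-mean differences are reported as degenerate (`degenerate = TRUE`,
#' infinite t, p reported as 0) rather than erroring.
#'
#' @param summaries Tibble with columns `neighborhood`, the donor column, the
#'   region-class column, and `percentage` (or `value_col`); one or more rows
#'   per donor x class (regions averaged first).
#' @param region_class_key Column with exactly two tissue classes.
#' @param donor_key Donor column (default `"donor_id"`).
#' @param neighborhood Optional: restrict to one neighborhood.
#' @param value_col Value column (default `"percentage"`).
#' @return A tibble, one row per neighborhood: class means, `n_pairs`,
#'   `statistic`, `df`, `p_value`, `degenerate`, `p_adjusted`.
#' @export
paired_region_test <- function(summaries, region_class_key,
                               donor_key = "donor_id", neighborhood = NULL,
                               value_col = "percentage") {
  check_value_cols(summaries, c("neighborhood", value_col, region_class_key,
                                donor_key))
  if (!is.null(neighborhood)) {
    summaries <- summaries[summaries$neighborhood %in% neighborhood, ]
  }
  classes <- sort(unique(as.character(summaries[[region_class_key]])))
  if (length(classes) != 2L) {
    stop("region class '", region_class_key, "' must have exactly 2 levels",
         call. = FALSE)
  }
  out <- summaries |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("neighborhood", donor_key, region_class_key)))) |>
    dplyr::summarise(value = mean(.data[[value_col]]), .groups = "drop") |>
    dplyr::group_by(.data$neighborhood) |>
    dplyr::group_modify(function(d, key) {
      wide <- tidyr::pivot_wider(d, names_from = dplyr::all_of(region_class_key),
                                 values_from = "value")
      incomplete <- wide[[donor_key]][is.na(wide[[classes[1L]]]) |
                                      is.na(wide[[classes[2L]]])]
      if (length(incomplete) > 0L) {
        stop("pairing error: donor(s) missing one side: ",
             paste(incomplete, collapse = ", "), call. = FALSE)
      }
      diffs <- wide[[classes[1L]]] - wide[[classes[2L]]]
      n <- length(diffs)
      if (stats::sd(diffs) == 0) {
        if (mean(diffs) == 0) {
          stat <- 0; p <- 1; degen <- FALSE
        } else {
          stat <- sign(mean(diffs)) * Inf; p <- 0; degen <- TRUE
        }
        return(tibble::tibble(class1 = classes[1L], class2 = classes[2L],
                              mean1 = mean(wide[[classes[1L]]]),
                              mean2 = mean(wide[[classes[2L]]]),
                              n_pairs = n, statistic = stat, df = n - 1,
                              p_value = p, degenerate = degen))
      }
      tt <- stats::t.test(wide[[classes[1L]]], wide[[classes[2L]]],
                          paired = TRUE)
      tibble::tibble(class1 = classes[1L], class2 = classes[2L],
                     mean1 = mean(wide[[classes[1L]]]),
                     mean2 = mean(wide[[classes[2L]]]),
                     n_pairs = n, statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p_value = tt$p.value,
                     degenerate = FALSE)
    }) |>
    dplyr::ungroup()
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Linear regression of neighborhood percentage on a donor covariate
#'
#' Ordinary least squares of the donor-mean neighborhood percentage on a
#' continuous donor covariate (e.g. BMI), per neighborhood; reports the
#' slope, intercept, Pearson r, and the two-sided p-value for the slope.
#'
#' @param summaries Donor-level tibble with `neighborhood`, the covariate
#'   column and `percentage` (or `value_col`).
#' @param covariate_key Continuous covariate column.
#' @param neighborhood Optional: restrict to one neighborhood.
#' @param value_col Value column (default `"percentage"`).
#' @return A tibble, one row per neighborhood: `slope`, `intercept`, `r`,
#'   `p_value`, `n`.
#' @export
covariate_regression <- function(summaries, covariate_key,
                                 neighborhood = NULL,
                                 value_col = "percentage") {
  check_value_cols(summaries, c("neighborhood", value_col, covariate_key))
  if (!is.null(neighborhood)) {
    summaries <- summaries[summaries$neighborhood %in% neighborhood, ]
  }
  summaries |>
    dplyr::filter(!is.na(.data[[covariate_key]])) |>
    dplyr::group_by(.data$neighborhood) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3L) {
        stop("insufficient replicates: regression needs >= 3 donors with the ",
             "covariate (", key$neighborhood, ": ", nrow(d), ")",
             call. = FALSE)
      }
      xv <- d[[covariate_key]]
      yv <- d[[value_col]]
      if (stats::sd(xv) == 0) {
        stop("degenerate design: covariate '", covariate_key,
             "' is constant", call. = FALSE)
      }
      fit <- stats::lm(yv ~ xv)
      coefs <- summary(fit)$coefficients
      r <- if (stats::sd(yv) == 0) 0 else stats::cor(xv, yv)
      tibble::tibble(
        slope = unname(coefs["xv", "Estimate"]),
        intercept = unname(coefs["(Intercept)", "Estimate"]),
        r = r,
        p_value = unname(coefs["xv", "Pr(>|t|)"]),
        n = nrow(d))
    }) |>
    dplyr::ungroup()
}
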