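#' Within-run / within-lab precision summary
#'
#' Per pool level: mean, sample SD (n-1 denominator) and CV% = 100 * SD /
#' mean. Within-lab designs pool all replicates of a level (e.g. the 80
#' results of a 2-per-run, 2-runs-per-day, 20-day design) into one total-SD
#' summary.
#'
#' @param replicates A data frame in long format with at least columns
#'   `pool` (level label) and `value` (mg/dL); extra grouping columns (day,
#'   run, site) are ignored by the summary.
#' @param design `"within_run"` or `"within_lab"` (recorded on the output).
#' @return A tibble with `pool`, `n`, `mean`, `sd`, `cv_pct` and a `design`
#'   column; `cv_pct` displays to one decimal via `cv_display`.
#' @export
precision_summary <- function(replicates, design = c("within_run", "within_lab")) {
  design <- match.arg(design)
  stopifnot(is.data.frame(replicates), all(c("pool", "value") %in% names(replicates)))
  out <- replicates |>
    dplyr::group_by(.data$pool) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$value),
                     sd = stats::sd(.data$value),
                     .groups = "drop")
  if (any(out$n < 2)) abort_domain("every pool needs at least 2 replicates")
  out |>
    dplyr::mutate(cv_pct = 100 * .data$sd / .data$mean,
                  cv_display = sprintf("%.1f", round_half_up(.data$cv_pct)),
                  design = design)
}

#' Limits of blank, detection and quantitation
#'
#' `LOB = mean_blank + 1.645 sd_blank`; `LOD = LOB + 1.645 sd_low` with the
#' low-level SD pooled across low pools; LOQ is the lowest dilution-series
#' level whose replicate CV is at or below `cv_limit` (default 20%) and
#' whose mean is at least the LOD. The ordering `lob <= lod <= loq` is
#' enforced by construction; when no level qualifies, `loq` is `NA` and
#' `loq_reached` is `FALSE`.
#'
#' @param blanks Replicate values of the blank material.
#' @param low_pools A list of replicate vectors from low-level pools.
#' @param dilution_series A data frame with columns `level` (nominal label
#'   or concentration) and `value` (replicate results), or `NULL` to skip
#'   the LOQ step.
#' @param cv_limit LOQ replicate-CV criterion in percent.
#' @return A list of class `sensitivity_result`: `lob`, `lod`, `loq`,
#'   `loq_reached`, and an `inputs` summary list.
#' @export
sensitivity_limits <- function(blanks, low_pools, dilution_series = NULL,
                               cv_limit = 20) {
  if (length(blanks) == 0) abort_domain("blank replicates are required")
  if (length(blanks) < 10)
    rlang::warn("fewer than 10 blank replicates; LOB estimate will be unstable")
  if (!is.list(low_pools)) low_pools <- list(low_pools)
  if (length(low_pools) < 1 || any(lengths(low_pools) < 2))
    abort_domain("at least one low pool with >= 2 replicates is required")
  mb <- mean(blanks); sb <- stats::sd(blanks)
  if (length(blanks) == 1) sb <- 0
  lob <- mb + 1.645 * sb
  # pooled low-level SD: variance pooled over pools weighted by df
  dfs <- lengths(low_pools) - 1
  vars <- vapply(low_pools, stats::var, numeric(1))
  sd_low <- sqrt(sum(dfs * vars) / sum(dfs))
  lod <- lob + 1.645 * sd_low
  loq <- NA_real_
  loq_reached <- FALSE
  levels_tbl <- NULL
  if (!is.null(dilution_series) && nrow(dilution_series) > 0) {
    stopifnot(all(c("level", "value") %in% names(dilution_series)))
    levels_tbl <- dilution_series |>
      dplyr::group_by(.data$level) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                       cv_pct = 100 * stats::sd(.data$value) / mean(.data$value),
                       .groups = "drop") |>
      dplyr::arrange(.data$mean)
    ok <- levels_tbl$cv_pct <= cv_limit & levels_tbl$mean >= lod
    if (any(ok)) {
      loq <- levels_tbl$mean[which(ok)[1]]
      loq_reached <- TRUE
    }
  }
  structure(list(lob = lob, lod = lod, loq = loq, loq_reached = loq_reached,
                 inputs = list(n_blank = length(blanks), mean_blank = mb,
                               sd_blank = sb, sd_low = sd_low,
                               cv_limit = cv_limit, levels = levels_tbl)),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> LOB %.2f, LOD %.2f, LOQ %s mg/dL\n",
              x$lob, x$lod,
              if (x$loq_reached) sprintf("%.2f", x$loq) else "not reached"))
  invisible(x)
}

#' Non-weighted Deming regression
#'
#' Errors-in-both-variables fit with error-variance ratio fixed at 1:
#' `slope = (S_yy - S_xx + sqrt((S_yy - S_xx)^2 + 4 S_xy^2)) / (2 S_xy)`,
#' `intercept = ybar - slope * xbar`, reported with the Pearson
#' correlation. Used for method-comparison studies where both assays carry
#' measurement error.
#'
#' @param x Comparator (reference-method) values.
#' @param y Test-method values.
#' @return A list of class `deming_fit`: `slope`, `intercept`, `pearson_r`,
#'   `n`, `lambda`, and the data (`x`, `y`).
#' @export
deming_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    abort_domain("Deming regression needs >= 3 paired values")
  if (stats::sd(x) == 0)
    rlang::abort("comparator values have zero variance",
                 class = "nmrelp_degenerate_error")
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- if (sxy == 0) {
    # no covariance: the lambda = 1 orthogonal fit degenerates; slope sign
    # is undefined, report 0 only when y is constant
    if (syy == 0) 0 else abort_domain("x and y are uncorrelated; Deming slope undefined")
  } else {
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  structure(list(slope = slope, intercept = mean(y) - slope * mean(x),
                 pearson_r = if (stats::sd(y) > 0) stats::cor(x, y) else NA_real_,
                 n = length(x), lambda = 1, x = x, y = y),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("<deming_fit> n=%d: y = %.4f x + %.4f (r = %.4f)\n",
              x$n, x$slope, x$intercept, x$pearson_r))
  invisible(x)
}

#' Linearity evaluation over mixed pools
#'
#' Serial mixtures of a low and a high pool have expected value
#' `(1 - f) * low + f * high` at high-pool fraction `f`. Measured means are
#' regressed on expected values (first-order fit) and per-mixture percent
#' deviations reported against a configurable limit.
#'
#' @param mixtures Data frame with columns `fraction_high` (0..1) and
#'   `value` (replicate measurements; several rows per mixture allowed).
#' @param low_value,high_value Endpoint pool values (mg/dL).
#' @param deviation_limit Percent deviation considered acceptable (default 10).
#' @return A list of class `linearity_result`: per-mixture tibble
#'   (`fraction_high`, `expected`, `measured`, `deviation_pct`, `flagged`),
#'   `slope`, `intercept`, `r_squared`, `max_abs_deviation_pct`.
#' @export
linearity_eval <- function(mixtures, low_value, high_value,
                           deviation_limit = 10) {
  stopifnot(is.data.frame(mixtures),
            all(c("fraction_high", "value") %in% names(mixtures)))
  if (nrow(mixtures) == 0) abort_domain("no mixtures supplied")
  if (any(mixtures$fraction_high < 0 | mixtures$fraction_high > 1))
    abort_domain("fraction_high must lie in [0, 1]")
  per <- mixtures |>
    dplyr::group_by(.data$fraction_high) |>
    dplyr::summarise(measured = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(expected = (1 - .data$fraction_high) * low_value +
                    .data$fraction_high * high_value,
                  deviation_pct = 100 * (.data$measured - .data$expected) /
                    .data$expected,
                  flagged = abs(.data$deviation_pct) > deviation_limit) |>
    dplyr::select("fraction_high", "expected", "measured",
                  "deviation_pct", "flagged")
  fit <- stats::lm(measured ~ expected, data = per)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((per$measured - mean(per$measured))^2)
  structure(list(mixtures = per,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 max_abs_deviation_pct = max(abs(per$deviation_pct)),
                 deviation_limit = deviation_limit),
            class = "linearity_result")
}

#' Percent bias against a target value
#'
#' `100 * (measured - target) / target`, the convention used for reference
#' material and standardization-program comparisons; displays to one
#' decimal.
#'
#' @param measured,target Values in mg/dL (vectorized); `target != 0`.
#' @return Percent bias (unrounded).
#' @export
percent_bias <- function(measured, target) {
  if (any(target == 0)) abort_domain("target must be nonzero")
  100 * (measured - target) / target
}

#' Mean absolute percent bias over a set of records
#'
#' @param records Data frame with columns `measured` and `target` (mg/dL),
#'   e.g. quarterly standardization-program pools.
#' @return Mean of `|percent_bias|` (unrounded; display to one decimal).
#' @export
mean_absolute_bias <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("measured", "target") %in% names(records)))
  if (nrow(records) == 0) abort_domain("no bias records supplied")
  mean(abs(percent_bias(records$measured, records$target)))
}

#' Interference evaluation
#'
#' Percent change of the spiked-sample mean relative to the control mean; a
#' substance interferes when the absolute change exceeds 10% (strictly).
#'
#' @param control,test Replicate values without / with the candidate
#'   interferent.
#' @param limit Flagging threshold in percent (default 10, strict).
#' @return A list with `percent_change` and `flagged`.
#' @export
interference_eval <- function(control, test, limit = 10) {
  if (length(control) == 0 || length(test) == 0)
    abort_domain("control and test replicates are both required")
  if (mean(control) == 0) abort_domain("control mean must be nonzero")
  change <- 100 * (mean(test) - mean(control)) / mean(control)
  list(percent_change = change, flagged = abs(change) > limit)
}

#' Stability evaluation against a baseline
#'
#' Percent difference of each timepoint mean from the baseline (day 0)
#' mean; acceptable when within +/- 10% inclusive.
#'
#' @param baseline Baseline mean (mg/dL), nonzero.
#' @param timepoints Data frame with columns `label` and `mean`.
#' @param limit Acceptability band in percent (default 10, inclusive).
#' @return A tibble with `label`, `mean`, `diff_pct`, `acceptable`.
#' @export
stability_eval <- function(baseline, timepoints, limit = 10) {
  if (baseline == 0) abort_domain("baseline must be nonzero")
  stopifnot(is.data.frame(timepoints),
            all(c("label", "mean") %in% names(timepoints)))
  timepoints |>
    dplyr::mutate(diff_pct = 100 * (.data$mean - baseline) / baseline,
                  acceptable = abs(.data$diff_pct) <= limit) |>
    tibble::as_tibble()
}

#' Collection-tube comparison against the reference tube
#'
#' Ordinary least-squares fit of the test tube's results on the reference
#' tube's (paired specimens), with 95% confidence intervals on slope and
#' intercept. The comparison is flagged when the slope deviates from 1 by
#' more than `slope_tol` or the mean proportional difference exceeds
#' `bias_limit` percent.
#'
#' @param reference_tube,test_tube Paired analyte values (same specimens).
#' @param slope_tol Allowed slope deviation from unity (default 0.10).
#' @param bias_limit Allowed mean proportional difference, percent
#'   (default 10).
#' @return A list of class `tube_comparison`: `slope`, `intercept`,
#'   `r_squared`, `slope_ci`, `intercept_ci`, `mean_bias_pct`, `flagged`.
#' @export
tube_comparison <- function(reference_tube, test_tube,
                            slope_tol = 0.10, bias_limit = 10) {
  if (length(reference_tube) != length(test_tube) || length(reference_tube) < 3)
    abort_domain("tube comparison needs >= 3 paired values")
  if (stats::sd(reference_tube) == 0)
    rlang::abort("reference tube values have zero variance",
                 class = "nmrelp_degenerate_error")
  fit <- stats::lm(test_tube ~ reference_tube)
  ci <- suppressWarnings(stats::confint(fit))
  slope <- unname(stats::coef(fit)[2])
  mean_bias <- mean(100 * (test_tube - reference_tube) / reference_tube)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((test_tube - mean(test_tube))^2)
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    slope_ci = unname(ci[2, ]),
    intercept_ci = unname(ci[1, ]),
    mean_bias_pct = mean_bias,
    flagged = abs(slope - 1) > slope_tol || abs(mean_bias) > bias_limit,
    n = length(reference_tube)
  ), class = "tube_comparison")
}

#' @export
print.tube_comparison <- function(x, ...) {
  cat(sprintf(
    "<tube_comparison> n=%d: slope %.3f [%.3f, %.3f], R2 %.4f, mean bias %.1f%%%s\n",
    x$n, x$slope, x$slope_ci[1], x$slope_ci[2], x$r_squared, x$mean_bias_pct,
    if (x$flagged) " FLAGGED" else ""))
  invisible(x)
}
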