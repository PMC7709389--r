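#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the regression vector of a PLS calibration
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return A tibble with one row per spectral variable: `index`, `ppm`
#'   (when the model lives on the canonical 1600-point grid), `coefficient`.
#' @method tidy pls_model
#' @export
tidy.pls_model <- function(x, ...) {
  p <- length(x$b)
  out <- tibble::tibble(index = seq_len(p), coefficient = x$b)
  if (p == 1600L) out <- tibble::add_column(out, ppm = elp_grid(), .after = "index")
  out
}

#' One-row summary of a PLS calibration
#'
#' `cv_cv_pct` is the coefficient of variation of cross-validation,
#' 100 * RMSE_CV / mean training concentration.
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return A one-row tibble: `analyte`, `a`, `n_used`,
#'   `n_outliers_removed`, `rmse_cv`, `cv_cv_pct`, `r_train`, `y_mean`.
#' @method glance pls_model
#' @export
glance.pls_model <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    analyte = x$analyte, a = x$a, n_used = d$n_used,
    n_outliers_removed = d$n_outliers_removed,
    rmse_cv = d$rmse_cv,
    cv_cv_pct = 100 * d$rmse_cv / x$y_mean,
    r_train = d$r_train, y_mean = x$y_mean
  )
}

#' @rdname deming_fit
#' @param x A `deming_fit`.
#' @param ... Unused.
#' @method tidy deming_fit
#' @export
tidy.deming_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname deming_fit
#' @method glance deming_fit
#' @export
glance.deming_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 pearson_r = x$pearson_r, n = x$n, lambda = x$lambda)
}

#' Plot an RMSE_CV curve
#'
#' @param object A [loocv_curve()] result.
#' @param ... Unused.
#' @method autoplot cv_curve
#' @export
autoplot.cv_curve <- function(object, ...) {
  a_star <- object$a[which.min(object$rmse_cv)]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$a, y = .data$rmse_cv)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = a_star, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "latent variables", y = "RMSE_CV (mg/dL)",
                  title = attr(object, "analyte"),
                  subtitle = sprintf("selected A = %d", a_star)) +
    ggplot2::theme_minimal()
}

#' Plot training agreement of a PLS calibration
#'
#' @param object A `pls_model`.
#' @param ... Unused.
#' @method autoplot pls_model
#' @export
autoplot.pls_model <- function(object, ...) {
  df <- tibble::tibble(reference = object$y, predicted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "reference (mg/dL)", y = "NMR-predicted (mg/dL)",
                  title = sprintf("%s calibration (R = %.3f)", object$analyte,
                                  object$diagnostics$r_train)) +
    ggplot2::theme_minimal()
}

#' Plot a Deming method-comparison fit
#'
#' @param object A `deming_fit`.
#' @param ... Unused.
#' @method autoplot deming_fit
#' @export
autoplot.deming_fit <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(x = "comparator (mg/dL)", y = "test method (mg/dL)",
                  subtitle = sprintf("Deming slope %.3f, intercept %.1f, r %.3f",
                                     object$slope, object$intercept,
                                     object$pearson_r)) +
    ggplot2::theme_minimal()
}
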