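#' Reportable ranges of the extended lipid panel
#'
#' The clinically reportable interval per analyte (mg/dL); predictions
#' outside it are censored to `"<low"` / `">high"` display strings. Derived
#' LDL-C and non-HDL-C have no published bounds and are reported uncensored
#' (but suppressed when any input analyte is censored).
#'
#' @return A tibble with columns `analyte`, `lower`, `upper`.
#' @export
reportable_ranges <- function() {
  tibble::tibble(
    analyte = c("TC", "TG", "HDLC", "APOB"),
    lower = c(66, 35, 14, 35),
    upper = c(868, 950, 152, 366)
  )
}

# constants of the NIH (Sampson) LDL-C equation
LDL_CONSTANTS <- list(tc_div = 0.948, hdl_div = 0.971, tg_div = 8.56,
                      cross_div = 2140, tg_sq_div = 16100, offset = 9.44)

# one-decimal rounding, half away from zero (R's round() is half-to-even)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' LDL cholesterol by the NIH (Sampson) equation
#'
#' `TC/0.948 - HDL-C/0.971 - (TG/8.56 + TG * nonHDL-C/2140 - TG^2/16100)
#' - 9.44`, with non-HDL-C = TC - HDL-C. The unrounded value is returned;
#' displays round to one decimal (half away from zero). Triglycerides above
#' 800 mg/dL exceed the equation's published validation range and trigger a
#' warning.
#'
#' @param tc,tg,hdl_c Total cholesterol, triglycerides and HDL cholesterol
#'   in mg/dL (`tc >= hdl_c >= 0`, `tg >= 0`); vectorized.
#' @return Estimated LDL-C in mg/dL (unrounded).
#' @export
#' @examples
#' round(compute_ldl_c(243.0, 139.7, 66.3), 1)  # 152.0
compute_ldl_c <- function(tc, tg, hdl_c) {
  if (any(!is.finite(tc) | !is.finite(tg) | !is.finite(hdl_c)))
    abort_domain("LDL-C inputs must be finite")
  if (any(hdl_c < 0) || any(tc < hdl_c) || any(tg < 0))
    abort_domain("LDL-C needs tc >= hdl_c >= 0 and tg >= 0")
  if (any(tg > 800))
    rlang::warn("TG > 800 mg/dL is outside the LDL-C equation's validated range")
  k <- LDL_CONSTANTS
  non_hdl <- tc - hdl_c
  tc / k$tc_div - hdl_c / k$hdl_div -
    (tg / k$tg_div + tg * non_hdl / k$cross_div - tg^2 / k$tg_sq_div) -
    k$offset
}

#' Choose the HDL-C model from the predicted triglyceride level
#'
#' Model 1 serves normal-triglyceride samples (TG < threshold), model 2 the
#' hypertriglyceridemic ones (TG >= threshold, default 250 mg/dL). Routing
#' always uses the uncensored TG prediction.
#'
#' @param predicted_tg PLS-predicted TG (mg/dL).
#' @param bundle A [model_bundle()] (only the threshold is used); may be
#'   omitted.
#' @return `1L` or `2L` (vectorized).
#' @export
route_hdl_model <- function(predicted_tg, bundle = NULL) {
  thr <- if (is.null(bundle)) 250 else bundle$tg_routing_threshold
  if (any(!is.finite(predicted_tg))) abort_domain("predicted TG must be finite")
  ifelse(predicted_tg >= thr, 2L, 1L)
}

#' Bundle the five calibration models of the extended lipid panel
#'
#' @param tc,tg,apob `pls_model`s for total cholesterol, triglycerides and
#'   apolipoprotein B.
#' @param hdl1 HDL-C model trained on normal-TG samples (TG < threshold).
#' @param hdl2 HDL-C model trained on high-TG samples (TG >= threshold).
#' @param tg_routing_threshold Routing threshold, mg/dL (default 250).
#' @param version Free-text bundle version string.
#' @return A list of class `elp_bundle`.
#' @export
model_bundle <- function(tc, tg, hdl1, hdl2, apob,
                         tg_routing_threshold = 250,
                         version = "0.1.0") {
  models <- list(tc = tc, tg = tg, hdl1 = hdl1, hdl2 = hdl2, apob = apob)
  if (tg_routing_threshold <= 0) abort_domain("routing threshold must be positive")
  p <- unique(vapply(models, function(m) length(m$x_mean), integer(1)))
  if (length(p) != 1)
    abort_domain("all five models must share one spectral grid")
  structure(c(models, list(tg_routing_threshold = tg_routing_threshold,
                           version = version)),
            class = "elp_bundle")
}

#' @export
print.elp_bundle <- function(x, ...) {
  cat(sprintf("<elp_bundle> v%s, routing at TG >= %g mg/dL\n",
              x$version, x$tg_routing_threshold))
  for (nm in c("tc", "tg", "hdl1", "hdl2", "apob")) print(x[[nm]])
  invisible(x)
}

#' Apply the reportable range to one analyte value
#'
#' Values below the lower bound (including negative predictions) censor to
#' `"<lower"`, above the upper bound to `">upper"`; in-range values display
#' with one decimal (half away from zero).
#'
#' @param value Measured/predicted concentration (mg/dL).
#' @param analyte `"TC"`, `"TG"`, `"HDLC"` or `"APOB"`.
#' @return A list with `flag` (`"in_range"`, `"below"`, `"above"`) and
#'   `display` (string).
#' @export
apply_reportable_range <- function(value, analyte) {
  if (!is.finite(value)) abort_domain("value must be finite")
  rr <- reportable_ranges()
  row <- rr[rr$analyte == analyte, ]
  if (nrow(row) != 1)
    abort_domain(sprintf("no reportable range for analyte '%s'", analyte))
  if (value < row$lower) {
    list(flag = "below", display = sprintf("<%g", row$lower))
  } else if (value > row$upper) {
    list(flag = "above", display = sprintf(">%g", row$upper))
  } else {
    list(flag = "in_range", display = sprintf("%.1f", round_half_up(value)))
  }
}

#' Predict the extended lipid panel for spectra
#'
#' TC, TG and apoB come from their own models; HDL-C from the model selected
#' by [route_hdl_model()] on the uncensored TG prediction. Non-HDL-C
#' (TC - HDL-C) and NIH-equation LDL-C derive from the unrounded, uncensored
#' predictions and are suppressed (NA, with the reason in `ldl_c_note`) when
#' any input analyte is censored. Censoring follows [reportable_ranges()].
#'
#' @param bundle An [model_bundle()].
#' @param x A feature vector, `elp_spectrum`, matrix of feature rows, or a
#'   list of spectra.
#' @param sample_ids Optional identifiers for the report rows.
#' @return A tibble of class `elp_result`: one row per spectrum with
#'   numeric `tc`, `tg`, `hdl_c`, `apob`, `non_hdl_c`, `ldl_c` (censored
#'   analytes NA), display strings `*_display`, per-analyte flags
#'   `*_flag`, `hdl_model_used`, and `ldl_c_note`.
#' @export
predict_elp <- function(bundle, x, sample_ids = NULL) {
  stopifnot(inherits(bundle, "elp_bundle"))
  X <- newdata_matrix(x, length(bundle$tc$x_mean))
  n <- nrow(X)
  if (is.null(sample_ids)) {
    sample_ids <- if (inherits(x, "elp_spectrum")) attr(x, "sample_id")
    else if (is.list(x) && !is.data.frame(x))
      vapply(x, function(s) {
        sid <- attr(s, "sample_id"); if (is.null(sid)) NA_character_ else sid
      }, character(1))
    else rownames(x)
  }
  if (is.null(sample_ids) || !length(sample_ids))
    sample_ids <- sprintf("S%04d", seq_len(n))
  tc_raw <- predict(bundle$tc, X)
  tg_raw <- predict(bundle$tg, X)
  apob_raw <- predict(bundle$apob, X)
  route <- route_hdl_model(tg_raw, bundle)
  hdl_raw <- ifelse(route == 1L, predict(bundle$hdl1, X), predict(bundle$hdl2, X))

  cens <- function(values, analyte) {
    res <- lapply(values, apply_reportable_range, analyte = analyte)
    list(flag = vapply(res, `[[`, character(1), "flag"),
         display = vapply(res, `[[`, character(1), "display"))
  }
  c_tc <- cens(tc_raw, "TC"); c_tg <- cens(tg_raw, "TG")
  c_hdl <- cens(hdl_raw, "HDLC"); c_apob <- cens(apob_raw, "APOB")

  inputs_ok <- c_tc$flag == "in_range" & c_tg$flag == "in_range" &
    c_hdl$flag == "in_range"
  non_hdl <- ifelse(c_tc$flag == "in_range" & c_hdl$flag == "in_range",
                    tc_raw - hdl_raw, NA_real_)
  ldl <- rep(NA_real_, n)
  note <- rep(NA_character_, n)
  for (i in which(inputs_ok)) {
    if (hdl_raw[i] < 0 || tc_raw[i] < hdl_raw[i] || tg_raw[i] < 0) {
      note[i] <- "LDL-C suppressed: predictions violate TC >= HDL-C >= 0"
    } else {
      ldl[i] <- withCallingHandlers(
        compute_ldl_c(tc_raw[i], tg_raw[i], hdl_raw[i]),
        warning = function(w) {
          note[i] <<- conditionMessage(w)
          invokeRestart("muffleWarning")
        })
    }
  }
  note[!inputs_ok] <- "LDL-C suppressed: input analyte outside reportable range"

  masked <- function(raw, flag) ifelse(flag == "in_range", raw, NA_real_)
  out <- tibble::tibble(
    sample_id = as.character(sample_ids),
    tc = masked(tc_raw, c_tc$flag),
    tg = masked(tg_raw, c_tg$flag),
    hdl_c = masked(hdl_raw, c_hdl$flag),
    apob = masked(apob_raw, c_apob$flag),
    non_hdl_c = non_hdl,
    ldl_c = ldl,
    tc_flag = c_tc$flag, tg_flag = c_tg$flag,
    hdl_c_flag = c_hdl$flag, apob_flag = c_apob$flag,
    tc_display = c_tc$display, tg_display = c_tg$display,
    hdl_c_display = c_hdl$display, apob_display = c_apob$display,
    non_hdl_c_display = ifelse(is.na(non_hdl), NA_character_,
                               sprintf("%.1f", round_half_up(non_hdl))),
    ldl_c_display = ifelse(is.na(ldl), NA_character_,
                           sprintf("%.1f", round_half_up(ldl))),
    hdl_model_used = route,
    ldl_c_note = note
  )
  class(out) <- c("elp_result", class(out))
  out
}

#' Audit HDL-C routing continuity near the threshold
#'
#' For samples whose predicted TG falls within `band` of the routing
#' threshold, computes both HDL-C models' predictions and their absolute
#' difference — a diagnostic of the discontinuity introduced by hard
#' routing, not an acceptance rule.
#'
#' @param bundle An [model_bundle()].
#' @param x Spectra (as in [predict_elp()]).
#' @param band Half-width of the TG window around the threshold (mg/dL).
#' @return A tibble with `sample_id`, `predicted_tg`, `hdl_model_1`,
#'   `hdl_model_2`, `abs_difference` for the in-band samples.
#' @export
routing_audit <- function(bundle, x, band = 2) {
  stopifnot(inherits(bundle, "elp_bundle"))
  X <- newdata_matrix(x, length(bundle$tc$x_mean))
  tg_raw <- predict(bundle$tg, X)
  sel <- abs(tg_raw - bundle$tg_routing_threshold) <= band
  h1 <- predict(bundle$hdl1, X[sel, , drop = FALSE])
  h2 <- predict(bundle$hdl2, X[sel, , drop = FALSE])
  tibble::tibble(
    sample_id = sprintf("S%04d", which(sel)),
    predicted_tg = tg_raw[sel],
    hdl_model_1 = h1, hdl_model_2 = h2,
    abs_difference = abs(h1 - h2)
  )
}
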