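SERIAL_VERSION <- "1"

pls_model_to_list <- function(model) {
  d <- model$diagnostics
  list(
    format = "nmrelp/pls_model",
    format_version = SERIAL_VERSION,
    analyte = model$analyte,
    a = model$a,
    x_mean = model$x_mean,
    y_mean = model$y_mean,
    b = model$b,
    diagnostics = list(
      n_used = d$n_used,
      n_outliers_removed = d$n_outliers_removed,
      rmse_cv = d$rmse_cv,
      r_train = d$r_train,
      rmse_cv_curve = if (is.null(d$rmse_cv_curve)) NULL else
        list(a = d$rmse_cv_curve$a, rmse_cv = d$rmse_cv_curve$rmse_cv)
    )
  )
}

pls_model_from_list <- function(x) {
  if (!identical(x$format, "nmrelp/pls_model"))
    abort_parse("not a serialized PLS calibration model")
  d <- x$diagnostics
  curve <- NULL
  if (!is.null(d$rmse_cv_curve)) {
    curve <- tibble::tibble(a = as.integer(unlist(d$rmse_cv_curve$a)),
                            rmse_cv = as.numeric(unlist(d$rmse_cv_curve$rmse_cv)))
    class(curve) <- c("cv_curve", class(curve))
  }
  structure(list(
    analyte = x$analyte,
    a = as.integer(x$a),
    x_mean = as.numeric(unlist(x$x_mean)),
    y_mean = as.numeric(x$y_mean),
    b = as.numeric(unlist(x$b)),
    diagnostics = list(
      n_used = as.integer(d$n_used),
      n_outliers_removed = as.integer(d$n_outliers_removed),
      rmse_cv = if (is.null(d$rmse_cv)) NA_real_ else as.numeric(d$rmse_cv),
      r_train = if (is.null(d$r_train)) NA_real_ else as.numeric(d$r_train),
      rmse_cv_curve = curve
    )
  ), class = "pls_model")
}

#' Serialize calibration models as versioned JSON
#'
#' Models are stored as explicit numeric arrays (`x_mean`, `b`, `y_mean`,
#' component count and diagnostics) rather than an opaque binary image, so
#' bundles diff cleanly and port across languages. The deserialized model
#' predicts identically; training internals (scores, weights) are not
#' persisted.
#'
#' @param model A `pls_model`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  jsonlite::write_json(pls_model_to_list(model), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  pls_model_from_list(jsonlite::read_json(path))
}

#' @rdname write_pls_model
#' @param bundle An [model_bundle()].
#' @export
write_model_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "elp_bundle"))
  obj <- list(
    format = "nmrelp/bundle",
    format_version = SERIAL_VERSION,
    version = bundle$version,
    tg_routing_threshold = bundle$tg_routing_threshold,
    models = lapply(bundle[c("tc", "tg", "hdl1", "hdl2", "apob")],
                    pls_model_to_list)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_model_bundle <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "nmrelp/bundle"))
    abort_parse("not a serialized ELP model bundle")
  m <- lapply(obj$models, pls_model_from_list)
  model_bundle(tc = m$tc, tg = m$tg, hdl1 = m$hdl1, hdl2 = m$hdl2,
               apob = m$apob,
               tg_routing_threshold = as.numeric(obj$tg_routing_threshold),
               version = obj$version)
}
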