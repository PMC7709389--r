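ANALYTES <- c("TC", "TG", "HDLC", "APOB")

#' Assemble a PLS training set
#'
#' @param X Numeric matrix of spectra rows (one feature vector per sample;
#'   1600 columns for the canonical analysis region, though any width is
#'   accepted for small constructed problems).
#' @param y Reference analyte concentrations (mg/dL), one per row of `X`.
#' @param analyte One of `"TC"`, `"TG"`, `"HDLC"`, `"APOB"`.
#' @param sample_ids Optional identifiers; defaults to rownames of `X`.
#' @return A list of class `elp_training_set`.
#' @export
training_set <- function(X, y, analyte = c("TC", "TG", "HDLC", "APOB"),
                         sample_ids = NULL) {
  analyte <- match.arg(analyte)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) abort_domain("nrow(X) must equal length(y)")
  if (nrow(X) < 3L) abort_domain("a training set needs at least 3 samples")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    abort_domain("training data must be finite")
  if (any(y < 0)) abort_domain("reference concentrations must be nonnegative")
  if (is.null(sample_ids)) sample_ids <- rownames(X)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(nrow(X)))
  structure(list(X = unname(X), y = y, analyte = analyte,
                 sample_ids = as.character(sample_ids)),
            class = "elp_training_set")
}

#' @export
print.elp_training_set <- function(x, ...) {
  cat(sprintf("<elp_training_set> %s: n=%d, p=%d, y range %.1f-%.1f mg/dL\n",
              x$analyte, nrow(x$X), ncol(x$X), min(x$y), max(x$y)))
  invisible(x)
}

# NIPALS decomposition for a single response on centered data.
# PLS1 weights are non-iterative: w_a = X'y / |X'y|. Returns the weights,
# loadings and regression pieces for the nested 1..A models.
nipals_pls1 <- function(Xc, yc, A, tol = 1e-24) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A)
  scale0 <- sum(Xc^2) * sum(yc^2)
  a_done <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw^2 <= tol * max(scale0, 1)) break
    w <- w / nw
    t_ <- Xc %*% w
    # re-orthogonalize against earlier scores: a no-op in exact arithmetic
    # that keeps high component counts numerically faithful
    if (a_done > 0) {
      Tp <- Tm[, seq_len(a_done), drop = FALSE]
      t_ <- t_ - Tp %*% (crossprod(Tp, t_) / colSums(Tp^2))
    }
    tt <- sum(t_^2)
    if (tt <= tol * max(sum(Xc^2), 1)) break
    p_ <- crossprod(Xc, t_) / tt
    q_ <- sum(t_ * yc) / tt
    Xc <- Xc - tcrossprod(t_, p_)
    yc <- yc - t_ * q_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; q[a] <- q_
    a_done <- a
  }
  list(W = W[, seq_len(a_done), drop = FALSE],
       P = P[, seq_len(a_done), drop = FALSE],
       T = Tm[, seq_len(a_done), drop = FALSE],
       q = q[seq_len(a_done)], A = a_done)
}

# nested predictions of new rows for models with 1..A components
nipals_predict_nested <- function(dec, Xnew_c) {
  m <- nrow(Xnew_c)
  preds <- matrix(0, m, dec$A)
  acc <- rep(0, m)
  Xd <- Xnew_c
  for (a in seq_len(dec$A)) {
    t_ <- Xd %*% dec$W[, a, drop = FALSE]
    acc <- acc + as.numeric(t_) * dec$q[a]
    Xd <- Xd - tcrossprod(t_, dec$P[, a, drop = FALSE])
    preds[, a] <- acc
  }
  preds
}

#' Fit a PLS1 calibration model
#'
#' Mean-centered NIPALS decomposition with `A` latent variables (no
#' per-variable scaling: spectral variables share units). Successive score
#' vectors are mutually orthogonal and the returned regression vector `b`
#' reproduces the fitted values of the A-component model.
#'
#' @param ts An [training_set()].
#' @param A Number of latent variables, `1 <= A <= min(n-1, p)`.
#' @return An object of class `pls_model` with elements `analyte`, `a`
#'   (components used), `x_mean`, `y_mean`, `b`, scores `T`, weights `W`,
#'   loadings `P`, y-loadings `q`, and a `diagnostics` list.
#' @export
fit_pls1 <- function(ts, A) {
  stopifnot(inherits(ts, "elp_training_set"))
  n <- nrow(ts$X); p <- ncol(ts$X)
  if (A < 1 || A > min(n - 1, p))
    abort_domain(sprintf("A must lie in 1..min(n-1, p) = 1..%d", min(n - 1, p)))
  if (stats::sd(ts$y) == 0)
    rlang::abort("response has zero variance; calibration is degenerate",
                 class = "nmrelp_degenerate_error")
  x_mean <- colMeans(ts$X)
  y_mean <- mean(ts$y)
  Xc <- sweep(ts$X, 2, x_mean)
  dec <- nipals_pls1(Xc, ts$y - y_mean, A)
  if (dec$A < 1)
    rlang::abort("predictors have zero variance; calibration is degenerate",
                 class = "nmrelp_degenerate_error")
  # b = W (P'W)^{-1} q gives the direct regression form of the nested model
  b <- dec$W %*% solve(crossprod(dec$P, dec$W), dec$q)
  fitted <- y_mean + as.numeric(Xc %*% b)
  mod <- structure(list(
    analyte = ts$analyte,
    a = dec$A,
    x_mean = x_mean,
    y_mean = y_mean,
    b = as.numeric(b),
    W = dec$W, P = dec$P, T = dec$T, q = dec$q,
    fitted = fitted,
    sample_ids = ts$sample_ids,
    y = ts$y,
    diagnostics = list(
      n_used = n,
      n_outliers_removed = 0L,
      rmse_cv_curve = NULL,
      rmse_cv = NA_real_,
      r_train = stats::cor(fitted, ts$y)
    )
  ), class = "pls_model")
  mod
}

#' @export
print.pls_model <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "<pls_model> %s: %d latent variables, n=%d (%d outliers removed), R=%.4f%s\n",
    x$analyte, x$a, d$n_used, d$n_outliers_removed, d$r_train,
    if (is.na(d$rmse_cv)) "" else sprintf(", RMSE_CV=%.2f mg/dL", d$rmse_cv)))
  invisible(x)
}

#' Predict analyte concentration from a spectrum
#'
#' `y_mean + (x - x_mean) . b`: predicting the training mean spectrum
#' returns exactly the training mean concentration.
#'
#' @param object A `pls_model`.
#' @param newdata A feature vector (length matching the model), an
#'   `elp_spectrum` (the canonical region is extracted first), a list of
#'   either, or a matrix with one row per sample.
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations (mg/dL).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- newdata_matrix(newdata, length(object$x_mean))
  as.numeric(object$y_mean + sweep(X, 2, object$x_mean) %*% object$b)
}

newdata_matrix <- function(newdata, p) {
  if (inherits(newdata, "elp_spectrum")) newdata <- extract_region(newdata)
  if (is.list(newdata) && !is.data.frame(newdata))
    return(do.call(rbind, lapply(newdata, function(s) newdata_matrix(s, p))))
  if (is.matrix(newdata)) {
    if (ncol(newdata) != p) abort_domain(
      sprintf("spectrum has %d points but the model grid has %d", ncol(newdata), p))
    return(unname(newdata))
  }
  x <- as.numeric(newdata)
  if (length(x) != p)
    abort_domain(sprintf("spectrum has %d points but the model grid has %d",
                         length(x), p))
  matrix(x, nrow = 1)
}

#' Root mean square error of cross-validation
#'
#' `sqrt(mean((e - p)^2))` between reference (chemically measured) and
#' cross-validation-predicted concentrations.
#'
#' @param e Reference values (mg/dL).
#' @param p Predicted values (mg/dL).
#' @return RMSE in mg/dL.
#' @export
rmse_cv <- function(e, p) {
  if (length(e) == 0 || length(e) != length(p))
    abort_domain("`e` and `p` must be non-empty and of equal length")
  sqrt(mean((e - p)^2))
}

#' Leave-one-out cross-validation curve
#'
#' For every left-out sample a mean-centered PLS1 model is fitted on the
#' remaining n-1 spectra and the held-out concentration predicted for each
#' component count 1..A_max (one decomposition per fold serves all A:
#' NIPALS component sequences are nested, so this equals refitting at each A
#' separately). The per-A RMSE_CV values are assembled with [rmse_cv()].
#'
#' The default `"fast"` method advances all folds together in
#' sample (kernel) space — PLS1 with response-only deflation and the weight
#' recursion that makes scores computable from the undeflated data — so each
#' component costs two matrix products on the n x n Gram matrix instead of n
#' separate NIPALS runs. It is algebraically identical to the `"per_fold"`
#' primal NIPALS path, which is retained as the reference implementation.
#'
#' @param ts An [training_set()].
#' @param A_max Largest number of latent variables to evaluate
#'   (`A_max <= n - 2`).
#' @param method `"fast"` (batched, default) or `"per_fold"` (one primal
#'   NIPALS decomposition per left-out sample).
#' @return A tibble of class `cv_curve` with columns `a`, `rmse_cv` and
#'   attributes `n`, `analyte`, `predictions` (n x A_max matrix of LOO
#'   predictions).
#' @export
loocv_curve <- function(ts, A_max, method = c("fast", "per_fold")) {
  stopifnot(inherits(ts, "elp_training_set"))
  method <- match.arg(method)
  n <- nrow(ts$X)
  if (A_max < 1 || A_max > n - 2)
    abort_domain(sprintf("A_max must lie in 1..n-2 = 1..%d", n - 2))
  preds <- if (method == "fast") loo_predictions_fast(ts$X, ts$y, A_max)
           else loo_predictions_per_fold(ts$X, ts$y, A_max)
  curve <- tibble::tibble(
    a = seq_len(A_max),
    rmse_cv = vapply(seq_len(A_max), function(a) rmse_cv(ts$y, preds[, a]),
                     numeric(1))
  )
  class(curve) <- c("cv_curve", class(curve))
  attr(curve, "n") <- n
  attr(curve, "analyte") <- ts$analyte
  attr(curve, "predictions") <- preds
  curve
}

loo_predictions_per_fold <- function(X, y, A_max) {
  n <- nrow(X)
  preds <- matrix(NA_real_, n, A_max)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    xm <- colMeans(Xi); ym <- mean(yi)
    dec <- nipals_pls1(sweep(Xi, 2, xm), yi - ym, A_max)
    pr <- ym + nipals_predict_nested(dec, matrix(X[i, ] - xm, nrow = 1))
    # components beyond the data rank add nothing: carry the last value
    if (dec$A < A_max)
      pr <- c(pr, rep(pr[length(pr)], A_max - dec$A))
    preds[i, ] <- pr
  }
  preds
}

# Batched dual-space LOO. All per-fold vectors live embedded in R^n with the
# left-out entry held at zero and the rest column-centered, so the centered
# fold kernel applied to any such vector is: zero entry i of K v, then
# re-center over the remaining entries. Response-only deflation plus the
# r-weight recursion (r_a = w_a - sum_j (p_j' w_a) r_j) keeps the Gram
# matrix fixed, so each component is two n x n matrix products shared by all
# folds.
loo_predictions_fast <- function(X, y, A_max, tol = 1e-24) {
  n <- nrow(X)
  K <- tcrossprod(X)
  ym <- (sum(y) - y) / (n - 1)               # per-fold training mean
  Ydef <- outer(y, rep(1, n)) - outer(rep(1, n), ym)
  diag(Ydef) <- 0
  # per-fold data scale for the degeneracy guard: sum of squares of the
  # centered fold predictors, from Gram-matrix identities
  dK <- diag(K); rs <- rowSums(K); tot <- sum(K)
  sumXc2 <- (sum(dK) - dK) - (tot - 2 * rs + dK) / (n - 1)
  sumYc2 <- colSums(Ydef^2)
  scale0 <- pmax(sumXc2 * sumYc2, 1)
  C_hist <- vector("list", A_max)
  T_hist <- vector("list", A_max)
  tt_hist <- matrix(0, A_max, n)
  alive <- rep(TRUE, n)
  acc <- rep(0, n)
  preds <- matrix(NA_real_, n, A_max)
  idx <- cbind(seq_len(n), seq_len(n))
  center_cols <- function(G) {
    G[idx] <- 0
    G <- sweep(G, 2, colSums(G) / (n - 1))
    G[idx] <- 0
    G
  }
  for (a in seq_len(A_max)) {
    G1 <- center_cols(K %*% Ydef)            # column i: Kc_(i) y_def
    nw2 <- colSums(Ydef * G1)
    dead_now <- !alive | nw2 <= tol * scale0
    nw <- sqrt(pmax(nw2, .Machine$double.xmin))
    Ca <- sweep(Ydef, 2, nw, `/`)
    if (a > 1) for (j in seq_len(a - 1)) {
      pw <- colSums(T_hist[[j]] * G1) / (tt_hist[j, ] * nw)
      pw[tt_hist[j, ] == 0] <- 0
      Ca <- Ca - sweep(C_hist[[j]], 2, pw, `*`)
    }
    Ca[, dead_now] <- 0
    G2 <- K %*% Ca                            # column i: K c_a (uncentered)
    d2 <- G2[idx]
    Ta <- center_cols(G2)
    m2 <- d2 - (colSums(G2) - d2) / (n - 1)   # score of the held-out sample
    # (colSums after zeroing diag happens inside center_cols; recompute here)
    tt <- colSums(Ta^2)
    dead_now <- dead_now | tt <= tol * pmax(sumXc2, 1)
    q <- ifelse(tt > 0, colSums(Ydef * Ta) / tt, 0)
    q[dead_now] <- 0
    Ta[, dead_now] <- 0
    Ca[, dead_now] <- 0
    alive <- alive & !dead_now
    Ydef <- Ydef - sweep(Ta, 2, q, `*`)
    t_new <- m2
    t_new[!alive & q == 0] <- 0
    acc <- acc + q * t_new
    preds[, a] <- ym + acc
    C_hist[[a]] <- Ca; T_hist[[a]] <- Ta; tt_hist[a, ] <- tt
  }
  preds
}

#' Select the number of latent variables
#'
#' Global minimum of the RMSE_CV curve; ties break toward fewer components.
#' When the minimum sits at the end of a strictly decreasing curve a warning
#' notes that the search bound may be too small.
#'
#' @param curve A [loocv_curve()] result (or any tibble with `a`, `rmse_cv`).
#' @return The selected component count.
#' @export
select_latent_variables <- function(curve) {
  if (nrow(curve) == 0) abort_domain("empty cross-validation curve")
  a_star <- curve$a[which.min(curve$rmse_cv)]
  k <- nrow(curve)
  if (a_star == curve$a[k] && k > 1 && all(diff(curve$rmse_cv) < 0))
    rlang::warn(paste0("RMSE_CV still decreasing at A_max = ", curve$a[k],
                       "; the latent-variable search bound may be too small"))
  a_star
}

#' DFFITS influence diagnostics for a PLS calibration
#'
#' Influence is measured in latent-variable (score) space: the scores of the
#' A-component fit, plus an intercept, form the regression design. For each
#' training sample, `dffits_i = (yhat_i - yhat_(i),i) / (s_(i) sqrt(h_ii))`
#' with leverage `h_ii = 1/n + t_i (T'T)^{-1} t_i'` and `s_(i)` the deleted
#' residual scale. Samples with `|dffits| >` the threshold (default
#' `2 sqrt((A+1)/n)`, the conventional cutoff) are flagged as outliers.
#'
#' @param ts An [training_set()].
#' @param A Number of latent variables for the underlying fit.
#' @param threshold Flagging cutoff; default `2 sqrt((A+1)/n)`.
#' @return A tibble with columns `sample_id`, `dffits`, `leverage`,
#'   `s_deleted`, `flagged`, plus attributes `threshold` and `a`.
#' @export
dffits_diagnostics <- function(ts, A, threshold = NULL) {
  stopifnot(inherits(ts, "elp_training_set"))
  n <- nrow(ts$X)
  if (n <= A + 2)
    abort_domain("n must exceed A + 2 for deletion estimates")
  fit <- fit_pls1(ts, A)
  A_used <- fit$a
  D <- cbind(1, fit$T)
  h <- rowSums((D %*% solve(crossprod(D))) * D)
  e <- ts$y - fit$fitted
  sse <- sum(e^2)
  df_del <- n - A_used - 2
  s2_del <- pmax((sse - e^2 / (1 - h)) / df_del, 0)
  dffits <- ifelse(s2_del > 0,
                   e * sqrt(h) / (sqrt(s2_del) * (1 - h)),
                   0)
  # a perfectly interpolating fit has no influence signal
  if (sse <= 1e-12 * max(sum((ts$y - mean(ts$y))^2), 1)) dffits[] <- 0
  if (is.null(threshold)) threshold <- 2 * sqrt((A_used + 1) / n)
  if (threshold <= 0) abort_domain("DFFITS threshold must be positive")
  out <- tibble::tibble(
    sample_id = ts$sample_ids,
    dffits = as.numeric(dffits),
    leverage = as.numeric(h),
    s_deleted = sqrt(s2_del),
    flagged = abs(dffits) > threshold
  )
  attr(out, "threshold") <- threshold
  attr(out, "a") <- A_used
  out
}

#' Train a calibration model with LOOCV selection and outlier removal
#'
#' The full calibration pipeline: (1) leave-one-out RMSE_CV curve over
#' `1..A_max` components and selection of the minimizing count; (2) DFFITS
#' screening at the selected count and single-pass removal of flagged
#' samples (no re-screening); (3) a fresh LOOCV curve, component selection
#' and final NIPALS fit on the reduced set. Diagnostics (samples used,
#' outliers removed, final RMSE_CV curve and minimum, training correlation)
#' are recorded on the returned model.
#'
#' @param ts An [training_set()].
#' @param A_max Upper bound of the latent-variable search (default 40).
#' @param dffits_threshold Outlier cutoff passed to [dffits_diagnostics()].
#' @return A `pls_model`.
#' @export
train_calibration <- function(ts, A_max = 40, dffits_threshold = NULL) {
  stopifnot(inherits(ts, "elp_training_set"))
  n <- nrow(ts$X)
  A_hi <- min(A_max, n - 2, ncol(ts$X))
  curve0 <- loocv_curve(ts, A_hi)
  a0 <- select_latent_variables(curve0)
  diag0 <- dffits_diagnostics(ts, a0, threshold = dffits_threshold)
  keep <- !diag0$flagged
  n_out <- sum(!keep)
  if (sum(keep) < a0 + 3)
    rlang::abort(sprintf(
      "outlier removal left %d samples, too few for a %d-component model",
      sum(keep), a0), class = "nmrelp_training_error")
  ts2 <- if (n_out > 0)
    training_set(ts$X[keep, , drop = FALSE], ts$y[keep], ts$analyte,
                 ts$sample_ids[keep])
  else ts
  A_hi2 <- min(A_max, nrow(ts2$X) - 2, ncol(ts2$X))
  curve <- loocv_curve(ts2, A_hi2)
  a_star <- select_latent_variables(curve)
  mod <- fit_pls1(ts2, a_star)
  mod$diagnostics$n_outliers_removed <- n_out
  mod$diagnostics$outlier_ids <- ts$sample_ids[!keep]
  mod$diagnostics$rmse_cv_curve <- curve
  mod$diagnostics$rmse_cv <- min(curve$rmse_cv)
  mod$diagnostics$initial_a <- a0
  mod
}
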