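test_that("degenerate and out-of-range fits are rejected", {
  ts <- random_training_set(12, 6, 1)
  expect_error(fit_pls1(ts, 0), class = "nmrelp_domain_error")
  expect_error(fit_pls1(ts, 12), class = "nmrelp_domain_error")
  flat <- training_set(ts$X, rep(5, 12), "TC")
  expect_error(fit_pls1(flat, 2), class = "nmrelp_degenerate_error")
})

test_that("a rank-one factor structure is fit exactly with one component", {
  set.seed(3)
  n <- 18; p <- 12
  t0 <- rnorm(n); p0 <- rnorm(p)
  X <- outer(t0, p0)
  y <- 3 * t0 + 40
  ts <- training_set(X, y, "TC")
  m <- fit_pls1(ts, 1)
  expect_lt(max(abs(m$fitted - y)) / diff(range(y)), 1e-10)

  # a held-out point on the same factor predicts at its construction value
  t_new <- 0.73
  expect_equal(predict(m, t_new * p0), 3 * t_new + 40, tolerance = 1e-8)
})

test_that("full-rank PLS equals ordinary least squares", {
  set.seed(4)
  n <- 30; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X %*% rnorm(p)) + rnorm(n)
  y <- y - min(y) + 10
  ts <- training_set(X, y, "APOB")
  m <- fit_pls1(ts, p)
  ols <- stats::lm.fit(cbind(1, X), y)
  expect_equal(m$fitted, unname(ols$fitted.values), tolerance = 1e-8)
})

test_that("prediction is centered and linear in the spectrum", {
  ts <- random_training_set(25, 10, 5)
  m <- fit_pls1(ts, 4)
  expect_identical(predict(m, m$x_mean), m$y_mean)
  delta <- rnorm(10)
  up <- predict(m, m$x_mean + delta)
  dn <- predict(m, m$x_mean - delta)
  expect_equal((up + dn) / 2, m$y_mean, tolerance = 1e-12)
  expect_error(predict(m, rnorm(9)), class = "nmrelp_domain_error")
})

test_that("NIPALS scores are orthogonal and training error is monotone in A", {
  ts <- random_training_set(40, 30, 6)
  m <- fit_pls1(ts, 8)
  G <- crossprod(m$T)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)

  rmse_a <- vapply(1:8, function(a) {
    sqrt(mean((fit_pls1(ts, a)$fitted - ts$y)^2))
  }, numeric(1))
  expect_true(all(diff(rmse_a) <= 1e-10))
})

test_that("prediction is equivariant under shifting and scaling the response", {
  ts <- random_training_set(20, 12, 7)
  x_new <- rnorm(12)
  m <- fit_pls1(ts, 3)
  p0 <- predict(m, x_new)
  m_shift <- fit_pls1(training_set(ts$X, ts$y + 37, "TC"), 3)
  expect_equal(predict(m_shift, x_new), p0 + 37, tolerance = 1e-9)
  m_scale <- fit_pls1(training_set(ts$X, ts$y * 2.5, "TC"), 3)
  expect_equal(predict(m_scale, x_new), p0 * 2.5, tolerance = 1e-9)
})

test_that("rmse_cv implements the root mean square error", {
  expect_identical(rmse_cv(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse_cv(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_error(rmse_cv(numeric(0), numeric(0)), class = "nmrelp_domain_error")
  expect_error(rmse_cv(1:3, 1:2), class = "nmrelp_domain_error")
})

test_that("LOO curve hits machine zero on noiseless linear data at full rank", {
  set.seed(8)
  n <- 20; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X %*% rnorm(p))
  y <- y - min(y) + 5
  ts <- training_set(X, y, "TG")
  curve <- loocv_curve(ts, p)
  expect_lt(curve$rmse_cv[p], 1e-8)
})

test_that("fast LOO equals the per-fold path and brute-force refitting", {
  for (seed in 1:3) {
    set.seed(seed)
    ts <- random_training_set(sample(15:25, 1), sample(6:12, 1), seed + 100)
    A_max <- 3
    fast <- loocv_curve(ts, A_max, method = "fast")
    slow <- loocv_curve(ts, A_max, method = "per_fold")
    brute <- loocv_brute(ts, A_max)
    expect_equal(fast$rmse_cv, slow$rmse_cv, tolerance = 1e-10)
    expect_equal(fast$rmse_cv, brute, tolerance = 1e-10)
  }
})

test_that("latent-variable selection takes the argmin with ties toward fewer", {
  mk <- function(v) tibble::tibble(a = seq_along(v), rmse_cv = v)
  expect_identical(select_latent_variables(mk(c(5, 4, 3, 2.4, 2.5))), 4L)
  expect_identical(select_latent_variables(mk(c(3, 2, 2))), 2L)
  expect_warning(a <- select_latent_variables(mk(c(3, 2.5, 2.1, 1.8))),
                 "search bound")
  expect_identical(a, 4L)
})

test_that("DFFITS matches the deletion-refit definition and flags planted outliers", {
  ts <- random_training_set(15, 6, 9)
  d <- dffits_diagnostics(ts, 2)
  expect_equal(d$dffits, dffits_brute(ts, 2), tolerance = 1e-8)

  # noiseless response in the scores: no influence signal at all
  set.seed(10)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- as.numeric(X %*% rnorm(8)); y <- y - min(y) + 1
  clean <- training_set(X, y, "TC")
  d0 <- dffits_diagnostics(clean, 8)
  expect_equal(d0$dffits, rep(0, 30))
  expect_false(any(d0$flagged))

  # one response shifted by ten residual SDs must be flagged
  set.seed(11)
  yn <- y + rnorm(30, 0, 2)
  resid_sd <- 2
  yn[17] <- yn[17] + 10 * resid_sd
  spiked <- training_set(X, pmax(yn, 0), "TC")
  ds <- dffits_diagnostics(spiked, 4)
  expect_true(ds$flagged[17])

  expect_error(dffits_diagnostics(random_training_set(6, 8, 1), 4),
               class = "nmrelp_domain_error")
})

test_that("training pipeline removes planted gross outliers and refits", {
  cfg <- quiet_config(21)
  samples <- sample_population(100, cfg)
  X <- feature_matrix(render_population(samples, cfg))
  # three gross reference errors
  bad <- c(7, 23, 41)
  y_bad <- samples$tc
  y_bad[bad] <- y_bad[bad] + c(150, -120, 180)
  ts_bad <- training_set(X, pmax(y_bad, 0), "TC")
  suppressWarnings(m <- train_calibration(ts_bad, A_max = 15))
  expect_identical(sort(m$diagnostics$outlier_ids),
                   sort(samples$sample_id[bad]))
  expect_identical(m$diagnostics$n_outliers_removed, 3L)

  # cleaning recovers held-out accuracy lost to contamination
  # (held-out population drawn under an independent seed)
  cfg_ho <- quiet_config(22)
  holdout <- sample_population(20, cfg_ho)
  X_ho <- feature_matrix(render_population(holdout, cfg_ho))
  suppressWarnings(m_dirty <- fit_pls1(ts_bad, m$a))
  r_clean <- cor(predict(m, X_ho), holdout$tc)
  r_dirty <- cor(predict(m_dirty, X_ho), holdout$tc)
  expect_gt(r_clean, r_dirty)
})

test_that("noiseless synthetic spectra are recovered perfectly for all four analytes", {
  cfg <- quiet_config(31)
  samples <- sample_population(45, cfg)
  X <- feature_matrix(render_population(samples, cfg))
  for (an in c("tc", "tg", "hdl_c", "apob")) {
    ts <- training_set(X, samples[[an]],
                       c(tc = "TC", tg = "TG", hdl_c = "HDLC",
                         apob = "APOB")[[an]])
    suppressWarnings(m <- train_calibration(ts, A_max = 11))
    expect_identical(m$diagnostics$n_outliers_removed, 0L)
    expect_gt(m$diagnostics$r_train, 1 - 1e-6)
  }
})

test_that("model JSON serialization round-trips predictions and diagnostics", {
  ts <- random_training_set(25, 14, 41)
  suppressWarnings(m <- train_calibration(ts, A_max = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_pls_model(m, path)
  back <- read_pls_model(path)
  x_new <- matrix(rnorm(3 * 14), 3, 14)
  expect_equal(predict(back, x_new), predict(m, x_new), tolerance = 1e-12)
  expect_identical(back$a, m$a)
  expect_equal(back$diagnostics$rmse_cv, m$diagnostics$rmse_cv)
  expect_equal(back$diagnostics$rmse_cv_curve$rmse_cv,
               m$diagnostics$rmse_cv_curve$rmse_cv)
})

test_that("glance and tidy summarize calibrations in broom style", {
  ts <- random_training_set(25, 14, 42)
  suppressWarnings(m <- train_calibration(ts, A_max = 5))
  g <- glance(m)
  expect_identical(nrow(g), 1L)
  expect_equal(g$cv_cv_pct, 100 * g$rmse_cv / g$y_mean)
  td <- tidy(m)
  expect_identical(nrow(td), 14L)
  expect_identical(td$coefficient, m$b)
})
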