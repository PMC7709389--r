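# shared fixtures, all built in code

# a config with every stochastic nuisance switched off: noiseless spectra
# that are exactly linear in the nine subclass concentrations
quiet_config <- function(seed = 1) {
  cfg <- default_population_config()
  cfg$seed <- seed
  cfg$spectrum$noise_sd <- 0
  cfg$spectrum$ppm_jitter_sd <- 0
  cfg$spectrum$nuisance_log_sd <- 0
  cfg
}

# fully silent renderer: no nuisance lines, flat zero baseline
bare_config <- function(seed = 1) {
  cfg <- quiet_config(seed)
  cfg$spectrum$lactate_amp <- 0
  cfg$spectrum$alanine_amp <- 0
  cfg$spectrum$bcaa_amp <- 0
  cfg$spectrum$baseline <- c(0, 0, 0)
  cfg
}

make_sample <- function(conc, seed = 1) {
  s <- tibble::as_tibble(as.list(setNames(conc, c("V1", "V2", "V3", "L1", "L2",
                                                  "L3", "H1", "H2", "H3"))))
  s$sample_id <- "fixture"
  s$render_seed <- seed
  s
}

random_training_set <- function(n, p, seed, analyte = "TC", noise = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- as.numeric(X %*% beta) + rnorm(n, 0, noise)
  y <- y - min(y) + 50
  training_set(X, y, analyte)
}

# brute-force LOO: refit from scratch for every fold AND every component
# count via fit_pls1; the independent oracle for the accelerated path
loocv_brute <- function(ts, A_max) {
  n <- nrow(ts$X)
  preds <- matrix(NA_real_, n, A_max)
  for (A in seq_len(A_max)) {
    for (i in seq_len(n)) {
      tsi <- training_set(ts$X[-i, , drop = FALSE], ts$y[-i], ts$analyte)
      m <- fit_pls1(tsi, A)
      preds[i, A] <- predict(m, ts$X[i, ])
    }
  }
  vapply(seq_len(A_max), function(A) rmse_cv(ts$y, preds[, A]), numeric(1))
}

# deletion-refit DFFITS oracle in score space: OLS on the full-fit scores
# with row i removed
dffits_brute <- function(ts, A) {
  fit <- fit_pls1(ts, A)
  D <- cbind(1, fit$T)
  n <- nrow(D)
  h <- diag(D %*% solve(crossprod(D)) %*% t(D))
  out <- numeric(n)
  for (i in seq_len(n)) {
    cf <- stats::lm.fit(D[-i, , drop = FALSE], ts$y[-i])
    s_i <- sqrt(sum(cf$residuals^2) / cf$df.residual)
    yhat_full <- fit$fitted[i]
    yhat_del <- sum(D[i, ] * cf$coefficients)
    out[i] <- (yhat_full - yhat_del) / (s_i * sqrt(h[i]))
  }
  out
}

# numeric lambda = 1 Deming oracle: minimize the orthogonal-residual sum
# sum((y - a - b x)^2) / (1 + b^2); the intercept profiles out to
# a = ybar - b xbar, leaving a 1-D search over the slope
deming_numeric <- function(x, y) {
  obj <- function(b) sum((y - (mean(y) - b * mean(x)) - b * x)^2) / (1 + b^2)
  ls <- unname(stats::coef(stats::lm(y ~ x))[2])
  fit <- stats::optimize(obj, c(ls - 2, ls + 2), tol = 1e-12)
  b <- fit$minimum
  c(intercept = mean(y) - b * mean(x), slope = b)
}
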