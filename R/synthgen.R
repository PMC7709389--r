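SUBCLASSES <- c("V1", "V2", "V3", "L1", "L2", "L3", "H1", "H2", "H3")

# run code under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default synthetic population configuration
#'
#' Reads the population/spectrum configuration shipped with the package
#' (`inst/extdata/default_population.yaml`): nine lipoprotein subclass
#' profiles (3 VLDL, 3 LDL, 3 HDL), correlated log-normal concentration
#' parameters with a 15% hypertriglyceridemic stratum, nuisance-signal and
#' baseline constants, noise and ppm-jitter levels, and the default seed.
#' Defaults are calibrated so the derived analyte population resembles a
#' clinical serum population: means near TC 181, TG 127, HDL-C 54, apoB 94
#' mg/dL with 1st-99th percentile spans inside TC 64-476, TG 24-886, HDL-C
#' 14-167, apoB 35-305 mg/dL.
#'
#' @param path Optional path to a YAML config; defaults to the shipped file.
#' @return A list with elements `profiles` (tibble), `population`,
#'   `spectrum`, `seed`.
#' @export
default_population_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_population.yaml", package = "nmrelp")
  cfg <- yaml::read_yaml(path)
  cfg$profiles <- dplyr::bind_rows(lapply(cfg$profiles, tibble::as_tibble))
  validate_profiles(cfg$profiles)
  cfg
}

#' @rdname default_population_config
#' @export
default_profiles <- function() default_population_config()$profiles

validate_profiles <- function(p) {
  stopifnot(is.data.frame(p), nrow(p) == 9L)
  if (!identical(p$name, SUBCLASSES))
    abort_domain("profiles must list subclasses V1,V2,V3,L1,L2,L3,H1,H2,H3 in order")
  num <- c("ch3_center", "ch2_center", "linewidth", "chol_coeff", "tg_coeff",
           "apob_coeff", "ch3_amp", "ch2_amp")
  if (any(p[num] < 0)) abort_domain("profile coefficients must be nonnegative")
  if (any(p$ch3_center >= p$ch2_center))
    abort_domain("ch3_center must be below ch2_center")
  is_hdl <- startsWith(p$name, "H")
  if (any((p$apob_coeff == 0) != is_hdl))
    abort_domain("apob_coeff must be zero exactly for the HDL subclasses")
  invisible(p)
}

# 9x9 log-scale correlation matrix from the block parameters
population_cor <- function(pop) {
  cls <- substr(SUBCLASSES, 1, 1)
  R <- matrix(0, 9, 9, dimnames = list(SUBCLASSES, SUBCLASSES))
  within <- c(V = pop$cor_within_vldl, L = pop$cor_within_ldl, H = pop$cor_within_hdl)
  between <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "")
    switch(key, "LV" = pop$cor_vldl_ldl, "HV" = pop$cor_vldl_hdl,
           "HL" = pop$cor_ldl_hdl)
  }
  for (i in 1:9) for (j in 1:9) {
    R[i, j] <- if (i == j) 1 else if (cls[i] == cls[j]) within[[cls[i]]] else
      between(cls[i], cls[j])
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    rlang::abort("population correlation matrix is not positive definite",
                 class = "nmrelp_config_error")
  R
}

#' Ground-truth analytes from subclass concentrations
#'
#' Total cholesterol is the cholesterol carried by all nine subclasses,
#' triglycerides likewise; HDL-C sums only the HDL subclasses' cholesterol;
#' apoB sums the VLDL and LDL apoB contributions (HDL particles carry no
#' apoB).
#'
#' @param concentrations A numeric 9-vector (order V1..H3), or a matrix /
#'   data frame with those nine columns, of nonnegative subclass
#'   concentrations.
#' @param profiles Subclass profile tibble (default [default_profiles()]).
#' @return A tibble with columns `tc`, `tg`, `hdl_c`, `apob` (mg/dL), one
#'   row per input row.
#' @export
compute_true_analytes <- function(concentrations, profiles = default_profiles()) {
  validate_profiles(profiles)
  C <- conc_matrix(concentrations)
  if (any(C < 0)) abort_domain("subclass concentrations must be nonnegative")
  is_hdl <- startsWith(SUBCLASSES, "H")
  tibble::tibble(
    tc    = as.numeric(C %*% profiles$chol_coeff),
    tg    = as.numeric(C %*% profiles$tg_coeff),
    hdl_c = as.numeric(C[, is_hdl, drop = FALSE] %*% profiles$chol_coeff[is_hdl]),
    apob  = as.numeric(C %*% profiles$apob_coeff)
  )
}

conc_matrix <- function(concentrations) {
  if (is.data.frame(concentrations)) {
    if (!all(SUBCLASSES %in% names(concentrations)))
      abort_domain("concentration data frame must carry columns V1..H3")
    C <- as.matrix(concentrations[SUBCLASSES])
  } else if (is.matrix(concentrations)) {
    if (ncol(concentrations) != 9L) abort_domain("need 9 subclass columns")
    C <- concentrations
  } else {
    if (length(concentrations) != 9L) abort_domain("need 9 subclass concentrations")
    C <- matrix(as.numeric(concentrations), nrow = 1)
  }
  storage.mode(C) <- "double"
  colnames(C) <- SUBCLASSES
  C
}

#' Draw a synthetic serum population
#'
#' Subclass concentrations follow a correlated log-normal; a Bernoulli
#' hypertriglyceridemic stratum (default 15%) shifts the VLDL log-means up
#' and is constrained by rejection to true TG at or above the routing
#' threshold (non-members below it), so the generated fraction with TG >=
#' 250 mg/dL is exactly binomial around the configured fraction. Ground
#' truths come from [compute_true_analytes()]; spectra are rendered lazily
#' by [render_spectrum()] using the per-sample `render_seed`, so the whole
#' population is reproducible from `config$seed` alone.
#'
#' @param n Number of samples (>= 0).
#' @param config Configuration list, see [default_population_config()].
#' @return A tibble with columns `sample_id`, `hyper_tg`, `V1`..`H3`, `tc`,
#'   `tg`, `hdl_c`, `apob`, `render_seed`.
#' @export
sample_population <- function(n, config = default_population_config()) {
  stopifnot(n >= 0)
  profiles <- config$profiles
  validate_profiles(profiles)
  pop <- config$population
  R <- population_cor(pop)
  if (n == 0) {
    return(tibble::tibble(sample_id = character(), hyper_tg = logical())[0, ])
  }
  L <- chol(R)
  mu <- as.numeric(pop$log_mean)
  sd <- as.numeric(pop$log_sd)
  shift <- c(rep(pop$hyper_tg_shift, 3), rep(0, 6))
  thr <- pop$tg_threshold
  with_seed(config$seed, {
    hyper <- stats::runif(n) < pop$hyper_tg_fraction
    C <- matrix(NA_real_, n, 9, dimnames = list(NULL, SUBCLASSES))
    pending <- seq_len(n)
    tries <- 0L
    while (length(pending) > 0 && tries < 1000L) {
      m <- length(pending)
      Z <- matrix(stats::rnorm(m * 9), m, 9) %*% L
      logc <- sweep(Z, 2, sd, `*`)
      logc <- sweep(logc, 2, mu, `+`)
      logc <- logc + outer(hyper[pending], shift)
      Cc <- exp(logc)
      tg <- as.numeric(Cc %*% profiles$tg_coeff)
      ok <- (tg >= thr) == hyper[pending]
      # degenerate (zero-variance) configs can never cross the threshold;
      # accept unconditionally so the draw still terminates
      if (all(sd == 0)) ok[] <- TRUE
      C[pending[ok], ] <- Cc[ok, , drop = FALSE]
      pending <- pending[!ok]
      tries <- tries + 1L
    }
    if (length(pending) > 0)
      rlang::abort("stratum rejection sampling did not converge; check config",
                   class = "nmrelp_config_error")
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    truths <- compute_true_analytes(C, profiles)
    tibble::tibble(
      sample_id = sprintf("SYN%05d", seq_len(n)),
      hyper_tg = hyper,
      tibble::as_tibble(C),
      truths,
      render_seed = seeds
    )
  })
}

lorentzian <- function(ppm, center, hwhm) {
  hwhm^2 / ((ppm - center)^2 + hwhm^2)
}

# line list for one sample: lipid CH3/CH2 lines plus nuisance signals;
# returns tibble(center, hwhm, height)
sample_line_list <- function(conc, profiles, spec, nuisance_scale) {
  carried <- conc * (profiles$chol_coeff + profiles$tg_coeff)
  lip <- tibble::tibble(
    center = c(profiles$ch3_center, profiles$ch2_center),
    hwhm   = rep(profiles$linewidth, 2),
    height = c(carried * profiles$ch3_amp, carried * profiles$ch2_amp)
  )
  half <- spec$doublet_split / 2
  nui <- tibble::tibble(
    center = c(1.33 - half, 1.33 + half, 1.48 - half, 1.48 + half,
               as.numeric(spec$bcaa_centers)),
    hwhm   = spec$nuisance_width,
    height = c(rep(spec$lactate_amp * nuisance_scale[1] / 2, 2),
               rep(spec$alanine_amp * nuisance_scale[2] / 2, 2),
               spec$bcaa_amp * nuisance_scale[3] * as.numeric(spec$bcaa_rel))
  )
  dplyr::bind_rows(lip, nui)
}

#' Render the NMR spectrum of a synthetic sample
#'
#' Lipid CH3 and CH2 Lorentzian lines for each subclass (height proportional
#' to concentration times carried cholesterol + triglyceride), sharp lactate
#' and alanine doublets and a branched-chain amino-acid multiplet cluster,
#' a fixed baseline polynomial, Gaussian noise scaled to the median line
#' height, and Normal ppm jitter on every line center. Deterministic given
#' the sample's `render_seed`.
#'
#' @param sample One row of [sample_population()] output (or a list with
#'   `V1`..`H3`, `sample_id`, `render_seed`).
#' @param config Configuration list (see [default_population_config()]).
#' @return An `elp_spectrum` covering at least 0.45-1.65 ppm at more than
#'   twice the canonical resolution.
#' @export
render_spectrum <- function(sample, config = default_population_config()) {
  profiles <- config$profiles
  spec <- config$spectrum
  conc <- as.numeric(sample[SUBCLASSES])
  if (anyNA(conc) || any(conc < 0))
    abort_domain("sample must carry nonnegative V1..H3 concentrations")
  seed <- if (!is.null(sample$render_seed)) as.integer(sample$render_seed) else 1L
  ppm <- seq(spec$ppm_max, spec$ppm_min, length.out = as.integer(spec$n_points))
  with_seed(seed, {
    nuisance_scale <- exp(stats::rnorm(3, 0, spec$nuisance_log_sd))
    lines <- sample_line_list(conc, profiles, spec, nuisance_scale)
    centers <- lines$center +
      stats::rnorm(nrow(lines), 0, spec$ppm_jitter_sd)
    signal <- rep(0, length(ppm))
    for (k in seq_len(nrow(lines))) {
      if (lines$height[k] == 0) next
      signal <- signal + lines$height[k] * lorentzian(ppm, centers[k], lines$hwhm[k])
    }
    b <- as.numeric(spec$baseline)
    baseline <- b[1] + b[2] * (ppm - 1) + b[3] * (ppm - 1)^2
    active <- lines$height[lines$height > 0]
    noise_scale <- if (length(active)) stats::median(active) else 0
    noise <- if (spec$noise_sd > 0 && noise_scale > 0)
      stats::rnorm(length(ppm), 0, spec$noise_sd * noise_scale) else 0
    sid <- if (!is.null(sample$sample_id)) sample$sample_id else NA_character_
    new_spectrum(ppm, signal + baseline + noise,
                 sample_id = sid, tube_type = "synthetic")
  })
}

#' Render spectra for a whole population
#'
#' @param samples Tibble from [sample_population()].
#' @inheritParams render_spectrum
#' @return A list of `elp_spectrum`, one per row.
#' @export
render_population <- function(samples, config = default_population_config()) {
  lapply(seq_len(nrow(samples)), function(i)
    render_spectrum(samples[i, ], config))
}

#' Add a Lorentzian interferent line to a spectrum
#'
#' Used to emulate direct spectral contributions of drugs or metabolites in
#' interference studies. The input spectrum is not modified.
#'
#' @param spectrum An `elp_spectrum`.
#' @param center Line position (ppm).
#' @param amplitude Peak height (intensity units); 0 returns the input
#'   unchanged.
#' @param width Lorentzian half-width at half-maximum (ppm), > 0.
#' @return A new `elp_spectrum`.
#' @export
add_interferent <- function(spectrum, center, amplitude, width) {
  stopifnot(inherits(spectrum, "elp_spectrum"))
  if (width <= 0) abort_domain("interferent `width` must be positive")
  out <- spectrum
  if (amplitude != 0)
    out$intensity <- out$intensity + amplitude * lorentzian(out$ppm, center, width)
  out
}
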