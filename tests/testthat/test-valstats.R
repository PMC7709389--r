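test_that("precision summaries use the sample SD and one-decimal CV display", {
  reps <- tibble::tibble(pool = rep("L", 3), value = c(1, 2, 3))
  out <- precision_summary(reps)
  expect_equal(out$mean, 2)
  expect_equal(out$sd, 1)
  expect_equal(out$cv_pct, 50)
  expect_identical(out$cv_display, "50.0")

  flat <- tibble::tibble(pool = rep(c("A", "B"), each = 4),
                         value = rep(c(7, 9), each = 4))
  out2 <- precision_summary(flat, "within_lab")
  expect_equal(out2$sd, c(0, 0))
  expect_equal(out2$cv_pct, c(0, 0))
  expect_identical(out2$design, rep("within_lab", 2))

  expect_error(precision_summary(tibble::tibble(pool = "x", value = 1)),
               class = "nmrelp_domain_error")
})

test_that("precision CV is invariant under rescaling the replicates", {
  set.seed(12)
  reps <- tibble::tibble(pool = rep(c("L", "M", "H"), each = 20),
                         value = abs(rnorm(60, rep(c(40, 100, 280), each = 20),
                                           rep(c(1, 2, 4), each = 20))))
  base <- precision_summary(reps)
  scaled <- precision_summary(dplyr::mutate(reps, value = value * 3.7))
  expect_equal(scaled$cv_pct, base$cv_pct, tolerance = 1e-12)
})

test_that("sensitivity limits follow the 1.645-quantile construction", {
  # hand-checked values: blank mean 2 sd 1 -> LOB 3.645; low sd 2 -> LOD 6.935
  mk <- function(m, s, n = 12) m + s * scale(rnorm(n))[, 1]
  set.seed(13)
  bl <- mk(2, 1)
  lo <- mk(10, 2)
  res2 <- sensitivity_limits(bl, list(lo))
  expect_equal(res2$lob, 3.645, tolerance = 1e-9)
  expect_equal(res2$lod, 6.935, tolerance = 1e-9)

  # zero-variance degenerate collapse
  res3 <- sensitivity_limits(rep(2, 10), list(rep(4, 5)))
  expect_equal(res3$lob, 2)
  expect_equal(res3$lod, 2)

  # LOQ: lowest qualifying dilution level, or a sentinel when none qualifies
  dil <- tibble::tibble(level = rep(c("d20", "d10", "d5"), each = 4),
                        value = c(mk(8, 4, 4), mk(15, 1, 4), mk(30, 1, 4)))
  res4 <- sensitivity_limits(bl, list(lo), dil)
  expect_true(res4$loq_reached)
  expect_equal(res4$loq, 15)       # d20 fails the 20% CV rule, d10 qualifies
  expect_true(res4$lob <= res4$lod && res4$lod <= res4$loq)

  res5 <- sensitivity_limits(bl, list(lo),
                             tibble::tibble(level = "d20",
                                            value = mk(8, 4, 4)))
  expect_false(res5$loq_reached)
  expect_true(is.na(res5$loq))

  expect_error(sensitivity_limits(numeric(0), list(1:3)),
               class = "nmrelp_domain_error")
})

test_that("Deming regression recovers exact lines and matches a numeric oracle", {
  x <- c(1, 2, 3, 4, 5)
  f1 <- deming_fit(x, x)
  expect_equal(f1$slope, 1)
  expect_equal(f1$intercept, 0)
  expect_equal(f1$pearson_r, 1)

  f2 <- deming_fit(x, 2 * x)
  expect_equal(f2$slope, 2)
  expect_equal(f2$intercept, 0, tolerance = 1e-12)

  y <- c(1.1, 1.9, 3.2, 3.8, 5.1)
  f3 <- deming_fit(x, y)
  oracle <- deming_numeric(x, y)
  expect_equal(f3$slope, oracle[["slope"]], tolerance = 1e-6)
  expect_equal(f3$intercept, oracle[["intercept"]], tolerance = 1e-6)

  expect_error(deming_fit(rep(3, 5), x), class = "nmrelp_degenerate_error")
  expect_error(deming_fit(1:2, 1:2), class = "nmrelp_domain_error")

  g <- glance(f3)
  expect_identical(g$n, 5L)
  expect_identical(g$lambda, 1)
  expect_identical(tidy(f3)$estimate, c(f3$intercept, f3$slope))
})

test_that("lambda = 1 Deming is symmetric on exact linear data", {
  x <- seq(10, 200, length.out = 15)
  y <- 1.7 * x - 4
  fwd <- deming_fit(x, y)
  rev <- deming_fit(y, x)
  expect_equal(fwd$slope, 1 / rev$slope, tolerance = 1e-10)
})

test_that("linearity evaluation mixes endpoint pools and flags deviations", {
  mx <- tibble::tibble(fraction_high = c(0, 0.25, 0.5, 0.75, 1))
  mx$value <- (1 - mx$fraction_high) * 50 + mx$fraction_high * 250
  res <- linearity_eval(mx, 50, 250)
  expect_equal(res$mixtures$expected[mx$fraction_high == 0.75], 200)
  expect_equal(res$slope, 1)
  expect_equal(res$intercept, 0, tolerance = 1e-10)
  expect_equal(res$r_squared, 1)
  expect_equal(res$max_abs_deviation_pct, 0)

  mx2 <- mx
  mx2$value[3] <- mx2$value[3] * 1.05
  res2 <- linearity_eval(mx2, 50, 250)
  dev3 <- res2$mixtures$deviation_pct[res2$mixtures$fraction_high == 0.5]
  expect_equal(dev3, 5)
  expect_false(res2$mixtures$flagged[res2$mixtures$fraction_high == 0.5])
  mx3 <- mx
  mx3$value[3] <- mx3$value[3] * 1.12
  res3 <- linearity_eval(mx3, 50, 250)
  expect_true(any(res3$mixtures$flagged))

  expect_error(linearity_eval(mx[0, ], 50, 250), class = "nmrelp_domain_error")
})

test_that("percent bias and mean absolute bias reproduce the printed arithmetic", {
  expect_equal(round(percent_bias(166.9, 169.4), 1), -1.5)
  expect_equal(round(percent_bias(157.3, 152.4), 1), 3.2)
  expect_identical(percent_bias(88, 88), 0)
  expect_error(percent_bias(10, 0), class = "nmrelp_domain_error")

  expect_equal(mean_absolute_bias(tibble::tibble(measured = 98, target = 100)), 2)
  expect_error(mean_absolute_bias(tibble::tibble(measured = numeric(0),
                                                 target = numeric(0))),
               class = "nmrelp_domain_error")
})

test_that("interference uses a strict 10% rule and stability an inclusive one", {
  expect_false(interference_eval(c(99, 101), c(99, 101))$flagged)
  i1 <- interference_eval(rep(100, 4), rep(112, 4))
  expect_equal(i1$percent_change, 12)
  expect_true(i1$flagged)
  i2 <- interference_eval(rep(100, 4), rep(90.5, 4))
  expect_equal(i2$percent_change, -9.5)
  expect_false(i2$flagged)
  expect_error(interference_eval(c(-1, 1), c(1, 2)), class = "nmrelp_domain_error")

  tp <- tibble::tibble(label = c("d7", "d14", "d30"),
                       mean = c(100, 110, 110.1))
  st <- stability_eval(100, tp)
  expect_identical(st$acceptable, c(TRUE, TRUE, FALSE))
  expect_equal(st$diff_pct, c(0, 10, 10.1))
  expect_error(stability_eval(0, tp), class = "nmrelp_domain_error")
})

test_that("tube comparison flags slopes far from unity", {
  ref <- c(40, 80, 120, 180, 250, 320)
  t1 <- tube_comparison(ref, ref)
  expect_equal(t1$slope, 1)
  expect_equal(t1$r_squared, 1)
  expect_false(t1$flagged)

  t2 <- tube_comparison(ref, 0.88 * ref)
  expect_equal(t2$slope, 0.88)
  expect_true(t2$flagged)

  t3 <- tube_comparison(ref, 0.95 * ref)
  expect_equal(t3$slope, 0.95)
  expect_false(t3$flagged)

  expect_error(tube_comparison(rep(5, 4), 1:4), class = "nmrelp_degenerate_error")
})
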