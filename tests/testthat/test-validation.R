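# Trueness, variance components, beta-expectation tolerance intervals,
# accuracy and linearity profiles.

test_that("trueness arithmetic", {
  tr <- trueness(c(12.55, 12.65), 12.5)  # mean 12.60 at nominal 12.50
  expect_equal(tr$mean_pred, 12.60)
  expect_equal(tr$recovery, 100.80)
  tr2 <- trueness(rep(10, 5), 10)
  expect_equal(tr2$recovery, 100)
  expect_equal(tr2$relative_bias, 0)
  tr3 <- trueness(11, 10)
  expect_equal(tr3$recovery, 110)
  expect_equal(tr3$relative_bias, 10)
  expect_error(trueness(c(1, 2), 0), "positive")
})

test_that("variance components match the hand-worked ANOVA", {
  # 2 series x 2 replicates: series means 10 and 20, grand mean 15
  vc <- variance_components(rbind(c(9, 11), c(19, 21)))
  expect_equal(vc$ms_within, 2)
  expect_equal(vc$ms_between, 100)
  expect_equal(vc$grand_mean, 15)
  expect_equal(vc$s_w2, 2)
  expect_equal(vc$s_b2, (100 - 2) / 2)
  expect_equal(vc$s_ip2, 2 + 49)
  # identical series -> between component clipped to zero
  m <- rbind(c(9, 11), c(9, 11), c(9, 11))
  vc0 <- variance_components(m)
  expect_equal(vc0$s_b2, 0)
  expect_equal(vc0$s_w2, var(c(-1, 1)) * 3 * 1 / (3 * 1))  # = 2
  expect_error(variance_components(matrix(1:3, 1)), "at least 2")
  expect_error(variance_components(rbind(c(1, NA), c(2, 3))), "unbalanced")
})

test_that("variance-component estimator recovers the generating model", {
  set.seed(7)
  est <- replicate(2000, {
    b <- rnorm(3, 0, 0.5)
    m <- matrix(rep(b, each = 4) + rnorm(12, 0, 1), nrow = 3, byrow = TRUE)
    vc <- variance_components(m)
    c(vc$s_w2, (vc$ms_between - vc$ms_within) / 4, vc$s_ip2)
  })
  expect_lt(abs(mean(est[1, ]) - 1) / 1, 0.1)        # within-series
  expect_lt(abs(mean(est[2, ]) - 0.25) / 0.25, 0.1)  # unclipped between
  expect_lt(abs(mean(est[3, ]) - 1.25) / 1.25, 0.1)  # intermediate
  # the clipped between-series estimate is non-negative by construction
  # (its mean is upward-biased at small ratios, hence the unclipped check)
})

test_that("tolerance interval reduces correctly and brackets the bias", {
  # s_b2 = 0: R = 0, closed-form reduction
  p <- 3; n <- 4; s_w2 <- 0.04
  ti <- tolerance_interval(0.5, s_w2, 0, p, n, nominal = 12.5)
  nu <- 1 / ((1 / n)^2 / (p - 1) + (1 - 1 / n) / (p * n))
  k <- qt(0.975, nu) * sqrt(1 + 1 / (p * n))
  rsd <- 100 * sqrt(s_w2) / 12.5
  expect_equal(ti$rel_tol_lower, 0.5 - k * rsd, tolerance = 1e-10)
  expect_equal(ti$rel_tol_upper, 0.5 + k * rsd, tolerance = 1e-10)
  # symmetry about the bias, always containing it
  set.seed(30)
  for (i in 1:20) {
    sw <- runif(1, 0.001, 0.1); sb <- runif(1, 0, 0.1)
    rb <- runif(1, -3, 3)
    t2 <- tolerance_interval(rb, sw, sb, 3, 4, 12.5)
    expect_equal(t2$rel_tol_upper - rb, rb - t2$rel_tol_lower,
                 tolerance = 1e-10)
    expect_true(t2$rel_tol_lower <= rb && rb <= t2$rel_tol_upper)
  }
  # degenerate: all variance zero
  td <- tolerance_interval(1.2, 0, 0, 3, 4, 12.5)
  expect_true(td$degenerate)
  expect_equal(td$rel_tol_lower, 1.2)
  expect_equal(td$rel_tol_upper, 1.2)
})

test_that("beta-expectation coverage is near 0.95 (Monte Carlo)", {
  set.seed(99)
  p <- 3; n <- 4; nominal <- 12.5; mu <- 12.52; sw <- 0.12; sb <- 0.06
  nsim <- 5000
  inside <- logical(nsim)
  for (s in seq_len(nsim)) {
    b <- rnorm(p, 0, sb)
    m <- matrix(mu + rep(b, each = n) + rnorm(p * n, 0, sw),
                nrow = p, byrow = TRUE)
    vc <- variance_components(m)
    rb <- 100 * (mean(m) - nominal) / nominal
    ti <- tolerance_interval(rb, vc$s_w2, vc$s_b2, p, n, nominal)
    rf <- 100 * (mu + rnorm(1, 0, sb) + rnorm(1, 0, sw) - nominal) / nominal
    inside[s] <- rf >= ti$rel_tol_lower && rf <= ti$rel_tol_upper
  }
  expect_lt(abs(mean(inside) - 0.95), 0.02)
})

test_that("accuracy profile applies the subset compliance rule", {
  mk_preds <- function(nominal, shift, spread) {
    d <- expand.grid(series = 1:3, replicate = 1:4)
    d$nominal <- nominal
    d$prediction <- nominal * (1 + shift / 100) +
      spread * rep(c(-1, 1, -0.5, 0.5), each = 3)
    d
  }
  good <- rbind(mk_preds(10, 0.3, 0.05), mk_preds(12.5, 0.5, 0.05),
                mk_preds(15, 0.2, 0.05))
  ap <- accuracy_profile(good, acceptance_rel = 5)
  expect_true(all(ap$levels$compliant))
  expect_equal(ap$validated_range, c(10, 15))
  # intervals consistent between relative and absolute limits
  expect_equal(ap$levels$abs_tol_lower,
               ap$levels$nominal * (1 + ap$levels$rel_tol_lower / 100),
               tolerance = 1e-10)
  expect_equal(ap$levels$abs_tol_upper,
               ap$levels$nominal * (1 + ap$levels$rel_tol_upper / 100),
               tolerance = 1e-10)
  expect_true(all(ap$levels$s_ip2 >= ap$levels$s_w2))
  # a biased noisy level breaks compliance
  bad <- rbind(mk_preds(10, -4, 0.4), mk_preds(12.5, 0.5, 0.05),
               mk_preds(15, 0.2, 0.05))
  ap2 <- accuracy_profile(bad, acceptance_rel = 5)
  expect_false(ap2$levels$compliant[1])
  expect_true(all(ap2$levels$compliant[2:3]))
  expect_equal(ap2$validated_range, c(12.5, 15))
  # widening the acceptance limit never removes compliance (monotonicity)
  ap3 <- accuracy_profile(bad, acceptance_rel = 15)
  expect_true(all(ap3$levels$compliant | !ap2$levels$compliant))
  expect_true(all(ap2$levels$compliant <= ap3$levels$compliant))
})

test_that("accuracy profile rejects unbalanced levels", {
  d <- data.frame(nominal = 10, series = c(1, 1, 2), prediction = c(9, 10, 11))
  expect_error(accuracy_profile(d), "unbalanced")
})

test_that("linearity profile fits OLS and applies acceptance limits", {
  d <- expand.grid(series = 1:3, replicate = 1:4,
                   nominal = c(10, 12.5, 15))
  d$prediction <- d$nominal
  lin <- linearity_profile(d, acceptance_rel = 5)
  expect_equal(lin$slope, 1)
  expect_equal(lin$intercept, 0, tolerance = 1e-12)
  expect_equal(lin$r2, 1)
  expect_equal(lin$levels$acceptance_lower[1], 9.5)
  expect_equal(lin$levels$acceptance_upper[1], 10.5)
  expect_true(all(lin$levels$compliant))
  # proportional 10 % over-prediction: perfect line, non-compliant levels
  d2 <- d; d2$prediction <- 1.1 * d2$nominal
  lin2 <- linearity_profile(d2, acceptance_rel = 5)
  expect_equal(lin2$slope, 1.1)
  expect_equal(lin2$r2, 1)
  expect_false(any(lin2$levels$compliant))
  expect_error(linearity_profile(data.frame(nominal = 10, series = 1,
                                            prediction = 10)),
               "2 distinct")
})

test_that("zero between-series noise closes the precision gap on average", {
  set.seed(11)
  gap <- replicate(500, {
    m <- matrix(12.5 + rnorm(12, 0, 0.12), nrow = 3)
    vc <- variance_components(m)
    100 * (sqrt(vc$s_ip2) - sqrt(vc$s_w2)) / vc$grand_mean
  })
  expect_lt(mean(gap), 0.1)
})

test_that("full validation report on synthetic data is assembled coherently", {
  ds <- cached_dataset(1)
  model <- calibrate(ds$calibration,
                     preprocess_spec("smoothing_savitzky_golay"),
                     "PLS", n_factors = 4)
  rep <- validate_model(model, ds$validation)
  lv <- rep$profile$levels
  expect_equal(lv$nominal, c(10, 12.5, 15))
  expect_equal(lv$p, rep(3, 3))
  expect_equal(lv$n, rep(4, 3))
  expect_true(all(lv$rel_tol_lower <= lv$relative_bias &
                    lv$relative_bias <= lv$rel_tol_upper))
  expect_equal(rep$linearity$slope, 1, tolerance = 0.05)
  expect_gt(rep$linearity$r2, 0.98)
})
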