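# Cross-validation figures of merit, factor selection, and the
# pre-treatment x method scan.

test_that("leave-one-out CV equals a naive refit loop (oracle)", {
  set.seed(20)
  X <- matrix(rnorm(6 * 10), 6, 10)
  y <- rnorm(6, 12.5, 1.5)
  cv <- cross_validate(X, y, "PLS", max_factors = 3)
  # independent brute-force loop, refitting from scratch each fold
  for (h in 1:3) {
    preds <- vapply(seq_len(6), function(i) {
      f <- fit_pls(X[-i, ], y[-i], max_factors = 3)
      predict(f, X[i, , drop = FALSE], h = min(h, f$n_factors))
    }, numeric(1))
    expect_equal(unname(cv$cv_predictions[, h]), preds, tolerance = 1e-12,
                 info = paste("h =", h))
    expect_equal(cv$metrics$rmsecv[h], sqrt(mean((preds - y)^2)),
                 tolerance = 1e-12)
    expect_equal(cv$metrics$bias[h], mean(preds - y), tolerance = 1e-12)
  }
})

test_that("CV figures of merit satisfy their algebraic identities", {
  set.seed(21)
  for (rep in 1:5) {
    X <- matrix(rnorm(12 * 15), 12, 15)
    y <- rnorm(12, 12.5, 1.5)
    cv <- cross_validate(X, y, "PCR", max_factors = 4)
    m <- cv$metrics
    # MSE = bias^2 + variance of errors, per factor count
    for (h in seq_len(nrow(m))) {
      err <- cv$cv_predictions[, h] - y
      expect_equal(m$rmsecv[h]^2, m$bias[h]^2 + mean((err - mean(err))^2),
                   tolerance = 1e-10)
    }
    expect_true(all(m$rmsecv >= 0))
    expect_true(all(m$r2 <= 1))
  }
})

test_that("RMSECV >= RMSEC at the same factor count (generalization gap)", {
  set.seed(22)
  ok <- vapply(1:20, function(i) {
    X <- matrix(rnorm(10 * 12), 10, 12)
    y <- rnorm(10, 12.5, 1.5)
    cv <- cross_validate(X, y, "PLS", max_factors = 3)
    all(cv$metrics$rmsecv >= cv$metrics$rmsec - 1e-12)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("noiseless calibration cross-validates to ~zero error", {
  ds <- cached_dataset(1, noise_free())
  pp <- apply_preprocess(ds$calibration, preprocess_spec("none"))
  cv <- cross_validate(pp$values, ds$calibration$meta$nominal_pct_ww, "PLS",
                       max_factors = 3)
  expect_lt(cv$metrics$rmsecv[1], 1e-6)
  expect_lt(cv$metrics$rmsec[1], 1e-6)
})

test_that("CV bias vanishes for an exactly proportional predictor", {
  y <- c(1, 2, 3, 4)
  X <- cbind(y, 2 * y, 0.5 * y)
  cv <- cross_validate(X, y, "PLS", max_factors = 1)
  expect_lt(abs(cv$metrics$bias[1]), 1e-10)
})

test_that("leave-group-out scheme runs and validates group size", {
  set.seed(23)
  X <- matrix(rnorm(12 * 8), 12, 8)
  y <- rnorm(12, 12.5, 1.5)
  cv <- cross_validate(X, y, "PLS", max_factors = 2, scheme = "lgo", k = 2)
  expect_equal(nrow(cv$cv_predictions), 12)
  expect_error(cross_validate(X, y, "PLS", scheme = "lgo", k = 5),
               "incompatible")
})

test_that("rmsep follows its definition", {
  set.seed(24)
  X <- matrix(rnorm(8 * 6), 8, 6)
  y <- rnorm(8, 12.5, 1.5)
  fit <- fit_pls(X, y, 2)
  # perfect predictions -> 0; constant shift e -> |e|
  expect_equal(rmsep(fit, X, predict(fit, X, 2), 2), 0)
  expect_equal(rmsep(fit, X, predict(fit, X, 2) - 0.3, 2), 0.3)
  expect_error(rmsep(fit, X[0, , drop = FALSE], numeric(0), 2), "empty")
  # hand arithmetic: yhat (10.1, 12.4, 15.2) vs y (10, 12.5, 15)
  expect_equal(sqrt(mean(c(0.1, -0.1, 0.2)^2)), 0.1414, tolerance = 1e-3)
})

test_that("factor selection applies the MSE-ratio rule", {
  # plateau from h = 3 within 5 %
  expect_equal(select_n_factors(c(0.9, 0.5, 0.300, 0.299, 0.2995)), 3)
  # worked curve: 0.33^2 <= 1.05 * 0.325^2 -> h = 2
  expect_equal(select_n_factors(c(0.40, 0.33, 0.325, 0.327)), 2)
  expect_equal(select_n_factors(0.5), 1)
  # stricter threshold moves the choice later
  expect_equal(select_n_factors(c(0.40, 0.33, 0.325, 0.327),
                                f_thresh = 1.0), 3)
  # F-test variant: threshold qf(0.75, 15, 15) ~ 1.47 admits h = 2 here
  expect_equal(select_n_factors(c(0.40, 0.33, 0.325, 0.327), rule = "ftest",
                                n = 15), 2)
  expect_error(select_n_factors(c(0.4, 0.3), rule = "ftest"), "required")
})

test_that("grid search covers all combinations and ranks by RMSECV", {
  ds <- cached_dataset(1, noise_free())
  gs <- grid_search(ds$calibration, ds$validation)
  expect_equal(nrow(gs$table), 18)  # 9 pre-treatments x 2 methods
  expect_true(all(is.na(gs$table$error)))
  # noiseless: every combination is essentially exact
  expect_true(all(gs$table$r2 > 0.999))
  ok <- !is.na(gs$table$rmsecv)
  expect_true(!is.unsorted(gs$table$rmsecv[ok]))
  expect_s3_class(gs$best$spec, "preprocess_spec")
  # a failing spec is flagged but the scan continues
  bad <- preprocess_spec("none", region = c(4100, 4000))
  bad$region <- c(3000, 2000)  # force empty intersection
  gs2 <- grid_search(ds$calibration, specs = list(bad = bad,
                                                  none = preprocess_spec()),
                     methods = "PLS")
  expect_equal(nrow(gs2$table), 2)
  expect_equal(sum(!is.na(gs2$table$error)), 1)
})

test_that("with additive noise only, smoothing outranks the gap derivative", {
  nm <- noise_model(sigma_additive = 0.015, sigma_scatter = 0,
                    sigma_series = 0)
  wins <- vapply(1:50, function(sd) {
    ds <- generate_protocol_dataset(build_protocol(), noise = nm, seed = sd)
    y <- ds$calibration$meta$nominal_pct_ww
    r <- vapply(c("smoothing_savitzky_golay", "norris_gap_first_derivative"),
                function(meth) {
                  pp <- apply_preprocess(ds$calibration,
                                         preprocess_spec(meth))
                  cv <- cross_validate(pp$values, y, "PLS")
                  cv$metrics$rmsecv[cv$h_selected]
                }, numeric(1))
    r[1] < r[2]
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
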