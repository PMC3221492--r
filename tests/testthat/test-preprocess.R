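# Pre-treatments, each checked against its defining algebra or a
# brute-force oracle.

test_that("region selection keeps exactly the in-range grid points", {
  ds <- cached_dataset(1)
  sel <- select_region(to_absorbance(ds$calibration), 7500, 4000)
  # brute-force enumeration oracle over the default grid
  oracle <- sum(seq(11000, 4000, by = -8) >= 4000 &
                  seq(11000, 4000, by = -8) <= 7500)
  expect_equal(length(sel$grid), oracle)
  expect_equal(length(sel$grid), 438)
  expect_true(all(sel$grid <= 7500 & sel$grid >= 4000))
  expect_identical(sel$meta, ds$calibration$meta)
  # full-range selection is the identity
  full <- select_region(ds$calibration, 11000, 4000)
  expect_identical(full$values, ds$calibration$values)
  expect_error(select_region(ds$calibration, 3000, 2000), "overlap")
})

test_that("moving average matches its window definition", {
  x <- matrix(seq_len(25), nrow = 1)  # ramp x_i = i
  s <- toy_set(x)
  expect_equal(moving_average(s, 1)$values, s$values,
               ignore_attr = TRUE)
  out <- moving_average(s, 3)$values[1, ]
  expect_equal(out[2:24], 2:24)            # interior: mean of {i-1,i,i+1}
  expect_equal(out[1], mean(1:2))          # shrunken edge window
  expect_equal(out[25], mean(24:25))
  cst <- toy_set(matrix(3.7, 1, 25))
  expect_equal(moving_average(cst, 11)$values, cst$values)
  expect_error(moving_average(s, 27), "window")
})

test_that("Savitzky-Golay reproduces polynomials and scaled derivatives", {
  i <- seq_len(31)
  quad <- toy_set(matrix(2 + 0.3 * i - 0.05 * i^2, 1))
  for (w in c(5, 11)) {
    expect_equal(savitzky_golay(quad, w, 2, 0)$values, quad$values,
                 tolerance = 1e-10)
  }
  h <- 8  # toy grid step
  ramp <- toy_set(matrix(1 + 4 * i, 1))
  d1 <- savitzky_golay(ramp, 11, 2, 1)$values[1, ]
  expect_equal(d1, rep(4 / h, 31), tolerance = 1e-10)
  d2 <- savitzky_golay(quad, 11, 2, 2)$values[1, ]
  expect_equal(d2, rep(-0.1 / h^2, 31), tolerance = 1e-10)
})

test_that("Savitzky-Golay equals brute-force windowed least squares", {
  set.seed(31)
  x <- rnorm(25)
  s <- toy_set(matrix(x, 1))
  h <- 8
  for (d in 0:2) {
    out <- savitzky_golay(s, 11, 2, d)$values[1, ]
    for (i in 6:20) {  # interior points
      win <- (i - 5):(i + 5)
      t <- -5:5
      fit <- lm(x[win] ~ t + I(t^2))
      expected <- switch(as.character(d),
                         "0" = unname(coef(fit)[1]),
                         "1" = unname(coef(fit)[2]) / h,
                         "2" = 2 * unname(coef(fit)[3]) / h^2)
      expect_equal(out[i], expected, tolerance = 1e-10,
                   info = sprintf("deriv %d point %d", d, i))
    }
  }
})

test_that("Norris gap derivative follows the stated finite differences", {
  n <- 41
  cst <- toy_set(matrix(5, 1, n))
  expect_equal(norris_gap_derivative(cst, 5, 5, 1)$values,
               matrix(0, 1, n), ignore_attr = TRUE)
  expect_equal(norris_gap_derivative(cst, 5, 5, 2)$values,
               matrix(0, 1, n), ignore_attr = TRUE)
  h <- 8
  i <- seq_len(n)
  ramp <- toy_set(matrix(2 * i, 1))
  expect_equal(norris_gap_derivative(ramp, 5, 5, 1)$values[1, ],
               rep(2 / h, n), tolerance = 1e-12)
  expect_equal(norris_gap_derivative(ramp, 5, 5, 2)$values[1, ],
               rep(0, n), tolerance = 1e-12)
  # quadratic with unit step grid: g=2, s=1 -> second derivative 2
  quad <- toy_set(matrix(i^2, 1), grid = rev(i))  # descending step 1
  out2 <- norris_gap_derivative(quad, 2, 1, 2)$values[1, ]
  expect_equal(out2[3:(n - 2)], rep(2, n - 4), tolerance = 1e-12)
  # edges replicate the nearest computable value
  expect_equal(out2[1], out2[3])
  expect_equal(out2[n], out2[n - 2])
  expect_error(norris_gap_derivative(toy_set(matrix(1:5, 1)), 5, 5, 1),
               "exceed")
})

test_that("SNV standardizes rows and is affine-invariant and idempotent", {
  set.seed(5)
  s <- toy_set(matrix(rnorm(60, 1, 0.2), nrow = 3))
  out <- snv(s)
  expect_equal(unname(rowMeans(out$values)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(out$values, 1, sd)), rep(1, 3),
               tolerance = 1e-12)
  aff <- toy_set(3.2 * s$values + 1.7)
  expect_equal(snv(aff)$values, out$values, tolerance = 1e-12)
  expect_equal(snv(out)$values, out$values, tolerance = 1e-12)
  expect_error(snv(toy_set(matrix(2, 2, 10))), "s01")
})

test_that("unit-vector and min/max normalizations satisfy their definitions", {
  set.seed(6)
  s <- toy_set(matrix(rnorm(40, 1, 0.3), nrow = 2))
  uv <- unit_vector_normalize(s)
  expect_equal(unname(sqrt(rowSums(uv$values^2))), c(1, 1),
               tolerance = 1e-12)
  mm <- minmax_normalize(s)
  expect_equal(unname(apply(mm$values, 1, min)), c(0, 0))
  expect_equal(unname(apply(mm$values, 1, max)), c(1, 1))
  # scale invariance (and offset invariance for min/max)
  s5 <- toy_set(5 * s$values)
  expect_equal(unit_vector_normalize(s5)$values, uv$values,
               tolerance = 1e-12)
  expect_equal(minmax_normalize(toy_set(5 * s$values + 2))$values,
               mm$values, tolerance = 1e-12)
  expect_equal(minmax_normalize(mm)$values, mm$values, tolerance = 1e-12)
  expect_error(unit_vector_normalize(toy_set(matrix(0, 1, 10))), "zero")
  expect_error(minmax_normalize(toy_set(matrix(1, 1, 10))), "constant")
})

test_that("deresolve block-averages and preserves means on full blocks", {
  v <- matrix(seq_len(439), 1)
  s <- toy_set(v, grid = seq(11000, by = -8, length.out = 439))
  out <- deresolve(s, 2)
  expect_equal(ncol(out$values), 220)  # 219 pairs + trailing singleton
  expect_equal(unname(out$values[1, 1]), 1.5)
  expect_equal(unname(out$values[1, 220]), 439)
  even <- toy_set(matrix(rnorm(40), 1))
  expect_equal(mean(deresolve(even, 4)$values), mean(even$values),
               tolerance = 1e-12)
  cst <- toy_set(matrix(2, 1, 20))
  expect_true(all(deresolve(cst, 5)$values == 2))
  expect_error(deresolve(cst, 20), "smaller")
  expect_error(deresolve(cst, 3.5))
})

test_that("pre-treatments are row-wise and pass metadata through", {
  ds <- cached_dataset(1)
  cal <- ds$calibration
  specs <- default_spec_list()
  for (nm in names(specs)) {
    full <- apply_preprocess(cal, specs[[nm]])
    expect_identical(full$meta, cal$meta, info = nm)
    # processing a single spectrum alone gives that row of the full result
    one <- apply_preprocess(cal[3], specs[[nm]])
    expect_equal(unname(one$values[1, ]), unname(full$values[3, ]),
                 tolerance = 1e-12, info = nm)
  }
})

test_that("preprocess_spec validates its parameters", {
  expect_error(preprocess_spec("smoothing_savitzky_golay",
                               window_points = 10))
  expect_error(preprocess_spec("smoothing_savitzky_golay", poly_order = 11))
  expect_error(preprocess_spec("deresolve", deresolve_factor = 1))
  expect_error(preprocess_spec("no_such_method"))
  sp <- preprocess_spec("norris_gap_first_derivative", gap_points = 3)
  expect_equal(sp$gap_points, 3L)
})
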