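# Spectral pre-treatments. All methods are strictly per-spectrum (row-wise):
# no information crosses samples, so they cannot leak across CV folds.
# Fixed pipeline order: -log10(R) transform -> region selection ->
# pre-treatment -> (centering inside the regression).

#' Names of the available pre-treatments
#' @return Character vector of the nine method names.
#' @export
preprocess_methods <- function() {
  c("none", "smoothing_moving_average", "smoothing_savitzky_golay",
    "unit_vector_normalization", "minmax_normalization", "snv",
    "norris_gap_first_derivative", "norris_gap_second_derivative",
    "deresolve")
}

#' Pre-treatment specification
#'
#' @param method One of [preprocess_methods()].
#' @param window_points Odd window width for smoothing methods (default 11).
#' @param poly_order Savitzky-Golay polynomial order (default 2).
#' @param derivative_order Savitzky-Golay derivative order (0 for smoothing).
#' @param gap_points,segment_points Norris gap derivative parameters
#'   (defaults 5 and 5; segment must be odd).
#' @param deresolve_factor Block size for deresolve (integer >= 2).
#' @param region Retained wavenumber region `c(high_cm1, low_cm1)`; default
#'   7500-4000 cm^-1, the region with the strongest analyte contrast.
#' @return Object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = "none", window_points = 11,
                            poly_order = 2, derivative_order = 0,
                            gap_points = 5, segment_points = 5,
                            deresolve_factor = 2,
                            region = c(7500, 4000)) {
  method <- match.arg(method, preprocess_methods())
  stopifnot(window_points %% 2 == 1, window_points > poly_order,
            gap_points >= 1, segment_points %% 2 == 1,
            deresolve_factor >= 2, deresolve_factor %% 1 == 0,
            length(region) == 2, region[1] > region[2],
            derivative_order %in% 0:2, derivative_order <= poly_order)
  structure(list(method = method, window_points = as.integer(window_points),
                 poly_order = as.integer(poly_order),
                 derivative_order = as.integer(derivative_order),
                 gap_points = as.integer(gap_points),
                 segment_points = as.integer(segment_points),
                 deresolve_factor = as.integer(deresolve_factor),
                 region = as.numeric(region)),
            class = "preprocess_spec")
}

#' @export
print.preprocess_spec <- function(x, ...) {
  cat(sprintf("Preprocess spec: %s, region %g-%g cm^-1\n",
              x$method, x$region[1], x$region[2]))
  invisible(x)
}

#' Pre-treatment label as printed in method-development tables
#' @param spec A `preprocess_spec`.
#' @return A short display label like "(c) Smoothing-SavitzkyGolay".
#' @export
spec_label <- function(spec) {
  lbl <- c(none = "(a) None",
           smoothing_moving_average = "(b) Smoothing-Moving Average",
           smoothing_savitzky_golay = "(c) Smoothing-SavitzkyGolay",
           unit_vector_normalization = "(d) Unit Vector Normalization",
           minmax_normalization = "(e) Min/max normalization",
           snv = "(f) Standard Normal Variate",
           norris_gap_first_derivative = "(g) Norris Gap first derivative",
           norris_gap_second_derivative = "(h) Norris Gap second derivative",
           deresolve = "(i) Deresolve")
  unname(lbl[spec$method])
}

#' The default scan: all nine pre-treatments
#' @param region Retained region, passed to every spec.
#' @return Named list of nine `preprocess_spec` objects.
#' @export
default_spec_list <- function(region = c(7500, 4000)) {
  mk <- function(method, ...) preprocess_spec(method, region = region, ...)
  list(
    none = mk("none"),
    smoothing_moving_average = mk("smoothing_moving_average"),
    smoothing_savitzky_golay = mk("smoothing_savitzky_golay",
                                  derivative_order = 0),
    unit_vector_normalization = mk("unit_vector_normalization"),
    minmax_normalization = mk("minmax_normalization"),
    snv = mk("snv"),
    norris_gap_first_derivative = mk("norris_gap_first_derivative"),
    norris_gap_second_derivative = mk("norris_gap_second_derivative"),
    deresolve = mk("deresolve")
  )
}

#' Restrict a SpectrumSet to a wavenumber region
#'
#' Keeps exactly the grid points with `low_cm1 <= wavenumber <= high_cm1`
#' (both ends inclusive); metadata is unchanged.
#'
#' @param s A `spectrum_set`.
#' @param high_cm1,low_cm1 Region bounds in cm^-1.
#' @return A `spectrum_set` on the restricted grid.
#' @export
select_region <- function(s, high_cm1 = 7500, low_cm1 = 4000) {
  stopifnot(inherits(s, "spectrum_set"), high_cm1 > low_cm1)
  keep <- s$grid >= low_cm1 & s$grid <= high_cm1
  if (!any(keep)) {
    stop(sprintf("region %g-%g cm^-1 does not overlap the grid (%g-%g)",
                 high_cm1, low_cm1, max(s$grid), min(s$grid)), call. = FALSE)
  }
  spectrum_set(s$grid[keep], s$values[, keep, drop = FALSE], s$meta,
               domain = s$domain)
}

# --- row-wise kernels on plain matrices -------------------------------------

.ma_row <- function(x, w) {
  n <- length(x)
  half <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# Savitzky-Golay convolution weights: value (or derivative) of the local LS
# polynomial at integer offset `at`, from a window of offsets -m..m.
.sg_weights <- function(window, poly, deriv, at = 0) {
  m <- (window - 1L) %/% 2L
  V <- outer(seq(-m, m), 0:poly, `^`)
  A <- solve(crossprod(V), t(V))          # (poly+1) x window
  ts <- at^pmax(0:poly - deriv, 0)
  fac <- ifelse(0:poly >= deriv,
                factorial(0:poly) / factorial(pmax(0:poly - deriv, 0)), 0)
  # d-th derivative of sum_k a_k t^k at t = `at`
  drop((fac * ts * (0:poly >= deriv)) %*% A)
}

.sg_row <- function(x, window, poly, deriv, h) {
  n <- length(x)
  if (window > n) stop("window larger than spectrum", call. = FALSE)
  m <- (window - 1L) %/% 2L
  out <- numeric(n)
  w0 <- .sg_weights(window, poly, deriv, at = 0)
  for (i in (m + 1L):(n - m)) out[i] <- sum(w0 * x[(i - m):(i + m)])
  # edges: fit on the first/last full window, evaluate at the edge offsets
  for (i in seq_len(m)) {
    out[i] <- sum(.sg_weights(window, poly, deriv, at = i - m - 1L) *
                    x[1:window])
    j <- n - m + i
    out[j] <- sum(.sg_weights(window, poly, deriv, at = i) *
                    x[(n - window + 1L):n])
  }
  out / h^deriv
}

.norris_row <- function(x, gap, seg, order, h) {
  n <- length(x)
  s2 <- (seg - 1L) %/% 2L
  reach <- gap + s2
  if (2L * reach + 1L > n) {
    stop("gap/segment exceed the spectrum length", call. = FALSE)
  }
  # centered segment means, defined where the full segment fits
  xbar <- rep(NA_real_, n)
  cs <- cumsum(c(0, x))
  for (j in (s2 + 1L):(n - s2)) xbar[j] <- (cs[j + s2 + 1L] - cs[j - s2]) / seg
  lo <- reach + 1L; hi <- n - reach
  out <- rep(NA_real_, n)
  for (i in lo:hi) {
    out[i] <- if (order == 1L) {
      (xbar[i + gap] - xbar[i - gap]) / (2 * gap * h)
    } else {
      (xbar[i - gap] - 2 * xbar[i] + xbar[i + gap]) / (gap * h)^2
    }
  }
  out[seq_len(lo - 1L)] <- out[lo]
  out[(hi + 1L):n] <- out[hi]
  out
}

.apply_rows <- function(s, f, domain = "preprocessed", grid = s$grid) {
  vals <- t(apply(s$values, 1, f))
  if (nrow(s$values) == 1L) vals <- matrix(vals, nrow = 1L)
  spectrum_set(grid, vals, s$meta, domain = domain)
}

# --- user-facing pre-treatments ---------------------------------------------

#' Moving-average smoothing
#'
#' Unweighted mean over a centered odd window; edge windows shrink (truncate)
#' so the grid length is preserved.
#'
#' @param s A `spectrum_set`.
#' @param window_points Odd window width.
#' @return Smoothed `spectrum_set` on the same grid.
#' @export
moving_average <- function(s, window_points = 11) {
  stopifnot(inherits(s, "spectrum_set"), window_points %% 2 == 1)
  if (window_points > length(s$grid)) {
    stop("window larger than spectrum", call. = FALSE)
  }
  .apply_rows(s, function(x) .ma_row(x, window_points), domain = s$domain)
}

#' Savitzky-Golay smoothing / derivative filter
#'
#' Local least-squares polynomial fit on a centered window; smoothing is the
#' fitted value, derivatives are the fitted polynomial's derivatives scaled
#' by `step^-derivative_order` (units per cm^-1 along the point index
#' direction). Edge points are obtained by fitting the first/last full window
#' and evaluating at the edge offsets, preserving grid length.
#'
#' @param s A `spectrum_set`.
#' @param window_points Odd window width (> poly_order); default 11.
#' @param poly_order Polynomial order; default 2.
#' @param derivative_order 0 (smoothing), 1 or 2.
#' @return Filtered `spectrum_set` on the same grid.
#' @export
savitzky_golay <- function(s, window_points = 11, poly_order = 2,
                           derivative_order = 0) {
  stopifnot(inherits(s, "spectrum_set"),
            window_points %% 2 == 1, window_points > poly_order,
            derivative_order %in% 0:2, derivative_order <= poly_order)
  h <- abs(s$grid[1] - s$grid[2])
  .apply_rows(s, function(x) .sg_row(x, window_points, poly_order,
                                     derivative_order, h),
              domain = if (derivative_order == 0) s$domain else "preprocessed")
}

#' Norris gap derivative
#'
#' Segment-smoothed finite-difference derivative: segment means of
#' `segment_points` centered points, differenced over a gap of `gap_points`.
#' Order 1: `(xbar[i+g] - xbar[i-g]) / (2 g h)`;
#' order 2: `(xbar[i-g] - 2 xbar[i] + xbar[i+g]) / (g h)^2`, `h` the grid
#' step. Edges replicate the nearest computable value.
#'
#' @param s A `spectrum_set`.
#' @param gap_points Gap `g` in points (>= 1).
#' @param segment_points Odd segment width.
#' @param order Derivative order, 1 or 2.
#' @return Derivative `spectrum_set` on the same grid.
#' @export
norris_gap_derivative <- function(s, gap_points = 5, segment_points = 5,
                                  order = 1) {
  stopifnot(inherits(s, "spectrum_set"), gap_points >= 1,
            segment_points %% 2 == 1, order %in% 1:2)
  h <- abs(s$grid[1] - s$grid[2])
  .apply_rows(s, function(x) .norris_row(x, as.integer(gap_points),
                                         as.integer(segment_points),
                                         as.integer(order), h))
}

#' Standard normal variate (SNV)
#'
#' Per spectrum: subtract the mean, divide by the standard deviation
#' (divisor n-1). Removes per-spectrum offset and multiplicative scatter.
#'
#' @param s A `spectrum_set`.
#' @return Standardized `spectrum_set`.
#' @export
snv <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  sds <- apply(s$values, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant spectrum (sd = 0), cannot apply SNV: ",
         paste(s$meta$sample_id[sds == 0], collapse = ", "), call. = FALSE)
  }
  .apply_rows(s, function(x) (x - mean(x)) / stats::sd(x))
}

#' Unit-vector normalization
#'
#' Per spectrum: divide by the Euclidean norm.
#' @param s A `spectrum_set`.
#' @return Normalized `spectrum_set`.
#' @export
unit_vector_normalize <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  nrms <- sqrt(rowSums(s$values^2))
  if (any(nrms == 0)) {
    stop("zero-norm spectrum, cannot normalize: ",
         paste(s$meta$sample_id[nrms == 0], collapse = ", "), call. = FALSE)
  }
  .apply_rows(s, function(x) x / sqrt(sum(x^2)))
}

#' Min/max normalization
#'
#' Per spectrum: map linearly onto [0, 1].
#' @param s A `spectrum_set`.
#' @return Normalized `spectrum_set`.
#' @export
minmax_normalize <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  rng <- apply(s$values, 1, function(x) diff(range(x)))
  if (any(rng == 0)) {
    stop("constant spectrum, cannot min/max normalize: ",
         paste(s$meta$sample_id[rng == 0], collapse = ", "), call. = FALSE)
  }
  .apply_rows(s, function(x) (x - min(x)) / (max(x) - min(x)))
}

#' Deresolve (resolution reduction)
#'
#' Boxcar mean over non-overlapping blocks of `factor` consecutive points;
#' the grid is replaced by block-center (mean) wavenumbers. A trailing
#' partial block is averaged as-is.
#'
#' @param s A `spectrum_set`.
#' @param factor Integer block size >= 2.
#' @return Down-resolved `spectrum_set` on the block-center grid.
#' @export
deresolve <- function(s, factor = 2) {
  stopifnot(inherits(s, "spectrum_set"), factor %% 1 == 0, factor >= 2)
  n <- length(s$grid)
  if (factor >= n) stop("factor must be smaller than the spectrum length",
                        call. = FALSE)
  blocks <- split(seq_len(n), ceiling(seq_len(n) / factor))
  new_grid <- vapply(blocks, function(ix) mean(s$grid[ix]), numeric(1))
  vals <- t(apply(s$values, 1, function(x) {
    vapply(blocks, function(ix) mean(x[ix]), numeric(1))
  }))
  if (nrow(s$values) == 1L) vals <- matrix(vals, nrow = 1L)
  spectrum_set(new_grid, vals, s$meta, domain = "preprocessed")
}

#' Apply the full fixed-order pre-treatment pipeline
#'
#' Order: absorbance transform (`-log10 R`, skipped if already absorbance) ->
#' region selection -> the spec's pre-treatment. This order is fixed and
#' recorded with every fitted model.
#'
#' @param s A `spectrum_set` (reflectance or absorbance domain).
#' @param spec A [preprocess_spec()].
#' @return Preprocessed `spectrum_set` ready for regression.
#' @export
apply_preprocess <- function(s, spec) {
  stopifnot(inherits(s, "spectrum_set"), inherits(spec, "preprocess_spec"))
  a <- if (s$domain == "reflectance") to_absorbance(s) else s
  a <- select_region(a, spec$region[1], spec$region[2])
  switch(spec$method,
    none = a,
    smoothing_moving_average = moving_average(a, spec$window_points),
    smoothing_savitzky_golay = savitzky_golay(a, spec$window_points,
                                              spec$poly_order,
                                              spec$derivative_order),
    unit_vector_normalization = unit_vector_normalize(a),
    minmax_normalization = minmax_normalize(a),
    snv = snv(a),
    norris_gap_first_derivative = norris_gap_derivative(a, spec$gap_points,
                                                        spec$segment_points,
                                                        1),
    norris_gap_second_derivative = norris_gap_derivative(a, spec$gap_points,
                                                         spec$segment_points,
                                                         2),
    deresolve = deresolve(a, spec$deresolve_factor)
  )
}
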