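# Synthetic NIR reflectance generator. Emulates the structure the calibration
# analysis assumes: linear component mixing in absorbance, per-spectrum
# baseline drift, a multiplicative scatter factor, a between-series
# (batch/day) random offset shared by all spectra of a series, and additive
# white noise. It does not attempt physically assigned meloxicam band
# positions or particle-size scattering physics.

# Run code with a fixed RNG seed, restoring the caller's RNG state.
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

#' Random library of pure-component absorbance spectra
#'
#' Each component gets `n_bands_per_component` Gaussian absorbance bands
#' (center, width, amplitude per unit mass fraction). The analyte
#' (meloxicam) is guaranteed one strong band inside the 7500-4000 cm^-1
#' calibration region well separated from all excipient band centers, so the
#' analyte is identifiable there.
#'
#' @param seed Integer seed; the library is deterministic given the seed.
#' @param n_bands_per_component Bands per component (>= 1).
#' @return Object of class `pure_spectra_library`: named list (one entry per
#'   component) of data frames with columns `center_cm1`, `width_cm1`,
#'   `amplitude`.
#' @export
make_pure_library <- function(seed = 1L, n_bands_per_component = 6L) {
  stopifnot(n_bands_per_component >= 1)
  comps <- blend_components()
  lib <- with_seed(seed, {
    out <- lapply(comps, function(cmp) {
      data.frame(
        center_cm1 = stats::runif(n_bands_per_component, 4200, 10800),
        width_cm1 = stats::runif(n_bands_per_component, 80, 300),
        amplitude = stats::runif(n_bands_per_component, 0.3, 2.0)
      )
    })
    names(out) <- comps
    # carve out an analyte-only window: push any excipient band whose center
    # falls in [5200, 6000] out of it, then give meloxicam a strong band there
    for (cmp in setdiff(comps, "meloxicam")) {
      b <- out[[cmp]]
      inside <- b$center_cm1 > 5200 & b$center_cm1 < 6000
      b$center_cm1[inside] <- b$center_cm1[inside] + 1000
      out[[cmp]] <- b
    }
    out$meloxicam$center_cm1[1] <- stats::runif(1, 5400, 5800)
    out$meloxicam$width_cm1[1] <- stats::runif(1, 100, 200)
    out$meloxicam$amplitude[1] <- stats::runif(1, 1.5, 2.0)
    out
  })
  structure(lib, class = "pure_spectra_library")
}

#' Pure-component absorbance on a grid
#'
#' @param lib A [make_pure_library()] object.
#' @param component Component name.
#' @param grid Wavenumber grid (cm^-1).
#' @return Absorbance per unit mass fraction at each grid point.
#' @export
pure_absorbance <- function(lib, component, grid) {
  b <- lib[[component]]
  if (is.null(b)) stop("unknown component: ", component, call. = FALSE)
  a <- numeric(length(grid))
  for (k in seq_len(nrow(b))) {
    a <- a + b$amplitude[k] *
      exp(-0.5 * ((grid - b$center_cm1[k]) / b$width_cm1[k])^2)
  }
  a
}

#' Noise model for synthetic spectra
#'
#' Magnitudes were calibrated once by simulation so that the full default
#' pipeline (Savitzky-Golay smoothing + PLS) lands a validation prediction
#' RSD of about 1 % (repeatability RSD ~1.1 %), then frozen. Additive noise
#' dominates; scatter and between-series effects are present but small, so
#' intermediate precision stays close to repeatability.
#'
#' @param sigma_additive SD of additive absorbance noise per point.
#' @param sigma_scatter SD of the per-spectrum multiplicative scatter factor
#'   (around 1).
#' @param sigma_series SD of the between-series absorbance offset (drawn once
#'   per series).
#' @param baseline_slope_range Per-spectrum baseline slope drawn uniformly
#'   from this range, in absorbance per 10^4 cm^-1.
#' @param baseline_offset_range Per-spectrum baseline offset range
#'   (absorbance).
#' @param reflectance_floor Clipping floor keeping the log transform finite.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma_additive = 0.015,
                        sigma_scatter = 0.010,
                        sigma_series = 0.002,
                        baseline_slope_range = c(-0.08, 0.08),
                        baseline_offset_range = c(0.10, 0.25),
                        reflectance_floor = 1e-6) {
  stopifnot(sigma_additive >= 0, sigma_scatter >= 0, sigma_series >= 0,
            length(baseline_slope_range) == 2,
            length(baseline_offset_range) == 2,
            reflectance_floor > 0)
  structure(list(sigma_additive = sigma_additive,
                 sigma_scatter = sigma_scatter,
                 sigma_series = sigma_series,
                 baseline_slope_range = sort(baseline_slope_range),
                 baseline_offset_range = sort(baseline_offset_range),
                 reflectance_floor = reflectance_floor),
            class = "noise_model")
}

#' A noiseless noise model (all variances and drifts zero)
#' @return A `noise_model` with every stochastic magnitude set to 0 and a
#'   flat zero baseline.
#' @export
noise_free <- function() {
  noise_model(sigma_additive = 0, sigma_scatter = 0, sigma_series = 0,
              baseline_slope_range = c(0, 0),
              baseline_offset_range = c(0, 0))
}

#' Simulate one reflectance spectrum
#'
#' Absorbance model: `A = sum_c w_c eps_c + b0 + b1 * (nu/1e4) + delta_series
#' + e`, then `A' = m * A` with `m ~ N(1, sigma_scatter^2)`,
#' `e ~ N(0, sigma_additive^2)` i.i.d. per point. Returned reflectance is
#' `10^(-A')`, clipped at the floor. Randomness for baseline, scatter and
#' additive noise is taken from the current RNG state; the series offset
#' `series_delta` is passed in (drawn once per series upstream).
#'
#' @param composition A [composition_for_level()] object.
#' @param lib A pure-spectra library.
#' @param noise A [noise_model()].
#' @param grid Wavenumber grid.
#' @param series_delta Between-series absorbance offset for this sample's
#'   series.
#' @return Numeric reflectance row over `grid`, values in (0, 1].
#' @export
simulate_spectrum <- function(composition, lib, noise, grid = default_grid(),
                              series_delta = 0) {
  stopifnot(inherits(composition, "blend_composition"),
            inherits(noise, "noise_model"))
  w <- composition$masses_mg / composition$total_mg
  a <- numeric(length(grid))
  for (cmp in names(w)) {
    a <- a + w[[cmp]] * pure_absorbance(lib, cmp, grid)
  }
  if (max(a) > -log10(noise$reflectance_floor)) {
    stop("composition absorbance would underflow reflectance below the floor",
         call. = FALSE)
  }
  b0 <- stats::runif(1, noise$baseline_offset_range[1],
                     noise$baseline_offset_range[2])
  b1 <- stats::runif(1, noise$baseline_slope_range[1],
                     noise$baseline_slope_range[2])
  e <- if (noise$sigma_additive > 0) {
    stats::rnorm(length(grid), 0, noise$sigma_additive)
  } else 0
  m <- if (noise$sigma_scatter > 0) stats::rnorm(1, 1, noise$sigma_scatter)
       else 1
  a_tot <- m * (a + b0 + b1 * grid / 1e4 + series_delta + e)
  pmin(pmax(10^(-a_tot), noise$reflectance_floor), 1)
}

#' Simulate calibration and validation spectra for a protocol
#'
#' One spectrum per protocol entry. Between-series offsets are drawn once per
#' (role, series): validation batches are new manufacture, so their series
#' offsets are independent of the calibration ones. Fully reproducible from
#' `seed`.
#'
#' @param protocol A [build_protocol()] object.
#' @param lib Pure-spectra library; default [make_pure_library()] with the
#'   same seed.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param grid Wavenumber grid.
#' @param compensator Passed to [composition_for_level()].
#' @return List with `calibration` and `validation` spectrum sets
#'   (reflectance domain).
#' @export
generate_protocol_dataset <- function(protocol,
                                      lib = make_pure_library(seed),
                                      noise = noise_model(),
                                      seed = 1L,
                                      grid = default_grid(),
                                      compensator = "isomalt") {
  stopifnot(inherits(protocol, "protocol_matrix"))
  e <- protocol$entries
  comps <- lapply(unique(e$meloxicam_pct_ww), composition_for_level,
                  compensator = compensator)
  names(comps) <- as.character(unique(e$meloxicam_pct_ww))

  with_seed(seed, {
    keys <- unique(paste(e$role, e$series))
    deltas <- stats::rnorm(length(keys), 0, noise$sigma_series)
    names(deltas) <- keys

    values <- matrix(NA_real_, nrow(e), length(grid))
    for (i in seq_len(nrow(e))) {
      values[i, ] <- simulate_spectrum(
        comps[[as.character(e$meloxicam_pct_ww[i])]], lib, noise, grid,
        series_delta = deltas[[paste(e$role[i], e$series[i])]])
    }
    meta <- data.frame(sample_id = e$sample_id, role = e$role,
                       series = e$series, level_index = e$level_index,
                       nominal_pct_ww = e$meloxicam_pct_ww,
                       stringsAsFactors = FALSE)
    cal <- e$role == "cal"
    list(
      calibration = spectrum_set(grid, values[cal, , drop = FALSE],
                                 meta[cal, , drop = FALSE], "reflectance"),
      validation = spectrum_set(grid, values[!cal, , drop = FALSE],
                                meta[!cal, , drop = FALSE], "reflectance")
    )
  })
}
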