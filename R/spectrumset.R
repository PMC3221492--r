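#' Construct a SpectrumSet
#'
#' Container for a set of spectra on a shared uniform wavenumber grid plus
#' per-sample metadata. The grid is stored in descending instrument order
#' (high to low cm^-1). `domain` records what the matrix values are:
#' raw reflectance in (0, 1], absorbance (-log10 reflectance), or the output
#' of a pre-treatment.
#'
#' @param grid Numeric vector of wavenumbers (cm^-1), uniformly spaced,
#'   descending.
#' @param values Numeric matrix, one row per sample, `length(grid)` columns.
#' @param meta Data frame with one row per sample; must contain columns
#'   `sample_id`, `role`, `series`, `level_index`, `nominal_pct_ww`.
#' @param domain One of `"reflectance"`, `"absorbance"`, `"preprocessed"`.
#' @return Object of class `spectrum_set`.
#' @export
spectrum_set <- function(grid, values, meta,
                         domain = c("reflectance", "absorbance",
                                    "preprocessed")) {
  domain <- match.arg(domain)
  values <- as.matrix(values)
  grid <- as.numeric(grid)
  if (length(grid) < 2) stop("grid needs at least 2 points", call. = FALSE)
  d <- diff(grid)
  if (any(d >= 0)) stop("grid must be strictly descending", call. = FALSE)
  if (domain != "preprocessed" &&
      max(abs(d - d[1])) > 1e-9 * abs(d[1])) {
    stop("grid must be uniformly spaced", call. = FALSE)
  }
  if (ncol(values) != length(grid)) {
    stop("values must have one column per grid point", call. = FALSE)
  }
  need <- c("sample_id", "role", "series", "level_index", "nominal_pct_ww")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("meta is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(meta) != nrow(values)) {
    stop("meta must have one row per spectrum", call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in meta", call. = FALSE)
  }
  if (domain == "reflectance" && any(values <= 0)) {
    stop("reflectance values must be strictly positive", call. = FALSE)
  }
  rownames(values) <- meta$sample_id
  structure(list(grid = grid, values = values,
                 meta = as.data.frame(meta, stringsAsFactors = FALSE),
                 domain = domain),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("SpectrumSet: %d spectra x %d points (%s), %g to %g cm^-1\n",
              nrow(x$values), length(x$grid), x$domain,
              max(x$grid), min(x$grid)))
  cat(sprintf("  roles: %s; series: %s; levels: %s\n",
              paste(unique(x$meta$role), collapse = "/"),
              paste(sort(unique(x$meta$series)), collapse = ","),
              paste(sort(unique(x$meta$level_index)), collapse = ",")))
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$values)

#' Number of spectra in a SpectrumSet
#' @param s A `spectrum_set`.
#' @return Integer count of spectra (rows).
#' @export
n_spectra <- function(s) nrow(s$values)

#' Subset a SpectrumSet by sample
#' @param x A `spectrum_set`.
#' @param i Row index (logical, integer, or sample_id character).
#' @param ... Unused.
#' @return A `spectrum_set` with the selected spectra.
#' @export
`[.spectrum_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$meta$sample_id)
  spectrum_set(x$grid, x$values[i, , drop = FALSE],
               x$meta[i, , drop = FALSE], domain = x$domain)
}

#' Convert reflectance to absorbance
#'
#' Applies the fixed first step of the pipeline, A = -log10(R), the
#' Beer-Lambert analogue under which component mixing is assumed linear.
#'
#' @param s A `spectrum_set` in the reflectance domain.
#' @return A `spectrum_set` in the absorbance domain.
#' @export
to_absorbance <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  if (s$domain == "absorbance") return(s)
  if (s$domain != "reflectance") {
    stop("to_absorbance() expects reflectance input", call. = FALSE)
  }
  spectrum_set(s$grid, -log10(s$values), s$meta, domain = "absorbance")
}

#' Default instrument wavenumber grid
#'
#' @param start_cm1,end_cm1,step_cm1 Grid bounds and spacing in cm^-1.
#' @return Descending numeric grid; defaults give 876 points from 11000 to
#'   4000 cm^-1 at 8 cm^-1 spacing.
#' @export
default_grid <- function(start_cm1 = 11000, end_cm1 = 4000, step_cm1 = 8) {
  stopifnot(start_cm1 > end_cm1, step_cm1 > 0)
  if (abs(((start_cm1 - end_cm1) / step_cm1) %% 1) > 1e-9) {
    stop("(start - end) must be divisible by step", call. = FALSE)
  }
  seq(start_cm1, end_cm1, by = -step_cm1)
}
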