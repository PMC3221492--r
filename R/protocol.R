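# Fixed tablet mass (mg) and the components that never vary across levels.
.TOTAL_MG <- 120
.FIXED_MG <- c(
  sodium_starch_glycolate = 6,
  silicon_dioxide = 1.2,
  magnesium_stearate = 0.6
)

#' Component names of the meloxicam tablet formulation
#'
#' @return Character vector of the six blend components in formulation order.
#' @export
blend_components <- function() {
  c("meloxicam", "isomalt", "microcrystalline_cellulose",
    "sodium_starch_glycolate", "silicon_dioxide", "magnesium_stearate")
}

#' Blend composition for a given meloxicam content
#'
#' Builds the per-tablet composition (mg) for a formulation level, keeping
#' tablet mass at exactly 120 mg. Meloxicam mass is `1.2 * meloxicam_pct_ww`
#' and one filler compensates so that masses always sum to 120 mg. By default
#' isomalt compensates while microcrystalline cellulose is fixed at 45 mg;
#' the roles can be swapped with `compensator`.
#'
#' @param meloxicam_pct_ww Meloxicam content, percent w/w of the blend.
#' @param compensator Which filler absorbs the meloxicam change:
#'   `"isomalt"` (default) or `"microcrystalline_cellulose"`.
#' @return An object of class `blend_composition`: a list with
#'   `level_pct_of_target` (percent of the 12.5 % w/w target formulation),
#'   `meloxicam_pct_ww`, `masses_mg` (named vector over the six components)
#'   and `total_mg`.
#' @examples
#' composition_for_level(12.5) # the 100 % target formulation
#' @export
composition_for_level <- function(meloxicam_pct_ww,
                                  compensator = c("isomalt",
                                                  "microcrystalline_cellulose")) {
  compensator <- match.arg(compensator)
  stopifnot(is.numeric(meloxicam_pct_ww), length(meloxicam_pct_ww) == 1L,
            is.finite(meloxicam_pct_ww))
  meloxicam_mg <- 1.2 * meloxicam_pct_ww
  fixed_filler <- if (compensator == "isomalt") {
    c(microcrystalline_cellulose = 45)
  } else {
    c(isomalt = 52.2)
  }
  other_mg <- sum(.FIXED_MG) + fixed_filler
  comp_mg <- .TOTAL_MG - meloxicam_mg - other_mg
  max_pct <- unname((.TOTAL_MG - other_mg) / 1.2)
  if (meloxicam_pct_ww <= 0 || comp_mg < 0) {
    stop(sprintf(
      "meloxicam_pct_ww = %g is outside the feasible range (0, %g] %% w/w for compensator '%s'",
      meloxicam_pct_ww, max_pct, compensator), call. = FALSE)
  }
  masses <- c(meloxicam = unname(meloxicam_mg), fixed_filler, .FIXED_MG)
  masses[compensator] <- unname(comp_mg)
  masses <- masses[blend_components()]
  structure(list(
    level_pct_of_target = 100 * meloxicam_pct_ww / 12.5,
    meloxicam_pct_ww = meloxicam_pct_ww,
    masses_mg = masses,
    total_mg = .TOTAL_MG
  ), class = "blend_composition")
}

#' @export
print.blend_composition <- function(x, ...) {
  cat(sprintf("Blend composition: %.2f %% w/w meloxicam (%.0f %% of target)\n",
              x$meloxicam_pct_ww, x$level_pct_of_target))
  m <- x$masses_mg
  for (nm in names(m)) cat(sprintf("  %-27s %7.2f mg\n", nm, m[[nm]]))
  cat(sprintf("  %-27s %7.2f mg\n", "total", x$total_mg))
  invisible(x)
}

#' Concentration levels of the calibration design
#'
#' @return Data frame with `level_index` (1-5), `level_pct_of_target`
#'   (80-120 %) and `meloxicam_pct_ww` (10.00-15.00 % w/w).
#' @export
design_levels <- function() {
  data.frame(
    level_index = 1:5,
    level_pct_of_target = seq(80, 120, by = 10),
    meloxicam_pct_ww = seq(80, 120, by = 10) * 12.5 / 100
  )
}

#' Calibration/validation protocol matrix
#'
#' Builds the experimental design: one calibration sample per
#' (level, series) cell over all five levels, and `val_reps` validation
#' replicates per series at the levels in `val_levels` (extreme and central
#' levels by default). With defaults this yields 15 calibration and 36
#' validation samples.
#'
#' @param n_series Number of independent batch series (>= 2).
#' @param val_levels Level indices carrying validation samples
#'   (subset of 1:5).
#' @param val_reps Validation replicates per series per level (>= 2).
#' @return Object of class `protocol_matrix`: list with `levels`
#'   (see [design_levels()]), `entries` (one row per physical sample:
#'   `sample_id`, `role`, `series`, `replicate`, `level_index`,
#'   `level_pct_of_target`, `meloxicam_pct_ww`) and `n_series`.
#'   Entries are ordered role (cal before val), then level, series, replicate.
#' @export
build_protocol <- function(n_series = 3, val_levels = c(1, 3, 5), val_reps = 4) {
  stopifnot(n_series >= 2, val_reps >= 2)
  if (!all(val_levels %in% 1:5)) {
    stop("val_levels must be a subset of {1,...,5}", call. = FALSE)
  }
  val_levels <- sort(unique(as.integer(val_levels)))
  lv <- design_levels()

  cal <- expand.grid(replicate = 1L, series = seq_len(n_series),
                     level_index = 1:5)
  val <- expand.grid(replicate = seq_len(val_reps),
                     series = seq_len(n_series),
                     level_index = val_levels)
  mk <- function(d, role) {
    d <- d[order(d$level_index, d$series, d$replicate), , drop = FALSE]
    d$role <- role
    d
  }
  entries <- rbind(mk(cal, "cal"), mk(val, "val"))
  entries <- merge(entries, lv, by = "level_index", sort = FALSE)
  entries <- entries[order(entries$role, entries$level_index,
                           entries$series, entries$replicate), ]
  entries$sample_id <- sprintf("%s_L%d_S%d_R%d", entries$role,
                               entries$level_index, entries$series,
                               entries$replicate)
  rownames(entries) <- NULL
  entries <- entries[, c("sample_id", "role", "series", "replicate",
                         "level_index", "level_pct_of_target",
                         "meloxicam_pct_ww")]
  structure(list(levels = lv, entries = entries, n_series = n_series,
                 val_levels = val_levels, val_reps = val_reps),
            class = "protocol_matrix")
}

#' @export
print.protocol_matrix <- function(x, ...) {
  n_cal <- sum(x$entries$role == "cal")
  n_val <- sum(x$entries$role == "val")
  cat(sprintf(
    "Protocol matrix: %d series x 5 levels; %d calibration, %d validation samples\n",
    x$n_series, n_cal, n_val))
  cat(sprintf("  validation levels: %s (%d replicates/series)\n",
              paste(x$val_levels, collapse = ", "), x$val_reps))
  invisible(x)
}

#' Export a protocol as a plain sample manifest
#'
#' One row per sample with its role, series, level and full per-component
#' composition; suitable for writing to CSV.
#'
#' @param protocol A [build_protocol()] object.
#' @param compensator Passed to [composition_for_level()].
#' @return Data frame: `sample_id`, `role`, `series`, `level_index`,
#'   `level_pct_of_target`, `meloxicam_pct_ww`, then one `<component>_mg`
#'   column per component.
#' @export
protocol_manifest <- function(protocol, compensator = "isomalt") {
  stopifnot(inherits(protocol, "protocol_matrix"))
  e <- protocol$entries
  comp <- t(vapply(e$meloxicam_pct_ww, function(p) {
    composition_for_level(p, compensator = compensator)$masses_mg
  }, numeric(6)))
  colnames(comp) <- paste0(blend_components(), "_mg")
  cbind(e[, c("sample_id", "role", "series", "level_index",
              "level_pct_of_target", "meloxicam_pct_ww")],
        as.data.frame(comp))
}
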