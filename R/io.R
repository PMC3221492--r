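# File formats and the command-line surface. The canonical spectrum format
# is a wide CSV: metadata columns then one column per wavenumber, stored in
# descending instrument order. A leading '#' comment line records tool
# version and seed.

.META_COLS <- c("sample_id", "role", "series", "level_index",
                "nominal_pct_ww")

.nirblend_version <- function() {
  as.character(utils::packageVersion("nirblend"))
}

#' Write a SpectrumSet as wide CSV
#'
#' @param s A `spectrum_set`.
#' @param path Output path.
#' @param seed Optional seed to record in the header comment.
#' @return `path`, invisibly.
#' @export
write_spectrumset <- function(s, path, seed = NA) {
  stopifnot(inherits(s, "spectrum_set"))
  d <- cbind(s$meta[.META_COLS], as.data.frame(s$values))
  names(d) <- c(.META_COLS, format(s$grid, trim = TRUE, scientific = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nirblend %s spectrumset domain=%s seed=%s",
                     .nirblend_version(), s$domain, seed), con)
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a SpectrumSet from wide CSV
#'
#' Accepts the format written by [write_spectrumset()]. Wavenumber columns
#' must be monotone; ascending grids are flipped to instrument order with a
#' message. Non-uniform grids, duplicate sample ids and missing metadata
#' columns are rejected.
#'
#' @param path Input path.
#' @param domain Value domain of the file (default `"reflectance"`).
#' @return A `spectrum_set`.
#' @export
read_spectrumset <- function(path, domain = "reflectance") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2) {
    stop("empty or header-only spectrum file: ", path, call. = FALSE)
  }
  d <- utils::read.csv(text = lines, check.names = FALSE,
                       stringsAsFactors = FALSE)
  miss <- setdiff(.META_COLS, names(d))
  if (length(miss)) {
    stop("missing metadata columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  wn_cols <- setdiff(names(d), .META_COLS)
  grid <- suppressWarnings(as.numeric(wn_cols))
  if (anyNA(grid)) {
    stop("non-numeric wavenumber column name: ",
         wn_cols[which(is.na(grid))[1]], call. = FALSE)
  }
  dg <- diff(grid)
  if (all(dg > 0)) {
    message("ascending wavenumber grid in ", path,
            ": flipping to instrument (descending) order")
    ord <- rev(seq_along(grid))
    grid <- grid[ord]
    wn_cols <- wn_cols[ord]
    dg <- diff(grid)
  }
  if (any(dg >= 0)) {
    bad <- which(dg >= 0)[1] + 1L
    stop("wavenumber columns out of order starting at column '",
         wn_cols[bad], "'", call. = FALSE)
  }
  vals <- as.matrix(d[, wn_cols, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals)) {
    bad_row <- which(apply(d[, wn_cols, drop = FALSE], 1,
                           function(r) anyNA(suppressWarnings(
                             as.numeric(r)))))[1]
    stop("malformed spectral values at data row ", bad_row,
         " (file line ", bad_row + 1L, " after comments)", call. = FALSE)
  }
  spectrum_set(grid, vals, d[.META_COLS], domain = domain)
}

#' Write the pre-treatment scan table as CSV
#'
#' Column layout mirrors the method-development tables: pre-treatment,
#' model, PC number, RMSECV, RMSEP, R^2, bias.
#'
#' @param gs A `grid_search_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_table <- function(gs, path) {
  stopifnot(inherits(gs, "grid_search_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nirblend %s gridsearch", .nirblend_version()), con)
  utils::write.csv(gs$table[, c("pretreatment", "model", "pc_number",
                                "rmsecv", "rmsep", "r2", "bias", "error")],
                   con, row.names = FALSE)
  invisible(path)
}

#' Write a validation report as tidy CSV
#'
#' Four blocks (trueness, precision, accuracy profile, linearity profile)
#' stacked in one tidy table with a `block` column, mirroring the standard
#' validation-report layout, plus the linearity fit as attribute rows.
#'
#' @param report A `validation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  lv <- report$profile$levels
  lin <- report$linearity
  blocks <- rbind(
    data.frame(block = "trueness", nominal = lv$nominal,
               value1 = lv$mean_pred, value2 = lv$recovery,
               value3 = NA_real_, value4 = NA_real_,
               label1 = "mean_pred", label2 = "recovery",
               label3 = NA, label4 = NA),
    data.frame(block = "precision", nominal = lv$nominal,
               value1 = lv$relative_bias, value2 = lv$rsd_repeatability,
               value3 = lv$rsd_intermediate, value4 = NA_real_,
               label1 = "relative_bias", label2 = "rsd_repeatability",
               label3 = "rsd_intermediate", label4 = NA),
    data.frame(block = "accuracy_profile", nominal = lv$nominal,
               value1 = lv$rel_tol_lower, value2 = lv$rel_tol_upper,
               value3 = lv$acceptance_lower, value4 = lv$acceptance_upper,
               label1 = "rel_tol_lower", label2 = "rel_tol_upper",
               label3 = "acceptance_lower", label4 = "acceptance_upper"),
    data.frame(block = "linearity_profile", nominal = lin$levels$nominal,
               value1 = lin$levels$abs_tol_lower,
               value2 = lin$levels$abs_tol_upper,
               value3 = lin$levels$acceptance_lower,
               value4 = lin$levels$acceptance_upper,
               label1 = "abs_tol_lower", label2 = "abs_tol_upper",
               label3 = "acceptance_lower", label4 = "acceptance_upper")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nirblend %s validation slope=%.6f intercept=%.6f r2=%.6f",
                     .nirblend_version(), lin$slope, lin$intercept, lin$r2),
             con)
  utils::write.csv(blocks, con, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Collects every tunable of the pipeline in one serializable list; every
#' CLI run writes the resolved configuration beside its outputs.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = ".") {
  structure(list(
    grid = list(start_cm1 = 11000, end_cm1 = 4000, step_cm1 = 8),
    region = c(7500, 4000),
    methods = c("PLS", "PCR"),
    max_factors = 10,
    cv_scheme = "loo", cv_group_size = 2,
    selection_rule = "ratio", f_thresh = 1.05,
    beta = 0.95, acceptance_rel = 5,
    noise = unclass(noise_model()),
    seed = as.integer(seed),
    out_dir = out_dir
  ), class = "run_config")
}

#' Write / read a run configuration (JSON)
#' @param config A `run_config`.
#' @param path File path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$noise <- do.call(noise_model, cfg$noise[setdiff(names(cfg$noise),
                                                      character(0))])
  cfg$noise <- unclass(cfg$noise)
  structure(cfg, class = "run_config")
}

# minimal --flag value parser for the CLI
.parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  pos <- character(0)
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        flags[[substring(a, 3)]] <- TRUE
        i <- i + 1L
      } else {
        flags[[substring(a, 3)]] <- args[i + 1L]
        i <- i + 2L
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = pos)
}

.cli_log <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}

#' Command-line entry point
#'
#' Commands: `simulate` (protocol -> calibration/validation CSVs),
#' `gridsearch` (CSV datasets -> ranked pre-treatment/method table),
#' `calibrate` (dataset + spec -> model JSON), `validate` (model +
#' validation CSV -> report CSV), `report` (print a saved model and report).
#' Returns an integer exit status instead of quitting, so it is testable;
#' the installed `nirblend` script wraps it with `quit(status = ...)`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
nirblend_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: nirblend <command> [--flags]",
    "  simulate   --seed S --out-dir D [--sigma-additive x ...]",
    "  gridsearch --cal cal.csv --val val.csv --out table.csv",
    "  calibrate  --cal cal.csv --method PLS|PCR --pretreatment NAME",
    "             --factors H --out model.json",
    "  validate   --model model.json --val val.csv --out report.csv",
    "             [--acceptance-rel 5] [--beta 0.95]",
    "  report     --model model.json", sep = "\n")
  status <- tryCatch({
    if (length(args) == 0) { message(usage); return(invisible(2L)) }
    cmd <- args[1]
    pf <- .parse_flags(args[-1])
    fl <- pf$flags
    getf <- function(name, default = NULL) {
      if (!is.null(fl[[name]])) fl[[name]] else default
    }
    reqf <- function(name) {
      v <- fl[[name]]
      if (is.null(v)) stop("missing required flag --", name, call. = FALSE)
      v
    }
    switch(cmd,
      simulate = {
        seed <- as.integer(getf("seed", 1))
        out_dir <- getf("out-dir", ".")
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        nm <- noise_model(
          sigma_additive = as.numeric(getf("sigma-additive",
                                           noise_model()$sigma_additive)),
          sigma_scatter = as.numeric(getf("sigma-scatter",
                                          noise_model()$sigma_scatter)),
          sigma_series = as.numeric(getf("sigma-series",
                                         noise_model()$sigma_series)))
        .cli_log("simulating protocol dataset, seed %d", seed)
        prot <- build_protocol()
        ds <- generate_protocol_dataset(prot, noise = nm, seed = seed)
        write_spectrumset(ds$calibration,
                          file.path(out_dir, "calibration.csv"), seed = seed)
        write_spectrumset(ds$validation,
                          file.path(out_dir, "validation.csv"), seed = seed)
        cfg <- run_config(seed = seed, out_dir = out_dir)
        cfg$noise <- unclass(nm)
        write_config(cfg, file.path(out_dir, "config.json"))
        .cli_log("wrote %d calibration and %d validation spectra to %s",
                 n_spectra(ds$calibration), n_spectra(ds$validation), out_dir)
        0L
      },
      gridsearch = {
        cal <- read_spectrumset(reqf("cal"))
        val <- read_spectrumset(reqf("val"))
        .cli_log("scanning %d pre-treatments x PLS/PCR", 9)
        gs <- grid_search(cal, val)
        print(gs)
        write_grid_table(gs, reqf("out"))
        .cli_log("wrote %s", reqf("out"))
        0L
      },
      calibrate = {
        cal <- read_spectrumset(reqf("cal"))
        spec <- preprocess_spec(getf("pretreatment",
                                     "smoothing_savitzky_golay"))
        h <- getf("factors")
        model <- calibrate(cal, spec, method = getf("method", "PLS"),
                           n_factors = if (is.null(h)) NULL
                                       else as.integer(h))
        write_model(model, reqf("out"))
        .cli_log("calibrated %s model (%d factors) -> %s", model$method,
                 model$n_factors, reqf("out"))
        0L
      },
      validate = {
        model <- read_model(reqf("model"))
        val <- read_spectrumset(reqf("val"))
        rep <- validate_model(model, val,
                              acceptance_rel = as.numeric(
                                getf("acceptance-rel", 5)),
                              beta = as.numeric(getf("beta", 0.95)))
        print(rep)
        write_validation_report(rep, reqf("out"))
        .cli_log("wrote %s", reqf("out"))
        0L
      },
      report = {
        model <- read_model(reqf("model"))
        print(model)
        0L
      },
      {
        message("unknown command: ", cmd, "\n", usage)
        2L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
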