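# ICH-style external validation via accuracy profiles: per-level trueness,
# precision from a one-way (series) random-effects ANOVA, beta-expectation
# tolerance intervals on the relative scale, linearity, and the compliance
# decision against relative acceptance limits.

#' Trueness of grouped predictions at one level
#'
#' @param predictions Predicted concentrations (% w/w) at the level.
#' @param nominal Nominal concentration (% w/w), > 0.
#' @return List: `mean_pred`, `recovery` (%, `100 * mean / nominal`),
#'   `relative_bias` (%, `100 * (mean - nominal) / nominal`).
#' @export
trueness <- function(predictions, nominal) {
  if (!is.numeric(nominal) || length(nominal) != 1 || nominal <= 0) {
    stop("nominal must be a single positive concentration", call. = FALSE)
  }
  stopifnot(length(predictions) >= 1)
  m <- mean(predictions)
  list(mean_pred = m, recovery = 100 * m / nominal,
       relative_bias = 100 * (m - nominal) / nominal)
}

#' Variance components from a balanced series x replicate design
#'
#' One-way random-effects ANOVA. Within-series variance is the within mean
#' square; the between-series component is `(MS_B - MS_W) / n`, clipped at
#' zero (the standard moment estimator); intermediate precision is their sum.
#'
#' @param predictions Numeric matrix, `p` series (rows) x `n` replicates
#'   (columns), or a data frame / list convertible to one.
#' @return List: `s_w2`, `s_b2`, `s_ip2` (variance components, (%w/w)^2),
#'   `grand_mean`, `p`, `n`, `ms_within`, `ms_between`, `df_within`,
#'   `df_between`.
#' @export
variance_components <- function(predictions) {
  m <- as.matrix(predictions)
  p <- nrow(m); n <- ncol(m)
  if (p < 2 || n < 2) {
    stop("need at least 2 series and 2 replicates per series", call. = FALSE)
  }
  if (anyNA(m)) stop("unbalanced design (missing cells) is not supported",
                     call. = FALSE)
  series_means <- rowMeans(m)
  grand <- mean(m)
  ms_w <- sum((m - series_means)^2) / (p * (n - 1))
  ms_b <- n * sum((series_means - grand)^2) / (p - 1)
  s_w2 <- ms_w
  s_b2 <- max(0, (ms_b - ms_w) / n)
  list(s_w2 = s_w2, s_b2 = s_b2, s_ip2 = s_w2 + s_b2, grand_mean = grand,
       p = p, n = n, ms_within = ms_w, ms_between = ms_b,
       df_within = p * (n - 1), df_between = p - 1)
}

#' Beta-expectation tolerance interval (relative scale)
#'
#' Interval expected to contain a proportion `beta` of future single
#' results, from the two-component (within/between series) precision model.
#' Satterthwaite degrees of freedom:
#' `nu = (R+1)^2 / ((R + 1/n)^2/(p-1) + (1 - 1/n)/(p n))` with
#' `R = s_b2/s_w2`, and limits
#' `relative_bias +/- t_{nu,(1+beta)/2} sqrt(1 + 1/(p n B^2)) RSD_IP`,
#' `B^2 = (R+1)/(nR+1)`, `RSD_IP = 100 sqrt(s_ip2)/nominal`.
#'
#' @param relative_bias Relative bias at the level (%).
#' @param s_w2,s_b2 Variance components from [variance_components()].
#' @param p,n Series count and replicates per series.
#' @param nominal Nominal concentration (% w/w) used to scale RSD_IP.
#' @param beta Expectation proportion, default 0.95.
#' @return List: `rel_tol_lower`, `rel_tol_upper` (%), `nu`, `coverage_k`
#'   (the multiplier of RSD_IP), `degenerate` (TRUE when both components are
#'   zero, in which case the interval collapses to the bias).
#' @export
tolerance_interval <- function(relative_bias, s_w2, s_b2, p, n, nominal,
                               beta = 0.95) {
  stopifnot(beta > 0, beta < 1, p >= 2, n >= 2, nominal > 0,
            s_w2 >= 0, s_b2 >= 0)
  s_ip2 <- s_w2 + s_b2
  if (s_ip2 == 0) {
    return(list(rel_tol_lower = relative_bias,
                rel_tol_upper = relative_bias,
                nu = NA_real_, coverage_k = 0, degenerate = TRUE))
  }
  R <- if (s_w2 == 0) 1e12 else s_b2 / s_w2
  B2 <- (R + 1) / (n * R + 1)
  nu <- (R + 1)^2 / ((R + 1 / n)^2 / (p - 1) + (1 - 1 / n) / (p * n))
  rsd_ip <- 100 * sqrt(s_ip2) / nominal
  k <- stats::qt((1 + beta) / 2, nu) * sqrt(1 + 1 / (p * n * B2))
  list(rel_tol_lower = relative_bias - k * rsd_ip,
       rel_tol_upper = relative_bias + k * rsd_ip,
       nu = nu, coverage_k = k, degenerate = FALSE)
}

#' Accuracy profile from external validation predictions
#'
#' One row per concentration level: trueness, precision RSDs,
#' beta-expectation tolerance limits (relative and absolute) and the
#' compliance decision (tolerance interval inside the acceptance interval).
#'
#' @param predictions Data frame with columns `nominal` (% w/w), `series`
#'   and `prediction` (% w/w); the design must be balanced within each level.
#' @param acceptance_rel Relative acceptance limit in % (default 5; a wider
#'   regulatory bound such as 15 can be passed instead).
#' @param beta Tolerance-interval expectation proportion (default 0.95).
#' @return Object of class `accuracy_profile`: data frame `levels` with
#'   columns `nominal`, `p`, `n`, `mean_pred`, `recovery`, `relative_bias`,
#'   `s_w2`, `s_b2`, `s_ip2`, `rsd_repeatability`, `rsd_intermediate`,
#'   `rel_tol_lower`, `rel_tol_upper`, `abs_tol_lower`, `abs_tol_upper`,
#'   `acceptance_lower`, `acceptance_upper`, `compliant`; plus
#'   `acceptance_rel`, `beta` and `validated_range` (range of contiguous
#'   compliant levels, NA if none).
#' @export
accuracy_profile <- function(predictions, acceptance_rel = 5, beta = 0.95) {
  stopifnot(is.data.frame(predictions),
            all(c("nominal", "series", "prediction") %in% names(predictions)),
            acceptance_rel > 0)
  levels_nominal <- sort(unique(predictions$nominal))
  rows <- lapply(levels_nominal, function(nom) {
    d <- predictions[predictions$nominal == nom, ]
    counts <- table(d$series)
    if (length(unique(counts)) != 1) {
      stop(sprintf("unbalanced replicates across series at level %g", nom),
           call. = FALSE)
    }
    p <- length(counts); n <- as.integer(counts[1])
    mat <- do.call(rbind, lapply(split(d$prediction, d$series), identity))
    tr <- trueness(d$prediction, nom)
    vc <- variance_components(mat)
    ti <- tolerance_interval(tr$relative_bias, vc$s_w2, vc$s_b2, p, n, nom,
                             beta)
    data.frame(
      nominal = nom, p = p, n = n,
      mean_pred = tr$mean_pred, recovery = tr$recovery,
      relative_bias = tr$relative_bias,
      s_w2 = vc$s_w2, s_b2 = vc$s_b2, s_ip2 = vc$s_ip2,
      rsd_repeatability = 100 * sqrt(vc$s_w2) / vc$grand_mean,
      rsd_intermediate = 100 * sqrt(vc$s_ip2) / vc$grand_mean,
      rel_tol_lower = ti$rel_tol_lower, rel_tol_upper = ti$rel_tol_upper,
      abs_tol_lower = nom * (1 + ti$rel_tol_lower / 100),
      abs_tol_upper = nom * (1 + ti$rel_tol_upper / 100),
      acceptance_lower = -acceptance_rel, acceptance_upper = acceptance_rel,
      compliant = ti$rel_tol_lower >= -acceptance_rel &
        ti$rel_tol_upper <= acceptance_rel
    )
  })
  lv <- do.call(rbind, rows)
  rownames(lv) <- NULL
  comp <- lv$compliant
  validated_range <- if (any(comp)) {
    runs <- rle(comp)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    iwin <- which.max(ifelse(runs$values, runs$lengths, 0))
    c(lv$nominal[starts[iwin]], lv$nominal[ends[iwin]])
  } else c(NA_real_, NA_real_)
  structure(list(levels = lv, acceptance_rel = acceptance_rel, beta = beta,
                 validated_range = validated_range),
            class = "accuracy_profile")
}

#' @export
print.accuracy_profile <- function(x, ...) {
  cat(sprintf("Accuracy profile (beta = %g, acceptance +/- %g %%)\n",
              x$beta, x$acceptance_rel))
  lv <- x$levels
  show <- data.frame(nominal = lv$nominal,
                     recovery = round(lv$recovery, 2),
                     rel_bias = round(lv$relative_bias, 4),
                     rsd_rep = round(lv$rsd_repeatability, 3),
                     rsd_ip = round(lv$rsd_intermediate, 3),
                     tol_lo = round(lv$rel_tol_lower, 3),
                     tol_hi = round(lv$rel_tol_upper, 3),
                     compliant = lv$compliant)
  print(show, row.names = FALSE)
  if (!anyNA(x$validated_range)) {
    cat(sprintf("Validated range: %g to %g %% w/w\n",
                x$validated_range[1], x$validated_range[2]))
  } else cat("No compliant level: method not validated at these limits\n")
  invisible(x)
}

#' Linearity profile of predictions versus nominal concentrations
#'
#' Ordinary least squares of predicted on introduced concentration over all
#' validation samples, with per-level absolute tolerance and acceptance
#' limits for plotting.
#'
#' @param predictions Data frame with `nominal` and `prediction` columns
#'   (>= 2 distinct levels).
#' @param acceptance_rel Relative acceptance limit (%).
#' @param profile Optional [accuracy_profile()] whose absolute tolerance
#'   limits are reused; recomputed here if omitted (requires `series`).
#' @return Object of class `linearity_fit`: `slope`, `intercept`, `r2`, and
#'   data frame `levels` (`nominal`, `abs_tol_lower`, `abs_tol_upper`,
#'   `acceptance_lower`, `acceptance_upper`, `compliant`).
#' @export
linearity_profile <- function(predictions, acceptance_rel = 5,
                              profile = NULL) {
  stopifnot(is.data.frame(predictions),
            all(c("nominal", "prediction") %in% names(predictions)))
  if (length(unique(predictions$nominal)) < 2) {
    stop("linearity needs at least 2 distinct concentration levels",
         call. = FALSE)
  }
  fit <- stats::lm(prediction ~ nominal, data = predictions)
  co <- stats::coef(fit)
  r2 <- summary(fit)$r.squared
  if (is.null(profile)) {
    profile <- accuracy_profile(predictions, acceptance_rel = acceptance_rel)
  }
  lv <- profile$levels
  levels <- data.frame(
    nominal = lv$nominal,
    abs_tol_lower = lv$abs_tol_lower, abs_tol_upper = lv$abs_tol_upper,
    acceptance_lower = lv$nominal * (1 - acceptance_rel / 100),
    acceptance_upper = lv$nominal * (1 + acceptance_rel / 100)
  )
  levels$compliant <- levels$abs_tol_lower >= levels$acceptance_lower &
    levels$abs_tol_upper <= levels$acceptance_upper
  structure(list(slope = unname(co["nominal"]),
                 intercept = unname(co["(Intercept)"]),
                 r2 = r2, levels = levels,
                 acceptance_rel = acceptance_rel),
            class = "linearity_fit")
}

#' @export
print.linearity_fit <- function(x, ...) {
  cat(sprintf("Linearity: slope %.4f, intercept %.4f, R^2 %.4f\n",
              x$slope, x$intercept, x$r2))
  print(round(x$levels[c("nominal", "abs_tol_lower", "abs_tol_upper",
                         "acceptance_lower", "acceptance_upper")], 3),
        row.names = FALSE)
  invisible(x)
}

#' Validate a calibration model on an external validation set
#'
#' Predicts the validation spectra and assembles the full validation report:
#' accuracy profile plus linearity profile.
#'
#' @param model A `calibration_model`.
#' @param val Validation `spectrum_set` with `series` and `nominal_pct_ww`
#'   metadata (balanced design within each level).
#' @param acceptance_rel Relative acceptance limit (%), default 5.
#' @param beta Tolerance-interval proportion, default 0.95.
#' @param h Factor count (default: the model's selection).
#' @return Object of class `validation_report`: `predictions` data frame,
#'   `profile` ([accuracy_profile()]) and `linearity`
#'   ([linearity_profile()]).
#' @export
validate_model <- function(model, val, acceptance_rel = 5, beta = 0.95,
                           h = model$n_factors) {
  stopifnot(inherits(model, "calibration_model"),
            inherits(val, "spectrum_set"))
  pred <- predict(model, val, h = h)
  d <- data.frame(sample_id = val$meta$sample_id,
                  series = val$meta$series,
                  nominal = val$meta$nominal_pct_ww,
                  prediction = unname(pred))
  profile <- accuracy_profile(d, acceptance_rel = acceptance_rel,
                              beta = beta)
  linearity <- linearity_profile(d, acceptance_rel = acceptance_rel,
                                 profile = profile)
  structure(list(predictions = d, profile = profile, linearity = linearity,
                 h = h),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  print(x$profile)
  print(x$linearity)
  invisible(x)
}
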