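# Cross-validation and the pre-treatment x regression-method scan.
# Pre-treatments are per-spectrum, so applying them before CV does not leak
# information across folds; centering is redone inside every fold's fit.

#' Cross-validate a latent-variable regression
#'
#' For each held-out unit the model is refit from scratch on the remainder
#' (including re-centering) and the unit is predicted at every factor count.
#'
#' @param X Preprocessed spectra matrix (n x p).
#' @param y Concentrations (% w/w).
#' @param method `"PLS"` or `"PCR"`.
#' @param max_factors Maximum factors to evaluate.
#' @param scheme `"loo"` (leave-one-out, default) or `"lgo"`
#'   (leave-group-out of `k` consecutive samples; n must be divisible by k).
#' @param k Group size for `"lgo"` (default 2, one spectrum per sample side).
#' @param X_val,y_val Optional external validation set for RMSEP.
#' @param f_thresh MSE-ratio threshold passed to [select_n_factors()].
#' @return Object of class `cv_result`: data frame `metrics` with one row
#'   per factor count (`h`, `rmsecv`, `rmsec`, `rmsep`, `bias`, `r2`
#'   squared Pearson of CV predictions vs y, `r2_ss` the 1 - SSE/SST form),
#'   plus `h_selected`, `method`, `cv_predictions` (n x H matrix).
#' @export
cross_validate <- function(X, y, method = c("PLS", "PCR"), max_factors = 10,
                           scheme = c("loo", "lgo"), k = 2,
                           X_val = NULL, y_val = NULL, f_thresh = 1.05) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(n >= 3, length(y) == n)
  folds <- if (scheme == "loo") {
    as.list(seq_len(n))
  } else {
    if (n %% k != 0) {
      stop(sprintf("leave-group-out group size %d incompatible with n = %d",
                   k, n), call. = FALSE)
    }
    split(seq_len(n), rep(seq_len(n %/% k), each = k))
  }
  fitter <- if (method == "PLS") fit_pls else fit_pcr

  full <- fitter(X, y, max_factors)
  H <- full$n_factors
  pred <- matrix(NA_real_, n, H)
  for (fold in folds) {
    f <- fitter(X[-fold, , drop = FALSE], y[-fold], max_factors)
    hf <- min(H, f$n_factors)
    for (h in seq_len(hf)) {
      pred[fold, h] <- predict(f, X[fold, , drop = FALSE], h = h)
    }
    if (hf < H) for (h in (hf + 1):H) pred[fold, h] <- pred[fold, hf]
  }

  err <- pred - y
  rmsecv <- sqrt(colMeans(err^2))
  bias <- colMeans(err)
  r2 <- apply(pred, 2, function(p) stats::cor(p, y)^2)
  r2_ss <- 1 - colSums(err^2) / sum((y - mean(y))^2)
  rmsec <- vapply(seq_len(H), function(h) {
    sqrt(mean((predict(full, X, h = h) - y)^2))
  }, numeric(1))
  rmsep_h <- if (!is.null(X_val)) {
    vapply(seq_len(H), function(h) rmsep(full, X_val, y_val, h), numeric(1))
  } else rep(NA_real_, H)

  metrics <- data.frame(h = seq_len(H), rmsecv = rmsecv, rmsec = rmsec,
                        rmsep = rmsep_h, bias = bias, r2 = r2, r2_ss = r2_ss)
  structure(list(metrics = metrics,
                 h_selected = select_n_factors(rmsecv, f_thresh = f_thresh),
                 method = method, scheme = scheme,
                 cv_predictions = pred, fit = full),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation (%s, %s): selected %d factor(s)\n",
              x$method, x$scheme, x$h_selected))
  print(round(x$metrics, 5), row.names = FALSE)
  invisible(x)
}

#' Root-mean-square error of prediction on an external set
#'
#' @param model A `nir_regression` (with `X_val` a preprocessed matrix) or a
#'   `calibration_model` (with `X_val` a raw `spectrum_set`).
#' @param X_val Validation spectra.
#' @param y_val Known concentrations (% w/w).
#' @param h Factor count.
#' @return RMSEP in % w/w.
#' @export
rmsep <- function(model, X_val, y_val, h) {
  if (inherits(model, "calibration_model")) {
    pred <- predict(model, X_val, h = h)
  } else {
    pred <- predict(model, X_val, h = h)
  }
  y_val <- as.numeric(y_val)
  if (length(y_val) == 0) stop("empty validation set", call. = FALSE)
  stopifnot(length(pred) == length(y_val))
  sqrt(mean((pred - y_val)^2))
}

#' Select the number of latent factors from an RMSECV curve
#'
#' Parsimony rule: the smallest h whose cross-validated MSE is within a
#' fixed ratio of the best over all factor counts, i.e.
#' `RMSECV(h)^2 <= f_thresh * min_h' RMSECV(h')^2`. An F-test variant
#' (Haaland-Thomas style) is available: it accepts the smallest h whose MSE
#' ratio to the minimum is below the F quantile at (n, n) degrees of freedom.
#'
#' @param rmsecv_curve Numeric vector, RMSECV at h = 1, 2, ...
#' @param f_thresh MSE ratio threshold (default 1.05, a 5 % tolerance).
#' @param rule `"ratio"` (default) or `"ftest"`.
#' @param n Number of samples (required for `rule = "ftest"`).
#' @param alpha Significance level for the F-test rule.
#' @return Selected factor count (>= 1).
#' @export
select_n_factors <- function(rmsecv_curve, f_thresh = 1.05,
                             rule = c("ratio", "ftest"), n = NULL,
                             alpha = 0.25) {
  rule <- match.arg(rule)
  stopifnot(length(rmsecv_curve) >= 1, all(rmsecv_curve >= 0))
  mse <- rmsecv_curve^2
  thr <- if (rule == "ratio") {
    f_thresh
  } else {
    if (is.null(n)) stop("n is required for the F-test rule", call. = FALSE)
    stats::qf(1 - alpha, n, n)
  }
  which(mse <= thr * min(mse))[1]
}

#' Scan pre-treatments and regression methods
#'
#' Cross-validates every (pre-treatment, method) combination on the
#' calibration set, selects the factor count for each, and reports RMSEP on
#' the validation set at that count. Failing combinations are flagged and
#' the scan continues.
#'
#' @param cal Calibration `spectrum_set` (reflectance domain).
#' @param val Optional validation `spectrum_set`.
#' @param specs List of [preprocess_spec()]s (default: all nine).
#' @param methods Character vector from `c("PLS", "PCR")`.
#' @param max_factors,scheme,k,f_thresh Passed to [cross_validate()].
#' @return Object of class `grid_search_result`: data frame `table` with
#'   columns `pretreatment`, `model`, `pc_number`, `rmsecv`, `rmsep`, `r2`,
#'   `bias` (plus `rmsec` and `error`), one row per combination, sorted by
#'   RMSECV ascending; and `best` (the top row's spec, method and h).
#' @export
grid_search <- function(cal, val = NULL, specs = default_spec_list(),
                        methods = c("PLS", "PCR"), max_factors = 10,
                        scheme = "loo", k = 2, f_thresh = 1.05) {
  stopifnot(length(specs) >= 1)
  y <- cal$meta$nominal_pct_ww
  rows <- list()
  details <- list()
  spec_names <- if (!is.null(names(specs))) names(specs)
                else vapply(specs, function(s) s$method, character(1))
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    for (method in methods) {
      key <- paste(spec_names[si], si, method, sep = ".")
      res <- tryCatch({
        Xc <- apply_preprocess(cal, spec)
        Xv <- if (!is.null(val)) apply_preprocess(val, spec) else NULL
        cv <- cross_validate(Xc$values, y, method, max_factors,
                             scheme = scheme, k = k,
                             X_val = if (!is.null(Xv)) Xv$values else NULL,
                             y_val = if (!is.null(val))
                               val$meta$nominal_pct_ww else NULL,
                             f_thresh = f_thresh)
        hs <- cv$h_selected
        m <- cv$metrics[hs, ]
        details[[key]] <- cv
        data.frame(pretreatment = spec_label(spec), model = method,
                   pc_number = hs, rmsecv = m$rmsecv, rmsep = m$rmsep,
                   r2 = m$r2, bias = m$bias, rmsec = m$rmsec,
                   error = NA_character_, spec_index = si,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(pretreatment = spec_label(spec), model = method,
                   pc_number = NA_integer_, rmsecv = NA_real_,
                   rmsep = NA_real_, r2 = NA_real_, bias = NA_real_,
                   rmsec = NA_real_, error = conditionMessage(e),
                   spec_index = si, stringsAsFactors = FALSE)
      })
      rows[[key]] <- res
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(is.na(tab$rmsecv), tab$rmsecv), ]
  rownames(tab) <- NULL
  best_key <- NULL
  if (any(!is.na(tab$rmsecv))) {
    top <- tab[!is.na(tab$rmsecv), ][1, ]
    best_key <- list(spec = specs[[top$spec_index]], method = top$model,
                     n_factors = top$pc_number)
  }
  structure(list(table = tab, best = best_key, details = details),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat("Pre-treatment x method scan (sorted by RMSECV):\n")
  tab <- x$table
  tab$rmsecv <- round(tab$rmsecv, 4); tab$rmsep <- round(tab$rmsep, 4)
  tab$r2 <- round(tab$r2, 4); tab$bias <- round(tab$bias, 4)
  print(tab[, c("pretreatment", "model", "pc_number", "rmsecv", "rmsep",
                "r2", "bias")], row.names = FALSE)
  if (!is.null(x$best)) {
    cat(sprintf("Best: %s + %s with %d factor(s)\n",
                spec_label(x$best$spec), x$best$method, x$best$n_factors))
  }
  invisible(x)
}
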