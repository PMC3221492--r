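# Latent-variable regression: univariate-response PLS (NIPALS) and principal
# component regression. X is mean-centered, never variance-scaled
# (spectroscopy convention). Predictions for h factors depend only on the
# first h factor triples, so a single fit serves all factor counts.

.DEFLATE_TOL <- 1e-12   # relative score-norm tolerance for early stopping

#' Fit a PLS1 calibration (NIPALS)
#'
#' NIPALS sequence on mean-centered data: weight `w_h = X_h' y_h` normalized
#' to unit length, scores `t_h = X_h w_h`, X-loading
#' `p_h = X_h' t_h / (t_h' t_h)`, y-loading `q_h = y_h' t_h / (t_h' t_h)`,
#' then deflation of X and y. The prediction vector for h factors is
#' `b(h) = W_h (P_h' W_h)^{-1} q_h`.
#'
#' @param X Numeric matrix (n samples x p variables), already preprocessed.
#' @param y Response vector (concentration, % w/w).
#' @param max_factors Maximum latent factors to extract (default 10).
#' @return Object of class `nir_regression` with fields `method`, `x_mean`,
#'   `y_mean`, `n_factors` (achieved), `B` (p x n_factors matrix whose h-th
#'   column is the full prediction vector using h factors) and the factor
#'   triples (`weights`, `loadings`, `scores`, `y_loadings`).
#' @export
fit_pls <- function(X, y, max_factors = 10) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2)
  if (stats::sd(y) == 0) stop("y has zero variance", call. = FALSE)
  max_factors <- min(max_factors, n - 1L, p)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean); yc <- y - y_mean

  W <- P <- matrix(0, p, max_factors)
  Tm <- matrix(0, n, max_factors)
  q <- numeric(max_factors)
  t0 <- NULL
  h <- 0L
  for (a in seq_len(max_factors)) {
    w <- drop(crossprod(Xc, yc))
    wn <- sqrt(sum(w^2))
    if (wn < .Machine$double.eps * 1e3) break
    w <- w / wn
    tt <- drop(Xc %*% w)
    tt2 <- sum(tt^2)
    if (is.null(t0)) t0 <- tt2
    if (tt2 < .DEFLATE_TOL * t0) break
    pl <- drop(crossprod(Xc, tt)) / tt2
    ql <- sum(yc * tt) / tt2
    Xc <- Xc - tcrossprod(tt, pl)
    yc <- yc - ql * tt
    h <- a
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- tt; q[a] <- ql
  }
  if (h == 0L) stop("no usable PLS factor could be extracted", call. = FALSE)
  W <- W[, seq_len(h), drop = FALSE]; P <- P[, seq_len(h), drop = FALSE]
  Tm <- Tm[, seq_len(h), drop = FALSE]; q <- q[seq_len(h)]
  B <- matrix(0, p, h)
  for (a in seq_len(h)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    B[, a] <- Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
  }
  structure(list(method = "PLS", x_mean = x_mean, y_mean = y_mean,
                 n_factors = h, B = B, weights = W, loadings = P,
                 scores = Tm, y_loadings = q),
            class = "nir_regression")
}

#' Fit a principal component regression
#'
#' Scores and loadings come from the SVD of mean-centered X (components in
#' decreasing singular-value order); y is regressed on the first h scores.
#'
#' @inheritParams fit_pls
#' @return Object of class `nir_regression` (see [fit_pls()]); `weights` and
#'   `loadings` both hold the PCA loadings.
#' @export
fit_pcr <- function(X, y, max_factors = 10) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2)
  if (stats::sd(y) == 0) stop("y has zero variance", call. = FALSE)
  max_factors <- min(max_factors, n - 1L, p)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean); yc <- y - y_mean

  sv <- svd(Xc)
  keep <- sv$d > .DEFLATE_TOL^0.5 * sv$d[1]
  h <- min(sum(keep), max_factors)
  if (h == 0L) stop("X has no variance", call. = FALSE)
  V <- sv$v[, seq_len(h), drop = FALSE]
  Tm <- sv$u[, seq_len(h), drop = FALSE] %*% diag(sv$d[seq_len(h)], h)
  # scores are orthogonal, so per-component coefficients are independent
  gamma <- drop(crossprod(Tm, yc)) / colSums(Tm^2)
  B <- matrix(0, p, h)
  for (a in seq_len(h)) {
    B[, a] <- V[, seq_len(a), drop = FALSE] %*% gamma[seq_len(a)]
  }
  structure(list(method = "PCR", x_mean = x_mean, y_mean = y_mean,
                 n_factors = h, B = B, weights = V, loadings = V,
                 scores = Tm, y_loadings = gamma),
            class = "nir_regression")
}

#' Predict concentrations from a fitted regression
#'
#' `yhat = y_mean + (x - x_mean)' b(h)`. With `h = 0` the null model
#' (calibration mean) is returned.
#'
#' @param object A `nir_regression` from [fit_pls()] or [fit_pcr()].
#' @param X_new Matrix of preprocessed spectra on the training grid.
#' @param h Number of factors to use (default: all achieved).
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations (% w/w).
#' @export
predict.nir_regression <- function(object, X_new, h = object$n_factors, ...) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(object$x_mean)) {
    stop("X_new has ", ncol(X_new), " variables; model expects ",
         length(object$x_mean), " (grid mismatch)", call. = FALSE)
  }
  stopifnot(h >= 0, h <= object$n_factors)
  if (h == 0) return(rep(object$y_mean, nrow(X_new)))
  drop(sweep(X_new, 2, object$x_mean) %*% object$B[, h]) + object$y_mean
}

#' Calibrate a model on a SpectrumSet
#'
#' Runs the fixed pipeline (absorbance transform, region selection,
#' pre-treatment), then fits PLS or PCR against the nominal concentrations
#' in the metadata. The returned model carries everything needed to predict
#' new raw reflectance spectra.
#'
#' @param cal A calibration `spectrum_set` (reflectance domain).
#' @param spec A [preprocess_spec()].
#' @param method `"PLS"` or `"PCR"`.
#' @param max_factors Maximum latent factors.
#' @param n_factors Factors to use at prediction time; default chosen later
#'   (can be set after cross-validation). If `NULL`, all achieved factors.
#' @return Object of class `calibration_model`: the regression fit plus the
#'   pre-treatment spec, training grid and selected factor count.
#' @export
calibrate <- function(cal, spec = preprocess_spec("smoothing_savitzky_golay"),
                      method = c("PLS", "PCR"), max_factors = 10,
                      n_factors = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(cal, "spectrum_set"))
  pp <- apply_preprocess(cal, spec)
  y <- cal$meta$nominal_pct_ww
  fit <- if (method == "PLS") fit_pls(pp$values, y, max_factors)
         else fit_pcr(pp$values, y, max_factors)
  if (is.null(n_factors)) n_factors <- fit$n_factors
  stopifnot(n_factors >= 1, n_factors <= fit$n_factors)
  structure(list(fit = fit, preprocess = spec, grid = pp$grid,
                 n_factors = as.integer(n_factors), method = method),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Calibration model: %s, %d factor(s) (max %d), %s\n",
              x$method, x$n_factors, x$fit$n_factors,
              spec_label(x$preprocess)))
  invisible(x)
}

#' Predict concentrations for raw spectra with a calibration model
#'
#' Applies the model's stored pre-treatment pipeline to the new spectra and
#' evaluates the regression at `h` factors.
#'
#' @param object A `calibration_model`.
#' @param newdata A `spectrum_set` (reflectance or absorbance) on the
#'   training instrument grid.
#' @param h Number of factors (default: the model's selected count).
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations (% w/w), named by
#'   sample_id.
#' @export
predict.calibration_model <- function(object, newdata,
                                      h = object$n_factors, ...) {
  stopifnot(inherits(newdata, "spectrum_set"))
  pp <- apply_preprocess(newdata, object$preprocess)
  if (length(pp$grid) != length(object$grid) ||
      max(abs(pp$grid - object$grid)) > 1e-9) {
    stop("preprocessed grid does not match the model's training grid",
         call. = FALSE)
  }
  stats::setNames(predict(object$fit, pp$values, h = h),
                  newdata$meta$sample_id)
}

#' Save a calibration model as portable JSON
#'
#' Full double precision is kept, so a reloaded model predicts identically.
#'
#' @param model A `calibration_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  # doubles are stored as %.17g strings: 17 significant digits round-trip
  # IEEE doubles exactly, so a reloaded model predicts bit-identically
  num <- function(x) {
    if (is.matrix(x)) {
      list(dim = dim(x), data = sprintf("%.17g", as.vector(x)))
    } else sprintf("%.17g", x)
  }
  obj <- list(
    format = "nirblend-model-1",
    method = model$method, n_factors = model$n_factors,
    preprocess = unclass(model$preprocess), grid = num(model$grid),
    fit = list(method = model$fit$method, x_mean = num(model$fit$x_mean),
               y_mean = num(model$fit$y_mean),
               n_factors = model$fit$n_factors,
               B = num(model$fit$B), weights = num(model$fit$weights),
               loadings = num(model$fit$loadings),
               scores = num(model$fit$scores),
               y_loadings = num(model$fit$y_loadings))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a calibration model saved by [write_model()]
#'
#' @param path File path.
#' @return A `calibration_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "nirblend-model-1")) {
    stop("not a nirblend model file: ", path, call. = FALSE)
  }
  sp <- obj$preprocess
  spec <- preprocess_spec(sp$method, sp$window_points, sp$poly_order,
                          sp$derivative_order, sp$gap_points,
                          sp$segment_points, sp$deresolve_factor, sp$region)
  denum <- function(x) {
    if (is.list(x)) {
      matrix(as.numeric(x$data), nrow = x$dim[1], ncol = x$dim[2])
    } else as.numeric(x)
  }
  fit <- obj$fit
  for (f in c("x_mean", "y_mean", "B", "weights", "loadings", "scores",
              "y_loadings")) {
    fit[[f]] <- denum(fit[[f]])
  }
  fit$n_factors <- as.integer(fit$n_factors)
  class(fit) <- "nir_regression"
  structure(list(fit = fit, preprocess = spec, grid = denum(obj$grid),
                 n_factors = as.integer(obj$n_factors), method = obj$method),
            class = "calibration_model")
}
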