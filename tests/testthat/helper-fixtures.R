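# Shared fixtures, built in code at test time.

# A small spectrum_set directly from a values matrix (descending toy grid).
toy_set <- function(values, grid = NULL, domain = "absorbance") {
  values <- as.matrix(values)
  if (is.null(grid)) grid <- seq(1000 + 8 * (ncol(values) - 1), 1000, by = -8)
  n <- nrow(values)
  meta <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                     role = "cal", series = 1L, level_index = 1L,
                     nominal_pct_ww = 12.5)
  spectrum_set(grid, values, meta, domain = domain)
}

# Default-protocol synthetic dataset, memoised per (seed, noise tag) so the
# heavier tests can share one simulation.
.ds_cache <- new.env(parent = emptyenv())
cached_dataset <- function(seed = 1L, noise = noise_model()) {
  key <- paste0(seed, "_", paste(unlist(noise)[1:3], collapse = "_"))
  if (is.null(.ds_cache[[key]])) {
    .ds_cache[[key]] <- generate_protocol_dataset(build_protocol(),
                                                  noise = noise, seed = seed)
  }
  .ds_cache[[key]]
}

# Independent OLS oracle on centered data (normal equations).
ols_oracle <- function(X, y) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  b <- solve(crossprod(Xc), crossprod(Xc, yc))
  list(predict = function(Xn) {
    drop(sweep(Xn, 2, colMeans(X)) %*% b) + mean(y)
  })
}
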