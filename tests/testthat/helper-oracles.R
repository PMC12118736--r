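# Independent oracles used by the tests; intentionally brute-force and kept
# separate from the package's own code paths.

# Per-pixel ordinary least squares of ln(S) on TE via lm.fit normal equations.
ols_loglinear_oracle <- function(te_ms, signal) {
  X <- cbind(1, te_ms)
  fit <- stats::lm.fit(X, log(signal))
  c(intercept = unname(fit$coefficients[1]), slope = unname(fit$coefficients[2]))
}

# All-intervals dwell oracle: longest t[j] - t[i] such that every sample in
# i..j stays within `radius` of sample i. O(n^2) via a distance matrix and
# running maxima.
dwell_oracle <- function(t, x, y, radius) {
  n <- length(t)
  if (n == 0) return(0)
  best <- 0
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    ok <- cummax(d[i:n]) <= radius
    j <- if (all(ok)) n else i + which(!ok)[1] - 2L
    best <- max(best, t[j] - t[i])
  }
  best
}

# Pairwise-distance oracle for the proximity binding rule: a spot is bound
# iff its (rounded) centre is within `radius` of some cell-mask pixel.
bound_oracle <- function(spot_centers, cell_mask, radius) {
  idx <- which(cell_mask, arr.ind = TRUE)
  cx <- idx[, 1] - 1; cy <- idx[, 2] - 1
  vapply(seq_len(nrow(spot_centers)), function(k) {
    dx <- cx - round(spot_centers$x[k])
    dy <- cy - round(spot_centers$y[k])
    min(sqrt(dx^2 + dy^2)) <= radius
  }, TRUE)
}

# Small noiseless helper: phantom + series + truth for round-trip tests.
roundtrip_phantom <- function(seed = 1, ...) {
  make_phantom(c(64, 64), lesion = "LCX", mpio_delta_r2star = 40,
               r2star_variation_sd = 3, t1_variation_frac = 0.05,
               t2_variation_frac = 0.05, seed = seed, ...)
}
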