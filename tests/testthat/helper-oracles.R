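# Independent oracles used across the test suite. These deliberately avoid
# the package's own computational paths.

# ICC(2,1) from a two-way ANOVA fitted with stats::lm/anova (independent of
# the closed-form mean-squares route used by icc21()).
icc21_aov_oracle <- function(x, y) {
  n <- length(x)
  d <- data.frame(score = c(x, y),
                  target = factor(rep(seq_len(n), 2L)),
                  rater = factor(rep(1:2, each = n)))
  ms <- stats::anova(stats::lm(score ~ target + rater, data = d))
  msr <- ms["target", "Mean Sq"]
  msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

# Exhaustive grid search of the 1-step objective over the constraint box.
grid_search_min_rss <- function(curve, bounds, n = 50) {
  b <- curve$b; y <- curve$signal
  fg <- seq(bounds$f_range[1], bounds$f_range[2], length.out = n)
  dsg <- seq(bounds$Dstar_range[1], bounds$Dstar_range[2], length.out = n)
  dg <- seq(bounds$D_range[1], bounds$D_range[2], length.out = n)
  E1 <- exp(-outer(dsg, b))
  E2 <- exp(-outer(dg, b))
  best <- Inf
  for (f in fg) {
    P <- f * E1
    Q <- matrix(y, nrow = n, ncol = length(b), byrow = TRUE) - (1 - f) * E2
    rss <- matrix(rowSums(P * P), n, n) +
      matrix(rowSums(Q * Q), n, n, byrow = TRUE) - 2 * (P %*% t(Q))
    best <- min(best, min(rss))
  }
  best
}

noiseless_curve <- function(f, Dstar, D, b = ivim_protocol_bvalues()) {
  ivim_curve(b, ivim_signal(list(f = f, Dstar = Dstar, D = D), b))
}

noisy_curve <- function(f, Dstar, D, snr, b = ivim_protocol_bvalues()) {
  sig <- ivim_signal(list(f = f, Dstar = Dstar, D = D), b) +
    stats::rnorm(length(b), 0, 1 / snr)
  structure(list(b = b, signal = sig), class = "ivim_curve")
}

# A tiny single-direction, single-repeat series from a voxel-signal matrix
# (rows = voxels in array order, cols = b-values).
toy_series <- function(signals, dims, b = ivim_protocol_bvalues()) {
  stopifnot(nrow(signals) == prod(dims), ncol(signals) == length(b))
  data <- array(0, c(dims, length(b)))
  for (v in seq_along(b)) data[, , , v] <- array(signals[, v], dims)
  ivim_series(data, b = b, direction = rep(1L, length(b)),
              repeats = rep(1L, length(b)))
}
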