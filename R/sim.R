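#' Design of a Monte Carlo IVIM noise experiment
#'
#' Describes the simulation study: how many random (f, D*, D) combinations
#' to draw uniformly within the constraint box, at which SNR levels to
#' corrupt the ideal decay curves, and on which b-values. The default SNR
#' grid is 15 to 80 in steps of 5 and the default b-values are the 13
#' protocol values; every combination is simulated at every SNR level.
#'
#' @param n_combinations Number of uniform parameter draws.
#' @param snr_levels Numeric vector of SNR values (all > 0).
#' @param b_values b-value vector, s/mm^2.
#' @param seed Master integer seed (required; every stochastic stage derives
#'   its stream from it).
#' @param bounds \code{\link{ivim_bounds}} sampling box.
#' @return A list of class \code{"ivim_sim_design"}.
#' @export
ivim_sim_design <- function(n_combinations,
                            snr_levels = seq(15, 80, by = 5),
                            b_values = ivim_protocol_bvalues(),
                            seed,
                            bounds = ivim_bounds()) {
  if (missing(seed) || is.null(seed))
    stop("a simulation design requires an explicit seed")
  if (any(snr_levels <= 0)) stop("SNR levels must be positive")
  structure(list(n_combinations = as.integer(n_combinations),
                 snr_levels = snr_levels, b_values = b_values,
                 seed = as.integer(seed), bounds = bounds),
            class = "ivim_sim_design")
}

#' Draw ground-truth parameter combinations
#'
#' Each of f, D* and D is drawn independently and uniformly over its
#' constraint interval; reproducible under the design seed.
#'
#' @param design An \code{\link{ivim_sim_design}}.
#' @return Data frame with columns \code{f}, \code{Dstar}, \code{D}, one row
#'   per combination.
#' @export
sample_truth <- function(design) {
  n <- design$n_combinations
  b <- design$bounds
  set.seed(design$seed)
  data.frame(f = stats::runif(n, b$f_range[1], b$f_range[2]),
             Dstar = stats::runif(n, b$Dstar_range[1], b$Dstar_range[2]),
             D = stats::runif(n, b$D_range[1], b$D_range[2]))
}

#' Add Gaussian noise at a given SNR
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation 1/snr to a
#' normalized signal (S0 = 1), the noise model of the Monte Carlo study.
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param clean_signal Numeric vector.
#' @param snr Positive scalar signal-to-noise ratio.
#' @return Noisy signal vector.
#' @export
add_noise <- function(clean_signal, snr) {
  if (snr <= 0) stop("snr must be positive")
  clean_signal + stats::rnorm(length(clean_signal), 0, 1 / snr)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation between two raters (here: ground truth and a fitted value)
#' over n targets:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + MS_E + \frac{2}{n}(MS_C - MS_E)}}
#' with the row (target), column (rater) and error mean squares of the
#' standard two-way ANOVA decomposition of the n x 2 table.
#'
#' @param x,y Numeric vectors of equal length (>= 2): the two raters'
#'   scores for the same targets.
#' @return Scalar in [-1, 1]; \code{NaN} when the table has zero total
#'   variance (agreement undefined).
#' @examples
#' icc21(1:10, 1:10)      # exact agreement: 1
#' icc21(1:4, 1:4 + 10)   # constant shift is penalized (absolute agreement)
#' @export
icc21 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 targets")
  tab <- cbind(x, y)
  k <- 2L
  grand <- mean(tab)
  if (sum((tab - grand)^2) == 0) return(NaN)
  row_m <- rowMeans(tab)
  col_m <- colMeans(tab)
  ss_row <- k * sum((row_m - grand)^2)
  ss_col <- n * sum((col_m - grand)^2)
  ss_tot <- sum((tab - grand)^2)
  ss_err <- ss_tot - ss_row - ss_col
  msr <- ss_row / (n - 1)
  msc <- ss_col / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Run the Monte Carlo noise-robustness experiment
#'
#' For every drawn parameter combination and every SNR level: evaluate the
#' bi-exponential model on the design b-values, add Gaussian noise with
#' sigma = 1/SNR, fit with each requested method, and summarise truth-vs-fit
#' agreement per (method, SNR, parameter) with ICC(2,1). Fits that fail are
#' excluded from their cell's ICC and counted. All converged fits enter the
#' ICC (including at-constraint solutions); the at-constraint rate is
#' reported per cell.
#'
#' @param design An \code{\link{ivim_sim_design}}.
#' @param methods Method tags to fit with.
#' @param control \code{\link{ivim_fit_control}} passed to the fitters.
#' @param noiseless If TRUE, skip the noise step (sigma = 0 limit).
#' @param progress Print one line per SNR level.
#' @return Object of class \code{"ivim_sim"}: list with \code{truth} (data
#'   frame), \code{raw} (one row per experiment x method: truth, snr,
#'   method, fitted values, resid_sq_norm, converged, any at-constraint
#'   flag) and \code{icc} (data frame: method, snr, parameter, icc,
#'   n_used, n_failed, boundary_rate).
#' @export
run_simulation <- function(design, methods = c("nlls1", "nlls2", "nlls3",
                                               "bayes"),
                           control = ivim_fit_control(),
                           noiseless = FALSE, progress = FALSE) {
  truth <- sample_truth(design)
  b <- design$b_values
  clean <- vapply(seq_len(nrow(truth)), function(i) {
    ivim_signal(list(f = truth$f[i], Dstar = truth$Dstar[i], D = truth$D[i]), b)
  }, numeric(length(b)))                      # nb x n matrix
  raw <- vector("list", length(design$snr_levels))
  for (si in seq_along(design$snr_levels)) {
    snr <- design$snr_levels[si]
    # one deterministic sub-stream per SNR level
    set.seed((design$seed + 7919L * si) %% .Machine$integer.max)
    rows <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      sig <- if (noiseless) clean[, i] else add_noise(clean[, i], snr)
      curve <- structure(list(b = b, signal = sig), class = "ivim_curve")
      fits <- ivim_fit_all(curve, bounds = design$bounds, methods = methods,
                           control = control)
      rows[[i]] <- data.frame(
        comb = i, snr = snr, method = methods,
        f_true = truth$f[i], Dstar_true = truth$Dstar[i], D_true = truth$D[i],
        f_fit = vapply(fits, function(x) if (isTRUE(x$converged)) x$params$f
                       else NA_real_, 0),
        Dstar_fit = vapply(fits, function(x) if (isTRUE(x$converged))
                           x$params$Dstar else NA_real_, 0),
        D_fit = vapply(fits, function(x) if (isTRUE(x$converged)) x$params$D
                       else NA_real_, 0),
        resid_sq_norm = vapply(fits, function(x) x$resid_sq_norm, 0),
        converged = vapply(fits, function(x) isTRUE(x$converged), TRUE),
        at_boundary = vapply(fits, function(x) isTRUE(any(x$at_boundary)),
                             TRUE),
        row.names = NULL)
    }
    raw[[si]] <- do.call(rbind, rows)
    if (progress)
      message(sprintf("simulated SNR %g (%d curves)", snr, nrow(truth)))
  }
  raw <- do.call(rbind, raw)
  icc <- .sim_icc_table(raw, methods, design$snr_levels)
  structure(list(design = design, truth = truth, raw = raw, icc = icc),
            class = "ivim_sim")
}

.sim_icc_table <- function(raw, methods, snr_levels) {
  cells <- expand.grid(method = methods, snr = snr_levels,
                       parameter = c("f", "Dstar", "D"),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(r) {
    m <- cells$method[r]; s <- cells$snr[r]; p <- cells$parameter[r]
    sub <- raw[raw$method == m & raw$snr == s, ]
    ok <- sub$converged & is.finite(sub[[paste0(p, "_fit")]])
    data.frame(method = m, snr = s, parameter = p,
               icc = if (sum(ok) >= 2)
                 icc21(sub[[paste0(p, "_true")]][ok],
                       sub[[paste0(p, "_fit")]][ok]) else NA_real_,
               n_used = sum(ok), n_failed = sum(!ok),
               boundary_rate = mean(sub$at_boundary[ok]))
  })
  do.call(rbind, res)
}

#' @export
print.ivim_sim <- function(x, ...) {
  cat(sprintf("IVIM Monte Carlo experiment: %d combinations x %d SNR levels (%d experiments)\n",
              x$design$n_combinations, length(x$design$snr_levels),
              x$design$n_combinations * length(x$design$snr_levels)))
  cat("ICC(2,1), truth vs fit:\n")
  print(utils::head(x$icc, 24), row.names = FALSE)
  if (nrow(x$icc) > 24) cat("  ...", nrow(x$icc) - 24, "more rows\n")
  invisible(x)
}

#' @export
plot.ivim_sim <- function(x, parameter = c("f", "D", "Dstar"), ...) {
  parameter <- match.arg(parameter)
  sub <- x$icc[x$icc$parameter == parameter, ]
  methods <- unique(sub$method)
  cols <- grDevices::hcl.colors(length(methods), "Dark 3")
  graphics::plot(range(sub$snr), c(min(0, min(sub$icc, na.rm = TRUE)), 1),
                 type = "n", xlab = "SNR", ylab = "ICC(2,1)",
                 main = sprintf("Truth-vs-fit agreement: %s", parameter), ...)
  for (i in seq_along(methods)) {
    s <- sub[sub$method == methods[i], ]
    graphics::lines(s$snr, s$icc, col = cols[i], type = "b", pch = 16)
  }
  graphics::abline(h = 0.8, lty = 3)
  graphics::legend("bottomright", legend = methods, col = cols, lty = 1,
                   pch = 16, bty = "n")
  invisible(x)
}
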