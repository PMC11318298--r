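#' Control settings for IVIM fitting
#'
#' Numerical settings shared by the four estimation strategies. The
#' non-linear least-squares (NLLS) fitters use a single deterministic start:
#' the box midpoint for the simultaneous (1-step) fit, and f = 0.1,
#' D* = 20 x 10^-3 mm^2/s for the segmented fits. The Bayesian engine is
#' either a deterministic adaptive-grid integration of the marginal
#' posterior (\code{"grid"}, default) or a seeded random-walk Metropolis
#' sampler (\code{"mcmc"}).
#'
#' @param ftol Relative tolerance on the NLLS objective.
#' @param maxiter Maximum NLLS iterations.
#' @param init_f,init_Dstar Deterministic starting values for the segmented
#'   fits (D* in mm^2/s).
#' @param boundary_tol Relative tolerance (fraction of each bound interval)
#'   used to decide that a solution sits on a constraint.
#' @param bayes_engine \code{"grid"} or \code{"mcmc"}.
#' @param bayes_grid_n Grid points per parameter and zoom stage.
#' @param bayes_stages Number of zoom stages for the grid engine.
#' @param bayes_samples Post-burn-in samples for the MCMC engine.
#' @param bayes_burn Burn-in samples for the MCMC engine.
#' @param bayes_seed Integer seed for the MCMC engine (required when
#'   \code{bayes_engine = "mcmc"}).
#' @return A list of class \code{"ivim_fit_control"}.
#' @export
ivim_fit_control <- function(ftol = 1e-10, maxiter = 1000,
                             init_f = 0.1, init_Dstar = 20e-3,
                             boundary_tol = 1e-8,
                             bayes_engine = c("grid", "mcmc"),
                             bayes_grid_n = 40, bayes_stages = 3,
                             bayes_samples = 4000, bayes_burn = 1000,
                             bayes_seed = NULL) {
  structure(list(ftol = ftol, maxiter = maxiter, init_f = init_f,
                 init_Dstar = init_Dstar, boundary_tol = boundary_tol,
                 bayes_engine = match.arg(bayes_engine),
                 bayes_grid_n = bayes_grid_n, bayes_stages = bayes_stages,
                 bayes_samples = bayes_samples, bayes_burn = bayes_burn,
                 bayes_seed = bayes_seed),
            class = "ivim_fit_control")
}

# Snap a solution onto a constraint when it lies within tolerance, and
# report which constraints are active. tol is relative to interval width.
.snap_bounds <- function(val, range, tol) {
  w <- max(diff(range), .Machine$double.eps)
  at <- c(lower = abs(val - range[1]) <= tol * w + 1e-12,
          upper = abs(val - range[2]) <= tol * w + 1e-12)
  if (at["lower"]) val <- range[1]
  if (at["upper"]) val <- range[2]
  list(val = val, at = unname(any(at)))
}

.new_ivim_fit <- function(curve, params, method, bounds, at_boundary,
                          converged, intercept_A = NULL, extra = list()) {
  out <- list(
    params = params,
    resid_sq_norm = if (converged) residual_norm(curve, params) else NA_real_,
    method = method,
    at_boundary = at_boundary,
    converged = converged,
    intercept_A = intercept_A,
    curve = curve,
    bounds = bounds
  )
  out[names(extra)] <- extra
  class(out) <- "ivim_fit"
  out
}

.as_curve <- function(x) {
  if (inherits(x, "ivim_curve")) return(x)
  if (is.data.frame(x) && all(c("b", "signal") %in% names(x)))
    return(ivim_curve(x$b, x$signal))
  stop("expected an 'ivim_curve' or a data frame with columns b and signal")
}

#' Fit the bi-exponential IVIM model to a signal decay curve
#'
#' Estimates the perfusion fraction f, pseudo-diffusion coefficient D* and
#' diffusion coefficient D from normalized diffusion-weighted signal decay,
#' using one of four strategies:
#' \describe{
#'   \item{\code{"nlls1"}}{1-step NLLS: all three parameters fitted
#'     simultaneously by bounded Levenberg-Marquardt from the box midpoint.}
#'   \item{\code{"nlls2"}}{2-step NLLS: D (and an offset A) first fitted to
#'     the high-b points (b > cutoff) as A exp(-bD); D is then fixed and f,
#'     D* fitted over all b-values.}
#'   \item{\code{"nlls3"}}{3-step NLLS: ordinary least squares of
#'     log(signal) on b over the high-b points gives D (minus the slope) and
#'     the b = 0 extrapolation A = exp(intercept), hence f = 1 - A; with f
#'     and D fixed, D* alone is then fitted by bounded 1-D minimisation.}
#'   \item{\code{"bayes"}}{Posterior mean of each parameter under uniform
#'     priors on the constraint box and a Gaussian likelihood whose noise
#'     scale is marginalised under a Jeffreys prior (the marginal posterior
#'     is proportional to RSS^(-n/2)).}
#' }
#'
#' @param object An \code{ivim_curve}, a data frame with columns \code{b}
#'   and \code{signal}, or a formula \code{signal ~ b} (with \code{data}).
#' @param method One of \code{"nlls1"}, \code{"nlls2"}, \code{"nlls3"},
#'   \code{"bayes"}. Default \code{"nlls3"}, the strategy with the lowest
#'   within-subject variability in resting muscle.
#' @param bounds An \code{\link{ivim_bounds}} constraint set.
#' @param control An \code{\link{ivim_fit_control}} settings list.
#' @param data Data frame, used when \code{object} is a formula.
#' @param ... Unused.
#' @return An object of class \code{"ivim_fit"} with elements \code{params}
#'   (an \code{\link{ivim_params}}), \code{resid_sq_norm} (squared L2 norm
#'   of residuals on the normalized signal), \code{method},
#'   \code{at_boundary} (named logical for f, Dstar, D), \code{converged},
#'   \code{intercept_A} (segmented fits only) and, for \code{"bayes"},
#'   \code{posterior_sd}.
#' @examples
#' b <- ivim_protocol_bvalues()
#' truth <- ivim_params(0.11, 28.4e-3, 1.36e-3)
#' curve <- ivim_curve(b, ivim_signal(truth, b))
#' fit <- ivim_fit(curve, method = "nlls3")
#' coef(fit)
#' @export
ivim_fit <- function(object, ...) UseMethod("ivim_fit")

#' @rdname ivim_fit
#' @export
ivim_fit.formula <- function(object, data, method = "nlls3",
                             bounds = ivim_bounds(),
                             control = ivim_fit_control(), ...) {
  mf <- stats::model.frame(object, data)
  curve <- ivim_curve(b = mf[[2L]], signal = mf[[1L]])
  ivim_fit(curve, method = method, bounds = bounds, control = control)
}

#' @rdname ivim_fit
#' @export
ivim_fit.data.frame <- function(object, method = "nlls3",
                                bounds = ivim_bounds(),
                                control = ivim_fit_control(), ...) {
  ivim_fit(.as_curve(object), method = method, bounds = bounds,
           control = control)
}

#' @rdname ivim_fit
#' @export
ivim_fit.ivim_curve <- function(object, method = c("nlls3", "nlls1", "nlls2",
                                                   "bayes"),
                                bounds = ivim_bounds(),
                                control = ivim_fit_control(), ...) {
  method <- match.arg(method)
  switch(method,
         nlls1 = .fit_nlls1(object, bounds, control),
         nlls2 = .fit_nlls2(object, bounds, control),
         nlls3 = .fit_nlls3(object, bounds, control),
         bayes = .fit_bayes(object, bounds, control))
}

# ---- 1-step NLLS --------------------------------------------------------
# Internally D and D* are carried in units of 1e-3 mm^2/s so the three
# coordinates have comparable magnitude for the Levenberg-Marquardt steps.
# A small fixed set of deterministic starts is tried and the solution with
# the lowest objective kept: the projected Levenberg-Marquardt iteration
# can stall on a box face (a boundary-local minimum) when started far from
# the optimum, and a segmented warm start recovers the interior solution.
.fit_nlls1 <- function(curve, bounds, control) {
  if (length(curve$b) < 4L)
    stop("1-step fit needs at least 4 points")
  b <- curve$b; y <- curve$signal
  lo <- c(bounds$f_range[1], bounds$Dstar_range[1] * 1e3, bounds$D_range[1] * 1e3)
  hi <- c(bounds$f_range[2], bounds$Dstar_range[2] * 1e3, bounds$D_range[2] * 1e3)
  clamp <- function(th) pmin(pmax(th, lo), hi)
  starts <- list((lo + hi) / 2,
                 clamp(c(control$init_f, control$init_Dstar * 1e3, 1.3)))
  seg <- try(suppressWarnings(.fit_nlls3(curve, bounds, control)),
             silent = TRUE)
  if (!inherits(seg, "try-error") && isTRUE(seg$converged)) {
    starts <- c(starts, list(clamp(c(seg$params$f, seg$params$Dstar * 1e3,
                                     seg$params$D * 1e3))))
  }
  resfun <- function(th) {
    y - (th[1] * exp(-b * th[2] * 1e-3) + (1 - th[1]) * exp(-b * th[3] * 1e-3))
  }
  fit <- NULL
  for (start in starts) {
    cand <- try(minpack.lm::nls.lm(
      par = start, lower = lo, upper = hi, fn = resfun,
      control = minpack.lm::nls.lm.control(ftol = control$ftol,
                                           maxiter = control$maxiter)),
      silent = TRUE)
    if (inherits(cand, "try-error") || !is.finite(sum(cand$par))) next
    if (is.null(fit) || cand$deviance < fit$deviance) fit <- cand
  }
  if (is.null(fit)) {
    return(.new_ivim_fit(curve, ivim_params(0, bounds$Dstar_range[1], 0),
                         "nlls1", bounds,
                         at_boundary = c(f = NA, Dstar = NA, D = NA),
                         converged = FALSE))
  }
  th <- fit$par
  sf  <- .snap_bounds(th[1], bounds$f_range, control$boundary_tol)
  sds <- .snap_bounds(th[2] * 1e-3, bounds$Dstar_range, control$boundary_tol)
  sd_ <- .snap_bounds(th[3] * 1e-3, bounds$D_range, control$boundary_tol)
  .new_ivim_fit(curve, ivim_params(sf$val, sds$val, sd_$val), "nlls1", bounds,
                at_boundary = c(f = sf$at, Dstar = sds$at, D = sd_$at),
                converged = fit$info %in% 1:4)
}

# ---- high-b helpers -----------------------------------------------------
.high_b_idx <- function(curve, bounds) which(curve$b > bounds$high_b_cutoff)

# ---- 2-step NLLS --------------------------------------------------------
.fit_nlls2 <- function(curve, bounds, control) {
  ih <- .high_b_idx(curve, bounds)
  if (length(ih) < 2L)
    stop("2-step fit needs at least 2 points with b > ", bounds$high_b_cutoff,
         " s/mm^2")
  bh <- curve$b[ih]; yh <- curve$signal[ih]
  # step A: A * exp(-b D) on the diffusion-only points
  resA <- function(th) yh - th[1] * exp(-bh * th[2] * 1e-3)
  fitA <- minpack.lm::nls.lm(
    par = c(1, max(bounds$D_range[1], 1e-3) * 1e3),
    lower = c(1e-8, bounds$D_range[1] * 1e3),
    upper = c(Inf, bounds$D_range[2] * 1e3),
    fn = resA,
    control = minpack.lm::nls.lm.control(ftol = control$ftol,
                                         maxiter = control$maxiter))
  A <- fitA$par[1]
  sD <- .snap_bounds(fitA$par[2] * 1e-3, bounds$D_range, control$boundary_tol)
  D <- sD$val
  # step B: D fixed, fit f and D* over all b-values
  b <- curve$b; y <- curve$signal
  e2 <- exp(-b * D)
  resB <- function(th) y - (th[1] * exp(-b * th[2] * 1e-3) + (1 - th[1]) * e2)
  fitB <- minpack.lm::nls.lm(
    par = c(control$init_f, control$init_Dstar * 1e3),
    lower = c(bounds$f_range[1], bounds$Dstar_range[1] * 1e3),
    upper = c(bounds$f_range[2], bounds$Dstar_range[2] * 1e3),
    fn = resB,
    control = minpack.lm::nls.lm.control(ftol = control$ftol,
                                         maxiter = control$maxiter))
  sf  <- .snap_bounds(fitB$par[1], bounds$f_range, control$boundary_tol)
  sds <- .snap_bounds(fitB$par[2] * 1e-3, bounds$Dstar_range,
                      control$boundary_tol)
  .new_ivim_fit(curve, ivim_params(sf$val, sds$val, D), "nlls2", bounds,
                at_boundary = c(f = sf$at, Dstar = sds$at, D = sD$at),
                converged = fitA$info %in% 1:4 && fitB$info %in% 1:4,
                intercept_A = A)
}

# ---- 3-step NLLS --------------------------------------------------------
.fit_nlls3 <- function(curve, bounds, control) {
  ih <- .high_b_idx(curve, bounds)
  if (length(ih) < 2L)
    stop("3-step fit needs at least 2 points with b > ", bounds$high_b_cutoff,
         " s/mm^2")
  bh <- curve$b[ih]; yh <- curve$signal[ih]
  if (any(yh <= 0))
    stop("3-step fit: non-positive signal in the high-b regime, log undefined")
  # step A: first-order polynomial in log space; slope = -D
  cf <- stats::lsfit(bh, log(yh))$coefficients
  A <- exp(unname(cf[1]))
  sD <- .snap_bounds(min(max(-unname(cf[2]), bounds$D_range[1]),
                         bounds$D_range[2]),
                     bounds$D_range, control$boundary_tol)
  D <- sD$val
  # step B: extrapolate the diffusion-only line to b = 0; A estimates 1 - f
  f <- 1 - A
  f_at <- FALSE
  if (f < bounds$f_range[1]) { f <- bounds$f_range[1]; f_at <- TRUE }
  if (f > bounds$f_range[2]) { f <- bounds$f_range[2]; f_at <- TRUE }
  # step C: with f and D fixed, bounded 1-D fit of D* on all b-values
  b <- curve$b; y <- curve$signal
  e2 <- (1 - f) * exp(-b * D)
  if (f <= 0) {
    # no perfusion compartment: D* is unidentifiable; park it on the lower
    # constraint and flag it so downstream exclusion rules can act
    params <- ivim_params(0, bounds$Dstar_range[1], D)
    return(.new_ivim_fit(curve, params, "nlls3", bounds,
                         at_boundary = c(f = f_at, Dstar = TRUE, D = sD$at),
                         converged = TRUE, intercept_A = A))
  }
  obj <- function(ds) { r <- y - (f * exp(-b * ds) + e2); sum(r * r) }
  opt <- stats::optimize(obj, interval = bounds$Dstar_range, tol = 1e-9)
  sds <- .snap_bounds(opt$minimum, bounds$Dstar_range, 1e-4)
  .new_ivim_fit(curve, ivim_params(f, sds$val, D), "nlls3", bounds,
                at_boundary = c(f = f_at, Dstar = sds$at, D = sD$at),
                converged = TRUE, intercept_A = A)
}

#' Fit one curve with every estimation strategy
#'
#' Runs the four fitters on the same curve; a failure in one method (for
#' example a 3-step log-transform on non-positive high-b signal) is recorded
#' as a non-converged result and never aborts the batch.
#'
#' @inheritParams ivim_fit
#' @param curve An \code{ivim_curve} (or data frame with b, signal).
#' @param methods Character vector of method tags to run.
#' @return Named list of \code{ivim_fit} objects (class
#'   \code{"ivim_fit_set"}), one per requested method; failed fits carry
#'   \code{converged = FALSE} and an \code{error} message.
#' @export
ivim_fit_all <- function(curve, bounds = ivim_bounds(),
                         methods = c("nlls1", "nlls2", "nlls3", "bayes"),
                         control = ivim_fit_control()) {
  curve <- .as_curve(curve)
  out <- lapply(methods, function(m) {
    tryCatch(ivim_fit(curve, method = m, bounds = bounds, control = control),
             error = function(e) {
               structure(list(params = NULL, resid_sq_norm = NA_real_,
                              method = m,
                              at_boundary = c(f = NA, Dstar = NA, D = NA),
                              converged = FALSE, curve = curve,
                              bounds = bounds,
                              error = conditionMessage(e)),
                         class = "ivim_fit")
             })
  })
  names(out) <- methods
  class(out) <- "ivim_fit_set"
  out
}

#' @export
print.ivim_fit_set <- function(x, ...) {
  cat(sprintf("IVIM fits, %d methods:\n", length(x)))
  for (f in x) {
    if (isTRUE(f$converged))
      cat(sprintf("  %-6s f=%.4f D*=%.2fe-3 D=%.3fe-3 rss=%.3g\n",
                  f$method, f$params$f, f$params$Dstar * 1e3,
                  f$params$D * 1e3, f$resid_sq_norm))
    else
      cat(sprintf("  %-6s FAILED (%s)\n", f$method,
                  if (is.null(f$error)) "did not converge" else f$error))
  }
  invisible(x)
}

# ---- S3 methods for ivim_fit -------------------------------------------

#' @export
print.ivim_fit <- function(x, ...) {
  cat(sprintf("IVIM fit (%s)\n", x$method))
  if (!isTRUE(x$converged)) {
    cat("  did not converge",
        if (!is.null(x$error)) paste0(": ", x$error) else "", "\n")
    return(invisible(x))
  }
  print(x$params)
  cat(sprintf("  squared residual norm: %.4g\n", x$resid_sq_norm))
  if (any(x$at_boundary, na.rm = TRUE))
    cat("  at constraint:", paste(names(x$at_boundary)[which(x$at_boundary)],
                                  collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.ivim_fit <- function(object, ...) {
  if (is.null(object$params)) return(c(f = NA_real_, Dstar = NA_real_,
                                       D = NA_real_, fDstar = NA_real_))
  c(f = object$params$f, Dstar = object$params$Dstar, D = object$params$D,
    fDstar = object$params$fDstar)
}

#' @export
predict.ivim_fit <- function(object, newdata = NULL, ...) {
  b <- if (is.null(newdata)) object$curve$b
       else if (is.data.frame(newdata)) newdata$b else newdata
  ivim_signal(object$params, b)
}

#' @export
fitted.ivim_fit <- function(object, ...) predict(object)

#' @export
residuals.ivim_fit <- function(object, ...) {
  object$curve$signal - fitted(object)
}

#' @export
summary.ivim_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.ivim_fit")
}

#' @export
print.summary.ivim_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (isTRUE(f$converged)) {
    r <- residuals(f)
    cat(sprintf("  residuals: min %.3g, median %.3g, max %.3g (n = %d)\n",
                min(r), stats::median(r), max(r), length(r)))
    if (!is.null(f$posterior_sd))
      cat(sprintf("  posterior SD: f %.3g, D* %.3g, D %.3g\n",
                  f$posterior_sd["f"], f$posterior_sd["Dstar"],
                  f$posterior_sd["D"]))
    if (!is.null(f$intercept_A))
      cat(sprintf("  high-b intercept A: %.4f\n", f$intercept_A))
  }
  invisible(x)
}

#' @export
plot.ivim_fit <- function(x, ...) {
  b <- x$curve$b
  graphics::plot(b, x$curve$signal, pch = 16, xlab = "b (s/mm^2)",
                 ylab = "S(b)/S0", main = sprintf("IVIM fit (%s)", x$method),
                 ...)
  bb <- seq(min(b), max(b), length.out = 200)
  graphics::lines(bb, ivim_signal(x$params, bb), col = "firebrick")
  graphics::legend("topright", bty = "n",
                   legend = sprintf("f=%.3f  D*=%.1fe-3  D=%.2fe-3",
                                    x$params$f, x$params$Dstar * 1e3,
                                    x$params$D * 1e3))
  invisible(x)
}

#' Simulate noisy replicates of a fitted decay curve
#'
#' Draws replicate curves from the fitted bi-exponential model with additive
#' i.i.d. Gaussian noise of standard deviation \code{1/snr} (S0 = 1).
#'
#' @param object An \code{ivim_fit}.
#' @param nsim Number of replicate curves.
#' @param seed Integer seed.
#' @param snr Signal-to-noise ratio at b = 0.
#' @param ... Unused.
#' @return A list of \code{ivim_curve} objects (not re-normalized, so the
#'   noise at b = 0 is preserved).
#' @export
simulate.ivim_fit <- function(object, nsim = 1, seed = NULL, snr = 50, ...) {
  if (!is.null(seed)) set.seed(seed)
  clean <- ivim_signal(object$params, object$curve$b)
  lapply(seq_len(nsim), function(i) {
    s <- add_noise(clean, snr)
    structure(list(b = object$curve$b, signal = s), class = "ivim_curve")
  })
}
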