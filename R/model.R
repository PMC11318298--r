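#' IVIM parameter set
#'
#' Container for the three unknowns of the bi-exponential intravoxel
#' incoherent motion (IVIM) model: the perfusion fraction \code{f}
#' (dimensionless), the pseudo-diffusion coefficient \code{Dstar} and the
#' diffusion coefficient \code{D} (both in mm^2/s). The perfusion-related
#' composite \code{fDstar = f * Dstar} is always recomputed from its factors
#' and can never be set independently.
#'
#' @param f Perfusion fraction, in \code{[0, 1]}.
#' @param Dstar Pseudo-diffusion coefficient, mm^2/s (e.g. \code{30e-3}).
#' @param D Diffusion coefficient, mm^2/s (e.g. \code{1.4e-3}).
#' @return An object of class \code{"ivim_params"}: a named list with fields
#'   \code{f}, \code{Dstar}, \code{D} and the derived \code{fDstar}.
#' @examples
#' p <- ivim_params(f = 0.11, Dstar = 28.4e-3, D = 1.36e-3)
#' p$fDstar # 0.11 * 28.4e-3
#' @export
ivim_params <- function(f, Dstar, D) {
  vals <- c(f = f, Dstar = Dstar, D = D)
  if (!all(is.finite(vals))) {
    stop("IVIM parameters must be finite, got: ",
         paste(sprintf("%s=%g", names(vals), vals), collapse = ", "))
  }
  if (any(vals < 0)) {
    stop("IVIM parameters must be non-negative")
  }
  if (f > 1) {
    stop("perfusion fraction f must not exceed 1")
  }
  structure(
    list(f = unname(f), Dstar = unname(Dstar), D = unname(D),
         fDstar = unname(f * Dstar)),
    class = "ivim_params"
  )
}

#' @export
print.ivim_params <- function(x, ...) {
  cat("IVIM parameters:\n")
  cat(sprintf("  f      = %.4f\n", x$f))
  cat(sprintf("  D*     = %.3f x 10^-3 mm^2/s\n", x$Dstar * 1e3))
  cat(sprintf("  D      = %.3f x 10^-3 mm^2/s\n", x$D * 1e3))
  cat(sprintf("  f.D*   = %.3f x 10^-3 mm^2/s\n", x$fDstar * 1e3))
  invisible(x)
}

#' @export
as.numeric.ivim_params <- function(x, ...) {
  c(f = x$f, Dstar = x$Dstar, D = x$D)
}

#' Fit constraints for IVIM estimation
#'
#' Closed box constraints applied by every fitter, plus the b-value cutoff
#' separating the diffusion-only (high-b) regime used by the segmented
#' fitters. Defaults are the constraints held constant across all
#' non-linear least-squares strategies: f in [0, 0.5], D* in
#' [1.5, 500] x 10^-3 mm^2/s, D in [0, 2.5] x 10^-3 mm^2/s, with the
#' high-b regime defined as b > 200 s/mm^2 (so b = 220 s/mm^2 is the first
#' high-b point of the default protocol). The D* floor of 1.5 x 10^-3
#' mm^2/s sits above typical resting-muscle D (~1.4 x 10^-3 mm^2/s), which
#' keeps the two decay regimes separated in practice even though the
#' intervals themselves overlap over [1.5, 2.5] x 10^-3 mm^2/s.
#'
#' @param f_range Length-2 numeric, bounds on f.
#' @param Dstar_range Length-2 numeric, bounds on D* (mm^2/s).
#' @param D_range Length-2 numeric, bounds on D (mm^2/s).
#' @param high_b_cutoff Scalar, s/mm^2; b-values strictly greater than this
#'   are treated as diffusion-only.
#' @return An object of class \code{"ivim_bounds"}.
#' @export
ivim_bounds <- function(f_range = c(0, 0.5),
                        Dstar_range = c(1.5e-3, 500e-3),
                        D_range = c(0, 2.5e-3),
                        high_b_cutoff = 200) {
  chk <- function(r, nm) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1] > r[2] || r[1] < 0)
      stop(nm, " must be a non-negative, ordered length-2 interval")
    r
  }
  structure(
    list(f_range = chk(f_range, "f_range"),
         Dstar_range = chk(Dstar_range, "Dstar_range"),
         D_range = chk(D_range, "D_range"),
         high_b_cutoff = high_b_cutoff),
    class = "ivim_bounds"
  )
}

#' @export
print.ivim_bounds <- function(x, ...) {
  cat("IVIM fit constraints:\n")
  cat(sprintf("  f  in [%g, %g]\n", x$f_range[1], x$f_range[2]))
  cat(sprintf("  D* in [%g, %g] x 10^-3 mm^2/s\n",
              x$Dstar_range[1] * 1e3, x$Dstar_range[2] * 1e3))
  cat(sprintf("  D  in [%g, %g] x 10^-3 mm^2/s\n",
              x$D_range[1] * 1e3, x$D_range[2] * 1e3))
  cat(sprintf("  high-b regime: b > %g s/mm^2\n", x$high_b_cutoff))
  invisible(x)
}

#' The 13 b-values of the reference acquisition protocol
#'
#' @return Numeric vector of b-values in s/mm^2:
#'   0, 10, 20, 40, 70, 110, 160, 220, 300, 400, 500, 600, 700.
#' @export
ivim_protocol_bvalues <- function() {
  c(0, 10, 20, 40, 70, 110, 160, 220, 300, 400, 500, 600, 700)
}

#' Normalized signal decay curve
#'
#' Pairs a strictly increasing b-value vector (first element 0) with the
#' normalized signal S(b)/S0. If \code{normalize = TRUE} the signal is
#' divided by its value at b = 0.
#'
#' @param b Numeric vector of b-values, s/mm^2; strictly increasing, b[1] = 0.
#' @param signal Numeric vector, same length as \code{b}.
#' @param normalize Divide \code{signal} by \code{signal[1]} (default TRUE).
#' @return An object of class \code{"ivim_curve"} with fields \code{b} and
#'   \code{signal} (with \code{signal[1] == 1}).
#' @export
ivim_curve <- function(b, signal, normalize = TRUE) {
  if (length(b) != length(signal))
    stop("b and signal must have the same length")
  if (length(b) < 2L)
    stop("a decay curve needs at least 2 points")
  if (b[1] != 0)
    stop("the first b-value must be 0 (the non-diffusion-weighted point)")
  if (any(diff(b) <= 0))
    stop("b-values must be strictly increasing")
  if (!all(is.finite(signal)))
    stop("signal contains non-finite values")
  if (normalize) {
    if (signal[1] <= 0) stop("cannot normalize: signal at b = 0 is not positive")
    signal <- signal / signal[1]
  }
  structure(list(b = as.numeric(b), signal = as.numeric(signal)),
            class = "ivim_curve")
}

#' @export
print.ivim_curve <- function(x, ...) {
  cat(sprintf("IVIM decay curve: %d b-values, b in [%g, %g] s/mm^2\n",
              length(x$b), min(x$b), max(x$b)))
  invisible(x)
}

#' Bi-exponential IVIM signal equation
#'
#' Evaluates the normalized signal
#' \deqn{S(b)/S_0 = f e^{-b D^*} + (1 - f) e^{-b D}}
#' elementwise over \code{b}.
#'
#' @param params An \code{ivim_params} object, or a named list/vector with
#'   \code{f}, \code{Dstar}, \code{D}.
#' @param b Non-negative b-value scalar or vector, s/mm^2.
#' @return Dimensionless signal, same length as \code{b}; equals 1 at b = 0.
#' @examples
#' ivim_signal(ivim_params(0.11, 28.4e-3, 1.36e-3), b = c(0, 220, 700))
#' @export
ivim_signal <- function(params, b) {
  if (any(b < 0)) stop("b-values must be non-negative")
  params$f * exp(-b * params$Dstar) + (1 - params$f) * exp(-b * params$D)
}

#' Mono-exponential decay with offset
#'
#' \code{A * exp(-b * D)}: the diffusion-only model used for the high-b
#' regime of the segmented fitters, where pseudo-diffusion has decayed away
#' and \code{A} absorbs the tissue fraction (1 - f).
#'
#' @param A Positive dimensionless offset.
#' @param D Diffusion coefficient, mm^2/s, non-negative.
#' @param b b-value scalar or vector, s/mm^2.
#' @return Signal values, same length as \code{b}.
#' @export
mono_exp_signal <- function(A, D, b) {
  if (A <= 0) stop("offset A must be positive")
  if (D < 0) stop("D must be non-negative")
  A * exp(-b * D)
}

#' Squared norm of fit residuals
#'
#' The squared Euclidean norm of the difference between a measured curve and
#' the bi-exponential model evaluated at given parameters; the goodness-of-fit
#' quantity recorded for every fitting method.
#'
#' @param curve An \code{ivim_curve}.
#' @param params An \code{ivim_params} (or compatible list).
#' @return Non-negative scalar; 0 iff the model passes through every point.
#' @export
residual_norm <- function(curve, params) {
  if (length(curve$b) != length(curve$signal))
    stop("curve b/signal length mismatch")
  r <- curve$signal - ivim_signal(params, curve$b)
  sum(r * r)
}
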