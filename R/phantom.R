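# Synthetic in-silico IVIM acquisitions: the generator emulates the
# reference lumbar-spine protocol (13 b-values, 3 diffusion directions,
# 4 repeats, 22 axial slices) with bi-exponential tissue decay and additive
# Gaussian noise, so every pipeline stage can be exercised without scanner
# data.

#' Specification of a synthetic IVIM phantom
#'
#' @param dims Grid dimensions (x, y, slices). Default 32 x 32 x 22.
#' @param regions Named list of tissue regions; each region is a list with
#'   \code{mask} (logical array over \code{dims}, or NULL to be placed
#'   automatically), \code{params} (an \code{\link{ivim_params}}) and
#'   \code{S0} (unnormalized b = 0 intensity; default 100). Region masks
#'   must not overlap. Default: a single centred rectangular "muscle"
#'   region with resting paraspinal-like values f = 0.11,
#'   D* = 28.4e-3 mm^2/s, D = 1.36e-3 mm^2/s.
#' @param snr Signal-to-noise ratio at b = 0 relative to the first region's
#'   S0 (noise SD = S0/snr); \code{Inf} for noiseless.
#' @param b_values,n_directions,n_repeats Protocol structure.
#' @param seed Integer seed (required whenever \code{snr} is finite).
#' @param noise One of \code{"gaussian"} (default, matching the Monte Carlo
#'   noise model) or \code{"rician"}.
#' @return List of class \code{"ivim_phantom_spec"}.
#' @export
phantom_spec <- function(dims = c(32, 32, 22),
                         regions = NULL,
                         snr = 50,
                         b_values = ivim_protocol_bvalues(),
                         n_directions = 3, n_repeats = 4,
                         seed = NULL,
                         noise = c("gaussian", "rician")) {
  noise <- match.arg(noise)
  if (is.null(regions)) {
    regions <- list(muscle = list(mask = NULL,
                                  params = ivim_params(0.11, 28.4e-3, 1.36e-3),
                                  S0 = 100))
  }
  if (is.finite(snr) && is.null(seed))
    stop("a finite-SNR phantom requires an explicit seed")
  structure(list(dims = dims, regions = regions, snr = snr,
                 b_values = b_values, n_directions = n_directions,
                 n_repeats = n_repeats, seed = seed, noise = noise),
            class = "ivim_phantom_spec")
}

# default placement: vertical bands in the central block, one per region,
# on every slice, separated by a 2-voxel background gap — distinct muscles
# are not voxel-adjacent, and the gap keeps the in-plane median filter from
# mixing tissues across a region interface
.default_region_masks <- function(dims, n) {
  x0 <- max(2L, floor(dims[1] * 0.2)); x1 <- min(dims[1] - 1L,
                                                 ceiling(dims[1] * 0.8))
  y0 <- max(2L, floor(dims[2] * 0.25)); y1 <- min(dims[2] - 1L,
                                                  ceiling(dims[2] * 0.75))
  cuts <- round(seq(x0, x1 + 1L, length.out = n + 1L))
  lapply(seq_len(n), function(i) {
    m <- array(FALSE, dims)
    xs <- cuts[i]:(cuts[i + 1L] - 1L)
    if (i < n) xs <- xs[xs <= cuts[i + 1L] - 3L]  # 2-voxel gap to next band
    m[xs, y0:y1, ] <- TRUE
    m
  })
}

#' Generate a synthetic IVIM acquisition
#'
#' Voxel signal is S0 times the bi-exponential decay of the voxel's region,
#' identical in distribution across diffusion directions (isotropic tissue,
#' matching the pipeline's direction averaging), plus Gaussian noise with
#' SD = S0_ref/snr on every volume. Background (air) voxels have zero mean
#' and the same noise SD, so the SNR estimator's background ROI behaves
#' like a real acquisition's. Deterministic under the spec seed.
#'
#' @param spec An \code{\link{phantom_spec}}.
#' @return List of class \code{"ivim_phantom"}: \code{series} (an
#'   \code{\link{ivim_series}}), \code{masks} (named list of logical
#'   arrays, one per region, plus \code{background}), \code{truth} (named
#'   list of \code{ivim_params} per region) and \code{truth_maps} (arrays
#'   of true f, Dstar, D; NA in background).
#' @export
generate_phantom <- function(spec) {
  dims <- spec$dims
  regions <- spec$regions
  need <- vapply(regions, function(r) is.null(r$mask), TRUE)
  if (any(need)) {
    auto <- .default_region_masks(dims, sum(need))
    k <- 0L
    for (i in which(need)) { k <- k + 1L; regions[[i]]$mask <- auto[[k]] }
  }
  cover <- Reduce(`+`, lapply(regions, function(r) r$mask + 0L))
  if (any(cover > 1L)) stop("phantom regions overlap")
  # b = 0 is acquired once per direction x repeat, like the weighted volumes
  vols <- expand.grid(direction = seq_len(spec$n_directions),
                      repeats = seq_len(spec$n_repeats),
                      b = spec$b_values)
  vols <- vols[order(vols$repeats, vols$direction, vols$b), ]
  nvol <- nrow(vols)
  data <- array(0, c(dims, nvol))
  tf <- array(NA_real_, dims); tds <- tf; td <- tf
  S0ref <- regions[[1]]$S0
  if (is.finite(spec$snr)) set.seed(spec$seed)
  sigma <- if (is.finite(spec$snr)) S0ref / spec$snr else 0
  decay <- lapply(regions, function(r) r$S0 * ivim_signal(r$params,
                                                          spec$b_values))
  for (i in seq_along(regions)) {
    m <- regions[[i]]$mask
    tf[m] <- regions[[i]]$params$f
    tds[m] <- regions[[i]]$params$Dstar
    td[m] <- regions[[i]]$params$D
  }
  for (v in seq_len(nvol)) {
    bi <- match(vols$b[v], spec$b_values)
    vol <- array(0, dims)
    for (i in seq_along(regions)) vol[regions[[i]]$mask] <- decay[[i]][bi]
    if (sigma > 0) {
      vol <- vol + array(stats::rnorm(prod(dims), 0, sigma), dims)
      if (spec$noise == "rician") {
        # magnitude of a complex signal with independent channel noise
        vol <- sqrt(pmax(vol, 0)^2 +
                      array(stats::rnorm(prod(dims), 0, sigma), dims)^2)
      }
    }
    data[, , , v] <- vol
  }
  masks <- lapply(regions, function(r) r$mask)
  masks$background <- cover == 0L
  series <- ivim_series(data, b = vols$b, direction = vols$direction,
                        repeats = vols$repeats)
  structure(list(series = series, masks = masks,
                 truth = lapply(regions, function(r) r$params),
                 truth_maps = list(f = tf, Dstar = tds, D = td),
                 spec = spec),
            class = "ivim_phantom")
}

#' @export
print.ivim_phantom <- function(x, ...) {
  cat(sprintf("Synthetic IVIM phantom: %s grid, %d region(s), SNR %g\n",
              paste(x$spec$dims, collapse = " x "),
              length(x$truth), x$spec$snr))
  invisible(x)
}

#' Generate a synthetic cohort of subjects
#'
#' Subject-level ground truths are drawn from Gaussians centred on a
#' template parameter set (truncated to the constraint box); each subject
#' can then be realised as phantoms or decay-curve sets for one or two
#' visits with identical truths and fresh noise — the structure needed for
#' temporal-stability, spatial-consistency and inter-session analyses.
#'
#' @param n_subjects Number of subjects.
#' @param template An \code{\link{ivim_params}} giving the cohort centre
#'   (default: resting paraspinal-like values f = 0.11, D* = 28.4e-3,
#'   D = 1.36e-3).
#' @param between_subject_sd Named numeric vector with elements \code{f},
#'   \code{Dstar}, \code{D}: between-subject SDs (0 collapses the cohort
#'   onto the template).
#' @param seed Integer seed.
#' @param bounds Truncation box.
#' @return List of class \code{"ivim_cohort"} with \code{truth} (data
#'   frame: subject, f, Dstar, D) and the generation settings.
#' @export
make_cohort <- function(n_subjects,
                        template = ivim_params(0.11, 28.4e-3, 1.36e-3),
                        between_subject_sd = c(f = 0.02, Dstar = 6.8e-3,
                                               D = 0.08e-3),
                        seed, bounds = ivim_bounds()) {
  if (n_subjects < 1) stop("need at least one subject")
  if (missing(seed)) stop("make_cohort requires an explicit seed")
  set.seed(seed)
  rtrunc <- function(n, mean, sd, range) {
    if (sd == 0) return(rep(mean, n))
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x < range[1] | x > range[2]))
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  truth <- data.frame(
    subject = seq_len(n_subjects),
    f = rtrunc(n_subjects, template$f, between_subject_sd[["f"]],
               bounds$f_range),
    Dstar = rtrunc(n_subjects, template$Dstar, between_subject_sd[["Dstar"]],
                   bounds$Dstar_range),
    D = rtrunc(n_subjects, template$D, between_subject_sd[["D"]],
               bounds$D_range))
  structure(list(truth = truth, template = template,
                 between_subject_sd = between_subject_sd, seed = seed,
                 bounds = bounds),
            class = "ivim_cohort")
}

#' @export
print.ivim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic IVIM cohort: %d subjects\n", nrow(x$truth)))
  print(utils::head(x$truth), row.names = FALSE)
  invisible(x)
}

#' Realise cohort subjects as ROI-level decay curves
#'
#' Generates, for each subject, noisy normalized decay curves at the
#' signal-averaging level of a given analysis: a curve averaged over
#' \code{n_voxels} voxels at voxel-level SNR \code{snr} has effective noise
#' SD \code{1/(snr * sqrt(n_voxels))}. Used to emulate per-repeat
#' whole-ROI curves, per-slice curves, or per-visit acquisitions without
#' building full image volumes.
#'
#' @param cohort An \code{\link{make_cohort}} result.
#' @param n_replicates Curves per subject (e.g. 4 repeats or 22 slices).
#' @param snr Voxel-level SNR.
#' @param n_voxels Number of voxels averaged into each curve.
#' @param b_values Protocol b-values.
#' @param seed Integer seed.
#' @return List (per subject) of lists of \code{ivim_curve}s.
#' @export
cohort_curves <- function(cohort, n_replicates, snr, n_voxels = 1,
                          b_values = ivim_protocol_bvalues(), seed) {
  if (missing(seed)) stop("cohort_curves requires an explicit seed")
  set.seed(seed)
  sd_eff <- 1 / (snr * sqrt(n_voxels))
  lapply(seq_len(nrow(cohort$truth)), function(s) {
    p <- list(f = cohort$truth$f[s], Dstar = cohort$truth$Dstar[s],
              D = cohort$truth$D[s])
    clean <- ivim_signal(p, b_values)
    lapply(seq_len(n_replicates), function(r) {
      sig <- clean + stats::rnorm(length(b_values), 0, sd_eff)
      structure(list(b = b_values, signal = sig), class = "ivim_curve")
    })
  })
}

#' Realise one cohort subject as a full phantom
#'
#' @param cohort An \code{\link{make_cohort}} result.
#' @param subject Subject index.
#' @param visit Visit number (enters the noise seed only; truths are
#'   identical across visits).
#' @param dims,snr,n_repeats,n_directions Phantom geometry and noise.
#' @return An \code{"ivim_phantom"}.
#' @export
cohort_phantom <- function(cohort, subject, visit = 1, dims = c(16, 16, 22),
                           snr = 45, n_repeats = 4, n_directions = 3) {
  tr <- cohort$truth[cohort$truth$subject == subject, ]
  spec <- phantom_spec(
    dims = dims,
    regions = list(muscle = list(mask = NULL,
                                 params = ivim_params(tr$f, tr$Dstar, tr$D),
                                 S0 = 100)),
    snr = snr, n_repeats = n_repeats, n_directions = n_directions,
    seed = (cohort$seed + 1000L * subject + 100000L * visit) %%
      .Machine$integer.max)
  generate_phantom(spec)
}
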