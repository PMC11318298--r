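# Voxelwise parameter maps and the masking rules applied before reporting.

#' Voxelwise IVIM fitting within an ROI
#'
#' Runs the voxel-level processing chain on a raw acquisition series —
#' 3x3 in-plane median filter, averaging over diffusion directions and
#' repeats, voxelwise normalization by the voxel's own averaged b = 0
#' signal — then fits every ROI voxel's decay curve with each requested
#' method and applies the exclusion rules (see
#' \code{\link{build_inclusion_mask}}).
#'
#' @param series An \code{ivim_series} (raw; set \code{preprocess = FALSE}
#'   if already filtered and averaged).
#' @param roi Logical array matching the series grid.
#' @param bounds \code{\link{ivim_bounds}}.
#' @param methods Method tags to fit with.
#' @param control \code{\link{ivim_fit_control}}.
#' @param preprocess Apply median filter + direction/repeat averaging.
#' @return Object of class \code{"ivim_maps"}: per method, arrays \code{f},
#'   \code{Dstar}, \code{D}, \code{fDstar}, \code{resid_sq_norm} (NA
#'   outside the ROI or on failure), \code{included} (logical) and
#'   \code{reason} (integer codes: 0 included, 1 outside ROI, 2 physicality,
#'   3 at-constraint, 4 fit failure), plus the averaged series.
#' @export
fit_voxelwise <- function(series, roi, bounds = ivim_bounds(),
                          methods = c("nlls1", "nlls2", "nlls3", "bayes"),
                          control = ivim_fit_control(), preprocess = TRUE) {
  if (!all(dim(roi) == dim(series$data)[1:3]))
    stop("ROI grid does not match the series grid")
  avg <- series
  if (preprocess) {
    avg <- median_filter_2d(avg)
    avg <- average_directions_and_repeats(avg, collapse_repeats = TRUE)
  }
  meta <- avg$meta
  o <- order(meta$b)
  bvals <- meta$b[o]
  vox <- which(roi)
  d3 <- dim(avg$data)[1:3]
  blank <- function() array(NA_real_, d3)
  maps <- lapply(methods, function(m) {
    list(f = blank(), Dstar = blank(), D = blank(), fDstar = blank(),
         resid_sq_norm = blank(),
         converged = array(NA, d3), at_boundary = array(NA, d3))
  })
  names(maps) <- methods
  # flatten volumes for fast voxel extraction
  nvox3 <- prod(d3)
  flat <- matrix(avg$data, nrow = nvox3)[, meta$volume[o], drop = FALSE]
  phys_bad <- rep(FALSE, nvox3)  # S(first DW b) > S(b = 0)
  for (v in vox) {
    sig <- flat[v, ]
    if (sig[1] <= 0) { phys_bad[v] <- TRUE; next }
    if (sig[2] > sig[1]) phys_bad[v] <- TRUE
    curve <- tryCatch(ivim_curve(bvals, sig), error = function(e) NULL)
    if (is.null(curve)) next
    fits <- ivim_fit_all(curve, bounds = bounds, methods = methods,
                         control = control)
    for (m in methods) {
      ft <- fits[[m]]
      maps[[m]]$converged[v] <- isTRUE(ft$converged)
      if (isTRUE(ft$converged)) {
        maps[[m]]$f[v] <- ft$params$f
        maps[[m]]$Dstar[v] <- ft$params$Dstar
        maps[[m]]$D[v] <- ft$params$D
        maps[[m]]$fDstar[v] <- ft$params$fDstar
        maps[[m]]$resid_sq_norm[v] <- ft$resid_sq_norm
        maps[[m]]$at_boundary[v] <- isTRUE(any(ft$at_boundary))
      }
    }
  }
  out <- structure(list(maps = maps, roi = roi, phys_bad = array(phys_bad, d3),
                        methods = methods, bounds = bounds, series = avg),
                   class = "ivim_maps")
  out$inclusion <- build_inclusion_mask(out)
  out
}

#' Voxel inclusion mask with exclusion reason codes
#'
#' Applies the final-mask rules to fitted parameter maps: a voxel is
#' excluded when (a) noise or motion pushed the signal of the first
#' diffusion-weighted volume above the non-diffusion-weighted volume
#' (S(b = 10) > S(b = 0) after averaging), or (b) the voxel's fitted f, D*
#' or D equals a fit constraint for the method under consideration, or (c)
#' the fit failed. Reason codes: 0 included, 1 outside ROI, 2 physicality,
#' 3 at-constraint, 4 failure.
#'
#' @param maps An \code{"ivim_maps"} object from \code{\link{fit_voxelwise}}.
#' @return Per method: list with \code{included} (logical array),
#'   \code{reason} (integer array) and \code{fraction_included} (scalar,
#'   over ROI voxels).
#' @export
build_inclusion_mask <- function(maps) {
  lapply(stats::setNames(maps$methods, maps$methods), function(m) {
    mp <- maps$maps[[m]]
    reason <- array(1L, dim(maps$roi))           # outside ROI
    inroi <- maps$roi
    reason[inroi] <- 0L
    reason[inroi & maps$phys_bad] <- 2L
    fail <- inroi & !maps$phys_bad & !vapply(mp$converged, isTRUE, TRUE)
    reason[fail] <- 4L
    bnd <- inroi & !maps$phys_bad & vapply(mp$converged, isTRUE, TRUE) &
      vapply(mp$at_boundary, isTRUE, TRUE)
    reason[bnd] <- 3L
    included <- reason == 0L
    list(included = included, reason = reason,
         fraction_included = sum(included) / sum(inroi))
  })
}

#' @export
print.ivim_maps <- function(x, ...) {
  cat("Voxelwise IVIM parameter maps\n")
  cat(sprintf("  grid: %s, ROI voxels: %d\n",
              paste(dim(x$roi), collapse = " x "), sum(x$roi)))
  for (m in x$methods)
    cat(sprintf("  %-6s included %.1f%% of ROI voxels\n", m,
                100 * x$inclusion[[m]]$fraction_included))
  invisible(x)
}

#' Summarise parameter maps over ROI labels
#'
#' Mean and SD of each IVIM parameter over the included voxels of each ROI
#' label, per method — the voxelwise-report layout (one row per method and
#' label).
#'
#' @param object An \code{"ivim_maps"}.
#' @param labels Named list of logical arrays (default: the fitting ROI as
#'   label \code{"roi"}).
#' @param ... Unused.
#' @return Data frame: method, label, n_included, fraction_included, then
#'   mean and SD columns for f, Dstar, D, fDstar and the mean squared
#'   residual norm.
#' @export
summary.ivim_maps <- function(object, labels = list(roi = object$roi), ...) {
  rows <- NULL
  for (m in object$methods) {
    inc <- object$inclusion[[m]]$included
    mp <- object$maps[[m]]
    for (lab in names(labels)) {
      sel <- inc & labels[[lab]]
      rows <- rbind(rows, data.frame(
        method = m, label = lab, n_included = sum(sel),
        fraction_included = sum(sel) / max(sum(labels[[lab]] & object$roi), 1L),
        f_mean = mean(mp$f[sel]), f_sd = stats::sd(mp$f[sel]),
        Dstar_mean = mean(mp$Dstar[sel]), Dstar_sd = stats::sd(mp$Dstar[sel]),
        D_mean = mean(mp$D[sel]), D_sd = stats::sd(mp$D[sel]),
        fDstar_mean = mean(mp$fDstar[sel]),
        fDstar_sd = stats::sd(mp$fDstar[sel]),
        mean_resid_sq_norm = mean(mp$resid_sq_norm[sel])))
    }
  }
  rows
}

#' ROI-mean parameters per method, shaped for inter-session comparison
#'
#' @param maps An \code{"ivim_maps"}.
#' @param subject Subject identifier to attach.
#' @param roi Optional label mask (default the fitting ROI).
#' @return Data frame with columns subject, method, f, Dstar, D, fDstar —
#'   the input rows expected by \code{\link{intersession_repeatability}}.
#' @export
roi_mean_parameters <- function(maps, subject, roi = maps$roi) {
  s <- summary(maps, labels = list(roi = roi))
  data.frame(subject = subject, method = s$method, f = s$f_mean,
             Dstar = s$Dstar_mean, D = s$D_mean, fDstar = s$fDstar_mean)
}

# ---- NIfTI / bval / bvec I/O -------------------------------------------

#' Write an IVIM series to NIfTI with FSL-style sidecars
#'
#' Writes the 4D series as NIfTI-1, the b-values/directions as FSL-style
#' \code{.bval}/\code{.bvec} text files, and the repeat structure as a JSON
#' sidecar.
#'
#' @param series An \code{ivim_series}.
#' @param prefix Output path prefix (files \code{<prefix>.nii.gz},
#'   \code{<prefix>.bval}, \code{<prefix>.bvec}, \code{<prefix>.json}).
#' @return The prefix, invisibly.
#' @export
write_ivim_series <- function(series, prefix) {
  img <- RNifti::asNifti(series$data, pixdim = series$spacing)
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  writeLines(paste(series$meta$b, collapse = " "), paste0(prefix, ".bval"))
  dirs <- series$meta$direction
  # unit vectors along axes per direction index; zero vector for b = 0 / NA
  bvec <- vapply(seq_len(nrow(series$meta)), function(i) {
    v <- c(0, 0, 0)
    if (!is.na(dirs[i]) && series$meta$b[i] > 0) v[((dirs[i] - 1) %% 3) + 1] <- 1
    v
  }, numeric(3))
  writeLines(apply(bvec, 1, paste, collapse = " "), paste0(prefix, ".bvec"))
  jsonlite::write_json(
    list(repeats = series$meta$repeats, direction = series$meta$direction,
         b = series$meta$b, spacing = series$spacing),
    paste0(prefix, ".json"), auto_unbox = FALSE, digits = NA, null = "null")
  invisible(prefix)
}

#' Read an IVIM series written by \code{\link{write_ivim_series}}
#'
#' @param prefix Path prefix as used when writing.
#' @return An \code{ivim_series}.
#' @export
read_ivim_series <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  b <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  dirn <- side$direction
  reps <- side$repeats
  ivim_series(array(as.numeric(img), dim = dim(img)), b = b,
              direction = as.integer(dirn), repeats = as.integer(reps),
              spacing = as.numeric(side$spacing))
}

#' Write parameter maps to NIfTI (one file per parameter per method)
#'
#' @param maps An \code{"ivim_maps"}.
#' @param dir Output directory (created if absent).
#' @return Character vector of file paths, invisibly.
#' @export
write_parameter_maps <- function(maps, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (m in maps$methods) {
    for (p in c("f", "Dstar", "D", "fDstar", "resid_sq_norm")) {
      arr <- maps$maps[[m]][[p]]
      path <- file.path(dir, sprintf("%s_%s.nii.gz", m, p))
      RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), path)
      paths <- c(paths, path)
    }
    path <- file.path(dir, sprintf("%s_included.nii.gz", m))
    RNifti::writeNifti(
      RNifti::asNifti(array(as.integer(maps$inclusion[[m]]$included),
                            dim(maps$roi))), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
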