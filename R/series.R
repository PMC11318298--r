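#' 4D diffusion-weighted image series with acquisition metadata
#'
#' Couples a 4D voxel array (x, y, slice, volume) with the per-volume
#' b-value, diffusion-direction and repeat indices of a multi-b-value,
#' multi-direction, multi-repeat acquisition, plus voxel geometry. Each
#' (b > 0, direction, repeat) triple must occur exactly once; b = 0 volumes
#' may occur with any multiplicity the scanner produced.
#'
#' @param data Numeric 4D array, dimensions (x, y, slice, volume).
#' @param b Numeric vector, one b-value (s/mm^2) per volume.
#' @param direction Integer vector, direction index per volume (NA once
#'   directions have been averaged).
#' @param repeats Integer vector, repeat index per volume (NA once repeats
#'   have been averaged).
#' @param spacing Voxel spacing in mm, length 3.
#' @param affine Optional 4x4 voxel-to-world matrix (carried through to
#'   NIfTI output).
#' @return An object of class \code{"ivim_series"}.
#' @export
ivim_series <- function(data, b, direction = rep(NA_integer_, length(b)),
                        repeats = rep(NA_integer_, length(b)),
                        spacing = c(1.5, 1.5, 8), affine = NULL) {
  if (length(dim(data)) != 4L)
    stop("data must be a 4D array (x, y, slice, volume)")
  nv <- dim(data)[4]
  if (length(b) != nv || length(direction) != nv || length(repeats) != nv)
    stop("metadata length (", length(b), ") does not match volume count (",
         nv, ")")
  meta <- data.frame(volume = seq_len(nv), b = b, direction = direction,
                     repeats = repeats)
  key <- meta[meta$b > 0, c("b", "direction", "repeats")]
  if (anyDuplicated(key))
    stop("duplicate (b, direction, repeat) triple in metadata")
  structure(list(data = data, meta = meta, spacing = spacing,
                 affine = affine),
            class = "ivim_series")
}

#' @export
print.ivim_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("IVIM series: %d x %d x %d voxels, %d volumes\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  b-values: %s s/mm^2\n",
              paste(sort(unique(x$meta$b)), collapse = ", ")))
  nd <- length(unique(stats::na.omit(x$meta$direction)))
  nr <- length(unique(stats::na.omit(x$meta$repeats)))
  if (nd) cat(sprintf("  %d diffusion direction(s)\n", nd))
  if (nr) cat(sprintf("  %d repeat(s)\n", nr))
  invisible(x)
}

# ---- median filtering ---------------------------------------------------

# Vectorised median-of-9 for the slice interior: a 25-comparator 9-input
# sorting network applied elementwise with pmin/pmax; the median is the
# 5th order statistic.
.median9 <- function(p) {
  net <- list(c(1, 4), c(2, 8), c(3, 6), c(5, 9), c(1, 8), c(3, 5), c(4, 9),
              c(6, 7), c(1, 3), c(2, 4), c(5, 6), c(8, 9), c(2, 5), c(4, 7),
              c(6, 8), c(1, 2), c(3, 5), c(4, 6), c(7, 9), c(3, 4), c(5, 6),
              c(7, 8), c(2, 3), c(4, 5), c(6, 7))
  for (cmp in net) {
    lo <- pmin(p[[cmp[1]]], p[[cmp[2]]])
    hi <- pmax(p[[cmp[1]]], p[[cmp[2]]])
    p[[cmp[1]]] <- lo; p[[cmp[2]]] <- hi
  }
  p[[5]]
}

.median_filter_slice <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  if (nr >= 3L && nc >= 3L) {
    ri <- 2:(nr - 1); ci <- 2:(nc - 1)
    p <- vector("list", 9)
    k <- 0L
    for (dj in -1:1) for (di in -1:1) {
      k <- k + 1L
      p[[k]] <- m[ri + di, ci + dj, drop = FALSE]
    }
    out[ri, ci] <- .median9(p)
  }
  # borders: reduced (truncated) neighbourhood — no padding invented
  border <- which(row(m) == 1 | row(m) == nr | col(m) == 1 | col(m) == nc)
  for (idx in border) {
    i <- (idx - 1L) %% nr + 1L
    j <- (idx - 1L) %/% nr + 1L
    out[i, j] <- stats::median(m[max(1, i - 1):min(nr, i + 1),
                                 max(1, j - 1):min(nc, j + 1)])
  }
  out
}

#' In-plane 3x3 median filter
#'
#' Applies a 2D 3x3 median filter to every slice of every volume. Border
#' voxels use the reduced (truncated) neighbourhood actually present in the
#' image rather than padded values.
#'
#' @param x An \code{ivim_series}, a 2D matrix, or a 3D array (filtered
#'   slice by slice).
#' @return Object of the same shape/class, filtered.
#' @export
median_filter_2d <- function(x) {
  if (inherits(x, "ivim_series")) {
    d <- dim(x$data)
    if (d[1] < 3L || d[2] < 3L) stop("in-plane grid must be at least 3 x 3")
    for (v in seq_len(d[4])) for (z in seq_len(d[3]))
      x$data[, , z, v] <- .median_filter_slice(x$data[, , z, v])
    return(x)
  }
  if (is.matrix(x)) return(.median_filter_slice(x))
  if (length(dim(x)) == 3L) {
    for (z in seq_len(dim(x)[3])) x[, , z] <- .median_filter_slice(x[, , z])
    return(x)
  }
  stop("unsupported input to median_filter_2d")
}

# ---- direction / repeat averaging --------------------------------------

#' Average over diffusion directions (and optionally repeats)
#'
#' Arithmetic mean over the three diffusion-encoding directions for each
#' b-value (always), and over the repeats as well when
#' \code{collapse_repeats} — the temporal-stability analysis keeps the
#' repeats separate. b = 0 volumes are averaged within the same grouping.
#'
#' @param series An \code{ivim_series} with direction metadata.
#' @param collapse_repeats Average over the repeat axis too (default TRUE).
#' @return An \code{ivim_series} whose volumes are one per b-value (and per
#'   repeat when repeats are kept), with direction set to NA.
#' @export
average_directions_and_repeats <- function(series, collapse_repeats = TRUE) {
  meta <- series$meta
  grp <- if (collapse_repeats) interaction(meta$b, drop = TRUE)
         else interaction(meta$b, meta$repeats, drop = TRUE)
  # completeness check: every b > 0 must have the full direction (x repeat)
  # complement in each group
  ndir <- length(unique(stats::na.omit(meta$direction)))
  nrep <- length(unique(stats::na.omit(meta$repeats)))
  expected <- if (collapse_repeats) ndir * max(nrep, 1L) else ndir
  for (g in levels(grp)) {
    sel <- meta[grp == g, ]
    if (sel$b[1] > 0 && nrow(sel) != expected)
      stop(sprintf("incomplete acquisition: b=%g has %d volume(s), expected %d (missing direction/repeat)",
                   sel$b[1], nrow(sel), expected))
  }
  d <- dim(series$data)
  keys <- unique(data.frame(b = meta$b,
                            repeats = if (collapse_repeats) NA_integer_
                                      else meta$repeats))
  keys <- keys[order(keys$repeats, keys$b), , drop = FALSE]
  out <- array(0, c(d[1:3], nrow(keys)))
  for (i in seq_len(nrow(keys))) {
    sel <- meta$b == keys$b[i] &
      (collapse_repeats | meta$repeats == keys$repeats[i])
    vols <- series$data[, , , meta$volume[sel], drop = FALSE]
    out[, , , i] <- apply(vols, 1:3, mean)
  }
  ivim_series(out, b = keys$b, repeats = keys$repeats,
              spacing = series$spacing, affine = series$affine)
}

# ---- SNR ----------------------------------------------------------------

#' Estimate image SNR from a b = 0 volume
#'
#' Mean signal in a muscle ROI divided by the standard deviation of an
#' equally sized ROI placed outside the body. No Rayleigh/Rician background
#' correction is applied by default (the plain ratio); set
#' \code{rayleigh_correction = TRUE} to divide the background SD by 0.655
#' for magnitude-image air statistics.
#'
#' @param b0_volume 3D numeric array (or 2D matrix).
#' @param muscle_roi,background_roi Logical arrays of the same shape with
#'   equal voxel counts.
#' @param rayleigh_correction Apply the 0.655 background-SD adjustment.
#' @return Scalar SNR estimate.
#' @export
estimate_snr <- function(b0_volume, muscle_roi, background_roi,
                         rayleigh_correction = FALSE) {
  if (sum(muscle_roi) == 0L || sum(background_roi) == 0L)
    stop("both ROIs must be non-empty")
  if (sum(muscle_roi) != sum(background_roi))
    stop("muscle and background ROIs must contain the same number of voxels (",
         sum(muscle_roi), " vs ", sum(background_roi), ")")
  s <- stats::sd(b0_volume[background_roi])
  if (s == 0) stop("background ROI has zero standard deviation")
  if (rayleigh_correction) s <- s / 0.655
  mean(b0_volume[muscle_roi]) / s
}

# ---- ROI curves ---------------------------------------------------------

#' ROI-averaged signal decay curve(s)
#'
#' Averages the signal over the ROI voxels for each b-value (and per repeat
#' when the series retains repeats and \code{per_repeat}), then normalizes
#' by the b = 0 mean. Use \code{scope = "per_slice"} for one curve per
#' slice (the spatial-consistency analysis); a slice with an empty ROI
#' yields \code{NULL}, not a zero curve.
#'
#' @param series A direction-averaged \code{ivim_series}.
#' @param roi Logical array matching the series grid.
#' @param scope \code{"whole"} or \code{"per_slice"}.
#' @param per_repeat Keep repeats separate (requires repeat metadata).
#' @return For \code{scope = "whole"}: an \code{ivim_curve}, or a list of
#'   curves (one per repeat) when \code{per_repeat}. For
#'   \code{"per_slice"}: a list with one entry per slice (NULL where the
#'   ROI is empty in that slice).
#' @export
roi_mean_curve <- function(series, roi, scope = c("whole", "per_slice"),
                           per_repeat = FALSE) {
  scope <- match.arg(scope)
  meta <- series$meta
  if (!all(is.na(meta$direction)))
    stop("average directions first (see average_directions_and_repeats)")
  if (per_repeat && all(is.na(meta$repeats)))
    stop("per_repeat requested but repeats have been collapsed")
  if (sum(roi) == 0L) stop("ROI is empty")
  curve_from <- function(voxmask) {
    if (sum(voxmask) == 0L) return(NULL)
    one <- function(sel) {
      m <- vapply(meta$volume[sel], function(v) {
        vol <- series$data[, , , v]
        mean(vol[voxmask])
      }, 0)
      o <- order(meta$b[sel])
      ivim_curve(meta$b[sel][o], m[o])
    }
    if (per_repeat) {
      reps <- sort(unique(meta$repeats))
      lapply(reps, function(r) one(meta$repeats == r))
    } else if (all(is.na(meta$repeats))) {
      one(rep(TRUE, nrow(meta)))
    } else {
      # repeats still present but a single collapsed curve requested:
      # average repeats at curve level (linear, so order is immaterial)
      reps <- sort(unique(meta$repeats))
      cs <- lapply(reps, function(r) one(meta$repeats == r))
      sig <- rowMeans(vapply(cs, function(cv) cv$signal,
                             numeric(length(cs[[1]]$b))))
      ivim_curve(cs[[1]]$b, sig, normalize = TRUE)
    }
  }
  if (scope == "whole") return(curve_from(roi))
  lapply(seq_len(dim(series$data)[3]), function(z) {
    m <- array(FALSE, dim(series$data)[1:3])
    m[, , z] <- roi[, , z]
    curve_from(m)
  })
}
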