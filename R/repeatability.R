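#' Within-subject coefficient of variation
#'
#' The root-mean-square within-subject CV: each subject contributes the
#' ratio of the sample SD to the mean of its replicate measurements, and
#' the summary over subjects is
#' \deqn{WS\text{-}CV = 100 \sqrt{\frac{1}{N}\sum_i s_i^2 / m_i^2}}
#' An alternative pooled form (square root of the mean within-subject
#' variance divided by the grand mean) is available via \code{type}.
#'
#' @param values Replicate measurements: a numeric matrix (rows = subjects,
#'   columns = replicates), a list of per-subject numeric vectors, or a
#'   single numeric vector (one subject).
#' @param type \code{"rms"} (default) or \code{"pooled"}.
#' @return WS-CV in percent (scalar >= 0).
#' @examples
#' ws_cv(c(90, 110))                      # one subject: 14.14%
#' ws_cv(rbind(c(90, 110), c(80, 120)))   # two subjects
#' @export
ws_cv <- function(values, type = c("rms", "pooled")) {
  type <- match.arg(type)
  if (is.matrix(values)) values <- asplit(values, 1)
  if (is.numeric(values)) values <- list(values)
  keep <- vapply(values, function(v) sum(is.finite(v)) >= 2L, TRUE)
  if (!all(keep)) {
    message(sum(!keep), " subject(s) with < 2 finite replicates excluded from WS-CV")
    values <- values[keep]
  }
  if (length(values) == 0L) stop("no subject with >= 2 replicates")
  m <- vapply(values, function(v) mean(v[is.finite(v)]), 0)
  s <- vapply(values, function(v) stats::sd(v[is.finite(v)]), 0)
  if (any(m <= 0))
    stop("non-positive replicate mean for subject(s) ",
         paste(which(m <= 0), collapse = ", "),
         "; the coefficient of variation is undefined")
  if (type == "rms") {
    100 * sqrt(mean(s^2 / m^2))
  } else {
    100 * sqrt(mean(s^2)) / mean(m)
  }
}

.ivim_param_cols <- c("f", "Dstar", "D", "fDstar")

# Fit a list of curves and return one row per curve per method.
.fit_curve_table <- function(curves, ids, bounds, methods, control) {
  rows <- lapply(seq_along(curves), function(i) {
    fits <- ivim_fit_all(curves[[i]], bounds = bounds, methods = methods,
                         control = control)
    do.call(rbind, lapply(fits, function(x) {
      cf <- coef(x)
      cbind(ids[i, , drop = FALSE],
            data.frame(method = x$method, f = cf["f"], Dstar = cf["Dstar"],
                       D = cf["D"], fDstar = cf["fDstar"],
                       resid_sq_norm = x$resid_sq_norm,
                       converged = isTRUE(x$converged), row.names = NULL))
    }))
  })
  do.call(rbind, rows)
}

.variability_report <- function(df, grouping) {
  structure(df, class = c("ivim_variability", "data.frame"),
            grouping = grouping)
}

#' @export
print.ivim_variability <- function(x, digits = 3, ...) {
  cat(sprintf("Within-subject variability (%s)\n", attr(x, "grouping")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Intra-session temporal stability
#'
#' Fits each repeat's ROI-averaged decay curve with every method, then
#' summarises the variability of the IVIM parameters across the repeats by
#' the within-subject CV, under the assumption that perfusion and diffusion
#' in resting muscle are constant over the few minutes of an acquisition.
#'
#' @param curves_by_subject A list (one element per subject) of lists of
#'   per-repeat \code{ivim_curve}s (typically 4 repeats).
#' @param bounds \code{\link{ivim_bounds}}.
#' @param methods Method tags.
#' @param control \code{\link{ivim_fit_control}}.
#' @return A list of class \code{"ivim_temporal"}: \code{fits} (tidy data
#'   frame subject x repeat x method), \code{report} (per method and
#'   parameter: WS-CV %, mean, SD across all fitted values, and the mean
#'   squared residual norm per method).
#' @export
temporal_stability <- function(curves_by_subject, bounds = ivim_bounds(),
                               methods = c("nlls1", "nlls2", "nlls3", "bayes"),
                               control = ivim_fit_control()) {
  n_sub <- length(curves_by_subject)
  curves <- list(); ids <- NULL
  for (s in seq_len(n_sub)) {
    reps <- curves_by_subject[[s]]
    if (length(reps) < 2L)
      stop("subject ", s, " has fewer than 2 repeats")
    for (r in seq_along(reps)) {
      curves[[length(curves) + 1L]] <- reps[[r]]
      ids <- rbind(ids, data.frame(subject = s, rep = r))
    }
  }
  tab <- .fit_curve_table(curves, ids, bounds, methods, control)
  report <- .wscv_report(tab, replicate_col = "rep", grouping = "repeats")
  structure(list(fits = tab, report = report), class = "ivim_temporal")
}

# WS-CV per (method, parameter) where each subject's replicate vector is
# values over `replicate_col`; failed fits drop out pairwise.
.wscv_report <- function(tab, replicate_col, grouping,
                         subject_cols = "subject") {
  out <- NULL
  for (m in unique(tab$method)) {
    sub <- tab[tab$method == m & tab$converged, ]
    for (p in .ivim_param_cols) {
      key <- interaction(sub[subject_cols], drop = TRUE)
      byv <- split(sub[[p]], key)
      w <- tryCatch(suppressMessages(ws_cv(byv)), error = function(e) NA_real_)
      out <- rbind(out, data.frame(
        method = m, parameter = p, wscv = w,
        mean = mean(sub[[p]], na.rm = TRUE),
        sd = stats::sd(sub[[p]], na.rm = TRUE),
        mean_resid_sq_norm = mean(sub$resid_sq_norm, na.rm = TRUE),
        n_failed = sum(tab$method == m & !tab$converged)))
    }
  }
  .variability_report(out, grouping)
}

#' @export
print.ivim_temporal <- function(x, ...) { print(x$report, ...); invisible(x) }

#' Intra-session spatial consistency
#'
#' Within each spinal segment (four adjacent slices), the IVIM parameters
#' of healthy paraspinal muscle are assumed spatially uniform, so the WS-CV
#' of slice-wise fitted parameters across the slices of one segment
#' measures spatial consistency. Per (method, parameter), each
#' subject-segment contributes one within-"subject" CV; the report gives
#' the mean and SD of the per-segment WS-CVs across segments.
#'
#' @param slice_fits Data frame with columns \code{subject}, \code{slice},
#'   \code{method}, \code{f}, \code{Dstar}, \code{D}, \code{fDstar},
#'   \code{resid_sq_norm}, \code{converged} — e.g. built by fitting
#'   per-slice ROI curves with \code{\link{ivim_fit_all}}.
#' @param segment_map Data frame with columns \code{slice}, \code{segment}
#'   assigning (typically 4) slices to each segment; unassigned slices are
#'   dropped.
#' @return List of class \code{"ivim_spatial"}: \code{per_segment} (WS-CV
#'   per method x parameter x segment) and \code{report} (mean and SD across
#'   segments per method x parameter).
#' @export
spatial_consistency <- function(slice_fits, segment_map) {
  df <- merge(slice_fits, segment_map, by = "slice")
  per_seg <- NULL
  for (m in unique(df$method)) {
    for (p in .ivim_param_cols) {
      for (g in unique(segment_map$segment)) {
        sub <- df[df$method == m & df$segment == g & df$converged, ]
        byv <- split(sub[[p]], sub$subject)
        byv <- byv[vapply(byv, function(v) sum(is.finite(v)) >= 2L, TRUE)]
        w <- if (length(byv)) tryCatch(suppressMessages(ws_cv(byv)),
                                       error = function(e) NA_real_)
             else NA_real_
        per_seg <- rbind(per_seg, data.frame(method = m, parameter = p,
                                             segment = g, wscv = w))
      }
    }
  }
  agg <- stats::aggregate(wscv ~ method + parameter, per_seg,
                          function(v) c(mean = mean(v, na.rm = TRUE),
                                        sd = stats::sd(v, na.rm = TRUE)))
  report <- data.frame(method = agg$method, parameter = agg$parameter,
                       wscv_mean = agg$wscv[, "mean"],
                       wscv_sd = agg$wscv[, "sd"])
  structure(list(per_segment = per_seg,
                 report = .variability_report(report, "slices within segment")),
            class = "ivim_spatial")
}

#' @export
print.ivim_spatial <- function(x, ...) { print(x$report, ...); invisible(x) }

#' Fit per-slice ROI curves into a tidy table
#'
#' Convenience wrapper turning a per-subject list of per-slice curves into
#' the tidy table expected by \code{\link{spatial_consistency}}.
#'
#' @param curves_by_subject List (per subject) of named or indexed lists of
#'   per-slice \code{ivim_curve}s; \code{NULL} entries (empty slice ROI) are
#'   skipped.
#' @inheritParams temporal_stability
#' @return Data frame: subject, slice, method, parameters, residual norm.
#' @export
fit_slice_curves <- function(curves_by_subject, bounds = ivim_bounds(),
                             methods = c("nlls1", "nlls2", "nlls3", "bayes"),
                             control = ivim_fit_control()) {
  curves <- list(); ids <- NULL
  for (s in seq_along(curves_by_subject)) {
    slices <- curves_by_subject[[s]]
    for (z in seq_along(slices)) {
      if (is.null(slices[[z]])) next
      curves[[length(curves) + 1L]] <- slices[[z]]
      ids <- rbind(ids, data.frame(subject = s, slice = z))
    }
  }
  .fit_curve_table(curves, ids, bounds, methods, control)
}

#' Inter-session repeatability of ROI-averaged parameters
#'
#' Compares ROI-mean IVIM parameters between two scan sessions: per subject
#' and method, the two visits form a replicate pair whose WS-CV measures
#' between-session repeatability. Subjects present in only one visit are
#' excluded (with a message).
#'
#' @param visit1,visit2 Data frames with columns \code{subject},
#'   \code{method}, \code{f}, \code{Dstar}, \code{D}, \code{fDstar} —
#'   ROI-mean parameters per subject and method, e.g. from
#'   \code{\link{summary.ivim_maps}}.
#' @return An \code{"ivim_variability"} data frame: WS-CV %, per-visit
#'   means per method and parameter.
#' @export
intersession_repeatability <- function(visit1, visit2) {
  common <- intersect(unique(visit1$subject), unique(visit2$subject))
  dropped <- setdiff(union(unique(visit1$subject), unique(visit2$subject)),
                     common)
  if (length(dropped))
    message("excluding subject(s) missing a visit: ",
            paste(dropped, collapse = ", "))
  v1 <- visit1[visit1$subject %in% common, ]
  v2 <- visit2[visit2$subject %in% common, ]
  out <- NULL
  for (m in intersect(unique(v1$method), unique(v2$method))) {
    s1 <- v1[v1$method == m, ]; s2 <- v2[v2$method == m, ]
    s1 <- s1[order(s1$subject), ]; s2 <- s2[order(s2$subject), ]
    for (p in .ivim_param_cols) {
      pairs <- Map(c, s1[[p]], s2[[p]])
      w <- tryCatch(suppressMessages(ws_cv(pairs)), error = function(e) NA_real_)
      out <- rbind(out, data.frame(method = m, parameter = p, wscv = w,
                                   mean_visit1 = mean(s1[[p]], na.rm = TRUE),
                                   mean_visit2 = mean(s2[[p]], na.rm = TRUE)))
    }
  }
  .variability_report(out, "sessions")
}
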