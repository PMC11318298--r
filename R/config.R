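# Run configuration: a single YAML file drives reproducible phantom, fit,
# simulation and repeatability runs. Every randomized stage must name an
# explicit seed; a missing seed is an error, never a silent default.

#' Read and validate a run configuration
#'
#' @param path Path to a YAML configuration file. Recognised top-level
#'   blocks: \code{bounds} (f_range, Dstar_range, D_range, high_b_cutoff),
#'   \code{methods} (character vector), \code{fitter} (arguments to
#'   \code{\link{ivim_fit_control}}), \code{simulation} (n_combinations,
#'   snr_levels, seed), \code{phantom} (dims, snr, seed, n_repeats,
#'   n_directions) and free-form \code{io} paths.
#' @return A list of class \code{"ivim_config"} with parsed \code{bounds},
#'   \code{control}, \code{methods} and the raw blocks.
#' @export
ivim_read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bargs <- list()
  if (!is.null(raw$bounds$f_range)) bargs$f_range <- as.numeric(raw$bounds$f_range)
  if (!is.null(raw$bounds$Dstar_range)) bargs$Dstar_range <- as.numeric(raw$bounds$Dstar_range)
  if (!is.null(raw$bounds$D_range)) bargs$D_range <- as.numeric(raw$bounds$D_range)
  if (!is.null(raw$bounds$high_b_cutoff)) bargs$high_b_cutoff <- as.numeric(raw$bounds$high_b_cutoff)
  bounds <- do.call(ivim_bounds, bargs)
  control <- do.call(ivim_fit_control,
                     if (is.null(raw$fitter)) list() else raw$fitter)
  methods <- if (is.null(raw$methods)) c("nlls1", "nlls2", "nlls3", "bayes")
             else unlist(raw$methods)
  bad <- setdiff(methods, c("nlls1", "nlls2", "nlls3", "bayes"))
  if (length(bad)) stop("unknown method(s) in config: ",
                        paste(bad, collapse = ", "))
  structure(list(bounds = bounds, control = control, methods = methods,
                 raw = raw, path = path),
            class = "ivim_config")
}

#' Write a configuration alongside run outputs
#'
#' Copies the run's configuration into the output directory so every
#' result directory records exactly how it was produced.
#'
#' @param config An \code{"ivim_config"}.
#' @param dir Output directory.
#' @return Path of the written file, invisibly.
#' @export
ivim_write_config <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "run_config.yaml")
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' Run the full fitting chain on a series + mask from disk
#'
#' Reads a NIfTI series (with bval/bvec/JSON sidecars) and an ROI mask,
#' executes the processing chain (median filter, direction/repeat
#' averaging, voxelwise fitting, exclusion rules), and writes parameter
#' maps (one NIfTI per parameter per method), a summary CSV and the
#' configuration into \code{out_dir}.
#'
#' @param series_prefix Prefix of the series files
#'   (\code{<prefix>.nii.gz/.bval/.bvec/.json}).
#' @param mask_path NIfTI mask path (non-zero = ROI).
#' @param config An \code{"ivim_config"}.
#' @param out_dir Output directory.
#' @return The \code{"ivim_maps"} object, invisibly.
#' @export
run_fit_pipeline <- function(series_prefix, mask_path, config, out_dir) {
  if (!file.exists(paste0(series_prefix, ".nii.gz")))
    stop("series not found: ", series_prefix, ".nii.gz")
  if (!file.exists(mask_path)) stop("mask not found: ", mask_path)
  series <- read_ivim_series(series_prefix)
  mask_img <- RNifti::readNifti(mask_path)
  roi <- array(as.numeric(mask_img) != 0, dim(mask_img))
  if (!all(dim(roi) == dim(series$data)[1:3]))
    stop("mask grid ", paste(dim(roi), collapse = "x"),
         " does not match series grid ",
         paste(dim(series$data)[1:3], collapse = "x"))
  maps <- fit_voxelwise(series, roi, bounds = config$bounds,
                        methods = config$methods, control = config$control)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_parameter_maps(maps, out_dir)
  utils::write.csv(summary(maps), file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  excl <- do.call(rbind, lapply(config$methods, function(m) {
    r <- maps$inclusion[[m]]$reason[maps$roi]
    data.frame(method = m, included = sum(r == 0L), physicality = sum(r == 2L),
               at_constraint = sum(r == 3L), failed = sum(r == 4L))
  }))
  utils::write.csv(excl, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  ivim_write_config(config, out_dir)
  invisible(maps)
}

#' Run the Monte Carlo simulation from a configuration
#'
#' @param config An \code{"ivim_config"} whose \code{simulation} block
#'   gives \code{n_combinations}, \code{snr_levels} and \code{seed}.
#' @param out_dir Output directory for \code{icc.csv}, \code{raw.csv} and
#'   the configuration.
#' @return The \code{"ivim_sim"} object, invisibly.
#' @export
run_simulation_config <- function(config, out_dir) {
  sim <- config$raw$simulation
  if (is.null(sim$seed)) stop("simulation block must name a seed")
  design <- ivim_sim_design(
    n_combinations = sim$n_combinations,
    snr_levels = if (is.null(sim$snr_levels)) seq(15, 80, by = 5)
                 else unlist(sim$snr_levels),
    seed = sim$seed, bounds = config$bounds)
  res <- run_simulation(design, methods = config$methods,
                        control = config$control)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(res$icc, file.path(out_dir, "icc.csv"), row.names = FALSE)
  utils::write.csv(res$raw, file.path(out_dir, "raw.csv"), row.names = FALSE)
  ivim_write_config(config, out_dir)
  invisible(res)
}

#' Run a repeatability report from a fitted-parameter table
#'
#' Accepts a CSV of per-subject per-replicate fitted parameters (columns
#' subject, replicate, method, f, Dstar, D, fDstar, and optionally
#' resid_sq_norm, converged) and writes the WS-CV report.
#'
#' @param table_path CSV path.
#' @param out_dir Output directory.
#' @return The report data frame, invisibly.
#' @export
run_repeatability_table <- function(table_path, out_dir) {
  tab <- utils::read.csv(table_path)
  need <- c("subject", "replicate", "method", "f", "Dstar", "D", "fDstar")
  if (!all(need %in% names(tab)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (is.null(tab$converged)) tab$converged <- TRUE
  if (is.null(tab$resid_sq_norm)) tab$resid_sq_norm <- NA_real_
  tab$rep <- tab$replicate
  report <- .wscv_report(tab, replicate_col = "rep", grouping = "replicates")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(report, file.path(out_dir, "wscv_report.csv"),
                   row.names = FALSE)
  invisible(report)
}
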