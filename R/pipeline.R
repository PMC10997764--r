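#' Configuration of an end-to-end pipeline run
#'
#' Exactly one of \code{preset} (synthetic run) or \code{stack} + \code{rois}
#' (real or pre-rendered data) must be given.
#'
#' @param preset synthetic stress label ("wounding", "xcc", "light",
#'   "heat", "null"), or NULL.
#' @param stack a \code{\link{frame_stack}}, or a TIFF path readable by
#'   \code{\link{read_frame_stack}}; NULL for synthetic runs.
#' @param rois a \code{\link{roi_set}} or ROI path prefix; NULL for
#'   synthetic runs.
#' @param curves named list of calibration curves, default
#'   \code{\link{default_curves}}.
#' @param labels sensor labels to process, default c("h2o2", "sa").
#' @param window moving-average smoothing width (points), default 10.
#' @param k_sd,sustain onset-detection parameters, see
#'   \code{\link{onset_time}}.
#' @param fit if TRUE, fit the reaction network to the extracted series.
#' @param fit_init initial \code{\link{kinetic_params}} for the fit
#'   (defaults to the preset's generating parameters when synthetic).
#' @param frozen parameter names frozen during the fit.
#' @param preset_args extra overrides for \code{\link{stress_preset}}.
#' @param seed seed for synthetic rendering and fit multistarts.
#' @param out_dir output directory, or NULL to skip writing files.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(preset = NULL, stack = NULL, rois = NULL,
                       curves = default_curves(), labels = c("h2o2", "sa"),
                       window = 10L, k_sd = 3, sustain = 3L, fit = FALSE,
                       fit_init = NULL, frozen = character(),
                       preset_args = list(), seed = 0L, out_dir = NULL) {
  if (is.null(preset) == (is.null(stack) || is.null(rois)))
    stop_input("specify exactly one of a synthetic preset or stack + rois")
  structure(list(preset = preset, stack = stack, rois = rois, curves = curves,
                 labels = labels, window = window, k_sd = k_sd,
                 sustain = sustain, fit = fit, fit_init = fit_init,
                 frozen = frozen, preset_args = preset_args,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @keywords internal
#' @noRd
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  stable <- config[setdiff(names(config), "out_dir")]
  saveRDS(stable, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Synthetic path: preset -> ground-truth fields -> rendered stack.
#' Both paths: ROI extraction -> ratiometric quench -> calibration
#' inversion -> wave features -> optional kinetic fit. Writes per-label
#' concentration CSVs, a features CSV and a JSON report (with provenance:
#' config hash, seed, package version, timestamps, clipping/saturation
#' warnings) into \code{out_dir} when set. Output CSVs are deterministic
#' given identical config and seed.
#'
#' @param config a \code{\link{run_config}}.
#' @return object of class \code{run_report}: list with \code{series}
#'   (per-label \code{\link{concentration_series}}), \code{features},
#'   \code{fit} (when requested), \code{truth} (synthetic runs),
#'   \code{provenance}, \code{warnings}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s (check inputs for this stage)",
                   name, conditionMessage(e)), call. = FALSE)
    })
  }
  truth <- NULL
  if (!is.null(config$preset)) {
    syn <- stage("synthesis", {
      args <- c(list(stress_label = config$preset, seed = config$seed),
                config$preset_args)
      cfg <- do.call(stress_preset, args)
      truth <- make_fields(cfg)
      c(render_stack(truth, cfg, config$curves), list(truth = truth, cfg = cfg))
    })
    stack <- syn$stack; rois <- syn$rois; truth <- syn$truth
    if (is.null(config$fit_init) && !is.null(syn$cfg$kinetic_params))
      config$fit_init <- syn$cfg$kinetic_params
  } else {
    stack <- stage("input", if (is.character(config$stack))
      read_frame_stack(config$stack) else config$stack)
    rois <- stage("input", if (is.character(config$rois))
      read_roi_set(config$rois) else config$rois)
  }

  series <- list(); features <- list(); warn <- list()
  for (lbl in intersect(config$labels, names(rois$masks))) {
    s <- stage(paste0("imaging:", lbl),
               stack_to_series(stack, rois, config$curves, lbl,
                               window = config$window))
    dist_cm <- if (lbl == "sa")
      sqrt(sum((roi_centroid(rois$masks[[lbl]]) - rois$stress_site)^2)) *
        stack$pixel_size else NULL
    f <- stage(paste0("features:", lbl),
               wave_features(s, distance_cm = dist_cm, k_sd = config$k_sd,
                             sustain = config$sustain))
    series[[lbl]] <- s
    features[[lbl]] <- f
    warn[[lbl]] <- list(n_clipped_negative = attr(s, "n_clipped_negative"),
                        n_saturated = attr(s, "n_saturated"))
  }

  fit <- NULL
  if (config$fit) {
    if (is.null(config$fit_init))
      stop_input("fit requested but no fit_init available")
    fit <- stage("kinetic-fit",
                 fit_kinetic_model(series$h2o2, series$sa, config$fit_init,
                                   frozen = config$frozen, seed = config$seed))
  }

  report <- structure(
    list(series = series, features = features, fit = fit, truth = truth,
         warnings = warn,
         provenance = list(config_hash = config_hash(config),
                           seed = config$seed,
                           package_version = as.character(
                             utils::packageVersion("phytowave")),
                           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @keywords internal
#' @noRd
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- report$provenance$config_hash
  for (lbl in names(report$series)) {
    s <- report$series[[lbl]]
    df <- data.frame(time_min = s$times, concentration_uM = s$values)
    path <- file.path(out_dir, paste0("series_", lbl, ".csv"))
    writeLines(paste0("# config_hash: ", hash), path)
    suppressWarnings(utils::write.table(df, path, append = TRUE, sep = ",",
                                        row.names = FALSE, qmethod = "double"))
  }
  f_path <- file.path(out_dir, "features.csv")
  tmp <- tempfile()
  write_features_csv(report$features, tmp)
  writeLines(c(paste0("# config_hash: ", hash), readLines(tmp)), f_path)
  unlink(tmp)
  if (!is.null(report$fit)) {
    utils::write.csv(report$fit$residual_h2o2,
                     file.path(out_dir, "residual_h2o2.csv"), row.names = FALSE)
    utils::write.csv(report$fit$residual_sa,
                     file.path(out_dir, "residual_sa.csv"), row.names = FALSE)
    write_kinetics_json(report$fit, file.path(out_dir, "fit.json"))
  }
  jsonlite::write_json(
    list(provenance = report$provenance,
         warnings = report$warnings,
         features = lapply(report$features, unclass)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(out_dir)
}
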