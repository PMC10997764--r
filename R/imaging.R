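#' Time-lapse nIR frame stack
#'
#' @param times minutes per frame, strictly increasing.
#' @param frames 3D numeric array (rows x cols x frames) of intensities
#'   (arbitrary counts >= 0).
#' @param pixel_size cm per pixel, > 0.
#' @param t_stress stress time in minutes.
#' @return object of class \code{frame_stack}.
#' @export
frame_stack <- function(times, frames, pixel_size, t_stress) {
  frames <- as.array(frames)
  if (length(dim(frames)) != 3L) stop_input("frames must be a rows x cols x frames array")
  if (dim(frames)[3L] != length(times))
    stop_input("number of frames must equal length(times)")
  assert_increasing(times)
  if (pixel_size <= 0) stop_input("pixel_size must be > 0")
  structure(list(times = as.numeric(times), frames = frames,
                 pixel_size = pixel_size, t_stress = t_stress),
            class = "frame_stack")
}

#' Labeled sensor-spot masks plus the stress-site coordinate
#'
#' @param masks named list of logical matrices; labels from
#'   \{"sa", "h2o2", "reference"\}. Masks must be non-empty, pairwise
#'   disjoint and share one shape. A reference mask is required for
#'   ratiometric processing.
#' @param stress_site pixel coordinate c(row, col), 0-based.
#' @return object of class \code{roi_set}.
#' @export
roi_set <- function(masks, stress_site) {
  if (!length(masks) || is.null(names(masks))) stop_input("masks must be a named list")
  shapes <- vapply(masks, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L) stop_input("all masks must share one shape")
  if (any(vapply(masks, function(m) !any(m), logical(1))))
    stop_input("masks must be non-empty")
  total <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(total > 1L)) stop_input("masks must be pairwise disjoint")
  structure(list(masks = masks, stress_site = as.numeric(stress_site)),
            class = "roi_set")
}

#' Per-frame intensity of one sensor ROI
#'
#' mode "mean": per-frame mean over the mask (reference and SA spots).
#' mode "top-quench": the 200 mask pixels with the largest total
#' first-to-last intensity drop are selected once for the whole record and
#' averaged per frame (H2O2 spots), so the series tracks one coherent,
#' maximally responding region.
#'
#' @param stack a \code{\link{frame_stack}}.
#' @param rois a \code{\link{roi_set}}.
#' @param label ROI label.
#' @param mode "mean" or "top-quench".
#' @param n_top pixels kept in top-quench mode, default 200. ROIs smaller
#'   than \code{n_top} use all pixels with a warning.
#' @return numeric vector of per-frame intensities.
#' @export
roi_intensity_series <- function(stack, rois, label, mode = c("mean", "top-quench"),
                                 n_top = 200L) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "frame_stack"), inherits(rois, "roi_set"))
  mask <- rois$masks[[label]]
  if (is.null(mask)) stop_input("no ROI labeled '", label, "'")
  sel <- which(mask)
  if (!length(sel)) stop_input("empty mask for '", label, "'")
  npx <- prod(dim(stack$frames)[1:2])
  flat <- matrix(stack$frames, npx, dim(stack$frames)[3L])[sel, , drop = FALSE]
  if (mode == "top-quench") {
    if (length(sel) < n_top) {
      warning(sprintf("ROI '%s' has %d < %d pixels; using all of them",
                      label, length(sel), n_top))
      n_top <- length(sel)
    }
    quench <- flat[, 1L] - flat[, ncol(flat)]
    keep <- order(quench, decreasing = TRUE)[seq_len(n_top)]
    flat <- flat[keep, , drop = FALSE]
  }
  colMeans(flat)
}

#' Ratiometric quench series from active and reference intensities
#'
#' Both series are normalized to their own pre-stress means, the active
#' is divided by the reference (cancelling shared multiplicative drift from
#' laser instability or leaf movement), and the fractional quench
#' r(t) = 1 - R(t) is smoothed with a centered moving average.
#'
#' @param active,reference per-frame intensity vectors of equal length.
#' @param times frame times, minutes.
#' @param t_stress stress time; >= 3 pre-stress frames are required.
#' @param window moving-average width in points, default 10.
#' @return numeric vector: smoothed fractional quench (quench positive).
#' @export
ratiometric_series <- function(active, reference, times, t_stress, window = 10L) {
  if (length(active) != length(reference) || length(active) != length(times))
    stop_input("active, reference and times must have equal length")
  pre <- times < t_stress
  if (sum(pre) < 3L) stop_input("need >= 3 pre-stress frames for the baseline")
  bad <- which(reference == 0)
  if (length(bad))
    stop(structure(class = c("phytowave_data_quality_error", "error", "condition"),
                   list(message = paste0("zero reference intensity at frame(s) ",
                                         paste(bad, collapse = ", ")),
                        call = sys.call())))
  ratio <- (active / mean(active[pre])) / (reference / mean(reference[pre]))
  moving_average(1 - ratio, window)
}

#' Convert a quench series to a concentration series
#'
#' Applies the inverse Langmuir calibration pointwise. Negative quench
#' (baseline jitter) clips to 0 uM; saturated points (r >= r_max) are set
#' to the configured ceiling; both counts are carried on the result as
#' attributes \code{n_clipped_negative} and \code{n_saturated}.
#'
#' @param quench fractional quench vector.
#' @param times frame times, minutes.
#' @param curve a \code{\link{calibration_curve}}.
#' @param t_stress stress time, min.
#' @param replicate_count carried metadata.
#' @param ceiling_uM saturation ceiling, default 10 * kd.
#' @return a \code{\link{concentration_series}}.
#' @export
series_to_concentration <- function(quench, times, curve, t_stress,
                                    replicate_count = 1L,
                                    ceiling_uM = 10 * curve$kd) {
  inv <- invert_response(curve, quench, clip = TRUE, ceiling_uM = ceiling_uM)
  out <- concentration_series(times, inv$conc, t_stress = t_stress,
                              replicate_count = replicate_count)
  attr(out, "n_clipped_negative") <- inv$n_clipped_negative
  attr(out, "n_saturated") <- inv$n_saturated
  out
}

#' Pixel-wise concentration map container
#'
#' @param times minutes per frame.
#' @param maps 3D array (rows x cols x frames) of concentrations (uM),
#'   NA outside sensor ROIs.
#' @param pixel_size cm per pixel.
#' @param saturated_pixel_count per-frame count of saturation-clipped pixels.
#' @return object of class \code{concentration_map}.
#' @export
concentration_map_obj <- function(times, maps, pixel_size,
                                  saturated_pixel_count = integer(length(times))) {
  structure(list(times = as.numeric(times), maps = maps,
                 pixel_size = pixel_size,
                 saturated_pixel_count = saturated_pixel_count),
            class = "concentration_map")
}

#' Pixel-wise concentration map from a frame stack
#'
#' Each pixel is normalized to its own pre-stress mean and divided by the
#' reference ROI's scalar drift series (reference and active spots are
#' spatially separate, so a per-pixel reference does not exist); the
#' resulting quench is inverted through the label's calibration curve.
#'
#' @param stack a \code{\link{frame_stack}}.
#' @param rois a \code{\link{roi_set}}.
#' @param curve_by_label named list of \code{\link{calibration_curve}}s,
#'   one entry per processed label.
#' @param labels labels to map, default all non-reference masks with a curve.
#' @param window moving-average width applied to the per-pixel quench along
#'   time, default 10.
#' @return a \code{\link{concentration_map}} (NA outside the processed ROIs).
#' @export
concentration_map <- function(stack, rois, curve_by_label,
                              labels = NULL, window = 10L) {
  stopifnot(inherits(stack, "frame_stack"), inherits(rois, "roi_set"))
  if (is.null(rois$masks[["reference"]]))
    stop_input("a reference mask is required for ratiometric maps")
  if (is.null(labels))
    labels <- intersect(setdiff(names(rois$masks), "reference"),
                        names(curve_by_label))
  nt <- length(stack$times)
  dims <- dim(stack$frames)[1:2]
  pre <- stack$times < stack$t_stress
  if (sum(pre) < 3L) stop_input("need >= 3 pre-stress frames for the baseline")
  ref <- roi_intensity_series(stack, rois, "reference", mode = "mean")
  ref_norm <- ref / mean(ref[pre])
  maps <- array(NA_real_, c(dims, nt))
  sat_count <- integer(nt)
  npx <- prod(dims)
  flat <- matrix(stack$frames, npx, nt)
  for (lbl in labels) {
    curve <- curve_by_label[[lbl]]
    if (is.null(curve)) stop_input("no calibration curve for label '", lbl, "'")
    sel <- which(rois$masks[[lbl]])
    px <- flat[sel, , drop = FALSE]
    px_norm <- px / rowMeans(px[, pre, drop = FALSE])
    quench <- 1 - sweep(px_norm, 2L, ref_norm, `/`)
    quench <- t(apply(quench, 1L, moving_average, window = window))
    inv <- invert_response(curve, as.vector(quench), clip = TRUE)
    conc <- matrix(inv$conc, nrow = length(sel))
    sat <- matrix(as.vector(quench) >= curve$r_max, nrow = length(sel))
    sat_count <- sat_count + colSums(sat)
    for (tt in seq_len(nt)) {
      m <- maps[, , tt]
      m[sel] <- conc[, tt]
      maps[, , tt] <- m
    }
  }
  concentration_map_obj(stack$times, maps, stack$pixel_size, sat_count)
}

#' End-to-end ROI concentration series from a frame stack
#'
#' Convenience wrapper: ROI intensity extraction (top-quench for h2o2,
#' mean otherwise), ratiometric normalization against the reference ROI,
#' smoothing, and calibration inversion.
#'
#' @inheritParams concentration_map
#' @param label ROI label to process.
#' @param mode intensity mode; default "top-quench" for "h2o2", else "mean".
#' @param window moving-average width, default 10.
#' @return a \code{\link{concentration_series}}.
#' @export
stack_to_series <- function(stack, rois, curve_by_label, label,
                            mode = NULL, window = 10L) {
  if (is.null(mode)) mode <- if (label == "h2o2") "top-quench" else "mean"
  act <- roi_intensity_series(stack, rois, label, mode = mode)
  ref <- roi_intensity_series(stack, rois, "reference", mode = "mean")
  quench <- ratiometric_series(act, ref, stack$times, stack$t_stress, window)
  series_to_concentration(quench, stack$times, curve_by_label[[label]],
                          t_stress = stack$t_stress)
}
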