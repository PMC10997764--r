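#' Read and write frame stacks as multi-page TIFF plus a JSON sidecar
#'
#' The stack is stored as one 32-bit float page per frame; acquisition
#' metadata (times_min, pixel_size_cm, t_stress_min) goes into a JSON
#' sidecar next to it. Intensities are scaled by \code{scale} on write and
#' unscaled on read, because TIFF float pages are stored in [0, 1].
#'
#' @param stack a \code{\link{frame_stack}}.
#' @param path TIFF path; the sidecar is \code{<path>.json}.
#' @param scale intensity divisor used to map counts into [0, 1]
#'   (default 65535).
#' @return \code{read_frame_stack}: a \code{\link{frame_stack}}.
#' @export
write_frame_stack <- function(stack, path, scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_input("the 'tiff' package is required for TIFF I/O")
  pages <- lapply(seq_along(stack$times), function(i) stack$frames[, , i] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(times_min = stack$times,
                            pixel_size_cm = stack$pixel_size,
                            t_stress_min = stack$t_stress,
                            intensity_scale = scale),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_input("the 'tiff' package is required for TIFF I/O")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
  frame_stack(meta$times_min, frames * meta$intensity_scale,
              meta$pixel_size_cm, meta$t_stress_min)
}

#' Write ROI masks as one-page TIFFs plus a JSON stress-site sidecar
#'
#' Masks are stored as 8-bit images (0/255), one file per label:
#' \code{<prefix>_<label>.tif}; the stress site goes into
#' \code{<prefix>_rois.json}.
#'
#' @param rois a \code{\link{roi_set}}.
#' @param prefix path prefix.
#' @return \code{read_roi_set}: a \code{\link{roi_set}}.
#' @export
write_roi_set <- function(rois, prefix) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_input("the 'tiff' package is required for TIFF I/O")
  for (lbl in names(rois$masks))
    tiff::writeTIFF(rois$masks[[lbl]] * 1.0, paste0(prefix, "_", lbl, ".tif"),
                    bits.per.sample = 8L)
  jsonlite::write_json(list(labels = names(rois$masks),
                            stress_site = rois$stress_site),
                       paste0(prefix, "_rois.json"), digits = NA)
  invisible(prefix)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(prefix) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_input("the 'tiff' package is required for TIFF I/O")
  meta <- jsonlite::read_json(paste0(prefix, "_rois.json"), simplifyVector = TRUE)
  masks <- lapply(meta$labels, function(lbl)
    tiff::readTIFF(paste0(prefix, "_", lbl, ".tif")) > 0.5)
  names(masks) <- meta$labels
  roi_set(masks, meta$stress_site)
}

#' Write a concentration map as multi-page float TIFF plus a CSV summary
#'
#' @param cmap a \code{\link{concentration_map}}.
#' @param path TIFF path; the per-frame summary goes to \code{<path>.csv}.
#' @param scale concentration divisor mapping uM into [0, 1] (default 1000).
#' @export
write_concentration_map <- function(cmap, path, scale = 1000) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_input("the 'tiff' package is required for TIFF I/O")
  pages <- lapply(seq_along(cmap$times), function(i) {
    m <- cmap$maps[, , i]
    m[is.na(m)] <- 0
    pmin(pmax(m / scale, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  summ <- data.frame(
    time_min = cmap$times,
    mean_uM = vapply(seq_along(cmap$times), function(i)
      mean(cmap$maps[, , i], na.rm = TRUE), numeric(1)),
    max_uM = vapply(seq_along(cmap$times), function(i)
      suppressWarnings(max(cmap$maps[, , i], na.rm = TRUE)), numeric(1)),
    saturated_pixels = cmap$saturated_pixel_count)
  utils::write.csv(summ, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
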