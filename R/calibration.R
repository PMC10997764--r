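#' Titration data for one sensor/analyte pair
#'
#' Bundles a titration series (analyte concentration versus fractional
#' fluorescence response) for calibration fitting. Responses are stored as
#' signed fractions with quenching positive and turn-on negative, one sign
#' convention everywhere.
#'
#' @param analyte character label, e.g. "SA".
#' @param concentrations numeric vector of analyte concentrations (uM),
#'   non-negative and strictly increasing.
#' @param responses numeric vector of fractional responses (dimensionless).
#' @param response_sd optional per-point standard deviation (>= 0).
#' @return object of class \code{titration_data}.
#' @export
titration_data <- function(analyte, concentrations, responses, response_sd = NULL) {
  if (length(concentrations) != length(responses))
    stop_input("concentrations and responses must have the same length")
  if (any(concentrations < 0)) stop_input("concentrations must be >= 0")
  assert_increasing(concentrations, "concentrations")
  if (!is.null(response_sd)) {
    if (length(response_sd) != length(responses) || any(response_sd < 0))
      stop_input("response_sd must be non-negative and match responses in length")
  }
  structure(list(analyte = as.character(analyte),
                 concentrations = as.numeric(concentrations),
                 responses = as.numeric(responses),
                 response_sd = response_sd),
            class = "titration_data")
}

#' Langmuir calibration curve of a nanosensor
#'
#' Holds the fitted parameters of the saturating binding model
#' r(c) = r_max * c / (K_D + c): the dissociation constant K_D (uM), the
#' maximal fractional quench r_max, and optionally the Pearson correlation
#' of the fit and the limit of detection.
#'
#' @param analyte character label.
#' @param kd dissociation constant K_D in uM, > 0.
#' @param r_max maximal fractional quench, in (0, 1].
#' @param fit_r optional Pearson correlation of fitted vs observed responses.
#' @param lod optional limit of detection (uM, >= 0).
#' @return object of class \code{calibration_curve}.
#' @export
calibration_curve <- function(analyte, kd, r_max, fit_r = NULL, lod = NULL) {
  if (!is.finite(kd) || kd <= 0) stop_input("kd must be > 0")
  if (!is.finite(r_max) || r_max <= 0 || r_max > 1)
    stop_input("r_max must be in (0, 1]")
  if (!is.null(lod) && lod < 0) stop_input("lod must be >= 0")
  structure(list(analyte = as.character(analyte), kd = kd, r_max = r_max,
                 fit_r = fit_r, lod = lod),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Langmuir calibration for %s: K_D = %.4g uM, r_max = %.4g",
              x$analyte, x$kd, x$r_max))
  if (!is.null(x$fit_r)) cat(sprintf(", R = %.4g", x$fit_r))
  if (!is.null(x$lod)) cat(sprintf(", LOD = %.3g uM", x$lod))
  cat("\n")
  invisible(x)
}

#' Fit the Langmuir adsorption model to titration data
#'
#' Fits r(c) = r_max * c / (K_D + c) by bounded nonlinear least squares
#' (Levenberg-Marquardt) with K_D multistarts on a log-spaced grid, because
#' the half-saturation point of sparse titrations can sit between decades.
#' Bounds: kd in (1e-3, 1e5) uM, r_max in (1e-3, 1].
#'
#' @param data a \code{\link{titration_data}} object with >= 4 points.
#' @param n_starts number of log-spaced K_D starting values (default 10).
#' @return a \code{\link{calibration_curve}} with \code{fit_r} set to the
#'   Pearson correlation of fitted vs observed responses.
#' @export
fit_langmuir <- function(data, n_starts = 10L) {
  stopifnot(inherits(data, "titration_data"))
  conc <- data$concentrations
  resp <- data$responses
  if (length(conc) < 4L) stop_input("at least 4 titration points are required")
  # fit on the magnitude branch; sign restored at the end
  sgn <- sign(sum(resp))
  if (sgn == 0 || all(abs(resp) < .Machine$double.eps)) {
    stop(structure(class = c("phytowave_fit_error", "error", "condition"),
                   list(message = "all responses are zero: r_max is not identifiable",
                        call = sys.call())))
  }
  y <- sgn * resp
  lower <- c(log(1e-3), 1e-3)
  upper <- c(log(1e5), 1)
  resid_fn <- function(p) y - (p[2] * conc / (exp(p[1]) + conc))
  kd_starts <- exp(seq(log(1e-2), log(1e4), length.out = n_starts))
  best <- NULL
  for (kd0 in kd_starts) {
    r0 <- min(1, max(1e-3, max(y)))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(log(kd0), r0), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || sse < best$sse) best <- list(par = fit$par, sse = sse)
  }
  if (is.null(best)) {
    stop(structure(class = c("phytowave_fit_error", "error", "condition"),
                   list(message = "Langmuir fit failed to converge from any start",
                        call = sys.call())))
  }
  kd <- exp(best$par[1]); r_max <- best$par[2]
  fitted <- r_max * conc / (kd + conc)
  fit_r <- if (stats::sd(fitted) > 0 && stats::sd(y) > 0)
    stats::cor(fitted, y) else NA_real_
  calibration_curve(data$analyte, kd = kd, r_max = r_max, fit_r = fit_r)
}

#' Evaluate a calibration curve at a concentration
#'
#' @param curve a \code{\link{calibration_curve}}.
#' @param c_uM concentration(s) in uM, >= 0. Vectorized.
#' @return fractional response r_max * c / (kd + c).
#' @export
response_at <- function(curve, c_uM) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(c_uM < 0)) stop_input("concentration must be >= 0")
  curve$r_max * c_uM / (curve$kd + c_uM)
}

#' Invert a calibration curve: fractional response to concentration
#'
#' Exact algebraic inverse c = kd * r / (r_max - r). Responses at or above
#' r_max correspond to unbounded concentration and raise a saturation error
#' (or, with \code{clip = TRUE}, are set to \code{ceiling_uM} and counted).
#' Negative responses (baseline jitter through the reference channel) clip
#' to 0 uM and are counted rather than raising, so pipelines survive noise.
#'
#' @param curve a \code{\link{calibration_curve}}.
#' @param r fractional response(s). Vectorized.
#' @param clip if TRUE, saturated responses are clipped to \code{ceiling_uM}
#'   instead of erroring (used by the imaging pipeline).
#' @param ceiling_uM concentration assigned to saturated responses when
#'   \code{clip = TRUE} (default 10 * kd, always reported, never silent).
#' @return list with \code{conc} (uM), \code{n_clipped_negative},
#'   \code{n_saturated}.
#' @export
invert_response <- function(curve, r, clip = FALSE, ceiling_uM = 10 * curve$kd) {
  stopifnot(inherits(curve, "calibration_curve"))
  sat <- r >= curve$r_max
  if (any(sat) && !clip) {
    stop(structure(class = c("phytowave_saturation_error", "error", "condition"),
                   list(message = sprintf(
                     "%d response(s) at or above r_max = %.4g: concentration unbounded",
                     sum(sat), curve$r_max), call = sys.call())))
  }
  neg <- r < 0
  r_clip <- pmin(pmax(r, 0), curve$r_max * (1 - 1e-12))
  conc <- curve$kd * r_clip / (curve$r_max - r_clip)
  conc[sat] <- ceiling_uM
  list(conc = conc,
       n_clipped_negative = sum(neg),
       n_saturated = sum(sat))
}

#' Limit of detection of a calibrated sensor
#'
#' The smallest concentration whose response reaches 3x the supplied noise
#' standard deviation (signal-to-noise >= 3), computed analytically as
#' \code{invert_response(curve, 3 * noise_sd)}.
#'
#' @param curve a \code{\link{calibration_curve}}.
#' @param noise_sd baseline noise SD on the fractional-response scale;
#'   must satisfy 0 < 3 * noise_sd < r_max.
#' @return concentration in uM.
#' @export
estimate_lod <- function(curve, noise_sd) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  target <- 3 * noise_sd
  if (target >= curve$r_max) {
    stop(structure(class = c("phytowave_saturation_error", "error", "condition"),
                   list(message = "3 * noise_sd reaches r_max: LOD undefined (saturated)",
                        call = sys.call())))
  }
  invert_response(curve, target)$conc
}

#' Screening table of sensor responses across analytes
#'
#' @param sensors character vector of sensor labels (rows).
#' @param analytes character vector of analyte labels (columns).
#' @param responses numeric matrix of signed fractional responses,
#'   dim |sensors| x |analytes|.
#' @return object of class \code{screen_table}.
#' @export
screen_table <- function(sensors, analytes, responses) {
  responses <- as.matrix(responses)
  if (!all(dim(responses) == c(length(sensors), length(analytes))))
    stop_input("responses must be a |sensors| x |analytes| matrix")
  dimnames(responses) <- list(sensors, analytes)
  structure(list(sensors = sensors, analytes = analytes, responses = responses),
            class = "screen_table")
}

#' Classify screening responses into hits
#'
#' Entries with response >= threshold are quench hits, <= -threshold are
#' turn-on hits, and everything between is inert. The boundary |r| equal to
#' the threshold counts as a hit (the dotted acceptance lines mark the edge
#' of sufficiency, inclusive).
#'
#' @param table a \code{\link{screen_table}}.
#' @param threshold positive fraction, default 0.20.
#' @return character matrix with entries "quench-hit", "turn-on-hit", "inert".
#' @export
classify_screen <- function(table, threshold = 0.20) {
  stopifnot(inherits(table, "screen_table"))
  if (threshold <= 0) stop_input("threshold must be > 0")
  r <- table$responses
  out <- matrix("inert", nrow(r), ncol(r), dimnames = dimnames(r))
  out[r >= threshold] <- "quench-hit"
  out[r <= -threshold] <- "turn-on-hit"
  out
}

#' Read/write titration data as CSV
#'
#' CSV columns: analyte, concentration_uM, response, response_sd (optional).
#' @param path file path.
#' @return \code{read_titration_csv}: a \code{\link{titration_data}}.
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sd <- if ("response_sd" %in% names(df) && !all(is.na(df$response_sd)))
    df$response_sd else NULL
  titration_data(df$analyte[1], df$concentration_uM, df$response, sd)
}

#' @rdname read_titration_csv
#' @param data a \code{\link{titration_data}}.
#' @export
write_titration_csv <- function(data, path) {
  df <- data.frame(analyte = data$analyte,
                   concentration_uM = data$concentrations,
                   response = data$responses)
  if (!is.null(data$response_sd)) df$response_sd <- data$response_sd
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read/write a calibration curve as JSON
#'
#' JSON fields: analyte, kd_uM, r_max, fit_r, lod_uM.
#' @param path file path.
#' @return \code{read_calibration_json}: a \code{\link{calibration_curve}}.
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_curve(x$analyte, kd = x$kd_uM, r_max = x$r_max,
                    fit_r = x$fit_r %||% NULL, lod = x$lod_uM %||% NULL)
}

#' @rdname read_calibration_json
#' @param curve a \code{\link{calibration_curve}}.
#' @export
write_calibration_json <- function(curve, path) {
  jsonlite::write_json(
    list(analyte = curve$analyte, kd_uM = curve$kd, r_max = curve$r_max,
         fit_r = curve$fit_r, lod_uM = curve$lod),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
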