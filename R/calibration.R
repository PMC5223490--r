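#' Linear density calibration model
#'
#' Maps scanner values to bone mineral density, `bmd = slope * value +
#' intercept` (mg/cm^3). `source` records how the model was obtained: from an
#' in-scan rod phantom, from a cross-device regression of paired VOI means,
#' or declared internally (e.g. a scanner's built-in calibration).
#'
#' @param slope mg/cm^3 per input unit; must be non-zero.
#' @param intercept mg/cm^3.
#' @param source `"in_scan_phantom"`, `"cross_device"` or `"internal"`.
#' @return object of class `calibration_model`.
#' @export
calibration_model <- function(slope, intercept,
                              source = c("internal", "in_scan_phantom",
                                         "cross_device")) {
  source <- match.arg(source)
  if (!is.finite(slope) || slope == 0) stop("slope must be finite and non-zero",
                                            call. = FALSE)
  if (!is.finite(intercept)) stop("intercept must be finite", call. = FALSE)
  structure(list(slope = slope, intercept = intercept, source = source),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> bmd = %.6g * value + %.6g  [%s]\n",
              x$slope, x$intercept, x$source))
  invisible(x)
}

#' Phantom rod region with known density
#'
#' @param mask a [mask3d()] over the rod.
#' @param known_density nominal rod density, mg/cm^3.
#' @return object of class `phantom_roi`.
#' @export
phantom_roi <- function(mask, known_density) {
  stopifnot(is_mask3d(mask))
  if (!is.finite(known_density)) stop("known_density must be finite", call. = FALSE)
  structure(list(mask = mask, known_density = known_density),
            class = "phantom_roi")
}

#' Fit an in-scan phantom calibration
#'
#' Ordinary least squares of the known rod densities on the measured rod mean
#' values, mimicking the in-scan calibration phantom placed under the knees
#' to convert scanner values to BMD.
#'
#' @param rois list of [phantom_roi()] with at least two distinct known
#'   densities.
#' @param v the [volume3d()] the rods were imaged in.
#' @return a [calibration_model()] with `source = "in_scan_phantom"`.
#' @export
fit_phantom_calibration <- function(rois, v) {
  stopifnot(is_volume3d(v))
  if (!is.list(rois) || length(rois) < 2L)
    stop("need at least 2 phantom rods", call. = FALSE)
  if (!all(vapply(rois, inherits, logical(1), "phantom_roi")))
    stop("`rois` must be a list of phantom_roi objects", call. = FALSE)
  known <- vapply(rois, function(r) r$known_density, numeric(1))
  if (length(unique(known)) < 2L)
    stop("degenerate fit: rod densities must be distinct", call. = FALSE)
  measured <- vapply(rois, function(r) mask_statistics(v, r$mask)$mean, numeric(1))
  if (stats::var(measured) == 0)
    stop("degenerate fit: measured rod means are identical", call. = FALSE)
  fit <- stats::lm(known ~ measured)
  calibration_model(slope = unname(stats::coef(fit)[2]),
                    intercept = unname(stats::coef(fit)[1]),
                    source = "in_scan_phantom")
}

#' Apply a density calibration to a volume
#'
#' `values <- slope * values + intercept`. In-scan calibrations convert
#' attenuation volumes to BMD; cross-device corrections re-map a volume that
#' is already in BMD units onto the other device's scale.
#'
#' @param v a [volume3d()].
#' @param c a [calibration_model()].
#' @return the calibrated [volume3d()] (`unit_tag = "bmd"`).
#' @export
apply_calibration <- function(v, c) {
  stopifnot(is_volume3d(v), inherits(c, "calibration_model"))
  if (c$source == "in_scan_phantom" && v$unit_tag == "bmd")
    stop("misuse: volume already calibrated to bmd; an in-scan calibration ",
         "applies to attenuation values", call. = FALSE)
  if (c$source == "cross_device" && v$unit_tag != "bmd")
    stop("misuse: cross-device correction applies to bmd volumes", call. = FALSE)
  volume3d(c$slope * v$values + c$intercept, spacing = v$spacing,
           origin = v$origin, unit_tag = "bmd", kernel_tag = v$kernel_tag)
}

#' Fit the cross-device BMD correction
#'
#' Regresses paired VOI-mean BMD of the higher-resolution device on the
#' clinical-CT values; the fitted line maps CT BMD onto the HR-pQCT scale
#' (HR-pQCT results stay unchanged, CT results are corrected). Cortical VOIs
#' are excluded from the fit by callers by convention; this function fits
#' whatever pairs it receives.
#'
#' @param paired_bmd data.frame or list with numeric `bmd_ct` and
#'   `bmd_hrpqct` of equal length >= 3.
#' @return a [calibration_model()] with `source = "cross_device"`.
#' @export
fit_cross_device_correction <- function(paired_bmd) {
  x <- as.numeric(paired_bmd$bmd_ct)
  y <- as.numeric(paired_bmd$bmd_hrpqct)
  if (length(x) != length(y)) stop("paired series must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired VOI means", call. = FALSE)
  if (stats::var(x) <= .Machine$double.eps * max(1, mean(x)^2))
    stop("degenerate spread in CT BMD values", call. = FALSE)
  fit <- stats::lm(y ~ x)
  calibration_model(slope = unname(stats::coef(fit)[2]),
                    intercept = unname(stats::coef(fit)[1]),
                    source = "cross_device")
}

#' Serialize a calibration model to JSON
#' @param c a [calibration_model()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_calibration <- function(c, path) {
  stopifnot(inherits(c, "calibration_model"))
  jsonlite::write_json(unclass(c), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a calibration model from JSON
#' @param path file written by [write_calibration()].
#' @return a [calibration_model()].
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(x$slope, x$intercept, x$source)
}

#' Build a simulated calibration-rod volume
#'
#' Convenience generator for calibration experiments: a small volume holding
#' cylindrical rods of stated densities over a uniform background, plus the
#' matching [phantom_roi()] list. The rod interiors are eroded by one voxel
#' when building the ROIs so blur at rod edges does not bias the fit.
#'
#' @param densities nominal rod densities, mg/cm^3 (>= 2 distinct values).
#' @param rod_radius rod radius, mm.
#' @param core_margin margin (mm) eroded from the rod radius when building
#'   the measurement ROIs, keeping PSF-blurred rod edges out of the fit.
#' @param spacing voxel spacing, mm.
#' @param background background value.
#' @return list with `volume` ([volume3d()], attenuation units holding the
#'   nominal densities) and `rois` (list of [phantom_roi()]).
#' @export
make_rod_phantom <- function(densities = c(0, 100, 200, 400, 800),
                             rod_radius = 1.5, core_margin = 0.6,
                             spacing = c(0.25, 0.25, 0.25),
                             background = -20) {
  if (length(densities) < 2L) stop("need at least 2 rods", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  n <- length(densities)
  pitch <- 4 * rod_radius
  ext <- c(pitch * n, 4 * rod_radius + 2, 4 * rod_radius + 2)
  d <- as.integer(round(ext / spacing))
  xs <- (seq_len(d[1]) - 0.5) * spacing[1]
  ys <- (seq_len(d[2]) - 0.5) * spacing[2]
  vals <- array(background, dim = d)
  rois <- vector("list", n)
  yc <- ext[2] / 2
  for (i in seq_len(n)) {
    xc <- (i - 0.5) * pitch
    disk <- outer((xs - xc)^2, (ys - yc)^2, "+") <= rod_radius^2
    core <- outer((xs - xc)^2, (ys - yc)^2, "+") <=
      max(rod_radius - core_margin, max(spacing))^2
    m <- array(FALSE, dim = d)
    v <- array(rep(disk, d[3]), dim = d)
    vals[v] <- densities[i]
    m[] <- rep(core, d[3])
    rois[[i]] <- phantom_roi(mask3d(m, spacing, spacing / 2), densities[i])
  }
  list(volume = volume3d(vals, spacing, spacing / 2, unit_tag = "attenuation"),
       rois = rois)
}
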