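#' Default configuration of an end-to-end simulation experiment
#'
#' Assembles the run configuration: imaging profiles, phantom geometry,
#' trabecular interior, segmentation/VOI/registration/texture settings, the
#' fabricated inter-scan misalignment the registration has to undo, and the
#' seed. Everything is a plain value, so a config round-trips through JSON
#' and a run is reproducible from config + seed.
#'
#' `scale = "study"` uses the study geometries (82 um HR-pQCT voxels, 0.25 x
#' 0.25 x 0.3 mm CT voxels) on a miniature knee; `scale = "small"` is a
#' coarse, fast configuration for smoke tests.
#'
#' @param seed integer master seed.
#' @param n_cases number of simulated knees.
#' @param out_dir output directory.
#' @param scale `"study"` or `"small"`.
#' @return named list (class `run_config`).
#' @export
default_run_config <- function(seed = 1L, n_cases = 2L, out_dir = tempfile("run"),
                               scale = c("study", "small")) {
  scale <- match.arg(scale)
  small <- scale == "small"
  res <- if (small) 0.1 else 0.08
  profiles <- if (small) {
    list(hrpqct = list(name = "custom", spacing = c(0.2, 0.2, 0.2),
                       psf_fwhm = 0.3, noise_sd = 50),
         ct_medium = list(name = "custom", spacing = c(0.5, 0.5, 0.6),
                          psf_fwhm = 0.9, noise_sd = 10),
         ct_sharp = list(name = "custom", spacing = c(0.5, 0.5, 0.6),
                         psf_fwhm = 0.6, noise_sd = 10))
  } else {
    list(hrpqct = list(name = "hrpqct"), ct_medium = list(name = "ct_medium"),
         ct_sharp = list(name = "ct_sharp"))
  }
  cfg <- list(
    seed = as.integer(seed),
    n_cases = as.integer(n_cases),
    out_dir = out_dir,
    profiles = profiles,
    phantom = list(condyle_radii = c(8, 8), condyle_offset = 4.5,
                   shaft_radius = 6, epiphysis_height = 10, shaft_length = 4,
                   cortical_thickness = if (small) 0.8 else 0.6,
                   cortical_density = 1100, soft_tissue_density = 30,
                   margin = if (small) 2.5 else 1.5, resolution = res),
    interior = list(trab_thickness = if (small) 0.25 else 0.15,
                    trab_separation = if (small) 1.2 else 0.8,
                    plate_fraction = 0.5, bone_density = 1000,
                    marrow_density = 30, jitter = 0.25),
    # simulated device responses: the CT maps attenuation linearly to density
    # through its in-scan rod phantom; the HR device applies an internal
    # calibration whose slightly different phantom material biases its BMD
    # scale (the source of the systematic cross-device difference)
    devices = list(ct = list(att_slope = 0.625, att_intercept = 10),
                   hr = list(bias_slope = 0.75, bias_intercept = 32)),
    misalignment = list(rotation_deg = c(2, -3, 4), translation = c(1.5, -1, 2)),
    segmentation = list(threshold = 300,
                        closing_radius = if (small) 0.8 else 0.5),
    voi = list(cortical_thickness = if (small) 1.0 else 0.8),
    registration = list(levels = c(4, 2, 1), n_points = 15000, maxit = 400),
    texture = list(entropy_bin_width = 25, entropy_range = c(-100, 1500),
                   local_radius = 1, aniso_radius = 1, variogram_lags = 1:4,
                   min_voxels = 27),
    stats = list(pct_err_reference = "hrpqct")
  )
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Schema and invariant checks with actionable messages. Violations of hard
#' invariants (negative noise, unknown profile, thickness >= separation, a
#' missing seed) are errors; deviations from the stated acquisition world
#' (e.g. an HR-pQCT/CT noise ratio other than 5) are reported as warnings.
#'
#' @param cfg a config list from [default_run_config()] (possibly edited).
#' @return list with `valid` (logical), `errors` and `warnings` (character
#'   vectors).
#' @export
validate_config <- function(cfg) {
  errors <- character()
  warnings <- character()
  req <- c("seed", "n_cases", "profiles", "phantom", "interior", "segmentation",
           "voi", "registration", "texture")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    errors <- c(errors, paste("missing config sections:", paste(miss, collapse = ", ")))
  if ("seed" %in% names(cfg) &&
      (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed)))
    errors <- c(errors, "seed must be a single integer")
  if ("profiles" %in% names(cfg)) {
    need <- c("hrpqct", "ct_medium", "ct_sharp")
    miss <- setdiff(need, names(cfg$profiles))
    if (length(miss))
      errors <- c(errors, paste("missing imaging profiles:", paste(miss, collapse = ", ")))
    for (nm in names(cfg$profiles)) {
      p <- cfg$profiles[[nm]]
      if (!is.null(p$name) &&
          !p$name %in% c("hrpqct", "ct_medium", "ct_sharp", "custom"))
        errors <- c(errors, paste0("unknown profile name '", p$name, "' in ", nm))
      if (!is.null(p$noise_sd) && p$noise_sd < 0)
        errors <- c(errors, paste0("negative noise_sd in profile ", nm))
      if (!is.null(p$spacing) && any(p$spacing <= 0))
        errors <- c(errors, paste0("non-positive spacing in profile ", nm))
      if (!is.null(p$psf_fwhm) && p$psf_fwhm < 0)
        errors <- c(errors, paste0("negative psf_fwhm in profile ", nm))
    }
    noise_of <- function(nm) {
      p <- cfg$profiles[[nm]]
      if (is.null(p)) return(NA_real_)
      tryCatch(do.call(imaging_profile, p)$noise_sd, error = function(e) NA_real_)
    }
    nh <- noise_of("hrpqct")
    nc <- noise_of("ct_medium")
    if (is.finite(nh) && is.finite(nc) && nc > 0 && abs(nh / nc - 5) > 1e-6)
      warnings <- c(warnings, sprintf(
        "hrpqct/ct noise ratio is %.3g, not the stated factor 5", nh / nc))
  }
  if ("interior" %in% names(cfg)) {
    it <- cfg$interior
    if (!is.null(it$trab_thickness) && !is.null(it$trab_separation) &&
        it$trab_thickness >= it$trab_separation)
      errors <- c(errors, "trabecular thickness must be below the separation")
    chk <- tryCatch({do.call(trabecular_params, c(it, list(seed = 1L))); NULL},
                    error = function(e) conditionMessage(e))
    if (!is.null(chk)) errors <- c(errors, paste("interior:", chk))
  }
  if ("segmentation" %in% names(cfg) && !is.null(cfg$segmentation$threshold) &&
      !is.finite(cfg$segmentation$threshold))
    errors <- c(errors, "segmentation threshold must be finite")
  list(valid = length(errors) == 0L, errors = errors, warnings = warnings)
}

#' Serialize a run configuration to JSON
#' @param cfg a run config list.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path file written by [write_config()].
#' @return run config list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(cfg) <- "run_config"
  cfg
}

# Build imaging_profile objects from the config's plain lists.
config_profiles <- function(cfg) lapply(cfg$profiles, function(p)
  do.call(imaging_profile, p))

# Simulate one bone of one case at all three profiles with device responses,
# calibrate, segment, place VOIs, register, transfer, and measure. Returns a
# list with texture records and stage diagnostics.
analyze_bone_case <- function(cfg, case, bone, profs) {
  seed0 <- cfg$seed + 101L * case + 7L * (bone == "tibia")
  interior <- do.call(trabecular_params,
                      c(cfg$interior, list(seed = seed0)))
  spec <- do.call(knee_phantom_spec,
                  c(list(bone = bone, interior = interior, seed = seed0),
                    cfg$phantom))
  ph <- generate_knee_phantom(spec)
  dev <- cfg$devices
  # clinical CT: attenuation response, then in-scan rod calibration back to BMD
  att <- volume3d(dev$ct$att_slope * ph$truth$values + dev$ct$att_intercept,
                  ph$truth$spacing, ph$truth$origin, unit_tag = "attenuation")
  rods <- make_rod_phantom(spacing = rep(cfg$phantom$resolution, 3L))
  rod_att <- volume3d(dev$ct$att_slope * rods$volume$values + dev$ct$att_intercept,
                      rods$volume$spacing, rods$volume$origin,
                      unit_tag = "attenuation")
  ct_med_att <- simulate_imaging(att, profs$ct_medium, seed = seed0 + 1L)
  ct_shp_att <- simulate_imaging(att, profs$ct_sharp, seed = seed0 + 2L)
  rod_img <- simulate_imaging(rod_att, imaging_profile(
    "custom", spacing = profs$ct_medium$spacing, psf_fwhm = profs$ct_medium$psf_fwhm,
    noise_sd = profs$ct_medium$noise_sd * abs(dev$ct$att_slope)), seed = seed0 + 3L)
  rois <- lapply(rods$rois, function(r)
    phantom_roi(transfer_vois(voi_set(list(rod.S1.medial = r$mask)),
                              rigid_transform(), rod_img)[[1]], r$known_density))
  cal_ct <- fit_phantom_calibration(rois, rod_img)
  ct_med <- apply_calibration(ct_med_att, cal_ct)
  ct_med$kernel_tag <- "medium"
  ct_shp <- apply_calibration(ct_shp_att, cal_ct)
  ct_shp$kernel_tag <- "sharp"
  # HR-pQCT: internal calibration with a slightly different phantom material
  hr_truth <- volume3d(dev$hr$bias_slope * ph$truth$values + dev$hr$bias_intercept,
                       ph$truth$spacing, ph$truth$origin, unit_tag = "bmd")
  hr_img <- simulate_imaging(hr_truth, profs$hrpqct, seed = seed0 + 4L)
  # fabricate the repositioning between the two acquisitions
  mis <- rigid_transform(rotation = cfg$misalignment$rotation_deg * pi / 180,
                         translation = cfg$misalignment$translation,
                         center = hr_img$origin +
                           (dim(hr_img$values) - 1) * hr_img$spacing / 2)
  hr_img <- apply_rigid_transform(hr_img, mis, background = cfg$phantom$soft_tissue_density)
  seg_ct <- segment_periosteal(ct_med, cfg$segmentation$threshold,
                               cfg$segmentation$closing_radius)
  seg_hr <- segment_periosteal(hr_img, cfg$segmentation$threshold,
                               cfg$segmentation$closing_radius)
  vois_ct <- define_vois(seg_ct, ph$geometry$shaft_axis, ph$geometry$growth_plate,
                         cfg$voi$cortical_thickness, ph$geometry$side_plane,
                         bone = bone)
  reg <- register_rigid(seg_hr, seg_ct, levels = cfg$registration$levels,
                        n_points = cfg$registration$n_points,
                        maxit = cfg$registration$maxit)
  vois_hr <- transfer_vois(vois_ct, reg, hr_img)
  seg_ct_on_hr <- transfer_vois(voi_set(list(femur.cortical.medial = seg_ct)),
                                reg, hr_img)[[1]]
  dice <- dice_ratio(seg_hr, seg_ct_on_hr)
  tset <- do.call(texture_settings, cfg$texture)
  res_ct <- compute_all(ct_shp, vois_ct, tset, v_bmd = ct_med, modality = "ct")
  res_hr <- compute_all(hr_img, vois_hr, tset, modality = "hrpqct")
  res <- rbind(res_ct, res_hr)
  res$case <- case
  res$bone <- bone
  list(results = res, dice = dice, registration = reg, calibration_ct = cal_ct)
}

#' Run the end-to-end simulation experiment
#'
#' For every simulated case and bone: ground-truth phantom, acquisition at
#' the three profiles with device-specific calibration responses, in-scan
#' phantom calibration of the CT data, independent periosteal segmentation in
#' both modalities, automatic VOI placement on the CT grid, rigid surface
#' registration, VOI transfer to the HR grid, BMD (medium kernel) and
#' texture (sharp kernel) measurement in both modalities, followed by the
#' cross-device BMD correction, regression/Bland-Altman comparison and the
#' resolution-dependence D summary. Stage failures are logged per case and
#' bone; the run continues with the remaining cases and fails only if every
#' case fails.
#'
#' @param cfg a validated config ([default_run_config()]).
#' @return the output directory, invisibly. Writes `results.csv`,
#'   `comparison.json`, `d_summary.csv`, `dice.csv`, `config.json` and
#'   `manifest.json` there; the collected tables are also attached as
#'   attributes `"results"`, `"comparison"`, `"d_summary"`, `"dice"`.
#' @export
run_experiment <- function(cfg) {
  rep_ <- validate_config(cfg)
  if (!rep_$valid)
    stop("invalid config: ", paste(rep_$errors, collapse = "; "), call. = FALSE)
  profs <- config_profiles(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  all_res <- list()
  dice_rows <- list()
  log <- character()
  for (case in seq_len(cfg$n_cases)) {
    for (bone in c("femur", "tibia")) {
      out <- tryCatch(analyze_bone_case(cfg, case, bone, profs),
                      error = function(e) e)
      if (inherits(out, "error")) {
        log <- c(log, sprintf("case %d %s FAILED: %s", case, bone,
                              conditionMessage(out)))
        next
      }
      log <- c(log, sprintf("case %d %s ok (dice %.4f)", case, bone, out$dice))
      all_res[[length(all_res) + 1L]] <- out$results
      dice_rows[[length(dice_rows) + 1L]] <-
        data.frame(case = case, bone = bone, dice = out$dice)
    }
  }
  if (!length(all_res))
    stop("all cases failed:\n", paste(log, collapse = "\n"), call. = FALSE)
  res <- do.call(rbind, all_res)
  dice_df <- do.call(rbind, dice_rows)
  comparison <- compare_modalities(res, pct_err_reference = cfg$stats$pct_err_reference)
  utils::write.csv(res, file.path(cfg$out_dir, "results.csv"), row.names = FALSE)
  utils::write.csv(dice_df, file.path(cfg$out_dir, "dice.csv"), row.names = FALSE)
  utils::write.csv(comparison$d_summary, file.path(cfg$out_dir, "d_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(comparison[c("regression", "bland_altman", "correction")],
                       file.path(cfg$out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  write_config(cfg, file.path(cfg$out_dir, "config.json"))
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("trabtex")),
         seed = cfg$seed, n_cases = cfg$n_cases, log = log,
         config_hash = unname(tools::md5sum(file.path(cfg$out_dir, "config.json")))),
    file.path(cfg$out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  out_dir <- cfg$out_dir
  attr(out_dir, "results") <- res
  attr(out_dir, "comparison") <- comparison
  attr(out_dir, "d_summary") <- comparison$d_summary
  attr(out_dir, "dice") <- dice_df
  invisible(out_dir)
}

#' Cross-modality comparison of a results table
#'
#' Fits the cross-device BMD correction on the trabecular VOI pairs (cortical
#' VOIs are excluded from the correction by convention), applies it to the CT
#' BMD values, and produces per-parameter regression, Bland-Altman (on
#' corrected BMD) and the two-stage D summary for the texture parameters.
#'
#' @param res results data.frame from [compute_all()] rows with added `case`
#'   column and `modality` in `c("ct", "hrpqct")`.
#' @param pct_err_reference `"hrpqct"` (default) or `"mean"`.
#' @return list with `correction` ([calibration_model()] coefficients),
#'   `regression` (per parameter), `bland_altman` (corrected BMD),
#'   `d_summary` (texture parameters, trabecular VOIs only).
#' @export
compare_modalities <- function(res, pct_err_reference = "hrpqct") {
  pars <- c("bmd_mean", "entropy", "global_inhomogeneity", "local_inhomogeneity",
            "anisotropy", "variogram_slope")
  key <- c("case", "voi_name")
  ct <- res[res$modality == "ct", c(key, pars)]
  hr <- res[res$modality == "hrpqct", c(key, pars)]
  mg <- merge(ct, hr, by = key, suffixes = c("_ct", "_hr"))
  if (!nrow(mg)) stop("no paired CT/HR-pQCT records", call. = FALSE)
  layer <- parse_voi_name(mg$voi_name)$layer
  trab <- layer != "cortical"
  corr <- fit_cross_device_correction(
    data.frame(bmd_ct = mg$bmd_mean_ct[trab], bmd_hrpqct = mg$bmd_mean_hr[trab]))
  bmd_ct_corr <- corr$slope * mg$bmd_mean_ct + corr$intercept
  regression <- lapply(stats::setNames(pars, pars), function(p) {
    x <- mg[[paste0(p, "_ct")]]
    y <- mg[[paste0(p, "_hr")]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]
    y <- y[ok]
    if (length(x) >= 3 && stats::var(x) > 0) unclass(linear_regression(x, y))
    else NULL
  })
  ref <- if (identical(pct_err_reference, "hrpqct")) mean(mg$bmd_mean_hr[trab])
  else mean(c(mg$bmd_mean_hr[trab], bmd_ct_corr[trab]))
  ba <- unclass(bland_altman(bmd_ct_corr[trab], mg$bmd_mean_hr[trab], ref))
  ba$within_loa <- all(ba$within_loa)
  dd <- do.call(rbind, lapply(setdiff(pars, "bmd_mean"), function(p) {
    ok <- trab & is.finite(mg[[paste0(p, "_ct")]]) &
      is.finite(mg[[paste0(p, "_hr")]]) & mg[[paste0(p, "_ct")]] != 0
    cbind(resolution_dependence(mg[[paste0(p, "_hr")]][ok],
                                mg[[paste0(p, "_ct")]][ok],
                                parameter = p, voi_name = mg$voi_name[ok]),
          case = mg$case[ok])
  }))
  list(correction = unclass(corr), regression = regression, bland_altman = ba,
       d_summary = d_summary(dd))
}
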