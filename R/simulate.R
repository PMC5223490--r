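# Run code with a local, restorable RNG state. All stochastic operations in
# the package route through this so a run is reproducible from its seeds.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Parameters of the digital trabecular-bone lattice
#'
#' The digital structure is a jittered orthogonal rod lattice with optional
#' plate insertions: square-section rods of width `trab_thickness` run along
#' all three axes on a cubic grid of pitch `trab_separation`; per cell, the
#' whole rod junction is displaced by one uniform random offset (so adjacent
#' rod segments stagger at cell boundaries), and a fraction `plate_fraction`
#' of cells carries a solid transverse plate of the same thickness centered
#' on the junction. Because the displacement moves each cell's geometry as a
#' unit, the bone volume per cell is independent of the jitter draw and the
#' volume fraction tracks the parameters exactly. Voxels take `bone_density` or `marrow_density` (mg/cm^3).
#' Defaults are typical human trabecular dimensions (thickness ~0.15 mm,
#' separation ~0.8 mm) with mineralized-tissue density 1000 mg/cm^3 over a
#' 30 mg/cm^3 marrow background.
#'
#' @param trab_thickness rod/plate thickness, mm.
#' @param trab_separation lattice pitch, mm; must exceed the thickness.
#' @param plate_fraction fraction of cells bearing a plate, in `[0,1]`.
#' @param bone_density,marrow_density tissue densities, mg/cm^3.
#' @param jitter rod-center displacement as a fraction of the separation,
#'   in `[0, 0.5]`.
#' @param heterogeneity fractional standard deviation of the large-scale
#'   modulation of the bone-tissue density (0 disables it and yields a pure
#'   two-valued lattice). Trabecular bone is not homogeneous at the
#'   millimeter scale — mineralization and remodeling vary regionally — and
#'   this low-frequency component is what survives clinical-CT blurring.
#' @param heterogeneity_scale correlation length of that modulation, mm.
#' @param seed integer seed for the jitter, plate and heterogeneity draws.
#' @return object of class `trabecular_params`.
#' @export
trabecular_params <- function(trab_thickness = 0.15, trab_separation = 0.8,
                              plate_fraction = 0.5, bone_density = 1000,
                              marrow_density = 30, jitter = 0.25,
                              heterogeneity = 0.25, heterogeneity_scale = 2,
                              seed = 1L) {
  if (trab_thickness <= 0 || trab_separation <= 0)
    stop("thickness and separation must be positive", call. = FALSE)
  if (trab_thickness >= trab_separation)
    stop("trabecular thickness must be smaller than the separation", call. = FALSE)
  if (bone_density <= marrow_density)
    stop("bone density must exceed marrow density", call. = FALSE)
  if (jitter < 0 || jitter > 0.5) stop("jitter must be in [0, 0.5]", call. = FALSE)
  if (plate_fraction < 0 || plate_fraction > 1)
    stop("plate_fraction must be in [0, 1]", call. = FALSE)
  if (heterogeneity < 0 || heterogeneity_scale <= 0)
    stop("heterogeneity must be >= 0 with a positive correlation length",
         call. = FALSE)
  structure(list(trab_thickness = trab_thickness, trab_separation = trab_separation,
                 plate_fraction = plate_fraction, bone_density = bone_density,
                 marrow_density = marrow_density, jitter = jitter,
                 heterogeneity = heterogeneity,
                 heterogeneity_scale = heterogeneity_scale,
                 seed = as.integer(seed)),
            class = "trabecular_params")
}

#' Bone volume fraction of the unjittered rod lattice
#'
#' Closed form for three orthogonal square rods of width t on a cubic grid of
#' pitch s (inclusion-exclusion over the three rod families):
#' `vf = 3 r^2 - 2 r^3` with `r = t / s`. Used as the analytic reference for
#' the generator.
#'
#' @param trab_thickness,trab_separation mm.
#' @return fraction in `[0, 1]`.
#' @export
lattice_fraction <- function(trab_thickness, trab_separation) {
  r <- trab_thickness / trab_separation
  3 * r^2 - 2 * r^3
}

#' Generate a digital trabecular-bone volume
#'
#' High-resolution two-valued ground-truth volume of the lattice described by
#' [trabecular_params()]. The default 0.02 mm isotropic grid is the micro-CT
#' scale; coarser grids may be used for desk-scale runs as long as they stay
#' finer than the simulated scanner voxels.
#'
#' @param p a [trabecular_params()].
#' @param extent physical size, mm (scalar or length-3); must cover at least
#'   five lattice periods per axis.
#' @param resolution isotropic voxel size of the ground truth, mm.
#' @return a [volume3d()] in calibrated units (`unit_tag = "bmd"`), with the
#'   generating parameters attached as attribute `"params"`.
#' @export
generate_trabecular_model <- function(p, extent = 4, resolution = 0.02) {
  stopifnot(inherits(p, "trabecular_params"))
  extent <- as.numeric(extent)
  if (length(extent) == 1L) extent <- rep(extent, 3L)
  if (any(extent < 5 * p$trab_separation))
    stop("extent must cover at least 5 lattice periods per axis", call. = FALSE)
  d <- pmax(1L, as.integer(round(extent / resolution)))
  s <- p$trab_separation
  th <- p$trab_thickness / 2
  nc <- as.integer(ceiling(extent / s)) + 1L
  draws <- with_seed(p$seed, {
    J <- array(runif(prod(nc) * 4L), dim = c(nc, 4L))
    nh <- as.integer(ceiling(extent / p$heterogeneity_scale)) + 2L
    list(J = J, H = array(stats::rnorm(prod(nh)), dim = nh))
  })
  J <- draws$J
  # layers 1-3: junction displacement in [-jitter, jitter] * separation;
  # layer 4 keeps U(0,1) for the plate selection
  for (l in 1:3) J[, , , l] <- (J[, , , l] * 2 - 1) * p$jitter * s
  # large-scale density modulation: coarse Gaussian field, trilinearly
  # interpolated onto the lattice grid
  hmod <- NULL
  if (p$heterogeneity > 0) {
    H <- draws$H
    hs <- p$heterogeneity_scale
    hmod <- array(cpp_resample_affine(as.double(H), dim(H), rep(hs, 3L),
                                      rep(-hs / 2, 3L), d, rep(resolution, 3L),
                                      rep(resolution / 2, 3L),
                                      cbind(diag(3), c(0, 0, 0)), TRUE, 0),
                  dim = d)
    hmod <- 1 + p$heterogeneity * hmod
  }
  coords <- function(n) (seq_len(n) - 0.5) * resolution
  xs <- coords(d[1]); ys <- coords(d[2]); zs <- coords(d[3])
  cell <- function(pos, nmax) pmin(as.integer(pos %/% s) + 1L, nmax)
  cx <- cell(xs, nc[1]); cy <- cell(ys, nc[2]); cz <- cell(zs, nc[3])
  fx <- xs - (cx - 1L) * s; fy <- ys - (cy - 1L) * s; fz <- zs - (cz - 1L) * s
  FX <- matrix(fx, d[1], d[2])
  FY <- matrix(fy, d[1], d[2], byrow = TRUE)
  base_idx <- outer(cx, (cy - 1L) * nc[1], "+")   # cell index within one z-layer
  ncc <- nc[1] * nc[2]
  lay <- function(l) (l - 1L) * prod(nc)
  vals <- array(p$marrow_density, dim = d)
  half <- s / 2
  plate_thr <- -1
  if (p$plate_fraction > 0) {
    # rank only over the cells the volume actually samples, so the realized
    # plate fraction does not drift with unused margin cells
    nu <- pmin(as.integer(ceiling(extent / s)), nc)
    u_all <- sort(as.vector(J[seq_len(nu[1]), seq_len(nu[2]), seq_len(nu[3]), 4L]))
    plate_thr <- u_all[max(1L, round(p$plate_fraction * length(u_all)))]
  }
  for (k in seq_len(d[3])) {
    idx <- base_idx + (cz[k] - 1L) * ncc
    dx <- FX - (half + J[idx + lay(1L)])
    dy <- FY - (half + J[idx + lay(2L)])
    dz <- fz[k] - (half + J[idx + lay(3L)])
    bone <-
      (abs(dy) < th & abs(dz) < th) |   # x-rods
      (abs(dx) < th & abs(dz) < th) |   # y-rods
      (abs(dx) < th & abs(dy) < th)     # z-rods
    if (p$plate_fraction > 0) {
      # rank-based threshold: exactly round(fraction * n_cells) cells carry a
      # plate, so the plate count is free of binomial placement noise
      bone <- bone | (J[idx + lay(4L)] <= plate_thr & abs(dz) < th)
    }
    slab <- vals[, , k]
    if (is.null(hmod)) {
      slab[bone] <- p$bone_density
    } else {
      bd <- pmax(p$bone_density * hmod[, , k], p$marrow_density)
      slab[bone] <- bd[bone]
    }
    vals[, , k] <- slab
  }
  v <- volume3d(vals, spacing = rep(resolution, 3L),
                origin = rep(resolution / 2, 3L), unit_tag = "bmd")
  attr(v, "params") <- p
  v
}

#' Generate a suite of trabecular structures along a progression sweep
#'
#' Produces `n` structures whose parameters interpolate linearly between the
#' endpoints of each sweep range. The default sweep co-varies thickness
#' (0.10 to 0.22 mm) and separation (1.1 to 1.4 mm) upwards — the direction
#' of the trabecular modifications reported with osteoarthritis progression
#' (thickened, more widely spaced subchondral trabeculae), at dimensions
#' typical of elderly donors — which makes the bone volume fraction increase
#' monotonically along the suite.
#'
#' @param n number of structures (>= 2).
#' @param sweep named list of length-2 ranges for any of the
#'   [trabecular_params()] fields `trab_thickness`, `trab_separation`,
#'   `plate_fraction`, `bone_density`, `marrow_density`, `jitter`.
#' @param extent physical size, mm; `NULL` (default) sizes each model to five
#'   lattice periods of its own separation.
#' @param resolution forwarded to [generate_trabecular_model()].
#' @param seed base seed; model i uses `seed + i - 1`.
#' @param base a [trabecular_params()] supplying non-swept fields.
#' @return list of [volume3d()] ground truths, each with its
#'   `trabecular_params` attached as attribute `"params"`.
#' @export
generate_model_suite <- function(n = 40,
                                 sweep = list(trab_thickness = c(0.10, 0.22),
                                              trab_separation = c(1.10, 1.40)),
                                 extent = NULL, resolution = 0.02, seed = 1L,
                                 base = trabecular_params()) {
  params <- suite_params(n, sweep, seed = seed, base = base)
  lapply(params, function(p)
    generate_trabecular_model(p, extent = extent %||% (5 * p$trab_separation),
                              resolution = resolution))
}

#' Parameter sets of a model-suite sweep
#'
#' The parameter interpolation behind [generate_model_suite()], exposed so
#' large suites can be generated (and discarded) one model at a time instead
#' of being held in memory together.
#'
#' @inheritParams generate_model_suite
#' @return list of `n` [trabecular_params()] objects.
#' @export
suite_params <- function(n = 40,
                         sweep = list(trab_thickness = c(0.10, 0.22),
                                      trab_separation = c(1.10, 1.40)),
                         seed = 1L, base = trabecular_params()) {
  if (n < 2L) stop("a suite needs n >= 2 structures", call. = FALSE)
  if (!length(sweep)) stop("empty sweep ranges", call. = FALSE)
  ok <- c("trab_thickness", "trab_separation", "plate_fraction", "bone_density",
          "marrow_density", "jitter", "heterogeneity", "heterogeneity_scale")
  if (!all(names(sweep) %in% ok))
    stop("unknown sweep fields: ",
         paste(setdiff(names(sweep), ok), collapse = ", "), call. = FALSE)
  if (any(vapply(sweep, length, integer(1)) != 2L))
    stop("each sweep range needs exactly two endpoints", call. = FALSE)
  alpha <- seq(0, 1, length.out = n)
  lapply(seq_len(n), function(i) {
    p <- unclass(base)
    for (f in names(sweep))
      p[[f]] <- sweep[[f]][1] * (1 - alpha[i]) + sweep[[f]][2] * alpha[i]
    p$seed <- as.integer(seed + i - 1L)
    do.call(trabecular_params, p)
  })
}

#' Imaging profile of a simulated scanner
#'
#' Presets reproduce the study geometries: `"hrpqct"` has isotropic 0.082 mm
#' voxels; the clinical-CT presets have 0.25 mm in-plane pixels with 0.3 mm
#' slice increment. The point-spread function is an isotropic Gaussian; the
#' sharp-kernel CT preset uses a narrower PSF than the medium one. Preset
#' noise keeps the ratio noise(HR-pQCT)/noise(CT) = 5 reported for these
#' protocols (50 vs 10 mg/cm^3).
#'
#' @param name `"hrpqct"`, `"ct_medium"`, `"ct_sharp"` or `"custom"`.
#' @param spacing voxel spacing, mm (required for `"custom"`).
#' @param psf_fwhm Gaussian PSF full width at half maximum, mm.
#' @param noise_sd additive Gaussian noise SD in calibrated units, mg/cm^3.
#' @param calibration optional [calibration_model()] describing the simulated
#'   device mapping from attenuation to density.
#' @return object of class `imaging_profile`.
#' @export
imaging_profile <- function(name = c("hrpqct", "ct_medium", "ct_sharp", "custom"),
                            spacing = NULL, psf_fwhm = NULL, noise_sd = NULL,
                            calibration = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
                   hrpqct = list(spacing = c(0.082, 0.082, 0.082),
                                 psf_fwhm = 0.13, noise_sd = 50),
                   ct_medium = list(spacing = c(0.25, 0.25, 0.3),
                                    psf_fwhm = 0.45, noise_sd = 10),
                   ct_sharp = list(spacing = c(0.25, 0.25, 0.3),
                                   psf_fwhm = 0.30, noise_sd = 10),
                   custom = list(spacing = NULL, psf_fwhm = 0, noise_sd = 0))
  spacing <- spacing %||% preset$spacing
  psf_fwhm <- psf_fwhm %||% preset$psf_fwhm
  noise_sd <- noise_sd %||% preset$noise_sd
  if (is.null(spacing)) stop("custom profiles need an explicit spacing", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0) || psf_fwhm < 0 || noise_sd < 0)
    stop("spacing must be positive; psf_fwhm and noise_sd non-negative",
         call. = FALSE)
  structure(list(name = name, spacing = spacing, psf_fwhm = psf_fwhm,
                 noise_sd = noise_sd, calibration = calibration),
            class = "imaging_profile")
}

#' @export
print.imaging_profile <- function(x, ...) {
  cat(sprintf("<imaging_profile> %s: spacing %s mm, PSF FWHM %.3g mm, noise SD %.3g\n",
              x$name, paste(x$spacing, collapse = "x"), x$psf_fwhm, x$noise_sd))
  invisible(x)
}

#' Simulate the acquisition of a ground-truth volume
#'
#' Imaging chain: Gaussian PSF blur (`psf_fwhm`), partial-volume box-average
#' resampling onto the profile grid (every ground-truth voxel contributes to
#' the scanner voxels it intersects in proportion to the shared volume, so
#' mass is conserved), then additive Gaussian noise of marginal SD
#' `noise_sd`. The noise field carries the reconstruction kernel's spatial
#' correlation: white noise is smoothed with the profile PSF (at the output
#' grid) and rescaled to the requested SD, as reconstructed CT noise is
#' correlated over the kernel scale. With `psf_fwhm = 0` the noise is white.
#' With a profile at the truth's own spacing, zero PSF and zero noise the
#' chain is the identity.
#'
#' @param truth a [volume3d()] whose spacing is at least as fine as the
#'   profile's on every axis.
#' @param prof an [imaging_profile()].
#' @param seed integer seed for the noise draw (required when `noise_sd > 0`).
#' @return a [volume3d()] on the profile grid; `unit_tag` inherited from the
#'   truth, `kernel_tag` from the profile name.
#' @export
simulate_imaging <- function(truth, prof, seed = NULL) {
  stopifnot(is_volume3d(truth), inherits(prof, "imaging_profile"))
  if (any(truth$spacing > prof$spacing + 1e-9))
    stop("profile spacing must be at least as coarse as the truth spacing",
         call. = FALSE)
  vals <- as.double(truth$values)
  d <- dim(truth$values)
  if (prof$psf_fwhm > 0) {
    kernels <- lapply(1:3, function(a) gauss_kernel(prof$psf_fwhm, truth$spacing[a]))
    if (any(vapply(kernels, length, integer(1)) > 1L))
      vals <- cpp_conv_sep(vals, d, kernels)
  }
  g <- output_grid(truth, prof$spacing)
  out <- box_average(array(vals, dim = d), truth$spacing, truth$origin, g)
  if (prof$noise_sd > 0) {
    if (is.null(seed))
      stop("noise_sd > 0 requires an explicit seed", call. = FALSE)
    noise <- with_seed(seed, stats::rnorm(prod(g$dim)))
    if (prof$psf_fwhm > 0) {
      nk <- lapply(1:3, function(a) gauss_kernel(prof$psf_fwhm, g$spacing[a]))
      if (any(vapply(nk, length, integer(1)) > 1L)) {
        noise <- cpp_conv_sep(noise, g$dim, nk)
        # blurring shrinks the marginal SD by prod_a ||w_a||_2; restore it
        atten <- prod(vapply(nk, function(w) sqrt(sum(w^2)), numeric(1)))
        noise <- noise / atten
      }
    }
    out <- out + array(noise * prof$noise_sd, dim = g$dim)
  }
  volume3d(out, spacing = g$spacing, origin = g$origin, unit_tag = truth$unit_tag,
           kernel_tag = switch(prof$name, ct_medium = "medium",
                               ct_sharp = "sharp", "native"))
}

# 1D fractional-overlap weights mapping n_in fine voxels onto n_out coarse
# voxels: W[o, i] is the length of overlap between fine voxel i and coarse
# voxel o, normalized per output row. Every fine voxel contributes to the
# coarse voxels it intersects in proportion to the shared length, which is
# the separable form of exact volume-weighted (partial-volume) averaging.
box_weights <- function(n_in, sp_in, o_in, n_out, sp_out, o_out) {
  a <- o_in - sp_in / 2 + (seq_len(n_in) - 1) * sp_in
  lo <- o_out - sp_out / 2 + (seq_len(n_out) - 1) * sp_out
  ov <- pmin(outer(lo + sp_out, a + sp_in, pmin) - outer(lo, a, pmax), sp_in)
  ov[ov < 0] <- 0
  ov / pmax(rowSums(ov), .Machine$double.xmin)
}

# Volume-weighted box averaging of a fine 3D array onto the coarse grid `g`,
# applied separably along the three axes.
box_average <- function(arr, spacing, origin, g) {
  d <- dim(arr)
  W1 <- box_weights(d[1], spacing[1], origin[1], g$dim[1], g$spacing[1], g$origin[1])
  W2 <- box_weights(d[2], spacing[2], origin[2], g$dim[2], g$spacing[2], g$origin[2])
  W3 <- box_weights(d[3], spacing[3], origin[3], g$dim[3], g$spacing[3], g$origin[3])
  a1 <- array(W1 %*% matrix(arr, d[1], d[2] * d[3]), dim = c(g$dim[1], d[2], d[3]))
  a2 <- aperm(array(W2 %*% matrix(aperm(a1, c(2, 1, 3)), d[2], g$dim[1] * d[3]),
                    dim = c(g$dim[2], g$dim[1], d[3])), c(2, 1, 3))
  array(matrix(a2, g$dim[1] * g$dim[2], d[3]) %*% t(W3), dim = g$dim)
}

# Normalized 1D Gaussian kernel for a PSF of the given FWHM, sampled at the
# voxel pitch and truncated at 3 sigma.
gauss_kernel <- function(fwhm, spacing) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  sv <- sigma / spacing
  if (sv < 0.2) return(1)
  r <- max(1L, as.integer(ceiling(3 * sv)))
  w <- exp(-0.5 * ((-r:r) / sv)^2)
  w / sum(w)
}
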