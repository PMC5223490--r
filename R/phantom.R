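#' Specification of a synthetic knee-bone phantom
#'
#' Describes one distal-femur-like or proximal-tibia-like body: two condylar
#' spheres merged with a shaft cylinder, a dense cortical shell of stated
#' thickness, a trabecular interior generated from [trabecular_params()], and
#' a soft-tissue background. The geometry needed for automatic VOI placement
#' (shaft axis, planar growth-plate approximation, medial/lateral split
#' plane) is part of the construction and is returned with the phantom.
#' Default dimensions are a desk-scale miniature (condyles of 8 mm radius)
#' rather than an anatomically sized knee.
#'
#' @param bone `"femur"` (articular surface at low z, shaft axis +z) or
#'   `"tibia"` (mirrored in z, shaft axis -z).
#' @param condyle_radii radii of the medial and lateral condylar spheres, mm.
#' @param condyle_offset half-distance between the condyle centers along the
#'   medial-lateral (x) axis, mm.
#' @param shaft_radius radius of the shaft cylinder, mm.
#' @param epiphysis_height distance from the articular surface to the
#'   growth-plate plane, mm.
#' @param shaft_length shaft extent beyond the growth plate, mm.
#' @param cortical_thickness cortical shell thickness, mm; must be at least
#'   one ground-truth voxel.
#' @param cortical_density,soft_tissue_density mg/cm^3.
#' @param interior a [trabecular_params()] for the trabecular compartment.
#' @param margin soft-tissue border around the bone, mm.
#' @param resolution ground-truth voxel size, mm (isotropic).
#' @param seed integer seed (forwarded to the interior lattice).
#' @return object of class `knee_phantom_spec`.
#' @export
knee_phantom_spec <- function(bone = c("femur", "tibia"),
                              condyle_radii = c(8, 8), condyle_offset = 4.5,
                              shaft_radius = 6, epiphysis_height = 10,
                              shaft_length = 6, cortical_thickness = 0.6,
                              cortical_density = 1100, soft_tissue_density = 30,
                              interior = trabecular_params(),
                              margin = 1.5, resolution = 0.08, seed = 1L) {
  bone <- match.arg(bone)
  stopifnot(inherits(interior, "trabecular_params"))
  if (length(condyle_radii) != 2L || any(condyle_radii <= 0))
    stop("`condyle_radii` must be two positive radii (mm)", call. = FALSE)
  if (cortical_thickness < resolution)
    stop("cortical_thickness must be at least one ground-truth voxel",
         call. = FALSE)
  if (epiphysis_height <= 0 || epiphysis_height >= 2 * max(condyle_radii) + shaft_length)
    stop("growth-plate plane must intersect the bone body", call. = FALSE)
  structure(list(bone = bone, condyle_radii = condyle_radii,
                 condyle_offset = condyle_offset, shaft_radius = shaft_radius,
                 epiphysis_height = epiphysis_height, shaft_length = shaft_length,
                 cortical_thickness = cortical_thickness,
                 cortical_density = cortical_density,
                 soft_tissue_density = soft_tissue_density, interior = interior,
                 margin = margin, resolution = resolution, seed = as.integer(seed)),
            class = "knee_phantom_spec")
}

#' Generate a synthetic knee-bone phantom
#'
#' Builds the ground-truth density volume described by a
#' [knee_phantom_spec()], its periosteal bone mask, and the VOI-placement
#' geometry. Deterministic given the spec.
#'
#' @param spec a [knee_phantom_spec()].
#' @return list with elements `truth` ([volume3d()], `unit_tag = "bmd"`),
#'   `bone_mask` ([mask3d()]), and `geometry` (list with `shaft_axis`,
#'   `growth_plate = list(point, normal)`, `side_plane = list(point, normal)`).
#'   The shaft axis points from the joint surface toward the physis; on the
#'   side plane, negative side = medial.
#' @export
generate_knee_phantom <- function(spec) {
  stopifnot(inherits(spec, "knee_phantom_spec"))
  res <- spec$resolution
  rmax <- max(spec$condyle_radii)
  ext <- c(2 * (spec$condyle_offset + rmax) + 2 * spec$margin,
           2 * rmax + 2 * spec$margin,
           spec$epiphysis_height + spec$shaft_length + 2 * spec$margin)
  d <- as.integer(round(ext / res))
  d[1:2] <- d[1:2] + d[1:2] %% 2L   # even in-plane dims: no voxel-center
                                    # column sits exactly on the mirror planes
  ext <- d * res            # snap to the voxel grid so mirror symmetry is exact
  xs <- (seq_len(d[1]) - 0.5) * res
  ys <- (seq_len(d[2]) - 0.5) * res
  zs <- (seq_len(d[3]) - 0.5) * res
  xc <- ext[1] / 2
  yc <- ext[2] / 2
  # articular surface at z = margin (before any mirroring)
  z_art <- spec$margin
  centers_x <- xc + c(-1, 1) * spec$condyle_offset
  z_cond <- z_art + spec$condyle_radii          # per-condyle sphere centers
  z_gp <- z_art + spec$epiphysis_height
  body <- array(FALSE, dim = d)
  dx2 <- lapply(1:2, function(i) (xs - centers_x[i])^2)
  dy2 <- (ys - yc)^2
  cyl <- outer((xs - xc)^2, dy2, "+") <= spec$shaft_radius^2
  for (k in seq_len(d[3])) {
    z <- zs[k]
    sl <- matrix(FALSE, d[1], d[2])
    for (i in 1:2) {
      rz2 <- spec$condyle_radii[i]^2 - (z - z_cond[i])^2
      if (rz2 > 0) sl <- sl | (outer(dx2[[i]], dy2, "+") <= rz2)
    }
    if (z >= min(z_cond) &&
        z <= z_art + spec$epiphysis_height + spec$shaft_length)
      sl <- sl | cyl   # shaft capped below the top margin so the body is closed
    body[, , k] <- sl
  }
  # cortical shell from the Euclidean distance to the background
  interior <- body &
    array(cpp_edt_sq(as.integer(!body), d, rep(res, 3L)) >
            spec$cortical_thickness^2, dim = d)
  ip <- spec$interior
  ip$seed <- spec$seed
  ip <- do.call(trabecular_params, unclass(ip))
  trab <- generate_trabecular_model(ip, extent = ext, resolution = res)
  stopifnot(identical(dim(trab$values), d))
  vals <- array(spec$soft_tissue_density, dim = d)
  vals[body] <- spec$cortical_density
  vals[interior] <- trab$values[interior]
  rm(trab, interior)
  flip <- identical(spec$bone, "tibia")
  if (flip) {
    vals <- vals[, , rev(seq_len(d[3]))]
    body <- body[, , rev(seq_len(d[3]))]
    z_gp <- ext[3] - z_gp
  }
  truth <- volume3d(vals, spacing = rep(res, 3L), origin = rep(res / 2, 3L),
                    unit_tag = "bmd")
  geometry <- list(shaft_axis = c(0, 0, if (flip) -1 else 1),
                   growth_plate = list(point = c(xc, yc, z_gp),
                                       normal = c(0, 0, 1)),
                   side_plane = list(point = c(xc, yc, 0),
                                     normal = c(1, 0, 0)))
  list(truth = truth,
       bone_mask = mask3d(body, spacing = rep(res, 3L), origin = rep(res / 2, 3L)),
       geometry = geometry)
}
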