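#' Automatic placement of the knee analysis VOIs for one bone
#'
#' From a solid periosteal bone mask plus the placement geometry (shaft axis,
#' planar growth-plate approximation, medial/lateral split plane), builds the
#' 8 per-bone VOIs: a cortical shell of the stated thickness (Euclidean
#' erosion difference, restricted to the joint side of the growth plate) and
#' the trabecular region between articular surface and growth plate split
#' along the shaft axis into three equal-thickness slabs — S1 nearest the
#' joint, S2, S3 nearest the physis — each divided into medial and lateral
#' compartments by the side plane.
#'
#' @param bone_mask a [mask3d()] of one solid bone body.
#' @param shaft_axis unit vector pointing from the joint surface toward the
#'   physis.
#' @param growth_plate list with `point` and `normal` (mm) describing the
#'   planar growth-plate approximation.
#' @param cortical_thickness cortical shell thickness, mm.
#' @param side_plane list with `point` and `normal`; voxels on the negative
#'   side of the plane are medial.
#' @param bone `"femur"` or `"tibia"`, used for the VOI names.
#' @return a [voi_set()] with 8 entries named `bone.layer.side`.
#' @export
define_vois <- function(bone_mask, shaft_axis, growth_plate, cortical_thickness,
                        side_plane, bone = c("femur", "tibia")) {
  bone <- match.arg(bone)
  stopifnot(is_mask3d(bone_mask))
  axis <- as.numeric(shaft_axis)
  if (length(axis) != 3L || sum(axis^2) < 1e-12)
    stop("degenerate shaft axis", call. = FALSE)
  axis <- axis / sqrt(sum(axis^2))
  d <- dim(bone_mask$values)
  sel <- which(bone_mask$values != 0L)
  if (!length(sel)) stop("empty bone mask", call. = FALSE)
  idx <- arrayInd(sel, d)
  pts <- sweep(sweep(idx - 1, 2L, bone_mask$spacing, "*"), 2L, bone_mask$origin, "+")
  gp_n <- as.numeric(growth_plate$normal)
  gp_n <- gp_n / sqrt(sum(gp_n^2))
  if (sum(gp_n * axis) < 0) gp_n <- -gp_n       # orient with the shaft axis
  s_gp <- as.numeric(pts %*% gp_n) - sum(as.numeric(growth_plate$point) * gp_n)
  if (!any(s_gp < 0) || !any(s_gp > 0))
    stop("growth-plate plane does not intersect the bone body", call. = FALSE)
  interior_all <- array(sqrt(cpp_edt_sq(as.integer(bone_mask$values == 0L), d,
                                        bone_mask$spacing)),
                        dim = d)[sel] > cortical_thickness
  joint_side <- s_gp < 0
  sp_n <- as.numeric(side_plane$normal)
  sp_n <- sp_n / sqrt(sum(sp_n^2))
  s_side <- as.numeric(pts %*% sp_n) - sum(as.numeric(side_plane$point) * sp_n)
  medial <- s_side < 0
  t_ax <- as.numeric(pts %*% axis)
  trab <- interior_all & joint_side
  if (!any(trab)) stop("empty trabecular compartment", call. = FALSE)
  t_lo <- min(t_ax[trab])
  t_hi <- max(t_ax[trab])
  h <- (t_hi - t_lo) / 3
  layer_sel <- list(
    cortical = !interior_all & joint_side,
    S1 = trab & t_ax < t_lo + h,
    S2 = trab & t_ax >= t_lo + h & t_ax < t_lo + 2 * h,
    S3 = trab & t_ax >= t_lo + 2 * h)
  masks <- list()
  for (layer in names(layer_sel)) {
    for (side in c("medial", "lateral")) {
      pick <- layer_sel[[layer]] & (if (side == "medial") medial else !medial)
      if (!any(pick))
        stop(sprintf("empty VOI: %s.%s.%s", bone, layer, side), call. = FALSE)
      m <- array(0L, dim = d)
      m[sel[pick]] <- 1L
      masks[[paste(bone, layer, side, sep = ".")]] <-
        mask3d(m, spacing = bone_mask$spacing, origin = bone_mask$origin)
    }
  }
  voi_set(masks)
}

#' Transfer VOIs onto another grid through a rigid transform
#'
#' Maps every VOI mask onto the target grid with nearest-neighbor pull-back
#' through `t` (the transform returned by [register_rigid()], mapping target
#' physical coordinates into the source domain). Layer disjointness is
#' re-enforced after resampling in the order cortical, S1, S2, S3.
#'
#' @param vois a [voi_set()] on the source grid.
#' @param t a [rigid_transform()] mapping target coordinates to source
#'   coordinates; use `rigid_transform()` (identity) for plain upsizing.
#' @param target_grid a [volume3d()] or [mask3d()] defining the output grid.
#' @return a [voi_set()] on the target grid.
#' @export
transfer_vois <- function(vois, t, target_grid) {
  stopifnot(inherits(vois, "voi_set"), inherits(t, "rigid_transform"))
  tg <- target_grid
  if (!is_volume3d(tg) && !is_mask3d(tg))
    stop("`target_grid` must be a volume3d or mask3d", call. = FALSE)
  M <- transform_matrix(t)
  d <- dim(tg$values)
  out <- list()
  claimed <- array(FALSE, dim = d)
  ord <- names(vois)[order(match(parse_voi_name(names(vois))$layer,
                                 c("cortical", "S1", "S2", "S3")))]
  for (nm in ord) {
    src <- vois[[nm]]
    vals <- cpp_resample_affine(as.double(src$values), dim(src$values),
                                src$spacing, src$origin, d, tg$spacing,
                                tg$origin, M, FALSE, 0)
    m <- array(vals != 0, dim = d) & !claimed
    if (!any(m))
      stop("VOI '", nm, "' is empty after transfer", call. = FALSE)
    claimed <- claimed | m
    out[[nm]] <- mask3d(m, spacing = tg$spacing, origin = tg$origin)
  }
  voi_set(out[names(vois)])
}
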