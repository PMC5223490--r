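#' Resample a volume onto a new voxel spacing
#'
#' Point-sampling resampler (nearest-neighbor or trilinear) used e.g. to
#' upsize a clinical-CT mask onto the HR-pQCT grid before dice computation.
#' The output grid covers the physical extent of the input (including the
#' half-voxel border), so the extent is preserved to within one voxel.
#'
#' @param v a [volume3d()] or [mask3d()].
#' @param target_spacing numeric length-3, mm, strictly positive.
#' @param interp `"linear"` or `"nearest"`; masks always use nearest.
#' @return object of the same class as `v` on the new grid.
#' @export
resample_volume <- function(v, target_spacing, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  is_mask <- is_mask3d(v)
  if (!is_mask && !is_volume3d(v)) stop("`v` must be a volume3d or mask3d", call. = FALSE)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("`target_spacing` must be strictly positive (mm)", call. = FALSE)
  if (is_mask) interp <- "nearest"
  g <- output_grid(v, target_spacing)
  identity_m <- cbind(diag(3), c(0, 0, 0))
  vals <- cpp_resample_affine(as.double(v$values), dim(v$values), v$spacing,
                              v$origin, g$dim, g$spacing, g$origin, identity_m,
                              interp == "linear", 0)
  out <- array(vals, dim = g$dim)
  if (is_mask) mask3d(out, spacing = g$spacing, origin = g$origin)
  else volume3d(out, spacing = g$spacing, origin = g$origin,
                unit_tag = v$unit_tag, kernel_tag = v$kernel_tag)
}

# Output grid covering the physical extent of `v` at the given spacing.
# Same spacing reproduces the input grid exactly.
output_grid <- function(v, spacing) {
  ext <- volume_extent(v)
  len <- ext["hi", ] - ext["lo", ]
  d <- pmax(1L, as.integer(round(len / spacing)))
  list(dim = d, spacing = spacing, origin = ext["lo", ] + spacing / 2)
}

#' Move a volume or mask by a rigid transform
#'
#' The object is moved by the transform (a point `p` of the object lands at
#' `T(p)`); the result is resampled on the input grid by pulling back through
#' the inverse map. Masks use nearest-neighbor interpolation. This is the tool
#' that fabricates a known misalignment for registration experiments.
#'
#' @param v a [volume3d()] or [mask3d()].
#' @param rotation angles (radians) as in [rigid_transform()], or a
#'   `rigid_transform` object (then `translation`/`center` are ignored).
#' @param translation mm triple.
#' @param center rotation center, mm; defaults to the volume's physical center.
#' @param interp `"linear"` or `"nearest"`; masks always use nearest.
#' @param background fill value outside the input extent.
#' @return object of the same class as `v`, same grid.
#' @export
apply_rigid_transform <- function(v, rotation = c(0, 0, 0),
                                  translation = c(0, 0, 0), center = NULL,
                                  interp = c("linear", "nearest"),
                                  background = 0) {
  interp <- match.arg(interp)
  is_mask <- is_mask3d(v)
  if (!is_mask && !is_volume3d(v)) stop("`v` must be a volume3d or mask3d", call. = FALSE)
  if (inherits(rotation, "rigid_transform")) {
    t <- rotation
  } else {
    if (is.null(center)) {
      d <- dim(v$values)
      center <- v$origin + (d - 1) * v$spacing / 2
    }
    t <- rigid_transform(rotation = rotation, translation = translation,
                         center = center)
  }
  M <- transform_matrix(invert_transform(t))
  if (is_mask) interp <- "nearest"
  vals <- cpp_resample_affine(as.double(v$values), dim(v$values), v$spacing,
                              v$origin, dim(v$values), v$spacing, v$origin, M,
                              interp == "linear", background)
  out <- array(vals, dim = dim(v$values))
  if (is_mask) mask3d(out, spacing = v$spacing, origin = v$origin)
  else volume3d(out, spacing = v$spacing, origin = v$origin,
                unit_tag = v$unit_tag, kernel_tag = v$kernel_tag)
}
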