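#' 3D scalar volume with voxel geometry
#'
#' A `volume3d` bundles a 3D numeric array with its voxel geometry: per-axis
#' voxel edge lengths (`spacing`, mm), the physical position of the center of
#' voxel `(1,1,1)` (`origin`, mm), a unit tag (`"attenuation"` before density
#' calibration, `"bmd"` after), and a reconstruction-kernel tag. Voxel indices
#' are 0-based in physical terms: the center of voxel `(i+1,j+1,k+1)` (R
#' indexing) sits at `origin + c(i,j,k) * spacing`.
#'
#' @param values 3D numeric array.
#' @param spacing numeric length-3, voxel edge lengths in mm (strictly
#'   positive). Anisotropic grids (e.g. 0.25 x 0.25 x 0.3 mm clinical CT) are
#'   kept anisotropic.
#' @param origin numeric length-3, mm. Default `c(0,0,0)`.
#' @param unit_tag `"attenuation"` or `"bmd"`.
#' @param kernel_tag `"medium"`, `"sharp"` or `"native"`.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(values, spacing, origin = c(0, 0, 0),
                     unit_tag = c("attenuation", "bmd"),
                     kernel_tag = c("native", "medium", "sharp")) {
  unit_tag <- match.arg(unit_tag)
  kernel_tag <- match.arg(kernel_tag)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive voxel edge lengths (mm)",
         call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite coordinates (mm)", call. = FALSE)
  if (any(dim(values) < 1L))
    stop("all three array dimensions must be >= 1", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = spacing, origin = origin,
                 unit_tag = unit_tag, kernel_tag = kernel_tag),
            class = "volume3d")
}

#' Binary 3D mask on a volume grid
#'
#' Same grid contract as [volume3d()]: a mask indexes a volume only if shape,
#' spacing and origin agree (within tolerance for the continuous fields).
#'
#' @param values 3D array, coerced to 0/1 integer.
#' @inheritParams volume3d
#' @return An object of class `mask3d`.
#' @export
mask3d <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three strictly positive lengths (mm)", call. = FALSE)
  v <- array(as.integer(values != 0), dim = dim(values))
  structure(list(values = v, spacing = spacing, origin = origin),
            class = "mask3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels, spacing %s mm, origin %s mm [%s, %s kernel]\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ","),
              x$unit_tag, x$kernel_tag))
  invisible(x)
}

#' @export
print.mask3d <- function(x, ...) {
  cat(sprintf("<mask3d> %s voxels, spacing %s mm, |M| = %d\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$values)))
  invisible(x)
}

is_volume3d <- function(x) inherits(x, "volume3d")
is_mask3d <- function(x) inherits(x, "mask3d")

#' Check that a mask and a volume share one grid
#'
#' @param a,b `volume3d` or `mask3d` objects.
#' @param tol tolerance (mm) for spacing/origin agreement.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_same_grid <- function(a, b, tol = 1e-6) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("grid mismatch: array dimensions differ", call. = FALSE)
  if (max(abs(a$spacing - b$spacing)) > tol)
    stop("grid mismatch: voxel spacing differs", call. = FALSE)
  if (max(abs(a$origin - b$origin)) > tol)
    stop("grid mismatch: origin differs", call. = FALSE)
  invisible(TRUE)
}

#' Summary statistics of a volume inside a mask
#'
#' Mean and standard deviation of the voxel values selected by a binary mask.
#' BMD in this package is exactly this mean, computed on a calibrated volume.
#' The SD uses the population convention (divide by n) like every other
#' second-moment statistic in the package.
#'
#' @param v a [volume3d()].
#' @param m a [mask3d()] on the same grid.
#' @return list with `n_voxels`, `mean`, `sd` (`sd` is `NA` for n < 2).
#' @export
mask_statistics <- function(v, m) {
  stopifnot(is_volume3d(v), is_mask3d(m))
  check_same_grid(v, m)
  sel <- m$values != 0L
  n <- sum(sel)
  if (n < 1L) stop("empty VOI: mask selects no voxels", call. = FALSE)
  vals <- v$values[sel]
  mu <- mean(vals)
  s <- if (n >= 2L) sqrt(mean((vals - mu)^2)) else NA_real_
  list(n_voxels = n, mean = mu, sd = s)
}

#' Named set of analysis VOIs
#'
#' The knee analysis uses 16 VOIs: for each bone (femur, tibia), a cortical
#' shell plus three trabecular layers (S1 subchondral-epiphyseal, S2
#' mid-epiphyseal, S3 juxtaphyseal), each split into medial and lateral
#' compartments. Names follow `bone.layer.side`, e.g. `"femur.S1.medial"`.
#'
#' @param masks named list of [mask3d()] objects.
#' @param check_complete if `TRUE`, require exactly the 16 canonical names.
#' @return An object of class `voi_set`.
#' @export
voi_set <- function(masks, check_complete = FALSE) {
  if (!is.list(masks) || is.null(names(masks)) || any(names(masks) == ""))
    stop("`masks` must be a named list of mask3d objects", call. = FALSE)
  if (!all(vapply(masks, is_mask3d, logical(1))))
    stop("all VOIs must be mask3d objects", call. = FALSE)
  if (check_complete) {
    missing <- setdiff(voi_names(), names(masks))
    if (length(missing))
      stop("incomplete VOI set, missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    if (length(masks) != 16L)
      stop("a complete VOI set has exactly 16 entries", call. = FALSE)
  }
  structure(masks, class = "voi_set")
}

#' Canonical names of the 16 knee VOIs
#'
#' @param bone restrict to one bone (`"femur"`, `"tibia"`) or both.
#' @return character vector of `bone.layer.side` names.
#' @export
voi_names <- function(bone = c("femur", "tibia")) {
  bone <- match.arg(bone, several.ok = TRUE)
  layers <- c("cortical", "S1", "S2", "S3")
  sides <- c("medial", "lateral")
  as.vector(t(outer(bone, as.vector(t(outer(layers, sides, paste, sep = "."))),
                    paste, sep = ".")))
}

#' Parse a VOI name into bone, layer and side
#' @param name VOI name(s) of the form `bone.layer.side`.
#' @return data.frame with columns `voi_name`, `bone`, `layer`, `side`.
#' @export
parse_voi_name <- function(name) {
  parts <- strsplit(as.character(name), ".", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad)) stop("VOI names must be bone.layer.side", call. = FALSE)
  data.frame(voi_name = name,
             bone = vapply(parts, `[`, character(1), 1L),
             layer = vapply(parts, `[`, character(1), 2L),
             side = vapply(parts, `[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

#' @export
print.voi_set <- function(x, ...) {
  cat(sprintf("<voi_set> %d VOIs: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

# Physical coordinates of all voxel centers along one axis.
axis_coords <- function(v, axis) {
  v$origin[axis] + (seq_len(dim(v$values)[axis]) - 1) * v$spacing[axis]
}

# Physical extent [lo, hi] per axis, including the half-voxel border.
volume_extent <- function(v) {
  d <- dim(v$values)
  lo <- v$origin - v$spacing / 2
  hi <- v$origin + (d - 0.5) * v$spacing
  rbind(lo = lo, hi = hi)
}
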