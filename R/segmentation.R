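# Exact-Euclidean binary morphology via the squared distance transform:
# dilation keeps voxels within `radius` mm of the foreground, erosion keeps
# voxels farther than `radius` mm from the background.
edt_dilate <- function(values, dim, spacing, radius) {
  d2 <- cpp_edt_sq(as.integer(values != 0), dim, spacing)
  array(d2 <= radius^2 + 1e-9, dim = dim)
}

edt_erode <- function(values, dim, spacing, radius) {
  d2 <- cpp_edt_sq(as.integer(values == 0), dim, spacing)
  array(d2 > radius^2 + 1e-9, dim = dim)
}

# Fill cavities: background components not connected to the volume border.
fill_holes <- function(values, dim) {
  bg <- as.integer(values == 0)
  cc <- cpp_cc_label(bg, dim)
  lab <- array(cc$labels, dim = dim)
  border <- unique(c(lab[c(1, dim[1]), , ], lab[, c(1, dim[2]), ],
                     lab[, , c(1, dim[3])]))
  border <- border[border > 0]
  array(values != 0 | !(lab %in% c(0L, border)), dim = dim)
}

largest_component <- function(values, dim, n_keep = 1L) {
  cc <- cpp_cc_label(as.integer(values != 0), dim)
  if (!length(cc$sizes)) return(array(FALSE, dim = dim))
  keep <- order(cc$sizes, decreasing = TRUE)[seq_len(min(n_keep, length(cc$sizes)))]
  array(cc$labels %in% keep, dim = dim)
}

#' Segment the periosteal bone surface (simplified)
#'
#' Threshold at a fixed calibrated density, morphologically close with a
#' Euclidean ball, keep the largest connected component (6-connectivity) and
#' fill interior cavities, returning one solid bone body. This is a
#' simplified surrogate for a full anatomical knee segmentation, intended for
#' the synthetic phantoms of this package.
#'
#' @param v a [volume3d()] calibrated to BMD.
#' @param threshold segmentation threshold, mg/cm^3.
#' @param closing_radius radius (mm) of the morphological closing ball; 0
#'   disables closing.
#' @return a [mask3d()].
#' @export
segment_periosteal <- function(v, threshold = 300, closing_radius = 0.5) {
  stopifnot(is_volume3d(v))
  if (v$unit_tag != "bmd")
    stop("segmentation expects a BMD-calibrated volume", call. = FALSE)
  d <- dim(v$values)
  m <- v$values >= threshold
  if (!any(m))
    stop("segmentation failure: no voxel reaches the threshold", call. = FALSE)
  if (closing_radius > 0) {
    m <- edt_dilate(m, d, v$spacing, closing_radius)
    m <- edt_erode(m, d, v$spacing, closing_radius)
  }
  m <- largest_component(m, d)
  m <- fill_holes(m, d)
  mask3d(m, spacing = v$spacing, origin = v$origin)
}

#' Dice overlap ratio of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; 1 means perfect overlap. Both masks
#' must live on the same grid — upsample the coarser one first (the
#' convention here is to compute dice on the finer, HR-pQCT-like grid).
#'
#' @param a,b [mask3d()] objects on one grid.
#' @return overlap fraction in `[0, 1]`.
#' @export
dice_ratio <- function(a, b) {
  stopifnot(is_mask3d(a), is_mask3d(b))
  check_same_grid(a, b)
  na <- sum(a$values)
  nb <- sum(b$values)
  if (na + nb == 0L) stop("dice undefined: both masks empty", call. = FALSE)
  2 * sum(a$values & b$values) / (na + nb)
}
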