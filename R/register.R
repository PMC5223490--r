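# Signed Euclidean distance map of a binary mask, in mm: positive outside,
# negative inside, ~0 on the surface. `pad_mm` embeds the mask in a larger
# background so distances remain exact for query points beyond the original
# extent (needed when a misaligned transform maps surface points outside).
signed_distance <- function(m, pad_mm = 0) {
  vals <- m$values
  origin <- m$origin
  if (pad_mm > 0) {
    pad <- as.integer(ceiling(pad_mm / m$spacing))
    d0 <- dim(vals)
    big <- array(0L, dim = d0 + 2L * pad)
    big[pad[1] + seq_len(d0[1]), pad[2] + seq_len(d0[2]),
        pad[3] + seq_len(d0[3])] <- vals
    vals <- big
    origin <- origin - pad * m$spacing
  }
  d <- dim(vals)
  din <- sqrt(cpp_edt_sq(as.integer(vals != 0L), d, m$spacing))
  dout <- sqrt(cpp_edt_sq(as.integer(vals == 0L), d, m$spacing))
  volume3d(array(din - dout, dim = d), spacing = m$spacing, origin = origin,
           unit_tag = "attenuation")
}

# Physical coordinates of the mask's boundary voxels (6-connectivity),
# deterministically subsampled to at most n_max points.
surface_points <- function(m, n_max = 15000L) {
  d <- dim(m$values)
  offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  er <- cpp_morph(as.integer(m$values), d, offs, FALSE)
  sel <- which(m$values != 0L & er == 0L)
  if (!length(sel)) sel <- which(m$values != 0L)
  if (length(sel) > n_max)
    sel <- sel[seq(1L, length(sel), length.out = n_max)]
  idx <- arrayInd(sel, d)
  sweep(sweep(idx - 1, 2L, m$spacing, "*"), 2L, m$origin, "+")
}

# Coarsen a mask by an integer factor of its own spacing (nearest-neighbor).
coarsen_mask <- function(m, factor) {
  if (factor <= 1) return(m)
  resample_volume(m, m$spacing * factor)
}

#' Rigid surface registration of two binary masks
#'
#' Estimates the 6-degree-of-freedom rigid transform aligning the moving
#' surface with the fixed surface, by minimizing the mean squared signed
#' Euclidean distance (computed on the moving mask's distance map) over the
#' fixed mask's boundary points. A multi-resolution schedule (default
#' coarsening factors 4, 2, 1) makes the optimization robust to misalignments
#' of several degrees and millimeters; optimization uses quasi-Newton (BFGS)
#' descent with angle/translation scaling and is deterministic given the
#' inputs.
#'
#' The returned transform maps fixed-domain physical coordinates into the
#' moving domain, i.e. it is directly usable to resample the moving image (or
#' its VOIs) onto the fixed grid via [transfer_vois()].
#'
#' @param fixed,moving non-empty [mask3d()] objects (any grids).
#' @param init initial [rigid_transform()] (default identity about the fixed
#'   surface centroid).
#' @param levels integer coarsening factors, finest last.
#' @param n_points maximum number of fixed surface points per level.
#' @param maxit optimizer iteration budget per level.
#' @return a [rigid_transform()]; attribute `"metric"` holds the final mean
#'   squared surface distance (mm^2).
#' @export
register_rigid <- function(fixed, moving, init = NULL, levels = c(4L, 2L, 1L),
                           n_points = 15000L, maxit = 400L) {
  stopifnot(is_mask3d(fixed), is_mask3d(moving))
  if (!sum(fixed$values) || !sum(moving$values))
    stop("registration needs non-empty masks", call. = FALSE)
  pts_fine <- surface_points(fixed, n_points)
  center <- colMeans(pts_fine)
  par <- if (is.null(init)) rep(0, 6) else {
    # re-center the init about our center
    M <- transform_matrix(init)
    t0 <- matrix_to_transform(M)
    c(t0$rotation, as.numeric(transform_points(t0, matrix(center, 1)) - center))
  }
  mov_ext <- volume_extent(moving)
  last_metric <- Inf
  level_metrics <- numeric(0)
  convergence_ok <- TRUE
  for (f in levels) {
    mov_l <- coarsen_mask(moving, f)
    if (!sum(mov_l$values)) next
    sdm <- signed_distance(mov_l, pad_mm = 3 * f)
    fix_l <- coarsen_mask(fixed, f)
    pts <- surface_points(fix_l, n_points)
    bg <- max(abs(sdm$values)) * 2 + sum(mov_ext["hi", ] - mov_ext["lo", ])
    metric_fun <- function(p) {
      tr <- rigid_transform(rotation = p[1:3], translation = p[4:6],
                            center = center)
      q <- transform_points(tr, pts)
      dv <- cpp_interp_points(as.double(sdm$values), dim(sdm$values),
                              sdm$spacing, sdm$origin, q, TRUE, bg)
      mean(dv^2)
    }
    tr0 <- rigid_transform(rotation = par[1:3], translation = par[4:6],
                           center = center)
    d0 <- cpp_interp_points(as.double(sdm$values), dim(sdm$values), sdm$spacing,
                            sdm$origin, transform_points(tr0, pts), TRUE, bg)
    if (all(d0 >= bg * 0.999))
      stop("initialization error: no overlap between masks at init", call. = FALSE)
    opt <- stats::optim(par, metric_fun, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-12,
                                       parscale = c(rep(0.02, 3), rep(1, 3))))
    if (opt$value <= metric_fun(par)) {
      par <- opt$par
      last_metric <- opt$value
    }
    level_metrics <- c(level_metrics, last_metric)
    if (opt$convergence != 0) convergence_ok <- FALSE
  }
  if (!convergence_ok)
    warning("registration did not fully converge within the iteration budget; ",
            "returning best transform found", call. = FALSE)
  out <- rigid_transform(rotation = par[1:3], translation = par[4:6],
                         center = center)
  attr(out, "metric") <- last_metric
  attr(out, "level_metrics") <- level_metrics
  out
}
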