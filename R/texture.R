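#' Shannon entropy of the VOI grey-value histogram
#'
#' Entropy (bits) of the fixed-range, fixed-bin-width histogram of the voxel
#' values inside the mask: `-sum p_i log2 p_i` over occupied bins. A fixed
#' binning keeps entropy comparable across modalities and VOIs; values
#' outside the range are clamped into the edge bins. Defaults: 25 mg/cm^3
#' bins over [-100, 1500).
#'
#' @param v a [volume3d()].
#' @param m a [mask3d()] on the same grid.
#' @param bin_width histogram bin width, mg/cm^3 (> 0).
#' @param range histogram range `c(lo, hi)`, hi exclusive.
#' @return entropy in bits (>= 0).
#' @export
entropy <- function(v, m, bin_width = 25, range = c(-100, 1500)) {
  stopifnot(is_volume3d(v), is_mask3d(m))
  check_same_grid(v, m)
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  if (range[2] <= range[1]) stop("histogram range must have hi > lo", call. = FALSE)
  vals <- v$values[m$values != 0L]
  if (!length(vals)) stop("empty VOI", call. = FALSE)
  nbin <- max(1L, as.integer(ceiling((range[2] - range[1]) / bin_width)))
  idx <- floor((vals - range[1]) / bin_width)
  idx <- pmin(pmax(idx, 0), nbin - 1L) + 1L
  p <- tabulate(idx, nbins = nbin) / length(vals)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Global inhomogeneity of a VOI
#'
#' The population standard deviation of all VOI voxel values — grey-value
#' fluctuation at the whole-VOI scale.
#'
#' @inheritParams entropy
#' @return mg/cm^3.
#' @export
global_inhomogeneity <- function(v, m) {
  st <- mask_statistics(v, m)
  if (st$n_voxels < 2L) stop("global inhomogeneity needs at least 2 voxels",
                             call. = FALSE)
  st$sd
}

#' Local inhomogeneity of a VOI
#'
#' Mean, over every VOI voxel whose full cubic `(2r+1)^3` neighborhood lies
#' inside the mask, of the population SD within that neighborhood —
#' grey-value fluctuation at the neighborhood scale. The radius is defined in
#' voxels, which deliberately makes the parameter resolution-dependent: the
#' same physical structure occupies fewer voxels on a coarser grid.
#'
#' @inheritParams entropy
#' @param radius neighborhood radius in voxels (default 1, i.e. 3x3x3).
#' @return mg/cm^3.
#' @export
local_inhomogeneity <- function(v, m, radius = 1L) {
  stopifnot(is_volume3d(v), is_mask3d(m))
  check_same_grid(v, m)
  res <- cpp_local_sd(as.double(v$values), as.integer(m$values), dim(v$values),
                      as.integer(radius))
  if (!any(res$valid))
    stop("no voxel has a complete interior neighborhood", call. = FALSE)
  mean(res$sd[res$valid])
}

#' Structure-tensor anisotropy of a VOI
#'
#' At each interior voxel the structure tensor averages the outer products of
#' central-difference grey-value gradients (physical spacing respected) over
#' the cubic `(2r+1)^3` neighborhood; local anisotropy is
#' `1 - lambda_min / lambda_max` of that tensor (0 where `lambda_max` is
#' below tolerance, e.g. in constant regions). The VOI value is the mean over
#' interior voxels. Bounded in `[0, 1]`; 0 for isotropic neighborhoods, 1
#' where the grey values vary along a single direction.
#'
#' @inheritParams entropy
#' @param radius tensor-averaging radius in voxels (default 1).
#' @param tol eigenvalue tolerance below which a tensor counts as zero.
#' @return dimensionless value in `[0, 1]`.
#' @export
anisotropy <- function(v, m, radius = 1L, tol = 1e-10) {
  stopifnot(is_volume3d(v), is_mask3d(m))
  check_same_grid(v, m)
  res <- cpp_structure_aniso(as.double(v$values), as.integer(m$values),
                             dim(v$values), v$spacing, as.integer(radius), tol)
  if (!any(res$valid))
    stop("no voxel has a complete interior neighborhood", call. = FALSE)
  mean(res$aniso[res$valid])
}

#' Semivariogram slope of a VOI
#'
#' Empirical semivariogram `gamma(h) = 0.5 * mean[(v(x+h) - v(x))^2]` over
#' axis-aligned in-mask voxel pairs at each physical lag, pooled over axes,
#' followed by an ordinary least-squares fit of `gamma` against `h` over the
#' requested lags. On anisotropic grids each axis contributes its own set of
#' physical lags. Lags without any admissible pair are dropped with a warning.
#'
#' @inheritParams entropy
#' @param lags_vox integer lags in voxels applied per axis (default 1:4).
#' @param axes axes to pool over (subset of 1:3).
#' @return slope in (mg/cm^3)^2 per mm.
#' @export
variogram_slope <- function(v, m, lags_vox = 1:4, axes = 1:3) {
  g <- semivariogram(v, m, lags_vox, axes)
  if (nrow(g) < 2L)
    stop("variogram needs at least 2 usable lags", call. = FALSE)
  unname(stats::coef(stats::lm(gamma ~ h, data = g))[2])
}

#' Empirical semivariogram of a VOI
#'
#' @inheritParams variogram_slope
#' @return data.frame with physical lag `h` (mm), semivariance `gamma`
#'   ((mg/cm^3)^2) and pair count `n_pairs`, one row per distinct lag.
#' @export
semivariogram <- function(v, m, lags_vox = 1:4, axes = 1:3) {
  stopifnot(is_volume3d(v), is_mask3d(m))
  check_same_grid(v, m)
  lags_vox <- as.integer(lags_vox)
  if (length(lags_vox) < 2L) stop("need at least 2 lags", call. = FALSE)
  if (any(lags_vox < 1L)) stop("lags must be positive voxel counts", call. = FALSE)
  d <- dim(v$values)
  acc <- list()
  for (a in axes) {
    for (k in lags_vox) {
      if (d[a] <= k) next
      n <- d[a]
      i1 <- seq_len(n - k)
      i2 <- i1 + k
      sl <- function(x, idx) {
        switch(a, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
               x[, , idx, drop = FALSE])
      }
      ok <- sl(m$values, i1) & sl(m$values, i2)
      np <- sum(ok)
      h <- k * v$spacing[a]
      key <- sprintf("%.9f", h)
      prev <- acc[[key]] %||% list(h = h, sse = 0, n = 0)
      if (np > 0) {
        dv <- (sl(v$values, i2) - sl(v$values, i1))[ok]
        prev$sse <- prev$sse + sum(dv^2)
      }
      prev$n <- prev$n + np
      acc[[key]] <- prev
    }
  }
  if (!length(acc)) stop("no admissible voxel pairs for any lag", call. = FALSE)
  out <- do.call(rbind, lapply(acc, function(e)
    data.frame(h = e$h, gamma = if (e$n > 0) 0.5 * e$sse / e$n else NA_real_,
               n_pairs = e$n)))
  out <- out[order(out$h), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$n_pairs == 0)) {
    warning("dropping lags with no admissible pairs", call. = FALSE)
    out <- out[out$n_pairs > 0, , drop = FALSE]
  }
  out
}

#' Texture computation settings
#'
#' @param entropy_bin_width,entropy_range histogram settings for [entropy()].
#' @param local_radius,aniso_radius neighborhood radii (voxels).
#' @param variogram_lags voxel lags for [variogram_slope()].
#' @param min_voxels minimum VOI size; smaller VOIs raise a per-VOI error.
#' @return list of settings for [compute_all()].
#' @export
texture_settings <- function(entropy_bin_width = 25,
                             entropy_range = c(-100, 1500),
                             local_radius = 1L, aniso_radius = 1L,
                             variogram_lags = 1:4, min_voxels = 27L) {
  list(entropy_bin_width = entropy_bin_width, entropy_range = entropy_range,
       local_radius = local_radius, aniso_radius = aniso_radius,
       variogram_lags = variogram_lags, min_voxels = min_voxels)
}

#' BMD and all five texture parameters for every VOI
#'
#' Computes the per-VOI record (BMD mean plus entropy, global and local
#' inhomogeneity, anisotropy, variogram slope). When a separate medium-kernel
#' volume is supplied via `v_bmd`, BMD is measured on it while texture is
#' measured on `v` (the sharp-kernel convention). A VOI below the minimum
#' size is skipped entirely; a parameter that cannot be computed on an
#' otherwise valid VOI (e.g. neighborhood statistics on a shell thinner than
#' the neighborhood) is reported as `NA`. All failures are collected as
#' warnings and in the `"failures"` attribute; the remaining VOIs and
#' parameters are still computed.
#'
#' @param v [volume3d()] calibrated to BMD; texture source.
#' @param vois a [voi_set()].
#' @param settings a [texture_settings()] list.
#' @param v_bmd optional [volume3d()] for the BMD means (defaults to `v`).
#' @param modality label stored with each record.
#' @return data.frame with one row per VOI, columns `voi_name`, `n_voxels`,
#'   `bmd_mean`, `entropy`, `global_inhomogeneity`, `local_inhomogeneity`,
#'   `anisotropy`, `variogram_slope`, `modality`.
#' @export
compute_all <- function(v, vois, settings = texture_settings(), v_bmd = NULL,
                        modality = NULL) {
  stopifnot(is_volume3d(v), inherits(vois, "voi_set"))
  if (v$unit_tag != "bmd")
    stop("texture is computed on BMD-calibrated volumes", call. = FALSE)
  v_bmd <- v_bmd %||% v
  modality <- modality %||% v$kernel_tag
  rows <- list()
  failures <- character()
  for (nm in names(vois)) {
    m <- vois[[nm]]
    n <- sum(m$values)
    if (n < settings$min_voxels) {
      failures <- c(failures, sprintf("%s: %d voxels (< %d minimum)", nm, n,
                                      settings$min_voxels))
      next
    }
    tp <- function(label, expr) {
      tryCatch(expr, error = function(e) {
        failures <<- c(failures, sprintf("%s/%s: %s", nm, label,
                                         conditionMessage(e)))
        NA_real_
      })
    }
    rec <- data.frame(
      voi_name = nm, n_voxels = n,
      bmd_mean = tp("bmd", mask_statistics(v_bmd, m)$mean),
      entropy = tp("entropy", entropy(v, m, settings$entropy_bin_width,
                                      settings$entropy_range)),
      global_inhomogeneity = tp("global_inhomogeneity",
                                global_inhomogeneity(v, m)),
      local_inhomogeneity = tp("local_inhomogeneity",
                               local_inhomogeneity(v, m, settings$local_radius)),
      anisotropy = tp("anisotropy", anisotropy(v, m, settings$aniso_radius)),
      variogram_slope = tp("variogram_slope",
                           variogram_slope(v, m, settings$variogram_lags)),
      modality = modality, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- rec
  }
  if (length(failures))
    warning("texture failed for ", length(failures), " VOI(s): ",
            paste(failures, collapse = "; "), call. = FALSE)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(voi_name = character(), n_voxels = integer(),
               bmd_mean = numeric(), entropy = numeric(),
               global_inhomogeneity = numeric(), local_inhomogeneity = numeric(),
               anisotropy = numeric(), variogram_slope = numeric(),
               modality = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}
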