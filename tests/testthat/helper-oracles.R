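# Shared fixtures and independent brute-force oracles. The oracles use plain
# loops over voxels/pairs and base-R eigen(), deliberately sharing no code
# with the implementations they check.

rand_volume <- function(d, spacing = c(1, 1, 1), lo = 0, hi = 400,
                        origin = c(0, 0, 0)) {
  volume3d(array(stats::runif(prod(d), lo, hi), dim = d), spacing = spacing,
           origin = origin, unit_tag = "bmd")
}

full_mask <- function(v) mask3d(array(TRUE, dim(v$values)), v$spacing, v$origin)

rand_mask <- function(v, p = 0.8) {
  m <- array(stats::runif(prod(dim(v$values))) < p, dim(v$values))
  if (!any(m)) m[1] <- TRUE
  mask3d(m, v$spacing, v$origin)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

oracle_entropy <- function(vals, bin_width, range) {
  nbin <- ceiling((range[2] - range[1]) / bin_width)
  counts <- numeric(nbin)
  for (x in vals) {
    b <- floor((x - range[1]) / bin_width) + 1
    b <- min(max(b, 1), nbin)
    counts[b] <- counts[b] + 1
  }
  p <- counts[counts > 0] / length(vals)
  -sum(p * log2(p))
}

oracle_local_sd <- function(v, m, r = 1L) {
  d <- dim(v)
  out <- c()
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!m[i, j, k]) next
    if (i <= r || j <= r || k <= r || i > d[1] - r || j > d[2] - r ||
        k > d[3] - r) next
    nb <- m[(i - r):(i + r), (j - r):(j + r), (k - r):(k + r)]
    if (!all(nb)) next
    out <- c(out, pop_sd(as.vector(v[(i - r):(i + r), (j - r):(j + r),
                                     (k - r):(k + r)])))
  }
  out
}

oracle_aniso <- function(v, m, spacing, r = 1L, tol = 1e-10) {
  d <- dim(v)
  gx <- gy <- gz <- array(NA_real_, d)
  gok <- array(FALSE, d)
  for (k in 2:(d[3] - 1)) for (j in 2:(d[2] - 1)) for (i in 2:(d[1] - 1)) {
    if (!m[i, j, k]) next
    if (!all(m[i + c(-1, 1), j, k], m[i, j + c(-1, 1), k], m[i, j, k + c(-1, 1)]))
      next
    gok[i, j, k] <- TRUE
    gx[i, j, k] <- (v[i + 1, j, k] - v[i - 1, j, k]) / (2 * spacing[1])
    gy[i, j, k] <- (v[i, j + 1, k] - v[i, j - 1, k]) / (2 * spacing[2])
    gz[i, j, k] <- (v[i, j, k + 1] - v[i, j, k - 1]) / (2 * spacing[3])
  }
  out <- c()
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!gok[i, j, k]) next
    if (i <= r || j <= r || k <= r || i > d[1] - r || j > d[2] - r ||
        k > d[3] - r) next
    ii <- (i - r):(i + r); jj <- (j - r):(j + r); kk <- (k - r):(k + r)
    if (!all(gok[ii, jj, kk])) next
    G <- cbind(as.vector(gx[ii, jj, kk]), as.vector(gy[ii, jj, kk]),
               as.vector(gz[ii, jj, kk]))
    S <- crossprod(G) / nrow(G)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    out <- c(out, if (max(ev) <= tol) 0 else 1 - min(ev) / max(ev))
  }
  out
}

oracle_variogram <- function(v, m, spacing, lags = 1:4, axes = 1:3) {
  d <- dim(v)
  acc <- list()
  for (a in axes) for (kk in lags) {
    if (d[a] <= kk) next
    sse <- 0; np <- 0
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      i2 <- i + (a == 1) * kk; j2 <- j + (a == 2) * kk; k2 <- k + (a == 3) * kk
      if (i2 > d[1] || j2 > d[2] || k2 > d[3]) next
      if (!m[i, j, k] || !m[i2, j2, k2]) next
      sse <- sse + (v[i2, j2, k2] - v[i, j, k])^2
      np <- np + 1
    }
    h <- kk * spacing[a]
    key <- sprintf("%.9f", h)
    prev <- acc[[key]]
    if (is.null(prev)) prev <- c(h = h, sse = 0, n = 0)
    prev["sse"] <- prev["sse"] + sse
    prev["n"] <- prev["n"] + np
    acc[[key]] <- prev
  }
  res <- do.call(rbind, acc)
  res <- res[res[, "n"] > 0, , drop = FALSE]
  data.frame(h = res[, "h"], gamma = 0.5 * res[, "sse"] / res[, "n"],
             n_pairs = res[, "n"])[order(res[, "h"]), ]
}

oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  se <- sqrt(sum((y - yhat)^2) / (n - 2) / sxx)
  p <- 2 * stats::pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
  list(slope = slope, intercept = intercept, r_squared = r2, p_value = p)
}

# a small, quick knee phantom spec for segmentation / VOI / registration tests
small_phantom_spec <- function(seed = 1, ...) {
  knee_phantom_spec(condyle_radii = c(4.5, 4.5), condyle_offset = 2.5,
                    shaft_radius = 3.2, epiphysis_height = 5.5,
                    shaft_length = 2.5, cortical_thickness = 0.5,
                    margin = 1.2, resolution = 0.12,
                    interior = trabecular_params(trab_thickness = 0.25,
                                                 trab_separation = 1.1,
                                                 seed = seed),
                    seed = seed, ...)
}

# coarse imaging profiles matched to the small phantom
small_hr_profile <- function(noise_sd = 0)
  imaging_profile("custom", spacing = c(0.25, 0.25, 0.25), psf_fwhm = 0.35,
                  noise_sd = noise_sd)
small_ct_profile <- function(noise_sd = 0)
  imaging_profile("custom", spacing = c(0.6, 0.6, 0.7), psf_fwhm = 1.0,
                  noise_sd = noise_sd)
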