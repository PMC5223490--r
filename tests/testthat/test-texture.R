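test_that("entropy matches hand-built histograms", {
  cv <- volume3d(array(250, c(3, 3, 3)), c(1, 1, 1), unit_tag = "bmd")
  expect_equal(entropy(cv, full_mask(cv)), 0)   # one occupied bin

  two <- volume3d(array(rep(c(10, 60), 4), c(2, 2, 2)), c(1, 1, 1))
  expect_equal(entropy(two, full_mask(two), bin_width = 50, range = c(0, 100)), 1)

  v8 <- volume3d(array(c(0, 0, 0, 0, 100, 100, 200, 300), c(2, 2, 2)), c(1, 1, 1))
  expect_equal(entropy(v8, full_mask(v8), bin_width = 100, range = c(0, 400)),
               1.75)   # p = {.5, .25, .125, .125}
  expect_error(entropy(v8, full_mask(v8), bin_width = 0), "positive")
  expect_error(entropy(v8, full_mask(v8), range = c(10, 10)), "hi > lo")

  # out-of-range values clamp into the edge bins
  vo <- volume3d(array(c(-500, 900, 50, 50, 50, 50, 50, 50), c(2, 2, 2)),
                 c(1, 1, 1))
  h <- entropy(vo, full_mask(vo), bin_width = 100, range = c(0, 400))
  expect_equal(h, oracle_entropy(as.vector(vo$values), 100, c(0, 400)))
})

test_that("global inhomogeneity is the population SD of the VOI", {
  v <- volume3d(array(c(0, 0, 100, 100), c(2, 2, 1)), c(1, 1, 1))
  expect_equal(global_inhomogeneity(v, full_mask(v)), 50)
  cv <- volume3d(array(9, c(3, 3, 3)), c(1, 1, 1))
  expect_equal(global_inhomogeneity(cv, full_mask(cv)), 0)
  set.seed(51)
  r <- rand_volume(c(5, 5, 5))
  m <- rand_mask(r, 0.7)
  expect_equal(global_inhomogeneity(r, m), mask_statistics(r, m)$sd)
})

test_that("local inhomogeneity equals the brute-force neighborhood oracle", {
  cv <- volume3d(array(5, c(5, 5, 5)), c(1, 1, 1))
  expect_equal(local_inhomogeneity(cv, full_mask(cv)), 0)

  # a VOI of exactly one 3^3 block reduces to its global SD
  set.seed(52)
  v <- rand_volume(c(5, 5, 5))
  m <- array(FALSE, c(5, 5, 5)); m[2:4, 2:4, 2:4] <- TRUE
  mm <- mask3d(m, c(1, 1, 1))
  expect_equal(local_inhomogeneity(v, mm), global_inhomogeneity(v, mm))

  for (rep in 1:8) {
    v <- rand_volume(c(6, 6, 6))
    m <- rand_mask(v, 0.9)
    orc <- oracle_local_sd(v$values, m$values == 1L, 1L)
    if (!length(orc)) next
    expect_equal(local_inhomogeneity(v, m), mean(orc), tolerance = 1e-12)
  }
  thin <- mask3d(array(rep(c(TRUE, FALSE), 108), c(6, 6, 6)), c(1, 1, 1))
  expect_error(local_inhomogeneity(rand_volume(c(6, 6, 6)), thin),
               "interior neighborhood")
})

test_that("anisotropy equals the brute-force structure-tensor oracle", {
  cv <- volume3d(array(5, c(5, 5, 5)), c(1, 1, 1))
  expect_equal(anisotropy(cv, full_mask(cv)), 0)   # zero-tensor convention

  # variation along one axis only: rank-1 tensor, anisotropy 1
  d <- c(6, 6, 6)
  ramp <- volume3d(array(rep(5 * (1:6), times = 36), dim = d), c(1, 1, 1))
  expect_equal(anisotropy(ramp, full_mask(ramp)), 1)
  # stripes of period 4 along x (period 2 is invisible to central differences)
  stripes <- volume3d(array(rep(c(0, 0, 100, 100), length.out = 216), dim = d),
                      c(1, 1, 1))
  expect_equal(anisotropy(stripes, full_mask(stripes)), 1)

  set.seed(53)
  for (rep in 1:8) {
    v <- rand_volume(c(6, 6, 6), spacing = c(0.7, 1, 1.3))
    m <- full_mask(v)
    orc <- oracle_aniso(v$values, m$values == 1L, v$spacing, 1L)
    expect_equal(anisotropy(v, m), mean(orc), tolerance = 1e-6)
  }
})

test_that("variogram slope matches closed forms and the pair-loop oracle", {
  cv <- volume3d(array(5, c(6, 6, 6)), c(1, 1, 1))
  expect_equal(variogram_slope(cv, full_mask(cv)), 0)

  # 1D ramp v = c*x: gamma(h) = c^2 h^2 / 2; OLS of the parabola over the lags
  cslope <- 4
  d <- c(12, 4, 4)
  ramp <- volume3d(array(rep(cslope * (0:11) * 0.5, times = 16), dim = d),
                   c(0.5, 1, 1))
  g <- semivariogram(ramp, full_mask(ramp), lags_vox = 1:4, axes = 1L)
  hs <- (1:4) * 0.5
  expect_equal(g$gamma, 0.5 * cslope^2 * hs^2, tolerance = 1e-10)
  fit <- oracle_ols(hs, 0.5 * cslope^2 * hs^2)
  expect_equal(variogram_slope(ramp, full_mask(ramp), lags_vox = 1:4, axes = 1L),
               fit$slope, tolerance = 1e-10)

  set.seed(54)
  for (rep in 1:5) {
    v <- rand_volume(c(6, 6, 6), spacing = c(0.7, 1, 1.3))
    m <- rand_mask(v, 0.85)
    g <- semivariogram(v, m)
    orc <- oracle_variogram(v$values, m$values == 1L, v$spacing)
    expect_equal(g$h, orc$h, tolerance = 1e-12)
    expect_equal(g$gamma, orc$gamma, tolerance = 1e-10)
    expect_equal(g$n_pairs, orc$n_pairs)
  }
  expect_error(semivariogram(cv, full_mask(cv), lags_vox = 1L), "2 lags")
  # sparse mask: lags without pairs are dropped with a warning, and fewer
  # than two surviving lags make the slope undefined
  sm <- array(FALSE, c(6, 6, 6)); sm[1:2] <- TRUE
  smm <- mask3d(sm, c(1, 1, 1))
  expect_warning(g2 <- semivariogram(cv, smm, lags_vox = 1:2), "dropping")
  expect_equal(nrow(g2), 1L)
  suppressWarnings(expect_error(variogram_slope(cv, smm, lags_vox = 1:2),
                                "2 usable lags"))
})

test_that("texture is shift invariant and scale covariant", {
  set.seed(55)
  rng <- c(-100, 1500)
  for (rep in 1:5) {
    v <- rand_volume(c(7, 7, 7), lo = 100, hi = 500)
    m <- full_mask(v)   # neighborhood statistics need complete interiors
    sh <- volume3d(v$values + 123, v$spacing, v$origin)
    k <- 2.5
    sc <- volume3d(v$values * k, v$spacing, v$origin)
    expect_equal(global_inhomogeneity(sh, m), global_inhomogeneity(v, m))
    expect_equal(local_inhomogeneity(sh, m), local_inhomogeneity(v, m))
    expect_equal(anisotropy(sh, m), anisotropy(v, m))
    expect_equal(variogram_slope(sh, m), variogram_slope(v, m))
    # entropy invariant when the histogram range shifts with the data
    expect_equal(entropy(sh, m, 25, rng + 123), entropy(v, m, 25, rng))
    expect_equal(global_inhomogeneity(sc, m), k * global_inhomogeneity(v, m))
    expect_equal(local_inhomogeneity(sc, m), k * local_inhomogeneity(v, m))
    expect_equal(variogram_slope(sc, m), k^2 * variogram_slope(v, m))
    expect_equal(anisotropy(sc, m), anisotropy(v, m), tolerance = 1e-9)
  }
})

test_that("compute_all yields one record per VOI, independent of order", {
  set.seed(56)
  v <- rand_volume(c(12, 12, 12), lo = 0, hi = 600)
  masks <- list()
  for (i in 1:4) {
    m <- array(FALSE, c(12, 12, 12))
    m[i:(i + 6), 2:11, 2:11] <- TRUE   # wide enough for 3^3 gradient interiors
    masks[[sprintf("femur.S%d.%s", (i - 1) %% 3 + 1,
                   c("medial", "lateral")[(i > 2) + 1])]] <-
      mask3d(m, v$spacing, v$origin)
  }
  vois <- voi_set(masks)
  res <- compute_all(v, vois, modality = "test")
  expect_equal(nrow(res), 4L)
  expect_true(all(is.finite(as.matrix(res[, 3:8]))))
  expect_true(all(res$entropy >= 0) && all(res$global_inhomogeneity >= 0))

  rev_res <- compute_all(v, voi_set(rev(masks)), modality = "test")
  rev_res <- rev_res[match(res$voi_name, rev_res$voi_name), ]
  rownames(rev_res) <- NULL
  attr(rev_res, "failures") <- attr(res, "failures") <- NULL
  expect_equal(rev_res, res)

  # all-constant interior: every parameter 0
  cvol <- volume3d(array(200, c(12, 12, 12)), c(1, 1, 1), unit_tag = "bmd")
  resc <- compute_all(cvol, vois)
  expect_true(all(resc$entropy == 0) && all(resc$global_inhomogeneity == 0) &&
                all(resc$anisotropy == 0) && all(resc$variogram_slope == 0))

  # undersized VOIs are skipped and reported
  tiny <- voi_set(list(femur.S1.medial = mask3d(
    array(c(rep(TRUE, 8), rep(FALSE, 1720)), c(12, 12, 12)), c(1, 1, 1))))
  expect_warning(res_t <- compute_all(v, tiny), "minimum")
  expect_equal(nrow(res_t), 0L)
})
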