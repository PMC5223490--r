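test_that("volume3d and mask3d enforce their grid invariants", {
  a <- array(0, c(2, 2, 2))
  expect_error(volume3d(a, spacing = c(1, -1, 1)), "positive")
  expect_error(volume3d(a, spacing = c(1, 1)), "positive")
  expect_error(volume3d(matrix(0, 2, 2), spacing = c(1, 1, 1)), "3D")
  expect_error(mask3d(a, spacing = c(0, 1, 1)), "positive")
  v <- volume3d(a, c(1, 1, 1))
  expect_s3_class(v, "volume3d")
  expect_identical(v$unit_tag, "attenuation")
  m <- mask3d(array(c(0, 2, -1, 0, 0, 0, 1, 0), c(2, 2, 2)), c(1, 1, 1))
  expect_identical(sort(unique(as.vector(m$values))), c(0L, 1L))
  b <- volume3d(a, c(1, 1, 1), origin = c(5, 0, 0))
  expect_error(check_same_grid(v, b), "origin")
})

test_that("mask_statistics matches hand and brute-force computation", {
  vals <- array(0, c(2, 2, 1))
  vals[] <- c(0, 0, 100, 100)
  v <- volume3d(vals, c(1, 1, 1))
  st <- mask_statistics(v, full_mask(v))
  expect_equal(st$mean, 50)
  expect_equal(st$sd, 50)  # population convention
  expect_equal(st$n_voxels, 4L)

  cv <- volume3d(array(100, c(3, 3, 3)), c(1, 1, 1))
  stc <- mask_statistics(cv, full_mask(cv))
  expect_equal(stc$mean, 100)
  expect_equal(stc$sd, 0)

  set.seed(42)
  for (rep in 1:10) {
    v <- rand_volume(c(6, 6, 6))
    m <- rand_mask(v, 0.6)
    st <- mask_statistics(v, m)
    sel <- v$values[m$values == 1L]
    expect_identical(st$n_voxels, length(sel))
    expect_equal(st$mean, mean(sel))
    expect_equal(st$sd, pop_sd(sel))
  }

  empty <- mask3d(array(FALSE, c(6, 6, 6)), c(1, 1, 1))
  v <- rand_volume(c(6, 6, 6))
  expect_error(mask_statistics(v, empty), "empty")
  # whole-volume mask equals unmasked statistics
  expect_equal(mask_statistics(v, full_mask(v))$mean, mean(v$values))
})

test_that("resample_volume preserves identity, constants and linear ramps", {
  set.seed(7)
  v <- rand_volume(c(8, 8, 8), spacing = c(0.5, 0.5, 0.5))
  same <- resample_volume(v, c(0.5, 0.5, 0.5))
  expect_equal(same$values, v$values)
  expect_equal(same$origin, v$origin)

  cv <- volume3d(array(7, c(6, 6, 6)), c(1, 1, 1))
  up <- resample_volume(cv, c(0.4, 0.4, 0.4))
  expect_true(all(abs(up$values - 7) < 1e-12))

  # linear ramp along x, 2x upsampling: compare to the analytic ramp at the
  # new voxel centers (interior, away from the clamped border)
  d <- c(10, 4, 4)
  xs <- (seq_len(d[1]) - 1) * 1.0
  ramp <- volume3d(array(rep(3 * xs, times = d[2] * d[3]), dim = d), c(1, 1, 1))
  up2 <- resample_volume(ramp, c(0.5, 1, 1), interp = "linear")
  xs_new <- up2$origin[1] + (seq_len(dim(up2$values)[1]) - 1) * 0.5
  inside <- xs_new >= 0 & xs_new <= max(xs)
  expect_lt(max(abs(up2$values[inside, 1, 1] - 3 * xs_new[inside])), 1e-9)

  expect_error(resample_volume(v, c(0, 1, 1)), "positive")
})

test_that("the 16-VOI naming scheme parses and validates", {
  expect_length(voi_names(), 16L)
  expect_length(voi_names("femur"), 8L)
  p <- parse_voi_name("tibia.S2.lateral")
  expect_identical(p$bone, "tibia")
  expect_identical(p$layer, "S2")
  expect_identical(p$side, "lateral")
  expect_error(parse_voi_name("justonename"), "bone.layer.side")

  m <- mask3d(array(TRUE, c(2, 2, 2)), c(1, 1, 1))
  masks <- setNames(rep(list(m), 16), voi_names())
  expect_s3_class(voi_set(masks, check_complete = TRUE), "voi_set")
  expect_error(voi_set(masks[-1], check_complete = TRUE), "missing")
  expect_error(voi_set(list(m)), "named")
})
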