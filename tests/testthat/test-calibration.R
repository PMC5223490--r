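make_rod_volume <- function(measured, n = 4) {
  # one 2x2xn block per rod holding the measured value
  k <- length(measured)
  vals <- array(0, c(4 * k, 4, n))
  rois <- vector("list", k)
  for (i in seq_len(k)) {
    xs <- (4 * (i - 1) + 2):(4 * (i - 1) + 3)
    vals[xs, 2:3, ] <- measured[i]
    m <- array(FALSE, dim(vals))
    m[xs, 2:3, ] <- TRUE
    rois[[i]] <- m
  }
  v <- volume3d(vals, c(1, 1, 1))
  list(volume = v,
       roi = function(i, known) phantom_roi(mask3d(rois[[i]], c(1, 1, 1)), known))
}

test_that("phantom calibration fits exact lines exactly", {
  rv <- make_rod_volume(c(100, 200))
  cal <- fit_phantom_calibration(list(rv$roi(1, 100), rv$roi(2, 200)), rv$volume)
  expect_equal(cal$slope, 1)
  expect_equal(cal$intercept, 0)
  expect_identical(cal$source, "in_scan_phantom")

  rv2 <- make_rod_volume(c(50, 150, 250))
  cal2 <- fit_phantom_calibration(list(rv2$roi(1, 0), rv2$roi(2, 100),
                                       rv2$roi(3, 200)), rv2$volume)
  expect_equal(cal2$slope, 1)
  expect_equal(cal2$intercept, -50)

  expect_error(fit_phantom_calibration(list(rv$roi(1, 100)), rv$volume),
               "2 phantom rods")
  expect_error(fit_phantom_calibration(list(rv$roi(1, 100), rv$roi(2, 100)),
                                       rv$volume), "distinct")
})

test_that("apply_calibration maps values linearly and tracks units", {
  v <- volume3d(array(400, c(3, 3, 3)), c(1, 1, 1))
  c1 <- calibration_model(0.75, 32.0, "in_scan_phantom")
  out <- apply_calibration(v, c1)
  expect_equal(out$values[1], 332.0)   # 0.75 * 400 + 32
  expect_identical(out$unit_tag, "bmd")
  expect_error(apply_calibration(out, c1), "misuse")

  ident <- calibration_model(1, 0, "in_scan_phantom")
  expect_equal(apply_calibration(v, ident)$values, v$values)
  c2 <- calibration_model(2, 10, "in_scan_phantom")
  expect_true(all(apply_calibration(volume3d(array(100, c(2, 2, 2)),
                                             c(1, 1, 1)), c2)$values == 210))
  expect_error(calibration_model(0, 5), "non-zero")
})

test_that("cross-device correction recovers construction lines and kills bias", {
  x <- c(100, 200, 300, 450, 600)
  cal <- fit_cross_device_correction(
    data.frame(bmd_ct = x, bmd_hrpqct = 0.75 * x + 32))
  expect_equal(cal$slope, 0.75, tolerance = 1e-12)
  expect_equal(cal$intercept, 32.0, tolerance = 1e-10)
  expect_identical(cal$source, "cross_device")

  cal_id <- fit_cross_device_correction(data.frame(bmd_ct = x, bmd_hrpqct = x))
  expect_equal(cal_id$slope, 1, tolerance = 1e-12)
  expect_equal(cal_id$intercept, 0, tolerance = 1e-10)

  set.seed(17)
  for (rep in 1:5) {
    xr <- stats::runif(20, 100, 700)
    yr <- 0.8 * xr + 25 + stats::rnorm(20, 0, 15)
    cal_n <- fit_cross_device_correction(data.frame(bmd_ct = xr, bmd_hrpqct = yr))
    orc <- oracle_ols(xr, yr)
    expect_equal(cal_n$slope, orc$slope, tolerance = 1e-10)
    expect_equal(cal_n$intercept, orc$intercept, tolerance = 1e-10)
    # correction zeroes the mean bias over its fitting set (OLS residual property)
    corrected <- cal_n$slope * xr + cal_n$intercept
    expect_lt(abs(mean(corrected - yr)), 1e-9)
  }
  expect_error(fit_cross_device_correction(data.frame(bmd_ct = c(1, 2),
                                                      bmd_hrpqct = c(1, 2))),
               "3 paired")
  expect_error(fit_cross_device_correction(
    data.frame(bmd_ct = c(5, 5, 5), bmd_hrpqct = c(1, 2, 3))), "degenerate")
})

test_that("calibration models serialize to JSON and back", {
  cal <- calibration_model(0.75, 32, "cross_device")
  f <- tempfile(fileext = ".json")
  write_calibration(cal, f)
  r <- read_calibration(f)
  expect_equal(r$slope, 0.75)
  expect_equal(r$intercept, 32)
  expect_identical(r$source, "cross_device")
})

test_that("apply o fit reproduces known rod densities on collinear data", {
  rv <- make_rod_volume(c(20, 120, 320))
  known <- c(0, 250, 750)   # collinear with measured: density = 2.5*m - 50
  cal <- fit_phantom_calibration(list(rv$roi(1, known[1]), rv$roi(2, known[2]),
                                      rv$roi(3, known[3])), rv$volume)
  out <- apply_calibration(rv$volume, cal)
  for (i in 1:3)
    expect_equal(out$values[4 * (i - 1) + 2, 2, 1], known[i], tolerance = 1e-9)
})
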