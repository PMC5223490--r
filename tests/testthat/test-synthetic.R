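test_that("trabecular parameters validate their invariants", {
  expect_error(trabecular_params(trab_thickness = 0.9, trab_separation = 0.8),
               "smaller")
  expect_error(trabecular_params(bone_density = 20, marrow_density = 30),
               "exceed")
  expect_error(trabecular_params(jitter = 0.7), "jitter")
  expect_error(trabecular_params(plate_fraction = 1.2), "plate_fraction")
  expect_error(trabecular_params(heterogeneity = -1), "heterogeneity")
})

test_that("the lattice generator is deterministic and matches its closed form", {
  p <- trabecular_params(trab_thickness = 0.2, trab_separation = 0.8,
                         plate_fraction = 0, jitter = 0, heterogeneity = 0,
                         seed = 3)
  v1 <- generate_trabecular_model(p, extent = 4.8, resolution = 0.02)
  v2 <- generate_trabecular_model(p, extent = 4.8, resolution = 0.02)
  expect_identical(v1$values, v2$values)

  vf <- mean(v1$values > 500)
  expect_lt(abs(vf - lattice_fraction(0.2, 0.8)) / lattice_fraction(0.2, 0.8),
            0.10)
  # two-valued identity: mean = vf * bone + (1 - vf) * marrow
  expect_equal(mean(v1$values), vf * 1000 + (1 - vf) * 30, tolerance = 1e-10)

  expect_error(generate_trabecular_model(p, extent = 2), "5 lattice periods")

  # jittered, plate-bearing lattice is still deterministic per seed
  pj <- trabecular_params(seed = 9)
  expect_identical(generate_trabecular_model(pj, extent = 4.2, resolution = 0.05)$values,
                   generate_trabecular_model(pj, extent = 4.2, resolution = 0.05)$values)
})

test_that("the model suite sweeps bone volume fraction monotonically", {
  suite <- generate_model_suite(n = 6, resolution = 0.05, seed = 21)
  expect_length(suite, 6L)
  vf <- vapply(suite, function(v) mean(v$values > 515), numeric(1))
  expect_true(all(diff(vf) > 0))
  # determinism
  suite2 <- generate_model_suite(n = 6, resolution = 0.05, seed = 21)
  expect_identical(suite[[3]]$values, suite2[[3]]$values)
  # degenerate sweep: equal endpoints differ only by seed
  s3 <- generate_model_suite(n = 2, sweep = list(trab_thickness = c(0.2, 0.2)),
                             extent = 4.2, resolution = 0.06, seed = 4)
  p1 <- attr(s3[[1]], "params"); p2 <- attr(s3[[2]], "params")
  expect_equal(p1$trab_thickness, p2$trab_thickness)
  expect_false(identical(p1$seed, p2$seed))
  expect_error(generate_model_suite(n = 1), "n >= 2")
  expect_error(generate_model_suite(n = 4, sweep = list()), "empty")
  expect_error(generate_model_suite(n = 4, sweep = list(bad_field = c(1, 2))),
               "unknown")
})

test_that("imaging profile presets encode the stated acquisition world", {
  hr <- imaging_profile("hrpqct")
  ctm <- imaging_profile("ct_medium")
  cts <- imaging_profile("ct_sharp")
  expect_equal(hr$spacing, c(0.082, 0.082, 0.082))
  expect_equal(ctm$spacing, c(0.25, 0.25, 0.3))
  expect_equal(hr$noise_sd / ctm$noise_sd, 5)
  expect_lt(cts$psf_fwhm, ctm$psf_fwhm)
  expect_error(imaging_profile("custom"), "spacing")
})

test_that("the imaging chain is the identity for a null profile", {
  set.seed(31)
  v <- rand_volume(c(10, 10, 10), spacing = c(0.1, 0.1, 0.1))
  prof <- imaging_profile("custom", spacing = v$spacing, psf_fwhm = 0,
                          noise_sd = 0)
  out <- simulate_imaging(v, prof)
  expect_equal(out$values, v$values, tolerance = 1e-10)
  expect_error(simulate_imaging(out, imaging_profile("custom",
                                                     spacing = c(0.05, 0.1, 0.1))),
               "coarse")
})

test_that("partial-volume averaging conserves the mean without noise", {
  p <- trabecular_params(seed = 5)
  v <- generate_trabecular_model(p, extent = 4.5, resolution = 0.05)
  # commensurate grid (0.25 = 5 x 0.05): box averaging tiles exactly
  prof <- imaging_profile("custom", spacing = c(0.25, 0.25, 0.25),
                          psf_fwhm = 0.4, noise_sd = 0)
  out <- simulate_imaging(v, prof)
  expect_lt(abs(mean(out$values) - mean(v$values)) / mean(v$values), 0.005)
})

test_that("added noise has the requested standard deviation", {
  flat <- volume3d(array(300, c(25, 25, 25)), spacing = c(0.1, 0.1, 0.1))
  prof <- imaging_profile("custom", spacing = c(0.1, 0.1, 0.1), psf_fwhm = 0,
                          noise_sd = 30)
  out <- simulate_imaging(flat, prof, seed = 8)
  expect_equal(mean(out$values), 300, tolerance = 1)
  expect_lt(abs(pop_sd(as.vector(out$values)) - 30) / 30, 0.05)
  expect_error(simulate_imaging(flat, prof), "seed")
  # determinism given seed
  out2 <- simulate_imaging(flat, prof, seed = 8)
  expect_identical(out$values, out2$values)
})

test_that("the knee phantom is one closed body with a denser shell", {
  spec <- small_phantom_spec(seed = 4)
  ph <- generate_knee_phantom(spec)
  d <- dim(ph$bone_mask$values)
  cc <- trabtex:::cpp_cc_label(as.integer(ph$bone_mask$values), d)
  expect_length(cc$sizes, 1L)   # one 6-connected component
  # interior strictly less dense than the cortical shell
  din <- sqrt(trabtex:::cpp_edt_sq(as.integer(ph$bone_mask$values == 0L), d,
                                   ph$bone_mask$spacing))
  shell <- ph$bone_mask$values == 1L & din <= spec$cortical_thickness
  interior <- ph$bone_mask$values == 1L & din > spec$cortical_thickness
  expect_lt(mean(ph$truth$values[interior]), mean(ph$truth$values[shell]))
  # deterministic regeneration
  ph2 <- generate_knee_phantom(spec)
  expect_identical(ph$truth$values, ph2$truth$values)
  expect_error(knee_phantom_spec(cortical_thickness = 0.05, resolution = 0.12),
               "voxel")
  # tibia variant mirrors the shaft axis
  expect_equal(generate_knee_phantom(small_phantom_spec(seed = 4, bone = "tibia")
                                     )$geometry$shaft_axis, c(0, 0, -1))
})
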