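test_that("dice ratio matches brute-force voxel counting", {
  a <- array(FALSE, c(6, 6, 6)); a[2:3, 2:3, 2:3] <- TRUE
  b <- array(FALSE, c(6, 6, 6)); b[3:4, 2:3, 2:3] <- TRUE
  ma <- mask3d(a, c(1, 1, 1)); mb <- mask3d(b, c(1, 1, 1))
  expect_equal(dice_ratio(ma, mb), 2 * 4 / (8 + 8))   # one-voxel x shift
  expect_equal(dice_ratio(ma, ma), 1.0)
  expect_equal(dice_ratio(ma, mb), dice_ratio(mb, ma))
  disj <- mask3d(array(c(TRUE, rep(FALSE, 215)), c(6, 6, 6)), c(1, 1, 1))
  other <- mask3d(array(c(FALSE, TRUE, rep(FALSE, 214)), c(6, 6, 6)), c(1, 1, 1))
  expect_equal(dice_ratio(disj, other), 0)
  empty <- mask3d(array(FALSE, c(6, 6, 6)), c(1, 1, 1))
  expect_error(dice_ratio(empty, empty), "undefined")
})

# one phantom + one simulated acquisition reused across the blocks below
ph <- generate_knee_phantom(small_phantom_spec(seed = 6))
img <- simulate_imaging(ph$truth, small_hr_profile(noise_sd = 10), seed = 61)

test_that("periosteal segmentation recovers the phantom body", {
  seg <- segment_periosteal(img, threshold = 300, closing_radius = 0.6)
  truth_on_grid <- transfer_vois(voi_set(list(femur.S1.medial = ph$bone_mask)),
                                 rigid_transform(), img)[[1]]
  expect_gte(dice_ratio(seg, truth_on_grid), 0.95)

  # thresholding is monotone before morphology
  v_thr <- function(thr) sum(img$values >= thr)
  thrs <- c(100, 200, 300, 500, 800)
  expect_true(all(diff(vapply(thrs, v_thr, numeric(1))) <= 0))

  flat <- volume3d(array(30, c(8, 8, 8)), c(1, 1, 1), unit_tag = "bmd")
  expect_error(segment_periosteal(flat, 300), "failure")
  expect_error(segment_periosteal(volume3d(array(1, c(4, 4, 4)), c(1, 1, 1)),
                                  300), "BMD")
})

test_that("define_vois builds 8 disjoint VOIs per bone, 16 per knee", {
  seg <- segment_periosteal(img, threshold = 300, closing_radius = 0.6)
  vois <- define_vois(seg, ph$geometry$shaft_axis, ph$geometry$growth_plate,
                      cortical_thickness = 0.8,
                      side_plane = ph$geometry$side_plane, bone = "femur")
  expect_length(vois, 8L)
  expect_setequal(names(vois), voi_names("femur"))

  # pairwise disjoint
  nm <- names(vois)
  for (i in seq_along(nm)) for (j in seq_along(nm)) if (i < j)
    expect_equal(sum(vois[[i]]$values & vois[[j]]$values), 0L,
                 info = paste(nm[i], nm[j]))

  # mirror symmetry of the phantom: medial/lateral counts within 1% when the
  # VOIs come from the (noise-free, fine-grid) ground-truth mask; the coarse
  # segmented grid adds up to a one-column imbalance on top
  vois_truth <- define_vois(ph$bone_mask, ph$geometry$shaft_axis,
                            ph$geometry$growth_plate, 0.8,
                            ph$geometry$side_plane, bone = "femur")
  for (layer in c("S1", "S2", "S3")) {
    nmed <- sum(vois_truth[[paste0("femur.", layer, ".medial")]]$values)
    nlat <- sum(vois_truth[[paste0("femur.", layer, ".lateral")]]$values)
    expect_lt(abs(nmed - nlat) / max(nmed, nlat), 0.01)
  }

  # a full knee = femur + tibia = 16 VOIs
  pht <- generate_knee_phantom(small_phantom_spec(seed = 6, bone = "tibia"))
  imgt <- simulate_imaging(pht$truth, small_hr_profile(noise_sd = 10), seed = 62)
  segt <- segment_periosteal(imgt, threshold = 300, closing_radius = 0.6)
  voist <- define_vois(segt, pht$geometry$shaft_axis, pht$geometry$growth_plate,
                       0.8, pht$geometry$side_plane, bone = "tibia")
  knee <- voi_set(c(unclass(vois), unclass(voist)), check_complete = TRUE)
  expect_length(knee, 16L)

  # moving the growth plate toward the joint shrinks the trabecular total
  gp2 <- ph$geometry$growth_plate
  gp2$point[3] <- gp2$point[3] - 1.5
  vois2 <- define_vois(seg, ph$geometry$shaft_axis, gp2, 0.8,
                       ph$geometry$side_plane, bone = "femur")
  tot <- function(vs) sum(vapply(vs[grep("S[123]", names(vs))],
                                 function(m) sum(m$values), numeric(1)))
  expect_lt(tot(vois2), tot(vois))

  # a plane that misses the bone is rejected
  gp3 <- ph$geometry$growth_plate
  gp3$point[3] <- 100
  expect_error(define_vois(seg, ph$geometry$shaft_axis, gp3, 0.8,
                           ph$geometry$side_plane), "intersect")
})

test_that("transfer_vois maps masks between grids and conserves volume", {
  seg <- segment_periosteal(img, threshold = 300, closing_radius = 0.6)
  vois <- define_vois(seg, ph$geometry$shaft_axis, ph$geometry$growth_plate,
                      0.8, ph$geometry$side_plane, bone = "femur")
  # identity transfer onto the same grid is a no-op
  same <- transfer_vois(vois, rigid_transform(), img)
  for (nm in names(vois))
    expect_identical(same[[nm]]$values, vois[[nm]]$values)

  # onto a 3x finer grid the voxel count scales by ~27
  fine <- resample_volume(img, img$spacing / 3)
  fine_vois <- transfer_vois(vois, rigid_transform(), fine)
  for (nm in c("femur.S2.medial", "femur.S3.lateral")) {
    ratio <- sum(fine_vois[[nm]]$values) / sum(vois[[nm]]$values)
    expect_lt(abs(ratio - 27) / 27, 0.05)
  }

  # transfer then inverse-transfer keeps each VOI nearly intact
  tr <- rigid_transform(c(1.5, -1, 2) * pi / 180, c(0.6, 0.4, -0.5),
                        center = colMeans(trabtex:::surface_points(seg, 4000)))
  there <- transfer_vois(vois, tr, img)
  back <- transfer_vois(there, invert_transform(tr), img)
  for (nm in c("femur.S2.medial", "femur.S3.lateral"))
    expect_gte(dice_ratio(back[[nm]], vois[[nm]]), 0.9)

  # a transform that moves the VOIs out of the grid empties them
  far <- rigid_transform(translation = c(500, 0, 0))
  expect_error(transfer_vois(vois, far, img), "empty after transfer")
})
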