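test_that("mask volume is exact integer arithmetic times voxel volume", {
  m <- array(FALSE, c(20, 20, 20)); m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(measure_volume(m, c(0.091, 0.091, 0.091)), 1000 * 0.091^3)
  expect_equal(1000 * 0.091^3, 0.7536, tolerance = 1e-4)
  expect_equal(measure_volume(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), 0)
  expect_equal(measure_volume(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)),
                              c(1, 1, 1)), 1.0)
  expect_error(measure_volume(m, c(0, 1, 1)), "positive")
})

test_that("CT segmentation recovers sphere volume and rejects empty images", {
  spec <- single_sphere_spec(6.23, 198)
  acq <- tight_acq(spec)
  ct <- simulate_ct(rasterize_phantom(spec, acq)$material_map, acq)
  seg <- segment_thyroid_ct(ct)
  expect_false(seg$empty)
  expect_equal(seg$n_components, 1L)
  expect_lt(abs(seg$volume_uL / (pi / 6 * 6.23^3) - 1), 0.02)
  # all-water image yields an explicit empty result, not an exception
  water <- voxel_image(array(0.1, c(10, 10, 10)), rep(0.2, 3),
                       units = "contrast_index")
  seg_w <- segment_thyroid_ct(water)
  expect_true(seg_w$empty)
  expect_equal(seg_w$volume_uL, 0)
})

test_that("two lobes beside an air tube segment as two components", {
  sph <- data.frame(cx = c(-4, 4), cy = 0, cz = 15,
                    inner_diameter_mm = 3.95, activity_kBq = 140,
                    contrast = TRUE)
  spec <- phantom_spec(cylinder_height_mm = 30, spheres = sph,
                       trachea = list(cx = 0, cy = 0, diameter_mm = 2))
  acq <- acquisition_model(
    ct_fov = list(origin = c(-6.5, -2.5, 12.5), size = c(13, 5, 5)))
  ct <- simulate_ct(rasterize_phantom(spec, acq)$material_map, acq)
  seg <- segment_thyroid_ct(ct)
  expect_equal(seg$n_components, 2L)
  # the air tube sits below the threshold: total volume is two lobes only
  expect_lt(abs(seg$volume_uL / (2 * pi / 6 * 3.95^3) - 1), 0.02)
})

test_that("CT-grid masks map onto the PET grid preserving volume", {
  pet <- voxel_image(array(0, c(20, 20, 20)), c(0.87, 0.87, 0.79))
  # CT grid covering exactly one interior PET voxel footprint
  ct <- voxel_image(array(0, c(100, 100, 100)), c(0.087, 0.087, 0.079),
                    origin = c(0.87 * 5, 0.87 * 5, 0.79 * 5))
  mask <- array(FALSE, dim(ct$data))
  mask[11:20, 11:20, 11:20] <- TRUE   # the footprint of PET voxel (7,7,7)
  out <- map_roi_to_pet(mask, ct, pet)
  expect_equal(sum(out), 1L)
  expect_true(out[7, 7, 7])
  # empty in, empty out
  expect_equal(sum(map_roi_to_pet(array(FALSE, dim(ct$data)), ct, pet)), 0L)
  # degenerate transform rejected
  expect_error(map_roi_to_pet(mask, ct, pet,
                              transform = list(R = diag(3) * 2, t = c(0, 0, 0))),
               "degenerate")
})

test_that("a CT sphere mask keeps its volume through majority resampling", {
  spec <- single_sphere_spec(6.23, 198, center = c(0, 0, 15))
  acq <- tight_acq(spec)
  maps <- rasterize_phantom(spec, acq)
  ct <- simulate_ct(maps$material_map, acq)
  seg <- segment_thyroid_ct(ct)
  pet_mask <- map_roi_to_pet(seg$mask, ct, maps$activity_map)
  vol_pet <- measure_volume(pet_mask, maps$activity_map$spacing)
  # majority resampling quantizes at the boundary: volume preserved to ~2%
  expect_lt(abs(vol_pet / seg$volume_uL - 1), 0.02)
})

test_that("ROI set geometry follows the fixed-width construction", {
  d <- c(60, 21, 60)
  mask <- array(FALSE, d); mask[30, 11, 30] <- TRUE
  pet <- voxel_image(array(0, d), c(0.87, 0.87, 0.79))
  rois <- build_roi_set(mask, pet, x_width = 20, y_width = 7, gap = 1,
                        margin = 5)
  # per-plane window is 20 x 20 for a single-voxel thyroid
  planes <- which(apply(rois$roi_x, 2, any))
  expect_equal(length(planes), 11L)          # 1 + 2 * margin
  expect_equal(sum(rois$roi_x[, planes[1], ]), 20L * 20L)
  expect_equal(sum(rois$roi_y[, planes[1], ]), 7L * 20L)
  expect_true(all(rois$roi_x[rois$roi_z]))
  expect_false(any(rois$roi_x & rois$roi_y))
  # thyroid at the image edge cannot host the window
  edge <- array(FALSE, d); edge[2, 11, 30] <- TRUE
  expect_error(build_roi_set(edge, pet), "bounds")
  expect_error(build_roi_set(array(FALSE, d), pet), "empty")
})

test_that("compensated activity recovers truth under uniform background", {
  # randomized constructions: T inside Z plus constant background outside Z
  set.seed(21)
  for (rep in 1:20) {
    d <- c(50, 11, 50)
    pet <- voxel_image(array(0, d), c(1, 1, 1))   # 1 uL voxels
    mask <- array(FALSE, d)
    mask[23:27, 5:7, 23:27] <- TRUE
    n_z <- sum(mask)
    T_kBq <- runif(1, 10, 200)
    c_bq <- runif(1, 0, 5000)                     # per-voxel background Bq/mL
    pet$data[mask] <- T_kBq * 1e6 / (n_z * prod(pet$spacing) / 1000) / 1000
    pet$data[!mask] <- c_bq
    rois <- build_roi_set(mask, pet, margin = 2)
    q <- quantify_thyroid_activity(pet, rois)
    expect_equal(q$A_thyr_kBq, T_kBq, tolerance = 1e-10)
  }
})

test_that("zero background reduces the compensation to the enclosing sum", {
  d <- c(50, 11, 50)
  pet <- voxel_image(array(0, d), c(1, 1, 1))
  mask <- array(FALSE, d); mask[24:26, 5:7, 24:26] <- TRUE
  pet$data[mask] <- 1e5
  rois <- build_roi_set(mask, pet, margin = 2)
  q <- quantify_thyroid_activity(pet, rois)
  expect_equal(q$A_thyr_kBq, q$A_x_kBq)
  expect_equal(q$A_y_kBq, 0)
})

test_that("background inside the outline biases the estimate by c * n_z", {
  # the compensation only subtracts over n_x - n_z pixels: ambient background
  # present inside Z remains, overestimating by exactly c * n_z
  d <- c(50, 11, 50)
  pet <- voxel_image(array(0, d), c(1, 1, 1))
  mask <- array(FALSE, d); mask[23:27, 5:7, 23:27] <- TRUE
  n_z <- sum(mask)
  T_kBq <- 100; c_bq <- 2000
  pet$data[mask] <- T_kBq * 1e6 / n_z + c_bq   # background everywhere
  pet$data[!mask] <- c_bq
  rois <- build_roi_set(mask, pet, margin = 2)
  q <- quantify_thyroid_activity(pet, rois)
  c_kBq_per_voxel <- c_bq * prod(pet$spacing) / 1e3 / 1e3
  expect_equal(q$A_thyr_kBq, T_kBq + c_kBq_per_voxel * n_z, tolerance = 1e-10)
})

test_that("negative compensated activity clamps to zero with a warning", {
  d <- c(50, 11, 50)
  pet <- voxel_image(array(0, d), c(1, 1, 1))
  mask <- array(FALSE, d); mask[24:26, 5:7, 24:26] <- TRUE
  rois <- build_roi_set(mask, pet, margin = 2)
  pet$data[rois$roi_y] <- 1000   # background band hotter than the window
  expect_warning(q <- quantify_thyroid_activity(pet, rois), "clamped")
  expect_equal(q$A_thyr_kBq, 0)
  expect_true(q$clamped)
})
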