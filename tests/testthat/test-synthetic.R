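test_that("phantom specification enforces its geometric invariants", {
  expect_s3_class(default_phantom_spec(), "phantom_spec")
  # overlapping spheres rejected
  sph <- data.frame(cx = c(0, 1), cy = 0, cz = 15,
                    inner_diameter_mm = 4, activity_kBq = 10, contrast = TRUE)
  expect_error(phantom_spec(spheres = sph, trachea = NULL), "overlap")
  # sphere poking out of the cylinder rejected
  sph2 <- data.frame(cx = 14, cy = 0, cz = 15, inner_diameter_mm = 4,
                     activity_kBq = 10, contrast = TRUE)
  expect_error(phantom_spec(spheres = sph2, trachea = NULL), "inside")
  # sphere on the trachea rejected
  sph3 <- data.frame(cx = 2, cy = 0, cz = 15, inner_diameter_mm = 4,
                     activity_kBq = 10, contrast = TRUE)
  expect_error(phantom_spec(cylinder_height_mm = 30, spheres = sph3),
               "trachea")
})

test_that("rasterized activity matches the analytic sphere volumes", {
  # analytic inner volumes from the printed inner diameters
  expect_equal(pi / 6 * 3.95^3, 32.27, tolerance = 1e-4)
  expect_equal(pi / 6 * 7.86^3, 254.3, tolerance = 1e-3)
  spec <- single_sphere_spec(7.86, 1765)
  acq <- tight_acq(spec)
  maps <- rasterize_phantom(spec, acq)
  # concentration level inside the sphere: activity / analytic volume
  conc_kBq_uL <- max(maps$activity_map$data) / 1e6
  expect_equal(conc_kBq_uL, 1765 / (pi / 6 * 7.86^3), tolerance = 1e-6)
  expect_equal(conc_kBq_uL, 6.94, tolerance = 1e-3)
  # total activity on the grid within 0.5% of the fill
  tot_kBq <- sum(maps$activity_map$data) *
    voxel_volume(maps$activity_map, "mL") / 1000
  expect_lt(abs(tot_kBq / 1765 - 1), 0.005)
})

test_that("zero-activity spheres contribute nothing", {
  spec <- single_sphere_spec(6.23, 0)
  maps <- rasterize_phantom(spec, tight_acq(spec))
  expect_true(all(maps$activity_map$data == 0))
})

test_that("rasterized sphere volume converges with supersampling", {
  spec <- single_sphere_spec(3.95, 140)
  for (ss in c(4L, 8L)) {
    maps <- rasterize_phantom(spec, tight_acq(spec, supersampling = ss))
    tot <- sum(maps$activity_map$data) *
      voxel_volume(maps$activity_map, "mL") / 1000
    expect_lt(abs(tot / 140 - 1), 0.005)
  }
})

test_that("PET simulation with no blur and no noise is the identity", {
  spec <- single_sphere_spec(6.23, 198)
  acq <- tight_acq(spec, psf_fwhm_mm = 0, positron_blur_mm = 0)
  maps <- rasterize_phantom(spec, acq)
  pet <- simulate_pet(maps$activity_map, acq)
  expect_lt(max(abs(pet$data - maps$activity_map$data)),
            1e-9 * max(maps$activity_map$data))
})

test_that("PET blur has the configured Gaussian width and conserves activity", {
  # point source on an empty grid
  arr <- array(0, c(41, 41, 41))
  arr[21, 21, 21] <- 1000
  img <- voxel_image(arr, c(0.5, 0.5, 0.5))
  acq <- acquisition_model(psf_fwhm_mm = 1.7, positron_blur_mm = 0)
  out <- simulate_pet(img, acq)
  # second-moment estimate of sigma along x through the center
  x <- voxel_centers(img, 1)
  w <- apply(out$data, 1, sum)
  mu <- sum(w * x) / sum(w)
  sigma <- sqrt(sum(w * (x - mu)^2) / sum(w))
  expect_equal(sigma, 1.7 / (2 * sqrt(2 * log(2))), tolerance = 0.02)
  expect_equal(sigma, 0.722, tolerance = 0.02)
  # conservation for an interior source
  expect_lt(abs(sum(out$data) / sum(img$data) - 1), 1e-3)
})

test_that("blurred phantom keeps total activity in a generous bounding region", {
  spec <- single_sphere_spec(6.23, 198)
  acq <- tight_acq(spec)
  maps <- rasterize_phantom(spec, acq)
  pet <- simulate_pet(maps$activity_map, acq)
  tot <- sum(pet$data) * voxel_volume(pet, "mL") / 1000
  expect_lt(abs(tot / 198 - 1), 0.01)
})

test_that("Poisson PET noise is seed-reproducible and unbiased at high counts", {
  spec <- single_sphere_spec(6.23, 198)
  acq <- tight_acq(spec, pet_noise = "poisson", sensitivity = 5)
  maps <- rasterize_phantom(spec, acq)
  a <- simulate_pet(maps$activity_map, acq, seed = 99)
  b <- simulate_pet(maps$activity_map, acq, seed = 99)
  expect_identical(a$data, b$data)
  c <- simulate_pet(maps$activity_map, acq, seed = 100)
  expect_false(identical(a$data, c$data))
  tot <- sum(a$data) * voxel_volume(a, "mL") / 1000
  expect_lt(abs(tot / 198 - 1), 0.02)
})

test_that("CT simulation produces the three material intensity levels", {
  spec <- single_sphere_spec(6.23, 198)
  acq <- tight_acq(spec)
  maps <- rasterize_phantom(spec, acq)
  ct <- simulate_ct(maps$material_map, acq)
  expect_setequal(unique(as.vector(ct$data)), c(0.1, 1.0))  # no air in FOV
  # all-water map is constant at the water level
  water <- voxel_image(array(1L, c(5, 5, 5)), rep(1, 3), units = "label")
  ct_w <- simulate_ct(water, acq)
  expect_true(all(ct_w$data == 0.1))
  # noisy version is deterministic per seed
  acq$ct_noise_sd <- 0.05
  n1 <- simulate_ct(maps$material_map, acq, seed = 3)
  n2 <- simulate_ct(maps$material_map, acq, seed = 3)
  expect_identical(n1$data, n2$data)
})

test_that("thresholding a noiseless contrast sphere recovers its volume", {
  spec <- single_sphere_spec(6.23, 198)
  acq <- tight_acq(spec)
  ct <- simulate_ct(rasterize_phantom(spec, acq)$material_map, acq)
  vol <- measure_volume(ct$data > 0.5, ct$spacing)
  expect_lt(abs(vol / 126.6 - 1), 0.02)
})

test_that("subject TAC generator matches its closed-form kinetics", {
  p <- kinetic_params(6.2, 0.15, 0.00421)
  # biological peak time: closed form vs dense grid search, near 24 h
  tp <- tac_peak_time(0.15, 0.00421)
  expect_equal(tp, 24.0, tolerance = 0.002)
  grid <- seq(0.01, 200, by = 0.01)
  bio <- (1 - exp(-0.15 * grid)) * exp(-0.00421 * grid)
  expect_equal(grid[which.max(bio)], tp, tolerance = 0.01)
  # zero at t = 0, peak scaling
  tac <- generate_subject_tac(p, 21.5, c(0, 3, 24, 48, 72))
  expect_equal(tac$activity_MBq[1], 0)
  nuc <- iodine124()
  bio_curve <- tac$true_MBq / decay_factor(tac$t_h, nuc)
  expect_equal(max(bio_curve), 0.062 * 21.5, tolerance = 1e-3)
  expect_equal(0.062 * 21.5, 1.333, tolerance = 1e-3)
})

test_that("TAC noise is reproducible and guarded", {
  p <- kinetic_params(5, 0.15, 0.004)
  a <- generate_subject_tac(p, 10, c(3, 24, 48, 72), noise_cv = 0.05, seed = 7)
  b <- generate_subject_tac(p, 10, c(3, 24, 48, 72), noise_cv = 0.05, seed = 7)
  expect_identical(a$activity_MBq, b$activity_MBq)
  expect_error(generate_subject_tac(p, 10, c(3, 24), noise_cv = -0.1), "noise_cv")
  expect_error(generate_subject_tac(p, 10, c(24, 3)), "increasing")
})

test_that("default cohort reproduces the study roster and uptake band", {
  co <- default_cohort(seed = 5)
  expect_equal(nrow(co$subjects), 7)
  expect_equal(co$subjects$administered_MBq[7], 0.70)
  expect_equal(co$subjects$weight_g, c(360, 372, 354, 394, 389, 533, 501))
  # noiseless peak fractions verified by grid search of each generated curve
  grid <- seq(0.01, 300, by = 0.05)
  for (i in seq_len(7)) {
    with(co$subjects[i, ], {
      bio <- (1 - exp(-k_u * grid)) * exp(-k_b * grid)
      tpk <- grid[which.max(bio)]
      expect_gt(tpk, 21.9); expect_lt(tpk, 26.1)
    })
    expect_gte(co$subjects$peak_fraction[i], 4.0)
    expect_lte(co$subjects$peak_fraction[i], 6.2)
  }
  # cohort CSV round trip
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(nrow(back), 28)
  expect_true(all(c("subject_id", "t_h", "activity_MBq", "weight_g") %in%
                  names(back)))
  unlink(path)
})
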