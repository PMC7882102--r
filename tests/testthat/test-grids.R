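# Grid data model, rigid resampling, morphology, calibration, container I/O.

test_that("constructors enforce the grid invariants", {
  expect_error(image_volume(array(0, c(4, 4, 4)), c(0, 2, 2), c(0, 0, 0)),
               "positive")
  expect_error(image_volume(array(NaN, c(4, 4, 4)), c(2, 2, 2), c(0, 0, 0)),
               "finite")
  expect_error(dose_grid(array(-1, c(4, 4, 4)), c(2, 2, 2), c(0, 0, 0)),
               "non-negative")
  expect_error(rigid_transform(t = c(Inf, 0, 0)), "finite")
  v <- image_volume(array(1, c(4, 4, 4)), c(1, 2, 3), c(-1, -2, -3))
  expect_equal(v$spacing, c(1, 2, 3))
})

test_that("rigid transform inverse undoes the forward map to 1e-9 mm", {
  tr <- rigid_transform(t = c(1.5, -2, 0.7), r = c(1.2, -0.8, 2),
                        center = c(10, -5, 3))
  pts <- matrix(rnorm(60, sd = 40), 20, 3)
  fwd <- transform_points(tr, pts)
  back <- inverse_points(tr, fwd)
  expect_lt(max(abs(back - pts)), 1e-9)
  # identity leaves points untouched
  expect_equal(transform_points(rigid_transform(), pts), pts)
})

test_that("identity resampling is bit-identical and integer shifts match array rolls", {
  dose <- uniform_dose(0, dim = c(16, 16, 12))
  arr <- array(0, dim(dose$dose))
  arr[5:12, 5:12, 4:9] <- rexp(8 * 8 * 6, 1 / 20)
  dose$dose <- arr
  expect_identical(resample_dose(dose, rigid_transform())$dose, arr)
  # translate by exactly one voxel along x: values move one index up
  sh <- resample_dose(dose, rigid_transform(t = c(dose$spacing[1], 0, 0)))
  roll <- array(0, dim(arr))
  roll[2:16, , ] <- arr[1:15, , ]
  expect_equal(sh$dose, roll, tolerance = 1e-12)
})

test_that("uniform dose interior is invariant under small shifts", {
  dose <- uniform_dose(50.4, dim = c(24, 24, 16))
  out <- resample_dose(dose, rigid_transform(t = c(2, 0, 0)))
  core <- out$dose[6:19, 6:19, 5:12]
  expect_equal(max(abs(core - 50.4)), 0, tolerance = 1e-12)
  expect_lte(max(out$dose), max(dose$dose))
  expect_gte(min(out$dose), 0)
})

test_that("resampling respects the energy bound and round-trips smooth doses", {
  # compact interior support: pure translation preserves total energy to
  # floating-point accuracy (trilinear weights partition unity)
  dim3 <- c(28, 28, 20)
  org <- -(dim3 - 1) / 2 * 2
  ax <- lapply(1:3, function(a) org[a] + (seq_len(dim3[a]) - 1) * 2)
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  blob <- 50 * exp(-r2 / (2 * 8^2))
  blob[r2 > 16^2] <- 0
  dose <- dose_grid(blob, c(2, 2, 2), org)
  sh <- resample_dose(dose, rigid_transform(t = c(1.4, -0.9, 0.6)))
  expect_lt(abs(sum(sh$dose) - sum(dose$dose)) / sum(dose$dose), 1e-6)
  # a band-limited (wide Gaussian) dose: rotation+translation keeps the sum
  # within the energy bound up to boundary leakage, and the round trip
  # reproduces the original within 1% of max dose
  dim3 <- c(64, 64, 64)
  org <- -(dim3 - 1) / 2 * 2
  ax <- lapply(1:3, function(a) org[a] + (seq_len(dim3[a]) - 1) * 2)
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  smooth <- 50 * exp(-r2 / (2 * 18^2))
  dose <- dose_grid(smooth, c(2, 2, 2), org)
  tr <- rigid_transform(t = c(1.4, -0.9, 0.6), r = c(1.1, 0.7, -1.6))
  fwd <- resample_dose(dose, tr)
  expect_lte(sum(fwd$dose), sum(dose$dose) * (1 + 1e-3))
  back <- resample_dose(fwd, rigid_transform(t = -tr$t, r = -tr$r))
  # note: rotation inverses do not exactly compose by negation, but at
  # <= 2 degrees the residual is far below the 1% interpolation allowance
  expect_lt(max(abs(back$dose - dose$dose)), 0.01 * max(dose$dose))
})

test_that("body expansion matches the analytic sphere volume and clips at edges", {
  dim3 <- c(75, 75, 75)
  sp <- c(2, 2, 2)
  sphere <- box_mask("tmp", c(1, 1, 1), dim3, sp)  # placeholder grid
  org <- sphere$origin
  ax <- lapply(1:3, function(a) org[a] + (seq_len(dim3[a]) - 1) * sp[a])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  body <- structure_mask("body", r2 <= 50^2, sp, org)
  grown <- expand_body_region(body, 20)
  vol <- sum(grown$mask) * prod(sp)
  expect_equal(vol, 4 / 3 * pi * 70^3, tolerance = 0.02)
  expect_true(all(grown$mask[body$mask]))          # output contains input
  expect_identical(expand_body_region(body, 0), body)
  expect_error(expand_body_region(body, -1), "non-negative")
  # touching the grid edge clips without error
  edge <- structure_mask("edge", r2 <= 70^2, sp, org)
  expect_silent(grown2 <- expand_body_region(edge, 20))
  expect_equal(sum(grown2$mask[1, , ]) > 0, TRUE)
})

test_that("HU-to-density curves interpolate, clamp and stay monotone", {
  curve <- hu_density_curve(c(-1000, 0, 1000), c(0, 1, 1.5), "test")
  expect_equal(eval_hu_curve(curve, 0), 1)
  expect_equal(eval_hu_curve(curve, 500), 1.25)
  expect_equal(eval_hu_curve(curve, 2000), 1.5)   # clamped
  expect_equal(eval_hu_curve(curve, -5000), 0)    # clamped low
  hu <- sort(runif(200, -2000, 3000))
  expect_true(all(diff(eval_hu_curve(curve, hu)) >= 0))
  expect_error(hu_density_curve(c(0, 0), c(1, 1)), "calibration")
  expect_error(hu_density_curve(c(0, 10), c(1, 0.5)), "calibration")
  # out-of-FOV voxels are excluded (NA) by apply_hu_curve
  vox <- array(0, c(4, 4, 4))
  vox[1, 1, 1] <- HU_OUT_OF_FOV
  vol <- image_volume(vox, c(2, 2, 2), c(0, 0, 0), fov_radius_mm = 100)
  red <- apply_hu_curve(vol, curve)
  expect_true(is.na(red[1, 1, 1]))
  expect_equal(red[2, 2, 2], 1)
})

test_that("limited-FOV stitching keeps CBCT inside and planning CT outside", {
  dim3 <- c(40, 40, 10)
  sp <- c(4, 4, 4)
  org <- -(dim3 - 1) / 2 * sp
  ax <- lapply(1:2, function(a) org[a] + (seq_len(dim3[a]) - 1) * sp[a])
  r <- sqrt(outer(ax[[1]]^2, ax[[2]]^2, `+`))
  plan_hu <- array(rep(10, prod(dim3)), dim3)
  planning <- image_volume(plan_hu, sp, org)
  fov_r <- 60
  inside <- array(rep(r <= fov_r, dim3[3]), dim3)
  cb <- plan_hu + 100
  cb[!inside] <- HU_OUT_OF_FOV
  cbct <- image_volume(cb, sp, org, fov_radius_mm = fov_r)
  out <- stitch_limited_fov(cbct, planning, rigid_transform())
  expect_false(any(out$voxels == HU_OUT_OF_FOV))
  expect_true(all(out$voxels[inside] == 110))
  expect_true(all(out$voxels[!inside] == 10))
  # identical CBCT and planning with identity registration: equality everywhere
  cb2 <- plan_hu
  cb2[!inside] <- HU_OUT_OF_FOV
  cbct2 <- image_volume(cb2, sp, org, fov_radius_mm = fov_r)
  expect_equal(stitch_limited_fov(cbct2, planning, rigid_transform())$voxels,
               plan_hu)
  expect_error(stitch_limited_fov(planning, planning, rigid_transform()),
               "fov_radius_mm")
})

test_that("portable container round trips are bit-exact", {
  tmp <- tempfile("container")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  vol <- image_volume(array(rnorm(4 * 5 * 6, 0, 500), c(4, 5, 6)),
                      c(1.25, 2, 3), c(-10.5, 0, 4), fov_radius_mm = 130)
  f <- file.path(tmp, "vol.fvol")
  write_grid(vol, f)
  back <- read_grid(f)
  expect_identical(back$voxels, vol$voxels)
  expect_identical(back$spacing, vol$spacing)
  expect_identical(back$origin, vol$origin)
  expect_identical(back$fov_radius_mm, vol$fov_radius_mm)
  dose <- uniform_dose(1.8, dim = c(5, 4, 3))
  dose$dose[2, 2, 2] <- pi
  f2 <- file.path(tmp, "dose.fvol")
  write_grid(dose, f2)
  expect_identical(read_grid(f2)$dose, dose$dose)
  m <- box_mask("CTV", c(2, 2, 2), c(6, 6, 6), c(2, 2, 2))
  f3 <- file.path(tmp, "m.fvol")
  write_grid(m, f3)
  expect_identical(read_grid(f3)$mask, m$mask)
  expect_identical(read_grid(f3)$name, "CTV")
  # registrations
  tr <- rigid_transform(t = c(0.25, -1, 2), r = c(0.5, 0, -1.5),
                        center = c(1, 2, 3))
  f4 <- file.path(tmp, "reg.json")
  write_registration(tr, f4)
  tr2 <- read_registration(f4)
  expect_equal(tr2$t, tr$t)
  expect_equal(tr2$r, tr$r)
  expect_equal(tr2$center, tr$center)
})
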