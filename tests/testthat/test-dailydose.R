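# Path-length dose perturbation, accumulation, DSC, deformation, paired test.

test_that("radiological depth reproduces analytic piecewise-constant integrals", {
  w <- slab_world()
  src <- c(0, 1000, 0)
  pt <- matrix(c(0, 0, 0), 1, 3)
  # from the body surface (y = 50 + half voxel) to the origin: 52.5 mm of water
  d0 <- radiological_depth(w$density, w$spacing, w$origin, src, pt, step = 0.5)
  expect_equal(d0, 52.5, tolerance = 0.01)
  # air gap: remove 2 layers (10 mm) inside the body upstream of the point
  gap <- w$density
  gap[, w$yaxis %in% c(25, 30), ] <- 0
  d1 <- radiological_depth(gap, w$spacing, w$origin, src, pt, step = 0.5)
  expect_equal(d1, 42.5, tolerance = 0.01)
  # bone slab: density 1.5 over 2 layers adds 0.5 * 10 mm
  bone <- w$density
  bone[, w$yaxis %in% c(25, 30), ] <- 1.5
  d2 <- radiological_depth(bone, w$spacing, w$origin, src, pt, step = 0.5)
  expect_equal(d2, 57.5, tolerance = 0.01)
  # source inside the volume is a geometry error
  expect_error(radiological_depth(w$density, w$spacing, w$origin,
                                  c(0, 0, 0), pt), "geometry")
})

test_that("identical anatomies reproduce the planned dose bit-for-bit", {
  w <- slab_world()
  beams <- beam_model(n_beams = 7, isocenter = c(0, 0, 0))
  out <- fraction_dose_estimate(w$planned, w$density, w$density, beams,
                                region = w$ctv, step = 1)
  expect_identical(out$dose, w$planned$dose)
  expect_true(all(attr(out, "factor") == 1))
})

test_that("upstream tissue attenuates and upstream gas boosts by the closed form", {
  w <- slab_world()
  beam <- beam_model(n_beams = 1, isocenter = c(0, 0, 0))
  mu <- beam$mu_eff
  # 15 mm extra unit-density tissue above the body (3 layers at 5 mm)
  gain <- w$density
  gain[, w$yaxis %in% c(55, 60, 65), ] <- 1
  est <- fraction_dose_estimate(w$planned, w$density, gain, beam,
                                region = w$ctv, step = 0.5)
  ratio <- mean_dose(est, w$ctv) / mean_dose(w$planned, w$ctv)
  expect_equal(ratio, exp(-mu * 15), tolerance = 0.005)
  # 20 mm gas pocket inside the body upstream of the target (4 layers)
  gas <- w$density
  gas[, w$yaxis %in% c(25, 30, 35, 40), ] <- 0
  est2 <- fraction_dose_estimate(w$planned, w$density, gas, beam,
                                 region = w$ctv, step = 0.5)
  ratio2 <- mean_dose(est2, w$ctv) / mean_dose(w$planned, w$ctv)
  expect_equal(ratio2, exp(mu * 20), tolerance = 0.005)
})

test_that("dose perturbation is monotone in upstream thickness", {
  w <- slab_world()
  beam <- beam_model(n_beams = 1, isocenter = c(0, 0, 0))
  layers_y <- c(55, 60, 65, 70, 75)
  dmean <- vapply(seq_along(layers_y), function(n) {
    gain <- w$density
    gain[, w$yaxis %in% layers_y[seq_len(n)], ] <- 1
    mean_dose(fraction_dose_estimate(w$planned, w$density, gain, beam,
                                     region = w$ctv, step = 1), w$ctv)
  }, 0)
  expect_true(all(diff(dmean) < 0))  # more upstream tissue, strictly less dose
  dgas <- vapply(seq_along(layers_y), function(n) {
    gas <- w$density
    gas[, w$yaxis %in% (c(25, 30, 35, 40, 45)[seq_len(n)]), ] <- 0
    mean_dose(fraction_dose_estimate(w$planned, w$density, gas, beam,
                                     region = w$ctv, step = 1), w$ctv)
  }, 0)
  expect_true(all(diff(dgas) > 0))   # more gas, strictly more dose
})

test_that("fraction comparison reports scaling differences with the plan sign convention", {
  w <- slab_world()
  frac_planned <- dose_grid(w$planned$dose / 28, w$spacing, w$origin)
  scaled <- dose_grid(frac_planned$dose * 0.98, w$spacing, w$origin)
  rec <- fraction_record(1, scaled)
  cmp <- compare_fraction(frac_planned, rec, list(w$ctv))
  expect_equal(cmp$dd98, 2, tolerance = 1e-9)
  expect_equal(cmp$dd2, 2, tolerance = 1e-9)
  # identical doses: exact zeros
  cmp0 <- compare_fraction(frac_planned, fraction_record(2, frac_planned),
                           list(w$ctv))
  expect_identical(cmp0$dd98, 0)
  # excluded records are skipped with their reason
  exrec <- fraction_record(3, scaled, excluded = TRUE, reason = "corrupt")
  expect_message(out <- compare_fraction(frac_planned, exrec, list(w$ctv)),
                 "corrupt")
  expect_true(out$excluded)
})

test_that("accumulation conserves identical fractions and scales for exclusions", {
  w <- slab_world()
  frac <- dose_grid(w$planned$dose / 28, w$spacing, w$origin)
  recs <- lapply(1:28, function(k) fraction_record(k, frac))
  acc <- accumulate_rigid(recs, w$planned, rois = list(w$ctv))
  expect_equal(acc$dose$dose, w$planned$dose, tolerance = 1e-9)
  expect_equal(acc$per_roi$dd98, 0, tolerance = 1e-9)
  # +/- 2% alternating fractions cancel exactly on accumulation
  up <- dose_grid(frac$dose * 1.02, w$spacing, w$origin)
  dn <- dose_grid(frac$dose * 0.98, w$spacing, w$origin)
  recs2 <- lapply(1:28, function(k) fraction_record(k, if (k %% 2) up else dn))
  acc2 <- accumulate_rigid(recs2, w$planned, rois = list(w$ctv))
  expect_equal(acc2$per_roi$dd98, 0, tolerance = 1e-9)
  # 6 exclusions: scale 28/22 and the excluded indices are logged
  recs3 <- lapply(1:28, function(k)
    fraction_record(k, frac, excluded = k <= 6, reason = "data corruption"))
  acc3 <- accumulate_rigid(recs3, w$planned)
  expect_equal(acc3$scale, 28 / 22)
  expect_equal(acc3$excluded, 1:6)
  expect_equal(acc3$dose$dose, w$planned$dose, tolerance = 1e-9)
  expect_error(accumulate_rigid(list(
    fraction_record(1, frac, excluded = TRUE, reason = "x")), w$planned),
    "empty course")
})

test_that("accumulation is linear in the fraction doses", {
  w <- slab_world(dim = c(20, 20, 10))
  set.seed(8)
  mk <- function(c0) {
    arr <- array(rexp(prod(w$dim), 1), w$dim) * c0
    dose_grid(arr, w$spacing, w$origin)
  }
  base <- lapply(1:5, function(k) mk(1))
  recs1 <- lapply(seq_along(base), function(k)
    fraction_record(k, base[[k]]))
  recs3 <- lapply(seq_along(base), function(k)
    fraction_record(k, dose_grid(base[[k]]$dose * 3, w$spacing, w$origin)))
  a1 <- accumulate_rigid(recs1, w$planned)
  a3 <- accumulate_rigid(recs3, w$planned)
  expect_equal(a3$dose$dose, 3 * a1$dose$dose, tolerance = 1e-12)
})

test_that("Dice coefficient handles identity, disjoint and half-overlap exactly", {
  dim3 <- c(30, 30, 15); sp <- c(2, 2, 2)
  cube <- box_mask("a", c(9, 9, 9), dim3, sp)
  expect_identical(dice_coefficient(cube, cube), 1)
  far <- box_mask("b", c(4, 4, 4), dim3, sp, center = c(20, 20, 0))
  near <- box_mask("c", c(4, 4, 4), dim3, sp, center = c(-20, -20, 0))
  expect_identical(dice_coefficient(far, near), 0)
  # 10-voxel cube shifted by 5 voxels: overlap 500 of 1000 -> DSC 0.5
  m1 <- array(FALSE, dim3); m1[1:10, 1:10, 1:10] <- TRUE
  m2 <- array(FALSE, dim3); m2[6:15, 1:10, 1:10] <- TRUE
  s1 <- structure_mask("s1", m1, sp, c(0, 0, 0))
  s2 <- structure_mask("s2", m2, sp, c(0, 0, 0))
  expect_identical(dice_coefficient(s1, s2), 0.5)
  expect_identical(dice_coefficient(s1, s2), dice_coefficient(s2, s1))
  e <- structure_mask("e", array(FALSE, dim3), sp, c(0, 0, 0))
  expect_error(dice_coefficient(e, e), "degenerate")
})

test_that("deformation pull-back matches shift and analytic-warp oracles", {
  dim3 <- c(20, 20, 12); sp <- c(2, 2, 2)
  org <- -(dim3 - 1) / 2 * sp
  set.seed(3)
  arr <- array(0, dim3)
  arr[6:15, 6:15, 4:9] <- rexp(600, 1 / 10)
  dose <- dose_grid(arr, sp, org)
  # zero field: identity
  z <- deformation_field(array(0, c(dim3, 3)), sp, org)
  expect_identical(apply_deformation(dose, z)$dose, arr)
  # constant one-voxel displacement equals the integer index shift
  disp <- array(0, c(dim3, 3)); disp[, , , 1] <- sp[1]
  shifted <- apply_deformation(dose, deformation_field(disp, sp, org))
  roll <- array(0, dim3); roll[1:19, , ] <- arr[2:20, , ]
  expect_equal(shifted$dose, roll, tolerance = 1e-12)
  # analytic linear warp composed with its exact inverse is the identity
  ph <- list(ct = image_volume(array(0, dim3), sp, org),
             isocenter = c(0, 0, 0))
  fwd <- make_analytic_dvf(ph, 0.08)
  pts <- voxel_centers(dose)
  n <- prod(dim3)
  # forward-then-inverse displacement residual vanishes (closed-form warp)
  warped_pts <- pts + matrix(fwd$disp, n, 3)
  u_inv_at_warped <- -0.08 / 1.08 * warped_pts  # inverse law about centre 0
  round_trip <- warped_pts + u_inv_at_warped
  expect_lt(max(abs(round_trip - pts)), 1e-10)
  expect_error(make_analytic_dvf(ph, -1), "invertibility")
  expect_identical(make_analytic_dvf(ph, 0)$disp, array(0, c(dim3, 3)))
})

test_that("paired t test matches the textbook formula and flags degeneracy", {
  set.seed(13)
  planned <- rnorm(13, 50, 0.5)
  delivered <- planned - rnorm(13, 0.1, 0.3)
  pt <- paired_comparison_test(planned, delivered)
  d <- planned - delivered
  t_ref <- mean(d) / (sd(d) / sqrt(length(d)))
  p_ref <- 2 * stats::pt(-abs(t_ref), length(d) - 1)
  expect_equal(pt$t, t_ref, tolerance = 1e-9)
  expect_equal(pt$p_value, p_ref, tolerance = 1e-9)
  expect_identical(pt$significant, p_ref < 0.05)
  # identical pairs and constant-offset pairs are degenerate, not errors
  expect_true(paired_comparison_test(1:3, 1:3)$degenerate)
  expect_true(paired_comparison_test(c(2, 3, 4), c(1, 2, 3))$degenerate)
  expect_error(paired_comparison_test(1, 1), "insufficient")
})
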