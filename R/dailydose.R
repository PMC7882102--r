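## CBCT-based daily dose estimation and course accumulation.
##
## The daily dose estimator is a primary-fluence path-length perturbation
## model: for each beam the planned dose in a voxel is rescaled by
## exp(-mu_eff * (radiological depth on the daily anatomy - radiological
## depth on the planning anatomy)). It captures the first-order mechanisms
## that drive day-to-day dose change in the pelvis — extra tissue upstream
## (weight gain) attenuates, a gas pocket upstream transmits — and is exact
## in the null case: identical anatomies reproduce the planned dose
## bit-for-bit. It is not a full superposition/convolution engine (no
## scatter-kernel deformation, no output/inverse-square remodelling).

#' Beam geometry and attenuation model for the daily dose estimate
#'
#' Coplanar equispaced gantry angles; source at `sad` mm from the isocenter,
#' gantry 0 anterior (+y), angles increasing clockwise when viewed from the
#' table's foot: source = iso + sad * (sin g, cos g, 0).
#'
#' @param n_beams number of fields (7 or 9 are the typical DMLC choices)
#' @param mu_eff effective linear attenuation per unit relative electron
#'   density path, 1/mm. Default 0.0035/mm, the broad-beam effective
#'   attenuation of a 10-MV photon beam in water beyond build-up
#'   (~3.5%/cm).
#' @param sad source-axis distance, mm
#' @param weights per-beam fraction of total dose (default equal; must sum
#'   to 1)
#' @param isocenter mm
#' @return an object of class `beam_model`
#' @export
beam_model <- function(n_beams = 7, mu_eff = 0.0035, sad = 1000,
                       weights = NULL, isocenter = c(0, 0, 0)) {
  stopifnot(n_beams >= 1, mu_eff > 0, sad > 0)
  gantry <- seq(0, 360, length.out = n_beams + 1)[seq_len(n_beams)]
  if (is.null(weights)) weights <- rep(1 / n_beams, n_beams)
  stopifnot(length(weights) == n_beams, all(weights > 0),
            abs(sum(weights) - 1) < 1e-9)
  g <- gantry * pi / 180
  sources <- cbind(isocenter[1] + sad * sin(g),
                   isocenter[2] + sad * cos(g),
                   isocenter[3] + 0 * g)
  structure(list(n_beams = as.integer(n_beams), gantry = gantry,
                 sources = sources, weights = weights, mu_eff = mu_eff,
                 sad = sad, isocenter = as.numeric(isocenter)),
            class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf("<beam_model> %d beams at gantry %s deg, SAD %g mm, mu_eff %g /mm\n",
              x$n_beams, paste(round(x$gantry, 1), collapse = "/"),
              x$sad, x$mu_eff))
  invisible(x)
}

#' Radiological depth along a source-to-voxel ray
#'
#' Line integral of relative electron density along the segment from the
#' beam source to each query point, by uniform-step midpoint ray marching
#' (step at most half the minimum voxel spacing unless overridden). Exact
#' for piecewise-constant densities up to step resolution. Density outside
#' the scanned volume is air (0).
#'
#' @param density 3D array of relative electron density (an
#'   [apply_hu_curve()] result), with grid metadata supplied via `spacing`
#'   and `origin`
#' @param spacing,origin grid metadata, mm
#' @param source beam source position, mm (must lie outside the volume)
#' @param pts n-by-3 matrix of query points, mm
#' @param step marching step, mm (default `min(spacing) / 2`)
#' @return equivalent path length, mm of unit-density material, per point
#' @export
radiological_depth <- function(density, spacing, origin, source, pts,
                               step = NULL) {
  stopifnot(is.array(density), length(dim(density)) == 3L)
  if (anyNA(density) || !all(is.finite(density)))
    stop("density must be finite (stitch the volume before depth evaluation)")
  if (min(density) < 0) stop("density must be non-negative")
  d <- dim(density)
  lo <- origin - 0.5 * spacing
  hi <- origin + (d - 0.5) * spacing
  if (all(source >= lo & source <= hi))
    stop("geometry error: beam source lies inside the density volume")
  if (is.null(step)) step <- min(spacing) / 2
  stopifnot(step > 0)
  radiological_depth_cpp(as.numeric(density), d, spacing, origin,
                         as.numeric(source), rbind(pts), step)
}

beam_depths <- function(density, spacing, origin, beams, pts, step = NULL) {
  lapply(seq_len(beams$n_beams), function(b)
    radiological_depth(density, spacing, origin, beams$sources[b, ], pts,
                       step = step))
}

#' Estimate the dose of the day from daily anatomy
#'
#' Applies the path-length perturbation model: for voxel `v` inside the
#' calculation region,
#' `delivered(v) = sum_b w_b * planned(v) * exp(-mu_eff * (depth_daily_b(v)
#' - depth_plan_b(v)))`.
#' Voxels outside the region copy the planned dose. Both density volumes
#' must live on the planning grid frame (stitch and register the CBCT
#' first). When the daily density equals the planning density the result is
#' bit-identical to the plan: the perturbation factor is computed as
#' `1 + sum_b w_b * expm1(...)`, which is exactly 1 at zero depth change.
#'
#' @param planned planned `dose_grid` (planning frame)
#' @param plan_density,daily_density 3D RED arrays on the planning dose grid
#' @param beams a `beam_model`
#' @param region optional `structure_mask` limiting the calculation (the
#'   body outline expanded 2 cm, see [expand_body_region()]); default all
#'   voxels
#' @param step ray-marching step, mm
#' @param plan_depth optional precomputed planning-anatomy depths (list of
#'   per-beam depth vectors over the region voxels), reused across fractions
#' @return a `dose_grid` with attribute `"factor"` (the per-voxel
#'   perturbation field, 1 outside the region)
#' @export
fraction_dose_estimate <- function(planned, plan_density, daily_density,
                                   beams, region = NULL, step = NULL,
                                   plan_depth = NULL) {
  stopifnot(inherits(planned, "dose_grid"), inherits(beams, "beam_model"))
  dm <- dim(planned$dose)
  if (!identical(dim(plan_density), dm) || !identical(dim(daily_density), dm))
    stop("frame error: density volumes must be on the planning dose grid")
  sel <- if (is.null(region)) rep(TRUE, prod(dm)) else {
    if (!identical(dim(region$mask), dm))
      stop("frame error: region mask must be on the planning dose grid")
    as.vector(region$mask)
  }
  pts <- voxel_centers(planned)[sel, , drop = FALSE]
  if (is.null(plan_depth))
    plan_depth <- beam_depths(plan_density, planned$spacing, planned$origin,
                              beams, pts, step = step)
  daily_depth <- beam_depths(daily_density, planned$spacing, planned$origin,
                             beams, pts, step = step)
  factor_sel <- rep(1, nrow(pts))
  delta <- 0
  for (b in seq_len(beams$n_beams)) {
    delta <- delta + beams$weights[b] *
      expm1(-beams$mu_eff * (daily_depth[[b]] - plan_depth[[b]]))
  }
  factor_sel <- factor_sel + delta
  fac <- rep(1, prod(dm))
  fac[sel] <- factor_sel
  out <- planned$dose * array(fac, dm)
  res <- dose_grid(out, planned$spacing, planned$origin, planned$frame_id)
  attr(res, "factor") <- array(fac, dm)
  res
}

#' One delivered fraction of a treatment course
#'
#' @param fraction_index 1-based fraction number (unique within a course)
#' @param delivered_dose the fraction's `dose_grid` (fraction frame)
#' @param registration online couch registration mapping planning to
#'   fraction frame (`rigid_transform`)
#' @param cbct optional daily `image_volume`
#' @param excluded logical; excluded fractions carry a `reason` and are
#'   omitted from accumulation
#' @param reason exclusion reason (required when `excluded`)
#' @return an object of class `fraction_record`
#' @export
fraction_record <- function(fraction_index, delivered_dose,
                            registration = rigid_transform(),
                            cbct = NULL, excluded = FALSE, reason = NULL) {
  stopifnot(inherits(delivered_dose, "dose_grid"),
            inherits(registration, "rigid_transform"))
  if (excluded && is.null(reason))
    stop("an excluded fraction must state a reason")
  structure(list(fraction_index = as.integer(fraction_index),
                 delivered_dose = delivered_dose, registration = registration,
                 cbct = cbct, excluded = isTRUE(excluded), reason = reason),
            class = "fraction_record")
}

#' Resample a fraction's delivered dose into the planning frame
#'
#' The registration maps planning-frame points to fraction-frame points, so
#' the planning-frame dose reads the fraction dose at the forward-mapped
#' position: `out(v) = delivered(T(v))`.
#' @param record a `fraction_record`
#' @return a `dose_grid` in the planning frame
#' @export
resample_to_planning <- function(record) {
  dose <- record$delivered_dose
  tr <- record$registration
  if (is_identity_transform(tr)) {
    out <- dose
    out$frame_id <- "planning"
    return(out)
  }
  pts <- transform_points(tr, voxel_centers(dose))
  vals <- trilinear_sample_cpp(as.numeric(dose$dose), dim(dose$dose),
                               dose$spacing, dose$origin, pts, 0)
  vals[vals < 0] <- 0
  dose_grid(array(vals, dim(dose$dose)), dose$spacing, dose$origin, "planning")
}

# relative differences for report tables: a 0 Gy planned metric with a 0 Gy
# delivered metric is a 0% difference (the correct limit; OARs far from the
# target have D98 = 0), while 0 planned with nonzero delivered is reported NA
# instead of aborting the course
rd_table <- function(pm, dm) {
  one <- function(p, d) {
    if (p == 0) {
      if (d == 0) 0 else NA_real_
    } else 100 * (p - d) / p
  }
  c(dd98 = one(pm$d98, dm$d98), dd2 = one(pm$d2, dm$d2),
    ddmean = one(pm$dmean, dm$dmean))
}

#' Compare one delivered fraction with its planned fraction dose
#'
#' The delivered dose is brought to the planning frame through the online
#' registration, then D98%, D2% and Dmean are compared ROI by ROI (signed
#' percent, planned minus delivered). Excluded fractions are skipped with
#' their logged reason.
#'
#' @param planned the fraction's planned `dose_grid` (planning frame; the
#'   course plan divided by the number of fractions)
#' @param record a `fraction_record`
#' @param rois list of `structure_mask`
#' @return data frame, one row per ROI (`fraction`, `roi`, `dd98`, `dd2`,
#'   `ddmean`, `excluded`), or the exclusion row when skipped
#' @export
compare_fraction <- function(planned, record, rois) {
  stopifnot(inherits(record, "fraction_record"))
  if (record$excluded) {
    message("fraction ", record$fraction_index, " excluded: ", record$reason)
    return(data.frame(fraction = record$fraction_index,
                      roi = NA_character_, dd98 = NA_real_, dd2 = NA_real_,
                      ddmean = NA_real_, excluded = TRUE))
  }
  delivered <- resample_to_planning(record)
  rows <- lapply(rois, function(roi) {
    dd <- rd_table(dvh_metrics(planned, roi), dvh_metrics(delivered, roi))
    data.frame(fraction = record$fraction_index, roi = roi$name,
               dd98 = dd[["dd98"]], dd2 = dd[["dd2"]],
               ddmean = dd[["ddmean"]], excluded = FALSE)
  })
  do.call(rbind, rows)
}

#' Accumulate delivered fractions in the planning frame
#'
#' Each non-excluded fraction dose is mapped to the planning frame through
#' its registration and summed. When fractions are missing the accumulated
#' dose is scaled by `n_planned / n_included` so it remains comparable with
#' the full-course plan (a documented normalisation choice). When every
#' record carries the multiplicative `"factor"` attribute produced by
#' [fraction_dose_estimate()] and an identity registration, the
#' accumulation is computed as `planned x mean(factor)` — algebraically the
#' same sum, but exact in floating point (the null course reproduces the
#' plan bit-for-bit).
#'
#' @param records list of `fraction_record`
#' @param planned full-course planned `dose_grid`
#' @param n_planned planned number of fractions (default `length(records)`)
#' @param rois optional list of `structure_mask` for the per-ROI comparison
#' @return object of class `accumulated_dose`: the accumulated `dose_grid`,
#'   scaling metadata and (if `rois` given) the per-ROI difference table
#' @export
accumulate_rigid <- function(records, planned, n_planned = length(records),
                             rois = NULL) {
  stopifnot(length(records) >= 1,
            all(vapply(records, inherits, TRUE, "fraction_record")))
  included <- Filter(function(r) !r$excluded, records)
  if (length(included) == 0)
    stop("empty course: all fractions are excluded")
  n_inc <- length(included)
  scale <- n_planned / n_inc
  exact <- all(vapply(included, function(r)
    !is.null(attr(r$delivered_dose, "factor")) &&
      is_identity_transform(r$registration), TRUE))
  if (exact) {
    fsum <- 0
    for (r in included) fsum <- fsum + attr(r$delivered_dose, "factor")
    acc_arr <- planned$dose * (fsum / n_inc)
  } else {
    acc_arr <- 0
    for (r in included) acc_arr <- acc_arr + resample_to_planning(r)$dose
    acc_arr <- acc_arr * scale
  }
  acc <- dose_grid(acc_arr, planned$spacing, planned$origin, "planning")
  per_roi <- NULL
  if (!is.null(rois)) {
    per_roi <- do.call(rbind, lapply(rois, function(roi) {
      dd <- rd_table(dvh_metrics(planned, roi), dvh_metrics(acc, roi))
      data.frame(roi = roi$name, dd98 = dd[["dd98"]], dd2 = dd[["dd2"]],
                 ddmean = dd[["ddmean"]])
    }))
  }
  structure(list(dose = acc, n_planned = n_planned, n_included = n_inc,
                 scale = scale,
                 excluded = vapply(Filter(function(r) r$excluded, records),
                                   function(r) r$fraction_index, 1L),
                 per_roi = per_roi),
            class = "accumulated_dose")
}

#' @export
print.accumulated_dose <- function(x, ...) {
  cat(sprintf("<accumulated_dose> %d / %d fractions included (scale %.4f)\n",
              x$n_included, x$n_planned, x$scale))
  if (length(x$excluded))
    cat("  excluded fractions:", paste(x$excluded, collapse = ", "), "\n")
  if (!is.null(x$per_roi)) print(x$per_roi, row.names = FALSE)
  invisible(x)
}

#' Dice similarity coefficient of two structure masks
#'
#' `2 |A intersect B| / (|A| + |B|)`, the standard overlap QA metric for
#' deformed contours; always in `[0, 1]`.
#'
#' @param a,b `structure_mask` objects on the same grid
#' @return numeric scalar in `[0, 1]`
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "structure_mask"), inherits(b, "structure_mask"))
  if (!same_grid(a, b)) stop("masks are on different grids")
  na <- sum(a$mask); nb <- sum(b$mask)
  if (na + nb == 0) stop("degenerate: both masks are empty")
  2 * sum(a$mask & b$mask) / (na + nb)
}

#' Deformation vector field on the planning grid
#'
#' Per-voxel displacement vectors (mm) mapping planning-frame positions to
#' fraction-frame positions. Produced by external deformable registration
#' (or the analytic test generator); this package consumes, never fits,
#' deformation fields.
#'
#' @param disp 4D numeric array `dim x 3` (last axis = displacement x/y/z)
#' @param spacing,origin grid metadata matching the planning dose grid
#' @return an object of class `deformation_field`
#' @export
deformation_field <- function(disp, spacing, origin) {
  stopifnot(is.array(disp), length(dim(disp)) == 4L, dim(disp)[4] == 3L)
  if (!all(is.finite(disp))) stop("displacement vectors must be finite")
  g <- new_grid(spacing, origin, dim(disp)[1:3])
  structure(list(disp = disp, spacing = g$spacing, origin = g$origin),
            class = "deformation_field")
}

#' Warp a fraction dose into the planning frame through a deformation field
#'
#' Pull-back interpolation: `out(v) = dose(v + displacement(v))` with
#' trilinear sampling. No Jacobian (energy/mass) correction is applied — a
#' documented simplification. Displacements mapping outside the fraction
#' grid zero-fill, and the count of such voxels is reported as an attribute.
#'
#' @param dose fraction-frame `dose_grid`
#' @param dvf a `deformation_field` on the planning grid
#' @return planning-frame `dose_grid` with attribute `"n_outside"`
#' @export
apply_deformation <- function(dose, dvf) {
  stopifnot(inherits(dose, "dose_grid"), inherits(dvf, "deformation_field"))
  dm <- dim(dvf$disp)[1:3]
  if (!identical(dim(dose$dose), dm))
    stop("frame error: deformation field grid does not match the dose grid")
  if (all(dvf$disp == 0)) {
    out <- dose
    out$frame_id <- "planning"
    attr(out, "n_outside") <- 0L
    return(out)
  }
  n <- prod(dm)
  pts <- voxel_centers(dose) + matrix(dvf$disp, n, 3)
  vals <- trilinear_sample_cpp(as.numeric(dose$dose), dim(dose$dose),
                               dose$spacing, dose$origin, pts, NA_real_)
  n_out <- sum(is.na(vals))
  vals[is.na(vals)] <- 0
  vals[vals < 0] <- 0
  out <- dose_grid(array(vals, dm), dose$spacing, dose$origin, "planning")
  attr(out, "n_outside") <- n_out
  out
}

#' Paired comparison of planned and delivered metrics
#'
#' Classical paired Student t test on per-case metric pairs, two-sided, with
#' the conventional 5% significance level. Zero-variance differences
#' (identical pairs, or a constant offset) are reported explicitly as
#' degenerate rather than producing an undefined statistic.
#'
#' @param planned,delivered numeric vectors of per-case metric values
#' @param alpha significance level (default 0.05)
#' @return object of class `paired_test`: `t`, `df`, `p_value`,
#'   `mean_difference`, `significant`, `degenerate`
#' @export
paired_comparison_test <- function(planned, delivered, alpha = 0.05) {
  stopifnot(length(planned) == length(delivered))
  if (length(planned) < 2)
    stop("insufficient data: paired test needs at least 2 pairs")
  d <- planned - delivered
  if (stats::sd(d) == 0) {
    return(structure(list(t = NA_real_, df = length(d) - 1, p_value = NA_real_,
                          mean_difference = mean(d), significant = NA,
                          degenerate = TRUE, alpha = alpha),
                     class = "paired_test"))
  }
  ht <- stats::t.test(planned, delivered, paired = TRUE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_difference = unname(ht$estimate),
                 significant = ht$p.value < alpha, degenerate = FALSE,
                 alpha = alpha),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<paired_test> degenerate: zero-variance differences (mean diff %.4g)\n",
                x$mean_difference))
  } else {
    cat(sprintf("<paired_test> t = %.4f, df = %d, p = %.4g (%ssignificant at %g%%)\n",
                x$t, x$df, x$p_value, if (x$significant) "" else "not ",
                100 * x$alpha))
  }
  invisible(x)
}
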