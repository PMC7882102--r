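## HU-to-relative-electron-density calibration and limited-FOV stitching.

#' HU-to-density calibration curve
#'
#' Piecewise-linear mapping from Hounsfield units to relative electron
#' density (RED). Each imaging chain (planning CT, CBCT) carries its own
#' curve because CBCT HU are systematically offset; dose estimation on CBCT
#' anatomy uses the CBCT curve so the offset cancels out of the density.
#' Evaluation between control points is linear; beyond the endpoints the
#' density is clamped.
#'
#' @param hu strictly increasing HU control points
#' @param density non-negative, non-decreasing RED values
#' @param label which scanner/protocol the curve calibrates
#' @return an object of class `hu_density_curve`
#' @export
hu_density_curve <- function(hu, density, label = "planning_ct") {
  hu <- as.numeric(hu); density <- as.numeric(density)
  if (length(hu) < 2L || length(hu) != length(density))
    stop("calibration error: need >= 2 (HU, density) control points")
  if (any(diff(hu) <= 0))
    stop("calibration error: HU control points must be strictly increasing")
  if (any(density < 0) || any(diff(density) < 0))
    stop("calibration error: densities must be non-negative and non-decreasing")
  structure(list(hu = hu, density = density, label = as.character(label)),
            class = "hu_density_curve")
}

#' @export
print.hu_density_curve <- function(x, ...) {
  cat(sprintf("<hu_density_curve> '%s', %d control points, HU [%g, %g] -> RED [%g, %g]\n",
              x$label, length(x$hu), min(x$hu), max(x$hu),
              min(x$density), max(x$density)))
  invisible(x)
}

#' Evaluate an HU-to-density curve
#' @param curve an `hu_density_curve`
#' @param hu numeric vector of HU
#' @return relative electron densities (clamped beyond the endpoints)
#' @export
eval_hu_curve <- function(curve, hu) {
  stats::approx(curve$hu, curve$density, xout = hu, rule = 2)$y
}

#' Convert an image volume to relative electron density
#'
#' Applies the calibration voxelwise. Out-of-FOV marker voxels are excluded:
#' they come back as `NA` so downstream stitching can fill them; a fully
#' reconstructed volume has none.
#'
#' @param vol an `image_volume`
#' @param curve an `hu_density_curve`
#' @return 3D numeric array of RED on the same grid (NA where out of FOV)
#' @export
apply_hu_curve <- function(vol, curve) {
  stopifnot(inherits(vol, "image_volume"), inherits(curve, "hu_density_curve"))
  hu <- vol$voxels
  oof <- hu == HU_OUT_OF_FOV
  red <- eval_hu_curve(curve, as.numeric(hu))
  red[oof] <- NA_real_
  array(red, dim(hu))
}

#' Default HU-to-density calibration curves
#'
#' A conventional bilinear water/bone calibration for the planning CT, and
#' the same anatomy points shifted by a constant HU offset for the CBCT
#' chain (CBCT HU are systematically biased; calibrating per modality is
#' what keeps the biased HU from perturbing the density).
#'
#' @param cbct_hu_offset constant HU bias of the CBCT chain
#' @return list with elements `planning` and `cbct`
#' @export
default_hu_curves <- function(cbct_hu_offset = 0) {
  pts_hu <- c(-1000, 0, 1000, 3000)
  pts_red <- c(0, 1, 1.55, 2.5)
  list(
    planning = hu_density_curve(pts_hu, pts_red, "planning_ct"),
    cbct = hu_density_curve(pts_hu + cbct_hu_offset, pts_red, "cbct")
  )
}

#' Stitch a limited-FOV CBCT with the planning CT
#'
#' CBCT reconstructions cover a fixed-diameter cylinder (typically 26 cm)
#' that may truncate the body outline. Inside the field-of-view cylinder the
#' output keeps the CBCT HU; outside it the planning CT is resampled through
#' the online registration (the couch-match transform mapping the planning
#' frame to the fraction frame), so the full body outline is available for
#' dose estimation. No out-of-FOV markers remain in the output.
#'
#' @param cbct an `image_volume` with `fov_radius_mm` set
#' @param planning the planning-CT `image_volume`
#' @param registration `rigid_transform` mapping planning frame to fraction
#'   frame
#' @return an `image_volume` on the CBCT grid with full coverage
#' @export
stitch_limited_fov <- function(cbct, planning, registration) {
  stopifnot(inherits(cbct, "image_volume"), inherits(planning, "image_volume"),
            inherits(registration, "rigid_transform"))
  if (is.null(cbct$fov_radius_mm))
    stop("configuration error: cbct has no fov_radius_mm; nothing to stitch")
  vox <- cbct$voxels
  oof <- vox == HU_OUT_OF_FOV
  if (any(oof)) {
    pts <- voxel_centers(cbct)[as.vector(oof), , drop = FALSE]
    # fraction-frame point -> planning-frame point through the inverse
    # registration, then read the planning CT there
    ppts <- inverse_points(registration, pts)
    vox[oof] <- sample_volume(planning, ppts)
  }
  image_volume(vox, cbct$spacing, cbct$origin, fov_radius_mm = NULL)
}
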