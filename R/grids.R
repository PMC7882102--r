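#' @useDynLib fracdose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd setNames approx quantile t.test
#' @importFrom utils write.csv read.csv
NULL

#' Out-of-field-of-view sentinel HU
#'
#' Voxels of a limited-FOV CBCT that lie outside the reconstructed cylinder
#' carry this marker value (a common scanner convention), distinguishable
#' from any valid HU including air (-1000).
#' @export
HU_OUT_OF_FOV <- -3024

## ---- internal grid helpers -------------------------------------------------

new_grid <- function(spacing, origin, dim) {
  stopifnot(length(spacing) == 3L, length(origin) == 3L, length(dim) == 3L)
  if (!all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be strictly positive and finite on all axes")
  if (!all(is.finite(origin)))
    stop("origin must be finite")
  list(spacing = as.numeric(spacing), origin = as.numeric(origin),
       dim = as.integer(dim))
}

grid_of <- function(x) {
  new_grid(x$spacing, x$origin, dim(first_array(x)))
}

first_array <- function(x) {
  if (!is.null(x$voxels)) x$voxels else if (!is.null(x$dose)) x$dose else x$mask
}

same_grid <- function(a, b, tol = 1e-6) {
  ga <- grid_of(a); gb <- grid_of(b)
  identical(ga$dim, gb$dim) &&
    all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol)
}

#' Physical coordinates of all voxel centres of a grid
#'
#' Voxel centres follow the package convention: 0-based index `i` on axis
#' `ax` sits at `origin[ax] + i * spacing[ax]` (mm). Returns an n-by-3
#' matrix in array (column-major) order.
#' @param x an `image_volume`, `dose_grid` or `structure_mask`
#' @return numeric matrix, one row per voxel, columns x/y/z in mm
#' @export
voxel_centers <- function(x) {
  g <- grid_of(x)
  ax <- lapply(1:3, function(a) g$origin[a] + (seq_len(g$dim[a]) - 1) * g$spacing[a])
  cbind(
    rep(ax[[1]], times = g$dim[2] * g$dim[3]),
    rep(rep(ax[[2]], each = g$dim[1]), times = g$dim[3]),
    rep(ax[[3]], each = g$dim[1] * g$dim[2])
  )
}

voxel_volume_mm3 <- function(x) prod(grid_of(x)$spacing)

## ---- image volume ----------------------------------------------------------

#' CT / CBCT image volume
#'
#' An axis-aligned voxel grid of Hounsfield units. `origin` is the physical
#' position (mm) of the centre of voxel (0,0,0); physical position of voxel
#' index `(i,j,k)` (0-based) is `origin + c(i,j,k) * spacing`. For CBCT
#' volumes with a limited reconstruction field of view, `fov_radius_mm` is
#' set and voxels outside the axial cylinder of that radius (centred on the
#' grid centre) carry [HU_OUT_OF_FOV].
#'
#' @param voxels 3D numeric array of HU
#' @param spacing per-axis voxel size, mm (length 3)
#' @param origin physical position of voxel (0,0,0) centre, mm (length 3)
#' @param fov_radius_mm optional axial field-of-view radius, mm
#' @return an object of class `image_volume`
#' @export
image_volume <- function(voxels, spacing, origin, fov_radius_mm = NULL) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  g <- new_grid(spacing, origin, dim(voxels))
  if (!all(is.finite(voxels)))
    stop("voxels must be finite")
  if (!is.null(fov_radius_mm)) {
    stopifnot(is.numeric(fov_radius_mm), fov_radius_mm > 0)
    fov_radius_mm <- as.numeric(fov_radius_mm)
  }
  structure(list(voxels = voxels, spacing = g$spacing, origin = g$origin,
                 fov_radius_mm = fov_radius_mm),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  hu <- x$voxels[x$voxels != HU_OUT_OF_FOV]
  cat(sprintf("  HU range [%.0f, %.0f]%s\n", min(hu), max(hu),
              if (!is.null(x$fov_radius_mm))
                sprintf("; limited FOV radius %.0f mm", x$fov_radius_mm) else ""))
  invisible(x)
}

## ---- dose grid -------------------------------------------------------------

#' Absorbed dose grid
#'
#' A voxel grid of absorbed dose in Gy on its own spacing/origin, tagged with
#' the coordinate frame it lives in (`"planning"` or a per-fraction label).
#'
#' @param dose 3D numeric array, Gy, non-negative
#' @param spacing mm per axis (length 3); 2 mm isotropic is the conventional
#'   treatment-planning resolution and the package default elsewhere
#' @param origin mm (length 3)
#' @param frame_id character frame label
#' @return an object of class `dose_grid`
#' @export
dose_grid <- function(dose, spacing, origin, frame_id = "planning") {
  stopifnot(is.array(dose), length(dim(dose)) == 3L)
  g <- new_grid(spacing, origin, dim(dose))
  if (!all(is.finite(dose)))
    stop("dose must be finite")
  if (min(dose) < 0)
    stop("dose must be non-negative everywhere")
  structure(list(dose = dose, spacing = g$spacing, origin = g$origin,
                 frame_id = as.character(frame_id)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$dose)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, spacing %s mm, frame '%s'\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              x$frame_id))
  cat(sprintf("  dose range [%.3f, %.3f] Gy\n", min(x$dose), max(x$dose)))
  invisible(x)
}

## ---- structure mask --------------------------------------------------------

#' Region-of-interest occupancy mask
#'
#' Boolean voxel occupancy for one ROI (CTV, PTV, body, bladder, rectum,
#' femoral heads, ...) on a named grid.
#'
#' @param name ROI label
#' @param mask 3D logical array
#' @param spacing mm per axis
#' @param origin mm
#' @return an object of class `structure_mask`
#' @export
structure_mask <- function(name, mask, spacing, origin) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (!is.logical(mask)) {
    mask <- array(as.logical(mask), dim(mask))
  }
  g <- new_grid(spacing, origin, dim(mask))
  structure(list(name = as.character(name), mask = mask,
                 spacing = g$spacing, origin = g$origin),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  d <- dim(x$mask)
  n <- sum(x$mask)
  cat(sprintf("<structure_mask> '%s': %d / %d voxels (%.2f cm^3) on %d x %d x %d grid\n",
              x$name, n, length(x$mask), n * voxel_volume_mm3(x) / 1000,
              d[1], d[2], d[3]))
  invisible(x)
}

#' Volume of a structure in cubic centimetres
#' @param roi a `structure_mask`
#' @return numeric scalar, cm^3
#' @export
mask_volume_cc <- function(roi) {
  sum(roi$mask) * voxel_volume_mm3(roi) / 1000
}

#' Distance to a structure surface
#'
#' Euclidean distance (mm) from every voxel centre to the nearest voxel of
#' the mask (0 inside the mask), via an exact separable distance transform.
#'
#' @param roi a `structure_mask`
#' @return 3D numeric array of distances, mm
#' @export
distance_to_mask <- function(roi) {
  if (!any(roi$mask)) stop("mask is empty: distance undefined")
  d <- edt_cpp(as.logical(roi$mask), dim(roi$mask), roi$spacing)
  array(d, dim(roi$mask))
}

#' Isotropically expand a structure mask
#'
#' Morphological expansion of a (body) mask by a Euclidean margin, used to
#' define the dose-calculation region extending a fixed distance (typically
#' 2 cm) outside the body outline so that weight change at the skin is
#' captured. Implemented as a Euclidean distance-transform threshold;
#' expansion is clipped at the grid bounds.
#'
#' @param body a `structure_mask`
#' @param margin_mm non-negative expansion margin, mm
#' @return a `structure_mask` containing the input
#' @export
expand_body_region <- function(body, margin_mm) {
  stopifnot(inherits(body, "structure_mask"))
  if (!is.numeric(margin_mm) || length(margin_mm) != 1L ||
      !is.finite(margin_mm) || margin_mm < 0)
    stop("margin_mm must be a single non-negative number")
  if (margin_mm == 0) return(body)
  d <- distance_to_mask(body)
  structure_mask(paste0(body$name, "+", margin_mm, "mm"),
                 d <= margin_mm, body$spacing, body$origin)
}
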