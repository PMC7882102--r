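## Rigid 6DOF transforms and dose resampling.

rot_matrix <- function(r_deg) {
  a <- r_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  # fixed intrinsic order pitch (x) -> roll (y) -> yaw (z)
  Rz %*% Ry %*% Rx
}

#' Six-degree-of-freedom rigid transform
#'
#' Three translations (mm) and three rotations (degrees) about a stated
#' centre, the model for residual patient setup error and for online couch
#' registrations. A point `p` maps to
#' `center + R %*% (p - center) + t`, with `R` composed in the fixed
#' intrinsic order pitch (about x), then roll (about y), then yaw (about z).
#' At the <= 2 degree angles of interest the order has negligible effect but
#' a convention must be fixed.
#'
#' @param t translation vector, mm (length 3)
#' @param r rotation angles, degrees (length 3: pitch, roll, yaw)
#' @param center rotation centre, mm (the plan isocenter)
#' @return an object of class `rigid_transform`
#' @export
rigid_transform <- function(t = c(0, 0, 0), r = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  t <- as.numeric(t); r <- as.numeric(r); center <- as.numeric(center)
  stopifnot(length(t) == 3L, length(r) == 3L, length(center) == 3L)
  if (!all(is.finite(c(t, r, center))))
    stop("transform parameters must be finite")
  structure(list(t = t, r = r, center = center), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%s) mm, r = (%s) deg, center = (%s) mm\n",
              paste(signif(x$t, 4), collapse = ", "),
              paste(signif(x$r, 4), collapse = ", "),
              paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

is_identity_transform <- function(tr, tol = 0) {
  all(abs(tr$t) <= tol) && all(abs(tr$r) <= tol)
}

#' Apply a rigid transform to points
#' @param tr a `rigid_transform`
#' @param pts n-by-3 matrix of physical coordinates, mm (a bare length-3
#'   vector is accepted as one point)
#' @return n-by-3 matrix of mapped coordinates
#' @export
transform_points <- function(tr, pts) {
  pts <- rbind(pts)
  if (ncol(pts) != 3L) stop("pts must be n x 3")
  R <- rot_matrix(tr$r)
  ctr <- matrix(tr$center, nrow(pts), 3, byrow = TRUE)
  (pts - ctr) %*% t(R) + ctr +
    matrix(tr$t, nrow(pts), 3, byrow = TRUE)
}

#' Map points through the inverse of a rigid transform
#'
#' `p = R^-1 (p' - t - center) + center`; exact inverse of
#' [transform_points()].
#' @param tr a `rigid_transform`
#' @param pts n-by-3 matrix, mm
#' @return n-by-3 matrix of pre-images
#' @export
inverse_points <- function(tr, pts) {
  pts <- rbind(pts)
  if (ncol(pts) != 3L) stop("pts must be n x 3")
  Rinv <- t(rot_matrix(tr$r))
  ctr <- matrix(tr$center, nrow(pts), 3, byrow = TRUE)
  (pts - ctr - matrix(tr$t, nrow(pts), 3, byrow = TRUE)) %*% t(Rinv) + ctr
}

#' Resample a dose grid through a rigid transform
#'
#' Produces the "blurred" dose: the isodose cloud is rigidly moved while the
#' grid stays fixed. Each output voxel takes the trilinear interpolation of
#' the input dose at the inverse-transformed voxel-centre position; positions
#' mapping outside the input grid read 0 Gy (dose supports are interior).
#' An exact identity transform returns the input unchanged (bit-identical).
#'
#' @param dose a `dose_grid`
#' @param transform a `rigid_transform`
#' @return a `dose_grid` on the same grid as the input
#' @export
resample_dose <- function(dose, transform) {
  stopifnot(inherits(dose, "dose_grid"), inherits(transform, "rigid_transform"))
  if (is_identity_transform(transform)) return(dose)
  pts <- inverse_points(transform, voxel_centers(dose))
  vals <- trilinear_sample_cpp(as.numeric(dose$dose), dim(dose$dose),
                               dose$spacing, dose$origin, pts, 0)
  vals[vals < 0] <- 0  # guard against signed interpolation round-off
  dose_grid(array(vals, dim(dose$dose)), dose$spacing, dose$origin,
            dose$frame_id)
}

#' Sample an image volume at arbitrary physical points
#'
#' Trilinear HU interpolation; points outside the scanned volume read
#' -1000 HU (air).
#' @param vol an `image_volume`
#' @param pts n-by-3 matrix, mm
#' @return numeric vector of HU
#' @export
sample_volume <- function(vol, pts) {
  trilinear_sample_cpp(as.numeric(vol$voxels), dim(vol$voxels),
                       vol$spacing, vol$origin, rbind(pts), -1000)
}
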