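## Cumulative DVH curves and the summary metrics D98%, D2%, Dmean.

roi_doses <- function(dose, roi) {
  stopifnot(inherits(dose, "dose_grid"), inherits(roi, "structure_mask"))
  if (!same_grid(dose, roi))
    stop("dose and ROI are on different grids; resample the ROI first")
  if (!any(roi$mask))
    stop("degenerate ROI: '", roi$name, "' has no voxels")
  as.numeric(dose$dose[roi$mask])
}

#' Cumulative dose-volume histogram
#'
#' Differential histogram of in-ROI voxel doses with uniform bins, cumulated
#' from the top: `cum_volume_fraction[i]` is the fraction of ROI volume
#' receiving at least `bin_edges[i]`. Total ROI volume is normalised to 1.
#' The binned curve is for plotting and export; summary metrics use exact
#' voxel ranks (see [dose_at_volume()]).
#'
#' @param dose a `dose_grid`
#' @param roi a `structure_mask` on the same grid
#' @param bin_width bin width in Gy (default 0.05)
#' @return an object of class `dvh_curve` with `bin_edges` (Gy) and
#'   `cum_volume_fraction`
#' @export
compute_dvh <- function(dose, roi, bin_width = 0.05) {
  stopifnot(bin_width > 0)
  d <- roi_doses(dose, roi)
  top <- max(d, 0)
  edges <- seq(0, top + bin_width, by = bin_width)
  # fraction of volume with dose >= edge
  cvf <- vapply(edges, function(e) mean(d >= e), 0)
  structure(list(bin_edges = edges, cum_volume_fraction = cvf,
                 roi = roi$name, bin_width = bin_width),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> ROI '%s', %d bins of %.3g Gy, D extends to %.2f Gy\n",
              x$roi, length(x$bin_edges), x$bin_width, max(x$bin_edges)))
  invisible(x)
}

#' @export
plot.dvh_curve <- function(x, ...) {
  graphics::plot(x$bin_edges, 100 * x$cum_volume_fraction, type = "s",
                 xlab = "Dose [Gy]", ylab = "Volume [%]",
                 main = paste("DVH:", x$roi), ...)
  invisible(x)
}

#' Export a DVH curve to CSV
#' @param curve a `dvh_curve`
#' @param path output CSV path (columns dose_Gy, volume_fraction)
#' @export
write_dvh_csv <- function(curve, path) {
  write.csv(data.frame(dose_Gy = curve$bin_edges,
                       volume_fraction = curve$cum_volume_fraction),
            path, row.names = FALSE)
  invisible(path)
}

#' Dose received by the hottest q% of an ROI (Dq%)
#'
#' Exact voxel-rank estimator: with the `N` in-ROI doses sorted in
#' decreasing order `v[1] >= ... >= v[N]`, the target rank is
#' `x = q/100 * N`; the value is `v[1]` for `x <= 1`, otherwise the linear
#' interpolation between the bracketing order statistics
#' `v[floor(x)] + (x - floor(x)) * (v[floor(x) + 1] - v[floor(x)])`
#' (at an integer rank, the order statistic itself). As q approaches 100
#' this tends to the in-ROI minimum dose.
#'
#' @param x a `dose_grid` (with `roi` supplied) or a numeric vector of voxel
#'   doses
#' @param q_percent volume percentage, strictly between 0 and 100
#' @param roi `structure_mask` (when `x` is a `dose_grid`)
#' @return Dq% in Gy
#' @export
dose_at_volume <- function(x, q_percent, roi = NULL) {
  if (!is.numeric(q_percent) || length(q_percent) != 1L ||
      !is.finite(q_percent) || q_percent <= 0 || q_percent >= 100)
    stop("q_percent must lie strictly between 0 and 100")
  d <- if (inherits(x, "dose_grid")) roi_doses(x, roi) else as.numeric(x)
  if (length(d) == 0) stop("degenerate ROI: no voxel doses")
  v <- sort(d, decreasing = TRUE)
  n <- length(v)
  r <- q_percent / 100 * n
  # snap ranks that are integer up to floating-point round-off (a volume
  # percentage printed from k/N must land back on rank k)
  if (abs(r - round(r)) < 1e-9 * n) r <- round(r)
  if (r <= 1) return(v[1])
  k <- floor(r)
  f <- r - k
  if (f == 0 || k >= n) v[min(k, n)] else v[k] + f * (v[k + 1] - v[k])
}

#' Mean dose in an ROI
#' @param dose a `dose_grid`
#' @param roi a `structure_mask` on the same grid
#' @return arithmetic mean of in-ROI voxel doses, Gy
#' @export
mean_dose <- function(dose, roi) {
  mean(roi_doses(dose, roi))
}

#' Summary DVH metrics for an ROI
#'
#' D98% (near-minimum), D2% (near-maximum) and Dmean of the ROI.
#'
#' @param dose a `dose_grid`
#' @param roi a `structure_mask`
#' @param prescription prescription dose in Gy (carried for reporting)
#' @return an object of class `dvh_metrics` with fields `d98`, `d2`,
#'   `dmean`, `roi`, `prescription`
#' @export
dvh_metrics <- function(dose, roi, prescription = NA_real_) {
  d <- roi_doses(dose, roi)
  structure(list(d98 = dose_at_volume(d, 98), d2 = dose_at_volume(d, 2),
                 dmean = mean(d), roi = roi$name,
                 prescription = prescription),
            class = "dvh_metrics")
}

#' @export
print.dvh_metrics <- function(x, ...) {
  cat(sprintf("<dvh_metrics> ROI '%s': D98%% = %.3f Gy, D2%% = %.3f Gy, Dmean = %.3f Gy\n",
              x$roi, x$d98, x$d2, x$dmean))
  if (is.finite(x$prescription))
    cat(sprintf("  prescription %.1f Gy\n", x$prescription))
  invisible(x)
}

#' Signed relative metric differences, planned minus delivered
#'
#' For each metric the difference is reported as
#' `100 * (planned - delivered) / planned` percent, so a positive value
#' means the delivered dose fell short of the plan (underdose) and a
#' negative value means a hot spot. Normalisation is by the planned metric
#' value; set `normalize` to a prescription dose to normalise by that
#' instead.
#'
#' @param planned,delivered `dvh_metrics` for the same ROI
#' @param normalize `NULL` (default: divide by the planned metric) or a
#'   positive dose in Gy to divide by
#' @return named numeric vector, percent: `dd98`, `dd2`, `ddmean`
#' @export
relative_difference <- function(planned, delivered, normalize = NULL) {
  stopifnot(inherits(planned, "dvh_metrics"), inherits(delivered, "dvh_metrics"))
  if (!identical(planned$roi, delivered$roi))
    stop("metrics are for different ROIs: ", planned$roi, " vs ", delivered$roi)
  one <- function(p, d) {
    den <- if (is.null(normalize)) p else normalize
    if (!is.finite(den) || den == 0)
      stop("undefined ratio: zero planned metric for ROI ", planned$roi)
    100 * (p - d) / den
  }
  c(dd98 = one(planned$d98, delivered$d98),
    dd2 = one(planned$d2, delivered$d2),
    ddmean = one(planned$dmean, delivered$dmean))
}

#' Check the three PTV planning goals
#'
#' Coverage goals of the whole-pelvis plan: at least 50% of the PTV receives
#' the prescription dose, at least 95% receives 98% of it, and no part of
#' the PTV receives 110% of it. For a 50.4 Gy prescription the thresholds
#' are 50.4, 49.392 and 55.44 Gy.
#'
#' @param dose a `dose_grid`
#' @param ptv the PTV `structure_mask`
#' @param prescription prescription dose, Gy (> 0)
#' @return object of class `plan_goal_report`: data frame with one row per
#'   goal (threshold_Gy, required, achieved volume fraction, pass)
#' @export
evaluate_plan_goals <- function(dose, ptv, prescription) {
  if (!is.numeric(prescription) || prescription <= 0)
    stop("prescription must be positive")
  d <- roi_doses(dose, ptv)
  vol_at <- function(thr) mean(d >= thr)
  goals <- data.frame(
    goal = c("V(Rx) >= 50%", "V(0.98 Rx) >= 95%", "V(1.10 Rx) = 0%"),
    threshold_Gy = prescription * c(1, 0.98, 1.10),
    required = c(0.50, 0.95, 0.00),
    direction = c(">=", ">=", "=="),
    stringsAsFactors = FALSE
  )
  goals$achieved <- vapply(goals$threshold_Gy, vol_at, 0)
  goals$pass <- ifelse(goals$direction == ">=",
                       goals$achieved >= goals$required,
                       goals$achieved == goals$required)
  structure(goals, class = c("plan_goal_report", "data.frame"))
}

#' @export
print.plan_goal_report <- function(x, ...) {
  cat("<plan_goal_report>\n")
  df <- as.data.frame(x)
  df$achieved <- sprintf("%.1f%%", 100 * df$achieved)
  print(df[, c("goal", "threshold_Gy", "achieved", "pass")], row.names = FALSE)
  invisible(x)
}

#' Export a metrics-difference table to CSV
#'
#' One row per ROI with the signed relative differences (`dd98`, `dd2`,
#' `ddmean`, percent), the layout of a per-structure comparison table.
#' @param rows data frame with columns roi, dd98, dd2, ddmean
#' @param path output CSV path
#' @export
write_metrics_csv <- function(rows, path) {
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
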