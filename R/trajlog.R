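## Trajectory-log parsing and machine-control error statistics.
##
## A trajectory log holds time-sampled expected and actual machine axis
## values (per-leaf MLC positions for both banks, cumulative MU, gantry
## angle, jaw positions) at a fixed sampling interval (20 ms on the modelled
## machine). Leaf positions follow the bank convention: bank A is the lower
## edge and bank B the upper edge of each pair in the leaf-travel direction,
## so pair gap = B - A >= 0 for any open pair.

#' Leaf-width profile of a multileaf collimator
#'
#' The Millennium-120 layout has 60 leaf pairs: 40 central pairs of 5 mm
#' width flanked by 2 x 10 outer pairs of 10 mm, stacked symmetrically about
#' the beam axis. Other MLCs can be described by passing widths directly to
#' [control_point_sequence()].
#'
#' @param name machine profile name; only `"millennium120"` is built in
#' @return numeric vector of per-pair leaf widths, mm, in stack order
#' @export
mlc_leaf_widths <- function(name = "millennium120") {
  switch(name,
    millennium120 = c(rep(10, 10), rep(5, 40), rep(10, 10)),
    stop("unknown MLC profile: ", name)
  )
}

# y interval (perpendicular to leaf travel) covered by each pair, centred
leaf_edges <- function(widths) {
  hi <- cumsum(widths) - sum(widths) / 2
  cbind(lo = hi - widths, hi = hi)
}

#' Per-control-point aperture description of a DMLC plan
#'
#' @param bank_a,bank_b numeric matrices, control points x leaf pairs, of
#'   leaf-end positions in mm (B >= A for open pairs)
#' @param mu cumulative fractional MU at each control point, in `[0, 1]`,
#'   non-decreasing
#' @param leaf_widths per-pair widths, mm (default Millennium-120)
#' @param jaw jaw window `c(x1, x2, y1, y2)` in mm; x clips the gap along
#'   leaf travel, y selects which pairs are exposed
#' @return an object of class `control_point_sequence`
#' @export
control_point_sequence <- function(bank_a, bank_b, mu,
                                   leaf_widths = mlc_leaf_widths(),
                                   jaw = c(-200, 200, -200, 200)) {
  bank_a <- rbind(bank_a); bank_b <- rbind(bank_b)
  stopifnot(identical(dim(bank_a), dim(bank_b)),
            ncol(bank_a) == length(leaf_widths),
            length(mu) == nrow(bank_a), length(jaw) == 4L)
  if (any(bank_b - bank_a < 0))
    stop("bank B position must be >= bank A position for every pair")
  if (any(mu < 0) || any(mu > 1) || any(diff(mu) < 0))
    stop("fractional MU must lie in [0,1] and be non-decreasing")
  structure(list(bank_a = bank_a, bank_b = bank_b, mu = as.numeric(mu),
                 leaf_widths = as.numeric(leaf_widths), jaw = as.numeric(jaw)),
            class = "control_point_sequence")
}

#' @export
print.control_point_sequence <- function(x, ...) {
  cat(sprintf("<control_point_sequence> %d control points, %d leaf pairs\n",
              nrow(x$bank_a), ncol(x$bank_a)))
  invisible(x)
}

#' Trajectory log of a delivered beam
#'
#' @param sampling_interval_ms sampling interval, ms (20 on the modelled
#'   machine)
#' @param t_ms sample timestamps, ms
#' @param mu_exp,mu_act expected / actual cumulative MU per sample
#'   (non-decreasing)
#' @param gantry_exp,gantry_act gantry angle per sample, deg
#' @param jaw_exp,jaw_act n x 4 matrices of jaw positions, mm
#' @param a_exp,a_act,b_exp,b_act n x n_pairs matrices of leaf positions for
#'   banks A and B, mm
#' @param beam_id label
#' @return an object of class `trajectory_log`
#' @export
trajectory_log <- function(sampling_interval_ms, t_ms, mu_exp, mu_act,
                           gantry_exp, gantry_act, jaw_exp, jaw_act,
                           a_exp, a_act, b_exp, b_act, beam_id = "beam") {
  stopifnot(sampling_interval_ms > 0)
  n <- length(t_ms)
  a_exp <- rbind(a_exp); a_act <- rbind(a_act)
  b_exp <- rbind(b_exp); b_act <- rbind(b_act)
  jaw_exp <- rbind(jaw_exp); jaw_act <- rbind(jaw_act)
  stopifnot(length(mu_exp) == n, length(mu_act) == n,
            nrow(a_exp) == n, nrow(a_act) == n,
            nrow(b_exp) == n, nrow(b_act) == n,
            identical(ncol(a_exp), ncol(a_act)),
            identical(ncol(a_exp), ncol(b_exp)),
            identical(ncol(a_exp), ncol(b_act)))
  if (any(diff(mu_exp) < 0))
    stop("integrity error: expected cumulative MU decreases")
  if (any(diff(mu_act) < 0))
    stop("integrity error: actual cumulative MU decreases")
  structure(list(sampling_interval_ms = sampling_interval_ms,
                 t_ms = as.numeric(t_ms),
                 mu_exp = as.numeric(mu_exp), mu_act = as.numeric(mu_act),
                 gantry_exp = as.numeric(gantry_exp),
                 gantry_act = as.numeric(gantry_act),
                 jaw_exp = jaw_exp, jaw_act = jaw_act,
                 a_exp = a_exp, a_act = a_act, b_exp = b_exp, b_act = b_act,
                 beam_id = as.character(beam_id)),
            class = "trajectory_log")
}

#' @export
print.trajectory_log <- function(x, ...) {
  cat(sprintf("<trajectory_log> beam '%s': %d samples @ %g ms, %d leaf pairs, %.1f MU\n",
              x$beam_id, length(x$t_ms), x$sampling_interval_ms,
              ncol(x$a_exp), max(x$mu_exp)))
  invisible(x)
}

## ---- text dialect ----------------------------------------------------------

#' Write a trajectory log in the portable text dialect
#'
#' One sample per line, comma-separated: timestamp, expected/actual MU,
#' expected/actual gantry, 4 expected + 4 actual jaw positions, then the
#' expected bank-A, actual bank-A, expected bank-B and actual bank-B leaf
#' positions. A small `#`-prefixed header carries the sampling interval,
#' beam id and pair count. Round trips via [read_log()] are field-exact.
#'
#' @param log a `trajectory_log`
#' @param path output path
#' @export
write_log <- function(log, path) {
  np <- ncol(log$a_exp)
  hdr <- c("# fracdose-trajectory-log: 1",
           paste0("# beam_id: ", log$beam_id),
           paste0("# sampling_interval_ms: ",
                  sprintf("%.17g", log$sampling_interval_ms)),
           paste0("# n_pairs: ", np),
           paste0("# n_samples: ", length(log$t_ms)))
  num <- function(x) sprintf("%.17g", x)
  rows <- vapply(seq_along(log$t_ms), function(i) {
    paste(num(c(log$t_ms[i], log$mu_exp[i], log$mu_act[i],
                log$gantry_exp[i], log$gantry_act[i],
                log$jaw_exp[i, ], log$jaw_act[i, ],
                log$a_exp[i, ], log$a_act[i, ],
                log$b_exp[i, ], log$b_act[i, ])), collapse = ",")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a trajectory log
#'
#' Only the portable text dialect written by [write_log()] is supported;
#' truncated or corrupted files are rejected (naming the offending record),
#' never silently clipped, and a decreasing MU stream is an integrity error.
#'
#' @param path log file path
#' @param dialect `"text"` (the portable record schema)
#' @return a `trajectory_log`
#' @export
read_log <- function(path, dialect = "text") {
  if (!identical(dialect, "text"))
    stop("format error: unsupported trajectory-log dialect '", dialect, "'")
  if (!file.exists(path)) stop("no such log file: ", path)
  lines <- readLines(path)
  if (length(lines) < 6 || lines[1] != "# fracdose-trajectory-log: 1")
    stop("format error: not a fracdose trajectory log: ", path)
  hval <- function(key) sub(paste0("^# ", key, ": "), "", lines[grepl(paste0("^# ", key, ": "), lines)][1])
  beam_id <- hval("beam_id")
  dt <- as.numeric(hval("sampling_interval_ms"))
  np <- as.integer(hval("n_pairs"))
  ns <- as.integer(hval("n_samples"))
  body <- lines[!grepl("^#", lines)]
  if (length(body) != ns)
    stop("integrity error: header declares ", ns, " samples, file holds ",
         length(body))
  ncols <- 13 + 4 * np
  vals <- matrix(NA_real_, ns, ncols)
  for (i in seq_len(ns)) {
    v <- suppressWarnings(as.numeric(strsplit(body[i], ",", fixed = TRUE)[[1]]))
    if (length(v) != ncols || anyNA(v))
      stop("integrity error: corrupted record at sample ", i)
    vals[i, ] <- v
  }
  ix <- function(from, len) from + seq_len(len) - 1
  trajectory_log(dt, vals[, 1], vals[, 2], vals[, 3], vals[, 4], vals[, 5],
                 vals[, ix(6, 4), drop = FALSE], vals[, ix(10, 4), drop = FALSE],
                 vals[, ix(14, np), drop = FALSE],
                 vals[, ix(14 + np, np), drop = FALSE],
                 vals[, ix(14 + 2 * np, np), drop = FALSE],
                 vals[, ix(14 + 3 * np, np), drop = FALSE],
                 beam_id = beam_id)
}

## ---- error statistics ------------------------------------------------------

new_log_error_stats <- function(mean, sd, n, max_abs, what, unit) {
  structure(list(mean = mean, sd = sd, n_samples = n, max_abs = max_abs,
                 what = what, unit = unit),
            class = "log_error_stats")
}

#' @export
print.log_error_stats <- function(x, ...) {
  cat(sprintf("<log_error_stats> %s: %.3f +/- %.3f %s (n = %d, max |err| = %.3f %s)\n",
              x$what, x$mean, x$sd, x$unit, x$n_samples, x$max_abs, x$unit))
  invisible(x)
}

mlc_diffs <- function(log, moving_only) {
  da <- log$a_act - log$a_exp
  db <- log$b_act - log$b_exp
  if (moving_only) {
    mov <- function(exp) {
      m <- abs(apply(exp, 2, function(col) c(0, diff(col)))) > 0
      m
    }
    d <- c(da[mov(log$a_exp)], db[mov(log$b_exp)])
  } else {
    d <- c(da, db)
  }
  d
}

#' MLC positional error statistics from trajectory logs
#'
#' Signed per-leaf per-sample differences (actual minus expected) pooled
#' over both banks, all leaves and all samples; mean and SD of the pooled
#' sample are reported, together with the maximum absolute error. With
#' `moving_only = TRUE` only samples where the expected position of that
#' leaf changed from the previous sample contribute (a configurable filter;
#' default pools all leaves).
#'
#' @param log a `trajectory_log` or a list of them (fractions/beams pooled)
#' @param moving_only restrict to moving leaves
#' @return a `log_error_stats` in mm
#' @export
mlc_error_stats <- function(log, moving_only = FALSE) {
  logs <- if (inherits(log, "trajectory_log")) list(log) else log
  stopifnot(length(logs) >= 1, all(vapply(logs, inherits, TRUE, "trajectory_log")))
  d <- unlist(lapply(logs, mlc_diffs, moving_only = moving_only))
  if (length(d) == 0) stop("no MLC samples to analyse")
  new_log_error_stats(mean(d), stats::sd(d), length(d), max(abs(d)),
                      "MLC position error (actual - expected)", "mm")
}

#' MU delivery error statistics from trajectory logs
#'
#' Per-sample differences of cumulative MU (actual minus expected). The
#' default statistic is the mean and SD of the absolute differences — a
#' magnitude statistic, matching how a positive mean with equal SD arises
#' from a one-sided delivery lag; `signed = TRUE` reports the signed
#' differences instead.
#'
#' @param log a `trajectory_log` or a list of them
#' @param signed report signed instead of absolute differences
#' @return a `log_error_stats` in MU
#' @export
mu_error_stats <- function(log, signed = FALSE) {
  logs <- if (inherits(log, "trajectory_log")) list(log) else log
  stopifnot(length(logs) >= 1, all(vapply(logs, inherits, TRUE, "trajectory_log")))
  d <- unlist(lapply(logs, function(l) l$mu_act - l$mu_exp))
  if (length(d) == 0) stop("no MU samples to analyse")
  dd <- if (signed) d else abs(d)
  new_log_error_stats(mean(dd), stats::sd(dd), length(dd), max(abs(d)),
                      if (signed) "MU error (actual - expected)"
                      else "MU error |actual - expected|", "MU")
}

#' Aperture statistics of a DMLC control-point sequence
#'
#' Per control point, aperture area is the sum over open leaf pairs of
#' (bank B - bank A) x leaf width, with the gap clipped to the x-jaw window
#' and pairs outside the y-jaw window excluded; mean gap width is the mean
#' over open pairs of the clipped gap. A pair is open iff its clipped gap
#' exceeds `closed_threshold` (default 0.5 mm, the parked closed-pair gap).
#' Results are averaged over control points.
#'
#' @param cps a `control_point_sequence`
#' @param closed_threshold closed-gap threshold, mm
#' @param total_mu total plan MU represented by `cps` (scales the reported
#'   `total_mu`; default 1 reports the fractional MU span)
#' @return list: `mean_aperture_cm2`, `mean_gap_mm`, `total_mu`,
#'   `per_control_point` data frame
#' @export
aperture_stats <- function(cps, closed_threshold = 0.5, total_mu = 1) {
  stopifnot(inherits(cps, "control_point_sequence"))
  edges <- leaf_edges(cps$leaf_widths)
  in_y <- edges[, "hi"] > cps$jaw[3] & edges[, "lo"] < cps$jaw[4]
  ncp <- nrow(cps$bank_a)
  area <- numeric(ncp); gapw <- numeric(ncp)
  for (i in seq_len(ncp)) {
    a <- pmax(cps$bank_a[i, ], cps$jaw[1])
    b <- pmin(cps$bank_b[i, ], cps$jaw[2])
    gap <- pmax(b - a, 0)
    open <- in_y & gap > closed_threshold
    area[i] <- sum(gap[open] * cps$leaf_widths[open]) / 100  # mm^2 -> cm^2
    gapw[i] <- if (any(open)) mean(gap[open]) else NA_real_
  }
  if (all(!is.finite(gapw)))
    warning("degenerate aperture: no open leaf pairs in any control point")
  list(mean_aperture_cm2 = mean(area),
       mean_gap_mm = mean(gapw[is.finite(gapw)]),
       total_mu = total_mu * (max(cps$mu) - min(cps$mu)),
       per_control_point = data.frame(cp = seq_len(ncp),
                                      aperture_cm2 = area, gap_mm = gapw))
}

#' Check log-derived statistics against configured QA tolerances
#'
#' Tolerances come from the user's QA programme configuration (e.g. the
#' machine-QA guideline their clinic follows); none are hard-coded. Each
#' supplied tolerance is compared against the corresponding statistic.
#'
#' @param stats named list of statistics, e.g.
#'   `list(mlc_max_abs_mm = ..., mu_mean = ...)`
#' @param tolerances named list of limits; every name must be present in
#'   `stats`
#' @return data frame with columns statistic, value, tolerance, pass
#' @export
tolerance_check <- function(stats, tolerances) {
  if (length(tolerances) == 0)
    stop("configuration error: empty tolerance table")
  missing <- setdiff(names(tolerances), names(stats))
  if (length(missing))
    stop("configuration error: no statistic for tolerance entr",
         if (length(missing) > 1) "ies " else "y ",
         paste(missing, collapse = ", "))
  data.frame(
    statistic = names(tolerances),
    value = vapply(names(tolerances), function(k) abs(stats[[k]]), 0),
    tolerance = vapply(tolerances, as.numeric, 0),
    pass = vapply(names(tolerances),
                  function(k) abs(stats[[k]]) <= tolerances[[k]], TRUE),
    row.names = NULL
  )
}

#' Per-beam log-QA report rows
#'
#' One row per beam: MLC mean/SD, MU mean/SD, maximum absolute MLC error and
#' aperture statistics, the layout exported to the pipeline's log-QA CSV.
#'
#' @param logs list of `trajectory_log`
#' @param cps_list optional list of matching `control_point_sequence`
#' @return data frame
#' @export
log_report <- function(logs, cps_list = NULL) {
  rows <- lapply(seq_along(logs), function(i) {
    l <- logs[[i]]
    ml <- mlc_error_stats(l)
    mu <- mu_error_stats(l)
    row <- data.frame(beam = l$beam_id,
                      mlc_mean_mm = ml$mean, mlc_sd_mm = ml$sd,
                      max_abs_mlc_mm = ml$max_abs,
                      mu_mean = mu$mean, mu_sd = mu$sd,
                      n_samples = length(l$t_ms))
    if (!is.null(cps_list)) {
      ap <- aperture_stats(cps_list[[i]])
      row$mean_aperture_cm2 <- ap$mean_aperture_cm2
      row$mean_gap_mm <- ap$mean_gap_mm
    }
    row
  })
  do.call(rbind, rows)
}
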