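## End-to-end orchestration of the three analyses: log QA, setup-error
## blurring, CBCT-course daily/accumulated dose; CSV outputs and a run
## manifest for provenance.

# small stable Adler-32 hash of any R object (provenance only)
config_hash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  cs <- 1 + cumsum(as.numeric(b))
  a <- cs[length(cs)] %% 65521
  s2 <- sum(cs %% 65521) %% 65521
  sprintf("%04x%04x", as.integer(s2), as.integer(a))
}

#' Pipeline configuration
#'
#' One config controls all three analyses; each stage can be toggled. The
#' master `seed` derives the per-stage seeds, so a run is reproducible from
#' the config alone.
#'
#' @param seed master seed
#' @param phantom a `phantom_config`
#' @param variation a `daily_variation_config` (its seed is overridden by
#'   the derived stage seed)
#' @param blur a `setup_error_config` (seed likewise derived)
#' @param log_errors a `log_error_model` (seed likewise derived)
#' @param n_fractions planned fractions (default 28)
#' @param prescription Gy (default 50.4)
#' @param n_beams daily-dose beam count (default 7)
#' @param exclude_fractions integer fraction indices excluded from the
#'   course (data corruption etc.); they are logged, skipped in comparison
#'   and compensated in accumulation
#' @param art_threshold_percent fractional CTV dD98% above which the
#'   adaptive-replanning flag is set (default 2)
#' @param stages character subset of `c("logs", "blur", "course")`
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1,
                            phantom = phantom_config(),
                            variation = daily_variation_config(),
                            blur = setup_error_config(),
                            log_errors = log_error_model(),
                            n_fractions = 28,
                            prescription = 50.4,
                            n_beams = 7,
                            exclude_fractions = integer(),
                            art_threshold_percent = 2,
                            stages = c("logs", "blur", "course")) {
  stopifnot(inherits(phantom, "phantom_config"),
            inherits(variation, "daily_variation_config"),
            inherits(blur, "setup_error_config"),
            inherits(log_errors, "log_error_model"),
            n_fractions >= 1, prescription >= 0,
            all(stages %in% c("logs", "blur", "course")))
  seed <- as.integer(seed)
  phantom$seed <- seed
  variation$seed <- seed + 1000L
  blur$seed <- seed + 2000L
  log_errors$seed <- seed + 3000L
  structure(list(seed = seed, phantom = phantom, variation = variation,
                 blur = blur, log_errors = log_errors,
                 n_fractions = as.integer(n_fractions),
                 prescription = prescription, n_beams = as.integer(n_beams),
                 exclude_fractions = as.integer(exclude_fractions),
                 art_threshold_percent = art_threshold_percent,
                 stages = stages),
            class = "pipeline_config")
}

# daily relative-electron-density volume on the planning grid: CBCT HU
# through the CBCT calibration inside the FOV (read in the fraction frame
# through the registration), planning density elsewhere
daily_density_on_plan <- function(phantom, plan_red, frac, curves) {
  cbct <- frac$cbct
  pts <- voxel_centers(phantom$ct)
  fpts <- transform_points(frac$registration, pts)
  r <- sqrt(fpts[, 1]^2 + fpts[, 2]^2)
  fov_r <- if (is.null(cbct$fov_radius_mm)) Inf else cbct$fov_radius_mm
  use_cbct <- r <= fov_r - max(cbct$spacing)
  red <- as.numeric(plan_red)
  if (any(use_cbct)) {
    hu <- sample_volume(cbct, fpts[use_cbct, , drop = FALSE])
    red[use_cbct] <- eval_hu_curve(curves$cbct, hu)
  }
  array(red, dim(phantom$ct$voxels))
}

#' Run the CBCT daily-dose course analysis
#'
#' For each fraction of a [make_daily_series()] course: the daily density is
#' assembled on the planning grid (CBCT calibration inside the FOV,
#' planning CT elsewhere), the fraction dose is estimated with the
#' path-length perturbation model inside the body + 2 cm region, compared
#' ROI by ROI against the planned fraction dose, and DSC of the daily organ
#' masks against planning is recorded; finally the non-excluded fractions
#' are accumulated and compared with the full plan.
#'
#' @param phantom a [make_phantom()] result
#' @param planned full-course planned `dose_grid`
#' @param series a [make_daily_series()] result
#' @param config a `pipeline_config` (exclusions, beams, thresholds)
#' @param step ray-marching step, mm (default half min spacing)
#' @return list: `per_fraction` (data frame), `accumulated`
#'   (`accumulated_dose`), `dsc` (data frame), `paired` (`paired_test` on
#'   CTV D98), `records`
#' @export
run_course <- function(phantom, planned, series, config, step = NULL) {
  curves <- default_hu_curves(config$variation$cbct_hu_offset)
  plan_red <- apply_hu_curve(phantom$ct, curves$planning)
  region <- expand_body_region(phantom$structures$body, 20)
  beams <- beam_model(config$n_beams, isocenter = phantom$isocenter)
  n <- length(series)
  frac_planned <- dose_grid(planned$dose * (1 / n), planned$spacing,
                            planned$origin, planned$frame_id)
  rois <- phantom$structures[c("ctv", "bladder", "rectum",
                               "femoral_head_R", "femoral_head_L")]
  sel <- as.vector(region$mask)
  pts <- voxel_centers(planned)[sel, , drop = FALSE]
  plan_depth <- beam_depths(plan_red, planned$spacing, planned$origin,
                            beams, pts, step = step)
  records <- vector("list", n)
  frac_rows <- list()
  dsc_rows <- list()
  for (k in seq_len(n)) {
    fr <- series[[k]]
    excl <- fr$fraction_index %in% config$exclude_fractions
    if (excl) {
      records[[k]] <- fraction_record(fr$fraction_index, frac_planned,
                                      fr$registration, cbct = fr$cbct,
                                      excluded = TRUE,
                                      reason = "data corruption")
      frac_rows[[k]] <- data.frame(fraction = fr$fraction_index,
                                   roi = NA_character_, dd98 = NA_real_,
                                   dd2 = NA_real_, ddmean = NA_real_,
                                   excluded = TRUE, art_flag = NA)
      next
    }
    daily_red <- daily_density_on_plan(phantom, plan_red, fr, curves)
    delivered <- fraction_dose_estimate(frac_planned, plan_red, daily_red,
                                        beams, region = region, step = step,
                                        plan_depth = plan_depth)
    rec <- fraction_record(fr$fraction_index, delivered, fr$registration,
                           cbct = fr$cbct)
    records[[k]] <- rec
    cmp <- compare_fraction(frac_planned, rec, rois)
    cmp$art_flag <- cmp$roi == "CTV" & cmp$dd98 > config$art_threshold_percent
    frac_rows[[k]] <- cmp
    dsc_rows[[k]] <- fraction_dsc(phantom, fr)
  }
  per_fraction <- do.call(rbind, frac_rows)
  accumulated <- accumulate_rigid(records, planned, n_planned = n,
                                  rois = rois)
  ctv_rows <- per_fraction[!is.na(per_fraction$roi) &
                             per_fraction$roi == "CTV", ]
  planned_d98 <- dvh_metrics(frac_planned, phantom$structures$ctv)$d98
  delivered_d98 <- planned_d98 * (1 - ctv_rows$dd98 / 100)
  paired <- paired_comparison_test(rep(planned_d98, nrow(ctv_rows)),
                                   delivered_d98)
  list(per_fraction = per_fraction, accumulated = accumulated,
       dsc = do.call(rbind, dsc_rows), paired = paired, records = records)
}

# DSC of daily organ masks against planning (daily organ geometry is known
# analytically for the synthetic course)
fraction_dsc <- function(phantom, frac) {
  cfg <- phantom$config
  sp <- cfg$spacing
  org <- phantom_origin(cfg)
  bl_scale <- if (is.null(frac$bladder_scale)) 1 else frac$bladder_scale
  daily_bladder <- structure_mask(
    "bladder",
    ellipsoid_mask(cfg, cfg$bladder_center,
                   rep(cfg$bladder_radius * bl_scale, 3)),
    sp, org)
  s <- phantom$structures
  data.frame(
    fraction = frac$fraction_index,
    roi = c("bladder", "rectum", "femoral_head_R", "femoral_head_L"),
    dsc = c(dice_coefficient(s$bladder, daily_bladder),
            1, 1, 1)  # rectum wall and bone do not deform in the generator
  )
}

#' Run the full three-component pipeline
#'
#' Generates the synthetic inputs, runs the enabled stages and writes the
#' report bundle to `out_dir`: `log_qa.csv`, `blur_sim.csv`,
#' `per_fraction.csv`, `accumulated.csv`, `dsc.csv`, `paired_test.csv` and
#' `manifest.json`. Rerunning with the same config reproduces every output
#' byte-identically.
#'
#' @param config a `pipeline_config`
#' @param out_dir output directory (created if missing)
#' @return (invisibly) list with the in-memory stage results and the
#'   manifest
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_all <- list()
  tick <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, s = proc.time()[["elapsed"]] - t0)
  }
  phantom <- make_phantom(config$phantom)
  planned <- make_plan_dose(phantom, prescription = config$prescription)
  results <- list()

  if ("logs" %in% config$stages) {
    st <- tick({
      cps <- make_control_points()
      logs <- lapply(seq_len(config$n_beams), function(b)
        make_trajectory_log(cps,
                            log_error_model(config$log_errors$mlc_bias_mm,
                                            config$log_errors$mlc_sd_mm,
                                            config$log_errors$mu_lag_mean,
                                            seed = config$log_errors$seed + b),
                            beam_id = paste0("beam", b)))
      rep <- log_report(logs, rep(list(cps), config$n_beams))
      write.csv(rep, file.path(out_dir, "log_qa.csv"), row.names = FALSE)
      list(report = rep, logs = logs)
    })
    results$logs <- st$value
    t_all$logs <- st$s
    message(sprintf("stage logs: %d beams analysed (%.1f s)",
                    config$n_beams, st$s))
  }

  if ("blur" %in% config$stages) {
    st <- tick({
      bs <- simulate_setup_errors(planned, phantom$structures$ctv,
                                  config$blur, isocenter = phantom$isocenter)
      write_blur_csv(bs, file.path(out_dir, "blur_sim.csv"))
      bs
    })
    results$blur <- st$value
    t_all$blur <- st$s
    message(sprintf("stage blur: %d simulations (%.1f s)",
                    config$blur$n_sims, st$s))
  }

  if ("course" %in% config$stages) {
    st <- tick({
      series <- make_daily_series(phantom, config$n_fractions,
                                  config$variation)
      course <- run_course(phantom, planned, series, config)
      write.csv(course$per_fraction,
                file.path(out_dir, "per_fraction.csv"), row.names = FALSE)
      write.csv(course$accumulated$per_roi,
                file.path(out_dir, "accumulated.csv"), row.names = FALSE)
      write.csv(course$dsc, file.path(out_dir, "dsc.csv"), row.names = FALSE)
      pt <- course$paired
      write.csv(data.frame(metric = "CTV_D98", t = pt$t, df = pt$df,
                           p_value = pt$p_value,
                           mean_difference_Gy = pt$mean_difference,
                           degenerate = pt$degenerate),
                file.path(out_dir, "paired_test.csv"), row.names = FALSE)
      course
    })
    results$course <- st$value
    t_all$course <- st$s
    message(sprintf(
      "stage course: %d fractions processed, %d excluded (%.1f s)",
      config$n_fractions, length(config$exclude_fractions), st$s))
  }

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    stage_seeds = list(variation = config$variation$seed,
                       blur = config$blur$seed,
                       logs = config$log_errors$seed),
    stages = config$stages,
    n_fractions = config$n_fractions,
    excluded_fractions = config$exclude_fractions,
    timings_s = t_all,
    package_version = as.character(utils::packageVersion("fracdose"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, manifest = manifest))
}
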