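## Synthetic pelvic phantom, plan dose, daily anatomies and trajectory logs.
##
## The phantom is deliberately minimal (elliptical body cylinder, ellipsoid
## CTV, spherical bladder and femoral heads, tubular rectum): the analyses
## downstream are mechanism-level — margins, penumbra, upstream path length —
## not anatomical fidelity.

#' Configuration of the synthetic pelvic phantom
#'
#' Defaults follow the study conditions of the modelled treatment: 2 mm
#' isotropic dose-calculation grid, a 7 mm isotropic CTV-to-PTV margin, and
#' organ geometries chosen so every structure lies inside the body and the
#' OARs are disjoint from the CTV.
#'
#' @param dim grid dimensions (voxels)
#' @param spacing voxel size, mm
#' @param body_semi_axes body ellipse semi-axes (x, y), mm; the body is an
#'   elliptical cylinder along z
#' @param ctv_semi_axes CTV ellipsoid semi-axes, mm
#' @param ctv_center CTV centre, mm
#' @param ptv_margin_mm isotropic CTV-to-PTV expansion, mm (default 7)
#' @param bladder_center,bladder_radius bladder sphere, mm
#' @param rectum_center_y,rectum_radius rectum tube (along z), mm
#' @param femhead_x,femhead_radius femoral-head spheres at (+/-x, 0, 0), mm
#' @param hu_soft,hu_bone,hu_gas tissue HU values
#' @param seed generator seed
#' @return an object of class `phantom_config`
#' @export
phantom_config <- function(dim = c(128, 128, 64), spacing = c(2, 2, 2),
                           body_semi_axes = c(115, 85),
                           ctv_semi_axes = c(45, 35, 42),
                           ctv_center = c(0, -10, 0),
                           ptv_margin_mm = 7,
                           bladder_center = c(0, 50, 0), bladder_radius = 20,
                           rectum_center_y = -62, rectum_radius = 10,
                           femhead_x = 78, femhead_radius = 20,
                           hu_soft = 20, hu_bone = 700, hu_gas = -1000,
                           seed = 1) {
  stopifnot(length(dim) == 3, all(dim >= 8), all(spacing > 0),
            ptv_margin_mm >= 0)
  if (any(c(ctv_semi_axes, bladder_radius, rectum_radius, femhead_radius) <= 0))
    stop("geometry error: zero-size organ")
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 body_semi_axes = body_semi_axes,
                 ctv_semi_axes = ctv_semi_axes, ctv_center = ctv_center,
                 ptv_margin_mm = ptv_margin_mm,
                 bladder_center = bladder_center,
                 bladder_radius = bladder_radius,
                 rectum_center_y = rectum_center_y,
                 rectum_radius = rectum_radius,
                 femhead_x = femhead_x, femhead_radius = femhead_radius,
                 hu_soft = hu_soft, hu_bone = hu_bone, hu_gas = hu_gas,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# centred grid origin so (0,0,0) mm is the grid centre
phantom_origin <- function(config) {
  -(config$dim - 1) / 2 * config$spacing
}

# coordinate arrays (mm) of the phantom grid, broadcast-ready
grid_coords <- function(config) {
  o <- phantom_origin(config)
  list(x = o[1] + (seq_len(config$dim[1]) - 1) * config$spacing[1],
       y = o[2] + (seq_len(config$dim[2]) - 1) * config$spacing[2],
       z = o[3] + (seq_len(config$dim[3]) - 1) * config$spacing[3])
}

# logical array of an ellipsoid; semi-axes in mm, Inf allowed (cylinder)
ellipsoid_mask <- function(config, center, semi) {
  cc <- grid_coords(config)
  dx2 <- ((cc$x - center[1]) / semi[1])^2
  dy2 <- ((cc$y - center[2]) / semi[2])^2
  dz2 <- if (is.finite(semi[3])) ((cc$z - center[3]) / semi[3])^2 else
    rep(0, length(cc$z))
  q <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  q <= 1
}

#' Generate the synthetic pelvic phantom
#'
#' Deterministic given the config. Returns the planning CT (HU) and masks
#' for body, CTV, PTV (CTV expanded isotropically by the configured margin,
#' via exact distance transform), bladder, rectum, both femoral heads and
#' bone.
#'
#' @param config a `phantom_config`
#' @return list: `ct` (`image_volume`), `structures` (named list of
#'   `structure_mask`), `isocenter` (mm), `config`
#' @export
make_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  sp <- config$spacing
  org <- phantom_origin(config)
  body <- ellipsoid_mask(config, c(0, 0, 0),
                         c(config$body_semi_axes, Inf))
  ctv <- ellipsoid_mask(config, config$ctv_center, config$ctv_semi_axes)
  bladder <- ellipsoid_mask(config, config$bladder_center,
                            rep(config$bladder_radius, 3))
  rectum <- ellipsoid_mask(config, c(0, config$rectum_center_y, 0),
                           c(config$rectum_radius, config$rectum_radius, Inf))
  fem_r <- ellipsoid_mask(config, c(config$femhead_x, 0, 0),
                          rep(config$femhead_radius, 3))
  fem_l <- ellipsoid_mask(config, c(-config$femhead_x, 0, 0),
                          rep(config$femhead_radius, 3))
  for (m in list(ctv, bladder, rectum, fem_r, fem_l))
    if (any(m & !body))
      stop("geometry error: structure extends outside the body")
  mk <- function(name, m) structure_mask(name, m, sp, org)
  ctv_mask <- mk("CTV", ctv)
  ptv <- expand_body_region(ctv_mask, config$ptv_margin_mm)
  ptv$name <- "PTV"
  if (any(ptv$mask & !body))
    stop("geometry error: PTV extends outside the body")
  bone <- fem_r | fem_l
  hu <- array(-1000, config$dim)
  hu[body] <- config$hu_soft
  hu[bladder] <- 10
  hu[bone] <- config$hu_bone
  structures <- list(
    body = mk("body", body), ctv = ctv_mask, ptv = ptv,
    bladder = mk("bladder", bladder), rectum = mk("rectum", rectum),
    femoral_head_R = mk("femoral_head_R", fem_r),
    femoral_head_L = mk("femoral_head_L", fem_l),
    bone = mk("bone", bone)
  )
  list(ct = image_volume(hu, sp, org),
       structures = structures,
       isocenter = config$ctv_center,
       config = config)
}

#' Synthetic planned dose for the phantom
#'
#' A prescription-level plateau exactly covering the PTV with a cosine
#' penumbra outside it: with `d` the Euclidean distance outside the PTV
#' surface, the dose is `Rx` for `d <= 0` and
#' `Rx * 0.5 * (1 + cos(pi * d / (2 * falloff_mm)))` out to `2 * falloff_mm`
#' (50% of prescription at `falloff_mm` outside the PTV), then 0. Because
#' the PTV is the CTV expanded by the planning margin, the uniform plateau
#' extends at least that margin beyond the CTV, which is the geometric
#' mechanism protecting coverage against small rigid setup errors. The
#' resulting plan satisfies the three PTV planning goals by construction
#' (verify with [evaluate_plan_goals()]).
#'
#' @param phantom a [make_phantom()] result
#' @param prescription prescription dose, Gy (default 50.4, delivered in 28
#'   daily fractions)
#' @param falloff_mm penumbra scale: distance outside the PTV at which the
#'   dose falls to 50% (default 5)
#' @return a `dose_grid` in the planning frame
#' @export
make_plan_dose <- function(phantom, prescription = 50.4, falloff_mm = 5) {
  if (!is.numeric(falloff_mm) || falloff_mm <= 0)
    stop("falloff_mm must be positive")
  ptv <- phantom$structures$ptv
  if (prescription == 0) {
    warning("zero prescription: all-zero dose, plan goals are degenerate")
    return(dose_grid(array(0, dim(ptv$mask)), ptv$spacing, ptv$origin))
  }
  d <- distance_to_mask(ptv)
  f <- ifelse(d <= 0, 1,
              ifelse(d >= 2 * falloff_mm, 0,
                     0.5 * (1 + cos(pi * d / (2 * falloff_mm)))))
  dose_grid(prescription * f, ptv$spacing, ptv$origin, "planning")
}

#' Configuration of day-to-day anatomical variation
#'
#' Models the interfractional change mechanisms of pelvic radiotherapy:
#' radial body-contour change (weight drift plus a random component, mm of
#' change at the skin per fraction), stochastic rectal gas pockets, bladder
#' filling scale, CBCT HU inaccuracy (constant offset plus Gaussian noise)
#' and the limited reconstruction field of view. With every magnitude at 0
#' the generated CBCT reproduces the planning anatomy exactly.
#'
#' @param weight_drift_mm_per_fraction systematic radial body change per
#'   fraction, mm (positive = gain)
#' @param weight_sd_mm random per-fraction radial change SD, mm
#' @param gas_probability per-fraction probability of a rectal gas pocket
#' @param gas_length_mm gas pocket length range along the rectum, mm
#' @param bladder_scale_sd SD of the per-fraction bladder radius scale
#'   (about 1)
#' @param cbct_hu_offset constant CBCT HU bias
#' @param cbct_noise_sd CBCT HU noise SD
#' @param fov_diameter_mm CBCT reconstruction field of view (default 260)
#' @param setup_sd_mm SD of the per-fraction residual registration
#'   translations, mm
#' @param seed generator seed
#' @return an object of class `daily_variation_config`
#' @export
daily_variation_config <- function(weight_drift_mm_per_fraction = 0,
                                   weight_sd_mm = 0,
                                   gas_probability = 0,
                                   gas_length_mm = c(15, 25),
                                   bladder_scale_sd = 0,
                                   cbct_hu_offset = 0,
                                   cbct_noise_sd = 0,
                                   fov_diameter_mm = 260,
                                   setup_sd_mm = 0,
                                   seed = 1) {
  stopifnot(weight_sd_mm >= 0, gas_probability >= 0, gas_probability <= 1,
            bladder_scale_sd >= 0, cbct_noise_sd >= 0, fov_diameter_mm > 0,
            setup_sd_mm >= 0)
  structure(list(weight_drift_mm_per_fraction = weight_drift_mm_per_fraction,
                 weight_sd_mm = weight_sd_mm,
                 gas_probability = gas_probability,
                 gas_length_mm = gas_length_mm,
                 bladder_scale_sd = bladder_scale_sd,
                 cbct_hu_offset = cbct_hu_offset,
                 cbct_noise_sd = cbct_noise_sd,
                 fov_diameter_mm = fov_diameter_mm,
                 setup_sd_mm = setup_sd_mm,
                 seed = as.integer(seed)),
            class = "daily_variation_config")
}

# daily anatomy HU volume for one fraction: regenerate the phantom with
# perturbed geometry parameters (analytic, so the null case is exact)
daily_anatomy <- function(phantom, body_delta_mm = 0, bladder_scale = 1,
                          gas = NULL) {
  cfg <- phantom$config
  if (body_delta_mm == 0 && bladder_scale == 1 && is.null(gas))
    return(phantom$ct)
  cfg2 <- cfg
  cfg2$body_semi_axes <- cfg$body_semi_axes + body_delta_mm
  cfg2$bladder_radius <- cfg$bladder_radius * bladder_scale
  body <- ellipsoid_mask(cfg2, c(0, 0, 0), c(cfg2$body_semi_axes, Inf))
  bladder <- ellipsoid_mask(cfg2, cfg2$bladder_center,
                            rep(cfg2$bladder_radius, 3))
  fem_r <- ellipsoid_mask(cfg2, c(cfg2$femhead_x, 0, 0),
                          rep(cfg2$femhead_radius, 3))
  fem_l <- ellipsoid_mask(cfg2, c(-cfg2$femhead_x, 0, 0),
                          rep(cfg2$femhead_radius, 3))
  hu <- array(-1000, cfg2$dim)
  hu[body] <- cfg2$hu_soft
  hu[bladder] <- 10
  hu[fem_r | fem_l] <- cfg2$hu_bone
  if (!is.null(gas)) {
    # gas pocket: a tube segment inside the rectum, anterior of the CTV's
    # posterior aspect, replacing soft tissue with gas HU
    gm <- ellipsoid_mask(cfg2, c(0, cfg2$rectum_center_y, gas$z_mm),
                         c(cfg2$rectum_radius, cfg2$rectum_radius,
                           gas$length_mm / 2))
    hu[gm] <- cfg2$hu_gas
  }
  image_volume(hu, cfg2$spacing, phantom_origin(cfg2))
}

# crop a full anatomy volume to the CBCT FOV cylinder and add HU corruption
as_cbct <- function(vol, variation, rng_noise = TRUE) {
  cfg_dim <- dim(vol$voxels)
  cc <- list(x = vol$origin[1] + (seq_len(cfg_dim[1]) - 1) * vol$spacing[1],
             y = vol$origin[2] + (seq_len(cfg_dim[2]) - 1) * vol$spacing[2])
  r2 <- outer(cc$x^2, cc$y^2, `+`)
  inside <- array(rep(r2 <= (variation$fov_diameter_mm / 2)^2, cfg_dim[3]),
                  cfg_dim)
  hu <- vol$voxels
  if (variation$cbct_hu_offset != 0) hu <- hu + variation$cbct_hu_offset
  if (rng_noise && variation$cbct_noise_sd > 0)
    hu <- hu + array(rnorm(length(hu), 0, variation$cbct_noise_sd), cfg_dim)
  hu[!inside] <- HU_OUT_OF_FOV
  image_volume(hu, vol$spacing, vol$origin,
               fov_radius_mm = variation$fov_diameter_mm / 2)
}

#' Generate a daily CBCT series for a treatment course
#'
#' Per fraction: the body contour changes radially by the configured drift
#' plus noise, a rectal gas pocket appears with the configured probability,
#' bladder filling varies, the anatomy is imaged as a CBCT (FOV crop, HU
#' offset, noise) and a residual registration is drawn. All draws are
#' seeded. With an all-zero variation config every fraction reproduces the
#' planning anatomy exactly.
#'
#' @param phantom a [make_phantom()] result
#' @param n_fractions number of fractions (default 28)
#' @param variation a `daily_variation_config`
#' @return list of per-fraction inputs: each element has `fraction_index`,
#'   `cbct` (`image_volume`), `registration` (`rigid_transform`),
#'   `anatomy` (the uncorrupted daily `image_volume`, for oracles),
#'   `body_delta_mm`, `has_gas`
#' @export
make_daily_series <- function(phantom, n_fractions = 28,
                              variation = daily_variation_config()) {
  stopifnot(inherits(variation, "daily_variation_config"), n_fractions >= 1)
  set.seed(variation$seed)
  lapply(seq_len(n_fractions), function(k) {
    delta <- variation$weight_drift_mm_per_fraction * k +
      (if (variation$weight_sd_mm > 0) rnorm(1, 0, variation$weight_sd_mm) else 0)
    bl_scale <- if (variation$bladder_scale_sd > 0)
      max(0.2, 1 + rnorm(1, 0, variation$bladder_scale_sd)) else 1
    gas <- NULL
    if (variation$gas_probability > 0 &&
        runif(1) < variation$gas_probability) {
      gas <- list(length_mm = runif(1, variation$gas_length_mm[1],
                                    variation$gas_length_mm[2]),
                  z_mm = 0)
    }
    anatomy <- daily_anatomy(phantom, body_delta_mm = delta,
                             bladder_scale = bl_scale, gas = gas)
    cbct <- as_cbct(anatomy, variation)
    reg <- if (variation$setup_sd_mm > 0)
      rigid_transform(t = rnorm(3, 0, variation$setup_sd_mm),
                      center = phantom$isocenter)
    else rigid_transform(center = phantom$isocenter)
    list(fraction_index = k, cbct = cbct, registration = reg,
         anatomy = anatomy, body_delta_mm = delta,
         bladder_scale = bl_scale, has_gas = !is.null(gas))
  })
}

#' Analytic deformation field for testing dose warping
#'
#' A uniform scaling warp about a centre: forward displacement
#' `u(x) = magnitude * (x - center)`, whose inverse is available in closed
#' form (`u_inv(x) = -magnitude / (1 + magnitude) * (x - center)`), so
#' warped results can be checked against exact compositions. Invertibility
#' requires `magnitude > -1`.
#'
#' @param phantom a [make_phantom()] result (supplies the grid)
#' @param magnitude scale increment (0 gives the zero field)
#' @param center warp centre, mm (default the isocenter)
#' @param inverse return the analytic inverse field instead
#' @return a `deformation_field`
#' @export
make_analytic_dvf <- function(phantom, magnitude, center = NULL,
                              inverse = FALSE) {
  if (!is.numeric(magnitude) || magnitude <= -1)
    stop("parameter error: magnitude must exceed -1 for invertibility")
  if (is.null(center)) center <- phantom$isocenter
  ct <- phantom$ct
  dm <- dim(ct$voxels)
  pts <- voxel_centers(ct)
  fac <- if (inverse) -magnitude / (1 + magnitude) else magnitude
  disp <- fac * sweep(pts, 2, center)
  deformation_field(array(disp, c(dm, 3)), ct$spacing, ct$origin)
}

#' Injected machine-error law for synthetic trajectory logs
#'
#' @param mlc_bias_mm,mlc_sd_mm Gaussian law of per-leaf per-sample MLC
#'   position error (actual minus expected)
#' @param mu_lag_mean MU delivery lag: per-sample exponential magnitude mean
#'   (actual trails expected); 0 disables
#' @param seed generator seed
#' @return an object of class `log_error_model`
#' @export
log_error_model <- function(mlc_bias_mm = 0, mlc_sd_mm = 0, mu_lag_mean = 0,
                            seed = 1) {
  stopifnot(mlc_sd_mm >= 0, mu_lag_mean >= 0)
  structure(list(mlc_bias_mm = mlc_bias_mm, mlc_sd_mm = mlc_sd_mm,
                 mu_lag_mean = mu_lag_mean, seed = as.integer(seed)),
            class = "log_error_model")
}

#' Synthetic sliding-window control-point sequence
#'
#' A simple DMLC pattern: a window of fixed width sweeps across the central
#' leaf pairs from `x_start` to `x_end`; outer pairs stay parked closed
#' under the jaws. Fractional MU is uniform across control points.
#'
#' @param n_cp number of control points
#' @param window_mm window width, mm
#' @param x_start,x_end sweep range of the leading edge, mm
#' @param open_pairs indices of swept (exposed) leaf pairs
#' @param leaf_widths per-pair widths, mm
#' @return a `control_point_sequence`
#' @export
make_control_points <- function(n_cp = 20, window_mm = 30, x_start = -50,
                                x_end = 50, open_pairs = 21:40,
                                leaf_widths = mlc_leaf_widths()) {
  np <- length(leaf_widths)
  edges <- leaf_edges(leaf_widths)
  lead <- seq(x_start, x_end, length.out = n_cp)
  bank_a <- matrix(0, n_cp, np)   # parked closed
  bank_b <- matrix(0.1, n_cp, np) # 0.1 mm parked gap, under jaws
  for (i in seq_len(n_cp)) {
    bank_a[i, open_pairs] <- lead[i] - window_mm
    bank_b[i, open_pairs] <- lead[i]
  }
  ylim <- range(edges[open_pairs, ])
  control_point_sequence(bank_a, bank_b,
                         mu = seq(0, 1, length.out = n_cp),
                         leaf_widths = leaf_widths,
                         jaw = c(x_start - window_mm - 5, x_end + 5,
                                 ylim[1], ylim[2]))
}

#' Synthesise a trajectory log from a control-point sequence
#'
#' The expected stream interpolates the control points at the machine
#' sampling interval, with cumulative MU linear in time; the requested
#' delivery duration must keep every leaf below the maximum leaf speed
#' (25 mm/s), otherwise a feasibility error is raised. The actual stream
#' adds the injected error law: Gaussian per-leaf position error and an
#' exponential MU delivery lag (clamped so cumulative MU stays
#' non-decreasing).
#'
#' @param cps a `control_point_sequence`
#' @param model a `log_error_model`
#' @param total_mu total beam MU
#' @param duration_s beam-on time, s
#' @param sampling_ms sampling interval, ms (default 20)
#' @param beam_id label
#' @return a `trajectory_log`
#' @export
make_trajectory_log <- function(cps, model = log_error_model(),
                                total_mu = 55, duration_s = 30,
                                sampling_ms = 20, beam_id = "beam") {
  stopifnot(inherits(cps, "control_point_sequence"),
            inherits(model, "log_error_model"),
            total_mu > 0, duration_s > 0, sampling_ms > 0)
  n_cp <- nrow(cps$bank_a)
  np <- ncol(cps$bank_a)
  # leaf speed feasibility at control-point resolution
  cp_dt <- duration_s * diff(cps$mu) / (max(cps$mu) - min(cps$mu))
  speed <- function(bank) {
    dpos <- abs(diff(bank))
    max(dpos / pmax(cp_dt, 1e-9))
  }
  vmax <- max(speed(cps$bank_a), speed(cps$bank_b))
  if (vmax > 25)
    stop(sprintf(
      "feasibility error: control-point motion needs %.1f mm/s (> 25 mm/s leaf-speed limit)",
      vmax))
  t_ms <- seq(0, duration_s * 1000, by = sampling_ms)
  frac <- t_ms / (duration_s * 1000)
  interp_bank <- function(bank) {
    apply(bank, 2, function(col) approx(cps$mu, col, xout = frac, rule = 2)$y)
  }
  a_exp <- interp_bank(cps$bank_a)
  b_exp <- interp_bank(cps$bank_b)
  mu_exp <- total_mu * frac
  set.seed(model$seed)
  noise <- function() {
    if (model$mlc_sd_mm > 0 || model$mlc_bias_mm != 0)
      matrix(rnorm(length(t_ms) * np, model$mlc_bias_mm, model$mlc_sd_mm),
             length(t_ms), np)
    else matrix(0, length(t_ms), np)
  }
  a_act <- a_exp + noise()
  b_act <- b_exp + noise()
  mu_act <- if (model$mu_lag_mean > 0) {
    # delivery lag: exponential-magnitude levels drawn every `block` samples
    # and interpolated linearly between them, so the lag varies slowly
    # enough that the actual cumulative-MU stream stays non-decreasing
    # (level changes are tiny against the per-sample MU increment) while
    # the per-sample lag magnitudes keep the exponential law's mean
    block <- 100L
    nb <- max(2L, ceiling(length(t_ms) / block) + 1L)
    levels <- stats::rexp(nb, 1 / model$mu_lag_mean)
    lag <- approx(x = seq(0, length(t_ms), length.out = nb),
                  y = levels, xout = seq_along(t_ms) - 1)$y
    pmax(mu_exp - lag, 0)
  } else mu_exp
  gantry <- rep(0, length(t_ms))
  jaw <- matrix(rep(cps$jaw, each = length(t_ms)), length(t_ms), 4)
  trajectory_log(sampling_ms, t_ms, mu_exp, mu_act, gantry, gantry,
                 jaw, jaw, a_exp, a_act, b_exp, b_act, beam_id = beam_id)
}
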