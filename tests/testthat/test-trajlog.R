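# Trajectory-log parsing, error statistics, aperture geometry.

# tiny hand-built log: n samples, np pairs, with chosen error fields
tiny_log <- function(n = 5, np = 4, mlc_offset = 0, mu_lag = 0) {
  t_ms <- seq(0, by = 20, length.out = n)
  mu <- seq(0, 10, length.out = n)
  a <- matrix(seq(-20, -10, length.out = n), n, np)
  b <- matrix(seq(10, 20, length.out = n), n, np)
  jaw <- matrix(rep(c(-50, 50, -50, 50), each = n), n, 4)
  trajectory_log(20, t_ms, mu, pmax(mu - mu_lag, 0), rep(0, n), rep(0, n),
                 jaw, jaw, a, a + mlc_offset, b, b + mlc_offset,
                 beam_id = "tiny")
}

test_that("log write/read round trips are field-identical and corruption is caught", {
  log <- tiny_log(n = 7, np = 3, mlc_offset = 0.05, mu_lag = 0.1)
  f <- tempfile(fileext = ".log")
  on.exit(unlink(f))
  write_log(log, f)
  back <- read_log(f)
  for (field in c("t_ms", "mu_exp", "mu_act", "a_exp", "a_act", "b_exp",
                  "b_act", "jaw_exp", "sampling_interval_ms", "beam_id")) {
    expect_equal(back[[field]], log[[field]], info = field)
  }
  # corrupt one record: error names the sample
  lines <- readLines(f)
  lines[8] <- paste0(lines[8], ",999")  # extra column on sample 3
  writeLines(lines, f)
  expect_error(read_log(f), "sample 3")
  # truncation is rejected, not clipped
  write_log(log, f)
  writeLines(readLines(f)[1:9], f)
  expect_error(read_log(f), "integrity")
  expect_error(read_log(f, dialect = "binary"), "dialect")
  expect_error(read_log(tempfile()), "no such")
})

test_that("MU monotonicity is an integrity invariant", {
  n <- 4
  mu_bad <- c(0, 2, 1.5, 3)
  jaw <- matrix(0, n, 4)
  a <- matrix(0, n, 2); b <- matrix(1, n, 2)
  expect_error(
    trajectory_log(20, seq_len(n), mu_bad, mu_bad, rep(0, n), rep(0, n),
                   jaw, jaw, a, a, b, b),
    "integrity")
})

test_that("MLC and MU error statistics recover trivial injected errors", {
  perfect <- tiny_log(mlc_offset = 0, mu_lag = 0)
  s0 <- mlc_error_stats(perfect)
  expect_equal(s0$mean, 0)
  expect_equal(s0$sd, 0)
  m0 <- mu_error_stats(perfect)
  expect_equal(m0$mean, 0)
  biased <- tiny_log(n = 6, mlc_offset = 0.05, mu_lag = 0.1)
  s1 <- mlc_error_stats(biased)
  expect_equal(s1$mean, 0.05)
  expect_equal(s1$sd, 0)
  expect_equal(s1$max_abs, 0.05)
  m1 <- mu_error_stats(biased)
  # first sample clamps at 0 (cumulative MU cannot be negative)
  d <- abs(biased$mu_act - biased$mu_exp)
  expect_equal(m1$mean, mean(d))
  m1s <- mu_error_stats(biased, signed = TRUE)
  expect_equal(m1s$mean, mean(biased$mu_act - biased$mu_exp))
})

test_that("pooling logs reproduces statistics of the concatenated samples", {
  l1 <- tiny_log(n = 5, mlc_offset = 0.1)
  l2 <- tiny_log(n = 9, mlc_offset = -0.2)
  pooled <- mlc_error_stats(list(l1, l2))
  d <- c(l1$a_act - l1$a_exp, l1$b_act - l1$b_exp,
         l2$a_act - l2$a_exp, l2$b_act - l2$b_exp)
  expect_identical(pooled$mean, mean(d))
  expect_identical(pooled$sd, sd(d))
  expect_identical(pooled$n_samples, length(d))
})

test_that("synthetic logs recover the injected Gaussian MLC error law", {
  cps <- make_control_points(n_cp = 10)
  log <- make_trajectory_log(cps, log_error_model(mlc_bias_mm = -0.01,
                                                  mlc_sd_mm = 0.02,
                                                  seed = 42),
                             total_mu = 55, duration_s = 20)
  s <- mlc_error_stats(log)
  n <- s$n_samples
  expect_gte(n, 1e5)
  se <- 0.02 / sqrt(n)
  expect_lt(abs(s$mean - (-0.01)), 3 * se)
  expect_lt(abs(s$sd - 0.02) / 0.02, 0.02)
})

test_that("synthetic logs recover the injected exponential MU lag mean", {
  cps <- make_control_points(n_cp = 10)
  log <- make_trajectory_log(cps, log_error_model(mu_lag_mean = 0.10,
                                                  seed = 9),
                             total_mu = 2000, duration_s = 1000)
  m <- mu_error_stats(log)
  # lag levels are drawn per ~100-sample block: the effective sample size
  # for the mean is the block count
  n_blocks <- length(log$t_ms) / 100
  se <- 0.10 / sqrt(n_blocks)
  expect_lt(abs(m$mean - 0.10), 3 * se)
  expect_true(all(diff(log$mu_act) >= 0))
})

test_that("aperture area and gap follow the leaf geometry", {
  # one open pair: gap 20 mm x width 5 mm = 1 cm^2
  widths <- mlc_leaf_widths()
  np <- length(widths)
  a <- rep(0, np); b <- rep(0.1, np)
  a[30] <- -10; b[30] <- 10
  cps <- control_point_sequence(a, b, mu = 0, leaf_widths = widths,
                                jaw = c(-50, 50, -100, 100))
  st <- aperture_stats(cps)
  expect_equal(st$mean_aperture_cm2, 1)
  expect_equal(st$mean_gap_mm, 20)
  # two control points with areas 1 and 3 cm^2 average to 2
  a2 <- rbind(a, a); b2 <- rbind(b, b)
  a2[2, 30] <- -10; b2[2, 30] <- 50  # gap 60 mm x 5 mm = 3 cm^2
  st2 <- aperture_stats(control_point_sequence(a2, b2, mu = c(0, 1),
                                               leaf_widths = widths,
                                               jaw = c(-50, 50, -100, 100)))
  expect_equal(st2$per_control_point$aperture_cm2, c(1, 3))
  expect_equal(st2$mean_aperture_cm2, 2)
  # bank exchange with flipped signs leaves the area invariant
  st3 <- aperture_stats(control_point_sequence(-b, -a, mu = 0,
                                               leaf_widths = widths,
                                               jaw = c(-50, 50, -100, 100)))
  expect_equal(st3$mean_aperture_cm2, st$mean_aperture_cm2)
  expect_warning(
    aperture_stats(control_point_sequence(rep(0, np), rep(0.1, np), mu = 0,
                                          leaf_widths = widths)),
    "degenerate")
})

test_that("aperture area matches a 2D rasterization oracle on random shapes", {
  set.seed(21)
  widths <- mlc_leaf_widths()
  np <- length(widths)
  edges_y <- cumsum(widths) - sum(widths) / 2
  for (rep_i in 1:3) {
    gaps <- runif(np, 0, 60) * (runif(np) < 0.6)
    ctrs <- runif(np, -20, 20)
    a <- ctrs - gaps / 2; b <- ctrs + gaps / 2
    cps <- control_point_sequence(a, b, mu = 0, leaf_widths = widths,
                                  jaw = c(-60, 60, -200, 200))
    st <- aperture_stats(cps, closed_threshold = 0.5)
    # rasterize at 0.5 mm in x, exact leaf strips in y
    xs <- seq(-59.75, 59.75, by = 0.5)
    area_mm2 <- 0
    for (p in seq_len(np)) {
      if (b[p] - a[p] > 0.5) {
        open_x <- sum(xs > max(a[p], -60) & xs < min(b[p], 60)) * 0.5
        area_mm2 <- area_mm2 + open_x * widths[p]
      }
    }
    expect_equal(st$mean_aperture_cm2, area_mm2 / 100, tolerance = 0.02)
  }
})

test_that("tolerance checks flag violations and reject bad configs", {
  st <- list(mlc_max_abs_mm = 0.01, mu_mean = 1.2)
  rep1 <- tolerance_check(st, list(mlc_max_abs_mm = 1))
  expect_true(all(rep1$pass))
  rep2 <- tolerance_check(st, list(mlc_max_abs_mm = 1, mu_mean = 1))
  expect_false(rep2$pass[rep2$statistic == "mu_mean"])
  expect_error(tolerance_check(st, list()), "configuration")
  expect_error(tolerance_check(st, list(gantry_deg = 1)), "configuration")
})

test_that("leaf-speed feasibility is enforced by the log generator", {
  cps <- make_control_points(n_cp = 5, x_start = -50, x_end = 50)
  # 100 mm sweep in 0.5 s needs 200 mm/s >> 25 mm/s
  expect_error(make_trajectory_log(cps, duration_s = 0.5), "feasibility")
  expect_silent(make_trajectory_log(cps, duration_s = 10))
})
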