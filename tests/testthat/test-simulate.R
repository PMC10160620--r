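test_that("stance profile boundary values and midstance valley are exact", {
  expect_equal(stance_profile(0, 2, 0.3), 0)
  expect_equal(stance_profile(1, 2, 0.3), 0, tolerance = 1e-12)
  expect_equal(stance_profile(0.5, 1.25, 0.4), 1.25 * (1 - 0.4))
  expect_error(stance_profile(1.2), "\\[0, 1\\]")
})

test_that("profile peak location matches a bisection oracle", {
  # independent oracle: bisection on the derivative cos(pi u) + 3 r cos(3 pi u)
  for (r in c(0.2, 0.4, 0.5)) {
    dfun <- function(u) cos(pi * u) + 3 * r * cos(3 * pi * u)
    lo <- 1e-9; hi <- 0.5 - 1e-9
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (sign(dfun(mid)) == sign(dfun(lo))) lo <- mid else hi <- mid
    }
    pk <- stance_profile_peak(1.25, r)
    expect_equal(pk$u_peak, (lo + hi) / 2, tolerance = 1e-9)
    expect_equal(pk$value, stance_profile((lo + hi) / 2, 1.25, r),
                 tolerance = 1e-9)
    # it is a local maximum with two peaks flanking a valley
    u <- seq(0, 1, by = 1e-3)
    f <- stance_profile(u, 1.25, r)
    expect_equal(max(f), pk$value, tolerance = 1e-5)  # grid resolution
  }
})

test_that("generator is deterministic under a fixed seed", {
  p <- gait_params(walk_duration = 10, sensor_noise_sd = 2, seed = 123)
  a <- simulate_subject(p, "a", "PD")
  b <- simulate_subject(p, "a", "PD")
  expect_identical(a$trace$left_sensors, b$trace$left_sensors)
  expect_identical(a$truth$events$time, b$truth$events$time)
})

test_that("parameter validation rejects impossible gaits", {
  expect_error(gait_params(stance_fraction_mean = 0.5), "double support")
  expect_error(gait_params(sensor_weights = rep(1, 8)), "sum to 1")
  expect_error(gait_params(stride_time_cv = -1), "nonnegative")
})

test_that("stride-time CV of ground truth matches the generator setting", {
  p <- gait_params(stride_time_cv = 2.2, walk_duration = 60, seed = 17)
  s <- simulate_subject(p, "cv", "PD")
  st <- s$truth$strides$stride_time
  cv <- 100 * sd(st) / mean(st)
  expect_lt(abs(cv - 2.2), 3)  # sampling error at ~55 strides
})

test_that("ground-truth phase components sum to the stride exactly", {
  p <- gait_params(stride_time_cv = 3, asymmetry_offset = 8,
                   walk_duration = 30, seed = 5)
  st <- simulate_subject(p, "x", "PD")$truth$strides
  swing <- st$stride_time - st$stance_time  # own swing = other's single support
  acc <- st$single_support_time + swing + st$ds_leading + st$ds_trailing
  expect_equal(acc, st$stride_time, tolerance = 1e-12)
})

test_that("noise-free peak force equals the analytic profile peak", {
  p <- gait_params(walk_duration = 20, seed = 3)
  s <- simulate_subject(p, "pk", "control")
  sig <- sum_sensors(s$trace)
  bw <- 73 * 9.80665
  pk <- stance_profile_peak(p$amplitude, p$shape_ratio)
  # skip the startup ramp
  peak_meas <- max(sig$fz_left[sig$sample_times > 2]) / bw
  expect_lt(abs(peak_meas - pk$value) / pk$value, 0.005)
})

test_that("turn segments inflate stride times and are labelled", {
  p <- gait_params(walk_duration = 40, turn_every = 12, seed = 9)
  st <- simulate_subject(p, "t", "PD")$truth$strides
  expect_true(any(st$turn))
  expect_gt(min(st$stride_time[st$turn]), 1.4 * median(st$stride_time[!st$turn]))
})

test_that("cohort speeds drawn across a band are re-filtered exactly", {
  co <- simulate_cohort(gait_params(walk_duration = 6),
                        gait_params(walk_duration = 6),
                        6, 6, speed_range = c(0.8, 1.5), seed = 21)
  sel <- select_speed_matched(co$demographics, 1.0, 1.3)
  manual <- co$demographics$subject_id[
    co$demographics$walking_speed >= 1.0 & co$demographics$walking_speed <= 1.3]
  expect_setequal(sel$subject_id, manual)
})

test_that("subject-level stance curves carry between-subject variation", {
  set.seed(31)
  X <- simulate_stance_curves(12)
  expect_equal(dim(X), c(12, 101))
  expect_equal(X[, 1], rep(0, 12))  # force zero at foot-strike
  expect_gt(min(apply(X[, 2:100], 2, sd)), 0)
})
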