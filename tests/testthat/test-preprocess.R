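test_that("sensor summation produces per-foot and total signals", {
  zero <- pulse_trace(10, starts = integer(0), len = 0)
  sig <- sum_sensors(zero)
  expect_true(all(sig$fz_left == 0) && all(sig$fz_total == 0))

  tr <- sensor_trace("s", c(0, 0.01), matrix(100, 2, 8), matrix(0, 2, 8),
                     body_mass = 70)
  sig <- sum_sensors(tr)
  expect_equal(sig$fz_left, c(800, 800))
  expect_equal(sig$fz_total, sig$fz_left + sig$fz_right)
  expect_equal(sig$body_weight, 70 * 9.80665)
})

test_that("noise floor uses strict less-than and is idempotent", {
  expect_equal(denoise_floor(c(0, 19.9, 20.0, 250)), c(0, 0, 20.0, 250))
  expect_equal(denoise_floor(rep(0, 5)), rep(0, 5))
  set.seed(2)
  x <- runif(500, 0, 100)
  expect_identical(denoise_floor(denoise_floor(x)), denoise_floor(x))
})

test_that("zero-phase filter preserves DC and matches the analytic response", {
  expect_lt(max(abs(lowpass_15hz(rep(700, 600), 100) - 700)), 1e-6)

  t <- seq(0, 20, by = 0.01)
  mid <- t > 5 & t < 15
  amp_of <- function(y, freq) {
    fit <- stats::lm(y[mid] ~ sin(2 * pi * freq * t[mid]) +
                       cos(2 * pi * freq * t[mid]) - 1)
    sqrt(sum(coef(fit)^2))
  }
  # analytic squared magnitude of the designed digital filter at 40 Hz
  bf <- signal::butter(4, 15 / 50)
  w <- 2 * pi * 40 / 100
  H2 <- Mod(sum(bf$b * exp(-1i * w * (0:4))) /
              sum(bf$a * exp(-1i * w * (0:4))))^2
  a40 <- amp_of(lowpass_15hz(sin(2 * pi * 40 * t), 100), 40)
  expect_lt(abs(a40 - H2) / H2, 0.01)
  # passband: 1 Hz preserved within 1%
  a1 <- amp_of(lowpass_15hz(sin(2 * pi * t), 100), 1)
  expect_lt(abs(a1 - 1), 0.01)
})

test_that("filter rejects too-short and under-sampled input", {
  expect_error(lowpass_15hz(rep(1, 10), 100), "too short")
  expect_error(lowpass_15hz(rep(1, 100), 25), "twice the filter cutoff")
})

test_that("filter linearity: total equals the sum of filtered feet", {
  set.seed(4)
  l <- runif(800, 0, 900); r <- runif(800, 0, 900)
  expect_lt(max(abs(lowpass_15hz(l + r, 100) -
                      (lowpass_15hz(l, 100) + lowpass_15hz(r, 100)))), 1e-6)
})

test_that("startup trimming drops exactly the first seconds", {
  n <- 1000
  tr <- pulse_trace(n, starts = c(100, 700), len = 200)
  sig <- sum_sensors(tr)  # times 0.00 .. 9.99
  out <- trim_startup(sig, 5)
  expect_length(out$sample_times, 500)
  expect_gte(min(out$sample_times), 5)
  expect_identical(trim_startup(sig, 0)$sample_times, sig$sample_times)
  short <- sum_sensors(pulse_trace(100, starts = 10, len = 50))
  expect_error(trim_startup(short, 5), "startup trim")
})

test_that("turn rule flags inflated runs plus their flanking strides", {
  same <- data.frame(stride_time = rep(1100, 20))
  expect_false(any(exclude_turns(same)$turn_excluded))

  st <- data.frame(stride_time = rep(1100, 20))
  st$stride_time[9:11] <- 1650
  flagged <- which(exclude_turns(st)$turn_excluded)
  expect_equal(flagged, 8:12)

  few <- data.frame(stride_time = c(1, 2, 3))
  expect_warning(out <- exclude_turns(few), "fewer than 5")
  expect_false(any(out$turn_excluded))
  expect_false(any(exclude_turns(st, rule = "none")$turn_excluded))
})

test_that("generator turns are caught and straight strides spared", {
  turn_hit <- straight_flag <- numeric(0)
  for (seed in 1:20) {
    st <- simulate_subject(gait_params(walk_duration = 45, turn_every = 12,
                                       stride_time_cv = 2.2, seed = seed),
                           "t", "PD")$truth$strides
    out <- exclude_turns(st)
    turn_hit <- c(turn_hit, out$turn_excluded[st$turn])
    # flanking strides are excluded by design; only count non-adjacent ones
    adj <- which(st$turn)
    adj <- unique(c(adj - 1L, adj + 1L))
    adj <- adj[adj >= 1 & adj <= nrow(st)]
    straight <- setdiff(which(!st$turn), adj)
    straight_flag <- c(straight_flag, out$turn_excluded[straight])
  }
  expect_gte(mean(turn_hit), 0.9)
  expect_lte(mean(straight_flag), 0.1)
})

test_that("per-foot vGRF recovers the analytic stance curve from sensors", {
  p <- gait_params(walk_duration = 20, sensor_noise_sd = 1.5, seed = 8)
  s <- simulate_subject(p, "w", "control")
  sig <- sum_sensors(s$trace)
  bw <- 73 * 9.80665
  st <- s$truth$strides[3, ]
  ev <- s$truth$events
  fs <- st$fs_time; to <- fs + st$stance_time / 1000
  i <- sig$sample_times >= fs & sig$sample_times <= to
  u <- (sig$sample_times[i] - fs) / (to - fs)
  expected <- stance_profile(u, p$amplitude, p$shape_ratio) * bw
  # 8 channels of sd-1.5 N noise truncated at 0 -> a few N per sample
  expect_lt(max(abs(sig$fz_left[i] - expected)), 8 * 1.5 * 4)
})
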