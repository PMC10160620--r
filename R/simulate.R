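#' Parameters of the synthetic gait generator
#'
#' Bundles the free parameters of the synthetic walker. Defaults emulate a
#' typical speed-matched older adult walking near 1.1 m/s: a two-peak
#' vertical ground reaction force of amplitude `A` body weights with shape
#' ratio `r`, Gaussian stride timing with a given mean and coefficient of
#' variation, and a stance fraction of 63.7% of the stride so that each
#' double-support occurrence spans 13.7% of the stride.
#'
#' @param amplitude Stance-profile amplitude A in body weights.
#' @param shape_ratio Third-harmonic shape ratio r (dimensionless, 0 <= r < 1);
#'   values around 0.4 give the canonical two-peak curve.
#' @param body_mass Body mass in kg.
#' @param stride_time_mean Mean stride time in ms.
#' @param stride_time_cv Stride-time coefficient of variation in percent.
#' @param stance_fraction_mean Stance duration as a fraction of stride;
#'   must exceed 0.5 (walking, not running). Each double-support occurrence
#'   emerges as `stance_fraction_mean - 0.5` of the stride.
#' @param asymmetry_offset Milliseconds added to the left-to-right step
#'   duration (and removed from the right-to-left step), creating
#'   left/right asymmetry; 0 gives a symmetric gait.
#' @param amplitude_jitter_cv Optional per-stride amplitude jitter CV in
#'   percent (default 0: peak forces identical across strides).
#' @param sensor_weights 8 nonnegative weights summing to 1 that decompose
#'   each foot's force onto the shoe's pressure sensors.
#' @param sensor_noise_sd I.i.d. Gaussian noise SD per sensor channel in N
#'   (truncated at 0 so forces stay nonnegative).
#' @param walk_duration Recording length in s.
#' @param speed Self-selected walking speed in m/s, reported in the
#'   demographics table.
#' @param turn_every Insert a turn (3 strides with stride time inflated
#'   1.5x) every `turn_every` seconds; 0 disables turns.
#' @param sampling_rate Hz.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A list of class `gait_params`.
#' @export
gait_params <- function(amplitude = 1.25, shape_ratio = 0.40,
                        body_mass = 73, stride_time_mean = 1071,
                        stride_time_cv = 2.2, stance_fraction_mean = 0.637,
                        asymmetry_offset = 0, amplitude_jitter_cv = 0,
                        sensor_weights = default_sensor_weights(),
                        sensor_noise_sd = 0, walk_duration = 90,
                        speed = 1.15, turn_every = 0, sampling_rate = 100,
                        seed = 1L) {
  p <- list(amplitude = amplitude, shape_ratio = shape_ratio,
            body_mass = body_mass, stride_time_mean = stride_time_mean,
            stride_time_cv = stride_time_cv,
            stance_fraction_mean = stance_fraction_mean,
            asymmetry_offset = asymmetry_offset,
            amplitude_jitter_cv = amplitude_jitter_cv,
            sensor_weights = sensor_weights,
            sensor_noise_sd = sensor_noise_sd,
            walk_duration = walk_duration, speed = speed,
            turn_every = turn_every, sampling_rate = sampling_rate,
            seed = as.integer(seed))
  validate_gait_params(p)
  class(p) <- "gait_params"
  p
}

default_sensor_weights <- function() {
  # heel -> forefoot load sharing; must sum to 1
  w <- c(0.20, 0.15, 0.10, 0.08, 0.10, 0.12, 0.13, 0.12)
  w / sum(w)
}

validate_gait_params <- function(p) {
  if (p$stance_fraction_mean <= 0.5 || p$stance_fraction_mean >= 1)
    stop("stance_fraction_mean must lie in (0.5, 1): double support would be negative")
  if (p$shape_ratio < 0 || p$shape_ratio >= 1)
    stop("shape_ratio must lie in [0, 1)")
  if (abs(sum(p$sensor_weights) - 1) > 1e-9 || any(p$sensor_weights < 0))
    stop("sensor_weights must be nonnegative and sum to 1")
  if (p$stride_time_cv < 0) stop("stride_time_cv must be nonnegative")
  if (p$body_mass <= 0) stop("body_mass must be positive")
  invisible(p)
}

#' Two-peak stance force profile
#'
#' Analytic model of the vertical ground reaction force over one stance:
#' `A * (sin(pi*u) + r * sin(3*pi*u))` in body weights, where `u` is the
#' normalized stance position. It is zero at foot-strike (`u = 0`) and
#' toe-off (`u = 1`) and, for `0 < r <= 0.5`, shows the canonical
#' loading/push-off double peak around a midstance valley.
#'
#' @param u Normalized stance position(s) in `[0, 1]`.
#' @param amplitude A, in body weights.
#' @param shape_ratio r, dimensionless.
#' @return Force in body weights, same length as `u`.
#' @export
stance_profile <- function(u, amplitude = 1.25, shape_ratio = 0.40) {
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  amplitude * (sin(pi * u) + shape_ratio * sin(3 * pi * u))
}

#' Peak location and value of the stance profile
#'
#' Finds the first local maximum of [stance_profile()] in (0, 0.5) by
#' root-finding on its derivative; by symmetry the second peak sits at
#' `1 - u`. Used as the analytic ground truth for peak forces.
#'
#' @inheritParams stance_profile
#' @return List with `u_peak` (normalized position of the first peak) and
#'   `value` (force in BW at the peak).
#' @export
stance_profile_peak <- function(amplitude = 1.25, shape_ratio = 0.40) {
  if (shape_ratio == 0) {
    return(list(u_peak = 0.5, value = amplitude))
  }
  dfun <- function(u) cos(pi * u) + 3 * shape_ratio * cos(3 * pi * u)
  root <- stats::uniroot(dfun, c(1e-9, 0.5 - 1e-9), tol = 1e-12)$root
  list(u_peak = root,
       value = stance_profile(root, amplitude, shape_ratio))
}

# Draw the per-step timing skeleton: left/right foot-strike and toe-off
# times plus per-stride labels. Step durations are i.i.d. Normal draws
# (so each foot's stride time, the sum of two consecutive steps, has the
# requested mean and CV), the left-to-right step is lengthened by the
# asymmetry offset and the right-to-left step shortened by it, and each
# stance ends one double-support duration ((stance_fraction - 0.5) of the
# stride) after the contralateral foot-strike. The offset therefore shows
# up in single-support and stance times, not in double support, and phase
# accounting stays exact. Turns are contiguous runs of 3 strides with
# stride time inflated 1.5x.
simulate_timeline <- function(p) {
  mean_s <- p$stride_time_mean / 1000
  # i.i.d. steps: stride = step + step => sd_step = sd_stride / sqrt(2)
  sd_step <- mean_s * (p$stride_time_cv / 100) / sqrt(2)
  n_strides <- ceiling(p$walk_duration / mean_s) + 4L
  n_steps <- 2L * n_strides
  step <- stats::rnorm(n_steps, mean_s / 2, sd_step)
  step <- pmax(step, 0.2 * mean_s)  # guard against absurd draws
  turn <- rep(FALSE, n_strides)
  if (p$turn_every > 0) {
    fs_nominal <- cumsum(c(0, step[-n_steps]))[seq(1L, n_steps, by = 2L)]
    k <- 1L
    next_turn <- p$turn_every
    while (k <= n_strides) {
      if (fs_nominal[k] >= next_turn) {
        idx <- k:min(k + 2L, n_strides)
        turn[idx] <- TRUE
        step[c(2L * idx - 1L, 2L * idx)] <- step[c(2L * idx - 1L, 2L * idx)] * 1.5
        next_turn <- next_turn + p$turn_every
        k <- k + 3L
      } else k <- k + 1L
    }
  }
  off <- p$asymmetry_offset / 1000
  step_eff <- step
  odd <- seq(1L, n_steps, by = 2L)          # left-to-right steps
  step_eff[odd] <- step_eff[odd] + off
  step_eff[-odd] <- step_eff[-odd] - off
  fs_all <- 0.5 + c(0, cumsum(step_eff[-n_steps]))  # first contact at 0.5 s
  fs_left <- fs_all[odd]
  fs_right <- fs_all[-odd]
  stride_left <- c(diff(fs_left), step[n_steps - 1L] + step[n_steps])
  stride_right <- c(diff(fs_right), stride_left[n_strides])
  ds_frac <- p$stance_fraction_mean - 0.5
  # left stance ends one double-support after the right foot-strike
  to_left <- fs_right + ds_frac * stride_left
  # right stance ends one double-support after the NEXT left foot-strike
  next_fs_left <- c(fs_left[-1L], fs_left[n_strides] + stride_left[n_strides])
  to_right <- next_fs_left + ds_frac * stride_right
  list(fs_left = fs_left, to_left = to_left,
       fs_right = fs_right, to_right = to_right,
       stride_left = stride_left, stride_right = stride_right,
       turn = turn)
}

# Render one foot's continuous force signal (in N) from its stance windows.
render_foot_force <- function(times, fs, to, amp_bw, shape_ratio, body_weight) {
  fz <- numeric(length(times))
  for (k in seq_along(fs)) {
    i0 <- findInterval(fs[k] - 1e-12, times) + 1L
    i1 <- findInterval(to[k] + 1e-12, times)
    if (i1 < i0) next
    i <- i0:i1
    u <- (times[i] - fs[k]) / (to[k] - fs[k])
    u <- pmin(pmax(u, 0), 1)  # guard grid-aligned boundary round-off
    fz[i] <- stance_profile(u, amp_bw[k], shape_ratio) * body_weight
  }
  fz
}

#' Simulate one subject's recording with known ground truth
#'
#' Builds alternating left/right foot-strike sequences from per-stride
#' durations drawn as Normal(mean, mean*cv/100), renders each stance with
#' the analytic two-peak profile scaled by body weight, decomposes each
#' foot's force onto 8 sensor channels, adds truncated Gaussian sensor
#' noise, applies a 2 s startup ramp, and (optionally) inserts turn
#' segments. All ground-truth events and per-stride features are recorded
#' before noise is added.
#'
#' @param params A [gait_params()] object.
#' @param subject_id Subject identifier.
#' @param group Group label for the ground truth ("PD" or "control").
#' @return List with `trace` (a [sensor_trace()]), `meta` (one-row
#'   demographics data.frame) and `truth` (list with `events` and `strides`
#'   data.frames).
#' @export
simulate_subject <- function(params, subject_id = "S1", group = "control") {
  validate_gait_params(params)
  p <- params
  set.seed(p$seed)
  tl <- simulate_timeline(p)
  times <- seq(0, p$walk_duration, by = 1 / p$sampling_rate)
  bw <- p$body_mass * GRAVITY

  n_l <- length(tl$fs_left)
  n_r <- length(tl$fs_right)
  amp_l <- p$amplitude * amp_jitter(n_l, p$amplitude_jitter_cv)
  amp_r <- p$amplitude * amp_jitter(n_r, p$amplitude_jitter_cv)
  fz_left <- render_foot_force(times, tl$fs_left, tl$to_left, amp_l,
                               p$shape_ratio, bw)
  fz_right <- render_foot_force(times, tl$fs_right, tl$to_right, amp_r,
                                p$shape_ratio, bw)

  ramp <- pmin(times / 2, 1)  # startup transient over the first 2 s
  fz_left <- fz_left * ramp
  fz_right <- fz_right * ramp

  left <- outer(fz_left, p$sensor_weights)
  right <- outer(fz_right, p$sensor_weights)
  if (p$sensor_noise_sd > 0) {
    left <- pmax(left + stats::rnorm(length(left), 0, p$sensor_noise_sd), 0)
    right <- pmax(right + stats::rnorm(length(right), 0, p$sensor_noise_sd), 0)
  }

  trace <- sensor_trace(subject_id, times, left, right,
                        sampling_rate = p$sampling_rate,
                        body_mass = p$body_mass)
  meta <- data.frame(
    subject_id = subject_id, group = group, sex = "unknown",
    age = NA_real_, height = NA_real_, body_mass = p$body_mass,
    walking_speed = p$speed, hoehn_yahr = NA_real_, updrs = NA_real_,
    tug = NA_real_, stringsAsFactors = FALSE)
  truth <- ground_truth(tl, p, amp_l, amp_r, group)
  list(trace = trace, meta = meta, truth = truth)
}

amp_jitter <- function(n, cv) {
  if (cv <= 0) rep(1, n) else pmax(stats::rnorm(n, 1, cv / 100), 0.5)
}

# Assemble the noise-free ground truth: the event table and the per-stride
# feature table the pipeline is expected to recover.
ground_truth <- function(tl, p, amp_l, amp_r, group) {
  ev <- rbind(
    data.frame(foot = "L", event = "FS", time = tl$fs_left),
    data.frame(foot = "L", event = "TO", time = tl$to_left),
    data.frame(foot = "R", event = "FS", time = tl$fs_right),
    data.frame(foot = "R", event = "TO", time = tl$to_right))
  ev <- ev[order(ev$time), ]
  rownames(ev) <- NULL

  pk <- stance_profile_peak(1, p$shape_ratio)
  n_l <- length(tl$fs_left)
  # left strides 2..n-1: the first has no preceding right toe-off and the
  # last no following foot-strike
  k <- 2:(n_l - 1L)
  fs <- tl$fs_left[k]; next_fs <- tl$fs_left[k + 1L]; to <- tl$to_left[k]
  c_fs <- tl$fs_right[k]          # right FS inside this cycle
  c_to <- tl$to_right[k - 1L]     # right stance ongoing at fs ends here
  strides <- data.frame(
    foot = "L", index = k, fs_time = fs,
    stride_time = (next_fs - fs) * 1000,
    stance_time = (to - fs) * 1000,
    single_support_time = (c_fs - c_to) * 1000,
    ds_leading = (c_to - fs) * 1000,
    ds_trailing = (to - c_fs) * 1000,
    fz_peak = amp_l[k] * pk$value,
    t_peak1 = pk$u_peak * (to - fs) * 1000,
    turn = tl$turn[k],
    stringsAsFactors = FALSE)
  list(events = ev, strides = strides, group = group,
       peak_bw_left = amp_l * pk$value, peak_bw_right = amp_r * pk$value)
}

#' Simulate a two-group cohort
#'
#' Draws per-subject stride-time means (and optionally other parameters)
#' around the group-level means, simulates each subject, and assembles the
#' demographics table. Walking speeds are drawn uniformly in `speed_range`
#' so that downstream speed-band selection is exercised.
#'
#' @param pd_params,control_params [gait_params()] giving each group's
#'   mean settings.
#' @param n_pd,n_control Group sizes.
#' @param between_sd_ms Between-subject SD of the stride-time mean, in ms.
#' @param speed_range Length-2 numeric, m/s; subject speeds are drawn
#'   uniformly in it.
#' @param asymmetry_sd_ms Between-subject SD of the per-step asymmetry
#'   offset, in ms (subject offsets drawn Normal(group offset, this)).
#' @param between_amp_sd Between-subject SD of the stance-profile
#'   amplitude, in BW.
#' @param updrs_speed_r Within the PD group, the target correlation
#'   between the disease-severity score and walking speed (the study
#'   population shows a positive one because of the narrow speed band).
#' @param seed Integer master seed; per-subject seeds are derived from it.
#' @return List with `traces` (list of [sensor_trace()]), `demographics`
#'   (data.frame) and `truths` (list of ground-truth objects).
#' @export
simulate_cohort <- function(pd_params, control_params, n_pd, n_control,
                            between_sd_ms = 80, speed_range = c(1.05, 1.25),
                            asymmetry_sd_ms = 10, between_amp_sd = 0.10,
                            updrs_speed_r = 0.36, seed = 1L) {
  stopifnot(n_pd >= 1L, n_control >= 1L)
  set.seed(seed)
  n <- n_pd + n_control
  groups <- c(rep("PD", n_pd), rep("control", n_control))
  base <- list(PD = pd_params, control = control_params)
  subj_seeds <- sample.int(2147483000L, n)
  stride_shift <- stats::rnorm(n, 0, between_sd_ms)
  speeds <- stats::runif(n, speed_range[1], speed_range[2])
  asym <- stats::rnorm(n, 0, asymmetry_sd_ms)
  amp_shift <- stats::rnorm(n, 0, between_amp_sd)
  masses <- stats::rnorm(n, 73, 11)
  masses <- pmax(masses, 45)

  traces <- vector("list", n)
  truths <- vector("list", n)
  metas <- vector("list", n)
  for (i in seq_len(n)) {
    p <- base[[groups[i]]]
    p$stride_time_mean <- p$stride_time_mean + stride_shift[i]
    p$asymmetry_offset <- p$asymmetry_offset + asym[i]
    p$amplitude <- max(p$amplitude + amp_shift[i], 0.8)
    p$speed <- speeds[i]
    p$body_mass <- masses[i]
    p$seed <- subj_seeds[i]
    id <- sprintf("%s%02d", ifelse(groups[i] == "PD", "Pt", "Co"), i)
    sub <- simulate_subject(p, subject_id = id, group = groups[i])
    traces[[i]] <- sub$trace
    truths[[i]] <- sub$truth
    truths[[i]]$subject_id <- id
    truths[[i]]$stride_time_mean <- p$stride_time_mean
    metas[[i]] <- sub$meta
  }
  demographics <- do.call(rbind, metas)
  demographics$age <- round(stats::rnorm(n, 64, 9))
  demographics$height <- round(stats::rnorm(n, 168, 8))
  demographics$sex <- sample(c("M", "F"), n, replace = TRUE)
  demographics$hoehn_yahr <- ifelse(groups == "PD",
                                    round(stats::rnorm(n, 2.2, 0.3), 1), 0)
  # severity score correlated with speed within the PD group (the narrow
  # speed band of the study population induces a positive association)
  z_speed <- scale(speeds)[, 1L]
  z <- updrs_speed_r * z_speed +
    sqrt(max(1 - updrs_speed_r^2, 0)) * stats::rnorm(n)
  demographics$updrs <- ifelse(groups == "PD", pmax(round(30 + 10 * z), 1), 0)
  demographics$tug <- round(stats::rnorm(n, ifelse(groups == "PD", 10.8, 10.0),
                                         ifelse(groups == "PD", 1.8, 1.4)), 1)
  list(traces = traces, demographics = demographics, truths = truths)
}

#' Simulate subject-level stance-normalized force curves
#'
#' Lightweight generator of per-subject mean stance curves on the 101-point
#' grid, used for calibrating the curve-level permutation test: each
#' subject's curve is the analytic two-peak profile with subject-specific
#' amplitude and shape drawn around the group means, plus smooth
#' low-frequency subject noise.
#'
#' @param n Number of subjects.
#' @param amplitude,shape_ratio Group-mean profile parameters.
#' @param amplitude_sd,shape_sd Between-subject SDs.
#' @param smooth_noise_sd SD (in BW) of a smooth random curve perturbation.
#' @return `n x 101` matrix of curves in BW.
#' @export
simulate_stance_curves <- function(n, amplitude = 1.25, shape_ratio = 0.40,
                                   amplitude_sd = 0.08, shape_sd = 0.03,
                                   smooth_noise_sd = 0.02) {
  u <- seq(0, 1, length.out = 101)
  amps <- stats::rnorm(n, amplitude, amplitude_sd)
  shps <- pmin(pmax(stats::rnorm(n, shape_ratio, shape_sd), 0), 0.9)
  curves <- t(vapply(seq_len(n), function(i) {
    base <- stance_profile(u, amps[i], shps[i])
    if (smooth_noise_sd > 0) {
      ph <- stats::runif(2, 0, 2 * pi)
      a <- stats::rnorm(2, 0, smooth_noise_sd)
      base <- base + a[1] * sin(2 * pi * u + ph[1]) * sin(pi * u) +
        a[2] * sin(4 * pi * u + ph[2]) * sin(pi * u)
    }
    base
  }, numeric(101)))
  curves
}

#' Write a simulated cohort to disk in the gaitpdb text layout
#'
#' One 19-column force record per subject (`<id>.txt`), a demographics
#' table (`demographics.tsv`) and a ground-truth sidecar
#' (`ground_truth_strides.tsv`).
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tr in cohort$traces)
    write_force_record(tr, file.path(dir, paste0(tr$subject_id, ".txt")))
  write_demographics(cohort$demographics, file.path(dir, "demographics.tsv"))
  gt <- do.call(rbind, lapply(cohort$truths, function(tt) {
    s <- tt$strides
    s$subject_id <- tt$subject_id
    s
  }))
  utils::write.table(gt, file.path(dir, "ground_truth_strides.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
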