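#' Sum sensor channels into per-foot and total force signals
#'
#' The per-foot vertical ground reaction force is the row-wise sum of that
#' shoe's 8 sensor channels; the total force is the sum over both feet.
#' Body weight is `body_mass * g` with g = 9.80665 m/s^2.
#'
#' @param trace A [sensor_trace()].
#' @return A `force_signal` list: `sample_times`, `fz_left`, `fz_right`,
#'   `fz_total` (N), `body_weight` (N or `NA`), `sampling_rate`,
#'   `subject_id`, and provenance `flags`.
#' @export
sum_sensors <- function(trace) {
  stopifnot(inherits(trace, "sensor_trace"))
  fz_left <- rowSums(trace$left_sensors)
  fz_right <- rowSums(trace$right_sensors)
  structure(
    list(subject_id = trace$subject_id,
         sample_times = trace$sample_times,
         fz_left = fz_left, fz_right = fz_right,
         fz_total = fz_left + fz_right,
         body_weight = if (is.na(trace$body_mass)) NA_real_
                       else trace$body_mass * GRAVITY,
         sampling_rate = trace$sampling_rate,
         flags = c(denoised = FALSE, filtered = FALSE, trimmed = FALSE)),
    class = "force_signal")
}

#' @export
print.force_signal <- function(x, ...) {
  cat(sprintf("<force_signal> subject %s: %d samples @ %g Hz [%s]\n",
              x$subject_id, length(x$sample_times), x$sampling_rate,
              paste(names(x$flags)[x$flags], collapse = ", ")))
  invisible(x)
}

#' Replace sub-threshold force values by zero
#'
#' Values strictly below `floor` newtons are zeroed (unloaded-shoe sensor
#' noise removal); values at or above the floor pass unchanged. Idempotent.
#'
#' @param x Numeric vector of forces in N.
#' @param floor Noise floor in N.
#' @return Numeric vector of the same length.
#' @export
denoise_floor <- function(x, floor = 20) {
  x[x < floor] <- 0
  x
}

# One causal IIR pass of the rational filter b(z)/a(z) with zero initial
# state, as the cascade of its MA (convolution) and AR (recursive) parts;
# both run in the C kernels of stats::filter. Start-up transients are the
# caller's concern (absorbed by reflection padding in lowpass_15hz).
iir_pass <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1L), x)
  ma <- as.numeric(stats::filter(xp, b, method = "convolution", sides = 1L))
  ma <- ma[nb:length(xp)]
  as.numeric(stats::filter(ma, -a[-1L], method = "recursive"))
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies a 4th-order low-pass Butterworth (designed with
#' [signal::butter()]) forward and backward, so the effective magnitude
#' response is the square of the single-pass response and the phase is
#' zero (events are not delayed). Edge transients are absorbed by odd
#' reflection padding before the forward pass.
#'
#' @param x Numeric signal.
#' @param sampling_rate Hz; must exceed twice the cutoff.
#' @param cutoff Cutoff frequency in Hz.
#' @param order Filter order of each pass.
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_15hz <- function(x, sampling_rate, cutoff = 15, order = 4) {
  if (sampling_rate <= 2 * cutoff)
    stop("sampling_rate must exceed twice the filter cutoff")
  bf <- signal::butter(order, cutoff / (sampling_rate / 2), type = "low")
  b <- bf$b; a <- bf$a
  pad <- min(length(x) - 1L, 300L)
  if (pad < 3L * (order + 1L))
    stop("signal too short to low-pass filter; skip filtering for this segment")
  # odd reflection padding at both ends
  head_pad <- 2 * x[1L] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - pad)]
  xe <- c(head_pad, x, tail_pad)
  y <- iir_pass(b, a, xe)
  y <- rev(iir_pass(b, a, rev(y)))
  y[(pad + 1L):(pad + length(x))]
}

#' Trim the startup window
#'
#' Removes all samples with `time < trim` seconds (the startup transient of
#' the recording); times are not re-zeroed.
#'
#' @param signal A `force_signal`.
#' @param trim Seconds to discard from the start.
#' @return The trimmed `force_signal`.
#' @export
trim_startup <- function(signal, trim = 5) {
  stopifnot(inherits(signal, "force_signal"))
  keep <- signal$sample_times >= trim
  if (!any(keep))
    stop("recording is not longer than the startup trim; nothing to analyse")
  signal$sample_times <- signal$sample_times[keep]
  signal$fz_left <- signal$fz_left[keep]
  signal$fz_right <- signal$fz_right[keep]
  signal$fz_total <- signal$fz_total[keep]
  signal$flags["trimmed"] <- TRUE
  signal
}

#' Denoise and filter a force signal in the prescribed order
#'
#' Applies the 20 N noise floor to each per-foot signal, then the
#' zero-phase low-pass filter, and recomputes the total as the sum of the
#' filtered per-foot signals. The floor-then-filter order is recorded in
#' the provenance flags.
#'
#' @param signal A `force_signal` from [sum_sensors()].
#' @param noise_floor_N Noise floor in N.
#' @param filter_cutoff_Hz,filter_order Low-pass settings.
#' @return The processed `force_signal`.
#' @export
preprocess_signal <- function(signal, noise_floor_N = 20,
                              filter_cutoff_Hz = 15, filter_order = 4) {
  stopifnot(inherits(signal, "force_signal"))
  signal$fz_left <- denoise_floor(signal$fz_left, noise_floor_N)
  signal$fz_right <- denoise_floor(signal$fz_right, noise_floor_N)
  signal$flags["denoised"] <- TRUE
  signal$fz_left <- lowpass_15hz(signal$fz_left, signal$sampling_rate,
                                 filter_cutoff_Hz, filter_order)
  signal$fz_right <- lowpass_15hz(signal$fz_right, signal$sampling_rate,
                                  filter_cutoff_Hz, filter_order)
  signal$fz_total <- signal$fz_left + signal$fz_right
  signal$flags["filtered"] <- TRUE
  signal
}

#' Flag turn strides by robust stride-time outlier detection
#'
#' The original corridor protocol contains turns at both ends that must be
#' excluded so only straight walking is analysed. This automated proxy
#' flags any stride whose stride time deviates from the per-subject median
#' by more than `k` scaled median absolute deviations (MAD x 1.4826), and
#' additionally flags one neighbouring stride on each side of every flagged
#' run. With fewer than 5 strides the rule degrades to keeping everything,
#' with a warning.
#'
#' @param strides Data frame with a `stride_time` column (ms), one row per
#'   stride in temporal order.
#' @param rule `"mad"` (default) or `"none"`.
#' @param k MAD multiplier.
#' @return `strides` with logical column `turn_excluded` added.
#' @export
exclude_turns <- function(strides, rule = c("mad", "none"), k = 3) {
  rule <- match.arg(rule)
  n <- nrow(strides)
  strides$turn_excluded <- rep(FALSE, n)
  if (rule == "none") return(strides)
  if (n < 5L) {
    warning("fewer than 5 strides: turn rule degraded to 'none'")
    return(strides)
  }
  st <- strides$stride_time
  med <- stats::median(st)
  mad <- stats::mad(st)  # scaled by 1.4826
  # a zero MAD means most strides are literally identical (noise-free
  # synthetic gait): any departure from the median is then an outlier
  flag <- if (mad == 0) abs(st - med) > 1e-9 * max(med, 1)
          else abs(st - med) > k * mad
  if (any(flag)) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      lo <- max(1L, starts[j] - 1L)
      hi <- min(n, ends[j] + 1L)
      flag[lo:hi] <- TRUE
    }
  }
  strides$turn_excluded <- flag
  strides
}
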