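#' Temporal variables of one stride frame
#'
#' From the event quintuple of a stride (same-foot FS to next FS):
#' stride time, stance time (FS to TO), single support time (contralateral
#' TO to contralateral FS, equivalent to the contralateral swing), and
#' double support time. The latter has a leading component (FS to
#' contralateral TO) and a trailing one (contralateral FS to TO); one
#' stride's double support time is reported as their mean by default, so a
#' stride contributes one number on the same scale as the conventional
#' per-occurrence double-support duration (`double_support = "sum"` reports
#' the sum instead). All durations in ms; percentages relative to stride
#' time.
#'
#' @param frame One row of [build_strides()] output.
#' @param double_support `"mean"` (default) or `"sum"` of the leading and
#'   trailing components.
#' @return One-row data frame of temporal features, or `NULL` (with reason
#'   attribute) for an invalid frame.
#' @export
temporal_features <- function(frame, double_support = c("mean", "sum")) {
  double_support <- match.arg(double_support)
  if (!isTRUE(frame$valid)) return(NULL)
  stride <- (frame$next_fs - frame$fs) * 1000
  stance <- (frame$to - frame$fs) * 1000
  ss <- (frame$contralateral_fs - frame$contralateral_to) * 1000
  ds_lead <- (frame$contralateral_to - frame$fs) * 1000
  ds_trail <- (frame$to - frame$contralateral_fs) * 1000
  ds <- if (double_support == "mean") (ds_lead + ds_trail) / 2
        else ds_lead + ds_trail
  data.frame(
    foot = frame$foot,
    stride_time = stride,
    stance_time = stance,
    single_support_time = ss,
    double_support_time = ds,
    ds_leading = ds_lead,
    ds_trailing = ds_trail,
    stance_pct = 100 * stance / stride,
    single_support_pct = 100 * ss / stride,
    double_support_pct = 100 * ds / stride,
    stringsAsFactors = FALSE)
}

# Index of the maximum, earliest sample on ties.
which_max_first <- function(x) which(x == max(x))[1L]

#' First and second force peaks of one stance
#'
#' The loading peak (`fz_peak1`) is the maximum over the first half of the
#' stance and the push-off peak (`fz_peak2`) the maximum over the second
#' half (halves split at 50% of stance duration; ties resolved to the
#' earliest sample). Peak times are reported relative to the foot-strike,
#' in ms and as a percentage of stride time; forces in body weights.
#'
#' @param fz Per-foot force (N) over the stance samples.
#' @param times Sample times (s) of those samples.
#' @param body_weight Body weight in N.
#' @param fs_time Foot-strike time (s).
#' @param stride_time Stride time in ms.
#' @return One-row data frame: `fz_peak1`, `t_peak1_ms`, `t_peak1_pct`,
#'   `fz_peak2`, `t_peak2_ms`, `t_peak2_pct`, `single_peak_flag`.
#' @export
force_peaks <- function(fz, times, body_weight, fs_time, stride_time) {
  v <- peaks_scalar(fz, times, body_weight, fs_time, stride_time)
  data.frame(fz_peak1 = v[1L], t_peak1_ms = v[2L], t_peak1_pct = v[3L],
             fz_peak2 = v[4L], t_peak2_ms = v[5L], t_peak2_pct = v[6L],
             single_peak_flag = as.logical(v[7L]))
}

# Unnamed-vector core of force_peaks, used in the per-stride hot loop.
peaks_scalar <- function(fz, times, body_weight, fs_time, stride_time) {
  if (length(fz) < 5L) stop("stance has fewer than 5 samples")
  if (is.na(body_weight)) stop("body mass unknown: cannot normalize by BW")
  mid <- fs_time + (times[length(times)] - fs_time) / 2
  n1 <- sum(times <= mid)
  i1 <- which_max_first(fz[seq_len(n1)])
  i2 <- which_max_first(fz[(n1 + 1L):length(fz)]) + n1
  # single-peaked stances: no interior valley between the two half maxima
  seg <- fz[i1:i2]
  single_peak <- length(seg) < 3L || min(seg) >= min(fz[i1], fz[i2]) - 1e-9
  c(fz[i1] / body_weight, (times[i1] - fs_time) * 1000,
    100 * (times[i1] - fs_time) * 1000 / stride_time,
    fz[i2] / body_weight, (times[i2] - fs_time) * 1000,
    100 * (times[i2] - fs_time) * 1000 / stride_time,
    as.numeric(single_peak))
}

#' Peak of the total force over one stance
#'
#' Maximum of the two-foot total force within the reference foot's stance
#' window, timed relative to that foot's foot-strike.
#'
#' @param fz_tot Total force (N) over the stance samples.
#' @param times Sample times (s).
#' @inheritParams force_peaks
#' @return One-row data frame: `fz_tot_peak`, `t_tot_peak_ms`,
#'   `t_tot_peak_pct`.
#' @export
total_peak <- function(fz_tot, times, body_weight, fs_time, stride_time) {
  i <- which_max_first(fz_tot)
  data.frame(
    fz_tot_peak = fz_tot[i] / body_weight,
    t_tot_peak_ms = (times[i] - fs_time) * 1000,
    t_tot_peak_pct = 100 * (times[i] - fs_time) * 1000 / stride_time)
}

# First strict local maximum at or after `from` (front foot) or last strict
# local maximum at or before `upto` (back foot); returns NULL if none.
local_max <- function(fz, times, window, last = FALSE) {
  i0 <- findInterval(window[1] - 1e-9, times) + 1L
  i1 <- findInterval(window[2] + 1e-9, times)
  if (i1 - i0 + 1L < 3L) return(NULL)
  i <- i0:i1
  seg <- fz[i]
  k <- which(diff(sign(diff(seg))) < 0) + 1L
  k <- k[seg[k] > seg[k - 1L] & seg[k] > seg[k + 1L]]
  if (!length(k)) return(NULL)
  k <- if (last) k[length(k)] else k[1L]
  list(value = seg[k], time = times[i[k]])
}

#' Weight-transfer dynamics across one double support
#'
#' Characterizes the step-to-step weight transfer: the first local maximum
#' of the front (newly striking) foot's force after its foot-strike
#' (`fz_peak_front`), the last local maximum of the back foot's force
#' before its toe-off (`fz_peak_back`), their signed difference
#' (`delta_fz`, BW) and the signed time between them (`gwt`, ms; positive
#' when the front peak comes after the back peak).
#'
#' @param fz_front,fz_back The two feet's force signals (N).
#' @param times Sample times (s), common to both.
#' @param front_fs Front-foot foot-strike time (s).
#' @param front_to Front-foot toe-off time (s), bounding the front search.
#' @param back_to Back-foot toe-off time (s).
#' @param back_fs Back-foot preceding foot-strike time (s), bounding the
#'   back search.
#' @param body_weight Body weight in N.
#' @return One-row data frame (`fz_peak_front`, `fz_peak_back`, `delta_fz`,
#'   `gwt`), or `NULL` if either local maximum is missing.
#' @export
weight_transfer <- function(fz_front, fz_back, times, front_fs, front_to,
                            back_to, back_fs, body_weight) {
  v <- wt_scalar(fz_front, fz_back, times, front_fs, front_to, back_to,
                 back_fs, body_weight)
  if (is.null(v)) return(NULL)
  data.frame(fz_peak_front = v[1L], fz_peak_back = v[2L],
             delta_fz = v[3L], gwt = v[4L])
}

wt_scalar <- function(fz_front, fz_back, times, front_fs, front_to,
                      back_to, back_fs, body_weight) {
  front <- local_max(fz_front, times, c(front_fs, front_to), last = FALSE)
  back <- local_max(fz_back, times, c(back_fs, back_to), last = TRUE)
  if (is.null(front) || is.null(back)) return(NULL)
  c(front$value / body_weight, back$value / body_weight,
    (front$value - back$value) / body_weight,
    (front$time - back$time) * 1000)
}

#' Symmetry index of a left/right variable pair
#'
#' `SI = |xr - xl| / (0.5 * (xr + xl)) * 100`; zero for a perfectly
#' symmetric gait.
#'
#' @param xr,xl Right and left values of the same variable (same units).
#' @return SI in percent.
#' @export
symmetry_index <- function(xr, xl) {
  s <- xr + xl
  # undefined (NA) when the denominator is nonpositive, e.g. for signed
  # variables whose left and right means cancel
  ifelse(is.na(s) | s <= 0, NA_real_, abs(xr - xl) / (0.5 * s) * 100)
}

#' Coefficient of variation
#'
#' `CV = 100 * sd / mean` with the sample (n-1) standard deviation.
#' Undefined (NA) for fewer than 2 values or a nonpositive mean.
#'
#' @param x Numeric vector.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m <= 0) return(NA_real_)
  100 * stats::sd(x) / m
}

#' Interpolate one stance onto the normalized 101-point grid
#'
#' Linear interpolation of the stance-phase force onto an equally spaced
#' grid of 101 points from 0% to 100% of stance, in body weights.
#'
#' @param fz Force (N) over the stance samples.
#' @param times Sample times (s).
#' @param body_weight Body weight in N.
#' @param n_points Grid size (101).
#' @return Numeric vector of length `n_points`.
#' @export
normalize_stance <- function(fz, times, body_weight, n_points = 101) {
  if (length(fz) < 5L) stop("stance too short to normalize")
  u <- (times - times[1L]) / (times[length(times)] - times[1L])
  stats::approx(u, fz / body_weight,
                xout = seq(0, 1, length.out = n_points))$y
}

# The per-subject scalar variables summarized across strides.
stride_variables <- function() {
  c("stride_time", "stance_time", "single_support_time",
    "double_support_time", "stance_pct", "single_support_pct",
    "double_support_pct", "fz_peak1", "t_peak1_ms", "t_peak1_pct",
    "fz_peak2", "t_peak2_ms", "t_peak2_pct", "fz_tot_peak",
    "t_tot_peak_ms", "t_tot_peak_pct", "fz_peak_front", "fz_peak_back",
    "delta_fz", "gwt", "abs_gwt")
}

#' Per-subject summary of stride features
#'
#' For every variable: per-foot mean across included strides, the reported
#' mean being the average of the left and right means; the coefficient of
#' variation computed per foot across strides then averaged; and the
#' symmetry index computed from the two per-foot means.
#'
#' @param strides Per-stride feature table (one row per stride, with
#'   `foot` and `excluded` columns) as produced by [extract_subject()].
#' @param meta One-row demographics data frame for the subject.
#' @return One-row data frame with `<var>_mean`, `<var>_cv`, `<var>_si`
#'   columns for every variable, `n_strides_used`, and the demographics
#'   columns; or `NULL` if either foot has fewer than 2 included strides.
#' @export
subject_summary <- function(strides, meta) {
  inc <- strides[!strides$excluded, , drop = FALSE]
  nl <- sum(inc$foot == "L")
  nr <- sum(inc$foot == "R")
  if (nl < 2L || nr < 2L) {
    warning(sprintf("subject %s: a foot has fewer than 2 included strides",
                    meta$subject_id))
    return(NULL)
  }
  out <- list()
  for (v in intersect(stride_variables(), names(inc))) {
    xl <- inc[[v]][inc$foot == "L"]
    xr <- inc[[v]][inc$foot == "R"]
    ml <- mean(xl, na.rm = TRUE)
    mr <- mean(xr, na.rm = TRUE)
    out[[paste0(v, "_mean")]] <- (ml + mr) / 2
    cvs <- c(coefficient_of_variation(xl[!is.na(xl)]),
             coefficient_of_variation(xr[!is.na(xr)]))
    out[[paste0(v, "_cv")]] <- mean(cvs, na.rm = TRUE)
    out[[paste0(v, "_si")]] <- symmetry_index(mr, ml)
  }
  out$n_strides_used <- nrow(inc)
  cbind(as.data.frame(out), meta, row.names = NULL)
}
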