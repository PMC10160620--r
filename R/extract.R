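#' Default pipeline configuration
#'
#' All tunable keys of the extraction pipeline with their defaults. Unknown
#' keys passed in `...` are rejected.
#'
#' @param ... Overrides of the documented keys.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    noise_floor_N = 20,        # sub-threshold forces zeroed
    filter_cutoff_Hz = 15,     # low-pass cutoff
    filter_order = 4,          # Butterworth order per pass
    startup_trim_s = 5,        # discarded from the start of each recording
    event_threshold_N = 20,    # FS/TO contact threshold
    min_phase_ms = 100,        # debounce for threshold chatter
    turn_rule = "mad",         # "mad" or "none"
    turn_mad_k = 3,            # MAD multiplier of the turn rule
    double_support = "mean",   # per-stride double support: "mean" or "sum"
    speed_lo = 1.0,            # speed-band selection, m/s
    speed_hi = 1.3,
    alpha = 0.05,              # significance level
    n_perm = 10000,            # permutations for the curve-level test
    n_points = 101)            # stance-normalization grid
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  cfg
}

#' Extract all per-stride features and stance curves for one subject
#'
#' Runs the full single-subject chain: sensor summation, 20 N denoising
#' then zero-phase low-pass filtering, startup trimming, threshold event
#' detection, stride assembly, temporal and force features per stride,
#' automated turn exclusion, and per-stride stance-normalized force curves
#' (per-foot and total).
#'
#' @param trace A [sensor_trace()] with `body_mass` set.
#' @param config A [pipeline_config()].
#' @return List: `strides` (per-stride feature table with `excluded` and
#'   `exclude_reason`), `curves_fz` and `curves_fz_tot` (matrices, one row
#'   per included stride, 101 columns), `qc` (named counts), `signal`
#'   (the processed `force_signal`).
#' @export
extract_subject <- function(trace, config = pipeline_config()) {
  sig <- sum_sensors(trace)
  sig <- preprocess_signal(sig, config$noise_floor_N,
                           config$filter_cutoff_Hz, config$filter_order)
  sig <- trim_startup(sig, config$startup_trim_s)
  ev_l <- detect_events(sig$fz_left, sig$sample_times,
                        config$event_threshold_N, config$min_phase_ms)
  ev_r <- detect_events(sig$fz_right, sig$sample_times,
                        config$event_threshold_N, config$min_phase_ms)
  frames <- build_strides(ev_l, ev_r)
  bw <- sig$body_weight
  tt <- sig$sample_times
  nf <- nrow(frames)

  # plain vectors: data.frame row access in a per-stride loop is too slow
  f_foot <- frames$foot; f_fs <- frames$fs; f_cto <- frames$contralateral_to
  f_cfs <- frames$contralateral_fs; f_to <- frames$to
  f_nfs <- frames$next_fs; f_valid <- frames$valid
  fs_l_prev <- ev_l$time[ev_l$event == "FS"]
  fs_r_prev <- ev_r$time[ev_r$event == "FS"]

  cols <- c("fs_time", "stride_time", "stance_time", "single_support_time",
            "double_support_time", "ds_leading", "ds_trailing",
            "stance_pct", "single_support_pct", "double_support_pct",
            "fz_peak1", "t_peak1_ms", "t_peak1_pct", "fz_peak2",
            "t_peak2_ms", "t_peak2_pct", "single_peak_flag",
            "fz_tot_peak", "t_tot_peak_ms", "t_tot_peak_pct",
            "fz_peak_front", "fz_peak_back", "delta_fz", "gwt", "abs_gwt")
  M <- matrix(NA_real_, nf, length(cols), dimnames = list(NULL, cols))
  curves_fz <- matrix(NA_real_, nf, config$n_points)
  curves_tot <- matrix(NA_real_, nf, config$n_points)
  ok <- logical(nf)

  for (k in seq_len(nf)) {
    if (!f_valid[k]) next
    stride <- (f_nfs[k] - f_fs[k]) * 1000
    stance <- (f_to[k] - f_fs[k]) * 1000
    ss <- (f_cfs[k] - f_cto[k]) * 1000
    ds_lead <- (f_cto[k] - f_fs[k]) * 1000
    ds_trail <- (f_to[k] - f_cfs[k]) * 1000
    ds <- if (config$double_support == "mean") (ds_lead + ds_trail) / 2
          else ds_lead + ds_trail
    own <- if (f_foot[k] == "L") sig$fz_left else sig$fz_right
    other <- if (f_foot[k] == "L") sig$fz_right else sig$fz_left
    i0 <- findInterval(f_fs[k] - 1e-9, tt) + 1L
    i1 <- findInterval(f_to[k] + 1e-9, tt)
    if (i1 - i0 + 1L < 5L) next
    idx <- i0:i1
    fz_st <- own[idx]; t_st <- tt[idx]

    fp <- peaks_scalar(fz_st, t_st, bw, f_fs[k], stride)
    tot_st <- sig$fz_total[idx]
    ip <- which_max_first(tot_st)

    # weight transfer at the leading double support: this foot is front,
    # the contralateral foot (stance from its previous FS to
    # contralateral_to) is back
    prev_fs <- if (f_foot[k] == "L") fs_r_prev else fs_l_prev
    prev_fs <- prev_fs[prev_fs < f_fs[k]]
    wt <- c(NA_real_, NA_real_, NA_real_, NA_real_)
    if (length(prev_fs)) {
      w <- wt_scalar(own, other, tt, f_fs[k], f_to[k], f_cto[k],
                     prev_fs[length(prev_fs)], bw)
      if (!is.null(w)) wt <- w
    }
    M[k, ] <- c(f_fs[k], stride, stance, ss, ds, ds_lead, ds_trail,
                100 * stance / stride, 100 * ss / stride, 100 * ds / stride,
                fp, tot_st[ip] / bw, (t_st[ip] - f_fs[k]) * 1000,
                100 * (t_st[ip] - f_fs[k]) * 1000 / stride,
                wt, abs(wt[4L]))
    u <- (t_st - t_st[1L]) / (t_st[length(t_st)] - t_st[1L])
    xout <- seq(0, 1, length.out = config$n_points)
    curves_fz[k, ] <- stats::approx(u, fz_st / bw, xout = xout)$y
    curves_tot[k, ] <- stats::approx(u, tot_st / bw, xout = xout)$y
    ok[k] <- TRUE
  }
  n_invalid <- sum(!f_valid)
  if (!any(ok))
    stop(sprintf("subject %s: no valid strides", trace$subject_id))
  strides <- data.frame(foot = f_foot[ok], M[ok, , drop = FALSE],
                        stringsAsFactors = FALSE)
  strides$single_peak_flag <- as.logical(strides$single_peak_flag)
  curves_fz <- curves_fz[ok, , drop = FALSE]
  curves_tot <- curves_tot[ok, , drop = FALSE]
  strides <- exclude_turns(strides, config$turn_rule, config$turn_mad_k)
  strides$excluded <- strides$turn_excluded
  strides$exclude_reason <- ifelse(strides$turn_excluded, "turn", "")
  keep <- !strides$excluded
  list(strides = strides,
       curves_fz = curves_fz[keep, , drop = FALSE],
       curves_fz_tot = curves_tot[keep, , drop = FALSE],
       qc = c(n_frames = nrow(frames),
              n_valid = sum(frames$valid),
              n_ordering_invalid = n_invalid,
              n_turn_excluded = sum(strides$turn_excluded),
              n_used = sum(keep)),
       signal = sig)
}

prev_event_before <- function(ev, type, t) {
  x <- ev$time[ev$event == type & ev$time < t]
  if (length(x)) x[length(x)] else NA_real_
}

#' Extract features for a whole cohort
#'
#' Runs [extract_subject()] per subject, isolating per-subject failures
#' (a failing subject is logged and skipped, never aborts the cohort), and
#' assembles per-subject summaries, mean stance curves, and a QC table.
#' Outputs are ordered by subject id so results do not depend on input
#' order.
#'
#' @param traces List of [sensor_trace()] (body mass may come from
#'   `demographics` when absent on the trace).
#' @param demographics Demographics data frame ([read_demographics()]).
#' @param config A [pipeline_config()].
#' @return List: `summaries` (one row per subject), `curves_fz`,
#'   `curves_fz_tot` (matrices of per-subject mean curves, rownames =
#'   subject ids), `qc` (per-subject QC counts), `failures` (named
#'   character vector of error messages).
#' @export
run_extract <- function(traces, demographics, config = pipeline_config()) {
  ids <- vapply(traces, function(tr) tr$subject_id, character(1))
  ord <- order(ids)
  traces <- traces[ord]
  ids <- ids[ord]
  summaries <- list(); curves <- list(); curves_tot <- list()
  qc <- list(); failures <- character(0)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    meta <- demographics[demographics$subject_id == tr$subject_id, ,
                         drop = FALSE]
    if (!nrow(meta)) {
      failures[tr$subject_id] <- "no demographics row"
      next
    }
    if (is.na(tr$body_mass)) tr$body_mass <- meta$body_mass[1L]
    res <- tryCatch(extract_subject(tr, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[tr$subject_id] <- conditionMessage(res)
      next
    }
    s <- subject_summary(res$strides, meta)
    if (is.null(s)) {
      failures[tr$subject_id] <- "fewer than 2 included strides on a foot"
      next
    }
    summaries[[tr$subject_id]] <- s
    curves[[tr$subject_id]] <- colMeans(res$curves_fz)
    curves_tot[[tr$subject_id]] <- colMeans(res$curves_fz_tot)
    qc[[tr$subject_id]] <- res$qc
  }
  if (!length(summaries)) stop("no subjects could be extracted")
  list(summaries = do.call(rbind, summaries),
       curves_fz = do.call(rbind, curves),
       curves_fz_tot = do.call(rbind, curves_tot),
       qc = do.call(rbind, qc),
       failures = failures)
}
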