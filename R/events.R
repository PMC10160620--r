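#' Detect foot-strike and toe-off events from a per-foot force signal
#'
#' Foot-strike (FS) is the first sample at or above `threshold` newtons
#' after a sub-threshold run; toe-off (TO) is the first sample strictly
#' below it after a supra-threshold run. Contact or swing phases shorter
#' than `min_phase` milliseconds are treated as threshold chatter and
#' merged into their neighbours before events are extracted. A leading TO
#' and a trailing FS are discarded so the sequence starts with an FS and
#' ends with a TO.
#'
#' @param fz Per-foot force in N (denoised and filtered).
#' @param sample_times Sample times in s.
#' @param threshold Contact threshold in N.
#' @param min_phase Debounce duration in ms.
#' @return Data frame with columns `event` ("FS"/"TO"), `time` (s) and
#'   `index` (sample index), strictly alternating FS, TO, FS, ...
#' @export
detect_events <- function(fz, sample_times, threshold = 20, min_phase = 100) {
  stopifnot(length(fz) == length(sample_times))
  above <- fz >= threshold
  if (!any(above)) stop("no supra-threshold samples: no gait detected")
  dt <- stats::median(diff(sample_times))
  min_len <- max(1L, round((min_phase / 1000) / dt))
  # debounce: repeatedly absorb the shortest interior run below min_len
  repeat {
    r <- rle(above)
    if (length(r$lengths) <= 2L) break
    interior <- 2L:(length(r$lengths) - 1L)
    short <- interior[r$lengths[interior] < min_len]
    if (!length(short)) break
    j <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    above[starts[j]:ends[j]] <- !r$values[j]
  }
  d <- diff(above)
  fs_idx <- which(d == 1L) + 1L
  to_idx <- which(d == -1L) + 1L
  ev <- rbind(data.frame(event = "FS", index = fs_idx),
              data.frame(event = "TO", index = to_idx))
  ev <- ev[order(ev$index), ]
  # trim so the sequence starts at FS and ends at TO
  while (nrow(ev) && ev$event[1L] == "TO") ev <- ev[-1L, , drop = FALSE]
  while (nrow(ev) && ev$event[nrow(ev)] == "FS")
    ev <- ev[-nrow(ev), , drop = FALSE]
  if (!nrow(ev)) stop("no complete contact phase detected")
  ev$time <- sample_times[ev$index]
  rownames(ev) <- NULL
  ev[, c("event", "time", "index")]
}

#' Assemble stride frames from the two feet's event sequences
#'
#' For each consecutive pair of same-foot foot-strikes, locates that foot's
#' toe-off plus the contralateral toe-off and foot-strike falling inside
#' the cycle, and checks the normal-walking ordering
#' `fs < contralateral_to < contralateral_fs < to < next_fs`. Frames
#' violating it (double contralateral contact, flight phases, missing
#' events) are kept with `valid = FALSE` and counted in the QC attributes.
#'
#' @param events_left,events_right Event tables from [detect_events()].
#' @return Data frame of stride frames (`foot`, `fs`, `contralateral_to`,
#'   `contralateral_fs`, `to`, `next_fs`, `valid`), ordered by `fs`, with
#'   a `qc` attribute giving per-foot counts.
#' @export
build_strides <- function(events_left, events_right) {
  frames_for <- function(ev, ev_c, foot) {
    fs <- ev$time[ev$event == "FS"]
    to <- ev$time[ev$event == "TO"]
    c_fs <- ev_c$time[ev_c$event == "FS"]
    c_to <- ev_c$time[ev_c$event == "TO"]
    if (length(fs) < 2L) return(NULL)
    out <- lapply(seq_len(length(fs) - 1L), function(k) {
      a <- fs[k]; b <- fs[k + 1L]
      own_to <- to[to > a & to < b]
      cto <- c_to[c_to > a & c_to < b]
      cfs <- c_fs[c_fs > a & c_fs < b]
      valid <- length(own_to) == 1L && length(cto) >= 1L &&
        length(cfs) == 1L
      cto1 <- if (length(cto)) cto[1L] else NA_real_
      cfs1 <- if (length(cfs)) cfs[1L] else NA_real_
      oto <- if (length(own_to)) own_to[1L] else NA_real_
      valid <- valid && !is.na(cto1) && !is.na(cfs1) &&
        a < cto1 && cto1 < cfs1 && cfs1 < oto && oto < b &&
        length(cto) == 1L
      data.frame(foot = foot, fs = a, contralateral_to = cto1,
                 contralateral_fs = cfs1, to = oto, next_fs = b,
                 valid = valid, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  fl <- frames_for(events_left, events_right, "L")
  fr <- frames_for(events_right, events_left, "R")
  frames <- rbind(fl, fr)
  if (is.null(frames) || !nrow(frames))
    stop("feet have no overlapping gait: cannot pair events")
  frames <- frames[order(frames$fs), ]
  rownames(frames) <- NULL
  attr(frames, "qc") <- c(n_frames = nrow(frames),
                          n_valid = sum(frames$valid),
                          n_invalid = sum(!frames$valid))
  frames
}
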