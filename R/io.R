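# Standard gravitational acceleration used for body-weight normalization.
GRAVITY <- 9.80665

#' Construct a raw multichannel shoe-sensor trace
#'
#' A `sensor_trace` holds one subject's raw recording: sample times, the
#' 8 force channels under each shoe, the nominal sampling rate, and (once
#' joined from the demographics table) the body mass used for body-weight
#' normalization.
#'
#' @param subject_id Character scalar.
#' @param sample_times Numeric vector of sample times in seconds, strictly
#'   increasing and nominally uniform.
#' @param left_sensors,right_sensors Numeric matrices with one row per
#'   sample and 8 columns (one per pressure sensor), forces in newtons.
#' @param sampling_rate Sampling rate in Hz (nominally 100).
#' @param body_mass Body mass in kg, or `NA` until demographics are joined.
#' @return An object of class `sensor_trace`.
#' @export
sensor_trace <- function(subject_id, sample_times, left_sensors,
                         right_sensors, sampling_rate = 100,
                         body_mass = NA_real_) {
  left_sensors <- as.matrix(left_sensors)
  right_sensors <- as.matrix(right_sensors)
  n <- length(sample_times)
  if (n > 0L && (ncol(left_sensors) != 8L || ncol(right_sensors) != 8L))
    stop("sensor matrices must have 8 columns")
  if (nrow(left_sensors) != n || nrow(right_sensors) != n)
    stop("sensor channel length does not match sample_times")
  if (any(!is.finite(sample_times)))
    stop("non-finite sample times")
  if (n > 1L && any(diff(sample_times) <= 0))
    stop("time column must be strictly increasing")
  if (any(!is.finite(left_sensors)) || any(!is.finite(right_sensors)))
    stop("non-finite force values")
  if (any(left_sensors < 0) || any(right_sensors < 0))
    stop("negative force values")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  structure(
    list(subject_id = as.character(subject_id),
         sample_times = as.numeric(sample_times),
         left_sensors = left_sensors,
         right_sensors = right_sensors,
         sampling_rate = sampling_rate,
         body_mass = body_mass),
    class = "sensor_trace")
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("<sensor_trace> subject %s: %d samples @ %g Hz (%.1f s)%s\n",
              x$subject_id, length(x$sample_times), x$sampling_rate,
              if (length(x$sample_times)) diff(range(x$sample_times)) else 0,
              if (is.na(x$body_mass)) "" else
                sprintf(", body mass %.1f kg", x$body_mass)))
  invisible(x)
}

#' Read a gaitpdb-style force record
#'
#' Parses the 19-column whitespace-delimited dialect used by the Physionet
#' gait-in-Parkinson's-disease database: time (s), 8 left-shoe sensor
#' forces (N), 8 right-shoe sensor forces (N), left total (N), right total
#' (N); no header, one row per sample at nominally 100 Hz. The two trailing
#' per-foot totals are checked against the recomputed sensor sums (the
#' pipeline always recomputes totals itself); a disagreement beyond
#' `total_tol` newtons on any sample raises a warning.
#'
#' @param file Path to a file, or a connection.
#' @param subject_id Subject identifier; defaults to the file base name
#'   stripped of its extension.
#' @param body_mass Optional body mass in kg to attach.
#' @param total_tol Tolerance in newtons for the stored-total cross-check.
#' @return A [sensor_trace()].
#' @export
read_force_record <- function(file, subject_id = NULL, body_mass = NA_real_,
                              total_tol = 0.5) {
  if (is.null(subject_id)) {
    subject_id <- if (is.character(file))
      sub("\\.[^.]*$", "", basename(file)) else "unknown"
  }
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(sensor_trace(subject_id, numeric(0),
                        matrix(numeric(0), 0, 8), matrix(numeric(0), 0, 8),
                        sampling_rate = 100, body_mass = body_mass))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(fields)
  bad <- which(ncols != 19L)
  if (length(bad))
    stop(sprintf("line %d: expected 19 columns, found %d",
                 bad[1], ncols[bad[1]]))
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 19L, byrow = TRUE)
  if (anyNA(m)) {
    bad_row <- which(apply(is.na(m), 1L, any))[1]
    stop(sprintf("line %d: non-numeric field", bad_row))
  }
  tt <- m[, 1L]
  if (length(tt) > 1L && any(diff(tt) <= 0))
    stop("time column is not strictly increasing")
  sampling_rate <- if (length(tt) > 1L) 1 / stats::median(diff(tt)) else 100
  left <- m[, 2:9, drop = FALSE]
  right <- m[, 10:17, drop = FALSE]
  stored_left <- m[, 18L]
  stored_right <- m[, 19L]
  dl <- abs(rowSums(left) - stored_left)
  dr <- abs(rowSums(right) - stored_right)
  if (any(dl > total_tol) || any(dr > total_tol))
    warning(sprintf(
      "stored per-foot totals disagree with sensor sums by up to %.2f N; using recomputed sums",
      max(dl, dr)))
  sensor_trace(subject_id, tt, left, right,
               sampling_rate = sampling_rate, body_mass = body_mass)
}

#' Write a force record in the gaitpdb 19-column dialect
#'
#' Totals are recomputed as the row-wise sums of each foot's 8 sensors.
#' Times and forces are written with 2 decimals (the 10 ms / centinewton
#' grid of the source format).
#'
#' @param trace A [sensor_trace()].
#' @param file Path or connection to write to.
#' @return Invisibly, the path/connection.
#' @export
write_force_record <- function(trace, file) {
  stopifnot(inherits(trace, "sensor_trace"))
  n <- length(trace$sample_times)
  if (n == 0L) {
    writeLines(character(0), file)
    return(invisible(file))
  }
  m <- cbind(trace$sample_times, trace$left_sensors, trace$right_sensors,
             rowSums(trace$left_sensors), rowSums(trace$right_sensors))
  lines <- apply(m, 1L, function(row) paste(sprintf("%.2f", row),
                                            collapse = "\t"))
  writeLines(lines, file)
  invisible(file)
}

#' Read a demographics table
#'
#' Reads a delimited (comma or tab, sniffed from the header line) table with
#' a header and returns one row per subject with the columns the pipeline
#' uses: `subject_id`, `group` ("PD"/"control"), `sex`, `age` (years),
#' `height` (cm), `body_mass` (kg), `walking_speed` (m/s), `hoehn_yahr`,
#' `updrs`, `tug` (s). Missing optional fields come back as `NA`, never as
#' zero. Nonstandard headers are mapped via `col_map`; a height column in
#' metres is converted when `height_unit = "m"`.
#'
#' @param file Path or connection.
#' @param col_map Named character vector mapping canonical names (names)
#'   to the file's header names (values), e.g.
#'   `c(subject_id = "ID", body_mass = "Weight")`.
#' @param height_unit `"cm"` (default) or `"m"`.
#' @return A data.frame with one row per subject.
#' @export
read_demographics <- function(file, col_map = NULL, height_unit = c("cm", "m")) {
  height_unit <- match.arg(height_unit)
  header <- readLines(file, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          na.strings = c("", "NA", "NaN"))
  canon <- c("subject_id", "group", "sex", "age", "height", "body_mass",
             "walking_speed", "hoehn_yahr", "updrs", "tug")
  nm <- names(df)
  for (k in names(col_map)) {
    hit <- match(col_map[[k]], nm)
    if (is.na(hit)) stop(sprintf("mapped column '%s' not found", col_map[[k]]))
    nm[hit] <- k
  }
  names(df) <- nm
  mandatory <- c("subject_id", "group", "body_mass", "walking_speed")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop(sprintf("demographics table lacks mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop(sprintf("duplicate subject_id: %s",
                 df$subject_id[duplicated(df$subject_id)][1]))
  grp <- tolower(as.character(df$group))
  grp[grp %in% c("pd", "parkinson", "patient")] <- "PD"
  grp[grp %in% c("control", "co", "healthy", "ctrl")] <- "control"
  if (!all(grp %in% c("PD", "control")))
    stop("group labels must be PD or control")
  df$group <- grp
  for (k in setdiff(canon, names(df))) df[[k]] <- NA
  if (!all(is.na(df$sex))) {
    sx <- toupper(substr(as.character(df$sex), 1L, 1L))
    sx[!sx %in% c("M", "F")] <- "unknown"
    df$sex <- sx
  }
  num_cols <- c("age", "height", "body_mass", "walking_speed",
                "hoehn_yahr", "updrs", "tug")
  for (k in num_cols) df[[k]] <- suppressWarnings(as.numeric(df[[k]]))
  if (height_unit == "m") df$height <- df$height * 100
  if (any(!is.na(df$body_mass) & df$body_mass <= 0))
    stop("body_mass must be positive")
  if (any(!is.na(df$walking_speed) & df$walking_speed < 0))
    stop("walking_speed must be nonnegative")
  df[canon]
}

#' Write a demographics table
#'
#' @param demographics Data frame as returned by [read_demographics()].
#' @param file Path or connection.
#' @return Invisibly, the path/connection.
#' @export
write_demographics <- function(demographics, file) {
  utils::write.table(demographics, file, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(file)
}
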