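#' Run the whole chain: simulate (optional), extract, compare
#'
#' One seed fixes the full chain; two runs with the same inputs and seed
#' produce identical reports. When `cohort` is `NULL` a synthetic cohort is
#' simulated from `pd_params`/`control_params`.
#'
#' @param cohort Optional list with `traces` and `demographics` (e.g. from
#'   [simulate_cohort()] or read from disk). Simulated when `NULL`.
#' @param pd_params,control_params [gait_params()] used when simulating.
#' @param n_pd,n_control Group sizes when simulating.
#' @param config A [pipeline_config()].
#' @param seed Master seed.
#' @param out_dir Optional directory; when given, feature tables, QC, the
#'   group tables and the resolved config are written there as delimited
#'   text.
#' @return List with `extraction` ([run_extract()] output) and `comparison`
#'   ([compare_cohorts()] output).
#' @export
run_all <- function(cohort = NULL, pd_params = gait_params(),
                    control_params = gait_params(stride_time_mean = 1107,
                                                 stride_time_cv = 2.1),
                    n_pd = 10, n_control = 10,
                    config = pipeline_config(), seed = 1L,
                    out_dir = NULL) {
  if (is.null(cohort))
    cohort <- simulate_cohort(pd_params, control_params, n_pd, n_control,
                              seed = seed)
  extraction <- run_extract(cohort$traces, cohort$demographics, config)
  comparison <- compare_cohorts(extraction, config, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(extraction$summaries,
                       file.path(out_dir, "subject_summaries.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(cbind(subject_id = rownames(extraction$qc),
                             as.data.frame(extraction$qc)),
                       file.path(out_dir, "qc_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    tabs <- c("characteristics", "temporal", "temporal_cv", "temporal_si",
              "force", "force_cv", "force_si")
    for (tb in tabs) {
      df <- comparison[[tb]]
      if (!is.null(df))
        utils::write.table(df, file.path(out_dir, paste0("table_", tb, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
    }
    spm_df <- data.frame(
      stance_pct = comparison$spm_fz$grid,
      t_fz = comparison$spm_fz$t_field,
      t_fz_tot = comparison$spm_fz_tot$t_field)
    utils::write.table(spm_df, file.path(out_dir, "spm_t_fields.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(c(
      sprintf("seed: %d", seed),
      sprintf("%s: %s", names(config), vapply(config, function(v)
        paste(format(v), collapse = " "), character(1)))),
      file.path(out_dir, "resolved_config.txt"))
  }
  list(extraction = extraction, comparison = comparison)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory with `<id>.txt` force records and
#'   `demographics.tsv`.
#' @param col_map,height_unit Passed to [read_demographics()].
#' @return List with `traces` and `demographics`.
#' @export
read_cohort <- function(dir, col_map = NULL, height_unit = "cm") {
  demo <- read_demographics(file.path(dir, "demographics.tsv"),
                            col_map = col_map, height_unit = height_unit)
  files <- file.path(dir, paste0(demo$subject_id, ".txt"))
  missing <- !file.exists(files)
  if (any(missing))
    warning(sprintf("%d force record(s) missing", sum(missing)))
  traces <- lapply(which(!missing), function(i)
    read_force_record(files[i], demo$subject_id[i],
                      body_mass = demo$body_mass[i]))
  list(traces = traces, demographics = demo)
}
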