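#' Select the speed-matched cohort
#'
#' Keeps subjects whose self-selected walking speed lies in the inclusive
#' band `[lo, hi]` m/s, so both groups are compared at matched speed.
#' Subjects with a missing speed are dropped with a warning.
#'
#' @param demographics Demographics data frame.
#' @param lo,hi Band limits in m/s (inclusive).
#' @return The filtered data frame, with a `counts` attribute giving the
#'   retained per-group n.
#' @export
select_speed_matched <- function(demographics, lo = 1.0, hi = 1.3) {
  if (!nrow(demographics)) {
    attr(demographics, "counts") <- c(PD = 0L, control = 0L)
    return(demographics)
  }
  sp <- demographics$walking_speed
  if (any(is.na(sp))) {
    warning(sprintf("%d subject(s) without walking speed dropped",
                    sum(is.na(sp))))
  }
  keep <- !is.na(sp) & sp >= lo & sp <= hi
  out <- demographics[keep, , drop = FALSE]
  attr(out, "counts") <- c(PD = sum(out$group == "PD"),
                           control = sum(out$group == "control"))
  out
}

#' Unpaired two-sided Student's t-test
#'
#' Classic pooled-variance t with `n_a + n_b - 2` degrees of freedom
#' (wraps [stats::t.test()] with `var.equal = TRUE`). Zero pooled variance
#' is handled explicitly: equal means give `t = 0, p = 1`; unequal means
#' give `p = 0` with a `degenerate` flag.
#'
#' @param a,b Numeric vectors of subject-level values.
#' @return List with `t`, `p`, `df`, `degenerate`.
#' @export
ttest_unpaired <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2L,
                  degenerate = FALSE))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                df = length(a) + length(b) - 2L, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}

#' Pearson correlation with two-sided p value
#'
#' Sample Pearson r with the t-transform p value
#' (`t = r * sqrt((n - 2) / (1 - r^2))`), via [stats::cor.test()].
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return List with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

# Vectorized pooled-variance t statistic at every grid point for a curve
# matrix X (subjects x points) split by the logical index `in_a`.
pointwise_t <- function(X, in_a) {
  na <- sum(in_a); nb <- sum(!in_a)
  A <- X[in_a, , drop = FALSE]; B <- X[!in_a, , drop = FALSE]
  ma <- colMeans(A); mb <- colMeans(B)
  va <- colSums(A^2) - na * ma^2
  vb <- colSums(B^2) - nb * mb^2
  sp2 <- (va + vb) / (na + nb - 2L)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (ma - mb) / se
  tt[se == 0 & ma == mb] <- 0
  tt
}

#' One-dimensional SPM two-sample t-test with a permutation threshold
#'
#' Computes the pointwise pooled-variance t statistic at each point of the
#' stance-normalized grid and a family-wise critical threshold as the
#' `1 - alpha` quantile of the permutation distribution of `max|t|` over
#' group-label permutations (complete enumeration when the number of
#' distinct assignments does not exceed `n_perm`, otherwise `n_perm`
#' Monte-Carlo permutations under `seed`). Contiguous runs where
#' `|t|` exceeds the threshold are reported as suprathreshold clusters.
#'
#' @param curves_a,curves_b Matrices of subject mean curves (one row per
#'   subject, same number of columns).
#' @param alpha Family-wise significance level.
#' @param n_perm Maximum number of permutations.
#' @param seed Integer seed for the Monte-Carlo case.
#' @return An `spm_result` list: `t_field`, `critical_threshold`,
#'   `clusters` (data.frame `start_pct`/`end_pct`), `max_abs_t`,
#'   `n_permutations`, `exhaustive`, `alpha`, `seed`.
#' @export
spm_ttest_1d <- function(curves_a, curves_b, alpha = 0.05, n_perm = 10000,
                         seed = 1L) {
  curves_a <- as.matrix(curves_a); curves_b <- as.matrix(curves_b)
  stopifnot(ncol(curves_a) == ncol(curves_b),
            nrow(curves_a) >= 2L, nrow(curves_b) >= 2L)
  X <- rbind(curves_a, curves_b)
  na <- nrow(curves_a); n <- nrow(X)
  labels_a <- seq_len(na)
  in_a <- seq_len(n) <= na
  t_obs <- pointwise_t(X, in_a)

  zero_var <- apply(X, 2L, function(col) stats::var(col) == 0)
  if (all(zero_var)) {
    warning("all grid points have zero variance: degenerate SPM input")
    grid <- seq(0, 100, length.out = ncol(X))
    return(structure(list(t_field = t_obs, critical_threshold = Inf,
                          clusters = data.frame(start_pct = numeric(0),
                                                end_pct = numeric(0)),
                          max_abs_t = 0, n_permutations = 0L,
                          exhaustive = TRUE, alpha = alpha,
                          seed = as.integer(seed), grid = grid),
                     class = "spm_result"))
  }
  if (any(zero_var))
    warning(sprintf("%d zero-variance grid point(s) dropped from max|t|",
                    sum(zero_var)))

  n_total <- choose(n, na)
  exhaustive <- n_total <= n_perm
  if (exhaustive) {
    combos <- utils::combn(n, na)
    perm_sets <- lapply(seq_len(ncol(combos)), function(j) combos[, j])
  } else {
    set.seed(seed)
    perm_sets <- c(list(labels_a),
                   lapply(seq_len(n_perm - 1L),
                          function(j) sample.int(n, na)))
  }
  max_t <- vapply(perm_sets, function(idx) {
    ia <- seq_len(n) %in% idx
    max(abs(pointwise_t(X, ia)[!zero_var]))
  }, numeric(1))
  crit <- stats::quantile(max_t, 1 - alpha, names = FALSE, type = 1)

  grid <- seq(0, 100, length.out = ncol(X))
  above <- abs(t_obs) > crit & !zero_var
  clusters <- if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    data.frame(start_pct = grid[starts[r$values]],
               end_pct = grid[ends[r$values]])
  } else data.frame(start_pct = numeric(0), end_pct = numeric(0))

  structure(list(t_field = t_obs, critical_threshold = crit,
                 clusters = clusters,
                 max_abs_t = max(abs(t_obs)[!zero_var]),
                 n_permutations = length(perm_sets),
                 exhaustive = exhaustive, alpha = alpha,
                 seed = as.integer(seed), grid = grid),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf(
    "<spm_result> max|t| = %.3f, critical threshold = %.3f (alpha = %g, %d %s permutations)\n",
    x$max_abs_t, x$critical_threshold, x$alpha, x$n_permutations,
    if (x$exhaustive) "exhaustive" else "Monte-Carlo"))
  if (nrow(x$clusters)) {
    cat("suprathreshold clusters (% of stance):\n")
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  %.0f%% - %.0f%%\n", x$clusters$start_pct[i],
                  x$clusters$end_pct[i]))
  } else cat("no suprathreshold clusters\n")
  invisible(x)
}

# Variable dictionary for the five group tables: display name, summary
# column, and which tables it feeds.
table_layout <- function() {
  temporal <- c(stride_time = "Stride time (ms)",
                single_support_time = "Single support time (ms)",
                single_support_pct = "Single support time (%)",
                double_support_time = "Double support time (ms)",
                double_support_pct = "Double support time (%)",
                stance_time = "Stance time (ms)",
                stance_pct = "Stance time (%)")
  force <- c(fz_peak1 = "Fz,peak1 (BW)",
             t_peak1_ms = "Time to Fz,peak1 (ms)",
             t_peak1_pct = "Time to Fz,peak1 (%)",
             fz_peak2 = "Fz,peak2 (BW)",
             t_peak2_ms = "Time to Fz,peak2 (ms)",
             t_peak2_pct = "Time to Fz,peak2 (%)",
             fz_tot_peak = "Fz,tot,peak (BW)",
             t_tot_peak_ms = "Time to Fz,tot,peak (ms)",
             t_tot_peak_pct = "Time to Fz,tot,peak (%)",
             fz_peak_front = "Fz,peak front (BW)",
             fz_peak_back = "Fz,peak back (BW)",
             delta_fz = "Delta Fz (BW)",
             abs_gwt = "Gait weight transfer (ms)")
  list(temporal = temporal, force = force)
}

group_stats_row <- function(values, groups, label) {
  a <- values[groups == "PD"]; b <- values[groups == "control"]
  n_a <- sum(!is.na(a)); n_b <- sum(!is.na(b))
  ht <- if (n_a >= 2L && n_b >= 2L) ttest_unpaired(a, b) else
    list(t = NA_real_, p = NA_real_)
  data.frame(variable = label,
             pd_mean = mean(a, na.rm = TRUE), pd_sd = stats::sd(a, na.rm = TRUE),
             control_mean = mean(b, na.rm = TRUE),
             control_sd = stats::sd(b, na.rm = TRUE),
             t = ht$t, p = ht$p, n_pd = n_a, n_control = n_b,
             stringsAsFactors = FALSE)
}

#' Compare PD and control cohorts
#'
#' Builds the five group-level tables (participant characteristics;
#' temporal variable means and CVs; temporal symmetry indices; force
#' variable means and CVs; force symmetry indices), each with group
#' means +/- SD and unpaired Student's t-test p values, plus the SPM
#' comparison of the per-foot and total stance-normalized force curves.
#'
#' @param extraction Result of [run_extract()] (summaries + mean curves).
#' @param config A [pipeline_config()]; `speed_lo`/`speed_hi` select the
#'   cohort, `alpha`/`n_perm` control the SPM test.
#' @param seed Seed for the SPM permutations.
#' @return A `cohort_comparison` list: `characteristics`, `temporal`,
#'   `temporal_si`, `force`, `force_si` (data frames), `spm_fz`,
#'   `spm_fz_tot` ([spm_ttest_1d()] results), `counts`, `updrs_speed_r`
#'   (Pearson r of disease score vs speed within PD, when scores vary).
#' @export
compare_cohorts <- function(extraction, config = pipeline_config(),
                            seed = 1L) {
  s <- extraction$summaries
  sel <- select_speed_matched(s, config$speed_lo, config$speed_hi)
  if (!nrow(sel)) stop("no subjects in the speed band")
  counts <- attr(sel, "counts")
  if (any(counts == 0)) stop("a group is empty after speed selection")
  groups <- sel$group
  lay <- table_layout()

  char_vars <- c(age = "Age (year)", height = "Height (cm)",
                 body_mass = "Body mass (kg)",
                 walking_speed = "Walking speed (m/s)",
                 hoehn_yahr = "Hoehn-Yahr scale", updrs = "UPDRS",
                 tug = "Timed up and go (s)")
  chars <- do.call(rbind, lapply(names(char_vars), function(v) {
    if (all(is.na(sel[[v]]))) return(NULL)
    group_stats_row(sel[[v]], groups, char_vars[[v]])
  }))

  make_table <- function(vars, suffix) {
    do.call(rbind, lapply(names(vars), function(v) {
      col <- paste0(v, suffix)
      if (!col %in% names(sel)) return(NULL)
      row <- group_stats_row(sel[[col]], groups, vars[[v]])
      prop_na <- min(mean(is.na(sel[[col]][groups == "PD"])),
                     mean(is.na(sel[[col]][groups == "control"])))
      row$flagged <- prop_na > 0.5
      row
    }))
  }
  temporal <- make_table(lay$temporal, "_mean")
  temporal_cv <- make_table(lay$temporal, "_cv")
  temporal_si <- make_table(lay$temporal, "_si")
  force <- make_table(lay$force, "_mean")
  force_cv <- make_table(lay$force, "_cv")
  force_si <- make_table(lay$force, "_si")

  ids <- sel$subject_id
  cfz <- extraction$curves_fz[ids, , drop = FALSE]
  ctot <- extraction$curves_fz_tot[ids, , drop = FALSE]
  spm_fz <- spm_ttest_1d(cfz[groups == "PD", , drop = FALSE],
                         cfz[groups == "control", , drop = FALSE],
                         alpha = config$alpha, n_perm = config$n_perm,
                         seed = seed)
  spm_tot <- spm_ttest_1d(ctot[groups == "PD", , drop = FALSE],
                          ctot[groups == "control", , drop = FALSE],
                          alpha = config$alpha, n_perm = config$n_perm,
                          seed = seed + 1L)

  pd <- sel[groups == "PD", ]
  updrs_speed <- if (sum(!is.na(pd$updrs)) >= 3L &&
                     stats::var(pd$updrs, na.rm = TRUE) > 0 &&
                     stats::var(pd$walking_speed, na.rm = TRUE) > 0)
    pearson(pd$updrs, pd$walking_speed) else NULL

  structure(list(characteristics = chars,
                 temporal = temporal, temporal_cv = temporal_cv,
                 temporal_si = temporal_si,
                 force = force, force_cv = force_cv, force_si = force_si,
                 spm_fz = spm_fz, spm_fz_tot = spm_tot,
                 counts = counts, updrs_speed_r = updrs_speed,
                 alpha = config$alpha),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> PD n = %d, control n = %d (speed-matched)\n",
              x$counts["PD"], x$counts["control"]))
  fmt <- function(df, title) {
    if (is.null(df) || !nrow(df)) return(invisible())
    cat("\n", title, "\n", sep = "")
    for (i in seq_len(nrow(df)))
      cat(sprintf("  %-28s %8.2f ± %-7.2f %8.2f ± %-7.2f p = %s\n",
                  df$variable[i], df$pd_mean[i], df$pd_sd[i],
                  df$control_mean[i], df$control_sd[i],
                  format.pval(df$p[i], digits = 2)))
  }
  fmt(x$characteristics, "Participant characteristics (PD vs control)")
  fmt(x$temporal, "Temporal variables")
  fmt(x$temporal_cv, "Temporal variables: coefficient of variation (%)")
  fmt(x$temporal_si, "Temporal variables: symmetry index (%)")
  fmt(x$force, "Force variables")
  fmt(x$force_cv, "Force variables: coefficient of variation (%)")
  fmt(x$force_si, "Force variables: symmetry index (%)")
  cat("\nSPM, per-foot force curve: ")
  cat(sprintf("max|t| = %.2f vs threshold %.2f -> %s\n",
              x$spm_fz$max_abs_t, x$spm_fz$critical_threshold,
              if (nrow(x$spm_fz$clusters)) "significant" else "not significant"))
  cat("SPM, total force curve:    ")
  cat(sprintf("max|t| = %.2f vs threshold %.2f -> %s\n",
              x$spm_fz_tot$max_abs_t, x$spm_fz_tot$critical_threshold,
              if (nrow(x$spm_fz_tot$clusters)) "significant" else "not significant"))
  if (!is.null(x$updrs_speed_r))
    cat(sprintf("UPDRS vs walking speed (PD): r = %.2f, p = %.3g\n",
                x$updrs_speed_r$r, x$updrs_speed_r$p))
  invisible(x)
}
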