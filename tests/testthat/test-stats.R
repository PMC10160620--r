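test_that("speed band selection is inclusive at both bounds", {
  d <- data.frame(subject_id = paste0("s", 1:5),
                  group = c("PD", "PD", "control", "control", "PD"),
                  walking_speed = c(0.99, 1.00, 1.15, 1.30, 1.31))
  sel <- select_speed_matched(d)
  expect_setequal(sel$walking_speed, c(1.00, 1.15, 1.30))
  empty <- select_speed_matched(d[0, ])
  expect_equal(nrow(empty), 0)
  d$walking_speed[2] <- NA
  expect_warning(sel2 <- select_speed_matched(d), "without walking speed")
  expect_equal(nrow(sel2), 2)
})

test_that("pooled t-test matches closed-form arithmetic", {
  same <- ttest_unpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  ht <- ttest_unpaired(c(1, 2, 3), c(2, 3, 4))
  expect_equal(ht$t, -1.2247, tolerance = 1e-4)
  expect_equal(ht$p, 0.2879, tolerance = 1e-3)
  expect_equal(ht$df, 4)
  zv <- ttest_unpaired(c(1, 1), c(2, 2))
  expect_equal(zv$p, 0)
  expect_true(zv$degenerate)
  const <- ttest_unpaired(c(5, 5, 5), c(5, 5))
  expect_equal(const$p, 1)
})

test_that("t-test power at the study's stride-time effect matches theory", {
  # d = 36 / 80.6 at n = 54/39: analytic power ~0.56 at alpha 0.05
  set.seed(61)
  rej <- mean(replicate(400, {
    a <- rnorm(54, 1071, 80.6); b <- rnorm(39, 1107, 80.6)
    ttest_unpaired(a, b)$p <= 0.05
  }))
  d <- 36 / 80.6
  ncp <- d * sqrt(54 * 39 / 93)
  crit <- qt(0.975, 91)
  power <- 1 - pt(crit, 91, ncp) + pt(-crit, 91, ncp)
  expect_lt(abs(rej - power), 0.08)  # binomial error at 400 replicates
})

test_that("pearson correlation and its p value behave", {
  x <- 1:20
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  set.seed(3)
  ind <- pearson(rnorm(1000), rnorm(1000))
  expect_lt(abs(ind$r), 0.1)
  # recovery of a true correlation at the study's n
  set.seed(5)
  rs <- replicate(2000, {
    z <- rnorm(54); e <- rnorm(54)
    pearson(z, 0.36 * z + sqrt(1 - 0.36^2) * e)$r
  })
  expect_lt(abs(mean(rs) - 0.36), 0.02)
  expect_error(pearson(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearson(1:2, 2:3), "at least 3")
})

test_that("identical groups give a flat zero t-field and no clusters", {
  set.seed(9)
  X <- simulate_stance_curves(8)
  res <- suppressWarnings(spm_ttest_1d(X, X, n_perm = 200, seed = 1))
  expect_true(all(res$t_field == 0))
  expect_equal(nrow(res$clusters), 0)
})

test_that("a strong constant offset is detected over the whole stance", {
  set.seed(10)
  A <- simulate_stance_curves(10)
  B <- A + 0.5
  res <- spm_ttest_1d(A, B, n_perm = 2000, seed = 2)
  expect_gt(res$max_abs_t, res$critical_threshold)
  expect_gt(nrow(res$clusters), 0)
  # the cluster spans essentially the whole stance
  expect_gt(sum(res$clusters$end_pct - res$clusters$start_pct), 90)
})

test_that("small groups are enumerated exhaustively and deterministically", {
  set.seed(11)
  A <- matrix(rnorm(4 * 21), 4, 21); B <- matrix(rnorm(4 * 21), 4, 21)
  res <- spm_ttest_1d(A, B, n_perm = 10000, seed = 3)
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, choose(8, 4))
  res2 <- spm_ttest_1d(A, B, n_perm = 10000, seed = 3)
  expect_identical(res$critical_threshold, res2$critical_threshold)
  expect_identical(res$t_field, res2$t_field)
  # threshold does not decrease as alpha decreases
  r05 <- spm_ttest_1d(A, B, alpha = 0.05, n_perm = 10000, seed = 3)
  r01 <- spm_ttest_1d(A, B, alpha = 0.01, n_perm = 10000, seed = 3)
  expect_gte(r01$critical_threshold, r05$critical_threshold)
})

test_that("cohort comparison assembles the five group tables", {
  co <- simulate_cohort(gait_params(stride_time_mean = 1071,
                                    asymmetry_offset = 11,
                                    walk_duration = 30),
                        gait_params(stride_time_mean = 1107,
                                    walk_duration = 30),
                        6, 6, seed = 33)
  ex <- suppressWarnings(run_extract(co$traces, co$demographics))
  cmp <- compare_cohorts(ex, pipeline_config(n_perm = 200), seed = 1)
  expect_s3_class(cmp, "cohort_comparison")
  expect_equal(nrow(cmp$temporal), 7)
  expect_equal(nrow(cmp$temporal_si), 7)
  expect_equal(nrow(cmp$force), 13)
  expect_equal(nrow(cmp$force_si), 13)
  expect_true(all(cmp$temporal$p >= 0 & cmp$temporal$p <= 1, na.rm = TRUE))
  expect_length(cmp$spm_fz$t_field, 101)
  expect_output(print(cmp), "SPM")
  # PD-like group constructed with larger asymmetry shows larger SI
  ss_si <- cmp$temporal_si[cmp$temporal_si$variable == "Single support time (ms)", ]
  expect_gt(ss_si$pd_mean, ss_si$control_mean)
})
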