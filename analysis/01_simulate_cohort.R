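#!/usr/bin/env Rscript

# Stage 1: simulate a speed-matched study cohort with known ground truth.
#
# Group settings mirror the study population this pipeline targets:
# PD-like subjects with mean stride time 1071 ms (within-subject CV 2.2%)
# and control-like subjects with 1107 ms (CV 2.1%), between-subject SD
# ~80 ms, walking speeds drawn across 1.05-1.25 m/s, n = 54 / 39.
# Writes gaitpdb-style force records, a demographics table and the
# ground-truth stride sidecar under results/cohort/.

suppressPackageStartupMessages(library(pdgait))

seed <- 1L
out_dir <- "results/cohort"

cohort <- simulate_cohort(
  pd_params = gait_params(stride_time_mean = 1071, stride_time_cv = 2.2),
  control_params = gait_params(stride_time_mean = 1107, stride_time_cv = 2.1),
  n_pd = 54, n_control = 39, seed = seed)

write_cohort(cohort, out_dir)

n_strides <- vapply(cohort$truths, function(tt) nrow(tt$strides), integer(1))
cat(sprintf("simulated %d subjects (%d PD, %d control), %d-%d strides each\n",
            nrow(cohort$demographics),
            sum(cohort$demographics$group == "PD"),
            sum(cohort$demographics$group == "control"),
            min(n_strides), max(n_strides)))
cat(sprintf("wrote force records + demographics + ground truth to %s\n",
            out_dir))
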