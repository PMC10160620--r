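# Shared fixtures, all built in code.

# A sensor_trace whose left/right totals are rectangular pulses, for exact
# event-detection arithmetic.
pulse_trace <- function(n = 1000, starts, len, level = 700, foot = "left",
                        dt = 0.01) {
  fz <- numeric(n)
  for (s in starts) fz[s:min(s + len - 1L, n)] <- level
  zero <- matrix(0, n, 8)
  m <- outer(fz, rep(1 / 8, 8))
  if (foot == "left")
    sensor_trace("pulse", (seq_len(n) - 1L) * dt, m, zero, body_mass = 70)
  else
    sensor_trace("pulse", (seq_len(n) - 1L) * dt, zero, m, body_mass = 70)
}

# A random valid trace for round-trip tests.
random_trace <- function(n = 100, seed = 1) {
  set.seed(seed)
  sensor_trace(sprintf("rnd%d", seed),
               (seq_len(n) - 1L) * 0.01,
               matrix(round(runif(n * 8, 0, 200), 2), n, 8),
               matrix(round(runif(n * 8, 0, 200), 2), n, 8),
               body_mass = 70)
}

# First grid sample at/after the analytic 20 N upcrossing (and first grid
# sample strictly after the downcrossing) of the noise-free stance profile:
# the ideal threshold detector applied to the continuous ground truth.
crossing_oracle <- function(truth_events, foot, amplitude, shape_ratio,
                            body_mass, threshold = 20, dt = 0.01) {
  bw <- body_mass * 9.80665
  u20 <- stats::uniroot(function(u)
    stance_profile(u, amplitude, shape_ratio) * bw - threshold,
    c(1e-12, 0.2), tol = 1e-14)$root
  ev <- truth_events[truth_events$foot == foot, ]
  fs <- ev$time[ev$event == "FS"]
  to <- ev$time[ev$event == "TO"]
  n <- min(length(fs), length(to))
  stance <- to[1:n] - fs[1:n]
  list(fs = ceiling((fs[1:n] + u20 * stance) / dt - 1e-9) * dt,
       to = ceiling((to[1:n] - u20 * stance) / dt + 1e-9) * dt)
}
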