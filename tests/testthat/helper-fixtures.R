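# Shared generators for randomized property tests. All randomness goes
# through withr-free local seeding so tests are reproducible.

rand_times <- function(n, t0 = 0, max_gap = 60000) {
  t0 + cumsum(sample.int(max_gap, n, replace = TRUE))
}

rand_series <- function(name = "X", n = 50, mean = 100, sd = 10,
                        p_missing = 0.1, p_artifact = 0.05) {
  tt <- rand_times(n)
  vv <- rnorm(n, mean, sd)
  qq <- sample(c("ok", "missing", "artifact"), n, replace = TRUE,
               prob = c(1 - p_missing - p_artifact, p_missing, p_artifact))
  vv[qq == "missing"] <- NA_real_
  time_series(channel(name), tt, vv, qq)
}

rand_stream <- function(channels = c("HR", "SBP"), n = 50, ...) {
  unified_stream("px", lapply(channels, function(ch)
    rand_series(ch, n = n, ...)))
}

# A profile with deterministic flat channels (no physiologic variability,
# no circadian), for noise-free limit checks.
flat_config <- function(..., channels = default_flat_defs()) {
  cohort_config(..., channel_defs = channels)
}

default_flat_defs <- function(hr_mean = 80) {
  cd <- wardforge:::default_channel_defs()
  cd$mean_sd <- 0
  cd$within_sd <- 0
  cd$circ_frac <- 0
  cd$mean_mean[cd$channel == "HR"] <- hr_mean
  cd
}

expect_series_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$times, b$times)
  expect_equal(a$quality, b$quality)
  expect_equal(a$values, b$values, tolerance = tol)
}
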