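# Virtual-patient generator: profile sampling, clean rendering, corruption,
# R-R interval derivation, and cohort-level parameter recovery.

test_that("profile sampling honours count, prevalence and bounds", {
  cfg <- cohort_config(n_patients = 500, seed = 3)
  ps <- sample_profiles(cfg)
  expect_length(ps, 500L)
  expect_true(all(vapply(ps, function(p)
    all(p$channels$mean >= cfg$channel_defs$lo &
          p$channels$mean <= cfg$channel_defs$hi), logical(1))))
  spo2 <- vapply(ps, function(p)
    p$channels$mean[p$channels$channel == "SpO2"], numeric(1))
  expect_true(all(spo2 <= 100))

  ps0 <- sample_profiles(cohort_config(n_patients = 50, psh_prevalence = 0,
                                       seed = 4))
  expect_false(any(vapply(ps0, `[[`, logical(1), "has_psh")))

  # empirical prevalence within 3 binomial SEs at n = 10000
  psb <- sample_profiles(cohort_config(n_patients = 10000,
                                       psh_prevalence = 0.5, seed = 5))
  prev <- mean(vapply(psb, `[[`, logical(1), "has_psh"))
  expect_lt(abs(prev - 0.5), 3 * sqrt(0.25 / 10000))

  expect_error(cohort_config(n_patients = 0), class = "wf_validation_error")
  expect_error(cohort_config(psh_prevalence = 1.5),
               class = "wf_validation_error")
})

test_that("clean rendering: noise-free limit and episode plateau arithmetic", {
  cfg <- flat_config(n_patients = 1, duration_hours = 4, seed = 9)
  p <- sample_profiles(cfg)[[1]]
  s <- render_clean_stream(p, list(), cfg, seed = 1)
  expect_true(all(s$series$HR$values == 80))
  expect_true(all(s$series$HR$quality == "ok"))

  # HR x1.4 on a flat 80 bpm baseline plateaus at 112 during the plateau
  ep <- episode_spec(3600e3, 60, mult = c(HR = 1.4), add = c(Temp = 1.0),
                     ramp_min = 5)
  s2 <- render_clean_stream(p, list(ep), cfg, seed = 1)
  hr <- s2$series$HR
  plateau <- hr$times >= 3600e3 + 5 * 60e3 & hr$times <= 3600e3 + 55 * 60e3
  expect_true(all(abs(hr$values[plateau] - 112) < 1e-9))
  before <- hr$times < 3600e3
  expect_true(all(hr$values[before] == 80))
  temp <- s2$series$Temp
  expect_true(all(abs(temp$values[plateau] - (36.9 + 1.0)) < 1e-9))
})

test_that("AR(1) coefficient zero gives white physiologic variability", {
  cd <- default_flat_defs()
  cd$within_sd[cd$channel == "HR"] <- 5
  cfg <- cohort_config(n_patients = 1, duration_hours = 48,
                       sample_period_ms = 30e3, ar1_phi = 0,
                       channel_defs = cd, seed = 2)
  p <- sample_profiles(cfg)[[1]]
  s <- render_clean_stream(p, list(), cfg, seed = 21)
  x <- s$series$HR$values
  n <- length(x)
  r1 <- stats::cor(x[-1], x[-n])
  expect_lt(abs(r1), 3 / sqrt(n))
})

test_that("corruption recovers its configured rates and is a no-op at zero", {
  cfg <- flat_config(n_patients = 1, duration_hours = 24,
                     sample_period_ms = 5000, seed = 31)
  p <- sample_profiles(cfg)[[1]]
  clean <- render_clean_stream(p, list(), cfg, seed = 32)

  noop <- corrupt_stream(clean, corruption_config(0, 0, 0), seed = 33,
                         profile = p)
  for (ch in names(clean$series))
    expect_series_equal(noop$series[[ch]], clean$series[[ch]])

  corr <- corrupt_stream(clean, corruption_config(), seed = 34, profile = p)
  qual <- unlist(lapply(corr$series, `[[`, "quality"))
  n <- length(qual) # 6 channels x 17280 samples
  expect_gt(n, 1e5)
  miss <- mean(qual == "missing")
  expect_lt(abs(miss - 0.05), 3 * sqrt(0.05 * 0.95 / n))

  # flat channel: residual SD over ok samples / mean ~ noise_sd_frac
  hr <- corr$series$HR
  ok <- wardforge:::ok_idx(hr)
  ratio <- stats::sd(hr$values[ok]) / 80
  se_sd <- 0.10 / sqrt(2 * (length(ok) - 1)) # closed-form SE of a sample SD
  expect_lt(abs(ratio - 0.10), 3 * se_sd)

  expect_error(corruption_config(missing_rate = 1.2),
               class = "wf_validation_error")
})

test_that("R-R interval generation inverts heart rate and recovers SDNN", {
  hr60 <- time_series(channel("HR"), (1:30) * 60e3, rep(60, 30))
  rr <- generate_rr_series(hr60, 0, seed = 41)
  expect_true(all(rr$values == 1000))

  hr120 <- time_series(channel("HR"), (1:30) * 60e3, rep(120, 30))
  rr2 <- generate_rr_series(hr120, 0, seed = 41)
  expect_true(all(rr2$values == 500))
  expect_equal(rr2$channel$modality, "time_series")

  rr3 <- generate_rr_series(hr60, 50, seed = 42)
  n <- length(rr3$values)
  expect_lt(abs(stats::sd(rr3$values) - 50), 3 * 50 / sqrt(2 * (n - 1)))

  bad <- time_series(channel("HR"), c(1000, 2000), c(60, -5))
  expect_error(generate_rr_series(bad, 0, seed = 1),
               class = "wf_validation_error")
})

test_that("cohorts are seed-deterministic and recover the episode rate", {
  cfg <- cohort_config(n_patients = 3, duration_hours = 6, seed = 77)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))

  cfg2 <- cohort_config(n_patients = 60, duration_hours = 24,
                        psh_prevalence = 1, episode_rate_per_hour = 0.2,
                        sample_period_ms = 600e3, seed = 78)
  co <- generate_cohort(cfg2)
  n_ep <- vapply(co$truth, length, integer(1))
  expect_lt(abs(mean(n_ep) - 4.8), 3 * sqrt(4.8 / 60))
  expect_length(co$streams, 60L)

  # non-carriers have empty truth; all truth intervals inside the span
  cfg3 <- cohort_config(n_patients = 20, psh_prevalence = 0.5,
                        duration_hours = 6, sample_period_ms = 600e3,
                        seed = 79)
  co3 <- generate_cohort(cfg3)
  carriers <- vapply(co3$profiles, `[[`, logical(1), "has_psh")
  expect_true(all(vapply(co3$truth[!carriers], length, integer(1)) == 0L))
  ti <- truth_intervals(co3)
  if (nrow(ti)) expect_true(all(ti$end_ms <= 6 * 3600e3 + 1e-6))
})

test_that("ground-truth plateau matches the configured effect exactly", {
  cfg <- flat_config(n_patients = 1, duration_hours = 6, psh_prevalence = 1,
                     seed = 80)
  p <- sample_profiles(cfg)[[1]]
  eff <- wardforge:::episode_effects(cfg$channel_defs)
  ep <- episode_spec(2 * 3600e3, 90, mult = eff$mult, add = eff$add,
                     ramp_min = 5)
  s <- render_clean_stream(p, list(ep), cfg, seed = 81)
  hr <- s$series$HR
  plateau <- hr$times >= ep$onset + 5 * 60e3 &
    hr$times <= ep$onset + 85 * 60e3
  expect_true(all(abs(hr$values[plateau] / 80 -
                        eff$mult[["HR"]]) < 1e-9))
})
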