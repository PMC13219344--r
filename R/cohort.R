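# Monte-Carlo virtual-patient simulator. Each patient gets per-channel
# Gaussian baselines drawn from population distributions, a circadian
# sinusoid, AR(1) physiologic variability, optional paroxysmal sympathetic
# hyperactivity (PSH) episodes -- trapezoidal surges in HR/BP/RR, additive in
# temperature -- and a corruption stage injecting motion artifacts, random
# missingness and proportional Gaussian sensor noise. Ground-truth episode
# intervals are retained so detection policies can be benchmarked.

# Population distributions of per-patient baseline means, within-patient
# AR(1) SD, circadian amplitude (fraction of the mean), physiologic clip
# bounds, and episode effect (multiplicative factor, or additive shift for
# temperature where a multiplicative degree-Celsius bump is not physiologic).
default_channel_defs <- function() {
  data.frame(
    channel   = c("HR",  "SBP", "DBP", "Temp", "RR",  "SpO2"),
    units     = c("bpm", "mmHg","mmHg","degC", "brpm","%"),
    mean_mean = c(82,    122,   74,    36.9,   17,    97),
    mean_sd   = c(12,    14,    9,     0.3,    3,     1.2),
    within_sd = c(3,     5,     4,     0.15,   1.2,   0.6),
    circ_frac = c(0.05,  0.04,  0.04,  0.008,  0.05,  0.002),
    lo        = c(30,    60,    30,    34,     5,     70),
    hi        = c(200,   220,   140,   41,     50,    100),
    effect    = c(1.70,  1.60,  1.35,  2.0,    1.80,  0.95),
    additive  = c(FALSE, FALSE, FALSE, TRUE,   FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Corruption stage configuration
#'
#' Defaults reproduce the simulated acquisition conditions: 5% random
#' missingness (missing completely at random, independent per sample), 10%
#' Gaussian noise (additive, SD = 10% of the channel's per-patient baseline
#' mean), and sparse motion-artifact spikes.
#'
#' @param noise_sd_frac additive noise SD as a fraction of the channel
#'   baseline mean.
#' @param missing_rate per-sample probability of a missing sample.
#' @param artifact_rate per-sample probability of an artifact spike (applied
#'   to non-missing samples).
#' @param artifact_magnitude_sd artifact displacement SD in multiples of the
#'   channel's within-patient SD.
#' @return An object of class `wf_corruption`.
#' @export
corruption_config <- function(noise_sd_frac = 0.10, missing_rate = 0.05,
                              artifact_rate = 0.002,
                              artifact_magnitude_sd = 8) {
  assert_scalar_number(noise_sd_frac, "noise_sd_frac", lo = 0)
  assert_scalar_number(missing_rate, "missing_rate", lo = 0, hi = 1)
  assert_scalar_number(artifact_rate, "artifact_rate", lo = 0, hi = 1)
  assert_scalar_number(artifact_magnitude_sd, "artifact_magnitude_sd", lo = 0)
  structure(list(noise_sd_frac = noise_sd_frac, missing_rate = missing_rate,
                 artifact_rate = artifact_rate,
                 artifact_magnitude_sd = artifact_magnitude_sd),
            class = "wf_corruption")
}

#' Cohort simulation configuration
#'
#' @param n_patients number of virtual patients.
#' @param psh_prevalence probability a patient carries PSH episodes.
#' @param duration_hours simulated span per patient.
#' @param sample_period_ms sampling period of the scalar vital channels.
#' @param corruption a [corruption_config()].
#' @param seed integer master seed; every per-patient stream is derived from
#'   it with [derive_seed()] so patient `k` is reproducible in isolation.
#' @param episode_rate_per_hour PSH episode onset rate (Poisson, per hour).
#' @param episode_duration_median_min median episode duration (log-normal).
#' @param episode_duration_sdlog log-SD of episode durations.
#' @param episode_ramp_min linear ramp up/down time of the trapezoidal
#'   episode shape, minutes.
#' @param ar1_phi lag-one autocorrelation of the within-patient physiologic
#'   variability (0 = white noise).
#' @param channel_defs channel definition table; see
#'   `wardforge:::default_channel_defs()` for the shipped defaults and column
#'   meanings. Override to change baselines or episode effect sizes.
#' @return An object of class `wf_cohort_config`.
#' @export
cohort_config <- function(n_patients = 500, psh_prevalence = 0.85,
                          duration_hours = 24, sample_period_ms = 60000,
                          corruption = corruption_config(), seed = 1L,
                          episode_rate_per_hour = 0.2,
                          episode_duration_median_min = 240,
                          episode_duration_sdlog = 0.4,
                          episode_ramp_min = 5, ar1_phi = 0.85,
                          channel_defs = default_channel_defs()) {
  assert_scalar_number(n_patients, "n_patients", lo = 1)
  assert_scalar_number(psh_prevalence, "psh_prevalence", lo = 0, hi = 1)
  assert_scalar_number(duration_hours, "duration_hours")
  if (duration_hours <= 0) stop_validation("duration_hours must be > 0")
  assert_scalar_number(sample_period_ms, "sample_period_ms", lo = 1)
  if (!inherits(corruption, "wf_corruption"))
    stop_validation("corruption must be a corruption_config()")
  assert_scalar_number(seed, "seed")
  assert_scalar_number(episode_rate_per_hour, "episode_rate_per_hour", lo = 0)
  assert_scalar_number(episode_duration_median_min,
                       "episode_duration_median_min", lo = 0.01)
  assert_scalar_number(episode_duration_sdlog, "episode_duration_sdlog",
                       lo = 0)
  assert_scalar_number(episode_ramp_min, "episode_ramp_min", lo = 0)
  assert_scalar_number(ar1_phi, "ar1_phi", lo = -0.999, hi = 0.999)
  need <- c("channel", "mean_mean", "mean_sd", "within_sd", "circ_frac",
            "lo", "hi", "effect", "additive")
  if (!all(need %in% names(channel_defs)))
    stop_validation("channel_defs must have columns: %s",
                    paste(need, collapse = ", "))
  if (any(channel_defs$mean_sd < 0) || any(channel_defs$within_sd < 0))
    stop_validation("channel SDs must be >= 0")
  structure(list(
    n_patients = as.integer(n_patients), psh_prevalence = psh_prevalence,
    duration_hours = duration_hours, sample_period_ms = sample_period_ms,
    corruption = corruption, seed = as.integer(seed),
    episode_rate_per_hour = episode_rate_per_hour,
    episode_duration_median_min = episode_duration_median_min,
    episode_duration_sdlog = episode_duration_sdlog,
    episode_ramp_min = episode_ramp_min, ar1_phi = ar1_phi,
    channel_defs = channel_defs
  ), class = "wf_cohort_config")
}

#' Specify one PSH episode
#'
#' Episodes are trapezoidal: a linear ramp to full effect, a plateau, and a
#' linear ramp back. Multiplicative factors must be >= 1 for the sympathetic
#' surge channels (HR, SBP, DBP, RR); SpO2 may dip (factor <= 1); temperature
#' uses an additive shift in degrees Celsius.
#'
#' @param onset_ms onset time, ms.
#' @param duration_min total duration, minutes (> 0).
#' @param mult named vector of multiplicative peak factors.
#' @param add named vector of additive peak shifts.
#' @param ramp_min ramp time, minutes.
#' @return An object of class `wf_episode`.
#' @export
episode_spec <- function(onset_ms, duration_min,
                         mult = c(HR = 1.7, SBP = 1.6, DBP = 1.35, RR = 1.8,
                                  SpO2 = 0.95),
                         add = c(Temp = 2.0), ramp_min = 5) {
  assert_scalar_number(onset_ms, "onset_ms")
  assert_scalar_number(duration_min, "duration_min")
  if (duration_min <= 0) stop_validation("episode duration must be > 0")
  surge <- intersect(names(mult), c("HR", "SBP", "DBP", "RR"))
  if (any(mult[surge] < 1))
    stop_validation("sympathetic surge factors (HR/SBP/DBP/RR) must be >= 1")
  structure(list(onset = onset_ms, duration_min = duration_min,
                 mult = mult, add = add, ramp_min = ramp_min),
            class = "wf_episode")
}

# Trapezoid in [0,1] over `times` for one episode.
episode_shape <- function(times, ep) {
  dur_ms <- ep$duration_min * 60000
  ramp_ms <- min(ep$ramp_min * 60000, dur_ms / 2)
  x <- times - ep$onset
  s <- numeric(length(times))
  inside <- x >= 0 & x <= dur_ms
  xi <- x[inside]
  up <- if (ramp_ms > 0) pmin(xi / ramp_ms, 1) else 1
  down <- if (ramp_ms > 0) pmin((dur_ms - xi) / ramp_ms, 1) else 1
  s[inside] <- pmin(up, down)
  s
}

#' Draw patient profiles for a cohort
#'
#' Per-patient baseline means are drawn from the population distributions in
#' `config$channel_defs` and clipped to the physiologic bounds (`lo`, `hi`);
#' PSH carrier status is Bernoulli with the configured prevalence; each
#' patient gets a uniform circadian phase.
#'
#' @param config a [cohort_config()].
#' @param seed optional override of `config$seed`.
#' @return List of `wf_profile` objects of length `config$n_patients`.
#' @export
sample_profiles <- function(config, seed = config$seed) {
  if (!inherits(config, "wf_cohort_config"))
    stop_validation("config must be a cohort_config()")
  lapply(seq_len(config$n_patients), function(k) {
    with_seed(derive_seed(seed, k, salt = 1L), {
      cd <- config$channel_defs
      mu <- rnorm(nrow(cd), cd$mean_mean, cd$mean_sd)
      mu <- pmin(pmax(mu, cd$lo), cd$hi)
      structure(list(
        patient_id = sprintf("P%04d", k),
        channels = data.frame(channel = cd$channel, units = cd$units,
                              mean = mu, sd = cd$within_sd,
                              circ_frac = cd$circ_frac,
                              stringsAsFactors = FALSE),
        circ_phase_ms = runif(1, 0, 24 * 3600e3),
        has_psh = runif(1) < config$psh_prevalence
      ), class = "wf_profile")
    })
  })
}

# Default episode effects from the channel definition table.
episode_effects <- function(channel_defs) {
  m <- channel_defs[!channel_defs$additive, ]
  a <- channel_defs[channel_defs$additive, ]
  list(mult = stats::setNames(m$effect, m$channel),
       add = stats::setNames(a$effect, a$channel))
}

# Draw the episode list for one PSH-positive patient: Poisson onsets,
# log-normal durations, truncated to the simulated span.
sample_episodes <- function(config, seed) {
  span_ms <- config$duration_hours * 3600e3
  eff <- episode_effects(config$channel_defs)
  with_seed(seed, {
    n_ep <- rpois(1, config$episode_rate_per_hour * config$duration_hours)
    if (n_ep == 0) return(list())
    onsets <- sort(runif(n_ep, 0, span_ms))
    durs <- rlnorm(n_ep, log(config$episode_duration_median_min),
                   config$episode_duration_sdlog)
    lapply(seq_len(n_ep), function(i) {
      dur <- min(durs[i], (span_ms - onsets[i]) / 60000)
      dur <- max(dur, 1)
      episode_spec(onsets[i], dur, mult = eff$mult, add = eff$add,
                   ramp_min = config$episode_ramp_min)
    })
  })
}

#' Render a clean (pre-corruption) patient stream
#'
#' Each channel is baseline mean x (1 + circadian sinusoid) + AR(1)
#' physiologic variability, then episode effects are applied: multiplicative
#' channels are scaled by `1 + (factor - 1) * shape(t)`, additive channels
#' shifted by `shift * shape(t)`, with `shape` the trapezoidal episode
#' envelope. Overlapping episodes combine by the per-sample maximum effect.
#' Deterministic given `(profile, episodes, seed)`.
#'
#' @param profile a `wf_profile` from [sample_profiles()].
#' @param episodes list of [episode_spec()].
#' @param config a [cohort_config()].
#' @param seed RNG seed for the AR(1) innovations.
#' @return A [unified_stream()] with quality all `"ok"`.
#' @export
render_clean_stream <- function(profile, episodes, config, seed) {
  span_ms <- config$duration_hours * 3600e3
  times <- seq(config$sample_period_ms, span_ms, by = config$sample_period_ms)
  n <- length(times)
  ch <- profile$channels
  series <- with_seed(seed, {
    lapply(seq_len(nrow(ch)), function(i) {
      circ <- ch$circ_frac[i] *
        sin(2 * pi * (times - profile$circ_phase_ms) / (24 * 3600e3))
      base <- ch$mean[i] * (1 + circ)
      if (ch$sd[i] > 0 && abs(config$ar1_phi) > 0) {
        innov_sd <- ch$sd[i] * sqrt(1 - config$ar1_phi^2)
        e <- rnorm(n, 0, innov_sd)
        ar <- as.numeric(stats::filter(e, config$ar1_phi,
                                       method = "recursive",
                                       init = rnorm(1, 0, ch$sd[i])))
      } else if (ch$sd[i] > 0) {
        ar <- rnorm(n, 0, ch$sd[i])
      } else {
        ar <- numeric(n)
      }
      v <- base + ar
      name <- ch$channel[i]
      if (length(episodes)) {
        # overlapping episodes merge by per-sample maximum effect
        mult_eff <- Reduce(pmax, lapply(episodes, function(ep) {
          if (!name %in% names(ep$mult)) return(numeric(length(times)))
          (ep$mult[[name]] - 1) * episode_shape(times, ep)
        }))
        add_eff <- Reduce(pmax, lapply(episodes, function(ep) {
          if (!name %in% names(ep$add)) return(numeric(length(times)))
          ep$add[[name]] * episode_shape(times, ep)
        }))
        # SpO2-style dips (factor < 1) merge toward the deepest dip
        dip_eff <- Reduce(pmin, lapply(episodes, function(ep) {
          if (!name %in% names(ep$mult)) return(numeric(length(times)))
          pmin((ep$mult[[name]] - 1), 0) * episode_shape(times, ep)
        }))
        v <- v * (1 + ifelse(mult_eff > 0, mult_eff, dip_eff)) + add_eff
      }
      if (name == "SpO2") v <- pmin(v, 100)
      time_series(channel(name, "scalar", units = ch$units[i],
                          nominal_rate = 1000 / config$sample_period_ms),
                  times, v)
    })
  })
  unified_stream(profile$patient_id, series,
                 metadata = c(has_psh = as.character(profile$has_psh)))
}

#' Corrupt a stream with missingness, artifacts and sensor noise
#'
#' Independently per sample: with `missing_rate` the sample becomes missing
#' (value `NA`, quality `"missing"`); among the rest, with `artifact_rate`
#' the value is displaced by `N(0, artifact_magnitude_sd * channel SD)` and
#' flagged `"artifact"`; all remaining samples receive additive
#' `N(0, (noise_sd_frac * baseline mean)^2)` noise. No clean copy is kept;
#' the clean stream is recoverable only by re-rendering from the same seed.
#'
#' @param stream a [unified_stream()].
#' @param corruption a [corruption_config()].
#' @param seed RNG seed.
#' @param profile optional `wf_profile` supplying the channel baseline mean
#'   and SD; if absent they are estimated from the stream itself.
#' @return The corrupted [unified_stream()].
#' @export
corrupt_stream <- function(stream, corruption, seed, profile = NULL) {
  if (!inherits(corruption, "wf_corruption"))
    stop_validation("corruption must be a corruption_config()")
  series <- with_seed(seed, {
    lapply(stream$series, function(ts) {
      name <- ts$channel$name
      if (!is.null(profile) && name %in% profile$channels$channel) {
        row <- profile$channels[profile$channels$channel == name, ]
        base_mean <- row$mean; ch_sd <- row$sd
      } else {
        base_mean <- mean(ts$values, na.rm = TRUE)
        ch_sd <- stats::sd(ts$values, na.rm = TRUE)
        if (is.na(ch_sd)) ch_sd <- 0
      }
      n <- length(ts$times)
      v <- ts$values; q <- ts$quality
      miss <- runif(n) < corruption$missing_rate
      art <- !miss & runif(n) < corruption$artifact_rate
      noise_sd <- corruption$noise_sd_frac * base_mean
      art_sd <- corruption$artifact_magnitude_sd *
        (if (ch_sd > 0) ch_sd else noise_sd)
      plain <- !miss & !art
      # draw per-category so a zero-rate stage leaves the stream untouched
      if (any(art)) v[art] <- v[art] + rnorm(sum(art), 0, art_sd)
      if (noise_sd > 0 && any(plain))
        v[plain] <- v[plain] + rnorm(sum(plain), 0, noise_sd)
      v[miss] <- NA_real_
      q[miss] <- "missing"; q[art] <- "artifact"
      time_series(ts$channel, ts$times, v, q)
    })
  })
  unified_stream(stream$patient_id, series, metadata = stream$metadata)
}

#' Derive an event-based R-R interval series from a heart-rate channel
#'
#' Beats are placed sequentially: each interval has local mean `60000 /
#' HR(t)` ms (stepwise-interpolated from the ok samples of `hr_series`) plus
#' Gaussian jitter with SD `hrv_sdnn_ms`, floored at 200 ms. Tachycardia
#' during an episode therefore shortens the generated intervals.
#'
#' @param hr_series a heart-rate [time_series()] in bpm, all values > 0.
#' @param hrv_sdnn_ms beat-to-beat jitter SD, ms (the SDNN the series should
#'   exhibit).
#' @param seed RNG seed.
#' @return An event-based [time_series()] named `RR_int` (ms); each sample's
#'   time is the beat time at the end of its interval.
#' @export
generate_rr_series <- function(hr_series, hrv_sdnn_ms, seed) {
  oi <- ok_idx(hr_series)
  if (!length(oi)) stop_validation("hr_series has no usable samples")
  hv <- hr_series$values[oi]; ht <- hr_series$times[oi]
  if (any(hv <= 0)) stop_validation("heart rate must be positive")
  assert_scalar_number(hrv_sdnn_ms, "hrv_sdnn_ms", lo = 0)
  t_end <- ht[length(ht)]
  with_seed(seed, {
    # pre-draw jitter in blocks; sequential placement, vector growth amortized
    times <- numeric(0); vals <- numeric(0)
    t <- ht[1]
    est_n <- ceiling((t_end - ht[1]) / (60000 / max(hv)) ) + 16L
    jit <- if (hrv_sdnn_ms > 0) rnorm(est_n, 0, hrv_sdnn_ms) else numeric(est_n)
    times <- numeric(est_n); vals <- numeric(est_n)
    i <- 0L
    while (t < t_end) {
      hr_now <- stats::approx(ht, hv, xout = t, method = "constant",
                              rule = 2)$y
      iv <- max(60000 / hr_now + (if (i < est_n) jit[i + 1L] else
        rnorm(1, 0, hrv_sdnn_ms)), 200)
      t <- t + iv
      if (t >= t_end) break
      i <- i + 1L
      if (i > length(times)) { length(times) <- 2L * i; length(vals) <- 2L * i }
      times[i] <- t; vals[i] <- iv
    }
    time_series(channel("RR_int", "time_series", units = "ms"),
                times[seq_len(i)], vals[seq_len(i)])
  })
}

#' Generate a labeled virtual-patient cohort
#'
#' Composes [sample_profiles()], per-patient episode sampling (Poisson
#' onsets, log-normal durations), [render_clean_stream()] and
#' [corrupt_stream()]. Fully reproducible from `config$seed`; patient `k`'s
#' stream depends only on `(config, k)`.
#'
#' @param config a [cohort_config()].
#' @return An object of class `wf_cohort`: `streams` (list of
#'   [unified_stream()]), `truth` (named list of episode lists), `profiles`,
#'   and the `config` echo.
#' @export
generate_cohort <- function(config) {
  profiles <- sample_profiles(config)
  streams <- vector("list", config$n_patients)
  truth <- vector("list", config$n_patients)
  for (k in seq_len(config$n_patients)) {
    p <- profiles[[k]]
    eps <- if (p$has_psh) sample_episodes(config, derive_seed(config$seed, k,
                                                              salt = 2L))
           else list()
    clean <- render_clean_stream(p, eps, config,
                                 derive_seed(config$seed, k, salt = 3L))
    streams[[k]] <- corrupt_stream(clean, config$corruption,
                                   derive_seed(config$seed, k, salt = 4L),
                                   profile = p)
    truth[[k]] <- eps
  }
  names(streams) <- names(truth) <-
    vapply(profiles, function(p) p$patient_id, character(1))
  structure(list(streams = streams, truth = truth, profiles = profiles,
                 config = config),
            class = "wf_cohort")
}

#' @export
print.wf_cohort <- function(x, ...) {
  n_ep <- sum(vapply(x$truth, length, integer(1)))
  cat(sprintf(
    "<wf_cohort> %d patients, %g h at %g s sampling, %d truth episodes\n",
    length(x$streams), x$config$duration_hours,
    x$config$sample_period_ms / 1000, n_ep))
  invisible(x)
}

#' Tabulate ground-truth episode intervals
#'
#' @param cohort a `wf_cohort`.
#' @return data.frame with `patient_id`, `onset_ms`, `end_ms`,
#'   `duration_min`.
#' @export
truth_intervals <- function(cohort) {
  rows <- lapply(names(cohort$truth), function(pid) {
    eps <- cohort$truth[[pid]]
    if (!length(eps)) return(NULL)
    data.frame(patient_id = pid,
               onset_ms = vapply(eps, function(e) e$onset, 0),
               end_ms = vapply(eps, function(e) e$onset +
                                 e$duration_min * 60000, 0),
               duration_min = vapply(eps, function(e) e$duration_min, 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(patient_id = character(),
                                      onset_ms = numeric(),
                                      end_ms = numeric(),
                                      duration_min = numeric())
  out
}

#' Export a cohort to plain-text files
#'
#' Writes one long-format stream CSV per patient plus `truth.json` (episode
#' intervals) and `cohort_config.json`.
#'
#' @param cohort a `wf_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pid in names(cohort$streams))
    write_stream(cohort$streams[[pid]], file.path(dir, paste0(pid, ".csv")))
  jsonlite::write_json(truth_intervals(cohort), file.path(dir, "truth.json"),
                       digits = NA)
  cfg <- cohort$config
  cfg$corruption <- unclass(cfg$corruption)
  jsonlite::write_json(unclass(cfg), file.path(dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
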