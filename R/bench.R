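# Validation harness: three assessment policies are replayed over labeled
# simulated cohorts and scored per assessment window against ground truth.
#   A ("manual"):   4-hourly spot checks, manual observation noise, static
#                   banded scale -- level-0 automation, emulated in silico.
#   B ("auto-calc"): hourly spot checks from sensor-quality samples, the
#                   same static scale -- level-1 automation.
#   C ("complex"):  continuous 30-min windows through the feature pipeline
#                   and the reference recurrent model -- level-2 automation.
# Metrics are aggregated over independent simulation runs with percentile
# bootstrap CIs and paired Wilcoxon signed-rank tests on per-run F1.

#' Spot-check scale for the PSH comparators
#'
#' Numeric-band transcription of the heart-rate, respiratory-rate and
#' systolic-BP components of the PSH Clinical Feature Scale (each 0-3
#' points) as a [static_score_spec()], so the manual and auto-calculation
#' policies score spot measurements the way the bedside scale bands them.
#' Temperature is deliberately absent: at the simulated sensor-noise scale
#' (SD = 10% of the baseline mean, i.e. several degrees Celsius) a
#' single-sample temperature band carries no signal, so a spot-check policy
#' that used it would be dominated by sensor noise rather than assessment
#' policy -- the quantity the benchmark compares.
#'
#' @return A [static_score_spec()].
#' @export
psh_spot_score_spec <- function() {
  bands <- function(cuts, pts) {
    data.frame(lo = c(-Inf, cuts), hi = c(cuts, Inf), points = pts)
  }
  static_score_spec(list(
    list(input = "HR", weight = 1,
         bands = bands(c(100, 120, 140), c(0, 1, 2, 3))),
    list(input = "RR", weight = 1,
         bands = bands(c(18, 24, 30), c(0, 1, 2, 3))),
    list(input = "SBP", weight = 1,
         bands = bands(c(140, 160, 180), c(0, 1, 2, 3)))
  ))
}

#' Specify an assessment comparator
#'
#' @param level `"A_manual"`, `"B_autocalc"`, `"C_complex"`, or the test
#'   stubs `"oracle"` (reads the truth labels) and `"random"` (Bernoulli
#'   decisions at `guess_rate`).
#' @param period_ms spot-check period for A/B (window width = period).
#' @param obs_noise_frac manual measurement noise SD as a fraction of the
#'   value (A only).
#' @param score_spec static scale for A/B; defaults to
#'   [psh_spot_score_spec()].
#' @param score_threshold alarm when the scale total reaches this value.
#' @param handle [predictor_handle()] for C.
#' @param width_ms,step_ms evaluation window geometry for C.
#' @param prob_threshold decision threshold on the model probability for C;
#'   defaults to the threshold stored in the handle (chosen on the training
#'   folds).
#' @param sample_tolerance_ms how far a spot check may reach for the
#'   nearest usable sensor sample.
#' @param guess_rate positive rate of the `"random"` stub.
#' @return An object of class `wf_comparator`.
#' @export
comparator_spec <- function(level = c("A_manual", "B_autocalc", "C_complex",
                                      "oracle", "random"),
                            period_ms = NULL, obs_noise_frac = NULL,
                            score_spec = psh_spot_score_spec(),
                            score_threshold = 4,
                            handle = NULL, width_ms = 1800e3,
                            step_ms = 1800e3, prob_threshold = NULL,
                            sample_tolerance_ms = 300e3, guess_rate = 0.5) {
  level <- match.arg(level)
  period_ms <- period_ms %||%
    switch(level, A_manual = 4 * 3600e3, B_autocalc = 3600e3, 3600e3)
  if (period_ms <= 0) stop_validation("spot-check period must be > 0")
  obs_noise_frac <- obs_noise_frac %||%
    (if (level == "A_manual") 0.05 else 0)
  structure(list(level = level, period_ms = period_ms,
                 obs_noise_frac = obs_noise_frac, score_spec = score_spec,
                 score_threshold = score_threshold, handle = handle,
                 width_ms = width_ms, step_ms = step_ms,
                 prob_threshold = prob_threshold,
                 sample_tolerance_ms = sample_tolerance_ms,
                 guess_rate = guess_rate),
            class = "wf_comparator")
}

# Nearest usable sample of one channel at each spot time, NA when none is
# within tolerance.
spot_values <- function(ts, spot_t, tolerance_ms) {
  oi <- ok_idx(ts)
  if (!length(oi)) return(rep(NA_real_, length(spot_t)))
  idx <- nearest_index(spot_t, ts$times[oi])
  ok <- abs(ts$times[oi][idx] - spot_t) <= tolerance_ms
  ifelse(ok, ts$values[oi][idx], NA_real_)
}

confusion_counts <- function(decision, label) {
  c(tp = sum(decision & label), fp = sum(decision & !label),
    tn = sum(!decision & !label), fn = sum(!decision & label))
}

#' Replay one comparator over a labeled cohort
#'
#' Decisions are made at the comparator's assessment epochs (spot times for
#' A/B, every evaluation window for C) and each assessment window is scored
#' against the ground-truth episode labels (50%-overlap rule). Windows where
#' a spot check finds no usable sample are reported separately and excluded
#' from the confusion counts.
#'
#' @param cohort a [generate_cohort()] result.
#' @param spec a [comparator_spec()].
#' @param seed RNG seed for the manual observation noise / random stub.
#' @return List: `decisions` (per-window data.frame), `confusion` (tp, fp,
#'   tn, fn), `n_unassessed`.
#' @export
run_comparator <- function(cohort, spec, seed = cohort$config$seed) {
  if (!inherits(spec, "wf_comparator")) stop_validation("not a wf_comparator")
  if (spec$level == "C_complex" && is.null(spec$handle))
    stop_config("C_complex comparator needs a trained model handle")
  span_ms <- cohort$config$duration_hours * 3600e3
  rows <- list()
  for (k in seq_along(cohort$streams)) {
    stream <- cohort$streams[[k]]
    pid <- names(cohort$streams)[k]
    truth <- cohort$truth[[pid]]
    if (spec$level %in% c("A_manual", "B_autocalc", "oracle", "random")) {
      spot_t <- seq(spec$period_ms, span_ms, by = spec$period_ms)
      label <- label_windows(spot_t, spec$period_ms, truth)
      if (spec$level == "oracle") {
        decision <- label
      } else if (spec$level == "random") {
        decision <- with_seed(derive_seed(seed, k, salt = 22L),
                              runif(length(spot_t)) < spec$guess_rate)
      } else {
        comps <- vapply(spec$score_spec$components, `[[`, character(1),
                        "input")
        vals <- vapply(comps, function(ch)
          spot_values(get_channel(stream, ch), spot_t,
                      spec$sample_tolerance_ms), numeric(length(spot_t)))
        vals <- matrix(vals, nrow = length(spot_t),
                       dimnames = list(NULL, comps))
        if (spec$obs_noise_frac > 0) {
          vals <- with_seed(derive_seed(seed, k, salt = 21L),
                            vals + matrix(rnorm(length(vals), 0,
                                                spec$obs_noise_frac *
                                                  abs(c(vals))),
                                          nrow = nrow(vals)))
        }
        score <- vapply(seq_along(spot_t), function(i)
          as.numeric(static_score(as.list(vals[i, ]), spec$score_spec)),
          numeric(1))
        decision <- ifelse(is.na(score), NA, score >= spec$score_threshold)
      }
      rows[[pid]] <- data.frame(patient_id = pid, t = spot_t,
                                decision = decision, label = label)
    } else {
      feats <- windowed_features(stream, spec$handle$input_channels,
                                 spec$width_ms, spec$step_ms,
                                 spec$handle$seq_len)
      p <- predict(spec$handle, feats$X)
      th <- spec$prob_threshold %||% spec$handle$threshold
      if (is.na(th)) th <- 0.5
      label <- label_windows(feats$t_end, spec$width_ms, truth)
      rows[[pid]] <- data.frame(patient_id = pid, t = feats$t_end,
                                decision = p >= th, label = label,
                                prob = p)
    }
  }
  dec <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  assessed <- !is.na(dec$decision)
  list(decisions = dec,
       confusion = confusion_counts(dec$decision[assessed],
                                    dec$label[assessed]),
       n_unassessed = sum(!assessed))
}

metric_row <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  c(accuracy = if (n > 0) (tp + tn) / n else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_)
}

#' Aggregate per-run confusion counts into a metrics table
#'
#' Computes accuracy, sensitivity, specificity and F1 per run, their means
#' across runs, percentile bootstrap 95% CIs (resampling runs), and paired
#' Wilcoxon signed-rank tests on per-run F1 between every comparator pair.
#' Runs where a metric's denominator is zero are excluded from that metric
#' with the exclusion count reported.
#'
#' @param confusions data.frame with columns `comparator`, `run`, `tp`,
#'   `fp`, `tn`, `fn` (one row per comparator per run; >= 2 runs).
#' @param bootstrap_reps bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `wf_metrics`: `table` (comparator, metric,
#'   mean, ci_lo, ci_hi, n_runs, n_excluded), `per_run`, `pairwise_p` (F1
#'   Wilcoxon matrix).
#' @export
compute_metrics <- function(confusions, bootstrap_reps = 1000, seed = 1L) {
  need <- c("comparator", "run", "tp", "fp", "tn", "fn")
  if (!all(need %in% names(confusions)))
    stop_validation("confusions needs columns: %s", paste(need, collapse = ", "))
  if (length(unique(confusions$run)) < 2L)
    stop_validation("need >= 2 runs for confidence intervals")
  per_run <- do.call(rbind, lapply(seq_len(nrow(confusions)), function(i) {
    m <- metric_row(confusions$tp[i], confusions$fp[i], confusions$tn[i],
                    confusions$fn[i])
    data.frame(comparator = confusions$comparator[i], run = confusions$run[i],
               metric = names(m), value = as.numeric(m),
               stringsAsFactors = FALSE)
  }))
  comparators <- unique(confusions$comparator)
  table <- do.call(rbind, lapply(comparators, function(cmp) {
    do.call(rbind, lapply(unique(per_run$metric), function(met) {
      v <- per_run$value[per_run$comparator == cmp & per_run$metric == met]
      ok <- !is.na(v)
      ci <- with_seed(derive_seed(seed, match(cmp, comparators),
                                  salt = match(met, unique(per_run$metric))), {
        if (sum(ok) >= 2) {
          bs <- vapply(seq_len(bootstrap_reps), function(b)
            mean(sample(v[ok], sum(ok), replace = TRUE)), numeric(1))
          stats::quantile(bs, c(0.025, 0.975), names = FALSE)
        } else c(NA_real_, NA_real_)
      })
      data.frame(comparator = cmp, metric = met,
                 mean = if (any(ok)) mean(v[ok]) else NA_real_,
                 ci_lo = ci[1], ci_hi = ci[2],
                 n_runs = sum(ok), n_excluded = sum(!ok),
                 stringsAsFactors = FALSE)
    }))
  }))
  pw <- matrix(NA_real_, length(comparators), length(comparators),
               dimnames = list(comparators, comparators))
  if (length(comparators) > 1) {
    runs <- sort(unique(per_run$run))
    f1 <- sapply(comparators, function(cmp)
      per_run$value[per_run$comparator == cmp & per_run$metric == "f1"
                    ][order(per_run$run[per_run$comparator == cmp &
                                          per_run$metric == "f1"])])
    for (a in seq_along(comparators))
      for (b in seq_along(comparators))
        if (a < b) {
          ok <- !is.na(f1[, a]) & !is.na(f1[, b])
          if (sum(ok) >= 2 && any(f1[ok, a] != f1[ok, b]))
            pw[a, b] <- pw[b, a] <-
              suppressWarnings(stats::wilcox.test(f1[ok, a], f1[ok, b],
                                                  paired = TRUE)$p.value)
        }
  }
  structure(list(table = table, per_run = per_run, pairwise_p = pw),
            class = "wf_metrics")
}

#' @export
print.wf_metrics <- function(x, digits = 4, ...) {
  cat("<wf_metrics>\n")
  t <- x$table
  t$mean <- round(t$mean, digits)
  t$ci_lo <- round(t$ci_lo, digits)
  t$ci_hi <- round(t$ci_hi, digits)
  print.data.frame(t, row.names = FALSE)
  if (any(!is.na(x$pairwise_p))) {
    cat("pairwise Wilcoxon (per-run F1) p-values:\n")
    print(signif(x$pairwise_p, 3))
  }
  invisible(x)
}

#' Experiment configuration
#'
#' @param cohort a [cohort_config()] describing each evaluation run's
#'   cohort; run `r` uses seed `seed + r`.
#' @param n_runs independent simulation runs.
#' @param bootstrap_reps bootstrap replicates for the CIs.
#' @param comparators named list of [comparator_spec()]s.
#' @param train_cfg a [reference_train_config()] used to train the
#'   reference model once (on a training cohort drawn with a seed disjoint
#'   from every evaluation run) when a `C_complex` comparator has no handle.
#' @param seed base seed.
#' @return An object of class `wf_experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(n_patients = 100),
                              n_runs = 100, bootstrap_reps = 1000,
                              comparators = list(
                                A_manual = comparator_spec("A_manual"),
                                B_autocalc = comparator_spec("B_autocalc"),
                                C_complex = comparator_spec("C_complex")),
                              train_cfg = reference_train_config(),
                              seed = 1L) {
  if (n_runs < 2) stop_validation("n_runs must be >= 2 for CIs")
  structure(list(cohort = cohort, n_runs = as.integer(n_runs),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 comparators = comparators, train_cfg = train_cfg,
                 seed = as.integer(seed)),
            class = "wf_experiment_config")
}

#' Run the comparator experiment
#'
#' Trains the reference model once (when needed), then for each run draws a
#' fresh cohort with seed `base seed + run index`, replays every comparator,
#' and aggregates the per-run confusion counts with [compute_metrics()].
#' Fully reproducible from the base seed.
#'
#' @param config an [experiment_config()].
#' @param progress print a line per run.
#' @return An object of class `wf_experiment`: `metrics` (a `wf_metrics`),
#'   `confusions`, `handle` (trained model, if any), `runtimes_s`
#'   (informative wall times per stage), `config`.
#' @export
run_experiment <- function(config, progress = FALSE) {
  if (!inherits(config, "wf_experiment_config"))
    stop_validation("not an experiment_config()")
  runtimes <- c()
  handle <- NULL
  needs_model <- any(vapply(config$comparators, function(s)
    s$level == "C_complex" && is.null(s$handle), logical(1)))
  if (needs_model) {
    t0 <- proc.time()[3]
    train_cohort_cfg <- config$cohort
    train_cohort_cfg$seed <- derive_seed(config$seed, 0L, salt = 30L)
    tc <- generate_cohort(train_cohort_cfg)
    tcfg <- config$train_cfg
    tcfg$seed <- derive_seed(config$seed, 0L, salt = 31L)
    handle <- train_reference_model(tc, tcfg)
    runtimes["train"] <- proc.time()[3] - t0
  }
  comps <- lapply(config$comparators, function(s) {
    if (s$level == "C_complex" && is.null(s$handle)) s$handle <- handle
    s
  })
  conf <- list()
  t0 <- proc.time()[3]
  for (r in seq_len(config$n_runs)) {
    run_cfg <- config$cohort
    run_cfg$seed <- config$seed + r
    cohort <- generate_cohort(run_cfg)
    for (nm in names(comps)) {
      res <- run_comparator(cohort, comps[[nm]],
                            seed = derive_seed(config$seed, r, salt = 40L))
      conf[[length(conf) + 1L]] <- data.frame(
        comparator = nm, run = r, tp = res$confusion["tp"],
        fp = res$confusion["fp"], tn = res$confusion["tn"],
        fn = res$confusion["fn"], n_unassessed = res$n_unassessed,
        stringsAsFactors = FALSE)
    }
    if (progress)
      message(sprintf("run %d/%d done (%.1f s)", r, config$n_runs,
                      proc.time()[3] - t0))
  }
  runtimes["runs"] <- proc.time()[3] - t0
  confusions <- do.call(rbind, c(conf, list(make.row.names = FALSE)))
  metrics <- compute_metrics(confusions, config$bootstrap_reps,
                             seed = derive_seed(config$seed, 1L, salt = 41L))
  structure(list(metrics = metrics, confusions = confusions, handle = handle,
                 runtimes_s = runtimes, config = config),
            class = "wf_experiment")
}

#' @export
print.wf_experiment <- function(x, ...) {
  cat(sprintf("<wf_experiment> %d run(s) x %d patients\n", x$config$n_runs,
              x$config$cohort$n_patients))
  print(x$metrics)
  invisible(x)
}

#' Export experiment outputs
#'
#' Writes `metrics.csv` (comparator, metric, mean, ci_lo, ci_hi, n_runs),
#' `confusions.csv`, `report.md` and `config_echo.json`.
#'
#' @param experiment a [run_experiment()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(experiment$metrics$table, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(experiment$confusions, file.path(dir, "confusions.csv"),
                   row.names = FALSE)
  cfg <- experiment$config
  echo <- list(n_runs = cfg$n_runs, n_patients = cfg$cohort$n_patients,
               duration_hours = cfg$cohort$duration_hours,
               seed = cfg$seed,
               comparators = names(cfg$comparators))
  jsonlite::write_json(echo, file.path(dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA)
  t <- experiment$metrics$table
  lines <- c("# Comparator benchmark", "",
             sprintf("%d runs x %d patients, base seed %d.", cfg$n_runs,
                     cfg$cohort$n_patients, cfg$seed), "",
             "| comparator | metric | mean | 95% CI |",
             "|---|---|---|---|",
             sprintf("| %s | %s | %.4f | [%.4f, %.4f] |", t$comparator,
                     t$metric, t$mean, t$ci_lo, t$ci_hi))
  writeLines(lines, file.path(dir, "report.md"))
  invisible(dir)
}

#' Indicator-throughput sweep over pipeline width
#'
#' Builds pipelines with increasing numbers of independent trend patterns
#' over duplicated vital channels, runs each over one simulated patient and
#' reports indicator counts and wall time. Wall times are informative only.
#'
#' @param config a [cohort_config()] (one patient is simulated from it).
#' @param variable_counts channel counts to sweep.
#' @return data.frame with one row per count: `n_channels`, `n_patterns`,
#'   `n_indicators`, `outputs_complete`, `wall_s`.
#' @export
complexity_sweep <- function(config = cohort_config(n_patients = 1),
                             variable_counts = c(2, 4, 8)) {
  cfg <- config
  cfg$n_patients <- 1L
  cohort <- generate_cohort(cfg)
  stream <- cohort$streams[[1]]
  base_ch <- names(stream$series)
  rows <- lapply(variable_counts, function(k) {
    chans <- character(k)
    for (i in seq_len(k)) {
      src <- stream$series[[base_ch[(i - 1) %% length(base_ch) + 1]]]
      nm <- sprintf("V%02d", i)
      chans[i] <- nm
      stream$series[[nm]] <- time_series(channel(nm, "scalar"), src$times,
                                         src$values, src$quality)
    }
    pats <- lapply(chans, function(ch) sprintf(
      "  - id: trend_%s\n    category: trend_delta\n    inputs: [%s]\n    params: {mode: slope, window_ms: 1800000}\n    output: slope_%s",
      ch, ch, ch))
    cfgtxt <- paste0("patterns:\n", paste(unlist(pats), collapse = "\n"))
    pl <- parse_pipeline(cfgtxt)
    t0 <- proc.time()[3]
    out <- run_pipeline(pl, stream)
    wall <- proc.time()[3] - t0
    data.frame(n_channels = k, n_patterns = k, n_indicators = length(out),
               outputs_complete = all(vapply(out, nrow, integer(1)) > 0),
               wall_s = wall)
  })
  do.call(rbind, rows)
}
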