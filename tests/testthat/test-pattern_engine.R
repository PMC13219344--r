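# Constructor kernel: config parsing and DAG assembly, the four pattern
# categories against closed-form oracles, and the reconfigurability
# invariant.

two_pattern_cfg <- "
patterns:
  - id: logic
    category: scalar_logic
    inputs: [sbp_drop]
    params: {rule: 'sbp_drop < -0.2', tolerance_ms: 900000}
    output: decomp
  - id: trend
    category: trend_delta
    inputs: [SBP]
    params: {mode: relative_change, window_ms: 900000}
    output: sbp_drop
"

test_that("pipeline parsing fixes a valid topological order", {
  pl <- parse_pipeline(two_pattern_cfg)
  expect_s3_class(pl, "wf_pipeline")
  expect_equal(pl$order, c("trend", "logic"))

  self_loop <- "
patterns:
  - id: a
    category: trend_delta
    inputs: [x]
    params: {mode: slope, window_ms: 60000}
    output: x
"
  expect_error(parse_pipeline(self_loop), "cycle", class = "wf_config_error")
  expect_error(parse_pipeline("patterns:\n  - id: a\n    category: wavelets\n    inputs: [x]\n    output: y\n"),
               "unknown category", class = "wf_config_error")
  expect_error(parse_pipeline("patterns:\n  - id: a\n    category: trend_delta\n    inputs: [x]\n    output: y\n"),
               "missing required", class = "wf_config_error")
  # modality mismatch caught when channels are declared
  mismatch <- "
channels: {ecg: time_series}
patterns:
  - id: a
    category: trend_delta
    inputs: [ecg]
    params: {mode: slope, window_ms: 60000}
    output: y
"
  expect_error(parse_pipeline(mismatch), "waveform",
               class = "wf_config_error")
})

test_that("engine order is a valid topological order on random DAGs", {
  set.seed(19)
  for (rep in 1:15) {
    k <- sample(3:8, 1)
    # pattern i may consume outputs of patterns with smaller index
    pats <- lapply(seq_len(k), function(i) {
      src <- if (i == 1 || runif(1) < 0.3) "HR"
             else sprintf("out%02d", sample(i - 1, 1))
      sprintf("  - id: p%02d\n    category: trend_delta\n    inputs: [%s]\n    params: {mode: slope, window_ms: 60000}\n    output: out%02d",
              i, src, i)
    })
    # shuffle declaration order
    txt <- paste0("patterns:\n",
                  paste(unlist(pats)[sample(k)], collapse = "\n"))
    pl <- parse_pipeline(txt)
    pos <- stats::setNames(seq_along(pl$order), pl$order)
    for (p in pl$patterns) {
      for (inp in p$inputs) {
        if (grepl("^out", inp)) {
          producer <- sprintf("p%s", sub("out", "", inp))
          expect_lt(pos[[producer]], pos[[p$id]])
        }
      }
    }
  }
})

test_that("scalar logic reproduces the sepsis-alert rule semantics", {
  fr <- structure(data.frame(t_ref = c(1, 2, 3), complete = TRUE,
                             Temp = c(38.5, 38.5, 37.0),
                             HR = c(105, 100, 120)),
                  class = c("wf_syncframes", "data.frame"))
  out <- scalar_logic(fr, "Temp > 38 AND HR > 100")
  expect_equal(out$value, c(TRUE, FALSE, FALSE)) # strict inequality at 100
  expect_error(scalar_logic(fr, "Temp > 38 AND WBC > 12"),
               class = "wf_config_error")
  expect_error(parse_rule("Temp > 38 AND system('ls')"),
               class = "wf_parse_error")
  expect_error(parse_rule("Temp >> 38"), class = "wf_parse_error")
})

test_that("random rules agree with direct expression-tree evaluation", {
  set.seed(23)
  vars <- c("HR", "Temp", "RR")
  gen_expr <- function(depth) {
    if (depth <= 0 || runif(1) < 0.4) {
      v <- sample(vars, 1)
      op <- sample(c(">", "<", ">=", "<=", "==", "!="), 1)
      thr <- round(runif(1, 0, 120), 1)
      list(kind = "cmp", var = v, op = op, thr = thr,
           text = sprintf("%s %s %s", v, op, thr))
    } else if (runif(1) < 0.25) {
      a <- gen_expr(depth - 1)
      list(kind = "not", a = a, text = sprintf("NOT (%s)", a$text))
    } else {
      a <- gen_expr(depth - 1); b <- gen_expr(depth - 1)
      op <- sample(c("AND", "OR"), 1)
      list(kind = tolower(op), a = a, b = b,
           text = sprintf("(%s) %s (%s)", a$text, op, b$text))
    }
  }
  eval_tree <- function(e, env) {
    switch(e$kind,
      cmp = get(e$op)(env[[e$var]], e$thr),
      not = !eval_tree(e$a, env),
      and = eval_tree(e$a, env) && eval_tree(e$b, env),
      or = eval_tree(e$a, env) || eval_tree(e$b, env))
  }
  for (rep in 1:40) {
    tree <- gen_expr(3)
    rule <- parse_rule(tree$text)
    env <- list(HR = runif(1, 0, 150), Temp = runif(1, 34, 41),
                RR = runif(1, 5, 40))
    expect_equal(wardforge:::eval_rule(rule, env), eval_tree(tree, env),
                 info = tree$text)
  }
})

test_that("trend patterns match hand arithmetic and regression closed form", {
  # systolic 120 -> 94 over 15 min: relative change -26/120, alarm on >20% drop
  ts <- time_series(channel("SBP"), c(0, 15 * 60e3) + 1, c(120, 94))
  out <- trend_delta(ts, temporal_window(15 * 60e3 + 2), "relative_change",
                     threshold = -0.20, direction = "below")
  expect_equal(out$value, -26 / 120, tolerance = 1e-12)
  expect_equal(round(out$value, 4), -0.2167)
  expect_true(out$alarm)

  flat <- time_series(channel("SBP"), (0:10) * 60e3, rep(110, 11))
  o1 <- trend_delta(flat, temporal_window(11 * 60e3), "slope")
  o2 <- trend_delta(flat, temporal_window(11 * 60e3), "relative_change",
                    threshold = -0.2, direction = "below")
  expect_equal(o1$value, 0)
  expect_equal(o2$value, 0)
  expect_false(o2$alarm)

  set.seed(29)
  for (rep in 1:15) {
    n <- sample(5:30, 1)
    tt <- sort(sample.int(3600e3, n))
    vv <- rnorm(n, 100, 20)
    ts <- time_series(channel("X"), tt, vv)
    out <- trend_delta(ts, temporal_window(3600e3), "slope")
    fit <- stats::lm(vv ~ I(tt / 60000))
    expect_equal(out$value[length(out$value)],
                 unname(stats::coef(fit)[2]), tolerance = 1e-8)
  }
})

test_that("HRV features match their defining formulas", {
  rr <- time_series(channel("RR_int", "time_series"),
                    c(1000, 2000, 3000), c(1000, 1000, 1000))
  out <- signal_features(rr, temporal_window(10e3),
                         c("mean_rr", "sdnn", "rmssd"))
  expect_equal(out$value[out$feature == "mean_rr"], 1000)
  expect_equal(out$value[out$feature == "sdnn"], 0)
  expect_equal(out$value[out$feature == "rmssd"], 0)

  rr2 <- time_series(channel("RR_int", "time_series"),
                     c(1000, 1900, 3000), c(1000, 900, 1100))
  out2 <- signal_features(rr2, temporal_window(10e3),
                          c("mean_rr", "sdnn", "rmssd"))
  expect_equal(out2$value[out2$feature == "rmssd"],
               sqrt((100^2 + 200^2) / 2), tolerance = 1e-12)
  expect_equal(round(out2$value[out2$feature == "rmssd"], 2), 158.11)
  expect_equal(out2$value[out2$feature == "sdnn"], 100)

  # a single interval yields no indicator rows
  rr3 <- time_series(channel("RR_int", "time_series"), 1000, 1000)
  expect_equal(nrow(signal_features(rr3, temporal_window(10e3), "sdnn")), 0L)
})

test_that("band power concentrates at an injected oscillation frequency", {
  # 0.1 Hz sinusoidal modulation of R-R intervals around 1000 ms
  t <- 0; times <- c(); vals <- c()
  while (t < 300e3) {
    iv <- 1000 + 50 * sin(2 * pi * 0.1 * t / 1000)
    t <- t + iv
    times <- c(times, t); vals <- c(vals, iv)
  }
  rr <- time_series(channel("RR_int", "time_series"), times, vals)
  w <- temporal_window(300e3)
  p_in <- signal_features(rr, w, "fft_band_power", band = c(0.08, 0.12))
  p_out <- signal_features(rr, w, "fft_band_power", band = c(0.15, 0.19))
  expect_gt(p_in$value[1] / p_out$value[1], 10)
})

test_that("pipeline DAG execution equals hand-coded composition", {
  cfg <- cohort_config(n_patients = 1, duration_hours = 6, seed = 55)
  s <- generate_cohort(cfg)$streams[[1]]
  pl <- parse_pipeline(two_pattern_cfg)
  out <- run_pipeline(pl, s)

  manual_trend <- trend_delta(s$series$SBP, temporal_window(900e3),
                              "relative_change")
  ts_trend <- time_series(channel("sbp_drop"), manual_trend$time,
                          manual_trend$value)
  s2 <- s; s2$series$sbp_drop <- ts_trend
  fr <- synchronize(s2, "sbp_drop", temporal_window(900e3, tolerance = 900e3))
  manual_logic <- scalar_logic(fr, "sbp_drop < -0.2")

  expect_equal(out$sbp_drop$time, manual_trend$time)
  expect_equal(out$sbp_drop$value, manual_trend$value)
  expect_equal(out$decomp$value, manual_logic$value)
})

test_that("independent patterns are order-invariant and swappable", {
  cfg <- cohort_config(n_patients = 1, duration_hours = 6, seed = 56)
  s <- generate_cohort(cfg)$streams[[1]]
  p_hr <- "    category: trend_delta\n    inputs: [HR]\n    params: {mode: slope, window_ms: 1800000}\n    output: hr_slope"
  p_bp <- "    category: trend_delta\n    inputs: [SBP]\n    params: {mode: relative_change, window_ms: 1800000}\n    output: bp_rel"
  cfg_ab <- paste0("patterns:\n  - id: a\n", p_hr, "\n  - id: b\n", p_bp)
  cfg_ba <- paste0("patterns:\n  - id: b\n", p_bp, "\n  - id: a\n", p_hr)
  out_ab <- run_pipeline(parse_pipeline(cfg_ab), s)
  out_ba <- run_pipeline(parse_pipeline(cfg_ba), s)
  expect_identical(out_ab$hr_slope$value, out_ba$hr_slope$value)
  expect_identical(out_ab$bp_rel$value, out_ba$bp_rel$value)

  # reconfigurability: replacing the SBP branch leaves the HR branch
  # bit-identical
  p_bp2 <- "    category: trend_delta\n    inputs: [SBP]\n    params: {mode: slope, window_ms: 900000}\n    output: bp_rel"
  cfg_swap <- paste0("patterns:\n  - id: a\n", p_hr, "\n  - id: b\n", p_bp2)
  out_swap <- run_pipeline(parse_pipeline(cfg_swap), s)
  expect_identical(out_swap$hr_slope$value, out_ab$hr_slope$value)
  expect_false(identical(out_swap$bp_rel$value, out_ab$bp_rel$value))

  # missing channel fails before any pattern runs
  expect_error(run_pipeline(parse_pipeline(cfg_ab),
                            unified_stream("p", list())),
               class = "wf_execution_error")
})

test_that("predictor handles enforce their contract", {
  stub <- predictor_handle("half", "constant", input_channels = c("a", "b"),
                           seq_len = 4, constant_value = 0.5)
  X <- array(rnorm(3 * 4 * 2), dim = c(3, 4, 2))
  out <- ml_inference(X, stub)
  expect_equal(out$value, rep(0.5, 3))
  expect_error(predict(stub, array(0, dim = c(3, 5, 2))),
               "arity", class = "wf_config_error")
})

test_that("reference architecture trains to separate a separable set", {
  set.seed(61)
  n <- 400; T <- 5; d <- 2
  y <- rep(c(0, 1), each = n / 2)
  X <- array(rnorm(n * T * d, sd = 1), dim = c(n, T, d))
  X[y == 1, , 1] <- X[y == 1, , 1] + 3 # linearly separable in channel-1 mean
  hold <- sample(n, n / 5)
  tr <- setdiff(seq_len(n), hold)

  # independent oracle: logistic regression on per-channel means
  feat <- cbind(rowMeans(X[, , 1]), rowMeans(X[, , 2]))
  glm_fit <- suppressWarnings(stats::glm(y[tr] ~ feat[tr, ],
                                         family = stats::binomial()))
  glm_p <- stats::plogis(cbind(1, feat[hold, ]) %*% stats::coef(glm_fit))
  expect_gte(mean((glm_p > 0.5) == y[hold]), 0.95)

  # reference recurrent layout: 64 + 32 units, dropout 0.2 between layers
  cfg <- reference_train_config()
  expect_equal(cfg$hidden, c(64L, 32L))
  expect_equal(cfg$dropout, 0.2)
  w <- wardforge:::.lstm_init(d, 64, 32, seed = 1)
  expect_equal(dim(w$W1), c(4 * 64, d + 64))
  expect_equal(dim(w$W2), c(4 * 32, 64 + 32))
  fit <- wardforge:::.lstm_train(w, X[tr, , ], y[tr], 6L, 64L, 0.01, 0.2, 7L)
  p <- wardforge:::.lstm_forward(fit$weights, X[hold, , ])
  expect_gte(mean((p > 0.5) == y[hold]), 0.95)
})

test_that("training splits by patient with disjoint folds and no leakage", {
  cfg <- cohort_config(n_patients = 10, duration_hours = 12,
                       psh_prevalence = 0.8, seed = 66)
  co <- generate_cohort(cfg)
  tcfg <- reference_train_config(epochs_max = 2L, seed = 6)
  h <- train_reference_model(co, tcfg)
  split <- attr(h, "split")
  expect_length(split$train, 8L) # 80% of 10 patients
  expect_length(intersect(split$train, split$validation), 0L)
  folds <- attr(h, "cv")$folds
  expect_length(folds, 5L)
  expect_setequal(unlist(folds), split$train) # cover the pool exactly once
  expect_equal(anyDuplicated(unlist(folds)), 0L)
  expect_true(h$threshold > 0 && h$threshold < 1)

  co0 <- generate_cohort(cohort_config(n_patients = 6, psh_prevalence = 0,
                                       duration_hours = 12, seed = 67))
  expect_error(train_reference_model(co0, tcfg),
               class = "wf_training_error")
})

test_that("bundled example pipelines parse and run over a simulated patient", {
  pdir <- system.file("extdata/pipelines", package = "wardforge")
  cfg <- cohort_config(n_patients = 1, duration_hours = 6, seed = 111)
  s <- generate_cohort(cfg)$streams[[1]]

  sep <- parse_pipeline(file.path(pdir, "sepsis_alert.yaml"))
  out <- run_pipeline(sep, s)
  expect_true(is.logical(out$sepsis_alert$value))

  dec <- parse_pipeline(file.path(pdir, "decompensation.yaml"))
  out2 <- run_pipeline(dec, s)
  expect_true(all(c("state", "z") %in% names(out2$sbp_drop15)))
  expect_true(all(out2$sbp_drop15$state %in%
                    c("normal", "warning", "pathological", "unassessed")))

  # the stress example needs its pluggable predictor and derived channels
  vst <- parse_pipeline(file.path(pdir, "vstress.yaml"))
  s$series$RR_int <- generate_rr_series(s$series$HR, 40, seed = 112)
  gsr <- s$series$HR
  s$series$GSR <- time_series(channel("GSR", "scalar", units = "uS"),
                              gsr$times, 2 + 0.01 * gsr$values, gsr$quality)
  handle <- predictor_handle("vstress_model", "constant",
                             input_channels = c("hrv.sdnn", "hrv.rmssd",
                                                "GSR"),
                             seq_len = 4L, constant_value = 0.85)
  out3 <- run_pipeline(vst, s, models = list(vstress_model = handle))
  expect_true(all(out3$v_stress$value == 0.85))
  expect_gt(nrow(out3$hrv.sdnn), 0)
})

test_that("predictor artifacts round-trip through handle.json + weights.json", {
  w <- wardforge:::.lstm_init(3, 8, 4, seed = 2)
  h <- predictor_handle("tiny", "lstm_binary",
                        input_channels = c("a", "b", "c"), seq_len = 6L,
                        norm = list(mean = c(0, 0, 0), sd = c(1, 1, 1)),
                        weights = w, hidden = c(8L, 4L), threshold = 0.4)
  d <- withr::local_tempdir()
  save_predictor(h, d)
  h2 <- load_predictor(d)
  expect_equal(h2$input_channels, h$input_channels)
  expect_equal(h2$threshold, 0.4)
  set.seed(3)
  X <- array(rnorm(5 * 6 * 3), dim = c(5, 6, 3))
  expect_equal(predict(h2, X), predict(h, X), tolerance = 1e-12)
})
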