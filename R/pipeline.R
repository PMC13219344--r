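# The constructor kernel. A pipeline is a declarative set of processing
# patterns -- scalar threshold logic, trend analysis, signal features, and
# ML inference -- whose input references (stream channels or upstream
# pattern outputs) form a DAG. Configs are YAML or JSON; validation rejects
# cycles, unresolved references, unknown categories, missing category
# parameters and (when channel modalities are declared) pattern/input
# modality mismatches before anything executes. Execution order is a
# deterministic topological sort with ties broken by pattern id.

PATTERN_CATEGORIES <- c("scalar_logic", "trend_delta", "signal_features",
                        "ml_inference")
SIGNAL_FEATURE_NAMES <- c("mean_rr", "sdnn", "rmssd", "fft_band_power")

required_params <- list(
  scalar_logic = "rule",
  trend_delta = c("mode", "window_ms"),
  signal_features = c("features", "window_ms"),
  ml_inference = c("model", "window_ms")
)

validate_pattern_def <- function(p) {
  for (f in c("id", "category", "output"))
    if (is.null(p[[f]]) || !nzchar(as.character(p[[f]])[1]))
      stop_config("pattern definition missing '%s'", f)
  if (!p$category %in% PATTERN_CATEGORIES)
    stop_config("pattern '%s': unknown category '%s'", p$id, p$category)
  p$inputs <- as.character(unlist(p$inputs))
  if (!length(p$inputs))
    stop_config("pattern '%s': needs at least one input", p$id)
  p$params <- p$params %||% list()
  miss <- setdiff(required_params[[p$category]], names(p$params))
  if (length(miss))
    stop_config("pattern '%s' (%s): missing required param(s): %s",
                p$id, p$category, paste(miss, collapse = ", "))
  if (p$category == "scalar_logic") {
    rule <- parse_rule(p$params$rule)
    unknown <- setdiff(rule$vars, p$inputs)
    if (length(unknown))
      stop_config("pattern '%s': rule references undeclared input(s): %s",
                  p$id, paste(unknown, collapse = ", "))
    p$params$rule_parsed <- rule
  }
  if (p$category == "trend_delta") {
    p$params$mode <- match.arg(p$params$mode, c("slope", "relative_change"))
    if (length(p$inputs) != 1L)
      stop_config("pattern '%s': trend_delta takes exactly one input", p$id)
  }
  if (p$category == "signal_features") {
    feats <- as.character(unlist(p$params$features))
    bad <- setdiff(feats, SIGNAL_FEATURE_NAMES)
    if (length(bad))
      stop_config("pattern '%s': unknown feature(s): %s", p$id,
                  paste(bad, collapse = ", "))
    if ("fft_band_power" %in% feats && is.null(p$params$band))
      stop_config("pattern '%s': fft_band_power requires a 'band' param", p$id)
    if (length(p$inputs) != 1L)
      stop_config("pattern '%s': signal_features takes exactly one input",
                  p$id)
    p$params$features <- feats
  }
  p
}

# Output names a pattern produces (signal_features may fan out per feature).
pattern_outputs <- function(p) {
  if (p$category == "signal_features" && length(p$params$features) > 1L)
    paste(p$output, p$params$features, sep = ".")
  else p$output
}

# Deterministic Kahn topological sort; ties by pattern id.
topo_sort <- function(patterns) {
  ids <- vapply(patterns, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop_config("duplicate pattern id(s): %s",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  prod_by <- character()
  for (i in seq_along(patterns))
    for (o in pattern_outputs(patterns[[i]])) {
      if (o %in% names(prod_by))
        stop_config("output '%s' produced by more than one pattern", o)
      prod_by[o] <- ids[i]
    }
  deps <- lapply(patterns, function(p) {
    unname(prod_by[intersect(p$inputs, names(prod_by))])
  })
  names(deps) <- ids
  order <- character()
  remaining <- ids
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(id)
      all(deps[[id]] %in% order), logical(1))]
    if (!length(ready)) {
      cyc <- paste(remaining, collapse = " -> ")
      stop_config("pipeline contains a cycle among patterns: %s", cyc)
    }
    nxt <- sort(ready)[1]
    order <- c(order, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  order
}

#' Parse and validate a pipeline definition
#'
#' Accepts YAML or JSON text (or a file path) with the layout
#' `patterns: [{id, category, inputs, params, output}]` plus optional
#' `channels: {name: modality}`, `rules: {rule_id: {...}}` and
#' `evaluate: {indicator: rule_id}` sections. Parsing fails on cycles,
#' duplicate ids or outputs, unknown categories, missing category
#' parameters, rule identifiers not among a pattern's inputs, and -- when
#' `channels` declares modalities -- on modality mismatches (scalar logic
#' and trend patterns consume `scalar` values; signal features consume
#' `time_series`).
#'
#' @param config pipeline definition: a file path or a single YAML/JSON
#'   string.
#' @return An object of class `wf_pipeline` with patterns in a
#'   deterministic topological execution order.
#' @export
parse_pipeline <- function(config) {
  if (length(config) == 1L && !grepl("\n", config) && file.exists(config)) {
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
  } else txt <- paste(config, collapse = "\n")
  def <- tryCatch(yaml::yaml.load(txt),
                  error = function(e) stop_config(
                    "pipeline config does not parse: %s", conditionMessage(e)))
  if (is.null(def$patterns) || !length(def$patterns))
    stop_config("pipeline config needs a non-empty 'patterns' list")
  patterns <- lapply(def$patterns, validate_pattern_def)
  ids <- vapply(patterns, `[[`, character(1), "id")
  order <- topo_sort(patterns)
  patterns <- patterns[match(order, ids)]

  produced <- unlist(lapply(patterns, pattern_outputs))
  channels <- def$channels %||% list()
  # every input must resolve to a declared channel or an upstream output;
  # undeclared names are allowed only when no channels section is present
  if (length(channels)) {
    for (p in patterns) {
      ext <- setdiff(p$inputs, produced)
      unknown <- setdiff(ext, names(channels))
      if (length(unknown))
        stop_config("pattern '%s': unresolved input(s): %s", p$id,
                    paste(unknown, collapse = ", "))
      in_mod <- vapply(p$inputs, function(i) {
        if (i %in% names(channels)) channels[[i]] else "scalar"
      }, character(1))
      if (p$category %in% c("scalar_logic", "trend_delta") &&
          any(in_mod == "time_series"))
        stop_config("pattern '%s': %s consumes scalar values but input is a waveform",
                    p$id, p$category)
      if (p$category == "signal_features" && any(in_mod != "time_series"))
        stop_config("pattern '%s': signal_features consumes time_series input",
                    p$id)
    }
  }

  rules <- lapply(def$rules %||% list(), function(r) {
    evaluation_rule(rule_id = r$rule_id %||% "rule",
                    mode = r$mode %||% "dynamic_z",
                    z_warn = r$z_warn %||% 2, z_path = r$z_path %||% 3,
                    lo = r$lo, hi = r$hi, min_n_eff = r$min_n_eff %||% 20)
  })
  bindings <- def$evaluate %||% list()
  for (ind in names(bindings))
    if (!bindings[[ind]] %in% names(rules))
      stop_config("evaluate binding for '%s' references unknown rule '%s'",
                  ind, bindings[[ind]])
  structure(list(patterns = patterns, order = order, channels = channels,
                 rules = rules, bindings = bindings),
            class = "wf_pipeline")
}

#' @export
print.wf_pipeline <- function(x, ...) {
  cat(sprintf("<wf_pipeline> %d pattern(s), execution order: %s\n",
              length(x$patterns), paste(x$order, collapse = " -> ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Pattern implementations. Each returns an indicator data.frame with columns
# time, value (plus alarm where a threshold is configured), carrying name
# and provenance attributes.

as_indicator <- function(time, value, name, provenance, alarm = NULL) {
  df <- data.frame(time = time, value = value)
  if (!is.null(alarm)) df$alarm <- alarm
  attr(df, "indicator") <- name
  attr(df, "provenance") <- provenance
  class(df) <- c("wf_indicator", "data.frame")
  df
}

#' Threshold logic over synchronized frames
#'
#' Applies a parsed boolean rule to every complete frame; incomplete frames
#' yield no indicator.
#'
#' @param frames a [synchronize()] result covering the rule's identifiers.
#' @param rule rule text or a [parse_rule()] object, e.g.
#'   `"Temp > 38 AND HR > 100"`.
#' @return Indicator data.frame (`time`, `value` logical).
#' @export
scalar_logic <- function(frames, rule) {
  if (is.character(rule)) rule <- parse_rule(rule)
  missing_ids <- setdiff(rule$vars, names(frames))
  if (length(missing_ids))
    stop_config("rule references unknown identifier(s): %s",
                paste(missing_ids, collapse = ", "))
  keep <- which(frames$complete)
  vals <- vapply(keep, function(i)
    eval_rule(rule, as.list(frames[i, rule$vars, drop = FALSE])),
    logical(1))
  as_indicator(frames$t_ref[keep], vals, "scalar_logic", rule$text)
}

#' Trend analysis over a stepped window
#'
#' `slope` is the least-squares slope of the ok samples in each window in
#' units/minute; `relative_change` is `(last - first) / first` over the
#' window. An optional threshold turns the series into a boolean alarm:
#' `alarm = value > threshold` when `direction = "above"`, `value <
#' threshold` when `"below"` (e.g. threshold -0.20, below, on a systolic BP
#' relative change flags a >20% drop).
#'
#' @param series a [time_series()].
#' @param window a [temporal_window()].
#' @param mode `"slope"` or `"relative_change"`.
#' @param step_ms step between window ends; defaults to the window width.
#' @param threshold,direction optional alarm threshold.
#' @return Indicator data.frame (`time`, `value`, optional `alarm`). Windows
#'   with insufficient samples emit no row.
#' @export
trend_delta <- function(series, window, mode = c("slope", "relative_change"),
                        step_ms = window$width, threshold = NULL,
                        direction = c("above", "below")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  slices <- window_slices(series, window, step_ms)
  oi <- ok_idx(series)
  t_out <- numeric(); v_out <- numeric()
  for (sl in slices) {
    idx <- intersect(sl$idx, oi)
    if (length(idx) < 2L) next
    tt <- series$times[idx]; vv <- series$values[idx]
    if (mode == "slope") {
      tm <- (tt - mean(tt)) / 60000 # minutes, centered
      v <- sum(tm * (vv - mean(vv))) / sum(tm^2)
    } else {
      if (vv[1] == 0) next
      v <- (vv[length(vv)] - vv[1]) / vv[1]
    }
    t_out <- c(t_out, sl$t_end); v_out <- c(v_out, v)
  }
  alarm <- NULL
  if (!is.null(threshold))
    alarm <- if (direction == "above") v_out > threshold else v_out < threshold
  as_indicator(t_out, v_out, paste0("trend_", mode), mode, alarm = alarm)
}

#' Heart-rate-variability / signal features over a stepped window
#'
#' For an event-based R-R interval series (or any sampled waveform):
#' `mean_rr` and `sdnn` are the mean and sample SD of the interval values in
#' the window, `rmssd` the root-mean-square of successive differences, and
#' `fft_band_power` the integrated periodogram power in `band` (Hz) after
#' mean removal and linear resampling of the interval series onto a uniform
#' grid (`resample_hz`).
#'
#' @param series a [time_series()]; values are R-R intervals in ms for the
#'   HRV features.
#' @param window a [temporal_window()].
#' @param features subset of `c("mean_rr", "sdnn", "rmssd",
#'   "fft_band_power")`.
#' @param step_ms step between window ends; defaults to the window width.
#' @param band two-element `c(f_lo, f_hi)` in Hz for `fft_band_power`.
#' @param resample_hz uniform resampling rate for the periodogram.
#' @return data.frame (`time`, `feature`, `value`); windows with fewer than
#'   two usable samples emit no rows.
#' @export
signal_features <- function(series, window, features,
                            step_ms = window$width, band = NULL,
                            resample_hz = 4) {
  features <- match.arg(features, SIGNAL_FEATURE_NAMES, several.ok = TRUE)
  if ("fft_band_power" %in% features &&
      (is.null(band) || length(band) != 2L))
    stop_config("fft_band_power requires band = c(f_lo, f_hi)")
  slices <- window_slices(series, window, step_ms)
  oi <- ok_idx(series)
  out <- list()
  for (sl in slices) {
    idx <- intersect(sl$idx, oi)
    if (length(idx) < 2L) next
    iv <- series$values[idx]; tt <- series$times[idx]
    for (f in features) {
      v <- switch(f,
        mean_rr = mean(iv),
        sdnn = stats::sd(iv),
        rmssd = sqrt(mean(diff(iv)^2)),
        fft_band_power = band_power(tt, iv, band, resample_hz))
      if (is.na(v)) next
      out[[length(out) + 1L]] <- data.frame(time = sl$t_end, feature = f,
                                            value = v)
    }
  }
  df <- if (length(out)) do.call(rbind, out)
        else data.frame(time = numeric(), feature = character(),
                        value = numeric())
  attr(df, "indicator") <- "signal_features"
  df
}

# Integrated one-sided periodogram power in [f_lo, f_hi] Hz of an
# irregularly timed series, after mean removal and linear resampling onto a
# uniform grid.
band_power <- function(times, values, band, resample_hz) {
  span_s <- (times[length(times)] - times[1]) / 1000
  n_grid <- floor(span_s * resample_hz) + 1L
  if (n_grid < 8L) return(NA_real_)
  grid <- seq(times[1], times[length(times)], length.out = n_grid)
  x <- stats::approx(times, values, xout = grid)$y
  x <- x - mean(x)
  n <- length(x)
  spec <- Mod(stats::fft(x))^2 / (n * resample_hz) # two-sided density
  k <- seq_len(floor(n / 2)) # positive frequencies
  freq <- k * resample_hz / n
  df <- resample_hz / n
  sel <- freq >= band[1] & freq <= band[2]
  2 * sum(spec[k[sel] + 1L]) * df
}

#' Run a pre-trained predictor over windowed features
#'
#' @param features an `(n, seq_len, channels)` array, or the list returned
#'   by [windowed_features()].
#' @param handle a [predictor_handle()].
#' @return Indicator data.frame (`time`, `value` probability); times are
#'   taken from the feature windows when available.
#' @export
ml_inference <- function(features, handle) {
  if (is.list(features) && !is.null(features$X)) {
    t_end <- features$t_end; X <- features$X
  } else {
    X <- features; t_end <- seq_len(dim(X)[1])
  }
  p <- predict(handle, X)
  as_indicator(t_end, p, handle$model_id, handle$model_id)
}

# ---------------------------------------------------------------------------
# Pipeline execution.

indicator_to_ts <- function(df, name) {
  time_series(channel(name, "scalar"), df$time, as.numeric(df$value))
}

#' Execute a validated pipeline over a patient stream
#'
#' Patterns run in the pipeline's topological order; each consumes stream
#' channels and/or upstream indicator series and appends its outputs to the
#' working set. The result is a pure function of `(pipeline, stream,
#' models)`. Indicators bound to evaluation rules additionally get `state`
#' and `z` columns from a per-indicator dynamic baseline (values are
#' evaluated against the baseline of strictly earlier samples, then folded
#' in).
#'
#' @param pipeline a [parse_pipeline()] result.
#' @param stream a [unified_stream()].
#' @param models named list of [predictor_handle()] objects for
#'   `ml_inference` patterns whose `model` param is not an artifact path.
#' @return Named list of indicator data.frames, one per pattern output.
#' @export
run_pipeline <- function(pipeline, stream, models = list()) {
  if (!inherits(pipeline, "wf_pipeline")) stop_validation("not a wf_pipeline")
  produced <- unlist(lapply(pipeline$patterns, pattern_outputs))
  needed <- setdiff(unlist(lapply(pipeline$patterns, `[[`, "inputs")),
                    produced)
  missing_ch <- setdiff(needed, names(stream$series))
  if (length(missing_ch))
    wf_stop("wf_execution_error", "stream lacks channel(s): %s",
            paste(missing_ch, collapse = ", "))

  env <- stream
  out <- list()
  for (p in pipeline$patterns) {
    prm <- p$params
    res <- switch(p$category,
      scalar_logic = {
        tol <- prm$tolerance_ms %||% 5000
        frames <- synchronize(env, p$inputs,
                              temporal_window(max(tol, 1), tolerance = tol))
        scalar_logic(frames, prm$rule_parsed %||% prm$rule)
      },
      trend_delta = {
        ts <- get_channel(env, p$inputs)
        trend_delta(ts, temporal_window(prm$window_ms),
                    mode = prm$mode,
                    step_ms = prm$step_ms %||% prm$window_ms,
                    threshold = prm$threshold,
                    direction = prm$direction %||% "above")
      },
      signal_features = {
        ts <- get_channel(env, p$inputs)
        signal_features(ts, temporal_window(prm$window_ms),
                        features = prm$features,
                        step_ms = prm$step_ms %||% prm$window_ms,
                        band = if (!is.null(prm$band))
                          as.numeric(unlist(prm$band)),
                        resample_hz = prm$resample_hz %||% 4)
      },
      ml_inference = {
        handle <- if (!is.null(models[[prm$model]])) models[[prm$model]]
                  else if (dir.exists(prm$model)) load_predictor(prm$model)
                  else stop_config("pattern '%s': model '%s' not supplied",
                                   p$id, prm$model)
        chans <- if (length(handle$input_channels)) handle$input_channels
                 else p$inputs
        feats <- windowed_features(env, chans, prm$window_ms,
                                   prm$step_ms %||% prm$window_ms,
                                   handle$seq_len)
        ml_inference(feats, handle)
      })
    outs <- pattern_outputs(p)
    if (p$category == "signal_features" && length(outs) > 1L) {
      for (f in prm$features) {
        sub <- res[res$feature == f, c("time", "value")]
        nm <- paste(p$output, f, sep = ".")
        out[[nm]] <- as_indicator(sub$time, sub$value, nm, p$id)
        env$series[[nm]] <- indicator_to_ts(sub, nm)
      }
    } else {
      if (p$category == "signal_features")
        res <- as_indicator(res$time, res$value, p$output, p$id)
      attr(res, "indicator") <- p$output
      attr(res, "provenance") <- p$id
      out[[p$output]] <- res
      if (nrow(res) > 0)
        env$series[[p$output]] <- indicator_to_ts(res, p$output)
    }
  }

  # dynamic evaluation bindings
  for (ind in names(pipeline$bindings)) {
    if (is.null(out[[ind]])) next
    rule <- pipeline$rules[[pipeline$bindings[[ind]]]]
    df <- out[[ind]]
    b <- new_baseline(ind, "exponential", halflife_ms = 3600e3)
    states <- character(nrow(df)); zs <- numeric(nrow(df))
    for (i in seq_len(nrow(df))) {
      ev <- evaluate_indicator(as.numeric(df$value[i]), b, rule,
                               time = df$time[i])
      states[i] <- ev$state; zs[i] <- ev$z
      b <- update_baseline(b, as.numeric(df$value[i]), df$time[i])
    }
    df$state <- states; df$z <- zs
    out[[ind]] <- df
  }
  out
}

#' Write indicator series to the long output CSV
#'
#' @param indicators result of [run_pipeline()].
#' @param patient_id patient the indicators belong to.
#' @param path output CSV (`patient_id,timestamp_ms,indicator,value,provenance`
#'   plus `state`/`z` when present).
#' @return `path`, invisibly.
#' @export
write_indicators <- function(indicators, patient_id, path) {
  rows <- lapply(names(indicators), function(nm) {
    df <- indicators[[nm]]
    if (!nrow(df)) return(NULL)
    data.frame(patient_id = patient_id, timestamp_ms = df$time,
               indicator = nm, value = as.numeric(df$value),
               provenance = attr(df, "provenance") %||% nm,
               state = if (!is.null(df$state)) df$state else NA_character_,
               z = if (!is.null(df$z)) df$z else NA_real_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
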