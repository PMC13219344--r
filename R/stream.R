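# Stream data model: channels, time series, unified per-patient streams, and
# long-format CSV/NDJSON I/O. Timestamps are integer epoch milliseconds; a
# missing sample keeps its slot with value NA and quality "missing" so that
# missingness rates stay measurable downstream.

MODALITIES <- c("scalar", "time_series", "structured", "complex")
QUALITY_LEVELS <- c("ok", "missing", "artifact")

#' Define a measurement channel
#'
#' A channel names one physiological signal and records its modality class:
#' `scalar` (discrete low-frequency vitals such as temperature or blood
#' pressure), `time_series` (high-frequency waveforms such as ECG or PPG),
#' `structured` (database records such as lab results), or `complex`
#' (high-dimensional payloads, carried only as opaque references).
#'
#' @param name channel identifier, unique within a stream.
#' @param modality one of `"scalar"`, `"time_series"`, `"structured"`,
#'   `"complex"`.
#' @param units unit string (informational).
#' @param nominal_rate nominal sampling rate in samples/second; `0` marks an
#'   event-based channel (e.g. R-R interval series).
#' @return An object of class `wf_channel`.
#' @examples
#' channel("HR", "scalar", units = "bpm", nominal_rate = 1 / 60)
#' @export
channel <- function(name, modality = "scalar", units = "", nominal_rate = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_validation("channel `name` must be a non-empty string")
  modality <- match.arg(modality, MODALITIES)
  assert_scalar_number(nominal_rate, "nominal_rate", lo = 0)
  structure(
    list(name = name, modality = modality, units = units,
         nominal_rate = nominal_rate),
    class = "wf_channel"
  )
}

#' Report the modality class of a channel
#'
#' Pipelines use the modality to reject pattern/input mismatches at parse
#' time (e.g. signal-feature patterns require `time_series` input).
#'
#' @param ch a [channel()].
#' @return The modality string.
#' @export
classify_modality <- function(ch) {
  if (!inherits(ch, "wf_channel")) stop_validation("not a wf_channel")
  ch$modality
}

#' Construct a quality-flagged time series
#'
#' @param ch a [channel()].
#' @param times strictly increasing integer epoch milliseconds.
#' @param values numeric values; `NA` only where quality is `"missing"`.
#' @param quality per-sample flags among `"ok"`, `"missing"`, `"artifact"`;
#'   defaults to `"ok"` except `"missing"` where `values` is `NA`.
#' @return An object of class `wf_timeseries`.
#' @export
time_series <- function(ch, times, values,
                        quality = ifelse(is.na(values), "missing", "ok")) {
  if (!inherits(ch, "wf_channel")) stop_validation("not a wf_channel")
  times <- as.numeric(times)
  values <- as.numeric(values)
  quality <- as.character(quality)
  n <- length(times)
  if (length(values) != n || length(quality) != n)
    stop_validation("times/values/quality lengths differ (%d/%d/%d)",
                    n, length(values), length(quality))
  if (n > 1L && any(diff(times) <= 0))
    stop_validation("timestamps must be strictly increasing in channel '%s'",
                    ch$name)
  bad <- setdiff(unique(quality), QUALITY_LEVELS)
  if (length(bad))
    stop_validation("unknown quality flag(s): %s", paste(bad, collapse = ", "))
  if (any(is.na(values) & quality != "missing"))
    stop_validation("NA value with non-missing quality in channel '%s'",
                    ch$name)
  structure(list(channel = ch, times = times, values = values,
                 quality = quality),
            class = "wf_timeseries")
}

#' @export
length.wf_timeseries <- function(x) length(x$times)

#' @export
print.wf_timeseries <- function(x, ...) {
  cat(sprintf("<wf_timeseries> %s [%s]: %d samples", x$channel$name,
              x$channel$modality, length(x$times)))
  if (length(x$times))
    cat(sprintf(", t = %.0f..%.0f ms, %d ok / %d missing / %d artifact",
                x$times[1], x$times[length(x$times)],
                sum(x$quality == "ok"), sum(x$quality == "missing"),
                sum(x$quality == "artifact")))
  cat("\n")
  invisible(x)
}

# Indices of usable samples. Artifact samples are excluded by default: the
# simulator flags them as corrupted and downstream statistics should not see
# them unless explicitly requested.
ok_idx <- function(ts, include_artifacts = FALSE) {
  keep <- ts$quality == "ok"
  if (include_artifacts) keep <- keep | ts$quality == "artifact"
  which(keep & !is.na(ts$values))
}

#' Bundle per-channel time series into one patient stream
#'
#' @param patient_id patient identifier.
#' @param series list of [time_series()]; channel names must be unique and
#'   become the element names.
#' @param metadata named character vector of free-form annotations.
#' @return An object of class `wf_stream`.
#' @export
unified_stream <- function(patient_id, series = list(), metadata = character()) {
  if (!length(patient_id) == 1L) stop_validation("patient_id must be scalar")
  nm <- vapply(series, function(s) s$channel$name, character(1))
  if (anyDuplicated(nm))
    stop_validation("duplicate channel name(s): %s",
                    paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(series) <- nm
  structure(list(patient_id = as.character(patient_id), series = series,
                 metadata = metadata),
            class = "wf_stream")
}

#' @export
print.wf_stream <- function(x, ...) {
  cat(sprintf("<wf_stream> patient %s: %d channel(s)\n", x$patient_id,
              length(x$series)))
  for (s in x$series) print(s)
  invisible(x)
}

get_channel <- function(stream, name) {
  if (!name %in% names(stream$series))
    stop_lookup("channel '%s' not present in stream for patient %s",
                name, stream$patient_id)
  stream$series[[name]]
}

# ---------------------------------------------------------------------------
# Long-format I/O. Schema: patient_id,timestamp_ms,channel,value,quality with
# an empty value field meaning a missing sample.

parse_quality <- function(value_chr, quality_chr, line, path) {
  q <- ifelse(!nzchar(quality_chr) | is.na(quality_chr), "ok", quality_chr)
  bad <- !q %in% QUALITY_LEVELS
  if (any(bad))
    stop_parse("%s:%d: unknown quality '%s'", path, line[which(bad)[1]],
               q[which(bad)[1]])
  empty <- !nzchar(value_chr) | is.na(value_chr)
  q[empty] <- "missing"
  q
}

#' Read a patient stream from a long-format file
#'
#' Accepts the long schema `patient_id,timestamp_ms,channel,value,quality`
#' either as RFC-4180 CSV or as NDJSON (one JSON object per line with the
#' same five keys). An empty `value` field is parsed as a missing sample.
#' Rows are grouped by channel (in order of first appearance) and sorted by
#' time; a duplicated timestamp within a channel is a validation error.
#'
#' @param path file to read.
#' @param format `"csv"` or `"ndjson"`.
#' @param modalities optional named character vector channel -> modality used
#'   to type the reconstructed channels; defaults to `"scalar"`.
#' @return A [unified_stream()].
#' @export
read_stream <- function(path, format = c("csv", "ndjson"), modalities = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io("file not found: %s", path)
  if (format == "csv") {
    df <- tryCatch(
      utils::read.csv(path, colClasses = "character", check.names = FALSE),
      error = function(e) stop_parse("%s: %s", path, conditionMessage(e)))
    need <- c("patient_id", "timestamp_ms", "channel", "value", "quality")
    if (!identical(names(df), need))
      stop_parse("%s: header must be %s", path, paste(need, collapse = ","))
    line <- seq_len(nrow(df)) + 1L
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop_parse(
                        "%s:%d: invalid JSON (%s)", path, i,
                        conditionMessage(e)))
      rec
    })
    df <- data.frame(
      patient_id = vapply(recs, function(r) as.character(r$patient_id), ""),
      timestamp_ms = vapply(recs, function(r) as.character(r$timestamp_ms), ""),
      channel = vapply(recs, function(r) as.character(r$channel), ""),
      value = vapply(recs, function(r) {
        v <- r$value
        if (is.null(v) || (length(v) == 1L && is.na(v))) "" else as.character(v)
      }, ""),
      quality = vapply(recs, function(r) as.character(r$quality %||% "ok"), ""),
      stringsAsFactors = FALSE
    )
    line <- seq_len(nrow(df))
  }

  t_num <- suppressWarnings(as.numeric(df$timestamp_ms))
  if (any(is.na(t_num)))
    stop_parse("%s:%d: non-numeric timestamp '%s'", path,
               line[which(is.na(t_num))[1]],
               df$timestamp_ms[which(is.na(t_num))[1]])
  v_chr <- df$value
  v_num <- suppressWarnings(as.numeric(v_chr))
  bad_v <- nzchar(v_chr) & !is.na(v_chr) & is.na(v_num)
  if (any(bad_v))
    stop_parse("%s:%d: non-numeric value '%s'", path, line[which(bad_v)[1]],
               v_chr[which(bad_v)[1]])
  qual <- parse_quality(v_chr, df$quality, line, path)
  v_num[qual == "missing"] <- NA_real_

  pid <- unique(df$patient_id)
  if (length(pid) > 1L)
    stop_validation("%s: stream files are per patient; found ids: %s", path,
                    paste(pid, collapse = ", "))
  if (length(pid) == 0L) pid <- "unknown"

  series <- list()
  for (ch_name in unique(df$channel)) {
    sel <- df$channel == ch_name
    o <- order(t_num[sel])
    tt <- t_num[sel][o]
    if (anyDuplicated(tt))
      stop_validation("%s: duplicated timestamp %.0f in channel '%s'",
                      path, tt[duplicated(tt)][1], ch_name)
    mod <- if (!is.null(modalities) && ch_name %in% names(modalities))
      modalities[[ch_name]] else "scalar"
    series[[ch_name]] <- time_series(channel(ch_name, mod),
                                     tt, v_num[sel][o], qual[sel][o])
  }
  unified_stream(pid, series)
}

#' Write a patient stream to a long-format file
#'
#' Inverse of [read_stream()]: emits one row per sample, channels in stream
#' order, samples in time order, missing values as empty fields. Values are
#' printed with 15 significant digits so a read/write round trip reproduces
#' the stream.
#'
#' @param stream a [unified_stream()].
#' @param path output file.
#' @param format `"csv"` or `"ndjson"`.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path, format = c("csv", "ndjson")) {
  format <- match.arg(format)
  rows <- lapply(stream$series, function(ts) {
    data.frame(patient_id = stream$patient_id,
               timestamp_ms = sprintf("%.0f", ts$times),
               channel = ts$channel$name,
               value = ifelse(is.na(ts$values), "",
                              sprintf("%.15g", ts$values)),
               quality = ts$quality, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) df <- data.frame(patient_id = character(),
                                    timestamp_ms = character(),
                                    channel = character(), value = character(),
                                    quality = character())
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      val <- if (nzchar(df$value[i])) as.numeric(df$value[i]) else NULL
      obj <- list(patient_id = df$patient_id[i],
                  timestamp_ms = as.numeric(df$timestamp_ms[i]),
                  channel = df$channel[i], value = val,
                  quality = df$quality[i])
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                  null = "null"), con)
    }
  }
  invisible(path)
}
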