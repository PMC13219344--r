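# Cross-channel temporal synchronization and windowing. The temporal window
# is the contract under which heterogeneous channels may be evaluated
# jointly: samples from different channels are matched only when they fall
# within the window's tolerance of the reference sample.

#' Define a temporal window
#'
#' @param width window width in milliseconds (`> 0`).
#' @param alignment `"trailing"` (window ends at the reference time) or
#'   `"centered"`.
#' @param tolerance cross-channel matching tolerance in milliseconds
#'   (`>= 0`); a sample from another channel is attached to a reference
#'   sample only if their times differ by at most this much.
#' @return An object of class `wf_window`.
#' @examples
#' temporal_window(width = 15 * 60e3, tolerance = 5000)
#' @export
temporal_window <- function(width, alignment = c("trailing", "centered"),
                            tolerance = 0) {
  assert_scalar_number(width, "width")
  if (width <= 0) stop_validation("window width must be > 0, got %s",
                                  format(width))
  if (tolerance < 0) stop_validation("tolerance must be >= 0, got %s",
                                     format(tolerance))
  alignment <- match.arg(alignment)
  structure(list(width = width, alignment = alignment, tolerance = tolerance),
            class = "wf_window")
}

# Nearest element of sorted vector `haystack` for each element of `needles`;
# ties (two candidates exactly equidistant) resolve to the earlier sample so
# results are deterministic. Returns an index vector (NA when haystack empty).
nearest_index <- function(needles, haystack) {
  m <- length(haystack)
  if (m == 0L) return(rep(NA_integer_, length(needles)))
  lo <- findInterval(needles, haystack)
  lo_c <- pmax(lo, 1L)
  hi_c <- pmin(lo + 1L, m)
  d_lo <- abs(needles - haystack[lo_c])
  d_hi <- abs(needles - haystack[hi_c])
  use_lo <- lo >= 1L & (lo + 1L > m | d_lo <= d_hi)
  ifelse(use_lo, lo_c, hi_c)
}

#' Synchronize channels onto a reference channel's timeline
#'
#' Builds one frame per usable sample of the reference channel (the first
#' name in `channels`). For every other channel the nearest ok-quality
#' sample within `window$tolerance` is attached together with its signed lag
#' (other minus reference, ms). A frame is `complete` when every requested
#' channel is present. Artifact-flagged samples are excluded unless
#' `include_artifacts = TRUE`; missing samples are never attached.
#'
#' @param stream a [unified_stream()].
#' @param channels character vector of channel names; first is the reference.
#' @param window a [temporal_window()]; only `tolerance` is used here.
#' @param include_artifacts also match artifact-flagged samples.
#' @return A data.frame of class `wf_syncframes` with columns `t_ref`,
#'   `complete`, then `<channel>` and `<channel>_lag_ms` per channel (the
#'   reference channel has lag 0 by construction).
#' @examples
#' bp <- time_series(channel("SBP"), c(10000), c(118))
#' hr <- time_series(channel("HR"), c(12000), c(92))
#' s <- unified_stream("p1", list(bp, hr))
#' synchronize(s, c("SBP", "HR"), temporal_window(5000, tolerance = 5000))
#' @export
synchronize <- function(stream, channels, window, include_artifacts = FALSE) {
  if (!inherits(window, "wf_window")) stop_validation("not a wf_window")
  if (length(channels) < 1L) stop_validation("need at least one channel")
  for (nm in channels) get_channel(stream, nm) # lookup errors up front

  ref <- get_channel(stream, channels[1])
  ri <- ok_idx(ref, include_artifacts)
  t_ref <- ref$times[ri]
  out <- data.frame(t_ref = t_ref, complete = TRUE)
  out[[channels[1]]] <- ref$values[ri]
  out[[paste0(channels[1], "_lag_ms")]] <- rep(0, length(t_ref))

  for (nm in channels[-1]) {
    ts <- get_channel(stream, nm)
    oi <- ok_idx(ts, include_artifacts)
    idx <- nearest_index(t_ref, ts$times[oi])
    lag <- ts$times[oi][idx] - t_ref
    hit <- !is.na(idx) & abs(lag) <= window$tolerance
    val <- ifelse(hit, ts$values[oi][idx], NA_real_)
    out[[nm]] <- val
    out[[paste0(nm, "_lag_ms")]] <- ifelse(hit, lag, NA_real_)
    out$complete <- out$complete & hit
  }
  class(out) <- c("wf_syncframes", "data.frame")
  out
}

#' Slice a time series into stepped windows
#'
#' Windows are half-open intervals `(t_end - width, t_end]` anchored so that
#' the first window begins just before the first sample; with
#' `step == width` every sample therefore lands in exactly one slice.
#'
#' @param ts a [time_series()].
#' @param window a [temporal_window()].
#' @param step distance between consecutive window ends, milliseconds (> 0).
#' @return A list of slices, each `list(t_end =, idx =)` with `idx` the
#'   sample indices inside the window (any quality; filter downstream).
#'   Empty series yield an empty list.
#' @export
window_slices <- function(ts, window, step) {
  if (!inherits(window, "wf_window")) stop_validation("not a wf_window")
  assert_scalar_number(step, "step")
  if (step <= 0) stop_validation("step must be > 0")
  n <- length(ts$times)
  if (n == 0L) return(list())
  t_min <- ts$times[1]; t_max <- ts$times[n]
  first_end <- t_min - 1 + window$width
  n_slices <- max(1, ceiling((t_max - first_end) / step) + 1)
  ends <- first_end + (seq_len(n_slices) - 1) * step
  lapply(ends, function(e) {
    inside <- which(ts$times > e - window$width & ts$times <= e)
    list(t_end = e, idx = inside)
  })
}
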