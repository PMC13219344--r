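# Dynamic evaluation: each indicator is judged against the patient's own
# running baseline (mean and SD over a trailing window, or exponentially
# weighted with a configured half-life) instead of fixed population cutoffs.
# The z-score of the incoming value against (mu_hist, sigma_hist) maps to
# normal / warning / pathological states. A static banded linear score is
# provided as the Generation-1 comparator.

#' Initialise a per-patient baseline tracker
#'
#' @param indicator indicator name the baseline tracks.
#' @param mode `"rolling"` (trailing time window) or `"exponential"`
#'   (exponentially weighted with a half-life).
#' @param window_ms trailing window width, ms (rolling mode).
#' @param halflife_ms weight half-life, ms (exponential mode).
#' @return An object of class `wf_baseline` with `mu_hist`, `sigma_hist` and
#'   `n_eff` fields, updated by [update_baseline()].
#' @export
new_baseline <- function(indicator, mode = c("rolling", "exponential"),
                         window_ms = 3600e3, halflife_ms = 3600e3) {
  mode <- match.arg(mode)
  assert_scalar_number(window_ms, "window_ms", lo = 1)
  assert_scalar_number(halflife_ms, "halflife_ms", lo = 1)
  structure(list(indicator = indicator, mode = mode, window_ms = window_ms,
                 halflife_ms = halflife_ms,
                 mu_hist = NA_real_, sigma_hist = NA_real_, n_eff = 0,
                 # rolling buffer / exponential sufficient statistics
                 buf_t = numeric(), buf_v = numeric(),
                 ew_mean = 0, ew_s = 0, ew_w = 0, last_t = NA_real_),
            class = "wf_baseline")
}

#' Fold one observation into a baseline
#'
#' Rolling mode keeps the samples inside the trailing window and maintains
#' mean and sample (n-1) SD; exponential mode applies the standard
#' exponentially weighted mean/variance update with per-gap decay
#' `0.5^(dt / halflife)`. Only ok-quality values should be offered.
#'
#' @param baseline a `wf_baseline`.
#' @param v observed value.
#' @param t observation time, ms (non-decreasing across calls).
#' @return The updated `wf_baseline`.
#' @examples
#' b <- new_baseline("HR", window_ms = 10e3)
#' for (i in 1:4) b <- update_baseline(b, c(1, 2, 3, 4)[i], i * 1000)
#' c(b$mu_hist, b$sigma_hist)
#' @export
update_baseline <- function(baseline, v, t) {
  if (!inherits(baseline, "wf_baseline")) stop_validation("not a wf_baseline")
  if (is.na(v)) stop_validation("baseline updates require an ok value")
  b <- baseline
  if (b$mode == "rolling") {
    keep <- b$buf_t > t - b$window_ms
    b$buf_t <- c(b$buf_t[keep], t)
    b$buf_v <- c(b$buf_v[keep], v)
    n <- length(b$buf_v)
    b$mu_hist <- mean(b$buf_v)
    b$sigma_hist <- if (n > 1) stats::sd(b$buf_v) else 0
    b$n_eff <- n
  } else {
    lam <- if (is.na(b$last_t)) 1 else 0.5^((t - b$last_t) / b$halflife_ms)
    w_new <- lam * b$ew_w + 1
    mu_old <- if (b$ew_w == 0) v else b$ew_mean
    mu_new <- mu_old + (v - mu_old) / w_new
    b$ew_s <- lam * b$ew_s + (v - mu_old) * (v - mu_new)
    b$ew_w <- w_new
    b$ew_mean <- mu_new
    b$mu_hist <- mu_new
    b$sigma_hist <- if (w_new > 1) sqrt(max(b$ew_s, 0) / (w_new - 1)) else 0
    b$n_eff <- w_new
    b$last_t <- t
  }
  b
}

#' Define an evaluation rule
#'
#' @param rule_id identifier.
#' @param mode `"dynamic_z"` (z-score against the patient baseline) or
#'   `"static_range"` (fixed bounds).
#' @param z_warn,z_path absolute z thresholds for warning / pathological
#'   (`0 < z_warn < z_path`).
#' @param lo,hi static range bounds (`lo < hi`), also used as the fallback
#'   while a dynamic baseline is still immature, when supplied.
#' @param min_n_eff effective sample count before dynamic mode activates.
#' @return An object of class `wf_eval_rule`.
#' @export
evaluation_rule <- function(rule_id = "default",
                            mode = c("dynamic_z", "static_range"),
                            z_warn = 2, z_path = 3, lo = NULL, hi = NULL,
                            min_n_eff = 20) {
  mode <- match.arg(mode)
  if (!(z_warn > 0 && z_path > z_warn))
    stop_validation("need 0 < z_warn < z_path (got %g, %g)", z_warn, z_path)
  if (!is.null(lo) && !is.null(hi) && !(lo < hi))
    stop_validation("static range requires lo < hi")
  if (mode == "static_range" && (is.null(lo) || is.null(hi)))
    stop_validation("static_range mode requires lo and hi")
  structure(list(rule_id = rule_id, mode = mode, z_warn = z_warn,
                 z_path = z_path, lo = lo, hi = hi, min_n_eff = min_n_eff),
            class = "wf_eval_rule")
}

static_range_state <- function(v, rule) {
  if (v >= rule$lo && v <= rule$hi) "normal" else "pathological"
}

#' Evaluate a value against a baseline under a rule
#'
#' Dynamic mode: `z = (v - mu_hist) / sigma_hist`; `|z| <= z_warn` is
#' normal, `z_warn < |z| <= z_path` warning, `|z| > z_path` pathological.
#' While the baseline is immature (`n_eff < min_n_eff`) the static range is
#' used when the rule carries one, otherwise the state is `unassessed`. A
#' degenerate baseline (`sigma_hist == 0`) yields z = 0 when `v == mu_hist`
#' and a pathological `+/-Inf` z otherwise.
#'
#' @param v observed value.
#' @param baseline a `wf_baseline`.
#' @param rule an [evaluation_rule()].
#' @param time optional timestamp echoed in the result.
#' @return An object of class `wf_evaluation`: `indicator`, `time`, `state`,
#'   `z`.
#' @export
evaluate_indicator <- function(v, baseline, rule, time = NA_real_) {
  if (!inherits(rule, "wf_eval_rule")) stop_validation("not a wf_eval_rule")
  z <- NA_real_
  if (rule$mode == "static_range") {
    state <- static_range_state(v, rule)
  } else if (baseline$n_eff < rule$min_n_eff) {
    state <- if (!is.null(rule$lo) && !is.null(rule$hi))
      static_range_state(v, rule) else "unassessed"
  } else if (baseline$sigma_hist == 0) {
    if (v == baseline$mu_hist) { z <- 0; state <- "normal" }
    else { z <- sign(v - baseline$mu_hist) * Inf; state <- "pathological" }
  } else {
    z <- (v - baseline$mu_hist) / baseline$sigma_hist
    a <- abs(z)
    state <- if (a <= rule$z_warn) "normal"
             else if (a <= rule$z_path) "warning" else "pathological"
  }
  structure(list(indicator = baseline$indicator %||% "value", time = time,
                 state = state, z = z),
            class = "wf_evaluation")
}

# ---------------------------------------------------------------------------
# Static banded linear score (Generation-1 comparator): H = sum_i w_i *
# band_i(x_i), each band function mapping the real line onto integer
# sub-scores.

#' Define a static banded linear score
#'
#' @param components list of components, each
#'   `list(input = <channel>, weight = <w>, bands = data.frame(lo, hi,
#'   points))`. Bands are half-open `[lo, hi)` intervals that must partition
#'   the real line (first `lo = -Inf`, last `hi = Inf`, contiguous).
#' @return An object of class `wf_score_spec`.
#' @export
static_score_spec <- function(components) {
  if (!length(components)) stop_validation("score needs >= 1 component")
  for (cmp in components) {
    if (is.null(cmp$input) || is.null(cmp$bands))
      stop_validation("each component needs input and bands")
    b <- cmp$bands
    if (!all(c("lo", "hi", "points") %in% names(b)))
      stop_validation("bands need lo/hi/points columns")
    o <- order(b$lo)
    b <- b[o, ]
    if (b$lo[1] != -Inf || b$hi[nrow(b)] != Inf ||
        (nrow(b) > 1 && any(b$hi[-nrow(b)] != b$lo[-1])))
      stop_validation("bands of '%s' must partition the real line", cmp$input)
    if (!all(is.finite(b$points)))
      stop_validation("band points must be finite")
  }
  structure(list(components = components), class = "wf_score_spec")
}

band_points <- function(x, bands) {
  i <- findInterval(x, bands$lo[order(bands$lo)])
  bands[order(bands$lo), ]$points[i]
}

#' Compute a static linear score for one synchronized frame
#'
#' `H = sum_i w_i * band_i(x_i)` over the spec's components. A frame missing
#' any required input yields `NA` (no score at that frame).
#'
#' @param frame named list (or one-row [synchronize()] data.frame) of input
#'   values.
#' @param spec a [static_score_spec()].
#' @return Numeric score, with the per-component contribution vector as the
#'   `"contributions"` attribute; `NA` when an input is absent.
#' @examples
#' spec <- static_score_spec(list(list(
#'   input = "SBP", weight = 1,
#'   bands = data.frame(lo = c(-Inf, 90), hi = c(90, Inf), points = c(3, 0)))))
#' static_score(list(SBP = 85), spec)
#' @export
static_score <- function(frame, spec) {
  if (!inherits(spec, "wf_score_spec")) stop_validation("not a wf_score_spec")
  vals <- vapply(spec$components, function(cmp) {
    x <- frame[[cmp$input]]
    if (is.null(x) || length(x) != 1L || is.na(x)) return(NA_real_)
    (cmp$weight %||% 1) * band_points(x, cmp$bands)
  }, numeric(1))
  if (anyNA(vals)) {
    out <- NA_real_
  } else {
    out <- sum(vals)
  }
  attr(out, "contributions") <-
    stats::setNames(vals, vapply(spec$components,
                                 function(cmp) cmp$input, character(1)))
  out
}

#' Score every complete frame of a synchronized series
#'
#' @param frames a [synchronize()] result.
#' @param spec a [static_score_spec()].
#' @return data.frame `time`, `value` (score; `NA` rows dropped).
#' @export
static_score_series <- function(frames, spec) {
  vals <- vapply(seq_len(nrow(frames)), function(i)
    as.numeric(static_score(as.list(frames[i, ]), spec)), numeric(1))
  keep <- !is.na(vals)
  data.frame(time = frames$t_ref[keep], value = vals[keep])
}
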