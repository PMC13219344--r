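# Data-defined clinical scale calculators. A scale is a sum-of-points table:
# named components whose categorical levels map to integer points, plus
# interpretation bands over the achievable total. Definitions ship as JSON
# fixtures (GCS and PSH-AM are bundled) and are user-replaceable; the
# calculator itself is table-driven and scale-agnostic.

#' Load a scale definition from a JSON fixture
#'
#' Fixture schema: `{scale_id, components: [{name, levels: {label:
#' points}}], bands: [{lo, hi, label}]}`. Every level must map to exactly
#' one finite point value; interpretation bands must be non-overlapping,
#' gap-free at integer resolution, and cover the achievable score range.
#'
#' @param path fixture file. Bundled fixtures live under
#'   `system.file("extdata/scales", package = "wardforge")`.
#' @return An object of class `wf_scale` with `min_total` / `max_total`
#'   computed from the table.
#' @examples
#' gcs <- load_scale(system.file("extdata/scales/gcs.json",
#'                               package = "wardforge"))
#' gcs$max_total
#' @export
load_scale <- function(path) {
  if (!file.exists(path)) stop_io("scale fixture not found: %s", path)
  def <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(def$scale_id) || is.null(def$components))
    stop_validation("%s: fixture needs scale_id and components", path)
  comps <- def$components
  if (!length(comps)) stop_validation("%s: components list is empty", path)
  comps <- lapply(comps, function(cmp) {
    if (is.null(cmp$name) || is.null(cmp$levels) || !length(cmp$levels))
      stop_validation("%s: component needs a name and non-empty levels", path)
    pts <- vapply(cmp$levels, function(p) {
      if (is.null(p) || !is.numeric(p) || length(p) != 1L || is.na(p))
        stop_validation("%s: component '%s' has a level without a point value",
                        path, cmp$name)
      as.numeric(p)
    }, numeric(1))
    list(name = cmp$name, levels = pts)
  })
  min_total <- sum(vapply(comps, function(c) min(c$levels), numeric(1)))
  max_total <- sum(vapply(comps, function(c) max(c$levels), numeric(1)))
  bands <- NULL
  if (!is.null(def$bands) && length(def$bands)) {
    bands <- do.call(rbind, lapply(def$bands, function(b)
      data.frame(lo = as.numeric(b$lo), hi = as.numeric(b$hi),
                 label = as.character(b$label), stringsAsFactors = FALSE)))
    bands <- bands[order(bands$lo), ]
    if (any(bands$hi < bands$lo))
      stop_validation("%s: band with hi < lo", path)
    n <- nrow(bands)
    if (n > 1 && any(bands$lo[-1] <= bands$hi[-n]))
      stop_validation("%s: overlapping interpretation bands", path)
    if (n > 1 && any(bands$lo[-1] > bands$hi[-n] + 1))
      stop_validation("%s: gap between interpretation bands", path)
    if (bands$lo[1] > min_total || bands$hi[n] < max_total)
      stop_validation("%s: bands do not cover achievable range [%g, %g]",
                      path, min_total, max_total)
  }
  structure(list(scale_id = def$scale_id, components = comps, bands = bands,
                 min_total = min_total, max_total = max_total),
            class = "wf_scale")
}

#' @export
print.wf_scale <- function(x, ...) {
  cat(sprintf("<wf_scale> %s: %d components, total range [%g, %g]\n",
              x$scale_id, length(x$components), x$min_total, x$max_total))
  invisible(x)
}

#' Score a set of observations on a loaded scale
#'
#' @param observations named list or character vector mapping every
#'   component name to one of its level labels.
#' @param scale a [load_scale()] definition.
#' @param time optional timestamp echoed in the result.
#' @return An object of class `wf_scale_result`: `scale_id`, `time`,
#'   `points` (per component), `total`, `interpretation`.
#' @examples
#' gcs <- load_scale(system.file("extdata/scales/gcs.json",
#'                               package = "wardforge"))
#' score_scale(c(eye = "spontaneous", verbal = "oriented",
#'               motor = "obeys_commands"), gcs)
#' @export
score_scale <- function(observations, scale, time = NA_real_) {
  if (!inherits(scale, "wf_scale")) stop_validation("not a wf_scale")
  obs <- as.list(observations)
  pts <- vapply(scale$components, function(cmp) {
    lvl <- obs[[cmp$name]]
    if (is.null(lvl))
      stop_validation("component '%s' not observed", cmp$name)
    if (!lvl %in% names(cmp$levels))
      stop_validation("unknown level '%s' for component '%s'", lvl, cmp$name)
    cmp$levels[[lvl]]
  }, numeric(1))
  names(pts) <- vapply(scale$components, `[[`, character(1), "name")
  total <- sum(pts)
  interp <- NA_character_
  if (!is.null(scale$bands)) {
    hit <- which(total >= scale$bands$lo & total <= scale$bands$hi)
    if (length(hit)) interp <- scale$bands$label[hit[1]]
  }
  structure(list(scale_id = scale$scale_id, time = time, points = pts,
                 total = total, interpretation = interp),
            class = "wf_scale_result")
}

#' @export
print.wf_scale_result <- function(x, ...) {
  cat(sprintf("<wf_scale_result> %s total %g (%s)\n", x$scale_id, x$total,
              x$interpretation))
  invisible(x)
}
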