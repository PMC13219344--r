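# Internal helpers: classed conditions, seed derivation, small validators.

wf_stop <- function(class, fmt, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(class, "wf_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = call)
  ))
}

stop_validation <- function(fmt, ...) wf_stop("wf_validation_error", fmt, ...)
stop_parse      <- function(fmt, ...) wf_stop("wf_parse_error", fmt, ...)
stop_config     <- function(fmt, ...) wf_stop("wf_config_error", fmt, ...)
stop_lookup     <- function(fmt, ...) wf_stop("wf_lookup_error", fmt, ...)
stop_io         <- function(fmt, ...) wf_stop("wf_io_error", fmt, ...)

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop_validation("`%s` must be a single number in [%s, %s], got %s",
                    name, format(lo), format(hi), deparse(x))
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_validation("`%s` must be TRUE or FALSE", name)
  invisible(x)
}

#' Derive a reproducible sub-seed from a base seed
#'
#' Splits one user-facing seed into independent per-unit seeds (per patient,
#' per run, per stage) so that unit `k` is reproducible in isolation without
#' consuming the global RNG stream. A multiplicative integer hash keeps the
#' result inside the 31-bit range `set.seed()` accepts.
#'
#' @param seed base integer seed.
#' @param k non-negative integer index of the sub-stream.
#' @param salt optional extra integer separating stages that share `k`.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k, salt = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.numeric(seed) %% m
  # iterated affine mixing; doubles hold products of < 2^31 * 48271 exactly
  s <- (s * 48271 + 1) %% m
  s <- (s + as.numeric(k) * 69621) %% m
  s <- (s * 16807 + as.numeric(salt) * 7) %% m
  s <- (s * 48271) %% m
  as.integer(s)
}

# Run code under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
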