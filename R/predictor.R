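# Predictor handles and the reference recurrent model. A handle wraps any
# window-level classifier behind a fixed contract: an ordered channel list,
# a sequence layout, normalization statistics, and an output semantic
# (probability in [0, 1]). The bundled reference model is a compact stacked
# LSTM (two recurrent layers of 64 and 32 units, dropout 0.2 between them)
# trained on labeled cohort windows.

#' Create a predictor handle
#'
#' @param model_id identifier.
#' @param type `"lstm_binary"` (bundled reference model), `"constant"`
#'   (fixed output, for stubs and smoke tests), or `"function"` (any
#'   `f(X) -> probs` supplied in `fn`).
#' @param input_channels ordered channel names forming the feature tensor.
#' @param seq_len time steps per window the model expects.
#' @param norm list with per-channel `mean` and `sd` used to z-score inputs.
#' @param weights model weights (lstm_binary).
#' @param hidden hidden layer sizes (lstm_binary).
#' @param dropout dropout rate used between the recurrent layers in training.
#' @param constant_value output of a `"constant"` predictor.
#' @param fn function for `"function"` type.
#' @param threshold decision threshold chosen at training time (optional).
#' @param output output semantics; only `"probability"` is defined.
#' @return An object of class `wf_predictor`.
#' @export
predictor_handle <- function(model_id, type = c("lstm_binary", "constant",
                                                "function"),
                             input_channels = character(), seq_len = 1L,
                             norm = NULL, weights = NULL,
                             hidden = c(64L, 32L), dropout = 0.2,
                             constant_value = 0.5, fn = NULL,
                             threshold = NA_real_,
                             output = "probability") {
  type <- match.arg(type)
  if (type == "lstm_binary" && is.null(weights))
    stop_config("lstm_binary handle needs weights")
  if (type == "function" && !is.function(fn))
    stop_config("function handle needs fn")
  structure(list(model_id = model_id, type = type,
                 input_channels = input_channels, seq_len = as.integer(seq_len),
                 norm = norm, weights = weights,
                 hidden = as.integer(hidden), dropout = dropout,
                 constant_value = constant_value, fn = fn,
                 threshold = threshold, output = output),
            class = "wf_predictor")
}

#' @export
print.wf_predictor <- function(x, ...) {
  cat(sprintf("<wf_predictor> %s [%s]", x$model_id, x$type))
  if (x$type == "lstm_binary")
    cat(sprintf(": LSTM %s, dropout %.2g, %d channels x %d steps",
                paste(x$hidden, collapse = "+"), x$dropout,
                length(x$input_channels), x$seq_len))
  cat("\n")
  invisible(x)
}

#' Predict window probabilities from a handle
#'
#' @param object a [predictor_handle()].
#' @param newdata numeric array `(n, seq_len, n_channels)` of normalized or
#'   raw features; raw features are normalized with the handle's stats.
#' @param raw set `FALSE` if `newdata` is already normalized.
#' @param ... unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.wf_predictor <- function(object, newdata, raw = TRUE, ...) {
  X <- newdata
  if (length(dim(X)) != 3L)
    stop_config("predictor input must be an (n, seq_len, channels) array")
  if (dim(X)[2] != object$seq_len ||
      (length(object$input_channels) &&
       dim(X)[3] != length(object$input_channels)))
    stop_config("feature arity mismatch: model '%s' expects %d steps x %d channels",
                object$model_id, object$seq_len,
                length(object$input_channels))
  if (object$type == "constant") return(rep(object$constant_value, dim(X)[1]))
  if (object$type == "function") return(object$fn(X))
  if (raw && !is.null(object$norm)) X <- normalize_tensor(X, object$norm)
  as.numeric(.lstm_forward(object$weights, X))
}

normalize_tensor <- function(X, norm) {
  for (j in seq_len(dim(X)[3]))
    X[, , j] <- (X[, , j] - norm$mean[j]) / norm$sd[j]
  X
}

#' Persist / restore a predictor handle as a JSON artifact
#'
#' The artifact directory holds `handle.json` (feature order, layout,
#' normalization, output semantics) and `weights.json`.
#'
#' @param handle a [predictor_handle()].
#' @param dir artifact directory.
#' @return `dir` (save) or the handle (load).
#' @export
save_predictor <- function(handle, dir) {
  if (handle$type != "lstm_binary")
    stop_config("only lstm_binary handles are persisted")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- handle[c("model_id", "type", "input_channels", "seq_len", "norm",
                   "hidden", "dropout", "threshold", "output")]
  jsonlite::write_json(meta, file.path(dir, "handle.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(lapply(handle$weights, unclass),
                       file.path(dir, "weights.json"), digits = NA)
  invisible(dir)
}

#' @rdname save_predictor
#' @param dir artifact directory containing `handle.json` and `weights.json`.
#' @export
load_predictor <- function(dir) {
  hp <- file.path(dir, "handle.json")
  wp <- file.path(dir, "weights.json")
  if (!file.exists(hp) || !file.exists(wp))
    stop_io("predictor artifact incomplete under %s", dir)
  meta <- jsonlite::fromJSON(hp)
  w <- jsonlite::fromJSON(wp)
  w$b1 <- as.numeric(w$b1); w$b2 <- as.numeric(w$b2)
  w$w_out <- as.numeric(w$w_out); w$b_out <- as.numeric(w$b_out)
  w$W1 <- as.matrix(w$W1); w$W2 <- as.matrix(w$W2)
  predictor_handle(meta$model_id, "lstm_binary",
                   input_channels = meta$input_channels,
                   seq_len = meta$seq_len,
                   norm = list(mean = as.numeric(meta$norm$mean),
                               sd = as.numeric(meta$norm$sd)),
                   weights = w, hidden = meta$hidden, dropout = meta$dropout,
                   threshold = meta$threshold %||% NA_real_,
                   output = meta$output)
}

# ---------------------------------------------------------------------------
# Windowed multichannel feature tensors and ground-truth window labels.

#' Extract a windowed multichannel feature tensor from a stream
#'
#' Windows are trailing `(t_end - width, t_end]` intervals stepped by
#' `step_ms`. Each channel is linearly interpolated over its ok-quality
#' samples onto `seq_len` evenly spaced points per window, bridging missing
#' and artifact-flagged samples.
#'
#' @param stream a [unified_stream()].
#' @param channels ordered channel names.
#' @param width_ms,step_ms window geometry.
#' @param seq_len points per window.
#' @return `list(t_end = <numeric>, X = <array (n, seq_len, channels)>)`.
#' @export
windowed_features <- function(stream, channels, width_ms, step_ms,
                              seq_len = 10L) {
  ref <- get_channel(stream, channels[1])
  slices <- window_slices(ref, temporal_window(width_ms), step_ms)
  t_end <- vapply(slices, `[[`, numeric(1), "t_end")
  n <- length(t_end)
  offs <- (seq_len(seq_len) - 0.5) / seq_len * width_ms
  grid <- rep(t_end - width_ms, each = seq_len) + offs # n * seq_len points
  X <- array(NA_real_, dim = c(n, seq_len, length(channels)))
  for (j in seq_along(channels)) {
    ts <- get_channel(stream, channels[j])
    oi <- ok_idx(ts)
    if (length(oi) < 2L)
      stop_validation("channel '%s' has < 2 usable samples", channels[j])
    v <- stats::approx(ts$times[oi], ts$values[oi], xout = grid,
                       rule = 2)$y
    X[, , j] <- matrix(v, nrow = n, byrow = TRUE)
  }
  list(t_end = t_end, X = X)
}

# Overlap labeling: a window is positive when its overlap with a truth
# episode reaches 50% of the shorter of (window width, episode duration), so
# short episodes inside long windows still count and long episodes covering
# a window count too.
label_windows <- function(t_end, width_ms, episodes) {
  if (!length(episodes)) return(rep(FALSE, length(t_end)))
  t_start <- t_end - width_ms
  lab <- rep(FALSE, length(t_end))
  for (ep in episodes) {
    e0 <- ep$onset; e1 <- ep$onset + ep$duration_min * 60000
    ov <- pmin(t_end, e1) - pmax(t_start, e0)
    need <- 0.5 * min(width_ms, e1 - e0)
    lab <- lab | (ov >= need)
  }
  lab
}

#' Training configuration for the reference model
#'
#' @param channels ordered input channels.
#' @param width_ms,step_ms assessment window geometry.
#' @param seq_len time steps per window fed to the LSTM.
#' @param hidden recurrent layer sizes.
#' @param dropout dropout rate between the recurrent layers.
#' @param epochs_max maximum training epochs; 5-fold cross-validation picks
#'   the early-stop epoch within this budget.
#' @param batch minibatch size.
#' @param lr Adam learning rate.
#' @param folds cross-validation folds over the training patients.
#' @param train_frac fraction of patients in the training pool (the rest is
#'   a held-out validation set; the split is by patient, never by window).
#' @param seed RNG seed for initialisation, shuffling and dropout.
#' @return A list of class `wf_train_config`.
#' @export
reference_train_config <- function(channels = c("HR", "SBP", "RR", "Temp",
                                                "SpO2"),
                                   width_ms = 1800e3, step_ms = 1800e3,
                                   seq_len = 10L, hidden = c(64L, 32L),
                                   dropout = 0.2, epochs_max = 6L,
                                   batch = 128L, lr = 0.003, folds = 5L,
                                   train_frac = 0.8, seed = 1L) {
  structure(list(channels = channels, width_ms = width_ms, step_ms = step_ms,
                 seq_len = as.integer(seq_len), hidden = as.integer(hidden),
                 dropout = dropout, epochs_max = as.integer(epochs_max),
                 batch = as.integer(batch), lr = lr, folds = as.integer(folds),
                 train_frac = train_frac, seed = as.integer(seed)),
            class = "wf_train_config")
}

# Assemble the window dataset for a set of patients.
cohort_windows <- function(cohort, cfg, patients = names(cohort$streams)) {
  xs <- list(); ys <- list(); pid <- list(); tend <- list()
  for (p in patients) {
    wf <- windowed_features(cohort$streams[[p]], cfg$channels, cfg$width_ms,
                            cfg$step_ms, cfg$seq_len)
    xs[[p]] <- wf$X
    ys[[p]] <- label_windows(wf$t_end, cfg$width_ms, cohort$truth[[p]])
    pid[[p]] <- rep(p, length(wf$t_end))
    tend[[p]] <- wf$t_end
  }
  ns <- vapply(xs, function(x) dim(x)[1], integer(1))
  X <- array(NA_real_, dim = c(sum(ns), cfg$seq_len, length(cfg$channels)))
  at <- 0L
  for (p in patients) {
    X[at + seq_len(ns[[p]]), , ] <- xs[[p]]
    at <- at + ns[[p]]
  }
  list(X = X, y = unlist(ys, use.names = FALSE),
       patient = unlist(pid, use.names = FALSE),
       t_end = unlist(tend, use.names = FALSE))
}

# Youden's J optimal threshold on (probs, labels).
youden_threshold <- function(p, y) {
  cand <- sort(unique(round(p, 4)))
  if (length(cand) > 200) cand <- stats::quantile(p, probs = seq(0, 1, length.out = 200),
                                                  names = FALSE)
  j <- vapply(cand, function(th) {
    pred <- p >= th
    sens <- if (any(y)) mean(pred[y]) else NA_real_
    spec <- if (any(!y)) mean(!pred[!y]) else NA_real_
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Train the reference recurrent model on a labeled cohort
#'
#' Windows are labeled positive when they overlap a ground-truth episode by
#' at least 50% (of the shorter of window and episode). Patients are split
#' 80/20 into a training pool and a held-out validation set (no patient
#' appears on both sides); 5-fold cross-validation over the training pool
#' selects the early-stop epoch, after which the model is refit on the full
#' pool for that many epochs. The decision threshold is chosen by Youden's J
#' on the pooled out-of-fold predictions.
#'
#' @param cohort a [generate_cohort()] result with both classes present.
#' @param cfg a [reference_train_config()].
#' @return A [predictor_handle()] with attributes `cv` (per-epoch fold
#'   losses), `holdout` (held-out accuracy/sensitivity/specificity at the
#'   chosen threshold) and `split` (patient id partition).
#' @export
train_reference_model <- function(cohort, cfg = reference_train_config()) {
  if (!inherits(cfg, "wf_train_config")) stop_validation("not a wf_train_config")
  patients <- names(cohort$streams)
  n_pat <- length(patients)
  if (n_pat < cfg$folds + 1L)
    stop_validation("need more patients than folds")

  split <- with_seed(derive_seed(cfg$seed, 1L, salt = 11L), {
    train_ids <- sort(sample(patients, round(cfg$train_frac * n_pat)))
    list(train = train_ids, validation = setdiff(patients, train_ids))
  })
  data <- cohort_windows(cohort, cfg)
  if (length(unique(data$y)) < 2L)
    wf_stop("wf_training_error", "cohort windows are single-class; cannot train")

  in_train <- data$patient %in% split$train
  norm <- list(
    mean = vapply(seq_along(cfg$channels), function(j)
      mean(data$X[in_train, , j]), numeric(1)),
    sd = vapply(seq_along(cfg$channels), function(j) {
      s <- stats::sd(data$X[in_train, , j]); if (s > 0) s else 1
    }, numeric(1))
  )
  Xn <- normalize_tensor(data$X, norm)

  # 5 disjoint patient folds covering the training pool exactly once
  folds <- with_seed(derive_seed(cfg$seed, 2L, salt = 11L), {
    ids <- sample(split$train)
    split(ids, rep(seq_len(cfg$folds), length.out = length(ids)))
  })

  fold_val_loss <- matrix(NA_real_, nrow = cfg$epochs_max, ncol = cfg$folds)
  oof_p <- rep(NA_real_, sum(in_train))
  oof_y <- data$y[in_train]
  train_rows <- which(in_train)
  for (f in seq_len(cfg$folds)) {
    va_pat <- folds[[f]]
    tr_rows <- which(in_train & !(data$patient %in% va_pat))
    va_rows <- which(data$patient %in% va_pat)
    w0 <- .lstm_init(length(cfg$channels), cfg$hidden[1], cfg$hidden[2],
                     derive_seed(cfg$seed, f, salt = 12L))
    fit <- .lstm_train(w0, Xn[tr_rows, , , drop = FALSE],
                       as.numeric(data$y[tr_rows]), cfg$epochs_max,
                       cfg$batch, cfg$lr, cfg$dropout,
                       derive_seed(cfg$seed, f, salt = 13L),
                       Xn[va_rows, , , drop = FALSE],
                       as.numeric(data$y[va_rows]))
    fold_val_loss[, f] <- fit$val_loss
    oof_p[match(va_rows, train_rows)] <-
      as.numeric(.lstm_forward(fit$weights, Xn[va_rows, , , drop = FALSE]))
  }
  best_epoch <- which.min(rowMeans(fold_val_loss))

  w0 <- .lstm_init(length(cfg$channels), cfg$hidden[1], cfg$hidden[2],
                   derive_seed(cfg$seed, 0L, salt = 12L))
  fit <- .lstm_train(w0, Xn[train_rows, , , drop = FALSE],
                     as.numeric(data$y[train_rows]), best_epoch,
                     cfg$batch, cfg$lr, cfg$dropout,
                     derive_seed(cfg$seed, 0L, salt = 13L))
  threshold <- youden_threshold(oof_p, oof_y)

  handle <- predictor_handle("psh_reference_lstm", "lstm_binary",
                             input_channels = cfg$channels,
                             seq_len = cfg$seq_len, norm = norm,
                             weights = fit$weights, hidden = cfg$hidden,
                             dropout = cfg$dropout, threshold = threshold)
  va_rows <- which(!in_train)
  hold <- NULL
  if (length(va_rows)) {
    pv <- as.numeric(.lstm_forward(fit$weights, Xn[va_rows, , , drop = FALSE]))
    yv <- data$y[va_rows]
    pred <- pv >= threshold
    hold <- c(accuracy = mean(pred == yv),
              sensitivity = if (any(yv)) mean(pred[yv]) else NA_real_,
              specificity = if (any(!yv)) mean(!pred[!yv]) else NA_real_)
  }
  attr(handle, "cv") <- list(val_loss = fold_val_loss,
                             best_epoch = best_epoch, folds = folds)
  attr(handle, "holdout") <- hold
  attr(handle, "split") <- split
  handle
}
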