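#' Fit the seizure-detection Transformer
#'
#' Trains the channel-token Transformer encoder on a set of labelled
#' rhythm-energy feature maps (one channels x 12 matrix per 4-s epoch,
#' from [build_feature_map()]). Optimisation minimises cross-entropy with
#' Adam, minibatches, and early stopping on a held-out validation split;
#' the best-validation parameters are kept. All randomness
#' (initialisation, split, shuffling, dropout) is driven by
#' `config$seed`, so refitting with the same seed reproduces the
#' parameters bit for bit.
#'
#' @param x list of feature matrices (channels x `d_model`), one per
#'   segment. Channel counts may differ between segments; the encoder has
#'   no positional encoding and the classifier max-pools over channels.
#' @param y labels: 0/1 vector (1 = seizure) or a factor with two levels
#'   (second level = seizure).
#' @param config an [encoder_config()].
#' @param normalize fit per-feature normalisation on `x` and store the
#'   statistics in the model for reuse at prediction time (see
#'   [normalize_features()]).
#' @param verbose print per-epoch losses.
#' @return An object of class `"seizure_transformer"`: a list with
#'   `params`, `config`, `history` (per-epoch train/validation loss),
#'   `best_epoch`, `feature_stats`, and `n_params`. Methods: `print`,
#'   `summary`, `predict`, `coef`, `plot`, [channel_attention()].
#' @examples
#' \donttest{
#' rec <- generate_eeg_record(duration_s = 240, n_channels = 4,
#'                            n_seizures = 2, seed = 7)
#' ds <- segment_record(rec, mode = "balanced", seed = 7)
#' fit <- seizure_transformer(featurize_dataset(ds)$maps, ds$labels,
#'                            encoder_config(n_layers = 2, max_epochs = 30))
#' }
#' @export
seizure_transformer <- function(x, y, config = encoder_config(),
                                normalize = TRUE, verbose = FALSE) {
  if (is.matrix(x)) x <- list(x)
  stopifnot(is.list(x), length(x) >= 2)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (length(y) != length(x)) stop("length(x) != length(y)")
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1 or a 2-level factor")
  if (length(unique(y)) < 2L) {
    stop("training data contain a single class; both classes are required")
  }
  widths <- vapply(x, ncol, integer(1))
  if (any(widths != config$d_model)) {
    stop("feature maps must have d_model = ", config$d_model, " columns")
  }

  feature_stats <- NULL
  if (normalize) {
    nf <- normalize_features(x)
    x <- nf$maps
    feature_stats <- nf$stats
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  n <- length(x)
  n_val <- max(0L, round(config$val_fraction * n))
  idx <- sample.int(n)
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- setdiff(idx, val_idx)
  # early stopping needs both classes in the monitor set
  if (n_val > 0 && length(unique(y[val_idx])) < 2L) {
    val_idx <- integer(0)
    tr_idx <- idx
  }

  params <- init_params(config)
  mstate <- zero_like(params)
  vstate <- zero_like(params)
  step <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  eval_loss <- function(ids) {
    mean(vapply(ids, function(i) {
      sample_loss(model_forward(x[[i]], params, config)$prob, y[i])
    }, numeric(1)))
  }

  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(tr_idx)
    batch_losses <- numeric(0)
    for (b0 in seq(1L, length(ord), by = config$batch_size)) {
      ids <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
      grad <- zero_like(params)
      loss <- 0
      for (i in ids) {
        fw <- model_forward(x[[i]], params, config, training = TRUE)
        loss <- loss + sample_loss(fw$prob, y[i])
        gi <- model_backward(x[[i]], y[i], fw, params, config)
        grad <- map_params(`+`, grad, gi)
      }
      m <- length(ids)
      grad <- map_params(function(g) g / m, grad)
      loss <- loss / m
      step <- step + 1L
      mstate <- map_params(function(ms, g) b1 * ms + (1 - b1) * g,
                           mstate, grad)
      vstate <- map_params(function(vs, g) b2 * vs + (1 - b2) * g^2,
                           vstate, grad)
      c1 <- 1 - b1^step; c2 <- 1 - b2^step
      params <- map_params(function(p, ms, vs) {
        p - config$lr * (ms / c1) / (sqrt(vs / c2) + eps)
      }, params, mstate, vstate)
      batch_losses <- c(batch_losses, loss)
    }
    train_loss <- mean(batch_losses)
    monitor <- if (length(val_idx) > 0) eval_loss(val_idx) else
      eval_loss(tr_idx)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = train_loss,
                                val_loss = monitor))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f",
                      epoch, train_loss, monitor))
    }
    if (monitor < best$loss - 1e-4) {   # min improvement to reset patience
      best <- list(loss = monitor, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  structure(list(params = best$params, config = config,
                 history = history, best_epoch = best$epoch,
                 feature_stats = feature_stats,
                 n_params = n_encoder_params(config),
                 n_train = length(tr_idx), n_val = length(val_idx)),
            class = "seizure_transformer")
}

#' Predict seizure probabilities for feature maps
#'
#' @param object a fitted [seizure_transformer()].
#' @param newdata list of feature matrices (channels x 12) or a single
#'   matrix. If the model stored normalisation statistics they are
#'   applied automatically; pass raw (unnormalised) feature maps.
#' @param type `"prob"` for an n x 2 probability matrix, `"class"` for a
#'   0/1 vector (threshold 0.5 on the seizure column), `"score"` for the
#'   seizure-probability vector.
#' @param attention also return the final-layer attention state; the
#'   result then carries an `"attention"` attribute (list, one entry per
#'   segment, each a list over layers of per-head matrices).
#' @param ... unused.
#' @return See `type`.
#' @export
predict.seizure_transformer <- function(object, newdata,
                                        type = c("prob", "class", "score"),
                                        attention = FALSE, ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) newdata <- list(newdata)
  if (!is.null(object$feature_stats)) {
    newdata <- normalize_features(newdata, stats = object$feature_stats)$maps
  }
  att <- if (attention) vector("list", length(newdata)) else NULL
  probs <- matrix(NA_real_, length(newdata), 2,
                  dimnames = list(NULL, c("non_seizure", "seizure")))
  for (i in seq_along(newdata)) {
    fw <- model_forward(newdata[[i]], object$params, object$config)
    probs[i, ] <- fw$prob
    if (attention) att[[i]] <- fw$enc$attention
  }
  out <- switch(type,
                prob = probs,
                class = as.integer(probs[, "seizure"] >= 0.5),
                score = probs[, "seizure"])
  if (attention) attr(out, "attention") <- att
  out
}

#' Per-channel attention weights
#'
#' Recovers which EEG channels the encoder attends to: the `h` head
#' matrices of the final encoder layer are summed and each column of the
#' summed matrix is averaged, giving one nonnegative weight per channel.
#' Channels with high weight are those the model treats as most
#' informative for the seizure decision.
#'
#' @param object either a fitted [seizure_transformer()] (then supply
#'   `newdata`, a feature map or list of maps, and weights are averaged
#'   over segments) or a raw attention state (list over layers of lists
#'   over heads of channel x channel matrices).
#' @param ... passed on; for the model method, `newdata`.
#' @return Numeric vector of channel weights (named when channel names
#'   are available).
#' @export
channel_attention <- function(object, ...) UseMethod("channel_attention")

#' @rdname channel_attention
#' @export
channel_attention.default <- function(object, ...) {
  last <- object[[length(object)]]
  summed <- Reduce(`+`, last)
  colMeans(summed)
}

#' @rdname channel_attention
#' @param newdata feature map(s) to compute attention on.
#' @export
channel_attention.seizure_transformer <- function(object, newdata, ...) {
  if (is.matrix(newdata)) newdata <- list(newdata)
  pr <- predict(object, newdata, type = "score", attention = TRUE)
  ws <- lapply(attr(pr, "attention"), channel_attention.default)
  w <- Reduce(`+`, ws) / length(ws)
  names(w) <- rownames(newdata[[1]])
  w
}

#' @export
print.seizure_transformer <- function(x, ...) {
  cat("Seizure-detection Transformer encoder\n")
  cat("  layers:", x$config$n_layers, " heads:", x$config$h,
      " d_model:", x$config$d_model, " block:", x$config$block, "\n")
  cat("  parameters:", x$n_params, "\n")
  cat("  trained", nrow(x$history), "epochs (best epoch", x$best_epoch,
      "), final val loss", sprintf("%.4f", min(x$history$val_loss)), "\n")
  invisible(x)
}

#' @export
summary.seizure_transformer <- function(object, ...) {
  structure(list(config = object$config, n_params = object$n_params,
                 history = object$history, best_epoch = object$best_epoch,
                 n_train = object$n_train, n_val = object$n_val,
                 normalized = !is.null(object$feature_stats)),
            class = "summary.seizure_transformer")
}

#' @export
print.summary.seizure_transformer <- function(x, ...) {
  print(x$config)
  cat("Trainable parameters:", x$n_params, "\n")
  cat("Training segments:", x$n_train, " validation:", x$n_val,
      if (x$normalized) " (features z-scored)" else "", "\n")
  h <- x$history
  cat(sprintf("Epochs run: %d; best epoch %d (val loss %.4f)\n",
              nrow(h), x$best_epoch, min(h$val_loss)))
  invisible(x)
}

#' @export
coef.seizure_transformer <- function(object, ...) {
  unlist(object$params)
}

#' Plot the training history
#'
#' @param x a fitted [seizure_transformer()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.seizure_transformer <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "Epoch", ylab = "Cross-entropy loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
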