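#' Training configuration
#'
#' The optimization recipe (Adam, initial learning rate 0.002, batch size
#' 32, 50 epochs, no schedule or early stopping; the last-epoch model is
#' evaluated) plus the preprocessing and ablation switches. Reduced
#' `epochs` values are appropriate for the scaled-down synthetic
#' experiments.
#'
#' @param lr Adam learning rate.
#' @param batch_size Trials per mini-batch.
#' @param epochs Training epochs.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @param view,backbone,pretrained,weights_file,use_transformer,n_layers,n_heads,ff_mult,dropout,positional_encoding,fusion_init
#'   Passed to [model_config()].
#' @param low,high Bandpass edges (Hz) for the scalogram view.
#' @param slice_s Slice length in seconds.
#' @param tfr_norm Scalogram scaling: `"per_dataset"` (z-standardize by
#'   training-set mean/sd, amplitude-preserving), `"per_map"` (each
#'   channel map divided by its own maximum, scale-invariant) or
#'   `"none"`.
#' @param raw_norm Raw-view normalization: `"zscore"` (per channel, per
#'   slice; scale-invariant) or `"scale"` (divide by one training-set RMS
#'   constant; preserves between-trial amplitude differences).
#' @return A `train_config` object.
#' @export
train_config <- function(lr = 0.002, batch_size = 32L, epochs = 50L,
                         seed = 1L,
                         view = "fused", backbone = "shuffle_micro",
                         pretrained = FALSE, weights_file = NULL,
                         use_transformer = TRUE, n_layers = 2L,
                         n_heads = 4L, ff_mult = 4L, dropout = 0.1,
                         positional_encoding = "sinusoidal",
                         fusion_init = "identity_zero",
                         low = 4, high = 40, slice_s = 0.5,
                         tfr_norm = c("per_dataset", "per_map", "none"),
                         raw_norm = c("zscore", "scale")) {
  if (lr <= 0) stop("`lr` must be positive")
  if (epochs < 1) stop("`epochs` must be >= 1")
  tfr_norm <- match.arg(tfr_norm)
  raw_norm <- match.arg(raw_norm)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 view = view, backbone = backbone, pretrained = pretrained,
                 weights_file = weights_file,
                 use_transformer = use_transformer,
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 ff_mult = as.integer(ff_mult), dropout = dropout,
                 positional_encoding = positional_encoding,
                 fusion_init = fusion_init,
                 low = low, high = high, slice_s = slice_s,
                 tfr_norm = tfr_norm, raw_norm = raw_norm),
            class = "train_config")
}

as_model_config <- function(cfg) {
  model_config(view = cfg$view, backbone = cfg$backbone,
               pretrained = cfg$pretrained, weights_file = cfg$weights_file,
               use_transformer = cfg$use_transformer,
               n_layers = cfg$n_layers, n_heads = cfg$n_heads,
               ff_mult = cfg$ff_mult, dropout = cfg$dropout,
               positional_encoding = cfg$positional_encoding,
               fusion_init = cfg$fusion_init)
}

#' Train a per-subject classifier
#'
#' End-to-end optimization of the fusion convolutions, CNN encoder,
#' Transformer and head under mean cross-entropy, with Adam. One
#' prediction is made per trial (the slice sequence is one sample).
#'
#' @param train_trials A `mieeg_dataset`, or a precomputed
#'   `mieeg_features` object.
#' @param cfg A [train_config()].
#' @param verbose Print the per-epoch mean loss?
#' @return A `mieeg_fit`: list with `model` (parameters plus the
#'   feature-preparation statistics needed at test time), `history`
#'   (mean training loss per epoch) and `cfg`.
#' @export
train_subject <- function(train_trials, cfg = train_config(),
                          verbose = FALSE) {
  feats <- if (inherits(train_trials, "mieeg_features")) train_trials
  else prepare_features(train_trials, cfg)
  labels <- feats$labels
  if (length(unique(labels)) < 2) {
    stop("training set must contain at least one trial per class")
  }
  n_trials <- length(feats$trials)
  n <- feats$n
  model <- mieeg_model(as_model_config(cfg), seed = cfg$seed, n_tokens = n)
  # fusion weights of an ablated branch are frozen at zero
  if (cfg$view == "tfr_only") {
    model$params$fus_Wr[] <- 0
    model$params$fus_br[] <- 0
  }
  if (cfg$view == "raw_only") {
    model$params$fus_Wt[] <- 0
    model$params$fus_bt[] <- 0
  }
  state <- adam_init(model$params)
  set.seed(cfg$seed)
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n_trials)
    losses <- c()
    for (start in seq(1, n_trials, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n_trials)]
      stopifnot(all(idx >= 1), all(idx <= n_trials))  # train-set indices only
      batch <- assemble_batch(feats, idx)
      fw <- model_forward(model, batch, n, train = TRUE)
      losses <- c(losses, cross_entropy_loss(fw$probs, labels[idx]))
      grads <- model_backward(model, fw, labels[idx])
      upd <- adam_step(model$params, grads, state, cfg$lr)
      model$params <- upd$params
      state <- upd$state
    }
    history[ep] <- mean(losses)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f", ep, history[ep]))
    }
  }
  model$prep <- feats$prep
  structure(list(model = model, history = history, cfg = cfg),
            class = "mieeg_fit")
}

#' @export
print.mieeg_fit <- function(x, ...) {
  cat(sprintf("MI-EEG fit: view = %s, backbone = %s, %d epochs, final loss %.4f\n",
              x$cfg$view, x$cfg$backbone, length(x$history),
              x$history[length(x$history)]))
  invisible(x)
}

#' Predict class probabilities for a dataset
#'
#' @param object A `mieeg_fit`.
#' @param newdata A `mieeg_dataset` or `mieeg_features`.
#' @param ... Unused.
#' @return Matrix of per-trial probabilities (columns left, right).
#' @export
predict.mieeg_fit <- function(object, newdata, ...) {
  feats <- if (inherits(newdata, "mieeg_features")) newdata
  else prepare_features(newdata, object$cfg, prep = object$model$prep)
  n <- feats$n
  n_trials <- length(feats$trials)
  out <- matrix(NA_real_, n_trials, 2,
                dimnames = list(NULL, c("left", "right")))
  for (start in seq(1, n_trials, by = 32L)) {
    idx <- start:min(start + 31L, n_trials)
    batch <- assemble_batch(feats, idx)
    fw <- model_forward(object$model, batch, n, train = FALSE)
    out[idx, ] <- fw$probs
  }
  out
}

#' Evaluate classification accuracy
#'
#' Per-trial argmax prediction; accuracy is `correct / total * 100`.
#'
#' @param fit A `mieeg_fit`.
#' @param test_trials A labeled `mieeg_dataset` or `mieeg_features`.
#' @return Accuracy in percent.
#' @export
evaluate <- function(fit, test_trials) {
  labels <- test_trials$labels
  if (length(labels) == 0) stop("test set is empty")
  probs <- predict(fit, test_trials)
  pred <- c("left", "right")[max.col(probs, ties.method = "first")]
  mean(pred == labels) * 100
}

#' Run an ablation grid
#'
#' Trains and evaluates every configuration on every subject and collects
#' per-subject accuracies with their mean and standard deviation, the
#' layout used for fusion-view / backbone / temporal-model comparisons.
#' Failed runs are recorded (accuracy `NA`, message kept in the
#' `"failures"` attribute), never silently dropped.
#'
#' @param datasets Named list of subjects; each element is
#'   `list(train = <mieeg_dataset>, test = <mieeg_dataset>)`.
#' @param grid Named list of [train_config()] objects.
#' @param verbose Print progress?
#' @return A `mieeg_ablation` data frame: one row per configuration,
#'   per-subject accuracy columns plus `mean` and `sd`.
#' @export
run_ablation <- function(datasets, grid, verbose = FALSE) {
  if (length(grid) == 0) stop("`grid` must contain at least one config")
  if (is.null(names(grid))) {
    names(grid) <- paste0("config", seq_along(grid))
  }
  subjects <- names(datasets)
  if (is.null(subjects)) {
    subjects <- paste0("S", seq_along(datasets))
    names(datasets) <- subjects
  }
  acc <- matrix(NA_real_, nrow = length(grid), ncol = length(subjects),
                dimnames = list(names(grid), subjects))
  failures <- list()
  for (g in names(grid)) {
    for (s in subjects) {
      res <- tryCatch({
        fit <- train_subject(datasets[[s]]$train, grid[[g]])
        evaluate(fit, datasets[[s]]$test)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[paste(g, s, sep = "/")]] <- conditionMessage(res)
      } else {
        acc[g, s] <- res
      }
      if (verbose) {
        message(sprintf("%s / %s: %s", g, s,
                        if (inherits(res, "error")) "FAILED"
                        else sprintf("%.2f%%", res)))
      }
    }
  }
  out <- data.frame(config = names(grid), acc, check.names = FALSE)
  out$mean <- apply(acc, 1, mean, na.rm = TRUE)
  out$sd <- apply(acc, 1, stats::sd, na.rm = TRUE)
  rownames(out) <- NULL
  structure(out, class = c("mieeg_ablation", "data.frame"),
            failures = failures)
}

#' @export
print.mieeg_ablation <- function(x, ...) {
  df <- as.data.frame(x)
  subj <- setdiff(names(df), c("config", "mean", "sd"))
  for (s in subj) df[[s]] <- sprintf("%.2f", df[[s]])
  df$`acc +/- sd` <- sprintf("%.2f +/- %.2f", x$mean, x$sd)
  df$mean <- NULL
  df$sd <- NULL
  print.data.frame(df, row.names = FALSE)
  fl <- attr(x, "failures")
  if (length(fl)) {
    cat("failures:\n")
    for (nm in names(fl)) cat("  ", nm, ": ", fl[[nm]], "\n", sep = "")
  }
  invisible(x)
}
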