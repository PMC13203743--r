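# The package's two standard synthetic benchmarks. Their defaults define
# the study conditions (sample sizes, effect sizes, training lengths) at
# a scale a single CPU handles in minutes; the vignette discusses the
# choices.

#' Held-out accuracy benchmark on lateralized-ERD data
#'
#' Generates independent balanced train and test sets with a
#' contralateral mu/beta event-related desynchronization of the given
#' depth, trains the full fused pipeline from random initialization, and
#' returns the held-out accuracy. With `erd_depth = 0.9` the classes are
#' strongly separable; with `erd_depth = 0` there is no class signal and
#' accuracy should sit at chance.
#'
#' @param erd_depth Fractional contralateral attenuation in `[0, 1]`.
#' @param n_train_per_class,n_test_per_class Trials per class.
#' @param epochs Training epochs (scaled-down from the full 50-epoch
#'   recipe).
#' @param seed Integer seed driving data generation and training.
#' @param cfg Optional [train_config()] overriding the defaults (its
#'   `seed`/`epochs` fields are still taken from the arguments).
#' @return List with `accuracy` (percent), `history` (training loss per
#'   epoch) and `n_test` (number of held-out trials).
#' @export
erd_benchmark <- function(erd_depth = 0.9, n_train_per_class = 100L,
                          n_test_per_class = 100L, epochs = 10L,
                          seed = 1L, cfg = NULL) {
  seed <- as.integer(seed) %% 100000L
  train <- generate_dataset(
    n_train_per_class, synth_params(erd_depth = erd_depth, seed = seed))
  test <- generate_dataset(
    n_test_per_class, synth_params(erd_depth = erd_depth,
                                   seed = seed + 50000L))
  if (is.null(cfg)) cfg <- train_config()
  cfg$epochs <- as.integer(epochs)
  cfg$seed <- seed
  fit <- train_subject(train, cfg)
  list(accuracy = evaluate(fit, test), history = fit$history,
       n_test = length(test$trials))
}

#' Fusion-view ablation on a broadband-amplitude-only class cue
#'
#' Generates data whose only class difference is a broadband
#' multiplicative gain (`erd_depth = 0`): the cue is removed from the
#' scalogram view by the 4--40 Hz bandpass plus per-map scaling, but
#' survives in the raw view under amplitude-preserving scaling. Trains
#' the fused, scalogram-only and raw-only variants for each seed and
#' returns per-view accuracies with their medians over seeds -- the
#' qualitative signature of the multi-view fusion gain.
#'
#' @param delta Broadband gain applied to left-hand trials.
#' @param n_per_class Trials per class in each training set (the shared
#'   test set uses the same size).
#' @param epochs,batch_size Scaled-down training length; smaller batches
#'   give the near-zero-initialized raw branch enough optimizer steps to
#'   be recruited.
#' @param seeds Integer seeds; each trains on its own generated dataset.
#' @return List with `accuracy` (views x seeds matrix), `median` (named
#'   per-view medians) and `gain` (median fused minus scalogram-only, in
#'   accuracy points).
#' @export
broadband_view_ablation <- function(delta = 0.5, n_per_class = 40L,
                                    epochs = 30L, batch_size = 16L,
                                    seeds = c(1L, 2L, 3L)) {
  seeds <- as.integer(seeds) %% 100000L
  views <- c("fused", "tfr_only", "raw_only")
  acc <- matrix(NA_real_, nrow = 3, ncol = length(seeds),
                dimnames = list(views, paste0("seed", seeds)))
  test <- generate_dataset(
    n_per_class, synth_params(erd_depth = 0, broadband_gain_delta = delta,
                              seed = max(seeds) + 60000L))
  for (k in seq_along(seeds)) {
    train <- generate_dataset(
      n_per_class, synth_params(erd_depth = 0,
                                broadband_gain_delta = delta,
                                seed = seeds[k]))
    for (v in views) {
      # symmetric random fusion initialization: a view comparison must not
      # privilege one branch at the start
      cfg <- train_config(epochs = epochs, batch_size = batch_size,
                          seed = seeds[k], view = v,
                          tfr_norm = "per_map", raw_norm = "scale",
                          fusion_init = "random")
      fit <- train_subject(train, cfg)
      acc[v, k] <- evaluate(fit, test)
    }
  }
  med <- apply(acc, 1, stats::median)
  list(accuracy = acc, median = med,
       gain = unname(med["fused"] - med["tfr_only"]))
}
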