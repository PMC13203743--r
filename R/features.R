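# Turning epoched trials into the cached, pooled two-view features the
# trainer consumes.
#
# Per trial: a bandpass-filtered copy feeds the scalogram (CWT) view, the
# as-recorded copy feeds the raw view. Each 0.5 s slice becomes
#   - a 3 x 125 x 125 channel-stacked scalogram, optionally per-map
#     scaled, then reduced by the parameter-free 5x5 average-pool stem;
#   - a normalized raw slice, replicated along frequency and reduced by
#     the same stem (replication and pooling commute, so only the
#     time-pooled waveform is materialized).
# Both 1x1 fusion convolutions and the pool are linear, so pooling before
# fusion is exact, not an approximation.

#' Prepare pooled two-view features for a dataset
#'
#' @param dataset A `mieeg_dataset` (from [generate_dataset()] or
#'   [extract_epochs()]).
#' @param cfg A [train_config()].
#' @param prep Feature statistics from a previous (training) call; when
#'   `NULL` they are computed from this dataset.
#' @param cwt A [cwt_config()]; built from `cfg` when `NULL`.
#' @return A `mieeg_features` list: `trials` (per trial, `Xt` and `Xr`
#'   pooled view matrices of shape `(625 * n) x 3`), `labels`, `n`
#'   (slices per trial), `prep`.
#' @export
prepare_features <- function(dataset, cfg = train_config(), prep = NULL,
                             cwt = NULL) {
  if (is.null(cwt)) {
    cwt <- cwt_config(fs = dataset$trials[[1]]$fs)
  }
  stem <- 5L
  n_trials <- length(dataset$trials)
  Xt_list <- vector("list", n_trials)
  Xr_list <- vector("list", n_trials)
  n_slices <- NULL
  for (k in seq_len(n_trials)) {
    trial <- dataset$trials[[k]]
    # epochs cut from a pre-filtered continuous recording carry their
    # filtered copy; standalone trials are filtered here
    filt_data <- if (!is.null(trial$data_filtered)) trial$data_filtered
    else bandpass_filter(trial, cfg$low, cfg$high)$data
    sl_f <- slice_trial(filt_data, cfg$slice_s, fs = trial$fs)
    sl_r <- slice_trial(trial$data, cfg$slice_s, fs = trial$fs)
    n_slices <- sl_f$n
    Xt_parts <- vector("list", sl_f$n)
    Xr_parts <- vector("list", sl_f$n)
    for (i in seq_len(sl_f$n)) {
      map <- build_cdml_tfr(sl_f$slices[[i]], cwt)
      if (cfg$tfr_norm == "per_map") {
        for (c in 1:3) {
          mx <- max(map[c, , ])
          if (mx > 1e-12) map[c, , ] <- map[c, , ] / mx
        }
      }
      Xt_parts[[i]] <- pool_view_tensor(map, stem)
      raw <- sl_r$slices[[i]]
      if (cfg$raw_norm == "zscore") raw <- normalize_raw(raw)
      # time-pool the raw slice, then replicate across pooled frequency
      tp <- t(sapply(seq_len(ncol(raw) %/% stem), function(b) {
        rowMeans(raw[, ((b - 1) * stem + 1):(b * stem), drop = FALSE])
      }))                                   # (T/stem) x C
      Xr_parts[[i]] <- tp[rep(seq_len(nrow(tp)), cwt$n_freqs %/% stem), ,
                          drop = FALSE]
    }
    Xt_list[[k]] <- do.call(rbind, Xt_parts)
    Xr_list[[k]] <- do.call(rbind, Xr_parts)
  }
  if (is.null(prep)) {
    allt <- unlist(Xt_list, use.names = FALSE)
    prep <- list(
      tfr_mean = if (cfg$tfr_norm == "per_dataset") mean(allt) else 0,
      tfr_sd = if (cfg$tfr_norm == "per_dataset")
        max(stats::sd(allt), 1e-12) else 1,
      raw_scale = if (cfg$raw_norm == "scale") {
        allr <- unlist(Xr_list, use.names = FALSE)
        max(sqrt(mean(allr^2)), 1e-12)
      } else 1)
  }
  trials <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    trials[[k]] <- list(
      Xt = (Xt_list[[k]] - prep$tfr_mean) / prep$tfr_sd,
      Xr = Xr_list[[k]] / prep$raw_scale)
  }
  structure(list(trials = trials, labels = dataset$labels,
                 n = n_slices, prep = prep),
            class = "mieeg_features")
}

# Row-bind the pooled views of the selected trials into one batch.
assemble_batch <- function(features, idx) {
  list(Xt = do.call(rbind, lapply(features$trials[idx], `[[`, "Xt")),
       Xr = do.call(rbind, lapply(features$trials[idx], `[[`, "Xr")))
}
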