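#' Zero-phase Butterworth bandpass filter
#'
#' Applies a 4th-order Butterworth bandpass forward and backward
#' (`signal::filtfilt`) to every channel, giving zero phase distortion.
#' The 4--40 Hz default retains the mu (8--13 Hz) and beta (13--30 Hz)
#' sensorimotor rhythms while suppressing high-frequency EMG and
#' low-frequency drift.
#'
#' @param trial An `epoched_trial`, or a channels x samples numeric matrix.
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param fs Sampling rate; taken from the trial when available.
#' @param order Butterworth order (per lowpass/highpass section).
#' @return Same type as the input, with `data` filtered per channel.
#' @export
bandpass_filter <- function(trial, low = 4, high = 40, fs = NULL, order = 4) {
  is_trial <- inherits(trial, "epoched_trial")
  x <- if (is_trial) trial$data else trial
  if (is.null(fs)) {
    if (is_trial) fs <- trial$fs else stop("`fs` required for matrix input")
  }
  if (!(0 < low && low < high && high < fs / 2)) {
    stop("band must satisfy 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  # remove the DC offset first: it lies far below the passband and would
  # otherwise leave forward-backward edge transients
  y <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch - mean(ch))))
  if (is_trial) {
    trial$data <- y
    trial
  } else {
    y
  }
}

#' Slice a trial into contiguous fixed-length segments
#'
#' Partitions a channels x L trial into `n = L / (fs * slice_s)`
#' non-overlapping slices of `T = fs * slice_s` samples each, in temporal
#' order. A 4 s trial at 250 Hz with the default 0.5 s slice length gives
#' n = 8 slices of 125 samples. Slicing is an exact partition:
#' concatenating the slices in order reproduces the trial.
#'
#' @param trial An `epoched_trial` or a channels x L matrix.
#' @param slice_s Slice length in seconds.
#' @param fs Sampling rate; taken from the trial when available.
#' @return A `slice_sequence`: list with `slices` (list of channels x T
#'   matrices), `n`, `T`, `fs`, `slice_s`.
#' @export
slice_trial <- function(trial, slice_s = 0.5, fs = NULL) {
  x <- if (inherits(trial, "epoched_trial")) trial$data else trial
  if (is.null(fs)) {
    if (inherits(trial, "epoched_trial")) fs <- trial$fs
    else stop("`fs` required for matrix input")
  }
  T_len <- fs * slice_s
  if (abs(T_len - round(T_len)) > 1e-9) {
    stop("`fs * slice_s` must be an integer number of samples")
  }
  T_len <- as.integer(round(T_len))
  L <- ncol(x)
  if (L %% T_len != 0) {
    stop("trial length ", L, " is not divisible by the slice length ",
         T_len, " (no implicit padding)")
  }
  n <- L %/% T_len
  slices <- lapply(seq_len(n), function(i) {
    x[, ((i - 1) * T_len + 1):(i * T_len), drop = FALSE]
  })
  structure(list(slices = slices, n = n, T = T_len, fs = fs,
                 slice_s = slice_s),
            class = "slice_sequence")
}

#' Reassemble a slice sequence into the original trial matrix
#'
#' Inverse of [slice_trial()]: column-binds the slices in temporal order.
#'
#' @param sl A `slice_sequence`.
#' @return A channels x L matrix.
#' @export
unslice <- function(sl) {
  do.call(cbind, sl$slices)
}

#' Normalize a raw-view slice
#'
#' Default (`method = "zscore"`): per-channel, per-slice z-score -- each
#' channel of the slice is centred and scaled to unit sample variance.
#' Constant channels map to all zeros (epsilon guard), and the result is
#' invariant under rescaling of the input. `method = "scale"` instead
#' divides by a single externally supplied scale constant, which preserves
#' relative amplitude differences between trials -- the appropriate choice
#' when broadband amplitude itself carries class information.
#'
#' @param slice Channels x T numeric matrix.
#' @param method `"zscore"` (default) or `"scale"`.
#' @param scale Positive scalar divisor for `method = "scale"` (typically
#'   a dataset-level RMS computed on the training set).
#' @param eps Guard added to the standard deviation.
#' @return Matrix of the same shape.
#' @export
normalize_raw <- function(slice, method = c("zscore", "scale"),
                          scale = 1, eps = 1e-12) {
  method <- match.arg(method)
  if (method == "scale") {
    if (!is.numeric(scale) || scale <= 0) stop("`scale` must be positive")
    return(slice / scale)
  }
  mu <- rowMeans(slice)
  centred <- slice - mu
  sd <- sqrt(rowSums(centred^2) / max(ncol(slice) - 1, 1))
  sweep(centred, 1, pmax(sd, eps), "/") * (sd > eps)
}
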