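#' Align a raw-signal slice to the scalogram shape
#'
#' Replicates the (normalized) raw slice along a trailing frequency axis:
#' `out[c, t, f] = slice[c, t]` for every `f` -- the outer product of each
#' channel's time course with an all-ones vector of length `F`. The result
#' has exactly the shape of the channel-stacked scalogram, so the two
#' views can be fused element-wise.
#'
#' @param raw_slice 3 x T numeric matrix (normalized raw view).
#' @param F Number of frequency planes (must match the scalogram's F).
#' @return `3 x T x F` array with identical frequency planes.
#' @export
align_raw <- function(raw_slice, F = 125L) {
  if (is.null(dim(raw_slice)) || length(dim(raw_slice)) != 2) {
    stop("`raw_slice` must be a channels x T matrix")
  }
  C <- nrow(raw_slice)
  T_len <- ncol(raw_slice)
  array(rep(as.numeric(raw_slice), F), dim = c(C, T_len, F))
}

#' Default fusion weights
#'
#' Two independent 3-channel-to-3-channel 1x1 convolutions, one per view.
#' The scalogram branch starts near the identity and the raw branch near
#' zero, so an untrained fused model behaves like the scalogram-only
#' baseline and recruits the raw view during training only when it helps.
#'
#' @param init `"identity_zero"` (identity-ish TFR conv, near-zero raw
#'   conv), or `"random"` (both small random).
#' @param sd Standard deviation of the random perturbation.
#' @param channels Channel count of both views.
#' @return List with elements `tfr` and `raw`, each `list(W, b)` where `W`
#'   is channels x channels (rows = output channels) and `b` length
#'   channels.
#' @export
fusion_weights <- function(init = c("identity_zero", "random"), sd = 0.01,
                           channels = 3L) {
  init <- match.arg(init)
  if (init == "identity_zero") {
    Wt <- diag(channels) + matrix(stats::rnorm(channels^2, 0, sd), channels)
    Wr <- matrix(stats::rnorm(channels^2, 0, sd), channels)
  } else {
    Wt <- matrix(stats::rnorm(channels^2, 0, 0.5), channels)
    Wr <- matrix(stats::rnorm(channels^2, 0, 0.5), channels)
  }
  list(tfr = list(W = Wt, b = numeric(channels)),
       raw = list(W = Wr, b = numeric(channels)))
}

#' Fuse the scalogram and aligned raw views
#'
#' Each view passes through its own 1x1 convolution (a per-pixel
#' channels x channels linear map plus bias) and the results are added
#' element-wise:
#' `out[, t, f] = W_tfr %*% tfr[, t, f] + b_tfr + W_raw %*% raw[, t, f] + b_raw`.
#' Spatial dimensions are unchanged. With the raw weights zeroed and an
#' identity scalogram convolution the output equals the scalogram tensor
#' exactly, which is the time-frequency-only ablation.
#'
#' @param tfr `C x T x F` scalogram tensor.
#' @param raw_aligned `C x T x F` aligned raw tensor (same shape).
#' @param weights As returned by [fusion_weights()].
#' @return `C x T x F` fused tensor.
#' @export
fuse <- function(tfr, raw_aligned, weights = fusion_weights()) {
  dt <- dim(tfr)
  if (!identical(dt, dim(raw_aligned))) {
    stop("views must share one shape; got ", paste(dt, collapse = "x"),
         " vs ", paste(dim(raw_aligned), collapse = "x"))
  }
  C <- dt[1]
  stopifnot(identical(dim(weights$tfr$W), c(C, C)),
            identical(dim(weights$raw$W), c(C, C)))
  mt <- matrix(tfr, nrow = C)        # C x (T*F), channels vary fastest
  mr <- matrix(raw_aligned, nrow = C)
  out <- weights$tfr$W %*% mt + weights$raw$W %*% mr +
    (weights$tfr$b + weights$raw$b)
  array(out, dim = dt)
}
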