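#' Parameters for the synthetic motor-imagery EEG generator
#'
#' Bundles every knob of the synthetic trial generator. The generator
#' emulates the statistical structure a few-channel (C3/Cz/C4)
#' motor-imagery decoder relies on: band-limited mu (8--13 Hz) and beta
#' (13--30 Hz) oscillations riding on 1/f (pink) background noise, with
#' contralateral event-related desynchronization (ERD) -- left-hand
#' imagery attenuates the oscillations on C4, right-hand imagery those on
#' C3, Cz is unaffected.
#'
#' `broadband_gain_delta` multiplies the *entire* left-hand trial by
#' `1 + broadband_gain_delta`. It exists to plant a class cue that lives
#' only in broadband amplitude, which scale-invariant per-map scalogram
#' normalization removes; it drives the multi-view fusion ablation.
#'
#' @param fs Sampling rate in Hz.
#' @param n_channels Electrode count; the three channels are interpreted
#'   in the order C3, Cz, C4.
#' @param epoch_s Epoch length in seconds; `fs * epoch_s` must be an
#'   integer.
#' @param mu_band,beta_band Numeric length-2 vectors `(low, high)` in Hz.
#' @param erd_depth Fractional attenuation in `[0, 1]` of the
#'   contralateral oscillation amplitude (0 = no class signal,
#'   1 = complete suppression).
#' @param noise_level Pink-noise RMS relative to the oscillation RMS.
#' @param broadband_gain_delta Class-dependent multiplicative gain applied
#'   to the full-band signal of left-hand trials.
#' @param seed Integer RNG seed used to derive per-trial seeds.
#' @return An object of class `synth_params` (a validated list).
#' @export
#' @examples
#' p <- synth_params(erd_depth = 0.8, seed = 1)
#' trial <- generate_trial("left", p, trial_seed = 7)
#' dim(trial$data) # 3 x 1000
synth_params <- function(fs = 250, n_channels = 3, epoch_s = 4.0,
                         mu_band = c(8, 13), beta_band = c(13, 30),
                         erd_depth = 0.75, noise_level = 1.0,
                         broadband_gain_delta = 0, seed = 1L) {
  if (erd_depth < 0 || erd_depth > 1) {
    stop("`erd_depth` must lie in [0, 1], got ", erd_depth)
  }
  n_samples <- fs * epoch_s
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("`fs * epoch_s` must be an integer number of samples")
  }
  for (band in list(mu_band, beta_band)) {
    if (length(band) != 2 || band[1] <= 0 || band[2] >= fs / 2 ||
        band[1] >= band[2]) {
      stop("frequency bands must satisfy 0 < low < high < fs/2")
    }
  }
  if (noise_level < 0) stop("`noise_level` must be nonnegative")
  structure(
    list(fs = fs, n_channels = as.integer(n_channels),
         epoch_s = epoch_s, n_samples = as.integer(round(n_samples)),
         mu_band = mu_band, beta_band = beta_band,
         erd_depth = erd_depth, noise_level = noise_level,
         broadband_gain_delta = broadband_gain_delta,
         seed = as.integer(seed)),
    class = "synth_params")
}

#' @export
print.synth_params <- function(x, ...) {
  cat("Synthetic MI-EEG parameters\n")
  cat(sprintf("  fs = %g Hz, %d channels (C3, Cz, C4), epoch %g s\n",
              x$fs, x$n_channels, x$epoch_s))
  cat(sprintf("  mu band %g-%g Hz, beta band %g-%g Hz\n",
              x$mu_band[1], x$mu_band[2], x$beta_band[1], x$beta_band[2]))
  cat(sprintf("  erd_depth = %g, noise_level = %g, broadband_gain_delta = %g\n",
              x$erd_depth, x$noise_level, x$broadband_gain_delta))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

# Pink (1/f) noise of unit RMS: shape a white spectrum by 1/sqrt(f).
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  # frequency index of each FFT bin (0, 1, ..., n/2, ..., 1)
  k <- c(0, seq_len(n - 1))
  k <- pmin(k, n - k)
  amp <- c(0, 1 / sqrt(k[-1]))
  x <- Re(stats::fft(sp * amp, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Generate one labeled synthetic MI-EEG trial
#'
#' Each channel is the sum of pink noise and two sinusoidal oscillations
#' (one mu-band, one beta-band) with per-trial random frequencies and
#' per-channel random phases. The contralateral channel's oscillation
#' amplitude is scaled by `1 - erd_depth` (C4 for left-hand, C3 for
#' right-hand imagery); finally left-hand trials are multiplied by
#' `1 + broadband_gain_delta`.
#'
#' The trial is a deterministic function of `(label, params, trial_seed)`:
#' the global RNG state is saved and restored, so calling this inside
#' other randomized code does not perturb it.
#'
#' @param label `"left"` or `"right"`.
#' @param params A [synth_params()] object.
#' @param trial_seed Integer seed for this trial.
#' @return An `epoched_trial`: list with `data` (3 x n_samples matrix, rows
#'   C3, Cz, C4), `label`, `fs`, and metadata fields.
#' @export
generate_trial <- function(label, params, trial_seed) {
  if (!inherits(params, "synth_params")) params <- do.call(synth_params, params)
  if (!is.character(label) || length(label) != 1 ||
      !label %in% c("left", "right")) {
    stop("`label` must be \"left\" or \"right\"")
  }
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(trial_seed))

  n <- params$n_samples
  t <- (seq_len(n) - 1) / params$fs
  f_mu <- stats::runif(1, params$mu_band[1], params$mu_band[2])
  f_beta <- stats::runif(1, params$beta_band[1], params$beta_band[2])

  data <- matrix(0, nrow = params$n_channels, ncol = n)
  # contralateral ERD: left-hand MI attenuates C4 (row 3), right-hand C3 (row 1)
  erd_scale <- rep(1, params$n_channels)
  if (label == "left") erd_scale[3] <- 1 - params$erd_depth
  if (label == "right") erd_scale[1] <- 1 - params$erd_depth
  for (c in seq_len(params$n_channels)) {
    phi_mu <- stats::runif(1, 0, 2 * pi)
    phi_beta <- stats::runif(1, 0, 2 * pi)
    osc <- sin(2 * pi * f_mu * t + phi_mu) + sin(2 * pi * f_beta * t + phi_beta)
    noise <- pink_noise(n) * params$noise_level
    data[c, ] <- erd_scale[c] * osc + noise
  }
  if (label == "left") data <- data * (1 + params$broadband_gain_delta)

  structure(
    list(data = data, label = label, fs = params$fs,
         channel_names = c("C3", "Cz", "C4")[seq_len(params$n_channels)],
         subject_id = NA_character_, session_id = NA_character_),
    class = "epoched_trial")
}

#' Generate a balanced labeled synthetic dataset
#'
#' Produces `2 * n_per_class` trials (labels alternate left/right in pairs)
#' with per-trial seeds derived deterministically from `params$seed`, so
#' the dataset is reproducible bit-for-bit.
#'
#' @param n_per_class Number of trials per class (>= 1).
#' @param params A [synth_params()] object.
#' @return A `mieeg_dataset`: list with `trials` (list of `epoched_trial`),
#'   `labels` (character vector) and `params`.
#' @export
generate_dataset <- function(n_per_class, params) {
  if (!inherits(params, "synth_params")) params <- do.call(synth_params, params)
  if (n_per_class < 1) stop("`n_per_class` must be >= 1")
  n_per_class <- as.integer(n_per_class)
  labels <- rep(c("left", "right"), n_per_class)
  # distinct, collision-free 32-bit per-trial seeds
  trial_seeds <- (as.numeric(params$seed) * 100003 +
                    seq_along(labels) * 7919) %% 2147483647
  trials <- mapply(function(lab, s) generate_trial(lab, params, s),
                   labels, trial_seeds, SIMPLIFY = FALSE)
  names(trials) <- NULL
  structure(list(trials = trials, labels = labels, params = params),
            class = "mieeg_dataset")
}

#' @export
print.mieeg_dataset <- function(x, ...) {
  cat(sprintf("MI-EEG dataset: %d trials (%s)\n", length(x$trials),
              paste(sprintf("%s: %d", names(table(x$labels)),
                            table(x$labels)), collapse = ", ")))
  if (length(x$trials)) {
    d <- dim(x$trials[[1]]$data)
    cat(sprintf("  trial shape %d x %d at %g Hz\n", d[1], d[2],
                x$trials[[1]]$fs))
  }
  invisible(x)
}

#' Integrated Welch-periodogram band power
#'
#' Welch power spectral density (Hamming-windowed segments, 50% overlap)
#' integrated over `[band[1], band[2]]` by the trapezoidal rule. Used as a
#' model-free oracle for the generator's class structure (ERD shows up as
#' reduced contralateral mu/beta power).
#'
#' @param signal Numeric vector.
#' @param band Length-2 numeric `(low, high)` in Hz, inside `(0, fs/2)`.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length (default `min(256, length(signal))`).
#' @return Nonnegative scalar band power (same units as `signal^2`).
#' @export
band_power <- function(signal, band, fs, nperseg = min(256L, length(signal))) {
  if (length(band) != 2 || band[1] <= 0 || band[2] >= fs / 2 ||
      band[1] >= band[2]) {
    stop("`band` must satisfy 0 < low < high < fs/2")
  }
  w <- welch_psd(signal, fs, nperseg)
  idx <- which(w$freq >= band[1] & w$freq <= band[2])
  if (length(idx) < 2) {
    return(sum(w$psd[idx]) * (w$freq[2] - w$freq[1]))
  }
  f <- w$freq[idx]
  p <- w$psd[idx]
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

# Welch PSD estimate (one-sided density), Hamming window, 50% overlap.
welch_psd <- function(x, fs, nperseg = min(256L, length(x))) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- hamming_window(nperseg)
  u <- sum(win^2)  # window power normalization
  nfft <- nperseg
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * win
    sp <- stats::fft(seg)
    px <- Mod(sp[seq_len(nfft %/% 2 + 1)])^2 / (fs * u)
    # fold two-sided power into the one-sided density
    if (nfft %% 2 == 0) {
      px[2:(length(px) - 1)] <- 2 * px[2:(length(px) - 1)]
    } else {
      px[2:length(px)] <- 2 * px[2:length(px)]
    }
    acc <- acc + px
  }
  list(freq = seq(0, nfft %/% 2) * fs / nfft, psd = acc / length(starts))
}
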