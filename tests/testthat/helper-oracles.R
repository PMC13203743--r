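# Independent brute-force oracles and small fixture builders shared by
# the test files. The oracles deliberately avoid the package's FFT /
# matrix code paths.

# Direct discrete wavelet correlation: C(b) = sum_k x[k] psi*((k-b)/s) / sqrt(s)
# with zero padding outside the signal.
oracle_cwt <- function(x, cfg) {
  T_len <- length(x)
  out <- matrix(0, T_len, cfg$n_freqs)
  for (q in seq_len(cfg$n_freqs)) {
    s <- cfg$scales[q]
    half <- ceiling(cfg$support * s)
    j <- (-half):half
    for (b in seq_len(T_len)) {
      k <- b + j
      ok <- k >= 1 & k <= T_len
      u <- j[ok] / s
      psi <- if (cfg$wavelet == "cmor") {
        pi^(-0.25) * exp(-u^2 / 2) * exp(1i * cfg$omega0 * u)
      } else {
        exp(-u^2 / 2) * cos(cfg$omega0 * u) + 0i
      }
      out[b, q] <- Mod(sum(x[k[ok]] * Conj(psi)) / sqrt(s))
    }
  }
  out
}

# Per-pixel fusion oracle: loops every (t, f) location and applies the
# two 3x3 channel maps by hand.
oracle_fuse <- function(tfr, raw, weights) {
  out <- array(0, dim = dim(tfr))
  for (t in seq_len(dim(tfr)[2])) {
    for (f in seq_len(dim(tfr)[3])) {
      out[, t, f] <- weights$tfr$W %*% tfr[, t, f] + weights$tfr$b +
        weights$raw$W %*% raw[, t, f] + weights$raw$b
    }
  }
  out
}

# Hand-coded single-head attention: explicit Q/K/V rows, softmax and
# weighted sum, no matrix shortcuts.
oracle_attention <- function(Q, K, V) {
  n <- nrow(Q)
  dk <- ncol(K)
  out <- matrix(0, n, ncol(V))
  W <- matrix(0, n, nrow(K))
  for (i in seq_len(n)) {
    scores <- vapply(seq_len(nrow(K)),
                     function(j) sum(Q[i, ] * K[j, ]) / sqrt(dk),
                     numeric(1))
    e <- exp(scores - max(scores))
    w <- e / sum(e)
    W[i, ] <- w
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  list(output = out, weights = W)
}

# Welch-free periodogram oracle for band power: direct FFT of the full
# signal, sum of |X|^2 over in-band bins (Parseval scaling).
oracle_band_fraction <- function(x, band, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  inband <- half & f >= band[1] & f <= band[2]
  2 * sum(sp[inband]) / stats::var(x)
}

# Small labeled dataset for smoke training tests.
toy_dataset <- function(n_per_class = 2, erd = 0.9, seed = 5) {
  generate_dataset(n_per_class,
                   synth_params(erd_depth = erd, noise_level = 0.5,
                                seed = seed))
}

# A GDF fixture on disk: 3 EEG + 2 EOG channels with cue events.
write_gdf_fixture <- function(path, n_samples = 2500, fs = 250,
                              onsets = c(200L, 1200L),
                              codes = c(769L, 770L), seed = 1) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  data <- matrix(stats::rnorm(5 * n_samples), 5)
  write_gdf(data, fs, c("C3", "Cz", "C4", "EOG:ch-L", "EOG:ch-R"),
            data.frame(onset_sample = onsets, code = codes), path)
  data
}
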