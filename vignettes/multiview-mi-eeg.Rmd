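---
title: "Multi-view fusion for few-channel motor-imagery EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view fusion for few-channel motor-imagery EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Two-class motor-imagery (MI) decoding from only three electrodes (C3,
Cz, C4 of the 10--20 system) is the setting of portable, consumer-grade
brain-computer interfaces. The physiological class signal is
event-related desynchronization (ERD): imagining a hand movement
attenuates the mu (8--13 Hz) and beta (13--30 Hz) sensorimotor rhythms
over the *contralateral* motor cortex -- left-hand imagery suppresses
power at C4, right-hand imagery at C3. With so few channels, spatial
filters have little to work with, and pipelines that classify
time-frequency images alone can discard amplitude and phase information
that some recordings need. `mieeg` implements a pipeline that keeps both
sources of information and lets the classifier weight them.

## The pipeline

Each labeled trial is a 3 x 1000 array: a 4 s cue-locked epoch at
250 Hz. The stages are:

1. **Filtering.** A 4th-order Butterworth bandpass (4--40 Hz), applied
   forward and backward (`signal::filtfilt`) for zero phase. This keeps
   the mu and beta rhythms and rejects drift and EMG. Channels are
   demeaned first; the DC offset lies far below the passband and would
   otherwise leave forward-backward edge transients. When epochs come
   from a continuous GDF recording, the *recording* is filtered before
   epoching so filter transients fall outside the trials; the raw view
   always uses the unfiltered signal.
2. **Slicing.** The trial is partitioned into n = 8 contiguous
   non-overlapping slices of 0.5 s (T = 125 samples). A slice carries
   short-range structure; the slice sequence carries the long-range
   temporal structure handled later by the Transformer. Slicing is an
   exact partition -- no padding, no overlap -- and trials whose length
   is not a multiple of the slice are rejected rather than padded.
3. **Scalogram view.** Each slice channel is tapered with a symmetric
   Hamming window (`0.54 - 0.46 cos(2 pi k / (T-1))`) and transformed
   with a continuous wavelet transform at F = 125 linearly spaced
   frequencies in 4--40 Hz, giving a 125 x 125 magnitude map per
   channel; the three maps are stacked like the planes of an RGB image
   (order C3, Cz, C4).
4. **Raw view.** Each (unfiltered) slice is normalized and replicated
   along a frequency axis (`out[c,t,f] = slice[c,t]`), so it has exactly
   the scalogram's shape.
5. **Fusion.** Each view passes through its own 1 x 1 convolution (a
   per-pixel 3 x 3 channel map with bias) and the results are added
   element-wise. Ablation switches freeze one branch at zero, giving the
   scalogram-only and raw-only variants exactly.
6. **Per-slice encoding.** A compact CNN encodes each fused
   3 x 125 x 125 tensor into a d = 32 vector; the n slice embeddings
   form the matrix M (d x n, columns in temporal order).
7. **Temporal model.** A 2-layer, 4-head Transformer encoder
   (scaled dot-product attention, `softmax(QK'/sqrt(d_k))V`, post-norm,
   sinusoidal positions) contextualizes the columns of M.
8. **Head and loss.** Token-mean pooling, a linear layer, softmax, and
   mean cross-entropy `L = -(1/N) sum_i log p_i(y_i)`, trained
   end-to-end with Adam (initial learning rate 0.002, batch size 32, 50
   epochs in the full recipe; no schedule, no early stopping; the
   last-epoch model is evaluated).

## The wavelet and its scale mapping

The wavelet is the classic complex Morlet
`psi(u) = pi^(-1/4) exp(-u^2/2) exp(i * omega0 * u)` with carrier
`omega0 = 5`. Analysis frequencies map to scales through
`s = fc * fs / f` with the nominal center frequency `fc = 0.8125`
(so s = 50.78125 at 4 Hz and 5.078125 at 40 Hz). Two deliberate
numerical choices:

- **Why `fc = 0.8125` and not `omega0 / (2 pi) = 0.7958`.** Coefficients
  are L2-normalized (`1/sqrt(s)`), so the magnitude of a pure sinusoid,
  viewed across scales, carries a `sqrt(s)` weighting that shifts its
  argmax by a factor `1/(1 + 1/(2 omega0^2))` (about -1.9%). Placing the
  nominal center frequency at 0.8125 -- slightly above the analytic
  value -- cancels this bias almost exactly, because
  `2 pi * 0.8125 = 5.105 ~ omega0 + 1/(2 omega0)`. The result: the
  time-averaged magnitude of a sinusoid at 5, 10, 20 or 35 Hz peaks
  within half a frequency bin (bin width 36/124 = 0.29 Hz) of the true
  frequency, which the tests assert. Using a wavelet whose analytic
  center frequency is exactly 0.8125 would instead displace peaks by up
  to 2.3 bins at 35 Hz.
- **Edges.** Slices are zero-padded for the convolution; the Hamming
  taper already suppresses the edge samples. The transform is computed
  by FFT convolution with precomputed kernels and is tested to agree
  with a direct discrete convolution oracle to better than 1e-6
  relative error.

## Normalization: two config axes that matter

Neither view's normalization is uniquely determined by the problem, so
both are explicit configuration axes of `train_config()`:

- `tfr_norm`: `"per_dataset"` (default) standardizes all scalogram
  values by the training set's scalar mean/sd -- amplitude differences
  *between* trials survive. `"per_map"` divides each channel map by its
  own maximum -- scale-invariant, the normalization used for scalogram
  displays. `"none"` leaves magnitudes untouched.
- `raw_norm`: `"zscore"` (default) z-scores each channel of each slice
  -- scale-invariant. `"scale"` divides everything by a single
  training-set RMS constant -- between-trial amplitude differences
  survive.

The choice decides which information each view can carry. A broadband
multiplicative amplitude cue is erased by any scale-invariant
normalization; it survives the raw view only under `"scale"`, and is
erased from the scalogram view by `"per_map"` (the wavelet transform is
linear, so a gain factors out of each map). The view-ablation benchmark
below exploits exactly this.

## The per-slice encoder

No pretrained vision backbone ships with the package; the encoder is a
compact CNN designed for the data regime (tens to hundreds of trials
per subject), in two variants selected by `backbone`:

- `"shuffle_micro"` (default): a parameter-free 5 x 5 average-pool stem
  (125 x 125 -> 25 x 25), a 3 x 3 convolution (3 -> 8) with ReLU, 5 x 5
  average pooling, then a channel-shuffle unit -- grouped 1 x 1
  convolution (8 -> 16, two groups), channel shuffle, depthwise 3 x 3,
  grouped 1 x 1 (16 -> 32) -- and global average pooling to d = 32.
  Grouped pointwise convolutions with a shuffle keep the parameter
  count low while still mixing information across groups.
- `"plain_micro"`: the same stem, two plain convolutions, global
  average pooling.

About 4k parameters in total -- deliberately small: per-subject MI
training sets have only a few hundred trials, and capacity is the main
overfitting risk. Global average pooling makes both encoders accept any
spatial size, so the full-resolution fused tensor is valid input.
`pretrained = TRUE` loads a user-supplied parameter file
(`weights_file`) from a previous run; no weights are bundled, and
ImageNet-style transfer initialization is out of scope (a known
limitation relative to transfer-learning pipelines on scalogram
images).

Two initialization details are load-bearing:

- **ReLU biases start at +0.1, not 0.** With zero biases the encoder is
  positively homogeneous (`m(a x) = a m(x)`), and the Transformer's
  LayerNorm is exactly invariant to a common scale of its input -- the
  combination is *structurally blind* to amplitude cues. Small positive
  biases break the homogeneity (and avoid dead ReLUs).
- **Fusion initialization** (`fusion_init`). The default
  `"identity_zero"` starts the scalogram branch near the identity and
  the raw branch near zero, so an untrained fused model behaves like the
  scalogram-only baseline and recruits the raw view only as training
  finds it useful. For *view comparisons* this asymmetry is the wrong
  prior -- it privileges one branch -- and when the scalogram view
  carries no class signal the near-zero raw branch can fail to receive
  usable gradient at small step counts. The view-ablation benchmark
  therefore uses `"random"`, which initializes both branches alike.

## The training internals

There is no deep-learning runtime behind the package: layers (dense,
grouped and depthwise convolution via im2col, average pooling,
LayerNorm, multi-head attention, dropout), their analytic backward
passes, and Adam are implemented in base R matrix code. Correctness is
pinned by finite-difference tests over every parameter group, and by
hand-coded oracles for attention and fusion. Everything is driven by a
single integer seed (initialization, batch shuffling, dropout), so a
fit is bit-reproducible.

One exact algebraic shortcut keeps training fast: the 5 x 5 pooling
stem, the frequency replication of the raw view, and the 1 x 1 fusion
convolutions are all linear maps, and non-overlapping average pooling
commutes with any per-pixel channel map. Features are therefore pooled
*once* per dataset before fusion, shrinking the cached tensors 25-fold
with bit-for-bit identical results (a property the test suite checks).

## The synthetic generator

`generate_trial()` builds what the pipeline assumes about MI-EEG and
nothing more: per channel, pink (1/f) noise -- white spectrum shaped by
`1/sqrt(f)` -- plus one mu-band and one beta-band sinusoid with
per-trial uniform frequencies and per-channel uniform phases.
`erd_depth` scales the contralateral channel's oscillation amplitude by
`1 - erd_depth` (C4 for left, C3 for right, Cz untouched);
`broadband_gain_delta` multiplies the whole left-hand trial by
`1 + delta`, planting a cue that lives only in broadband amplitude.
Defaults chosen once as the study conditions: `noise_level = 1` (noise
RMS equal to oscillation RMS, a low-SNR but workable regime),
`erd_depth = 0.75` (deep ERD within the physiologically reported
range); the benchmarks below override these with their stated values.

What the generator does *not* emulate: eye-blink/EMG artifacts, volume
conduction between channels, non-stationary band power, 1/f exponents
that vary by site, inter-subject variability. Green tests on synthetic
data therefore demonstrate that the pipeline extracts the structures it
claims to extract -- not that it reaches any particular accuracy on
recorded EEG.

## The two standard benchmarks

Problem sizes are chosen so each benchmark runs in minutes on one CPU;
both are also recomputed by `scripts/acceptance.R`.

**ERD separability and null calibration** (`erd_benchmark()`): 100
trials/class for training and testing, 10 epochs, random
initialization, default normalizations. At `erd_depth = 0.9` the
held-out accuracy should exceed 90% (observed: 100% at seed 1); at
`erd_depth = 0` it should sit inside the 95% binomial interval around
50% for 200 test trials (43.1--56.9%).

**Broadband-cue view ablation** (`broadband_view_ablation()`): data
with `erd_depth = 0` and `broadband_gain_delta = 0.5` -- the only class
signal is amplitude. Configuration: `tfr_norm = "per_map"` (erases the
cue from the scalogram view), `raw_norm = "scale"` (preserves it in the
raw view), symmetric random fusion init, 40 trials/class, 30 epochs at
batch size 16 (smaller batches give enough optimizer steps at this
sample size), three seeds. Expected signature, asserted as medians over
seeds: fused and raw-only beat scalogram-only by at least 10 accuracy
points. Observed at seeds 1--3: scalogram-only stays at chance (50%),
raw-only reaches 95--100%, fused 96--100%.

## Degenerate inputs and tie-breaks

Constant raw channels z-score to zeros via an epsilon guard; zero
slices give zero scalograms; probability ties in `evaluate()` resolve
to the first class (`max.col(ties.method = "first")`) so evaluation is
deterministic; cue events whose window leaves the recording are dropped
with a warning, and an all-dropped extraction is an error rather than
an empty result. Weight files with mismatched shapes are rejected by
name.

## Applying the pipeline to recorded data

For a standard 3-channel MI session in GDF format (cue codes 769/770 at
the start of the imagery interval):

```{r, eval = FALSE}
rec <- load_gdf_session("B0101T.gdf")
ds <- extract_epochs(rec, window = c(0, 4), filter_band = c(4, 40))
fit <- train_subject(ds, train_config())   # full 50-epoch recipe
evaluate(fit, extract_epochs(load_gdf_session("B0104E.gdf"),
                             window = c(0, 4), filter_band = c(4, 40)))
```

Train on the first three sessions of a subject, evaluate on the last
two, and repeat per subject; per-subject accuracies are summarized as
mean +/- sd by `run_ablation()`. Expect full-scale runs to take hours
on one CPU with this base-R training loop -- it is built for
correctness and desk-scale experiments, not GPU-scale throughput. All
cue-valid trials are kept (no artifact rejection); rejected-trial
markers in the annotations are ignored by default.

## Known limitations

- No pretrained (ImageNet-style) backbone initialization is available;
  transfer-learning comparisons require the user to supply weights.
- The encoder is a compact stand-in sized for desk-scale data, not a
  0.6M-parameter production backbone; absolute accuracies on recorded
  data will differ from pipelines built around larger pretrained CNNs.
- The GDF reader covers the motor-imagery dialect (GDF 2.x, sample
  types int8/16/32, uint8/16/32, float32/64, mode-1/3 event tables),
  not the full format.
- Training is single-threaded base R; the full 50-epoch recipe on real
  session sizes is slow.
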