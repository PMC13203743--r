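test_that("parameter validation rejects out-of-range settings", {
  expect_error(synth_params(erd_depth = 1.2), "erd_depth")
  expect_error(synth_params(erd_depth = -0.1), "erd_depth")
  expect_error(synth_params(fs = 250, epoch_s = 4.001), "integer")
  expect_error(synth_params(mu_band = c(0, 13)), "bands")
  expect_error(generate_trial("up", synth_params()), "left")
  expect_error(generate_dataset(0, synth_params()), "n_per_class")
})

test_that("trials are deterministic in (label, params, seed) and leave the RNG alone", {
  p <- synth_params(erd_depth = 0.5, seed = 3)
  t1 <- generate_trial("left", p, trial_seed = 7)
  t2 <- generate_trial("left", p, trial_seed = 7)
  expect_identical(t1$data, t2$data)
  expect_equal(dim(t1$data), c(3L, 1000L))

  set.seed(123)
  before <- rnorm(3)
  set.seed(123)
  invisible(generate_trial("right", p, trial_seed = 1))
  expect_identical(rnorm(3), before)

  d1 <- generate_dataset(4, p)
  d2 <- generate_dataset(4, p)
  expect_identical(d1, d2)
})

test_that("datasets are balanced with the requested trial count", {
  ds <- generate_dataset(100, synth_params(seed = 1))
  expect_length(ds$trials, 200)
  expect_equal(unname(table(ds$labels)["left"]), 100L)
  expect_equal(unname(table(ds$labels)["right"]), 100L)
})

test_that("contralateral mu power is suppressed for the imagined hand", {
  # left-hand imagery attenuates C4 (row 3); frozen example at deep ERD
  p <- synth_params(erd_depth = 0.8, noise_level = 0.1)
  tr <- generate_trial("left", p, trial_seed = 7)
  ratio <- band_power(tr$data[3, ], c(8, 13), 250) /
    band_power(tr$data[1, ], c(8, 13), 250)
  expect_lt(ratio, 0.5)

  # class-mean C4/C3 log-power ratios have opposite signs
  ds <- generate_dataset(50, synth_params(erd_depth = 0.8, seed = 11))
  lr <- vapply(ds$trials, function(t) {
    log(band_power(t$data[3, ], c(8, 13), 250) /
          band_power(t$data[1, ], c(8, 13), 250))
  }, numeric(1))
  expect_lt(mean(lr[ds$labels == "left"]), 0)
  expect_gt(mean(lr[ds$labels == "right"]), 0)
})

test_that("the contralateral/ipsilateral power ratio decreases in erd_depth", {
  depths <- c(0.2, 0.5, 0.8)
  mean_ratio <- vapply(depths, function(d) {
    ds <- generate_dataset(25, synth_params(erd_depth = d, seed = 21))
    r <- vapply(ds$trials[ds$labels == "left"], function(t) {
      band_power(t$data[3, ], c(8, 13), 250) /
        band_power(t$data[1, ], c(8, 13), 250)
    }, numeric(1))
    mean(r)
  }, numeric(1))
  expect_true(all(diff(mean_ratio) < 0))
})

test_that("without ERD or broadband gain no class effect is detectable", {
  ds <- generate_dataset(40, synth_params(erd_depth = 0,
                                          broadband_gain_delta = 0,
                                          seed = 31))
  stat <- vapply(ds$trials, function(t) {
    log(band_power(t$data[3, ], c(8, 13), 250) /
          band_power(t$data[1, ], c(8, 13), 250))
  }, numeric(1))
  obs <- abs(mean(stat[ds$labels == "left"]) -
               mean(stat[ds$labels == "right"]))
  set.seed(99)
  null <- replicate(499, {
    perm <- sample(ds$labels)
    abs(mean(stat[perm == "left"]) - mean(stat[perm == "right"]))
  })
  p_val <- (1 + sum(null >= obs)) / 500
  expect_gt(p_val, 0.05)
})

test_that("band_power integrates the Welch periodogram over the band", {
  t <- (0:999) / 250
  s10 <- sin(2 * pi * 10 * t)
  expect_equal(band_power(rep(0, 1000), c(8, 13), 250), 0)
  # a unit sinusoid has variance 0.5; nearly all of it lies in its band
  expect_gt(band_power(s10, c(8, 13), 250), 0.9 * 0.5)
  expect_lt(band_power(s10, c(20, 30), 250), 0.01 * 0.5)
  # agrees with a plain full-length periodogram oracle on band fractions
  expect_gt(oracle_band_fraction(s10, c(8, 13), 250), 0.99)
  expect_error(band_power(s10, c(10, 200), 250), "fs/2")
})

test_that("the broadband gain scales left-hand trials only", {
  p0 <- synth_params(erd_depth = 0, broadband_gain_delta = 0, seed = 8)
  p1 <- synth_params(erd_depth = 0, broadband_gain_delta = 0.5, seed = 8)
  l0 <- generate_trial("left", p0, 4)
  l1 <- generate_trial("left", p1, 4)
  r0 <- generate_trial("right", p0, 4)
  r1 <- generate_trial("right", p1, 4)
  expect_equal(l1$data, 1.5 * l0$data, tolerance = 1e-12)
  expect_identical(r1$data, r0$data)
})
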