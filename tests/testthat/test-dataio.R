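test_that("GDF writer/reader round-trip preserves data, events and fs", {
  f <- withr::local_tempfile(fileext = ".gdf")
  data <- write_gdf_fixture(f)
  rec <- load_gdf_session(f)
  expect_s3_class(rec, "raw_recording")
  expect_equal(rec$fs, 250)
  expect_equal(rec$channel_names, c("C3", "Cz", "C4"))  # EOG dropped
  expect_equal(nrow(rec$events), 2)
  expect_equal(rec$events$onset_sample, c(200L, 1200L))
  expect_equal(rec$events$code, c(769L, 770L))
  # float32 storage: 1e-7 relative precision
  expect_lt(max(abs(rec$data - data[1:3, ])), 1e-6)
})

test_that("non-GDF input and cue-free recordings are rejected", {
  f <- withr::local_tempfile(fileext = ".gdf")
  writeLines("definitely not a gdf file", f)
  expect_error(read_gdf(f), "not a GDF")
  expect_error(read_gdf(file.path(tempdir(), "absent.gdf")), "not found")

  g <- withr::local_tempfile(fileext = ".gdf")
  write_gdf_fixture(g, onsets = c(100L), codes = c(768L))  # no 769/770
  expect_error(load_gdf_session(g), "cue events")
})

test_that("an independent GDF parser agrees with ours on a fixture", {
  # cross-check against mne-python, which ships its own GDF reader
  f <- tempfile(fileext = ".gdf")
  on.exit(unlink(f))
  write_gdf_fixture(f)
  out <- suppressWarnings(system2(
    "python", c("-c", shQuote(paste0(
      "import mne,json;",
      "r=mne.io.read_raw_gdf('", f, "',verbose='ERROR');",
      "print(json.dumps({'sfreq':r.info['sfreq'],'n':int(r.n_times),",
      "'ch':r.ch_names[:3],",
      "'onsets':[float(a['onset']) for a in r.annotations],",
      "'desc':[a['description'] for a in r.annotations]}))"))),
    stdout = TRUE, stderr = FALSE))
  info <- jsonlite::fromJSON(out[length(out)])
  expect_equal(info$sfreq, 250)
  expect_equal(info$n, 2500L)
  expect_equal(info$ch, c("C3", "Cz", "C4"))
  expect_equal(info$onsets, c(200, 1200) / 250)
  expect_equal(info$desc, c("769", "770"))
})

test_that("epoch extraction is index-exact with half-open windows", {
  f <- withr::local_tempfile(fileext = ".gdf")
  onsets <- as.integer(seq(0, 13500, by = 1500))[1:10]
  write_gdf_fixture(f, n_samples = 15000,
                    onsets = onsets,
                    codes = rep(c(769L, 770L), 5))
  rec <- load_gdf_session(f)
  ep <- extract_epochs(rec, window = c(0, 4))
  expect_length(ep$trials, 10)
  expect_equal(ep$labels, rep(c("left", "right"), 5))
  for (k in c(1, 4, 10)) {
    expect_equal(dim(ep$trials[[k]]$data), c(3L, 1000L))
    # trial sample j equals recording sample onset + j (0-based onset)
    expect_identical(ep$trials[[k]]$data,
                     rec$data[, (onsets[k] + 1):(onsets[k] + 1000)])
  }
})

test_that("events whose window leaves the recording are dropped, not padded", {
  f <- withr::local_tempfile(fileext = ".gdf")
  write_gdf_fixture(f, n_samples = 2000, onsets = c(0L, 1500L),
                    codes = c(769L, 770L))
  rec <- load_gdf_session(f)
  expect_warning(ep <- extract_epochs(rec, window = c(0, 4)), "dropped")
  expect_length(ep$trials, 1)
  expect_equal(ep$labels, "left")
  # a window too long for every event is an error, not an empty result
  expect_error(
    suppressWarnings(extract_epochs(rec, window = c(0, 10))),
    "inside the recording")
})

test_that("a filtered copy cut from the continuous recording rides along", {
  f <- withr::local_tempfile(fileext = ".gdf")
  write_gdf_fixture(f, n_samples = 4000, onsets = c(500L, 2500L),
                    codes = c(769L, 770L))
  rec <- load_gdf_session(f)
  ep <- extract_epochs(rec, window = c(0, 4), filter_band = c(4, 40))
  filt_full <- bandpass_filter(rec$data, 4, 40, fs = rec$fs)
  expect_equal(ep$trials[[2]]$data_filtered, filt_full[, 2501:3500])
  expect_identical(ep$trials[[2]]$data, rec$data[, 2501:3500])
})

test_that("the dataset container round-trips bit-identically", {
  ds <- toy_dataset(n_per_class = 2, seed = 77)
  f <- withr::local_tempfile(fileext = ".rds")
  write_dataset(ds, f)
  back <- read_dataset(f)
  expect_identical(back, ds)
  g <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1, 2), g)
  expect_error(read_dataset(g), "mieeg_dataset")
})
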