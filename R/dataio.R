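# GDF 2.x reading/writing and epoch extraction.
#
# No R package on hand reads GDF, so a minimal reader for the motor-
# imagery dialect (3 EEG + optional EOG channels, one cue event per
# trial) is implemented here, following the published byte layout of the
# GDF 2.20 fixed header, channel headers and event table. A matching
# writer exists mainly to build small test fixtures.

GDF_LEFT_CUE <- 769L   # 0x0301
GDF_RIGHT_CUE <- 770L  # 0x0302

read_u16 <- function(con) {
  v <- readBin(con, "integer", 1, size = 2, signed = FALSE,
               endian = "little")
  v
}

read_u32 <- function(con, n = 1) {
  v <- readBin(con, "integer", n, size = 4, endian = "little")
  ifelse(v < 0, v + 2^32, v)
}

read_i64 <- function(con) {
  lo <- read_u32(con)
  hi <- read_u32(con)
  hi * 2^32 + lo
}

#' Read a GDF 2.x recording
#'
#' Parses the fixed header, channel headers, data records and event table
#' of a GDF 2.x file. Sample values are converted to physical units via
#' the per-channel digital/physical calibration. Channels whose label
#' contains "EOG" are dropped.
#'
#' @param path Path to a GDF 2.x file.
#' @return A `raw_recording`: list with `data` (channels x samples matrix),
#'   `fs`, `channel_names`, `events` (data frame with 0-based
#'   `onset_sample` and integer `code`), `subject_id`, `session_id`.
#' @export
read_gdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- rawToChar(readBin(con, "raw", 8))
  if (!startsWith(version, "GDF")) {
    stop("not a GDF file (header starts with \"",
         substr(version, 1, 8), "\")")
  }
  vnum <- suppressWarnings(as.numeric(substr(version, 5, 8)))
  if (is.na(vnum) || vnum < 1.9) {
    stop("unsupported GDF version \"", version, "\" (need GDF 2.x)")
  }
  patient <- rawToChar(readBin(con, "raw", 66))
  seek(con, 184)
  header_nbytes <- read_u16(con) * 256
  seek(con, 236)
  n_records <- read_i64(con)
  dur_num <- read_u32(con)
  dur_den <- read_u32(con)
  nchan <- read_u16(con)
  if (nchan < 1 || nchan > 512) stop("implausible channel count ", nchan)
  seek(con, 256)  # skip 2 reserved bytes; channel headers start here

  # channel headers: field-by-field blocks
  labels <- vapply(seq_len(nchan), function(i) {
    trimws(rawToChar(readBin(con, "raw", 16)))
  }, character(1))
  seek(con, (80 + 6) * nchan, origin = "current")
  seek(con, 2 * nchan, origin = "current")   # physical dimension codes
  phys_min <- readBin(con, "double", nchan, endian = "little")
  phys_max <- readBin(con, "double", nchan, endian = "little")
  dig_min <- readBin(con, "double", nchan, endian = "little")
  dig_max <- readBin(con, "double", nchan, endian = "little")
  seek(con, 68 * nchan, origin = "current")  # prefilter (obsolete)
  seek(con, 3 * 4 * nchan, origin = "current")  # lowpass/highpass/notch
  n_samps <- readBin(con, "integer", nchan, size = 4, endian = "little")
  gdftyp <- readBin(con, "integer", nchan, size = 4, endian = "little")
  seek(con, header_nbytes)

  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L,
                 `6` = 4L, `16` = 4L, `17` = 8L)
  sz <- type_size[as.character(gdftyp)]
  if (any(is.na(sz))) {
    stop("unsupported GDF sample type(s): ",
         paste(unique(gdftyp[is.na(sz)]), collapse = ", "))
  }
  bytes_per_record <- sum(sz * n_samps)

  read_samples <- function(typ, n) {
    switch(as.character(typ),
           `1` = readBin(con, "integer", n, size = 1, signed = TRUE),
           `2` = readBin(con, "integer", n, size = 1, signed = FALSE),
           `3` = readBin(con, "integer", n, size = 2, signed = TRUE,
                         endian = "little"),
           `4` = readBin(con, "integer", n, size = 2, signed = FALSE,
                         endian = "little"),
           `5` = readBin(con, "integer", n, size = 4, endian = "little"),
           `6` = read_u32(con, n),
           `16` = readBin(con, "double", n, size = 4, endian = "little"),
           `17` = readBin(con, "double", n, endian = "little"))
  }

  chans <- lapply(seq_len(nchan), function(i) {
    vector("list", n_records)
  })
  for (r in seq_len(n_records)) {
    for (ch in seq_len(nchan)) {
      chans[[ch]][[r]] <- read_samples(gdftyp[ch], n_samps[ch])
    }
  }
  cal <- (phys_max - phys_min) / (dig_max - dig_min)
  cal[!is.finite(cal)] <- 1
  data <- do.call(rbind, lapply(seq_len(nchan), function(ch) {
    dig <- unlist(chans[[ch]], use.names = FALSE)
    phys_min[ch] + (dig - dig_min[ch]) * cal[ch]
  }))

  # event table
  events <- data.frame(onset_sample = integer(0), code = integer(0))
  seek(con, header_nbytes + n_records * bytes_per_record)
  mode_raw <- readBin(con, "raw", 1)
  if (length(mode_raw) == 1) {
    etmode <- as.integer(mode_raw)
    ne_b <- as.integer(readBin(con, "raw", 3))
    n_events <- ne_b[1] + ne_b[2] * 256 + ne_b[3] * 65536
    readBin(con, "double", 1, size = 4, endian = "little")  # event fs
    if (n_events > 0 && etmode %in% c(1L, 3L)) {
      pos <- read_u32(con, n_events)           # 1-based
      typ <- readBin(con, "integer", n_events, size = 2, signed = FALSE,
                     endian = "little")
      events <- data.frame(onset_sample = as.integer(pos - 1),
                           code = as.integer(typ))
    }
  }

  fs <- n_samps[1] * dur_den / dur_num
  keep <- !grepl("EOG", labels, ignore.case = TRUE)
  structure(list(data = data[keep, , drop = FALSE], fs = fs,
                 channel_names = labels[keep], events = events,
                 subject_id = trimws(strsplit(patient, " ")[[1]][1]),
                 session_id = basename(path)),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("Recording %s: %d channels x %d samples at %g Hz, %d events\n",
              x$session_id, nrow(x$data), ncol(x$data), x$fs,
              nrow(x$events)))
  invisible(x)
}

#' Load and validate a motor-imagery GDF session
#'
#' Reads a GDF file with [read_gdf()] and checks the motor-imagery
#' dialect: at least three EEG channels (the first three are interpreted
#' as C3, Cz, C4) and at least one left-hand (code 769) or right-hand
#' (code 770) cue event.
#'
#' @param path Path to the GDF file.
#' @return A validated `raw_recording` restricted to the first three EEG
#'   channels.
#' @export
load_gdf_session <- function(path) {
  rec <- read_gdf(path)
  if (nrow(rec$data) < 3) {
    stop("expected at least 3 EEG channels, found ", nrow(rec$data))
  }
  rec$data <- rec$data[1:3, , drop = FALSE]
  rec$channel_names <- rec$channel_names[1:3]
  cues <- rec$events$code %in% c(GDF_LEFT_CUE, GDF_RIGHT_CUE)
  if (!any(cues)) {
    stop("no motor-imagery cue events (codes 769/770) in ", path)
  }
  rec
}

#' Write a GDF 2.20 file
#'
#' Emits a minimal but standard-conforming GDF 2.20 file: one data record
#' holding all samples as float32 with identity calibration, and a mode-1
#' event table. Intended for building small fixtures and for exporting
#' synthetic recordings.
#'
#' @param data Channels x samples numeric matrix.
#' @param fs Sampling rate (Hz).
#' @param channel_names Character vector, one name per channel.
#' @param events Data frame with 0-based `onset_sample` and `code`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gdf <- function(data, fs, channel_names, events, path) {
  nchan <- nrow(data)
  n_samples <- ncol(data)
  stopifnot(length(channel_names) == nchan)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, width) {
    r <- charToRaw(substr(s, 1, width))
    c(r, rep(as.raw(0x20), width - length(r)))
  }
  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2,
                                endian = "little")
  w_u32 <- function(v) writeBin(as.integer(v), con, size = 4,
                                endian = "little")

  header_blocks <- 1 + nchan  # 256-byte blocks
  # fixed header (256 bytes)
  writeBin(charToRaw("GDF 2.20"), con)
  writeBin(pad("X X", 66), con)                    # patient id
  writeBin(rep(as.raw(0), 10), con)                # reserved
  writeBin(rep(as.raw(0), 4), con)                 # sadm/weight/height/ghi
  writeBin(pad("synthetic", 64), con)              # recording id
  writeBin(rep(as.raw(0), 16), con)                # loc + vhsv
  writeBin(rep(as.raw(0), 16), con)                # meas date + birthday
  w_u16(header_blocks)
  writeBin(rep(as.raw(0), 6), con)                 # reserved
  writeBin(rep(as.raw(0), 8 + 6 + 6), con)         # equipment/ip/headsize
  writeBin(rep(0, 6), con, size = 4)               # ref + gnd (float32)
  w_u32(1); w_u32(0)                               # n_records (int64 LE)
  w_u32(n_samples); w_u32(fs)                      # record duration num/den
  w_u16(nchan)
  writeBin(rep(as.raw(0), 2), con)                 # reserved

  # channel headers, field-major
  for (nm in channel_names) writeBin(pad(nm, 16), con)
  writeBin(rep(as.raw(0x20), 80 * nchan), con)     # transducer
  writeBin(rep(as.raw(0x20), 6 * nchan), con)      # physical dim (obsolete)
  for (i in seq_len(nchan)) w_u16(4275)            # uV
  rng <- max(abs(data), 1)
  writeBin(rep(-rng, nchan), con)                  # phys min
  writeBin(rep(rng, nchan), con)                   # phys max
  writeBin(rep(-rng, nchan), con)                  # dig min
  writeBin(rep(rng, nchan), con)                   # dig max
  writeBin(rep(as.raw(0), 68 * nchan), con)        # prefilter (obsolete)
  writeBin(rep(0, 3 * nchan), con, size = 4)       # lowpass/highpass/notch
  writeBin(rep(as.integer(n_samples), nchan), con, size = 4,
           endian = "little")
  writeBin(rep(16L, nchan), con, size = 4, endian = "little")  # float32
  writeBin(rep(0, 3 * nchan), con, size = 4)       # xyz
  writeBin(rep(0, 5 * nchan), con, size = 4)       # impedance block (2.19+)

  # one data record, channel-sequential
  for (ch in seq_len(nchan)) {
    writeBin(as.numeric(data[ch, ]), con, size = 4, endian = "little")
  }

  # event table, mode 1
  n_events <- nrow(events)
  writeBin(as.raw(1), con)
  writeBin(as.raw(c(n_events %% 256, (n_events %/% 256) %% 256,
                    n_events %/% 65536)), con)
  writeBin(as.numeric(fs), con, size = 4, endian = "little")
  if (n_events > 0) {
    w_u32(as.integer(events$onset_sample) + 1L)    # 1-based positions
    w_u16(as.integer(events$code))
  }
  invisible(path)
}

#' Extract cue-locked epochs from a recording
#'
#' Cuts one half-open, 0-based sample window `[onset + start_s * fs,
#' onset + end_s * fs)` per cue event (left 769, right 770). Events whose
#' window does not lie fully inside the recording are dropped with a
#' warning. When `filter_band` is given, the continuous recording is
#' bandpass filtered first and each trial keeps that filtered copy in
#' `data_filtered` next to the as-recorded `data`, so edge transients
#' stay outside the epochs and the raw view stays unfiltered.
#'
#' @param recording A `raw_recording`.
#' @param window Length-2 numeric `(start_s, end_s)` relative to the cue;
#'   the motor-imagery interval starts at the cue, so the default `(0, 4)`
#'   covers seconds 3--7 of a standard trial whose cue appears at 3 s.
#' @param filter_band Optional `(low, high)` Hz bandpass applied to the
#'   continuous recording for the filtered copy.
#' @return A `mieeg_dataset` of `epoched_trial`s.
#' @export
extract_epochs <- function(recording, window = c(0, 4),
                           filter_band = NULL) {
  fs <- recording$fs
  L <- round((window[2] - window[1]) * fs)
  if (L <= 0) stop("window must have positive length")
  cues <- recording$events[
    recording$events$code %in% c(GDF_LEFT_CUE, GDF_RIGHT_CUE), ,
    drop = FALSE]
  if (nrow(cues) == 0) stop("recording has no cue events")
  filtered <- if (!is.null(filter_band)) {
    bandpass_filter(recording$data, filter_band[1], filter_band[2], fs = fs)
  }
  trials <- list()
  labels <- character(0)
  dropped <- 0L
  for (e in seq_len(nrow(cues))) {
    start <- cues$onset_sample[e] + round(window[1] * fs)  # 0-based
    if (start < 0 || start + L > ncol(recording$data)) {
      dropped <- dropped + 1L
      next
    }
    sel <- (start + 1):(start + L)
    tr <- structure(
      list(data = recording$data[, sel, drop = FALSE],
           label = if (cues$code[e] == GDF_LEFT_CUE) "left" else "right",
           fs = fs, channel_names = c("C3", "Cz", "C4"),
           subject_id = recording$subject_id,
           session_id = recording$session_id),
      class = "epoched_trial")
    if (!is.null(filtered)) {
      tr$data_filtered <- filtered[, sel, drop = FALSE]
    }
    trials[[length(trials) + 1L]] <- tr
    labels <- c(labels, tr$label)
  }
  if (length(trials) == 0) {
    stop("no cue event window lies fully inside the recording")
  }
  if (dropped > 0) {
    warning(dropped, " cue event(s) dropped: window extends beyond the ",
            "recording")
  }
  structure(list(trials = trials, labels = labels, params = NULL),
            class = "mieeg_dataset")
}

#' Write a dataset container
#'
#' Serializes a `mieeg_dataset` (trial arrays, label vector, parameter
#' record) to a single portable file via R's native serialization;
#' [read_dataset()] restores it bit-identically.
#'
#' @param dataset A `mieeg_dataset`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "mieeg_dataset"))
  saveRDS(dataset, path, version = 3)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  ds <- readRDS(path)
  if (!inherits(ds, "mieeg_dataset")) {
    stop("file does not contain a mieeg_dataset: ", path)
  }
  ds
}
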