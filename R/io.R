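#' Write / read a recording as delimited text
#'
#' Plain-text fallback format: comment header lines (`# key = value`) with
#' the sampling rate and stimulus metadata, then one column per channel in
#' volts, tab-separated, one row per sample.
#'
#' @param rec An [ssep_recording()].
#' @param path Output file path.
#' @return `path`, invisibly (writer); an [ssep_recording()] (reader).
#' @export
write_recording_txt <- function(rec, path) {
  stopifnot(inherits(rec, "ssep_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(fs = rec$fs, stim_onset = rec$stim_onset,
            stim_duration = rec$stim_duration, stim_freq = rec$stim_freq)
  writeLines(sprintf("# %s = %.10g", names(meta), meta), con)
  writeLines(sprintf("# run_id = %s", rec$run_id), con)
  writeLines(paste(rec$channel_labels, collapse = "\t"), con)
  utils::write.table(format(rec$data, digits = 10, trim = TRUE), con,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_txt
#' @export
read_recording_txt <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.+)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  body_start <- length(hdr) + 1L
  labels <- strsplit(lines[body_start], "\t")[[1]]
  data <- utils::read.table(text = lines[-seq_len(body_start)], sep = "\t")
  data <- as.matrix(data)
  ssep_recording(
    data, fs = as.numeric(kv$fs), stim_onset = as.numeric(kv$stim_onset),
    stim_duration = as.numeric(kv$stim_duration),
    stim_freq = as.numeric(kv$stim_freq),
    run_id = if (is.null(kv$run_id)) basename(path) else kv$run_id,
    channel_labels = labels
  )
}

# ---- EDF / BDF ------------------------------------------------------------

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as EDF
#'
#' European Data Format: 256-byte fixed ASCII header, 256 bytes per signal,
#' then 16-bit little-endian integer data records of 1 s each. Voltages are
#' stored in microvolts with per-signal linear scaling covering the data
#' range. The recording is truncated to a whole number of 1-s records.
#'
#' @param rec An [ssep_recording()].
#' @param path Output path (conventionally `.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "ssep_recording"))
  if (!is_whole(rec$fs)) stop("EDF export requires an integer sampling rate",
                              call. = FALSE)
  fs <- as.integer(round(rec$fs))
  ns <- ncol(rec$data)
  n_rec <- floor(nrow(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one 1-s data record", call. = FALSE)
  data_uV <- volts_to_uV(rec$data[seq_len(n_rec * fs), , drop = FALSE])

  phys_min <- apply(data_uV, 2, min)
  phys_max <- apply(data_uV, 2, max)
  span <- phys_max - phys_min
  phys_min <- ifelse(span == 0, phys_min - 1, phys_min)
  phys_max <- ifelse(span == 0, phys_max + 1, phys_max)
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field(sprintf("Startdate X X X X run %s", rec$run_id), 80),
    "01.01.00", "00.00.00",
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  sig_hdr <- paste0(
    paste(vapply(rec$channel_labels, pad_field, character(1), width = 16),
          collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.8g", phys_min), pad_field, character(1), 8),
          collapse = ""),
    paste(vapply(sprintf("%.8g", phys_max), pad_field, character(1), 8),
          collapse = ""),
    paste(rep(pad_field(dig_min, 8), ns), collapse = ""),
    paste(rep(pad_field(dig_max, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(fs, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  )
  writeChar(sig_hdr, con, eos = NULL)
  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((data_uV[rows, ch] - phys_min[ch]) * gain[ch] + dig_min)
      writeBin(as.integer(pmax(dig_min, pmin(dig_max, dig))), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_ascii <- function(con, n) trimws(readChar(con, n, useBytes = TRUE))

#' Read an EDF or BDF recording
#'
#' Reads continuous EDF (16-bit) or BIOSEMI BDF (24-bit) files. All signals
#' must share one sampling rate. Stimulus metadata (onset, duration,
#' modulation frequency) is not part of EDF; supply it directly or through a
#' sidecar metadata file (see [read_dataset()]).
#'
#' @param path Path to the `.edf`/`.bdf` file.
#' @param stim_onset,stim_duration,stim_freq Stimulus metadata, seconds/Hz.
#' @param run_id Run identifier; defaults to the file name.
#' @return An [ssep_recording()] (voltages in volts).
#' @export
read_edf <- function(path, stim_onset = 0, stim_duration = NULL,
                     stim_freq = NULL, run_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  version_byte <- readBin(con, "raw", 1)
  magic <- readChar(con, 7, useBytes = TRUE)
  is_bdf <- identical(as.integer(version_byte), 255L) &&
    identical(magic, "BIOSEMI")
  readChar(con, 160, useBytes = TRUE)             # patient + recording id
  readChar(con, 16, useBytes = TRUE)              # date + time
  readChar(con, 8, useBytes = TRUE)               # header bytes
  readChar(con, 44, useBytes = TRUE)              # reserved
  n_rec <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  labels <- vapply(seq_len(ns), function(i) read_ascii(con, 16), character(1))
  readChar(con, 80 * ns, useBytes = TRUE)         # transducer
  readChar(con, 8 * ns, useBytes = TRUE)          # phys dim
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)),
                     numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)),
                     numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)),
                    numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)),
                    numeric(1))
  readChar(con, 80 * ns, useBytes = TRUE)         # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(read_ascii(con, 8)),
                integer(1))
  readChar(con, 32 * ns, useBytes = TRUE)         # reserved
  if (length(unique(spr)) != 1) {
    stop("signals with differing sampling rates are not supported", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  data <- matrix(0, n_rec * spr[1], ns)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- if (is_bdf) {
        raw3 <- readBin(con, "raw", 3 * spr[ch])
        b <- matrix(as.integer(raw3), nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        ifelse(v >= 8388608, v - 16777216, v)
      } else {
        readBin(con, "integer", spr[ch], size = 2, endian = "little")
      }
      rows <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      data[rows, ch] <- (dig - dig_min[ch]) * gain[ch] + phys_min[ch]
    }
  }
  if (is.null(stim_duration)) stim_duration <- nrow(data) / fs - stim_onset
  if (is.null(stim_freq)) stim_freq <- NA_real_
  ssep_recording(
    data * 1e-6, fs = fs, stim_onset = stim_onset,
    stim_duration = stim_duration, stim_freq = stim_freq,
    run_id = if (is.null(run_id)) basename(path) else run_id,
    channel_labels = labels
  )
}

# ---- dataset-level IO -----------------------------------------------------

#' Write a multi-run dataset with sidecar metadata
#'
#' One file per run (EDF by default, or delimited text) plus, per run, a
#' plain-text sidecar `<run>.meta` with `key = value` lines (`fs`,
#' `stim_onset`, `stim_duration`, `stim_freq`, `run_id`, and `seed` when
#' known), and — when the dataset carries a ground-truth envelope — a single
#' `envelope_truth.csv` with columns `time, amplitude`.
#'
#' @param dataset List of [ssep_recording()]s (e.g. an `ssep_dataset`).
#' @param dir Output directory (created if needed).
#' @param format `"edf"` or `"txt"`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = c("edf", "txt")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- attr(dataset, "config")
  for (i in seq_along(dataset)) {
    rec <- dataset[[i]]
    stem <- file.path(dir, sprintf("run%02d", i))
    if (format == "edf") write_edf(rec, paste0(stem, ".edf"))
    else write_recording_txt(rec, paste0(stem, ".txt"))
    meta <- c(
      sprintf("fs = %.10g", rec$fs),
      sprintf("stim_onset = %.10g", rec$stim_onset),
      sprintf("stim_duration = %.10g", rec$stim_duration),
      sprintf("stim_freq = %.10g", rec$stim_freq),
      sprintf("run_id = %s", rec$run_id),
      if (!is.null(cfg)) sprintf("seed = %d", cfg$seed)
    )
    writeLines(meta, paste0(stem, ".meta"))
  }
  truth <- attr(dataset, "envelope_truth")
  if (!is.null(truth)) {
    utils::write.csv(truth, file.path(dir, "envelope_truth.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a multi-run dataset written by [write_dataset()]
#'
#' @param dir Directory containing run files and `.meta` sidecars.
#' @return An `ssep_dataset` (list of recordings), with the envelope ground
#'   truth re-attached when `envelope_truth.csv` is present.
#' @export
read_dataset <- function(dir) {
  metas <- sort(list.files(dir, pattern = "\\.meta$", full.names = TRUE))
  if (!length(metas)) stop("no .meta sidecar files found in ", dir, call. = FALSE)
  runs <- lapply(metas, function(mf) {
    kv <- list()
    for (ln in readLines(mf)) {
      m <- regmatches(ln, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.+)$", ln))[[1]]
      if (length(m) == 3) kv[[m[2]]] <- trimws(m[3])
    }
    stem <- sub("\\.meta$", "", mf)
    f_edf <- paste0(stem, ".edf"); f_txt <- paste0(stem, ".txt")
    if (file.exists(f_edf)) {
      read_edf(f_edf, stim_onset = as.numeric(kv$stim_onset),
               stim_duration = as.numeric(kv$stim_duration),
               stim_freq = as.numeric(kv$stim_freq), run_id = kv$run_id)
    } else if (file.exists(f_txt)) {
      read_recording_txt(f_txt)
    } else {
      stop("no data file found for sidecar ", mf, call. = FALSE)
    }
  })
  truth_path <- file.path(dir, "envelope_truth.csv")
  truth <- if (file.exists(truth_path)) utils::read.csv(truth_path) else NULL
  structure(runs, class = "ssep_dataset", envelope_truth = truth)
}
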