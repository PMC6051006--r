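#' @name epoch_io
#' @title Epoch I/O: delimited text and EDF
#' @description
#' Cohorts are stored as one file per epoch plus a JSON manifest
#' (`manifest.json`) recording ids, groups, sampling rates, generator
#' parameters and ground-truth fractions when synthetic. Delimited text
#' round-trips losslessly (17 significant digits); EDF round-trips up to the
#' format's 16-bit quantization of the declared physical range.
NULL

fmt_full <- function(x) sprintf("%.17g", x)

#' Write a cohort to disk
#'
#' @param cohort An `eeg_cohort` (or list of epochs).
#' @param path Output directory (created if needed).
#' @param format `"csv"` (one single-column `uV` file per epoch, lossless) or
#'   `"edf"` (one single-channel 16-bit EDF per epoch).
#' @return Invisibly, the manifest file path.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "edf")) {
  format <- match.arg(format)
  epochs <- if (inherits(cohort, "eeg_cohort")) cohort$epochs else cohort
  if (format == "edf" && length(epochs) == 0L)
    stop_input("cannot write an empty cohort as EDF")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop_io("cannot create output directory ", path)
  files <- character(length(epochs))
  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    fname <- paste0(ep$epoch_id, if (format == "csv") ".csv" else ".edf")
    fpath <- file.path(path, fname)
    if (format == "csv") {
      writeLines(c("uV", fmt_full(ep$samples)), fpath)
    } else {
      edf_write(fpath, list(ep$samples), fs = ep$fs, labels = ep$epoch_id)
    }
    files[i] <- fname
  }
  records <- data.frame(
    epoch_id = vapply(epochs, `[[`, character(1), "epoch_id"),
    group = vapply(epochs, `[[`, character(1), "group"),
    file = files,
    fs = vapply(epochs, `[[`, numeric(1), "fs"),
    n_samples = vapply(epochs, function(e) length(e$samples), integer(1)))
  man <- list(format = format, epochs = records)
  if (inherits(cohort, "eeg_cohort")) {
    man$seed <- cohort$params$seed
    man$generator <- cohort$params[c("fs", "duration_s", "total_power",
                                     "trend_amplitude")]
    man$band_stats <- cohort$params$band_stats
    man$ground_truth <- cohort$manifest
  }
  mpath <- file.path(path, "manifest.json")
  jsonlite::write_json(man, mpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mpath)
}

#' Read a cohort of epochs from disk
#'
#' Reads the directory's `manifest.json` and loads each referenced file.
#' Multi-channel EDF files are reduced to one epoch according to
#' `channel_agg`.
#'
#' @param path Directory written by [write_cohort()] (or hand-assembled with
#'   a compatible manifest).
#' @param channel_agg `"mean"` (average across channels) or `"single:<label>"`
#'   to pick one channel of multi-channel EDF input.
#' @return An `eeg_cohort` (without generator params unless recorded).
#' @export
read_epochs <- function(path, channel_agg = "mean") {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath)) stop_io("missing manifest.json in ", path)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  records <- man$epochs
  epochs <- list()
  for (i in seq_len(NROW(records))) {
    fpath <- file.path(path, records$file[i])
    if (!file.exists(fpath)) stop_io("manifest references missing file ", fpath)
    if (grepl("\\.csv$", fpath)) {
      lines <- readLines(fpath)
      if (length(lines) < 1L || lines[1] != "uV")
        stop_io("malformed epoch csv (expected 'uV' header): ", fpath)
      samples <- as.numeric(lines[-1])
      if (anyNA(samples)) stop_io("non-numeric sample values in ", fpath)
      fs <- records$fs[i]
    } else {
      edf <- edf_read(fpath)
      fs <- edf$fs
      sig <- edf$signals
      if (length(sig) == 1L) samples <- sig[[1]]
      else if (identical(channel_agg, "mean"))
        samples <- Reduce(`+`, sig) / length(sig)
      else if (startsWith(channel_agg, "single:")) {
        lab <- sub("^single:", "", channel_agg)
        j <- match(lab, edf$labels)
        if (is.na(j)) stop_input("channel '", lab, "' not found in ", fpath)
        samples <- sig[[j]]
      } else stop_config("unknown channel_agg: ", channel_agg)
    }
    if (!is.na(records$n_samples[i]) && length(samples) != records$n_samples[i])
      stop_io("sample count mismatch for ", records$epoch_id[i])
    epochs[[records$epoch_id[i]]] <-
      eeg_epoch(samples, fs, epoch_id = records$epoch_id[i],
                group = records$group[i])
  }
  structure(list(epochs = epochs, manifest = records,
                 params = list(seed = man$seed)), class = "eeg_cohort")
}

# ---- minimal EDF (16-bit European Data Format), one data record ----

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop_io("EDF header field too long: '", x, "'")
  formatC(x, width = width, flag = "-")
}

#' Write signals to a minimal EDF file
#'
#' One data record holding all samples; physical dimension microvolts;
#' symmetric integer physical range covering the data (so header values
#' round-trip exactly through their ASCII fields).
#'
#' @param path Output file.
#' @param signals List of equal-length numeric vectors (channels).
#' @param fs Sampling rate in Hz shared by all channels.
#' @param labels Channel labels (<= 16 ASCII chars).
#' @return Invisibly, `path`.
#' @export
edf_write <- function(path, signals, fs, labels = NULL) {
  if (length(signals) == 0L) stop_input("no signals to write")
  ns <- length(signals)
  n <- unique(vapply(signals, length, integer(1)))
  if (length(n) != 1L) stop_input("all channels must have the same length")
  if (is.null(labels)) labels <- paste0("ch", seq_len(ns))
  dur <- n / fs
  pmax_v <- max(1, ceiling(max(abs(unlist(signals)))))
  pmin_v <- -pmax_v
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("synthetic subject", 80),
    edf_pad("eegsubband cohort", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(1, 8), edf_pad(format(dur, digits = 8), 8), edf_pad(ns, 4),
    paste(vapply(labels, edf_pad, character(1), width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),          # transducer
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),         # physical dim
    paste(rep(edf_pad(pmin_v, 8), ns), collapse = ""),
    paste(rep(edf_pad(pmax_v, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),          # prefiltering
    paste(rep(edf_pad(n, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  scale <- (dmax - dmin) / (pmax_v - pmin_v)
  for (sig in signals) {
    dig <- as.integer(round((sig - pmin_v) * scale) + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a minimal EDF file
#'
#' Supports the subset written by [edf_write()] plus any standard EDF with a
#' whole number of data records and identical sampling rate across channels.
#'
#' @param path EDF file.
#' @return List: `signals` (list of numeric vectors, physical units),
#'   `fs`, `labels`.
#' @export
edf_read <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop_io("not an EDF file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    out <- readChar(con, w, useBytes = TRUE)
    if (nchar(out, type = "bytes") < w) stop_io("truncated EDF header: ", path)
    trimws(out)
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (anyNA(c(hdr_bytes, n_rec, dur, ns)) || ns < 1L)
    stop_io("malformed EDF header: ", path)
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16); fld(80); dims <- fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80); spr <- as.integer(fld(8)); fld(32)
  if (anyNA(c(pmin, pmax, dmin, dmax, spr))) stop_io("malformed EDF signal headers: ", path)
  expected <- hdr_bytes + 2 * n_rec * sum(spr)
  if (sz < expected) stop_io("truncated EDF data (", sz, " < ", expected,
                             " bytes): ", path)
  fs <- spr / dur
  if (length(unique(fs)) != 1L)
    stop_io("channels disagree on sampling rate in ", path)
  signals <- lapply(seq_len(ns), function(i) numeric(0))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2L, endian = "little")
      phys <- (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) + pmin[i]
      signals[[i]] <- c(signals[[i]], phys)
    }
  }
  list(signals = signals, fs = fs[1], labels = labels)
}

#' Write result tables and a JSON run log
#'
#' @param tables Named list of data.frames; each is written as
#'   `<name>.csv` with a stable column order.
#' @param out_dir Output directory (created if needed).
#' @param run_info Optional named list (seed, parameters, ...) recorded in
#'   `run_log.json` along with the package version.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, run_info = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_io("cannot create output directory ", out_dir)
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  log <- c(list(package = "eegsubband",
                version = as.character(utils::packageVersion("eegsubband"))),
           run_info)
  lp <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, lp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, lp))
}

#' Write a feature table as CSV
#'
#' Canonical header `epoch_id,group,delta_pct,theta_pct,alpha_pct,beta_pct`
#' (the residual column is an internal diagnostic and is included last).
#'
#' @param features A `feature_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(features, path) {
  cols <- c("epoch_id", "group", "delta_pct", "theta_pct", "alpha_pct",
            "beta_pct")
  if ("residual_pct" %in% names(features)) cols <- c(cols, "residual_pct")
  write.csv(features[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table CSV
#' @param path CSV written by [write_feature_table()].
#' @return A `feature_table` data.frame.
#' @export
read_feature_table <- function(path) {
  ft <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_id", "group", "delta_pct", "theta_pct", "alpha_pct", "beta_pct")
  if (!all(need %in% names(ft)))
    stop_io("feature table missing columns: ",
            paste(setdiff(need, names(ft)), collapse = ", "))
  class(ft) <- c("feature_table", class(ft))
  ft
}
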