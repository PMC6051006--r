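#' EEG epoch container
#'
#' An epoch is the unit of analysis throughout the package: a single-channel
#' EEG segment in microvolts at a fixed sampling rate, optionally carrying a
#' diagnostic group label.
#'
#' @param samples Numeric vector of sample values in microvolts. Must be
#'   finite and non-empty.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param epoch_id Character identifier, unique within a cohort.
#' @param group One of `"normal"`, `"encephalopathy"`, `"unknown"`.
#' @return An object of class `eeg_epoch`: a list with elements `samples`,
#'   `fs`, `epoch_id`, `group`.
#' @examples
#' e <- eeg_epoch(sin(2 * pi * 10 * seq(0, 1, by = 1 / 250)), fs = 250)
#' e
#' @export
eeg_epoch <- function(samples, fs, epoch_id = "epoch",
                      group = c("unknown", "normal", "encephalopathy")) {
  group <- match.arg(group)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop_input("epoch has no samples")
  if (!all(is.finite(samples))) stop_input("epoch samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_input("fs must be a positive scalar (Hz)")
  structure(list(samples = samples, fs = fs,
                 epoch_id = as.character(epoch_id), group = group),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch '%s'> %d samples @ %g Hz (%.3g s), group=%s, RMS=%.3g uV\n",
              x$epoch_id, length(x$samples), x$fs, length(x$samples) / x$fs,
              x$group, sqrt(mean(x$samples^2))))
  invisible(x)
}

#' @export
length.eeg_epoch <- function(x) length(x$samples)

# accept either an epoch or a bare numeric vector + fs
as_samples <- function(x, fs = NULL) {
  if (inherits(x, "eeg_epoch")) return(list(samples = x$samples, fs = x$fs))
  if (is.null(fs)) stop_input("fs is required when the input is a bare numeric vector")
  list(samples = as.numeric(x), fs = fs)
}
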