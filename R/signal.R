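#' Construct a single-channel signal
#'
#' A lightweight container for a uniformly sampled one-dimensional time
#' series, typically a single EEG channel in microvolts.
#'
#' @param samples Numeric vector of amplitude values (length >= 2, all
#'   finite).
#' @param fs Sampling rate in Hz (strictly positive). Default 173.61, the
#'   rate of the Bonn university EEG distribution.
#' @param label Optional class tag, e.g. `"normal"`, `"interictal"`,
#'   `"ictal"`.
#' @return An object of class `eeg_signal`: a list with elements `samples`,
#'   `fs` and `label`.
#' @examples
#' x <- ts_signal(sin(2 * pi * 5 * (0:499) / 100), fs = 100)
#' x
#' @export
ts_signal <- function(samples, fs = 173.61, label = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("a signal needs at least 2 samples, got ", length(samples))
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("signal samples must all be finite (no NA/NaN/Inf)")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single strictly positive number")
  structure(list(samples = samples, fs = as.numeric(fs), label = label),
            class = "eeg_signal")
}

#' @export
print.eeg_signal <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<eeg_signal> %d samples @ %.6g Hz (%.3g s)%s\n",
              length(x$samples), x$fs, dur,
              if (is.null(x$label)) "" else paste0(", label: ", x$label)))
  invisible(x)
}

#' Test for / coerce to eeg_signal
#'
#' `as_ts_signal()` accepts an `eeg_signal` (returned unchanged) or a bare
#' numeric vector (wrapped with the supplied `fs`).
#'
#' @param x Object to test or coerce.
#' @param fs Sampling rate used when `x` is a bare numeric vector.
#' @return `is_ts_signal()` a logical; `as_ts_signal()` an `eeg_signal`.
#' @export
is_ts_signal <- function(x) inherits(x, "eeg_signal")

#' @rdname is_ts_signal
#' @export
as_ts_signal <- function(x, fs = 173.61) {
  if (is_ts_signal(x)) return(x)
  if (is.numeric(x)) return(ts_signal(x, fs = fs))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to eeg_signal")
}

#' Extract a prefix window from a signal
#'
#' Returns the first `floor(length_s * fs)` samples as a new signal with the
#' same sampling rate and label. Windows are anchored at the start of the
#' record so that every (record, window length) cell of a sweep is
#' comparable.
#'
#' @param signal An [ts_signal()] object.
#' @param length_s Window length in seconds (strictly positive).
#' @return An `eeg_signal` holding the prefix window.
#' @examples
#' rec <- ts_signal(rnorm(4096), fs = 173.61)
#' length(window_signal(rec, 1)$samples)   # 173 samples
#' @export
window_signal <- function(signal, length_s) {
  signal <- as_ts_signal(signal)
  if (!is.numeric(length_s) || length(length_s) != 1L || length_s <= 0)
    stop("length_s must be a single positive number")
  n <- floor(length_s * signal$fs)
  if (n > length(signal$samples))
    stop(sprintf(
      "window of %.6g s (%d samples at %.6g Hz) exceeds record length %d",
      length_s, n, signal$fs, length(signal$samples)))
  ts_signal(signal$samples[seq_len(n)], fs = signal$fs, label = signal$label)
}
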