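#' Pure sinusoid test signal
#'
#' Unit-amplitude sine with phase 0 at t = 0, sampled at `fs_hz` for
#' `duration_s` seconds. Deterministic and noise-free; used by the
#' consistency sweep over data lengths and bin counts.
#'
#' @param freq_hz Frequency in Hz (> 0).
#' @param fs_hz Sampling rate in Hz (> 0). A rate at or below the Nyquist
#'   limit `2 * freq_hz` triggers a warning, not an error, so aliasing can
#'   be studied deliberately.
#' @param duration_s Duration in seconds (> 0).
#' @return An [ts_signal()] of `round(fs_hz * duration_s)` samples.
#' @examples
#' s <- sinusoid(50, 500, 2)   # 1000 samples
#' s$samples[1]                # 0
#' @export
sinusoid <- function(freq_hz, fs_hz = 500, duration_s = 2) {
  stopifnot(is.numeric(freq_hz), freq_hz > 0,
            is.numeric(fs_hz), fs_hz > 0,
            is.numeric(duration_s), duration_s > 0)
  if (fs_hz <= 2 * freq_hz)
    warning(sprintf("fs = %.6g Hz does not exceed the Nyquist rate for %.6g Hz; the sampled sinusoid is aliased",
                    fs_hz, freq_hz))
  n <- round(fs_hz * duration_s)
  t <- (seq_len(n) - 1) / fs_hz
  ts_signal(sin(2 * pi * freq_hz * t), fs = fs_hz)
}

#' Surrogate EEG record
#'
#' Seeded generator of single-channel EEG-like records in three regimes:
#'
#' * `normal` — band-limited 1/f-shaped background noise (0.5–40 Hz).
#' * `interictal` — the same background plus sporadic high-amplitude
#'   biphasic transients (epileptiform discharges); their rate and
#'   amplitude scale with `effect`.
#' * `ictal` — background plus a sustained high-amplitude rhythmic
#'   spike-wave component with a fundamental drawn in 3–5 Hz, the canonical
#'   generalized-seizure signature; amplitude scales with `effect`.
#'
#' `effect = 0` removes every class-specific component, collapsing all
#' three regimes onto the same background generator (a null dataset). The
#' generator is a controlled test fixture for the analysis pipeline, not a
#' physiological model.
#'
#' @param class `"normal"`, `"interictal"` or `"ictal"`.
#' @param fs Sampling rate in Hz.
#' @param n_samples Record length in samples.
#' @param seed Integer seed; identical arguments give bit-identical output.
#' @param effect Non-negative class-separation strength (1 = default
#'   regime).
#' @return An [ts_signal()] with `label` set to `class`.
#' @examples
#' rec <- surrogate_record("ictal", seed = 7)
#' rec
#' @export
surrogate_record <- function(class = c("normal", "interictal", "ictal"),
                             fs = 173.61, n_samples = 4096L, seed = 1L,
                             effect = 1) {
  class <- match.arg(class)
  stopifnot(is.numeric(effect), length(effect) == 1L, effect >= 0)
  n_samples <- check_count(n_samples, "n_samples")
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  x <- band_noise(n_samples, fs, f_lo = 0.5, f_hi = 40)
  bg_sd <- 50                       # background scale, arbitrary µV-like units
  x <- bg_sd * x
  dur <- n_samples / fs
  t <- (seq_len(n_samples) - 1) / fs

  if (class == "interictal") {
    # sporadic biphasic transients: Ricker wavelets, ~100 ms, random sign
    n_spk <- stats::rpois(1, lambda = 0.5 * dur * effect)
    if (n_spk > 0) {
      centers <- stats::runif(n_spk, 0.1, dur - 0.1)
      amps <- effect * bg_sd * stats::runif(n_spk, 3, 5) *
        sample(c(-1, 1), n_spk, replace = TRUE)
      sigma <- 0.02                 # seconds; sharp spike
      for (k in seq_len(n_spk)) {
        u <- (t - centers[k]) / sigma
        x <- x + amps[k] * (1 - u^2) * exp(-u^2 / 2)
      }
    }
  } else if (class == "ictal") {
    # sustained rhythmic spike-wave: 3-5 Hz fundamental plus harmonics
    f0 <- stats::runif(1, 3, 5)
    phi <- stats::runif(1, 0, 2 * pi)
    theta <- 2 * pi * f0 * t + phi
    sw <- sin(theta) + 0.6 * sin(2 * theta + 1.2) + 0.3 * sin(3 * theta + 2.4)
    sw <- sw / sqrt(mean(sw^2))
    x <- x + effect * 3 * bg_sd * sw
  }
  ts_signal(x, fs = fs, label = class)
}

# 1/f-amplitude band-limited Gaussian noise via FFT filtering, unit
# population SD. Uses the current RNG stream.
band_noise <- function(n, fs, f_lo, f_hi) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)              # two-sided frequency axis
  gain <- ifelse(f >= f_lo & f <= f_hi, 1 / sqrt(pmax(f, 1)), 0)
  x <- Re(stats::fft(spec * gain, inverse = TRUE)) / n
  x / sqrt(mean((x - mean(x))^2))
}

#' Bonn-style five-set surrogate dataset
#'
#' Generates the full five-set layout used by the Bonn EEG distribution:
#' sets A and B are normal, C and D interictal, and E ictal, each holding
#' `records_per_set` records of `n_samples` samples at `fs` Hz. Per-record
#' seeds are derived from the master seed through a set/record counter, so
#' generating fewer records per set never changes the content of the ones
#' that are generated.
#'
#' @param seed Master integer seed.
#' @param records_per_set Number of records per set (>= 1; the reference
#'   layout uses 100).
#' @param effect Class-separation strength passed to [surrogate_record()].
#' @param fs Sampling rate in Hz.
#' @param n_samples Record length in samples.
#' @return A [labeled_dataset()].
#' @examples
#' ds <- make_bonn_like(seed = 1, records_per_set = 2)
#' ds
#' @export
make_bonn_like <- function(seed, records_per_set = 100L, effect = 1,
                           fs = 173.61, n_samples = 4096L) {
  records_per_set <- check_count(records_per_set, "records_per_set")
  set_ids <- c("A", "B", "C", "D", "E")
  sets <- lapply(seq_along(set_ids), function(si) {
    cls <- set_class_map()[[set_ids[si]]]
    lapply(seq_len(records_per_set), function(ri) {
      surrogate_record(cls, fs = fs, n_samples = n_samples,
                       seed = derive_seed(seed, si, ri), effect = effect)
    })
  })
  names(sets) <- set_ids
  labeled_dataset(sets)
}

# counter-based per-record seed; distinct (set, record) counters map to
# distinct seeds below 2^31 for any master seed
derive_seed <- function(seed, set_index, record_index) {
  base <- as.integer(seed) %% 100000L
  base * 20011L + set_index * 100000L + record_index
}
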