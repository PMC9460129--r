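# Voltage-to-displacement calibration and Hamming-windowed single-sided
# amplitude spectra of tracing-vibration displacement traces.

#' Construct a vibration trace
#'
#' A uniformly sampled time series recorded while the tactile sensor traces
#' a sample, either as raw strain-gauge voltage or as vertical displacement.
#'
#' @param values Numeric series, length >= 2.
#' @param sampling_rate Sampling rate in Hz (the study apparatus records at
#'   10 kHz).
#' @param unit `"volt"` (raw gauge output) or `"micrometer"` (displacement).
#' @param sample_id,repetition Provenance of the recording.
#' @return Object of class `vibration_trace`.
#' @export
vibration_trace <- function(values, sampling_rate = 10000,
                            unit = c("micrometer", "volt"),
                            sample_id = NA_character_, repetition = 1L) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(values), length(values) >= 2L,
            is.numeric(sampling_rate), sampling_rate > 0, repetition >= 1L)
  structure(list(values = as.numeric(values),
                 sampling_rate = sampling_rate, unit = unit,
                 sample_id = as.character(sample_id),
                 repetition = as.integer(repetition)),
            class = "vibration_trace")
}

#' @export
print.vibration_trace <- function(x, ...) {
  cat(sprintf("Vibration trace '%s' rep %d: %d samples @ %g Hz (%.3g s), unit %s\n",
              x$sample_id, x$repetition, length(x$values), x$sampling_rate,
              length(x$values) / x$sampling_rate, x$unit))
  invisible(x)
}

#' Convert strain-gauge voltage to vertical displacement
#'
#' Applies the sensor's linear calibration `d = -1409.4 V + 710.35`
#' (micrometres from volts). The constant 710.35 um offset is the static
#' preload of the leaf spring; it lands in the DC bin and is removed before
#' spectral analysis.
#'
#' @param x Numeric voltage series, or a [vibration_trace()] with unit
#'   `"volt"`. A trace already in micrometres is returned unchanged with a
#'   warning.
#' @return Same shape as the input, in micrometres.
#' @examples
#' strain_to_displacement(0)   # 710.35
#' @export
strain_to_displacement <- function(x) {
  if (inherits(x, "vibration_trace")) {
    if (x$unit == "micrometer") {
      warning("trace is already in micrometres; returning it unchanged")
      return(x)
    }
    x$values <- -1409.4 * x$values + 710.35
    x$unit <- "micrometer"
    return(x)
  }
  stopifnot(is.numeric(x))
  -1409.4 * x + 710.35
}

#' Single-sided amplitude spectrum of a displacement trace
#'
#' The trace (micrometres) is reduced to at most `n_fft` samples (central
#' portion by default, where tracing is in steady state), mean-removed,
#' multiplied by a Hamming window, zero-padded to `n_fft` and transformed
#' with an FFT. Amplitudes are single-sided and divided by the window's
#' coherent gain (`sum(w)/2` per side), so a pure sinusoid at a bin
#' frequency reports its time-domain peak amplitude in the peak bin.
#'
#' @param trace A [vibration_trace()] in micrometres.
#' @param n_fft FFT length; default 32768 points (2^15, covering a 3 s trace
#'   at 10 kHz with zero padding).
#' @param segment For traces longer than `n_fft`: analyse the `"center"`
#'   (default) or the `"start"` of the trace.
#' @return Object of class `amplitude_spectrum` with fields `frequency`
#'   (Hz, 0 to Nyquist), `amplitude` (um peak per bin), `window`, `n_fft`,
#'   `sampling_rate`, `sample_id`, `repetition`.
#' @examples
#' tr <- vibration_trace(10 * sin(2 * pi * 100 * seq(0, 0.4095, by = 1e-4)),
#'                       10000)
#' sp <- compute_spectrum(tr, n_fft = 4096)
#' sp$amplitude[which.min(abs(sp$frequency - 100))]  # ~10
#' @export
compute_spectrum <- function(trace, n_fft = 32768L,
                             segment = c("center", "start")) {
  stopifnot(inherits(trace, "vibration_trace"))
  if (trace$unit != "micrometer") {
    stop("trace must be in micrometres; apply strain_to_displacement() first")
  }
  segment <- match.arg(segment)
  n_fft <- as.integer(n_fft)
  stopifnot(n_fft >= 8L)
  x <- trace$values
  if (length(x) > n_fft) {
    off <- if (segment == "center") (length(x) - n_fft) %/% 2L else 0L
    x <- x[(off + 1L):(off + n_fft)]
  }
  x <- x - mean(x)
  w <- signal::hamming(length(x))
  xw <- x * w
  if (length(xw) < n_fft) xw <- c(xw, numeric(n_fft - length(xw)))
  X <- stats::fft(xw)
  half <- n_fft %/% 2L + 1L
  amp <- Mod(X[seq_len(half)]) / sum(w)
  # double every bin that has a mirrored negative-frequency partner
  dbl <- seq_len(half) > 1L & (n_fft %% 2L == 1L | seq_len(half) < half)
  amp[dbl] <- 2 * amp[dbl]
  structure(list(frequency = (seq_len(half) - 1L) * trace$sampling_rate / n_fft,
                 amplitude = amp, window = "hamming", n_fft = n_fft,
                 sampling_rate = trace$sampling_rate,
                 sample_id = trace$sample_id, repetition = trace$repetition),
            class = "amplitude_spectrum")
}

#' @export
print.amplitude_spectrum <- function(x, ...) {
  cat(sprintf("Amplitude spectrum '%s' rep %d: %d bins, df = %g Hz, %s window (n_fft %d)\n",
              x$sample_id, x$repetition, length(x$frequency),
              x$sampling_rate / x$n_fft, x$window, x$n_fft))
  invisible(x)
}

#' Amplitude spectrum in decibels
#'
#' `20 * log10(amplitude / ref)`; zero (or sub-floor) amplitudes are clamped
#' to `floor_db` so the dB view is finite everywhere.
#'
#' @param spec An `amplitude_spectrum`, or a numeric amplitude vector.
#' @param ref Reference amplitude (default 1 um, matching the dB scale of
#'   the threshold curves).
#' @param floor_db Value assigned to zero amplitude.
#' @return For a spectrum input, an object of class `db_spectrum` with
#'   fields `frequency` and `db`; for a numeric input, a numeric vector.
#' @export
spectrum_to_db <- function(spec, ref = 1, floor_db = -120) {
  stopifnot(ref > 0)
  to_db <- function(a) {
    out <- rep(floor_db, length(a))
    pos <- a > 0
    out[pos] <- pmax(20 * log10(a[pos] / ref), floor_db)
    out
  }
  if (is.numeric(spec)) return(to_db(spec))
  stopifnot(inherits(spec, "amplitude_spectrum"))
  structure(list(frequency = spec$frequency, db = to_db(spec$amplitude),
                 ref = ref, floor_db = floor_db,
                 sample_id = spec$sample_id, repetition = spec$repetition),
            class = "db_spectrum")
}

#' Convert decibel amplitudes back to linear units
#'
#' Inverse of [spectrum_to_db()] above the floor.
#'
#' @param db Numeric dB values.
#' @param ref Reference amplitude.
#' @return Numeric amplitudes.
#' @export
db_to_amplitude <- function(db, ref = 1) ref * 10^(db / 20)

#' Build a dB spectrum object directly
#'
#' Convenience constructor for analytic or fixture spectra specified in dB.
#'
#' @param frequency Ascending frequencies (Hz).
#' @param db dB values, same length.
#' @param sample_id,repetition Optional provenance.
#' @return A `db_spectrum`.
#' @export
db_spectrum <- function(frequency, db, sample_id = NA_character_,
                        repetition = 1L) {
  stopifnot(length(frequency) == length(db), length(frequency) >= 2L,
            !is.unsorted(frequency, strictly = TRUE))
  structure(list(frequency = as.numeric(frequency), db = as.numeric(db),
                 ref = 1, floor_db = min(db),
                 sample_id = as.character(sample_id),
                 repetition = as.integer(repetition)),
            class = "db_spectrum")
}

#' Read a vibration trace from CSV
#'
#' Expects columns `time_s` and `value`; the sampling rate is inferred from
#' the median time step unless given.
#'
#' @param path CSV file.
#' @param unit Unit of `value`.
#' @param sample_id,repetition Provenance.
#' @param sampling_rate Override the inferred rate (Hz).
#' @return A [vibration_trace()].
#' @export
read_trace_csv <- function(path, unit = c("volt", "micrometer"),
                           sample_id = NA_character_, repetition = 1L,
                           sampling_rate = NULL) {
  unit <- match.arg(unit)
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "value") %in% names(d)))
  if (is.null(sampling_rate)) {
    sampling_rate <- 1 / stats::median(diff(d$time_s))
  }
  vibration_trace(d$value, sampling_rate, unit, sample_id, repetition)
}

#' Write an amplitude spectrum to CSV
#'
#' @param spec An `amplitude_spectrum`.
#' @param path Output CSV (`frequency_hz`, `amplitude_um`).
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "amplitude_spectrum"))
  utils::write.csv(data.frame(frequency_hz = spec$frequency,
                              amplitude_um = spec$amplitude),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' @param path CSV with columns `sample_id`, `mu_prime` and optionally
#'   `ra_um`, `wa_um`, `normal_force_n`.
#' @return Data frame; errors if `mu_prime` is missing or non-positive.
#' @export
read_sample_metadata <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "mu_prime") %in% names(d)))
  if (any(!is.finite(d$mu_prime)) || any(d$mu_prime <= 0)) {
    stop("'mu_prime' must be positive for every sample")
  }
  d
}
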