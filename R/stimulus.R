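#' Define a periodic pulse-train stimulation protocol
#'
#' A protocol describes a rectangular pulse train: pulses of height
#' `amplitude` and width `pulse_width_s` repeating at `frequency_hz`,
#' starting at `onset_s` and lasting `duration_s`. The duty cycle
#' `d = frequency_hz * pulse_width_s` must lie in (0, 1].
#'
#' @param frequency_hz Fundamental repetition rate (Hz).
#' @param pulse_width_s Duration of each pulse (s).
#' @param amplitude Pulse height (arbitrary units, > 0).
#' @param onset_s Start time of the train within the recording (s).
#' @param duration_s Total stimulation time (s).
#' @param label Free-text description (e.g. `"620nm visual"`).
#' @return An object of class `stim_protocol`.
#' @examples
#' stim_protocol(0.6, 0.4, label = "620nm visual, 400 ms")
#' @export
stim_protocol <- function(frequency_hz, pulse_width_s, amplitude = 1,
                          onset_s = 0, duration_s = Inf,
                          label = "") {
  stopifnot(is.numeric(frequency_hz), frequency_hz > 0,
            is.numeric(pulse_width_s), pulse_width_s > 0,
            is.numeric(amplitude), amplitude > 0,
            onset_s >= 0, duration_s > 0)
  if (pulse_width_s > 1 / frequency_hz + 1e-12) {
    stop("pulse_width_s must not exceed the period 1/frequency_hz ",
         "(duty cycle must be <= 1)")
  }
  structure(list(frequency_hz = frequency_hz,
                 pulse_width_s = pulse_width_s,
                 amplitude = amplitude,
                 onset_s = onset_s,
                 duration_s = duration_s,
                 label = label),
            class = "stim_protocol")
}

#' Duty cycle of a protocol
#'
#' @param protocol A [stim_protocol()].
#' @return `frequency_hz * pulse_width_s`, the on-fraction of each period.
#' @export
duty_cycle <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  protocol$frequency_hz * protocol$pulse_width_s
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %.4g Hz, %.4g-ms pulses (duty %.3g), A = %.3g\n",
              x$frequency_hz, 1000 * x$pulse_width_s, duty_cycle(x),
              x$amplitude))
  cat(sprintf("  onset %.3g s, duration %s s%s\n", x$onset_s,
              format(x$duration_s),
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

#' Sample a rectangular pulse train
#'
#' Samples the protocol's ideal rectangular pulse train at rate `fs`.
#' Sample `i` (0-based) maps to time `i/fs`; each pulse occupies the
#' left-closed, right-open window `[onset + k/f, onset + k/f + width)`,
#' so a sample landing exactly on a pulse offset is low.
#'
#' @param protocol A [stim_protocol()].
#' @param fs Sampling rate (Hz); must exceed twice the fundamental.
#' @param total_duration_s Length of the returned signal (s).
#' @return Numeric vector of length `round(fs * total_duration_s)`.
#' @examples
#' p <- stim_protocol(0.6, 0.4)
#' x <- pulse_train(p, fs = 500, total_duration_s = 10)
#' mean(x == 1)  # the duty cycle, 0.24
#' @export
pulse_train <- function(protocol, fs, total_duration_s) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive number")
  if (fs <= 2 * protocol$frequency_hz)
    stop("fs must exceed twice the fundamental frequency")
  if (total_duration_s < protocol$onset_s)
    stop("total_duration_s must be at least onset_s")
  n <- round(fs * total_duration_s)
  f <- protocol$frequency_hz
  stim_end <- min(total_duration_s,
                  protocol$onset_s + protocol$duration_s)
  x <- numeric(n)
  # explicit per-pulse sample windows: sample i (0-based) is high iff
  # i/fs lies in [start, start + width); the epsilon guards make edge
  # rounding consistent across pulses when boundaries hit sample times
  k <- 0
  repeat {
    start <- protocol$onset_s + k / f
    if (start >= stim_end - 1e-12) break
    i0 <- ceiling(start * fs - 1e-9)
    i1 <- ceiling((start + protocol$pulse_width_s) * fs - 1e-9) - 1
    i1 <- min(i1, n - 1, ceiling(stim_end * fs - 1e-9) - 1)
    if (i0 <= i1) x[(i0 + 1):(i1 + 1)] <- protocol$amplitude
    k <- k + 1
  }
  x
}

#' Closed-form Fourier series of a rectangular pulse train
#'
#' For an ideal rectangular pulse train of height `A` and duty cycle `d`,
#' the mean level is `A*d` and the amplitude of the n-th harmonic
#' (at frequency `n*f`) is `A_n = (2A / (n*pi)) * |sin(n*pi*d)|`.
#' Harmonics with integer `n*d` fall on zeros of the sinc envelope and
#' vanish exactly; for a 50%-duty square wave all even harmonics vanish.
#' This is the analytic oracle against which measured spectra of
#' non-sinusoidal stimulus-locked responses are compared.
#'
#' @param protocol A [stim_protocol()].
#' @param n_harmonics Number of harmonics to return (>= 1).
#' @return An object of class `harmonic_spectrum`: list with `dc`,
#'   `harmonic_amplitudes` (length `n_harmonics`), `freqs_hz` and the
#'   generating `protocol`.
#' @examples
#' fourier_oracle(stim_protocol(1, 0.5), 4)$harmonic_amplitudes
#' @export
fourier_oracle <- function(protocol, n_harmonics) {
  stopifnot(inherits(protocol, "stim_protocol"),
            is.numeric(n_harmonics), n_harmonics >= 1)
  n <- seq_len(as.integer(n_harmonics))
  d <- duty_cycle(protocol)
  A <- protocol$amplitude
  amps <- (2 * A / (n * pi)) * abs(sin(n * pi * d))
  # snap sinc-envelope zeros (integer n*d) to exact zero
  amps[abs(n * d - round(n * d)) < 1e-12] <- 0
  structure(list(dc = A * d,
                 harmonic_amplitudes = amps,
                 freqs_hz = n * protocol$frequency_hz,
                 protocol = protocol),
            class = "harmonic_spectrum")
}

#' @export
print.harmonic_spectrum <- function(x, ...) {
  cat(sprintf("<harmonic_spectrum> dc = %.4g; %d harmonics of %.4g Hz\n",
              x$dc, length(x$harmonic_amplitudes),
              x$protocol$frequency_hz))
  print(data.frame(n = seq_along(x$harmonic_amplitudes),
                   freq_hz = x$freqs_hz,
                   amplitude = x$harmonic_amplitudes))
  invisible(x)
}
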