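#' Specification of a synthetic EEG/EMG recording
#'
#' Parameters of the ground-truth generator. Defaults emulate a 24-h
#' mouse telemetry recording at 500 Hz scored in 5-s epochs under a
#' 12 h:12 h light/dark cycle, starting at ZT3 (the standard
#' stimulation start): light-period transition probabilities favour
#' sleep, dark-period ones favour wake; NREM epochs carry a
#' delta-band oscillation, REM epochs a theta-band oscillation, wake
#' is desynchronized and low-amplitude; EMG tone separates wake
#' (high) from NREM and REM (atonia). The per-pulse evoked potential
#' is a damped slow ring (1.0-Hz ring, 0.3-s decay) whose energy is
#' concentrated at low frequency, so a 0.6-Hz pulse train produces a
#' dominant fundamental line plus harmonics, as observed for
#' visual-evoked responses to slow periodic stimulation.
#'
#' @param fs Sampling rate (Hz).
#' @param epoch_len_s Scoring epoch (s); `fs * epoch_len_s` must be an
#'   integer.
#' @param total_hours Recording length (h).
#' @param start_zt ZT hour of the first sample (ZT0 = lights-on).
#' @param transition_light,transition_dark 3x3 per-epoch transition
#'   matrices over (WAKE, NREM, REM); rows must sum to 1.
#' @param initial_state State of epoch 0.
#' @param state_spectra Per-state oscillator parameters: for NREM and
#'   REM a band `c(lo, hi)` (Hz) and RMS amplitude (uV); for wake a
#'   broadband band and RMS.
#' @param background 1/f background: `exponent` (PSD slope) and
#'   `scale` (RMS, uV); `scale = 0` disables it.
#' @param emg_rms Named per-state EMG RMS levels (uV); must satisfy
#'   `WAKE > NREM >= REM`.
#' @param evoked Per-pulse evoked-potential kernel: `amplitude` (peak,
#'   uV; 0 disables), `decay_s` (exponential decay time-constant),
#'   `ring_hz` (ring frequency).
#' @param noise_seed RNG seed (integer).
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(fs = 500, epoch_len_s = 5, total_hours = 24,
                       start_zt = 3,
                       transition_light = default_transitions()$light,
                       transition_dark = default_transitions()$dark,
                       initial_state = "WAKE",
                       state_spectra = list(
                         NREM = list(band = c(0.5, 2.5), rms = 40),
                         REM  = list(band = c(5.5, 7.5), rms = 30),
                         WAKE = list(band = c(0.5, 30), rms = 12)),
                       background = list(exponent = 1.0, scale = 10),
                       emg_rms = c(WAKE = 30, NREM = 8, REM = 4),
                       evoked = list(amplitude = 25, decay_s = 0.3,
                                     ring_hz = 1.0),
                       noise_seed = 1L) {
  spec <- structure(list(fs = fs, epoch_len_s = epoch_len_s,
                         total_hours = total_hours, start_zt = start_zt,
                         transition_light = transition_light,
                         transition_dark = transition_dark,
                         initial_state = initial_state,
                         state_spectra = state_spectra,
                         background = background, emg_rms = emg_rms,
                         evoked = evoked,
                         noise_seed = as.integer(noise_seed)),
                    class = "synth_spec")
  validate_synth_spec(spec)
  spec
}

#' Default light/dark epoch transition matrices
#'
#' Per-5-s-epoch probabilities over (WAKE, NREM, REM). The light-period
#' matrix favours sleep (mice are nocturnal), the dark-period matrix
#' favours wake; REM is entered only from NREM, as in normal rodent
#' sleep.
#' @return List with 3x3 matrices `light` and `dark`.
#' @export
default_transitions <- function() {
  s <- vigilance_states()
  light <- matrix(c(0.90, 0.10, 0.00,
                    0.05, 0.93, 0.02,
                    0.08, 0.02, 0.90),
                  nrow = 3, byrow = TRUE, dimnames = list(s, s))
  dark <- matrix(c(0.970, 0.030, 0.000,
                   0.090, 0.895, 0.015,
                   0.120, 0.030, 0.850),
                 nrow = 3, byrow = TRUE, dimnames = list(s, s))
  list(light = light, dark = dark)
}

validate_synth_spec <- function(spec) {
  stopifnot(spec$fs > 0, spec$epoch_len_s > 0, spec$total_hours > 0)
  spe <- spec$fs * spec$epoch_len_s
  if (abs(spe - round(spe)) > 1e-9)
    stop("fs * epoch_len_s must be an integer")
  for (tm in list(spec$transition_light, spec$transition_dark)) {
    if (!is.matrix(tm) || any(dim(tm) != 3))
      stop("transition matrices must be 3x3")
    if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-12))
      stop("each transition-matrix row must be non-negative and sum to 1")
  }
  e <- spec$emg_rms
  if (!(e[["WAKE"]] > e[["NREM"]] && e[["NREM"]] >= e[["REM"]]))
    stop("emg_rms must satisfy WAKE > NREM >= REM")
  if (!spec$initial_state %in% vigilance_states())
    stop("initial_state must be WAKE, NREM or REM")
  invisible(spec)
}

#' Generate a ground-truth hypnogram
#'
#' Epoch-resolution Markov-chain state sequence: each epoch's
#' transition matrix is the light or dark matrix according to the
#' epoch's ZT. Seeded and reproducible from `spec$noise_seed`.
#'
#' @param spec A [synth_spec()].
#' @return A [hypnogram()] with `attr(,"start_zt")` from the spec.
#' @export
generate_hypnogram <- function(spec) {
  validate_synth_spec(spec)
  if (spec$total_hours <= 0) stop("total_hours must be positive")
  ne <- round(spec$total_hours * 3600 / spec$epoch_len_s)
  set.seed(spec$noise_seed)
  states <- character(ne)
  cur <- spec$initial_state
  s <- vigilance_states()
  for (i in seq_len(ne)) {
    states[i] <- cur
    zt <- (spec$start_zt + (i - 1) * spec$epoch_len_s / 3600) %% 24
    tm <- if (zt < 12) spec$transition_light else spec$transition_dark
    cur <- sample(s, 1, prob = tm[cur, ])
  }
  hypnogram(states, epoch_len_s = spec$epoch_len_s,
            start_zt = spec$start_zt)
}

# Gaussian 1/f^exponent noise of unit RMS, synthesized by spectral
# shaping in sqrt-Hann chunks with 50% overlap-add (power-complementary,
# so the output is stationary with no seams).
pink_noise <- function(n, fs, exponent) {
  L <- 2^17
  if (n < L) L <- 2^ceiling(log2(max(n, 1024)))
  H <- L %/% 2
  w <- sqrt(0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L)))  # periodic root-Hann
  f <- (0:(L %/% 2)) * fs / L
  gain <- c(0, f[-1]^(-exponent / 2))
  # keep samples H+1 .. H+n so every kept sample has full two-window
  # (power-complementary) coverage
  out <- numeric(n + 2 * L)
  nchunks <- ceiling((n + H) / H) + 1
  for (ck in seq_len(nchunks)) {
    half <- (stats::rnorm(L %/% 2 + 1) +
               1i * stats::rnorm(L %/% 2 + 1)) / sqrt(2)
    half[1] <- 0
    half[L %/% 2 + 1] <- Re(half[L %/% 2 + 1]) * sqrt(2)
    spec_full <- c(half, Conj(rev(half[2:(L %/% 2)])))
    spec_full[1:(L %/% 2 + 1)] <- spec_full[1:(L %/% 2 + 1)] * gain
    spec_full[(L %/% 2 + 2):L] <- spec_full[(L %/% 2 + 2):L] *
      rev(gain[2:(L %/% 2)])
    x <- Re(stats::fft(spec_full, inverse = TRUE)) / L
    a <- (ck - 1) * H + 1
    out[a:(a + L - 1)] <- out[a:(a + L - 1)] + x * w
  }
  out <- out[H + seq_len(n)]
  out / stats::sd(out)
}

# raised-cosine gate for a state run: 1 inside, 0.1-s crossfade ramps
# centered on the run boundaries
run_envelope <- function(m, ramp_n, ramp_in, ramp_out) {
  env <- rep(1, m)
  if (ramp_in && m >= ramp_n) {
    u <- (seq_len(ramp_n) - 0.5) / ramp_n
    env[seq_len(ramp_n)] <- sin(pi * u / 2)^2
  }
  if (ramp_out && m >= ramp_n) {
    u <- (seq_len(ramp_n) - 0.5) / ramp_n
    env[m - ramp_n + seq_len(ramp_n)] <- rev(sin(pi * u / 2)^2)
  }
  env
}

# band-limited Gaussian noise of target RMS (butterworth + filtfilt,
# generated with warm-up padding to suppress filter transients)
bandlimited_noise <- function(m, fs, band, rms) {
  pad <- round(3 * fs)
  x <- stats::rnorm(m + 2 * pad)
  ny <- fs / 2
  bf <- signal::butter(2, c(max(band[1], 0.01), min(band[2], 0.99 * ny)) / ny,
                       type = "pass")
  x <- signal::filtfilt(bf, x)
  x <- x[pad + seq_len(m)]
  s <- stats::sd(x)
  if (s == 0) return(numeric(m))
  x / s * rms
}

#' Per-pulse evoked-potential kernel
#'
#' Damped oscillation `exp(-t/decay) * sin(2*pi*ring*t)` over
#' `[0, 5*decay]`, normalized to the requested peak amplitude.
#'
#' @param evoked List with `amplitude`, `decay_s`, `ring_hz`.
#' @param fs Sampling rate (Hz).
#' @return Numeric vector (empty when `amplitude = 0`).
#' @export
evoked_kernel <- function(evoked, fs) {
  if (evoked$amplitude == 0) return(numeric(0))
  t <- seq(0, 5 * evoked$decay_s, by = 1 / fs)
  k <- exp(-t / evoked$decay_s) * sin(2 * pi * evoked$ring_hz * t)
  k / max(abs(k)) * evoked$amplitude
}

#' Generate a synthetic EEG/EMG recording
#'
#' EEG = 1/f background + state-gated band-limited oscillators (gated
#' by the hypnogram with 0.1-s raised-cosine crossfades at state
#' boundaries, to avoid broadband boundary clicks) + (optionally) the
#' evoked kernel placed at every pulse onset of the protocol. EMG =
#' white noise with per-state RMS, crossfaded at boundaries. Seeded
#' from `spec$noise_seed + 1` (offset from the hypnogram stream), so
#' identical spec + seed give bit-identical recordings, and the same
#' seed with/without a protocol shares its noise realization.
#'
#' @param hyp A [hypnogram()] (typically from [generate_hypnogram()]).
#' @param spec A [synth_spec()]; its epoch grid must match `hyp`.
#' @param protocol Optional [stim_protocol()]. Pulse onsets trigger the
#'   evoked kernel; the protocol's `amplitude` multiplies the kernel.
#' @return An [recording()] with the protocol stored as annotation.
#' @export
generate_recording <- function(hyp, spec, protocol = NULL) {
  validate_synth_spec(spec)
  stopifnot(inherits(hyp, "hypnogram"))
  if (abs(attr(hyp, "epoch_len_s") - spec$epoch_len_s) > 1e-9)
    stop("hypnogram epoch length does not match spec")
  fs <- spec$fs
  spe <- round(fs * spec$epoch_len_s)
  n <- nrow(hyp) * spe
  set.seed(spec$noise_seed + 1L)

  eeg <- if (spec$background$scale > 0)
    pink_noise(n, fs, spec$background$exponent) * spec$background$scale
  else numeric(n)

  ramp_n <- round(0.1 * fs)
  half <- ramp_n %/% 2
  lab <- as.character(hyp$state)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  emg_env <- numeric(n)
  for (j in seq_along(r$values)) {
    s <- r$values[j]
    a <- (starts[j] - 1) * spe + 1
    b <- ends[j] * spe
    a2 <- max(1, a - half); b2 <- min(n, b + half)
    m <- b2 - a2 + 1
    env <- run_envelope(m, ramp_n, ramp_in = a2 > 1, ramp_out = b2 < n)
    par <- spec$state_spectra[[s]]
    if (!is.null(par) && par$rms > 0)
      eeg[a2:b2] <- eeg[a2:b2] +
        bandlimited_noise(m, fs, par$band, par$rms) * env
    emg_env[a2:b2] <- emg_env[a2:b2] + spec$emg_rms[[s]] * env
  }
  emg <- stats::rnorm(n) * emg_env

  if (!is.null(protocol) && spec$evoked$amplitude > 0) {
    k <- evoked_kernel(spec$evoked, fs) * protocol$amplitude
    dur <- n / fs
    stim_end <- min(dur, protocol$onset_s + protocol$duration_s)
    onsets <- if (stim_end > protocol$onset_s)
      seq(protocol$onset_s, stim_end - 1e-9,
          by = 1 / protocol$frequency_hz)
    else numeric(0)
    for (t0 in onsets) {
      i0 <- round(t0 * fs) + 1
      len <- min(length(k), n - i0 + 1)
      if (len > 0) eeg[i0:(i0 + len - 1)] <- eeg[i0:(i0 + len - 1)] +
          k[seq_len(len)]
    }
  }
  recording(eeg, emg, fs = fs, start_zt = attr(hyp, "start_zt"),
            subject_id = sprintf("synthetic-seed%d", spec$noise_seed),
            protocol = protocol)
}

#' Noiseless calibration signals
#'
#' Pure sine or rectangular pulse-train test signals, mirroring the
#' bench demonstration that a sinusoid yields a single spectral peak
#' while a square wave yields a fundamental plus integer harmonics.
#' The EMG channel is all-zero.
#'
#' @param kind `"sine"` or `"square"`.
#' @param frequency_hz Fundamental frequency (Hz).
#' @param pulse_width_s Pulse width (s); required for `"square"`.
#' @param fs Sampling rate (Hz).
#' @param duration_s Signal length (s).
#' @param amplitude Peak amplitude.
#' @return An [recording()].
#' @export
calibration_signal <- function(kind = c("sine", "square"), frequency_hz,
                               pulse_width_s = NULL, fs = 500,
                               duration_s = 60, amplitude = 1) {
  kind <- match.arg(kind)
  n <- round(fs * duration_s)
  if (kind == "sine") {
    t <- (seq_len(n) - 1) / fs
    x <- amplitude * sin(2 * pi * frequency_hz * t)
    proto <- NULL
  } else {
    if (is.null(pulse_width_s))
      stop("square calibration signals need pulse_width_s")
    proto <- stim_protocol(frequency_hz, pulse_width_s,
                           amplitude = amplitude,
                           label = "calibration square")
    x <- pulse_train(proto, fs, duration_s)
  }
  recording(x, numeric(n), fs = fs,
            subject_id = paste0("calibration-", kind), protocol = proto)
}
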