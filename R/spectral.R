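#' Frequency grid of the epoch PSD
#'
#' Bin `k` (0-based) is centered at `k * fs / nfft` Hz. With the default
#' 5-s, 500-Hz epochs zero-padded to 4096 points the spacing is
#' 500/4096 = 0.1220703125 Hz, matching the conventional 0.12207-Hz
#' resolution of rodent sleep-EEG spectra.
#'
#' @param fs Sampling rate (Hz).
#' @param nfft FFT length (default 4096).
#' @return Numeric vector of one-sided bin-center frequencies
#'   (length `nfft/2 + 1`).
#' @export
psd_freqs <- function(fs = 500, nfft = 4096) {
  (0:(nfft %/% 2)) * fs / nfft
}

# symmetric Hann window, as used by conventional sleep-EEG FFT software
hanning_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

#' Power spectrum of one scoring epoch
#'
#' Applies a Hann window to the epoch, zero-pads to `nfft` samples and
#' returns the squared modulus of the one-sided FFT. No single-sided
#' energy doubling or density scaling is applied: all downstream use is
#' relative (cross-state normalization cancels scale).
#'
#' @param x Numeric vector, one epoch of samples (length `fs *
#'   epoch_len_s`, at most `nfft`).
#' @param fs Sampling rate (Hz).
#' @param nfft FFT length; default 4096 (the only power of two giving
#'   the 0.12207-Hz grid at fs = 500 for 5-s epochs).
#' @param expected_len If non-NULL, the epoch length is checked against
#'   it (default `2500` when `fs = 500`).
#' @return Numeric vector of raw power per bin on the [psd_freqs()] grid.
#' @export
epoch_psd <- function(x, fs = 500, nfft = 4096,
                      expected_len = round(fs * 5)) {
  stopifnot(is.numeric(x))
  if (!is.null(expected_len) && length(x) != expected_len)
    stop("epoch has ", length(x), " samples; expected ", expected_len)
  n <- length(x)
  if (n > nfft) stop("epoch longer than nfft")
  xw <- x * hanning_window(n)
  X <- stats::fft(c(xw, rep(0, nfft - n)))
  Mod(X[1:(nfft %/% 2 + 1)])^2
}

#' Standard analysis band definitions
#'
#' Closed intervals of bin-center frequency (Hz). `stimulation`
#' (0.49-0.61) and `delta_analysis` (0.49-4.52) are the stimulation-band
#' and delta-band analysis intervals; their printed edges are the
#' 2-decimal-rounded bin centers 0.4883/0.6104/4.5166 of the 0.12207-Hz
#' grid. `delta_scoring` (0.5-4.5) and `theta` (4-9) are the scoring
#' bands; `total` (0.5-20) is the normalization band.
#'
#' @param name One of `"stimulation"`, `"delta_analysis"`,
#'   `"delta_scoring"`, `"theta"`, `"total"`.
#' @return A `band_definition`: list with `lo_hz`, `hi_hz`, `name`.
#' @export
band_definition <- function(name = c("stimulation", "delta_analysis",
                                     "delta_scoring", "theta", "total")) {
  name <- match.arg(name)
  edges <- switch(name,
                  stimulation    = c(0.49, 0.61),
                  delta_analysis = c(0.49, 4.52),
                  delta_scoring  = c(0.5, 4.5),
                  theta          = c(4, 9),
                  total          = c(0.5, 20))
  band(edges[1], edges[2], name)
}

#' Custom frequency band
#' @param lo_hz,hi_hz Band edges (Hz), `0 < lo_hz < hi_hz`.
#' @param name Band label.
#' @return A `band_definition` object.
#' @export
band <- function(lo_hz, hi_hz, name = "custom") {
  stopifnot(lo_hz > 0, lo_hz < hi_hz)
  structure(list(lo_hz = lo_hz, hi_hz = hi_hz, name = name),
            class = "band_definition")
}

#' Bins belonging to a band
#'
#' Membership is decided on the bin center rounded to 2 decimals, lying
#' in the closed interval `[lo_hz, hi_hz]` — so the stimulation band
#' (0.49-0.61) resolves to bins 4-5 and the analysis delta band
#' (0.49-4.52) to bins 4-37 of the default grid.
#'
#' @param band A [band()] or [band_definition()].
#' @param freqs Bin-center frequencies, default [psd_freqs()].
#' @return Integer indices into `freqs` (1-based).
#' @export
band_bins <- function(band, freqs = psd_freqs()) {
  stopifnot(inherits(band, "band_definition"))
  r <- round(freqs, 2)
  idx <- which(r >= band$lo_hz & r <= band$hi_hz)
  if (length(idx) == 0)
    stop("band [", band$lo_hz, ", ", band$hi_hz,
         "] contains no bins of the grid")
  idx
}

#' Artifact exclusion mask from per-epoch metrics
#'
#' Epoch `i` is flagged iff `|m_i - mean(m)| > multiplier * SEM(m)`,
#' with `SEM = sd(m)/sqrt(N)` over all epochs of the recording — the
#' literal "more than 10xSEM" exclusion rule, two-sided, applied to the
#' per-epoch EEG RMS. The multiplier is configurable; note that for
#' large N the rule is aggressive since the SEM shrinks as 1/sqrt(N).
#'
#' @param epoch_metrics Numeric vector of per-epoch metrics (EEG RMS).
#' @param multiplier Exclusion multiplier (default 10); `Inf` disables
#'   exclusion.
#' @return Logical vector: `TRUE` = excluded as artifact.
#' @export
artifact_mask <- function(epoch_metrics, multiplier = 10) {
  stopifnot(is.numeric(epoch_metrics), multiplier > 0)
  n <- length(epoch_metrics)
  if (n < 2) return(rep(FALSE, n))
  m <- mean(epoch_metrics)
  sem <- stats::sd(epoch_metrics) / sqrt(n)
  if (!is.finite(multiplier)) return(rep(FALSE, n))
  abs(epoch_metrics - m) > multiplier * sem
}

# split a recording channel into complete epochs (matrix: samples x epochs)
epoch_matrix <- function(x, fs, epoch_len_s) {
  spe <- round(fs * epoch_len_s)
  ne <- floor(length(x) / spe)
  matrix(x[seq_len(ne * spe)], nrow = spe, ncol = ne)
}

#' State-conditioned normalized power spectral density
#'
#' Computes the per-epoch Hann/FFT power spectrum ([epoch_psd()]),
#' drops artifact epochs, averages within each vigilance state over the
#' analysis window, and normalizes across states: the reference value
#' `R` is the mean over the states present of each state's summed mean
#' power over the total band (0.5-20 Hz), and every bin is expressed as
#' `100 * P / R` (percent of reference). By construction the
#' equal-weight mean across states of the per-state 0.5-20 Hz totals is
#' 100%. The reported grid covers bins whose rounded centers fall in
#' [0.49, 20] Hz (bins 4-163 by default), so the stimulation band's
#' first bin (0.4883 Hz) is retained.
#'
#' @param rec An [recording()].
#' @param hyp A [hypnogram()] covering the window.
#' @param window_s Optional `c(start, end)` in seconds from the start of
#'   the recording (default: full recording). Both 24-h and 2-h windows
#'   are supported this way.
#' @param artifact_multiplier Multiplier for [artifact_mask()] computed
#'   on per-epoch EEG RMS over the *whole* recording (default 10).
#' @param nfft FFT length (default 4096).
#' @return A `state_psd` object: list with `freqs`, `power` (named list
#'   of per-state normalized spectra; states with zero usable epochs are
#'   absent), `n_epochs` (named counts), `reference_value` (raw units),
#'   `artifact_excluded` (count), `window_s`.
#' @export
state_psd <- function(rec, hyp, window_s = NULL,
                      artifact_multiplier = 10, nfft = 4096) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(hyp, "hypnogram"))
  epoch_len_s <- attr(hyp, "epoch_len_s")
  spe <- round(rec$fs * epoch_len_s)
  em <- epoch_matrix(rec$eeg, rec$fs, epoch_len_s)
  ne <- ncol(em)
  if (nrow(hyp) < ne)
    stop("hypnogram (", nrow(hyp), " epochs) does not cover the ",
         "recording (", ne, " epochs)")
  if (is.null(window_s)) window_s <- c(0, ne * epoch_len_s)
  starts <- (seq_len(ne) - 1) * epoch_len_s
  in_win <- starts >= window_s[1] & (starts + epoch_len_s) <= window_s[2]
  if (!any(in_win)) stop("analysis window contains no complete epoch")

  rms <- sqrt(colMeans(em^2))
  art <- artifact_mask(rms, artifact_multiplier) | hyp$artifact[seq_len(ne)]

  freqs_all <- psd_freqs(rec$fs, nfft)
  keep_bins <- which(round(freqs_all, 2) >= 0.49 & round(freqs_all, 2) <= 20)
  total_bins_local <- which(round(freqs_all[keep_bins], 2) >= 0.5)

  use <- in_win & !art
  states <- as.character(hyp$state[seq_len(ne)])
  power <- list(); counts <- integer(0)
  for (s in vigilance_states()) {
    idx <- which(use & states == s)
    counts[s] <- length(idx)
    if (length(idx) == 0) next
    acc <- numeric(length(keep_bins))
    for (i in idx)
      acc <- acc + epoch_psd(em[, i], rec$fs, nfft)[keep_bins]
    power[[s]] <- acc / length(idx)
  }
  if (length(power) == 0) stop("no usable epochs in any state")
  R <- mean(vapply(power, function(p) sum(p[total_bins_local]), 0))
  power <- lapply(power, function(p) 100 * p / R)
  structure(list(freqs = freqs_all[keep_bins], power = power,
                 n_epochs = counts, reference_value = R,
                 artifact_excluded = sum(art & in_win),
                 window_s = window_s,
                 epoch_len_s = epoch_len_s, nfft = nfft, fs = rec$fs),
            class = "state_psd")
}

#' @export
print.state_psd <- function(x, ...) {
  cat(sprintf("<state_psd> %.4g-%.4g Hz in %.5g-Hz bins; window %g-%g s\n",
              min(x$freqs), max(x$freqs), diff(x$freqs[1:2]),
              x$window_s[1], x$window_s[2]))
  cat("  epochs:", paste(names(x$n_epochs), x$n_epochs, collapse = ", "),
      sprintf(" (artifact-excluded: %d)\n", x$artifact_excluded))
  invisible(x)
}

#' Tidy data.frame view of a state PSD
#' @param x A `state_psd`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return data.frame with columns `state`, `freq_hz`, `power_pct`,
#'   `n_epochs`.
#' @export
as.data.frame.state_psd <- function(x, row.names = NULL,
                                    optional = FALSE, ...) {
  do.call(rbind, lapply(names(x$power), function(s) {
    data.frame(state = s, freq_hz = x$freqs, power_pct = x$power[[s]],
               n_epochs = unname(x$n_epochs[s]))
  }))
}

#' Band power of a normalized state spectrum
#'
#' Sum of normalized power over the band's bins (membership by
#' 2-decimal rounding of bin centers, closed interval).
#'
#' @param psd A `state_psd` (from [state_psd()]).
#' @param band A [band_definition()] or [band()].
#' @param state State label; required when the PSD holds several states.
#' @return Scalar band power in percent-of-reference units.
#' @export
band_power <- function(psd, band, state = NULL) {
  stopifnot(inherits(psd, "state_psd"))
  if (is.null(state)) {
    if (length(psd$power) != 1)
      stop("psd holds several states; give `state`")
    state <- names(psd$power)
  }
  if (!state %in% names(psd$power))
    stop("no spectrum for state ", state,
         " (states present: ", paste(names(psd$power), collapse = ", "), ")")
  idx <- band_bins(band, psd$freqs)
  sum(psd$power[[state]][idx])
}

#' Percent change of a quantity vs. baseline
#'
#' @param stim_value Value under stimulation.
#' @param baseline_value Baseline value (> 0).
#' @return `100 * (stim - baseline) / baseline`.
#' @examples
#' percent_change(1.644, 1.0)  # 64.4
#' @export
percent_change <- function(stim_value, baseline_value) {
  if (any(baseline_value <= 0)) stop("baseline_value must be > 0")
  100 * (stim_value - baseline_value) / baseline_value
}

#' Per-epoch spectrogram of one vigilance state
#'
#' Raw (un-normalized) per-epoch power spectra of the requested state's
#' artifact-free epochs, columns ordered on the epoch time axis; epochs
#' of other states leave gaps in `epoch_start_s`.
#'
#' @inheritParams state_psd
#' @param state State label (`"WAKE"`, `"NREM"`, `"REM"`).
#' @return List with `freqs`, `power` (bins x epochs matrix),
#'   `epoch_start_s`, `state`.
#' @export
spectrogram <- function(rec, hyp, state, artifact_multiplier = 10,
                        nfft = 4096) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(hyp, "hypnogram"),
            state %in% vigilance_states())
  epoch_len_s <- attr(hyp, "epoch_len_s")
  em <- epoch_matrix(rec$eeg, rec$fs, epoch_len_s)
  ne <- ncol(em)
  rms <- sqrt(colMeans(em^2))
  art <- artifact_mask(rms, artifact_multiplier) | hyp$artifact[seq_len(ne)]
  idx <- which(as.character(hyp$state[seq_len(ne)]) == state & !art)
  freqs_all <- psd_freqs(rec$fs, nfft)
  keep <- which(round(freqs_all, 2) >= 0.49 & round(freqs_all, 2) <= 20)
  pw <- vapply(idx, function(i) epoch_psd(em[, i], rec$fs, nfft)[keep],
               numeric(length(keep)))
  list(freqs = freqs_all[keep],
       power = matrix(pw, nrow = length(keep)),
       epoch_start_s = (idx - 1) * epoch_len_s, state = state)
}
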