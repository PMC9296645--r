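#' Detect spectral peaks
#'
#' Local maxima (strictly greater than both neighbours) whose height is
#' at least `rel_threshold` times the global maximum. Ties between
#' equal maxima separated by lower bins are both reported. Endpoints
#' are not peaks; an all-zero spectrum yields an empty list.
#'
#' @param psd A `state_psd` (single state, or give `state`) or a
#'   numeric power vector.
#' @param freqs Bin-center frequencies; taken from the `state_psd` when
#'   omitted.
#' @param rel_threshold Height threshold as a fraction of the global
#'   maximum (default 0.01).
#' @param state State label when `psd` holds several states.
#' @return A `peak_list`: data.frame with `freq_hz`, `power`,
#'   `prominence`, plus attribute `rel_threshold`.
#' @export
detect_peaks <- function(psd, freqs = NULL, rel_threshold = 0.01,
                         state = NULL) {
  stopifnot(rel_threshold > 0, rel_threshold < 1)
  if (inherits(psd, "state_psd")) {
    if (is.null(state)) {
      if (length(psd$power) != 1)
        stop("psd holds several states; give `state`")
      state <- names(psd$power)
    }
    freqs <- psd$freqs
    p <- psd$power[[state]]
  } else {
    p <- as.numeric(psd)
    if (is.null(freqs)) stop("freqs required for a raw spectrum")
  }
  stopifnot(length(p) == length(freqs), length(p) > 0)
  empty <- data.frame(freq_hz = numeric(0), power = numeric(0),
                      prominence = numeric(0))
  if (max(p) <= 0)
    return(structure(empty, rel_threshold = rel_threshold,
                     class = c("peak_list", "data.frame")))
  n <- length(p)
  if (n < 3)
    return(structure(empty, rel_threshold = rel_threshold,
                     class = c("peak_list", "data.frame")))
  i <- 2:(n - 1)
  is_pk <- p[i] > p[i - 1] & p[i] > p[i + 1]
  idx <- i[is_pk & p[i] >= rel_threshold * max(p)]
  prom <- vapply(idx, function(j) peak_prominence(p, j), 0)
  structure(data.frame(freq_hz = freqs[idx], power = p[idx],
                       prominence = prom),
            rel_threshold = rel_threshold,
            class = c("peak_list", "data.frame"))
}

# topographic prominence: height above the higher of the two valley
# floors encountered before reaching higher ground (or the spectrum
# edge) on each side
peak_prominence <- function(p, j) {
  n <- length(p)
  higher_l <- which(p[seq_len(j - 1)] > p[j])
  from_l <- if (length(higher_l)) max(higher_l) + 1 else 1
  valley_l <- min(p[from_l:j])
  higher_r <- which(p[(j + 1):n] > p[j])
  to_r <- if (length(higher_r)) j + min(higher_r) - 1 else n
  valley_r <- min(p[j:to_r])
  p[j] - max(valley_l, valley_r)
}

#' Match peaks to integer harmonics of a fundamental
#'
#' Harmonic index `n` is matched if some peak lies within
#' `tol_bins * delta_f` of `n * f0`. The default tolerance of one bin
#' accommodates fundamentals that fall between bin centers (0.6 Hz sits
#' between the 0.4883- and 0.6104-Hz bins of the default grid).
#'
#' @param peaks A `peak_list` from [detect_peaks()].
#' @param f0 Fundamental frequency (Hz, > 0).
#' @param tol_bins Matching tolerance in bins (default 1).
#' @param delta_f Bin spacing (Hz); default the 0.12207-Hz grid.
#' @param n_max Highest harmonic index to consider; default up to the
#'   largest peak frequency.
#' @return Sorted integer vector of matched harmonic indices.
#' @export
harmonic_structure <- function(peaks, f0, tol_bins = 1,
                               delta_f = 500 / 4096, n_max = NULL) {
  stopifnot(inherits(peaks, "peak_list"), f0 > 0)
  if (nrow(peaks) == 0) return(integer(0))
  if (is.null(n_max)) n_max <- max(1, floor(max(peaks$freq_hz) / f0 + 0.5))
  tol <- tol_bins * delta_f
  matched <- vapply(seq_len(n_max), function(n)
    any(abs(peaks$freq_hz - n * f0) <= tol + 1e-12), logical(1))
  which(matched)
}

#' Compare measured harmonic peaks to the Fourier oracle
#'
#' For each harmonic with non-zero oracle amplitude, the measured
#' amplitude is `sqrt(peak power)` rescaled so that the fundamental
#' matches the oracle exactly (consistent scaling calibrated on
#' n = 1); the per-harmonic relative amplitude error
#' `|measured - A_n| / A_n` is returned. A missing expected harmonic is
#' reported as error 1 (absent). Intended for noiseless calibration
#' input.
#'
#' @param peaks A `peak_list` measured on a calibration spectrum.
#' @param oracle A `harmonic_spectrum` from [fourier_oracle()].
#' @param tol_bins,delta_f Peak-to-harmonic matching tolerance, as in
#'   [harmonic_structure()].
#' @return data.frame: `n`, `freq_hz`, `oracle_amplitude`,
#'   `measured_amplitude` (NA when absent), `rel_error`.
#' @export
compare_to_oracle <- function(peaks, oracle, tol_bins = 1,
                              delta_f = 500 / 4096) {
  stopifnot(inherits(peaks, "peak_list"),
            inherits(oracle, "harmonic_spectrum"))
  f0 <- oracle$protocol$frequency_hz
  tol <- tol_bins * delta_f
  nn <- which(oracle$harmonic_amplitudes > 0)
  meas_amp <- vapply(nn, function(n) {
    hit <- which(abs(peaks$freq_hz - n * f0) <= tol + 1e-12)
    if (length(hit) == 0) return(NA_real_)
    sqrt(max(peaks$power[hit]))
  }, 0)
  if (length(nn) == 0) stop("oracle has no non-zero harmonics")
  if (is.na(meas_amp[1]))
    stop("fundamental not found among peaks; cannot calibrate scale")
  scale <- oracle$harmonic_amplitudes[nn[1]] / meas_amp[1]
  scaled <- meas_amp * scale
  rel <- abs(scaled - oracle$harmonic_amplitudes[nn]) /
    oracle$harmonic_amplitudes[nn]
  rel[is.na(rel)] <- 1
  data.frame(n = nn, freq_hz = nn * f0,
             oracle_amplitude = oracle$harmonic_amplitudes[nn],
             measured_amplitude = scaled, rel_error = rel)
}
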