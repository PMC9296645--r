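#' Vigilance-state labels
#'
#' The three vigilance states used throughout: `WAKE`, `NREM`, `REM`.
#' @return Character vector of the state labels, in canonical order.
#' @export
vigilance_states <- function() c("WAKE", "NREM", "REM")

#' Construct an EEG/EMG recording
#'
#' Paired EEG and EMG sample streams at a common fixed sampling rate.
#' Time convention: sample `i` (0-based) covers `[i/fs, (i+1)/fs)`.
#'
#' @param eeg Numeric vector, EEG samples (uV, nominal).
#' @param emg Numeric vector, EMG samples (uV, nominal); same length as
#'   `eeg`.
#' @param fs Sampling rate (Hz), default 500 (the telemetry rate).
#' @param start_zt Zeitgeber time of sample 0, in hours since lights-on
#'   (ZT0 = lights-on; 12 h light : 12 h dark).
#' @param subject_id Subject label.
#' @param protocol Optional [stim_protocol()] annotation describing
#'   stimulation delivered during the recording.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(eeg, emg, fs = 500, start_zt = 0,
                      subject_id = "synthetic", protocol = NULL) {
  stopifnot(is.numeric(eeg), is.numeric(emg), fs > 0)
  if (length(eeg) != length(emg))
    stop("eeg and emg must have equal length")
  if (!is.null(protocol)) stopifnot(inherits(protocol, "stim_protocol"))
  structure(list(eeg = as.numeric(eeg), emg = as.numeric(emg),
                 fs = fs, start_zt = start_zt,
                 subject_id = subject_id, protocol = protocol),
            class = "eeg_recording")
}

#' Duration of a recording in seconds
#' @param rec An [recording()].
#' @return Length of the sample streams divided by `fs`.
#' @export
rec_duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  length(rec$eeg) / rec$fs
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> '%s': %.6g s at %g Hz (ZT%.3g start)%s\n",
              x$subject_id, rec_duration(x), x$fs, x$start_zt,
              if (!is.null(x$protocol)) " + stimulation" else ""))
  invisible(x)
}

#' Construct a hypnogram
#'
#' Per-epoch vigilance-state labels with artifact flags. Epoch `e`
#' (0-based) covers samples `[e*fs*epoch_len_s, (e+1)*fs*epoch_len_s)`.
#'
#' @param states Character or factor vector over `WAKE`/`NREM`/`REM`.
#' @param epoch_len_s Epoch length in seconds (default 5).
#' @param artifact Logical vector of per-epoch artifact flags (recycled
#'   if scalar).
#' @param start_zt Zeitgeber time (hours) of epoch 0.
#' @return An object of class `hypnogram`: a data.frame with columns
#'   `epoch_index`, `start_s`, `state`, `artifact` and attributes
#'   `epoch_len_s`, `start_zt`.
#' @export
hypnogram <- function(states, epoch_len_s = 5, artifact = FALSE,
                      start_zt = 0) {
  states <- as.character(states)
  if (!all(states %in% vigilance_states()))
    stop("states must be WAKE, NREM or REM")
  stopifnot(epoch_len_s > 0)
  n <- length(states)
  artifact <- rep_len(as.logical(artifact), n)
  out <- data.frame(epoch_index = seq_len(n) - 1L,
                    start_s = (seq_len(n) - 1L) * epoch_len_s,
                    state = factor(states, levels = vigilance_states()),
                    artifact = artifact)
  structure(out, epoch_len_s = epoch_len_s, start_zt = start_zt,
            class = c("hypnogram", "data.frame"))
}

#' @export
print.hypnogram <- function(x, ...) {
  n <- nrow(x)
  tab <- table(x$state)
  cat(sprintf("<hypnogram> %d epochs of %g s (%.3g h), %d artifact\n",
              n, attr(x, "epoch_len_s"),
              n * attr(x, "epoch_len_s") / 3600, sum(x$artifact)))
  print(tab)
  invisible(x)
}

#' Number of complete epochs of a recording
#' @param rec An [recording()].
#' @param epoch_len_s Epoch length (s).
#' @return Integer count of complete epochs; a trailing partial epoch is
#'   not counted.
#' @export
n_epochs <- function(rec, epoch_len_s = 5) {
  spe <- rec$fs * epoch_len_s
  if (abs(spe - round(spe)) > 1e-9)
    stop("fs * epoch_len_s must be an integer number of samples")
  as.integer(floor(length(rec$eeg) / round(spe)))
}
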