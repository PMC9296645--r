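#' Per-epoch scoring features
#'
#' Splits the recording into complete scoring epochs (a trailing
#' partial epoch is dropped) and computes, per epoch, the band powers
#' used by the scoring rules — delta 0.5-4.5 Hz, theta 4-9 Hz, total
#' 0.5-20 Hz, from the raw Hann/FFT epoch spectrum — plus the EEG RMS
#' amplitude and EMG RMS.
#'
#' @param rec An [recording()].
#' @param epoch_len_s Epoch length in seconds (default 5).
#' @param nfft FFT length (default 4096).
#' @return data.frame with one row per epoch: `epoch_index`, `start_s`,
#'   `delta_power`, `theta_power`, `total_power`, `eeg_amplitude`,
#'   `emg_rms`.
#' @export
compute_epoch_features <- function(rec, epoch_len_s = 5, nfft = 4096) {
  stopifnot(inherits(rec, "eeg_recording"))
  ne <- n_epochs(rec, epoch_len_s)
  if (ne < 1) stop("recording shorter than one epoch")
  em_eeg <- epoch_matrix(rec$eeg, rec$fs, epoch_len_s)
  em_emg <- epoch_matrix(rec$emg, rec$fs, epoch_len_s)
  freqs <- psd_freqs(rec$fs, nfft)
  bd <- band_bins(band_definition("delta_scoring"), freqs)
  bt <- band_bins(band_definition("theta"), freqs)
  btot <- band_bins(band_definition("total"), freqs)
  delta <- theta <- total <- numeric(ne)
  for (i in seq_len(ne)) {
    p <- epoch_psd(em_eeg[, i], rec$fs, nfft)
    delta[i] <- sum(p[bd]); theta[i] <- sum(p[bt]); total[i] <- sum(p[btot])
  }
  data.frame(epoch_index = seq_len(ne) - 1L,
             start_s = (seq_len(ne) - 1L) * epoch_len_s,
             delta_power = delta, theta_power = theta, total_power = total,
             eeg_amplitude = sqrt(colMeans(em_eeg^2)),
             emg_rms = sqrt(colMeans(em_emg^2)))
}

#' Calibrate scoring thresholds from epoch features
#'
#' The EMG threshold separates the two modes of the per-epoch EMG-RMS
#' distribution (high muscle tone in wake, atonia in sleep): 1-D
#' 2-means clustering, threshold at the midpoint of the two cluster
#' centers. If the distribution is effectively unimodal (cluster
#' separation below three times the pooled within-cluster spread, or zero
#' variance), the calibration falls back to the 75th percentile with a
#' warning. The theta/delta ratio threshold defaults to 2.0.
#'
#' @param features data.frame from [compute_epoch_features()] (>= 100
#'   epochs recommended).
#' @param theta_delta_threshold REM theta/delta ratio threshold
#'   (default 2.0).
#' @return List with `emg` (EMG RMS threshold), `theta_delta`, and
#'   `emg_fallback` (logical: percentile fallback used).
#' @export
calibrate_thresholds <- function(features, theta_delta_threshold = 2.0) {
  stopifnot(is.data.frame(features), "emg_rms" %in% names(features))
  m <- features$emg_rms
  fallback <- FALSE
  if (length(unique(m)) < 3 || stats::sd(m) == 0) {
    fallback <- TRUE
  } else {
    km <- stats::kmeans(m, centers = range(m), iter.max = 50)
    cen <- sort(as.numeric(km$centers))
    within_sd <- sqrt(km$tot.withinss / max(1, length(m) - 2))
    # a split unimodal Gaussian yields diff/within-sd ~ 2.65; require > 3
    if (diff(cen) < 3 * within_sd || any(km$size == 0)) {
      fallback <- TRUE
    } else {
      thr <- mean(cen)
    }
  }
  if (fallback) {
    warning("EMG RMS distribution looks unimodal; ",
            "falling back to the 75th percentile threshold")
    thr <- stats::quantile(m, 0.75, names = FALSE)
  }
  list(emg = thr, theta_delta = theta_delta_threshold,
       emg_fallback = fallback)
}

#' Score epochs into vigilance states
#'
#' Decision tree mirroring the conventional scoring criteria, in
#' precedence order: tonic/phasic motor activity defines wake (EMG RMS
#' above the EMG threshold); among low-EMG epochs, a theta/delta power
#' ratio above the ratio threshold indicates REM (theta-dominant,
#' atonic); everything else is NREM (delta-dominant, synchronized).
#' Epochs with zero delta and theta power are scored NREM by convention.
#' An optional 2-epoch majority smoother is available but off by
#' default (no minimum-bout post-filter is applied otherwise).
#'
#' @param features data.frame from [compute_epoch_features()].
#' @param thresholds List from [calibrate_thresholds()] (fields `emg`,
#'   `theta_delta`).
#' @param epoch_len_s Epoch length for the returned hypnogram (s).
#' @param start_zt ZT hour of epoch 0 for the returned hypnogram.
#' @param smooth Apply the majority smoother (default FALSE).
#' @return A [hypnogram()] with one state per feature row.
#' @export
score_epochs <- function(features, thresholds, epoch_len_s = 5,
                         start_zt = 0, smooth = FALSE) {
  stopifnot(all(c("emg_rms", "theta_power", "delta_power") %in%
                  names(features)))
  td <- ifelse(features$delta_power == 0,
               ifelse(features$theta_power == 0, 0, Inf),
               features$theta_power / features$delta_power)
  st <- ifelse(features$emg_rms > thresholds$emg, "WAKE",
               ifelse(td > thresholds$theta_delta, "REM", "NREM"))
  if (smooth) st <- majority_smooth(st)
  hypnogram(st, epoch_len_s = epoch_len_s, start_zt = start_zt)
}

# replace singleton epochs flanked by an identical pair (2-epoch majority)
majority_smooth <- function(st) {
  n <- length(st)
  if (n < 3) return(st)
  out <- st
  for (i in 2:(n - 1)) {
    if (st[i] != st[i - 1] && st[i - 1] == st[i + 1]) out[i] <- st[i - 1]
  }
  out
}

#' Score a single epoch
#'
#' Single-epoch form of [score_epochs()]; a total function over the
#' feature space given calibrated thresholds.
#'
#' @param features One-row data.frame (or list) with `emg_rms`,
#'   `theta_power`, `delta_power`.
#' @param thresholds List with `emg` and `theta_delta`.
#' @return One of `"WAKE"`, `"NREM"`, `"REM"`.
#' @export
score_epoch <- function(features, thresholds) {
  if (features$emg_rms > thresholds$emg) return("WAKE")
  if (features$delta_power == 0)
    return(if (features$theta_power == 0) "NREM" else "REM")
  if (features$theta_power / features$delta_power > thresholds$theta_delta)
    return("REM")
  "NREM"
}

#' Per-block state amounts
#'
#' Time and percent time in each vigilance state within consecutive
#' blocks of `block_hours` (3-h or 12-h in the standard analyses).
#' Artifact epochs are excluded from the denominator. A trailing
#' partial block is dropped. Blocks are tagged light/dark from their
#' midpoint ZT (ZT0 = lights-on, 12:12 LD cycle).
#'
#' @param hyp A [hypnogram()].
#' @param block_hours Block length in hours (default 3).
#' @return data.frame: `block`, `zt_start_h`, `period`
#'   (`"light"`/`"dark"`), `state`, `seconds`, `percent`.
#' @export
state_amounts <- function(hyp, block_hours = 3) {
  stopifnot(inherits(hyp, "hypnogram"), block_hours > 0)
  el <- attr(hyp, "epoch_len_s")
  epb <- block_hours * 3600 / el
  if (abs(epb - round(epb)) > 1e-9)
    stop("block_hours must be an integer number of epochs")
  epb <- round(epb)
  nb <- floor(nrow(hyp) / epb)
  if (nb < 1) stop("hypnogram shorter than one block")
  start_zt <- attr(hyp, "start_zt")
  out <- list()
  for (b in seq_len(nb)) {
    idx <- ((b - 1) * epb + 1):(b * epb)
    st <- hyp$state[idx]; ok <- !hyp$artifact[idx]
    zt0 <- start_zt + (b - 1) * block_hours
    mid <- (zt0 + block_hours / 2) %% 24
    per <- if (mid < 12) "light" else "dark"
    denom <- sum(ok) * el
    for (s in vigilance_states()) {
      secs <- sum(st == s & ok) * el
      out[[length(out) + 1]] <- data.frame(
        block = b, zt_start_h = zt0, period = per, state = s,
        seconds = secs,
        percent = if (denom > 0) 100 * secs / denom else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Bout statistics of a hypnogram
#'
#' A bout is a maximal run of identical consecutive state labels;
#' artifact epochs break runs and belong to no bout. Counts, mean bout
#' durations and total time per state are returned; by construction
#' `bout_count * mean_bout_duration_s = total_time_s` exactly.
#'
#' @param hyp A [hypnogram()].
#' @return data.frame: `state`, `bout_count`, `mean_bout_duration_s`,
#'   `total_time_s`.
#' @export
bout_analysis <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"), nrow(hyp) > 0)
  el <- attr(hyp, "epoch_len_s")
  lab <- as.character(hyp$state)
  lab[hyp$artifact] <- "ARTIFACT"
  r <- rle(lab)
  out <- lapply(vigilance_states(), function(s) {
    k <- which(r$values == s)
    n <- length(k)
    tot <- sum(r$lengths[k]) * el
    data.frame(state = s, bout_count = n,
               mean_bout_duration_s = if (n > 0) tot / n else NA_real_,
               total_time_s = tot)
  })
  do.call(rbind, out)
}

#' Scoring agreement with a reference hypnogram
#'
#' @param scored,truth Two [hypnogram()]s of equal length.
#' @return Fraction of epochs with identical state labels.
#' @export
scoring_agreement <- function(scored, truth) {
  stopifnot(inherits(scored, "hypnogram"), inherits(truth, "hypnogram"))
  n <- min(nrow(scored), nrow(truth))
  mean(as.character(scored$state[seq_len(n)]) ==
         as.character(truth$state[seq_len(n)]))
}
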