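pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Minimal European Data Format writer: two int16 channels labelled
#' `EEG` and `EMG`, 1-s data records, physical range symmetric about
#' zero at the channel's absolute maximum (so the quantization step is
#' `2*max|x| / 65535`). The recording is truncated to whole 1-s
#' records. The subject id and start ZT are stored in the header.
#'
#' @param rec An [recording()]; `fs` must be an integer.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer needs integer fs")
  fs <- round(fs)
  nrec <- floor(length(rec$eeg) / fs)
  if (nrec < 1) stop("recording shorter than one 1-s data record")
  chans <- list(EEG = rec$eeg[seq_len(nrec * fs)],
                EMG = rec$emg[seq_len(nrec * fs)])
  ns <- 2L
  pmax <- vapply(chans, function(x) max(abs(x), 1e-6), 0)
  dmin <- -32768; dmax <- 32767

  zt_s <- round(rec$start_zt * 3600)
  start_time <- sprintf("%02d.%02d.%02d", (zt_s %/% 3600) %% 24,
                        (zt_s %/% 60) %% 60, zt_s %% 60)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con,
                                     nchars = width, eos = NULL)
  wr("0", 8)
  wr(rec$subject_id, 80)
  wr(sprintf("Startdate 01-JAN-2000 ZT %.6g", rec$start_zt), 80)
  wr("01.01.00", 8)
  wr(start_time, 8)
  wr(256 * (1 + ns), 8)
  wr("", 44)
  wr(nrec, 8)
  wr(1, 8)
  wr(ns, 4)
  for (nm in names(chans)) wr(nm, 16)
  for (nm in names(chans)) wr("", 80)
  for (nm in names(chans)) wr("uV", 8)
  for (nm in names(chans)) wr(sprintf("%.8g", -pmax[[nm]]), 8)
  for (nm in names(chans)) wr(sprintf("%.8g", pmax[[nm]]), 8)
  for (nm in names(chans)) wr(dmin, 8)
  for (nm in names(chans)) wr(dmax, 8)
  for (nm in names(chans)) wr("", 80)
  for (nm in names(chans)) wr(fs, 8)
  for (nm in names(chans)) wr("", 32)

  dig <- lapply(names(chans), function(nm) {
    x <- chans[[nm]]
    as.integer(round((x + pmax[[nm]]) / (2 * pmax[[nm]]) *
                       (dmax - dmin) + dmin))
  })
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in dig) writeBin(ch[idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' Reads the two channels labelled `EEG` and `EMG` written by
#' [write_edf()] (or any EDF with those labels and equal sampling
#' rates). Errors name the available channels when a label is missing,
#' and reject channels with mismatched sampling rates.
#'
#' @param path EDF file path.
#' @return An [recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                        # version
  subject <- rd(80)
  rec_id <- rd(80)
  rd(8)                        # startdate
  start_time <- rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)   # transducer
  for (i in seq_len(ns)) rd(8)    # phys dim
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)   # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)

  need <- c("EEG", "EMG")
  if (!all(need %in% labels))
    stop("EDF file lacks channel(s) ",
         paste(setdiff(need, labels), collapse = ", "),
         "; available: ", paste(labels, collapse = ", "))
  ie <- match("EEG", labels); im <- match("EMG", labels)
  if (spr[ie] != spr[im])
    stop("EEG and EMG sampling rates differ (",
         spr[ie], " vs ", spr[im], " samples per record)")
  fs <- spr[ie] / rec_dur

  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- integer(nrec * spr[i])
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                   endian = "little")
      raw[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- v
    }
  }
  phys <- function(i) (raw[[i]] - dmin[i]) / (dmax[i] - dmin[i]) *
    (pmax[i] - pmin[i]) + pmin[i]
  hms <- as.numeric(strsplit(start_time, ".", fixed = TRUE)[[1]])
  zt <- if (length(hms) == 3 && !anyNA(hms))
    hms[1] + hms[2] / 60 + hms[3] / 3600 else 0
  # prefer the exact ZT stashed in the recording-id field, if present
  m <- regmatches(rec_id, regexpr("ZT [-0-9.eE+]+", rec_id))
  if (length(m) == 1) zt <- as.numeric(sub("ZT ", "", m))
  recording(phys(ie), phys(im), fs = fs, start_zt = zt,
            subject_id = subject)
}

#' Write a hypnogram to CSV
#'
#' Dialect: header `epoch_index,start_s,state,artifact` with states
#' `WAKE`/`NREM`/`REM` and artifact as `TRUE`/`FALSE`.
#'
#' @param hyp A [hypnogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  utils::write.csv(as.data.frame(hyp), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a hypnogram from CSV
#'
#' @param path CSV in the [write_hypnogram_csv()] dialect.
#' @param start_zt ZT hour of epoch 0 (not stored in the dialect).
#' @return A [hypnogram()].
#' @export
read_hypnogram_csv <- function(path, start_zt = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "start_s", "state", "artifact")
  if (!all(need %in% names(df)))
    stop("hypnogram CSV must have columns ",
         paste(need, collapse = ", "))
  el <- if (nrow(df) > 1) as.numeric(df$start_s[2] - df$start_s[1]) else 5
  hypnogram(df$state, epoch_len_s = el,
            artifact = as.logical(df$artifact), start_zt = start_zt)
}

#' Default pipeline configuration
#'
#' @return Named list of the pipeline's tunable settings: `seed`,
#'   `subjects`, `synthetic` (overrides for [synth_spec()]),
#'   `protocol` (arguments of [stim_protocol()]), `analysis`
#'   (`window_hours`, `block_hours`, `artifact_multiplier`,
#'   `theta_delta_threshold`, `smooth_scoring`), `output_dir`.
#' @export
default_config <- function() {
  list(seed = 1L,
       subjects = 2L,
       synthetic = list(total_hours = 1),
       protocol = list(frequency_hz = 0.6, pulse_width_s = 0.4,
                       amplitude = 1, onset_s = 0, duration_s = Inf,
                       label = "620nm visual"),
       analysis = list(window_hours = NULL, block_hours = 3,
                       artifact_multiplier = 10,
                       theta_delta_threshold = 2,
                       smooth_scoring = FALSE),
       output_dir = NULL)
}

merge_validate <- function(user, defaults, where) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
  utils::modifyList(defaults, user)
}

#' Read and validate a pipeline configuration file
#'
#' YAML key-value file; unknown keys are rejected with a message
#' naming them. Missing keys take the [default_config()] values.
#'
#' @param path YAML file path, or a list already in config form.
#' @return Validated config list.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  def <- default_config()
  out <- merge_validate(cfg, def, "top level")
  for (k in c("protocol", "analysis")) {
    if (!is.null(cfg[[k]]))
      out[[k]] <- merge_validate(cfg[[k]], def[[k]], k)
  }
  if (!is.null(cfg$synthetic)) {
    allowed <- setdiff(names(formals(synth_spec)), "noise_seed")
    unknown <- setdiff(names(cfg$synthetic), allowed)
    if (length(unknown) > 0)
      stop("unknown config key(s) in synthetic: ",
           paste(unknown, collapse = ", "))
  }
  out$seed <- as.integer(out$seed)
  out
}
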