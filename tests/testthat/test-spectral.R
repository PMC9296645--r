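test_that("the epoch PSD grid reproduces the 0.12207-Hz bin spacing", {
  f <- psd_freqs(500, 4096)
  expect_equal(f[2] - f[1], 500 / 4096)
  expect_equal(round(f[2] - f[1], 5), 0.12207)
  expect_equal(f, (0:2048) * 500 / 4096)
})

test_that("epoch_psd rejects wrong-length epochs and maps zero to zero", {
  expect_error(epoch_psd(stats::rnorm(100)), "expected 2500")
  expect_true(all(epoch_psd(rep(0, 2500)) == 0))
})

test_that("a 1.22-Hz sine epoch peaks at bin 10 of the default grid", {
  t <- (0:2499) / 500
  p <- epoch_psd(sin(2 * pi * 1.22 * t))
  expect_identical(which.max(p) - 1L, 10L)   # 10 * 0.12207 = 1.2207 Hz
})

test_that("epoch_psd agrees bin-for-bin with a brute-force DFT", {
  set.seed(4)
  for (i in 1:3) {
    x <- stats::rnorm(250)
    p <- epoch_psd(x, fs = 50, nfft = 512, expected_len = 250)
    pn <- naive_psd(x, 512)
    expect_lt(max(abs(p - pn) / pmax(pn, max(pn) * 1e-12)), 1e-9)
  }
  # spot-check bins of a full-size 2500-sample epoch against the
  # definition sum
  x <- stats::rnorm(2500)
  p <- epoch_psd(x)
  xw <- c(x * sleepwave:::hanning_window(2500), rep(0, 4096 - 2500))
  j <- 0:4095
  for (k in c(0, 5, 10, 100, 1024, 2048)) {
    ref <- Mod(sum(xw * exp(-2i * pi * j * k / 4096)))^2
    expect_equal(p[k + 1], ref, tolerance = 1e-9)
  }
})

test_that("the windowed epoch spectrum satisfies Parseval's relation", {
  t <- (0:2499) / 500
  x <- 3 * sin(2 * pi * 3.7 * t)
  # un-padded transform: total two-sided power equals N * windowed energy
  p <- epoch_psd(x, nfft = 2500)
  total <- p[1] + p[1251] + 2 * sum(p[2:1250])
  xw <- x * sleepwave:::hanning_window(2500)
  expect_equal(total, 2500 * sum(xw^2), tolerance = 1e-6)
})

test_that("the artifact rule excludes only epochs beyond the SEM multiple", {
  expect_identical(artifact_mask(rep(2, 50)), rep(FALSE, 50))
  m <- c(rep(1, 1000), 100)
  mask <- artifact_mask(m)
  # brute-force mean/SEM reference
  ref <- abs(m - mean(m)) > 10 * stats::sd(m) / sqrt(length(m))
  expect_identical(mask, ref)
  expect_true(mask[1001])
  expect_false(any(mask[1:1000]))
  expect_identical(artifact_mask(m, multiplier = Inf), rep(FALSE, 1001))
  expect_identical(artifact_mask(3), FALSE)    # N = 1: no exclusions
})

test_that("identical spectra across states each normalize to a 100% total", {
  set.seed(10)
  ep <- stats::rnorm(2500)
  rec <- tiled_recording(ep, 30)
  hyp <- hypnogram(rep(vigilance_states(), 10))
  ps <- state_psd(rec, hyp, artifact_multiplier = Inf)
  tot <- band_definition("total")
  for (s in vigilance_states())
    expect_equal(band_power(ps, tot, s), 100, tolerance = 1e-9)
  expect_equal(ps$n_epochs, c(WAKE = 10L, NREM = 10L, REM = 10L))
})

test_that("normalization turns raw state totals 2:1:0 into 200/100/0 percent", {
  raw <- c(2, 1, 0)                  # per-state raw totals
  R <- mean(raw)                     # equal-weight reference
  expect_equal(100 * raw / R, c(200, 100, 0))
})

test_that("cross-state normalization conserves the equal-weight 100% mean", {
  for (seed in c(1, 2)) {
    sp <- synth_spec(total_hours = 0.1, noise_seed = seed)
    hyp <- generate_hypnogram(sp)
    rec <- generate_recording(hyp, sp)
    ps <- state_psd(rec, hyp)
    tot <- band_definition("total")
    totals <- vapply(names(ps$power),
                     function(s) band_power(ps, tot, s), 0)
    expect_equal(mean(totals), 100, tolerance = 1e-6)
  }
})

test_that("band membership by rounded bin centers matches direct enumeration", {
  f <- psd_freqs()
  # independent enumeration of k * delta-f rounded to 2 decimals
  enum <- function(lo, hi) which(round((0:2048) * 500 / 4096, 2) >= lo &
                                   round((0:2048) * 500 / 4096, 2) <= hi)
  expect_identical(band_bins(band_definition("stimulation"), f),
                   enum(0.49, 0.61))
  expect_identical(band_bins(band_definition("stimulation"), f), 5:6)
  expect_identical(band_bins(band_definition("delta_analysis"), f), 5:38)
  expect_identical(band_bins(band_definition("theta"), f),
                   enum(4, 9))
  expect_error(band_bins(band(20.001, 20.002), f), "no bins")
})

test_that("band power of a flat unit spectrum counts its bins", {
  ps <- structure(list(freqs = psd_freqs()[5:164],
                       power = list(NREM = rep(1, 160)),
                       n_epochs = c(NREM = 1L)),
                  class = "state_psd")
  expect_equal(band_power(ps, band_definition("stimulation"), "NREM"), 2)
  expect_equal(band_power(ps, band_definition("delta_analysis"), "NREM"),
               34)
})

test_that("percent change reports the reporting-convention scale", {
  expect_equal(percent_change(1, 1), 0)
  expect_equal(percent_change(1.644, 1.0), 64.4)
  expect_equal(percent_change(0.919, 1.0), -8.1)
  expect_error(percent_change(1, 0), "baseline")
})

test_that("spectrograms are columnwise epoch spectra of the requested state", {
  set.seed(12)
  ep <- stats::rnorm(2500)
  rec <- tiled_recording(ep, 12)
  hyp <- hypnogram(rep(c("NREM", "WAKE"), 6))
  sg <- spectrogram(rec, hyp, "NREM", artifact_multiplier = Inf)
  expect_identical(ncol(sg$power), 6L)
  expect_equal(sg$epoch_start_s, seq(0, 55, by = 10))
  # stationary input: all columns equal
  expect_lt(max(abs(sg$power - sg$power[, 1])), 1e-8)
})

test_that("the stimulation-band row of the spectrogram rises after stimulus onset", {
  sp <- synth_spec(total_hours = 0.2, noise_seed = 14,
                   evoked = list(amplitude = 80, decay_s = 0.3,
                                 ring_hz = 1))
  hyp <- hypnogram(rep("NREM", 144))
  proto <- stim_protocol(0.6, 0.4, onset_s = 360)
  rec <- generate_recording(hyp, sp, proto)
  sg <- spectrogram(rec, hyp, "NREM", artifact_multiplier = Inf)
  sb <- band_bins(band_definition("stimulation"), sg$freqs)
  row <- colSums(sg$power[sb, , drop = FALSE])
  pre <- row[sg$epoch_start_s < 355]
  post <- row[sg$epoch_start_s >= 365]
  expect_gt(mean(post), 2 * mean(pre))
})
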