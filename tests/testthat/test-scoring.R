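make_sine_rec <- function(freq, hours = NULL, n_sec = 60, emg = 0) {
  n <- round(500 * n_sec)
  t <- (seq_len(n) - 1) / 500
  recording(sin(2 * pi * freq * t), rep(emg, n))
}

test_that("epoch features separate delta- and theta-band tones", {
  f2 <- compute_epoch_features(make_sine_rec(2))
  expect_true(all(f2$delta_power > f2$theta_power))
  expect_true(all(f2$emg_rms == 0))
  f7 <- compute_epoch_features(make_sine_rec(7))
  expect_true(all(f7$theta_power > f7$delta_power))
  expect_true(all(f7$delta_power >= 0))
})

test_that("a 3600-s recording yields exactly 720 epoch-feature records", {
  rec <- recording(stats::rnorm(3600 * 500), stats::rnorm(3600 * 500))
  feats <- compute_epoch_features(rec)
  expect_identical(nrow(feats), 720L)
  expect_identical(feats$epoch_index, 0:719)
  # trailing partial epoch dropped
  rec2 <- recording(stats::rnorm(17 * 500), stats::rnorm(17 * 500))
  expect_identical(nrow(compute_epoch_features(rec2)), 3L)
})

test_that("the scoring decision tree follows EMG then theta/delta precedence", {
  thr <- list(emg = 10, theta_delta = 2)
  # motor activity defines wake regardless of spectra
  expect_identical(score_epoch(list(emg_rms = 20, theta_power = 100,
                                    delta_power = 1), thr), "WAKE")
  # atonia + delta-dominant -> NREM
  expect_identical(score_epoch(list(emg_rms = 1, theta_power = 10,
                                    delta_power = 100), thr), "NREM")
  # atonia + theta/delta above threshold -> REM
  expect_identical(score_epoch(list(emg_rms = 1, theta_power = 30,
                                    delta_power = 10), thr), "REM")
  # degenerate zero spectra scored NREM by convention
  expect_identical(score_epoch(list(emg_rms = 1, theta_power = 0,
                                    delta_power = 0), thr), "NREM")
  # scorer is total on a random feature grid
  set.seed(1)
  grid <- data.frame(emg_rms = stats::runif(300, 0, 30),
                     theta_power = stats::runif(300, 0, 50),
                     delta_power = stats::runif(300, 0, 50))
  st <- vapply(seq_len(300), function(i)
    score_epoch(grid[i, ], thr), "")
  expect_true(all(st %in% vigilance_states()))
})

test_that("vectorized scoring matches the single-epoch scorer", {
  set.seed(2)
  feats <- data.frame(emg_rms = stats::runif(200, 0, 30),
                      theta_power = stats::runif(200, 0, 50),
                      delta_power = stats::runif(200, 0, 50))
  thr <- list(emg = 12, theta_delta = 2)
  hyp <- score_epochs(feats, thr)
  one <- vapply(seq_len(200), function(i) score_epoch(feats[i, ], thr), "")
  expect_identical(as.character(hyp$state), one)
})

test_that("EMG threshold calibration lands between well-separated modes", {
  set.seed(7)
  emg <- c(stats::rnorm(300, 5, 0.7), stats::rnorm(200, 25, 2))
  feats <- data.frame(emg_rms = emg, theta_power = 1, delta_power = 1)
  thr <- calibrate_thresholds(feats)
  expect_false(thr$emg_fallback)
  expect_gt(thr$emg, 8); expect_lt(thr$emg, 22)
  # brute-force 1-D 2-means oracle: exhaustive split minimizing
  # within-class sum of squares
  s <- sort(emg)
  wss <- vapply(seq_len(length(s) - 1), function(k) {
    a <- s[1:k]; b <- s[(k + 1):length(s)]
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }, 0)
  k <- which.min(wss)
  oracle_mid <- (mean(s[1:k]) + mean(s[(k + 1):length(s)])) / 2
  expect_equal(thr$emg, oracle_mid, tolerance = 0.05)
})

test_that("unimodal or constant EMG falls back to the 75th percentile with a warning", {
  feats <- data.frame(emg_rms = rep(3, 150), theta_power = 1,
                      delta_power = 1)
  expect_warning(thr <- calibrate_thresholds(feats), "unimodal")
  expect_true(thr$emg_fallback)
  expect_equal(thr$emg, 3)
  set.seed(8)
  feats2 <- data.frame(emg_rms = stats::rnorm(500, 10, 2),
                       theta_power = 1, delta_power = 1)
  expect_warning(thr2 <- calibrate_thresholds(feats2), "unimodal")
  expect_equal(thr2$emg, stats::quantile(feats2$emg_rms, 0.75,
                                         names = FALSE))
})

test_that("state amounts per block respect light/dark tagging and denominators", {
  # all-wake: 100% wake in every block
  h <- hypnogram(rep("WAKE", 24 * 720), start_zt = 0)
  am <- state_amounts(h, block_hours = 3)
  expect_identical(length(unique(am$block)), 8L)
  expect_identical(sum(am$period == "light") / 3, 4 * 3 / 3)
  expect_true(all(am$percent[am$state == "WAKE"] == 100))
  expect_true(all(am$percent[am$state != "WAKE"] == 0))
  expect_identical(unique(am$period[am$block <= 4]), "light")
  expect_identical(unique(am$period[am$block > 4]), "dark")

  # alternating wake/NREM: 50/50/0
  h2 <- hypnogram(rep(c("WAKE", "NREM"), 3 * 720 / 2), start_zt = 0)
  am2 <- state_amounts(h2, block_hours = 3)
  expect_equal(am2$percent[am2$state == "WAKE"], 50)
  expect_equal(am2$percent[am2$state == "NREM"], 50)
  expect_equal(am2$percent[am2$state == "REM"], 0)

  # artifact epochs leave the denominator
  st <- rep("WAKE", 2160); art <- rep(FALSE, 2160); art[1:216] <- TRUE
  am3 <- state_amounts(hypnogram(st, artifact = art), block_hours = 3)
  expect_equal(am3$seconds[am3$state == "WAKE"], (2160 - 216) * 5)
  expect_equal(am3$percent[am3$state == "WAKE"], 100)

  # trailing partial block dropped
  h4 <- hypnogram(rep("WAKE", 2160 + 100))
  expect_identical(length(unique(state_amounts(h4, 3)$block)), 1L)
})

test_that("bout analysis counts maximal runs and partitions state time", {
  h <- hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "NREM", "WAKE"))
  b <- bout_analysis(h)
  expect_equal(b$bout_count[b$state == "WAKE"], 2)
  expect_equal(b$mean_bout_duration_s[b$state == "WAKE"], 7.5)
  expect_equal(b$bout_count[b$state == "NREM"], 1)
  expect_equal(b$mean_bout_duration_s[b$state == "NREM"], 15)
  expect_equal(b$bout_count[b$state == "REM"], 0)

  # single-state hypnogram: one bout of k*5 s
  b2 <- bout_analysis(hypnogram(rep("REM", 13)))
  expect_equal(b2$bout_count[b2$state == "REM"], 1)
  expect_equal(b2$total_time_s[b2$state == "REM"], 65)

  # strictly alternating states: every bout one epoch
  b3 <- bout_analysis(hypnogram(rep(c("WAKE", "NREM"), 20)))
  expect_true(all(b3$mean_bout_duration_s[b3$bout_count > 0] == 5))

  # artifact epochs break runs and belong to no bout
  h4 <- hypnogram(rep("NREM", 5), artifact = c(F, F, T, F, F))
  b4 <- bout_analysis(h4)
  expect_equal(b4$bout_count[b4$state == "NREM"], 2)
  expect_equal(b4$total_time_s[b4$state == "NREM"], 20)
})

test_that("bout durations partition state time on random hypnograms", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(20:400, 1)
    st <- sample(vigilance_states(), n, replace = TRUE)
    art <- stats::runif(n) < 0.1
    h <- hypnogram(st, artifact = art)
    b <- bout_analysis(h)
    ok <- b$bout_count > 0
    expect_equal(b$bout_count[ok] * b$mean_bout_duration_s[ok],
                 b$total_time_s[ok])
    expect_equal(sum(b$total_time_s) + sum(art) * 5, n * 5)
  }
})

test_that("majority smoothing removes isolated single-epoch intrusions when enabled", {
  feats <- data.frame(emg_rms = c(1, 1, 20, 1, 1),
                      theta_power = 1, delta_power = 10)
  thr <- list(emg = 10, theta_delta = 2)
  raw <- score_epochs(feats, thr)
  expect_identical(as.character(raw$state),
                   c("NREM", "NREM", "WAKE", "NREM", "NREM"))
  sm <- score_epochs(feats, thr, smooth = TRUE)
  expect_true(all(sm$state == "NREM"))
})
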