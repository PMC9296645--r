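# shared test utilities

# brute-force DFT (definition sum), used as the independent spectral oracle
naive_psd <- function(x, nfft) {
  xw <- c(x * sleepwave:::hanning_window(length(x)),
          rep(0, nfft - length(x)))
  j <- 0:(nfft - 1)
  X <- vapply(0:(nfft %/% 2), function(k)
    sum(xw * exp(-2i * pi * j * k / nfft)), complex(1))
  Mod(X)^2
}

# harmonic amplitudes of a sampled train measured by a long rectangular
# DFT with bins aligned to n*f (n_periods periods exactly)
dft_harmonics <- function(x, n_periods, n_max) {
  X <- Mod(stats::fft(x)) / length(x)
  2 * X[(1:n_max) * n_periods + 1]
}

# stationary distribution of a 3x3 row-stochastic matrix
stationary_dist <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# recording made by tiling one fixed epoch (identical spectra everywhere)
tiled_recording <- function(epoch, n_epochs, fs = 500) {
  recording(rep(epoch, n_epochs), rep(0, length(epoch) * n_epochs),
            fs = fs)
}

quiet_pipeline <- function(cfg) suppressMessages(run_pipeline(cfg))
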