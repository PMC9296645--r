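Package: sleepwave
Title: Sleep EEG Spectral Analysis Under Low-Frequency Periodic Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mouse sleep EEG/EMG recordings under
    low-frequency (0.6/1.2 Hz) periodic visual or optogenetic stimulation:
    vigilance-state scoring in 5-s epochs (Wake/NREM/REM), state-conditioned
    power spectral density on a 0.12207-Hz grid with cross-state
    normalization, stimulation-band and delta-band power changes, harmonic
    analysis of non-sinusoidal stimulus-locked responses against a
    closed-form Fourier-series oracle, and sleep-architecture statistics.
    Includes a synthetic EEG/EMG generator with known ground truth
    (state-dependent spectra, light/dark-modulated Markovian sleep
    architecture, stimulus-locked evoked responses) and minimal EDF I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
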