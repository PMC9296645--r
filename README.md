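# sleepwave

Spectral analysis of mouse sleep EEG under low-frequency periodic
stimulation.

Slow oscillations (~0.5–1 Hz) dominate the NREM-sleep EEG, and driving
them with slow periodic stimuli — flickering light during sleep, or
optogenetic pulses to cortical neurons — is a candidate non-invasive
intervention in neurodegeneration models. Quantifying such experiments
requires a specific analysis chain, which this package implements as
tested, reusable R functions:

* **Vigilance-state scoring** of EEG/EMG telemetry in 5-s epochs
  (Wake/NREM/REM) by a calibrated decision tree: EMG tone defines
  wake, the theta/delta ratio separates REM from NREM.
* **State-conditioned PSD** per the field's convention: Hann window,
  FFT on the 0.12207-Hz grid (500 Hz / 4096), artifact exclusion by an
  SEM rule, per-state averaging and cross-state normalization to a
  per-animal reference (the equal-weight mean of per-state 0.5–20 Hz
  totals), so each state's spectrum is in % of reference.
* **Band powers and percent change vs. baseline** for the stimulation
  band (0.49–0.61 Hz), delta (0.49–4.52 Hz) and theta (4–9 Hz).
* **Harmonic analysis**: a periodic but non-sinusoidal evoked response
  produces spectral lines at the stimulus rate *f* and its integer
  multiples *nf*. For a rectangular pulse train of height *A* and duty
  cycle *d* the line amplitudes are closed-form,
  `A_n = (2A/(n*pi)) * |sin(n*pi*d)|`, and the package verifies
  measured spectra against this analytic oracle (one peak for a sine;
  fundamental + harmonics for a square; weaker lines for shorter
  pulses).
* **Sleep architecture**: per-block amounts (3-h/12-h, light/dark
  tagged), bout counts and durations.
* **Paired statistics**: two-tailed paired t-tests across subjects
  with mean ± SEM summaries.
* **Synthetic ground truth**: a seeded EEG/EMG generator (Markovian
  light/dark sleep architecture, state-gated delta/theta oscillators
  over 1/f background, state-dependent EMG tone, stimulus-locked
  evoked responses) exercises the whole chain with known answers.
  Minimal two-channel EDF I/O and a hypnogram CSV dialect are included
  for real data.

## Worked example

Two hours of synthetic data, scored and contrasted with and without a
0.6-Hz, 400-ms visual-stimulation pulse train (same noise seed, so the
only difference is the evoked response):

```r
library(sleepwave)

spec  <- synth_spec(total_hours = 2, noise_seed = 42)
truth <- generate_hypnogram(spec)
proto <- stim_protocol(0.6, 0.4, label = "620nm visual, 400 ms")
base  <- generate_recording(truth, spec)            # baseline day
stim  <- generate_recording(truth, spec, proto)     # stimulation day

feats <- compute_epoch_features(stim)
thr   <- calibrate_thresholds(feats)
hyp   <- score_epochs(feats, thr, start_zt = 3)
scoring_agreement(hyp, truth)
#> [1] 1

psd_b <- state_psd(base, truth, artifact_multiplier = 100)
psd_s <- state_psd(stim, truth, artifact_multiplier = 100)
psd_s
#> <state_psd> 0.4883-19.9 Hz in 0.12207-Hz bins; window 0-7200 s
#>   epochs: WAKE 422, NREM 817, REM 200  (artifact-excluded: 1)

sb <- band_definition("stimulation")
percent_change(band_power(psd_s, sb, "NREM"),
               band_power(psd_b, sb, "NREM"))
#> [1] 13.5
```

The scorer recovers the ground-truth hypnogram exactly here (the
generator's states are well separated; on real data expect less), and
stimulation-band power rises in every state — NREM by 13.5% (12.32 →
13.99 % of reference), wake from 0.51 to 3.21, REM from 0.45 to 3.08.
The explicit `artifact_multiplier = 100` relaxes the literal
`10*SEM/sqrt(N)` exclusion rule, which censors long mixed-state
recordings heavily (see the methods vignette).

The stimulation-day spectrum shows the evoked line structure — a peak
at the fundamental and harmonics at integer multiples of 0.6 Hz:

```r
pk <- detect_peaks(psd_s, state = "WAKE")
head(pk[order(-pk$power), ], 4)
#>     freq_hz     power prominence
#> 1 0.6103516 1.8351493 0.46143675
#> 2 1.2207031 1.3656978 1.04894283
#> 3 1.8310547 0.3673333 0.18326899
#> 4 2.3193359 0.1861595 0.04956708
harmonic_structure(pk, 0.6)[1:5]
#> [1] 1 2 3 4 5
```

(0.6 Hz falls between bin centers; the nearest bin is 0.6104 Hz, which
is why harmonic matching tolerates ±1 bin.) Paired contrasts across
subjects use the standard report format:

```r
paired_t(c(8.2, 6.9, 7.4), c(9.0, 7.8, 7.7))
#> t(2) = 3.592, p = 0.06952 (two-tailed paired)
#>   mean diff = 0.6667 +/- 0.1856 (SEM), n = 3
```

`run_pipeline(default_config())` chains all stages for a set of
simulated subjects and writes six result tables plus a manifest; see
`?run_pipeline` and the methods vignette
(`vignettes/sleepwave-methods.Rmd`) for the model, parameter meanings
and numerical choices.

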