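---
title: "Methods: spectral analysis of sleep EEG under slow periodic stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral analysis of sleep EEG under slow periodic stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepwave)
```

## Scientific setting

Slow oscillations (~0.5–1 Hz) are the dominant cortical rhythm of NREM
sleep, and boosting them — by sensory or optogenetic stimulation at a
matching rate — is of interest as a non-invasive intervention in
neurodegeneration models. `sleepwave` implements the analysis chain
used to quantify such experiments in mice: EEG/EMG telemetry at 500 Hz
is scored into Wake/NREM/REM in 5-s epochs, power spectral density
(PSD) is estimated per epoch and averaged per state, spectra are
normalized across states so animals can be compared, and
baseline-vs-stimulation contrasts are tested with paired t-tests.
Because a periodic but non-sinusoidal evoked response concentrates its
energy at the stimulus repetition rate *f* and its integer multiples
*nf*, the package also carries an analytic Fourier-series oracle for
rectangular pulse trains and a peak/harmonic detector to verify that
measured spectra have the expected line structure.

Everything is exercised against a synthetic EEG/EMG generator with
known ground truth; no animal data is required or bundled.

## The spectral estimator

Each 5-s epoch (2500 samples at 500 Hz) is multiplied by a symmetric
Hann window, zero-padded to 4096 samples and transformed with the FFT;
the squared modulus of the one-sided transform is the epoch's power
spectrum. The FFT length is the one deliberate numerical choice here:
4096 is the only power of two for which the bin spacing at 500 Hz,
`500/4096 = 0.1220703125` Hz, reproduces the conventional 0.12207-Hz
resolution of rodent sleep-EEG spectra. No single-sided energy
doubling or density scaling is applied because every downstream
quantity is relative — the cross-state normalization cancels any
common scale factor (this is recorded in the output metadata).

Per state, artifact-free epoch spectra are averaged; the reference
value `R` is the equal-weight mean over the states present of each
state's summed power over the total band (0.5–20 Hz), and each bin is
reported as `100 * P / R`. By construction the equal-weight mean of
the per-state 0.5–20 Hz totals is exactly 100%, a property asserted in
the test suite on every input.

Band membership is decided on bin centers rounded to two decimals,
lying in a closed interval. This makes the analysis bands resolve
exactly as printed: the stimulation band 0.49–0.61 Hz is bins 4–5
(centers 0.4883 and 0.6104 Hz, i.e. the printed edges *are* rounded
bin centers) and the analysis delta band 0.49–4.52 Hz is bins 4–37.
The scoring delta band (0.5–4.5 Hz) and the analysis delta band
(0.49–4.52 Hz) are kept as two distinct definitions because they play
different roles (state discrimination vs. effect quantification), and
the reported grid keeps bin 4 (0.4883 Hz) so the stimulation band is
complete even though totals are formed over 0.5–20 Hz.

### Artifact rejection

Epochs are excluded when their EEG RMS deviates from the
recording-wide mean by more than `multiplier × SEM`, with
`SEM = sd/sqrt(N)` over all epochs and a default multiplier of 10.
This is the literal reading of the "more than 10×SEM" convention; the
metric (per-epoch EEG RMS), the population (all epochs of the
recording) and two-sidedness are our declared interpretation, and the
multiplier is configurable. Note a property of the literal rule: since
the SEM shrinks as `1/sqrt(N)`, long recordings are censored
aggressively (with ~10⁳ epochs the threshold is a fraction of one SD).
We keep the literal rule as the default because it is what the
convention states; analyses that prefer a conventional outlier rule
can raise the multiplier or pass `Inf` to disable exclusion.

## Vigilance-state scoring

Scoring is a decision tree over per-epoch features, in the precedence
order of the standard criteria: motor activity defines wake (EMG RMS
above a threshold); among atonic epochs a theta/delta power ratio
above a threshold indicates REM; everything else is NREM. Epochs with
zero power in both bands are scored NREM by convention and the scorer
is total — every epoch receives a label.

Operator-assisted commercial scoring does not publish numeric
thresholds, so the package calibrates its own: the EMG threshold is
the midpoint of the two modes of the per-epoch EMG-RMS distribution,
found by 1-D 2-means clustering. If the distribution is effectively
unimodal — cluster separation under three times the pooled
within-cluster spread, the ratio at which a split unimodal Gaussian
(≈2.65) is rejected — calibration falls back to the 75th percentile
and warns. The theta/delta threshold defaults to 2.0; the published
criteria are qualitative, and 2.0 cleanly separates theta-dominant
from delta-dominant epochs under the generator's spectra. This
calibration scheme is validated only against synthetic ground truth
(≥90% epoch agreement in the test suite); on real data it is a
starting point, not a substitute for visual confirmation.

No minimum-bout post-filter is applied by default, since the standard
criteria do not describe one; a 2-epoch majority smoother is available
but off.

Sleep architecture is summarized as per-block amounts (3-h or 12-h
blocks, tagged light/dark from the block midpoint ZT; artifact epochs
leave the denominator; a trailing partial block is dropped rather than
padded) and as bouts — maximal runs of identical labels, broken by
artifact epochs — whose counts and mean durations partition state time
exactly.

## Pulse trains and the harmonic oracle

A stimulation protocol is an ideal rectangular pulse train: height
`A`, width `w`, rate `f`, duty cycle `d = f·w ∈ (0, 1]`. Pulses are
left-closed/right-open in time (a sample exactly at pulse offset is
low), which makes duty-cycle accounting unambiguous, and edges are not
band-limited — the electronic drive is effectively ideal at these
rates, and the oracle assumes ideal rectangles. The pulse rise time of
the physical hardware is not modelled (it is unknown, and irrelevant
below ~100 Hz).

The Fourier series of that train is closed-form: mean `A·d` and
harmonic amplitudes

\[ A_n = \frac{2A}{n\pi}\,\lvert\sin(n\pi d)\rvert , \]

with exact zeros wherever `n·d` is an integer (for a 50%-duty square
wave all even harmonics vanish). This is the independent oracle for
harmonic structure: the test suite checks that long noiseless trains
measured by DFT match it to within 2% away from the sinc-envelope
zeros (where the relative error is unconditioned because the line
itself vanishes), and the calibration demonstration — a sine gives one
spectral peak, a square gives fundamental plus integer harmonics, and
10-ms pulses drive the fundamental far more weakly than 400-ms pulses
(`A_1 ∝ sin(πd)`) — is reproduced end to end.

Peak detection uses strict local maxima at ≥1% of the spectrum
maximum (the published figures show peaks but never quantify them;
1% keeps all visible harmonics while rejecting Hann sidelobes, which
sit near −62 dB in power). Harmonic matching tolerates ±1 bin because
the 0.6-Hz fundamental falls between bin centers (nearest 0.6104 Hz).
Amplitude comparison against the oracle rescales measured `sqrt(power)`
so the fundamental matches exactly, making the check scale-invariant;
a missing expected harmonic counts as relative error 1.

## The synthetic generator

The generator produces what the analysis assumes, and only that:

* **Sleep architecture** — a first-order Markov chain over
  Wake/NREM/REM at epoch resolution, with separate transition matrices
  for light and dark periods (12 h:12 h cycle, ZT0 = lights-on,
  recordings starting at ZT3 like the stimulation protocols). The
  default matrices give persistent bouts and more sleep in the light
  period, as in nocturnal mice; REM is entered only from NREM.
* **State spectra** — a 1/f background (default exponent 1.0, a
  typical EEG spectral slope; configurable) synthesized by spectral
  shaping in power-complementary root-Hann chunks, plus state-gated
  band-limited oscillators: delta-band noise (0.5–2.5 Hz, 40 µV RMS)
  in NREM, theta-band (5.5–7.5 Hz, 30 µV RMS) in REM, low-amplitude
  broadband (12 µV RMS) in wake. Oscillators switch with a 0.1-s
  raised-cosine crossfade at state boundaries so that transitions do
  not inject broadband clicks for the artifact stage to flag.
* **EMG tone** — white noise at per-state RMS (wake 30, NREM 8, REM
  4 µV), crossfaded the same way; the generator's separability
  assumption is `WAKE > NREM ≥ REM`.
* **Evoked response** — a per-pulse kernel stamped at every pulse
  onset (equivalently, the kernel convolved with the protocol's
  impulse train). The default kernel is a damped slow ring,
  `exp(-t/0.3 s)·sin(2π·1.0 Hz·t)`, normalized to its peak amplitude.
  The kernel shape was a genuinely open choice: no evoked waveform is
  published for this preparation. We chose a slow-wave-like kernel
  whose spectrum is maximal at low frequency because the comb of
  harmonic lines is weighted by the kernel's transform — a kernel
  peaked near 5 Hz would make the dominant line land near 5 Hz rather
  than at the fundamental, contradicting the observed dominance of the
  0.6-Hz peak. The evoked amplitude is a free parameter (the
  literature gives no µV value) and is swept in the tests; the
  monotonicity of stimulation-band power in evoked amplitude is one of
  the asserted properties.

What the generator does **not** emulate: spindles, K-complexes and
other transients; state-dependent 1/f slope changes; movement and
electrode artifacts with realistic waveforms; traveling-wave dynamics
of the evoked response; inter-animal variability in spectra beyond the
seed. Passing tests therefore show that the pipeline's operations are
correct on signals with the assumed statistical structure — they do
not certify scoring accuracy or artifact handling on real telemetry.

Reproducibility is bit-exact: the hypnogram stream is seeded from
`noise_seed` and the recording stream from `noise_seed + 1`, so the
same spec yields identical data and the same seed with and without a
protocol shares its noise realization (which makes paired
with/without-stimulation contrasts sharp).

## Statistics

Baseline-vs-stimulation contrasts use two-tailed paired t-tests on
per-subject values, `t = mean(d)/(sd(d)/√n)` with `n−1` df; subjects
missing a state on either day are dropped pairwise, which is why the
df varies across states. Degenerate zero-variance differences are
flagged rather than erroring. Summaries are mean ± SEM. No
multiple-testing correction is applied by default, matching the
per-band reporting convention; a Benjamini–Hochberg helper is provided
for users who want it. The test suite checks the type-I error of the
paired test at n = 11 (the visual-stimulation group size) over 10,000
null simulations.

## Pipeline and I/O

`run_pipeline()` composes the stages for a set of simulated subjects:
paired baseline/stimulation recordings per subject, threshold
calibration and scoring per day, state PSDs, band powers and percent
changes, per-block amounts, bout statistics, harmonic peak reports and
the paired-t table, with a manifest recording the config hash and
versions. Signals interchange as EDF (a minimal 16-bit two-channel
reader/writer is included; EDF is the polysomnography interchange
standard, and exports from proprietary telemetry formats to EDF are
routine), hypnograms as `epoch_index,start_s,state,artifact` CSV, and
all result tables as tidy CSV. Time conventions are 0-based
throughout: sample `i` covers `[i/fs, (i+1)/fs)`, epoch `e` covers
samples `[e·5·fs, (e+1)·5·fs)`.

One open normalization question is decided here: for short analysis
windows (e.g. 2-h), the reference `R` is recomputed within the window
rather than reused from the 24-h analysis. Recomputing keeps the
normalization identity exact on every reported spectrum; users who
want a day-wide reference can compute the 24-h `state_psd()` and take
`reference_value` from it.

## Problem sizes and costs

The bundled tests run the generator at 6 min–2 h per recording and
24 h for architecture-level checks; these sizes give stable spectral
estimates (≥70 epochs per state at 2 h) while keeping the whole suite
under a minute of compute. The scoring-recovery property uses 2-h
recordings at three seeds; the acceptance script uses a 20-min
NREM-labelled recording with the evoked amplitude set well above the
noise floor, which is ample for localizing the dominant spectral peak.

## Known limitations

* The artifact rule's literal SEM scaling makes the default exclusion
  rate depend strongly on recording length; treat the multiplier as an
  analysis parameter.
* Threshold calibration assumes a bimodal EMG distribution; datasets
  dominated by one state will trigger the percentile fallback, whose
  threshold is arbitrary.
* The EDF writer covers exactly the two-channel uniform-rate case the
  pipeline needs; it is not a general EDF+ implementation.
* Harmonic amplitude comparison presumes noiseless calibration input;
  on noisy spectra the sqrt-power amplitudes are biased by the noise
  floor.
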