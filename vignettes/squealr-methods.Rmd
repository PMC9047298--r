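---
title: "Objective assessment of porcine voice: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective assessment of porcine voice: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squealr)
```

## The problem

Assessing voice quality in a pig model of laryngeal surgery requires
objective, rater-independent acoustic measures. Squeals — high-pitched,
orally emitted vocalizations assumed to originate at the vocal folds — are
the natural unit of analysis, but they are largely *aperiodic*: classical
human-voice measures that depend on a tracked fundamental frequency
(jitter, shimmer, and to a large extent CPP) return mostly noise on such
signals. `squealr` therefore implements a battery of fourteen aperiodic
parameters that describe the spectral energy distribution, its stability
over time, and coarse waveform properties, and tests whether they shift
between two recording phases (e.g. before and shortly after vocal fold
surgery), separately for each animal.

## The analysis pipeline

The stages run in a fixed order, each producing a table that can be
checkpointed to CSV:

1. **Audio ingestion** (`read_wav()`, `extract_segment()`): recordings are
   converted to mono by keeping the left channel, and each squeal clip is
   peak-normalized to the [-1, 1] range. Normalization is per squeal:
   absolute level is meaningless in a free-field recording, and per-clip
   scaling makes every downstream parameter a function of the clip alone.
2. **Screening** (`screen_squeals()`): a squeal enters analysis iff its
   duration is at least 0.3 s, its mean background-noise rating over the
   raters (each scoring 0–2) does not exceed 1.00, and it carries no
   artifact flag. The rating comparison is performed on the integer rating
   sum against `threshold * n_raters`, so a mean of exactly 1.00 is
   included regardless of floating-point representation. Rules are
   reported in the order duration → noise → artifact.
3. **Feature extraction** (`extract_features()`, `squeal_parameters()`):
   the fourteen parameters below.
4. **Statistics** (`compare_phases()`): per animal, one one-sided Wilcoxon
   rank-sum test per parameter against its expected direction of change,
   then Benjamini–Yekutieli FDR control at 5% within the animal. Animals
   are never pooled or compared with each other.

## Windowing schemes and the fourteen parameters

Three windowing schemes are used (`window_plan()`):

* **total** — one rectangular window over the entire squeal (maximal
  frequency resolution);
* **partial** — eleven evenly spaced, contiguous Hamming windows of length
  `floor(N/11)` tiling the squeal, the trailing remainder unused; windows
  2–10 are the "inner" windows;
* **consecutive** — overlapping Hamming frames, 1024 samples with 50%
  overlap by default, i.e. roughly 23 ms frames at 44.1 kHz.

"Evenly spaced" partial windows are realized as contiguous non-overlapping
equal-length tiles. This is the simplest reading consistent with both an
even spacing and well-defined inner windows; the literature the parameters
come from does not pin down a window length, so this is a package design
decision, recorded here.

On these schemes:

| Parameter | Windowing | Definition |
|---|---|---|
| PF | total | frequency of the highest energy-spectrum peak |
| Q50 | total | frequency splitting total spectral energy 50:50 |
| Q50_2, Q50_10 | partial | Q50 of inner windows 2 and 10 |
| Q50_min | partial | minimum Q50 over inner windows 2–10 |
| Q50_n | partial | index (2–10) of the extreme inner-window Q50 |
| Q50W | consecutive | Q50 of the bin-wise average frame spectrum |
| Q25 | consecutive | per-frame 25% quantile, averaged |
| Dur | total | squeal duration in seconds |
| SF | consecutive | per-frame spectral flatness, averaged |
| SF_Q50 | total | whole-signal flatness divided by Q50 |
| Flux | consecutive | mean over frame pairs of the summed squared differences of percent-normalized magnitude spectra |
| RMSI | total | RMS of the peak-normalized waveform |
| HNR | total | frame-wise autocorrelation harmonicity, averaged |

Numerical conventions, chosen once and used everywhere:

* FFT length equals window length (no zero padding); spectra are
  one-sided with bin `k` at `k * fs / N`; the DC bin participates in all
  spectral sums.
* Energy spectra are scaled so Parseval's identity holds exactly
  (`sum(energy) == sum(x^2)`), which makes the scaling testable.
* Spectral quantiles return the first bin frequency whose cumulative
  energy reaches the requested fraction — a dividing frequency, not an
  interpolant. Ties in `peak_frequency()` and `Q50_n` resolve to the
  lowest frequency/index, for determinism.
* Flux normalizes each frame's magnitude spectrum to sum to 100 before
  differencing, making it invariant to amplitude differences between
  frames; squared differences are summed over frequency and averaged over
  neighboring-frame pairs (`flux_reduce = "sum"` retains the grand-sum
  alternative).
* Spectral flatness of an exactly constant spectrum returns 1 without
  passing through logs, and any zero bin yields 0 (no flooring).

`Q50_n` deserves a note: its verbal description in the source literature
(the window where higher harmonics are *least* dominant) and its
operational definition (the window with the *highest* Q50) point in
opposite directions. The operational definition is followed; the
`q50n_mode = "min"` switch preserves the other reading.

### HNR and CPP on aperiodic voice

HNR is computed as a frame-wise normalized cross-correlation harmonicity:
analysis frames two pitch-floor periods long (floor 75 Hz, 50% hop,
mean-removed), the correlation maximized over lags corresponding to pitch
candidates between the floor and 1000 Hz, per-frame harmonicity
`10 log10(r / (1 - r))`, averaged over frames. This is a self-contained
implementation that promises *qualitative* behavior — strongly periodic
signals score far above noise — not bit equivalence with any external
voice tool; on largely aperiodic voice any HNR is of limited
interpretability, which is one of the battery's own findings about
F0-adjacent measures. CPP (cepstral peak prominence over a linear trend in
the 60–1000 Hz quefrency band) is provided for descriptive use only and is
excluded from the statistical battery, as are jitter and shimmer, which
are not implemented at all: on aperiodic squeals they mostly measure the
failure modes of F0 tracking.

## Statistics

One-sided tests are used because each parameter comes with a directional
expectation, and a two-sided test would spend power on the direction the
physiology rules out. The default directions (`default_hypotheses()`)
encode the expected consequences of losing high-frequency energy after
surgery: all frequency-location parameters (PF, Q50 family, Q50W, Q25)
down; SF, Flux and RMSI up (noisier, less stable, less peaked voice); Dur
and HNR down. Two entries are genuinely ambiguous and overridable: `Q50_n`
(an index, weakly informative) defaults to "decrease" with the frequency
family, and `SF_Q50` (flatness numerator up, Q50 denominator down)
defaults to "increase" with its numerator.

The rank-sum test is exact (full enumeration) when the combined sample is
at most 20 without ties, and a normal approximation with tie and
continuity corrections otherwise — small per-animal squeal sets are the
norm, and the exact small-sample branch is directly checkable against
enumeration. Benjamini–Yekutieli is used rather than Benjamini–Hochberg
because the fourteen parameters are heavily dependent (several are
functions of the same spectrum), and BY controls the FDR under arbitrary
dependence at the price of the harmonic-sum factor `c(m) = sum(1/i)`.

## The synthetic squeal simulator

Real squeal recordings cannot ship with the package, so every stage is
validated on `generate_squeal()` / `generate_cohort()`: a stack of
harmonics of a fundamental contour, amplitudes flat up to a corner
frequency (`rolloff_cutoff`) and falling at `rolloff_db_per_octave` above
it, plus white Gaussian noise at a fixed clip-level SNR, an overall Hann
amplitude contour (with a small floor so clips never decay to silence),
and peak normalization. Defaults: flat 1300 Hz fundamental, 30 harmonics
(capped below Nyquist), 8 kHz corner, 12 dB/octave, 20 dB SNR, 0.5 s.
The impaired voice is emulated by lowering the corner to 2 kHz, which
reproduces the two signatures the statistics must detect: spectral energy
condenses into low frequencies (Q-parameters fall), and — because the
percent-normalized magnitude spectrum becomes concentrated in a few
dominant bins whose relative fluctuation against the fixed-SNR noise floor
is larger — spectral flux rises.

The fundamental contour defaults to *flat* (`f0_start == f0_end`). An
intra-squeal glide makes every harmonic sweep across analysis bins between
consecutive frames, which injects sweep-driven flux into whichever cohort
glides more; with a flat contour the pre/post flux contrast isolates the
spectral-envelope attenuation itself. Gliding stimuli remain available by
setting the two endpoints apart, and per-squeal pitch variation is instead
provided between squeals by the cohort jitter.

`generate_cohort()` perturbs each squeal's model multiplicatively
(log-normal: 5% on the fundamental, 10% on the corner frequency, 15% on
duration floored at 0.3 s) and additively on SNR (SD 3 dB), and draws
three per-rater noise scores with probabilities 0.6/0.3/0.1 for ratings
0/1/2 — a mostly clean recording session with occasional noisy squeals.
These values were fixed once as a plausible within-animal spread for
field recordings and are not tuned thereafter.

What the simulator does **not** emulate: nonlinear phenomena of real pig
voice (biphonation, subharmonics, deterministic chaos), grunt-like
low-frequency calls, reverberation and nonstationary background noise, or
correlated rater behavior. Passing the simulation-based checks therefore
demonstrates that the pipeline recovers the modeled spectral contrast at
realistic sample sizes and noise levels — not that any particular real
cohort will show the same significance pattern.

## Validation problem sizes

The test suite validates, among others: spectral quantiles against a
brute-force cumulative scan on 1000 random spectra; the exact rank-sum
branch against full enumeration for all splits of up to 10 observations;
the BY step-up against a hand-applied formula and its containment in
BH rejections on 1000 random p-vectors; FDR calibration on 200 simulated
null animals (20 + 20 squeals of 0.3 s each); and ≥ 90% power with correct
directions for Q50 and Flux over 50 replicate attenuation cohorts of the
same size. `scripts/acceptance.R` re-runs the same analyses at smaller
sizes (60 null animals, 20 power replicates) to produce a machine-readable
summary in a few minutes on one CPU.

## Known limitations

* Partial-window semantics ("evenly spaced") and the flux reduction
  ("average" vs "sum over time") are under-determined in the source
  literature; both package choices are recorded above and the alternative
  flux reduction is exposed as an option.
* HNR and CPP are qualitative re-implementations, not clones of any
  specific voice-analysis tool.
* The Wilcoxon normal approximation is used above combined n = 20; for
  heavily tied data (e.g. `Q50_n`, an integer in 2–10) p-values rely on
  the tie-corrected approximation, and constant parameters are reported as
  p = 1 with a degenerate-data warning.
* Screening treats "high subjective pitch" (part of squeal identification)
  as upstream: the package screens candidate squeals, it does not detect
  them in continuous recordings.
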