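---
title: "Discovering common EEG workload indicators by consensus feature selection"
author: "eegworkload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering common EEG workload indicators by consensus feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegworkload)
```

## The problem

Operators supervising remote vehicles under degraded communication
(transmission delay, information dropout) experience graded cognitive
workload. EEG band powers are among the most direct objective workload
indicators, but per-subject feature rankings differ wildly, which makes it
hard to name a *common* set of spectral indicators for a population. This
package implements a complete analysis chain for that problem:

1. windowed spectral band-power features per channel, normalized to a
   resting baseline;
2. per-subject feature ranking by joint mutual information (JMI), with
   information-gain and two-sample-t comparators;
3. a rank-position **consensus weighting**: each subject's top-10 features
   are pooled, and a feature scores the sum of `1.0, 0.9, ..., 0.1` over
   the positions at which it appears — the score rewards both frequency of
   appearance and rank position;
4. LDA accuracy curves over growing prefixes of the consensus ordering,
   stopped when three consecutive accuracy comparisons become
   non-significant;
5. a repeated-measures validation battery (Shapiro–Wilk gate, Friedman
   omnibus, Wilcoxon signed-rank post-hoc with Bonferroni correction)
   applied to subjective workload ratings, heart rate, and the aggregated
   consensus EEG metric.

Because the motivating experiment's recordings are confidential, the
package ships a fully seeded synthetic cohort generator that emulates the
study design; every stage is testable end to end without any data
download.

## The experimental design being emulated

Sixteen subjects each experience four conditions — `LowLow`, `LowHigh`,
`HighLow`, `HighHigh` (communication delay crossed with information
dropout) — twice, in 4-minute trials, wearing a 14-channel 128 Hz headset
(AF3, F7, F3, FC5, T7, P7, O1, O2, P8, T8, FC6, F4, F8, AF4), with a
1-minute resting baseline. Conditions map to ordinal workload levels
0, 1, 1, 2: the two mixed conditions are exchangeable in expectation,
which encodes the observation that only the extreme contrast is reliably
separable.

```{r config}
cfg <- cohortConfig()          # all defaults = the emulated design
cfg@nSubjects; cfg@fs; cfg@trialSeconds; cfg@conditions
```

## The signal model

Each channel is a pink (1/f power) background plus band-limited Gaussian
oscillations in the three classified bands (Theta 4–7.5 Hz, Alpha 8–12 Hz,
Beta 13–35 Hz). Both components are synthesized in the frequency domain,
so nothing above the band edges (and in particular above Nyquist) is ever
generated. This is deliberately *not* a biophysical model — no dipoles, no
volume conduction, no cross-channel covariance structure — because the
downstream analysis consumes band powers only; the model is the simplest
one whose band powers can be controlled exactly.

Workload effects are multiplicative power slopes at 19 (channel, band)
pairs spanning frontal, temporal, parietal and occipital sites
(`defaultEffectMap()`): at workload level `L` the oscillation power is
scaled by `1 + slope * L` (default slope 0.15 per level). Three noise
sources give the data realistic between-recording structure:

* a per-(subject, channel) amplitude gain (log-sd 0.2) — cancels under
  baseline normalization, as electrode impedance differences largely do;
* a per-trial broadband power gain (log-sd 0.12) — the dominant noise
  term for trial-aggregated metrics, it does **not** cancel;
* a per-subject responsiveness jitter on the effect slope (log-sd 0.25).

The effect slope and the trial gain were fixed together from the reported
statistics of the emulated study: its EEG metric separated the extreme
conditions decisively (Friedman chi-squared 31.3; extreme Wilcoxon pair
p < 0.001) while the mixed contrasts hovered at p = 0.01–0.03. A paired
effect size near 1.8 for the extreme contrast and near 0.9 for
single-level contrasts reproduces exactly that pattern, and
`slope = 0.15`, `trialGainSd = 0.12` achieve those effect sizes under the
1-minute-per-condition-per-repetition aggregation.

Heart rate (8 Hz) and the 1–7 subjective workload score are drawn from
per-condition distributions matched to the reported condition means and
standard deviations (HR means 72.47, 78.94, 73.76, 83.73 bpm; rating means
4.4, 5.0, 4.7, 5.9). Only means and stds are reported for these metrics,
so the split of each condition's variance into a between-subject trait, a
per-trial condition response, and within-trial sampling noise is this
package's choice; the split is fixed so that the reported paired-test
outcomes reproduce (extreme contrast significant at the Bonferroni level,
mixed contrasts mostly not). Concretely: rating trait sd 2.1 (implying a
cross-condition subject correlation near 0.88, which is what the reported
p = 0.002 at n = 16 requires), HR trait sd 3.5 bpm and per-trial response
sd `min(0.66 * sd_c, 8)` bpm. Ratings are rounded and clamped to [1, 7];
heart rate is truncated at 30 bpm.

What the generator does *not* emulate: real artifact morphology (blinks
and spikes are injected as stylized templates via `injectArtifacts()`),
non-stationarity within trials, volume-conducted cross-channel
correlation, and any behavioral or task dynamics. Passing tests therefore
demonstrate that the *analysis chain* behaves correctly and recovers known
injected structure — not that it would reach any particular accuracy on
real recordings.

## Preprocessing

`preprocessRecording()` applies, in order: pretrial baseline correction
(first 200 ms), a 2–43 Hz zero-phase FIR band-pass, robust spike gating,
and frontal-reference blink suppression.

Numerical choices worth stating:

* The FIR is a Hamming-window design of order `4 * fs` (513 taps at
  128 Hz), applied by FFT convolution with exact group-delay
  compensation — a linear-phase filter delayed by exactly `order/2`
  samples, so window boundaries align between raw and filtered data.
  Stopband attenuation exceeds 50 dB one octave below the low edge;
  passband ripple is below 0.1 dB. A realizable band-pass is *not*
  idempotent to machine precision (its passband ripple applies twice);
  linearity, which does hold to 1e-9, is what the tests assert.
* Spike gating thresholds the per-channel robust z-score
  (median/MAD) at 8, padding detections by 200 ms per side, and marks
  samples in an artifact mask rather than altering them; windows touching
  masked samples are dropped, never interpolated. This is an automated,
  conservative stand-in for the manual removal of electrode-movement
  spikes and is not equivalent to expert editing.
* Blink suppression regresses the 0.5–4 Hz component of the mean frontal
  signal (AF3, AF4, F7, F8) out of every channel. This is a deliberate,
  documented simplification of ICA-component classifiers such as MARA,
  which are out of scope; it guarantees per-channel variance never
  increases and barely touches blink-free data (per-channel correlation
  with the input above 0.99 in tests).
* Baseline correction uses each trial's own first 200 ms; whether the
  original analysis used the trial or the session baseline for this step
  is unstated, and the per-trial choice keeps recordings self-contained.

## Spectral features

`windowedPsd()` computes Hamming-tapered FFT periodograms on 10-s windows
with 50% overlap (47 windows per 4-minute trial), energy-normalized so the
integrated PSD equals the mean signal power. Band powers integrate the
PSD over half-open intervals `[low, high)` — shared edges are never double
counted. Two band presets ship: the five-band decomposition (Delta 2–4,
Theta 4–8, Alpha 8–12, Beta 12–30, Gamma 30–40 Hz) and the three-band
classification set (Theta 4–7.5, Alpha 8–12, Beta 13–35 Hz). The
classified feature space uses the three-band set — that is the set the
analysis is about — giving 3 x 14 = 42 features.

"Relative" normalization divides each window's (channel, band) power by
the same subject's same-(channel, band) power from the resting baseline
recording; division by the window's own broadband power is available via
`normalize = "broadband"`. Ratio indices — engagement `EI =
beta/(alpha+theta)`, task-load `TLI = theta/alpha`, `TBR = theta/beta` —
are computed from the absolute band powers (they are scale-invariant) and
are excluded from ranking after the correlation screen
(`correlationScreen()`, threshold |r| > 0.8 against the parent bands),
mirroring the observation that ratios carry little information beyond
their parents. Windows inherit their trial's condition label; windows are
classified individually (no per-trial averaging before classification),
with trial-level aggregation deferred to the validation stage.

## Ranking, consensus, and the stopping rule

The mutual-information estimator is the plug-in estimate on 5-bin
equal-frequency discretization — the standard choice in the JMI
literature; the bin count is a documented default, not a claim about the
original analysis. JMI ranks greedily: the first feature maximizes
`I(X; Y)`; each later pick maximizes the summed pairwise joint information
`sum_s I((X_f, X_s); Y)` over already-selected features `s`. All ties
break lexicographically by feature id, so rankings are deterministic and
platform-independent. The two-sample-t comparator contrasts the extreme
conditions (the four-class-to-two-sample mapping is this package's
choice; the source analysis does not state one).

`consensusScores()` pools each subject's top 10 features (16 x 10 = 160
pooled entries) and scores each feature by summing position weights 1.0
down to 0.1 (`positionWeight()`): a feature at position 1 for one subject
and position 7 for another scores 1.0 + 0.4 = 1.4. Ties in the final
ordering break by higher appearance count, then feature id — the source
reports no ties, so the rule is ours. The total score is conserved:
every subject contributes exactly 5.5.

Classification is per subject — consistent with one ranking per
participant — and reported numbers are grand averages across subjects,
with repeat r of every subject aligned by the shared split seed.
`ldaEval()` uses stratified 70/30 splits (stratification is our choice,
preventing class starvation), plain pooled-covariance LDA (no
regularization; zero-variance columns are dropped per split), a 10-fold
cross-validation sanity check on the training portion, and 30 seeded
repeats. The stopping rule walks the accuracy curve comparing consecutive
counts' per-repeat held-out scores with two-sample t-tests; after three
consecutive non-significant comparisons it returns the count that produced
the first of them. The choice of *what* the two samples are is the most
direct reading of "comparing consecutive classification results": the two
sets of 30 per-repeat held-out scores.

## Validation battery

The gate runs Shapiro–Wilk on two-way residuals, log-transforms and
retests on rejection — and the battery then proceeds nonparametrically
regardless, because the original route (overruling a passing test by
visual Q–Q inspection) cannot be automated faithfully; the gate's evidence
is reported, not acted on. The Friedman statistic is computed in-package
(mid-ranks, tie correction, chi-squared with k − 1 df, asymptotic p) so
that fully tied rows degenerate cleanly to chi2 = 0, p = 1;
`stats::friedman.test` serves as an independent cross-check in the test
suite. Post-hoc testing uses all six paired two-sided Wilcoxon
signed-rank tests, asymptotic with continuity correction (exact tables
add nothing at n = 16), against the Bonferroni threshold 0.05 / 6 =
0.0083. The EEG scalar entering the battery is the mean relative power
over the consensus top set and all windows of a subject-condition — the
simplest defensible aggregation; the source does not state one.

## A worked run

Problem sizes here are scaled down (4 subjects, 1-minute trials, 8
repeats) to keep the vignette quick; the same pipeline runs unchanged at
the full design scale.

```{r run, eval = FALSE}
cfg <- cohortConfig(nSubjects = 4, trialSeconds = 60, baselineSeconds = 30,
                    seed = 7)
res <- runWorkloadPipeline(cfg, evalProtocol(nRepeats = 8, seed = 1),
                           maxCurveFeatures = 25)
res$consensus          # population-level feature scores
res$selectedCount      # feature count fixed by the stopping rule
res$reports$EEG        # Friedman + Wilcoxon on the consensus EEG metric
```

## Known limitations

* The synthetic cohort shares none of the confidential study's actual
  recordings; absolute accuracies are not comparable to any published
  number, and the package makes no attempt to reproduce them.
* The blink/spike stages are stylized stand-ins; on real data an
  ICA-based pipeline should replace `suppressBlinks()`.
* The MI estimator's bin count (5) and the LDA's lack of shrinkage are
  defaults appropriate at hundreds of windows; with far fewer windows per
  class both should be revisited.
* Mixed conditions are exchangeable by construction; any empirical
  asymmetry between `LowHigh` and `HighLow` is outside this generator's
  vocabulary.
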