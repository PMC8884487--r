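---
title: "Temporal-coherence figure-ground stimuli and the synthetic MEG analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal-coherence figure-ground stimuli and the synthetic MEG analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonecoh)
```

## The paradigm

`tonecoh` implements an auditory figure-ground paradigm built on *temporal
coherence*: a scene of 20 amplitude-modulated tones in which, during defined
1-s windows, N of the tones suddenly share one modulation envelope. Because
every tone keeps the same within-channel modulation statistics throughout,
the only cue that a "figure" has appeared is the correlation of envelopes
*across* tonotopic channels - a binding computation that must happen
centrally, downstream of the cochlea. The package provides four layers:

1. **Stimulus synthesis** - the tone bank, stochastic envelopes, coherence
   schedules, session layout, WAV/event-log output.
2. **Periphery validation** - a gammatone filterbank "cochlear oracle" that
   verifies the design claims on the rendered audio, plus a correlation
   model observer.
3. **Synthetic cohort generation** - two groups (26 typically developing,
   21 ASD) of source-space auditory-cortex epoch sets with the response
   structure the paradigm probes, plus behavioral phenotypes.
4. **Analysis** - evoked window scores, multitaper induced spectra, the
   mixed-effects group x condition model, SVM diagnosis classification,
   and brain-behavior regression.

The generator exists so that every downstream stage is testable end to end
without any data download; it is first-class, seeded, and calibrated code,
not a test fixture.

## Stimulus model

**Tone placement.** Twenty carriers span 200 Hz to 8 kHz with equal spacing
on the ERB-number scale $E(f) = 21.4\,\log_{10}(4.37 f_{\mathrm{kHz}} + 1)$,
the standard moderate-level calibration derived from simultaneous-masking
estimates of cochlear tuning. The paradigm names the scale but not the
formula; we adopt this calibration and keep the constants in
`erb_scale_params()` so alternatives remain pluggable. The resulting
adjacent spacing is $\approx 1.445$ ERB ("about 1.5 cochlear filters"), so
adjacent tones interact only weakly at the periphery. Each tone plays at
60 dB SPL; the 20-tone power sum gives an overall level of
$60 + 10\log_{10} 20 \approx 73$ dB SPL. Since absolute SPL is a playback
property, the waveform is calibrated digitally: RMS 1.0 is defined as
100 dB SPL (configurable).

**Envelopes.** Each envelope is half-wave-rectified, smoothed, band-limited
(4-24 Hz) Gaussian noise, normalized to a fixed RMS per 1-s realization.
The processing order - band-pass (zero-phase brick wall), rectify, smooth
(Gaussian low-pass, half-power 24 Hz), normalize - follows the natural
reading of the design; the Gaussian smoother has an everywhere-positive
kernel, so nonnegativity survives smoothing exactly. Internally the chain
runs at a reduced sample rate (the smoothed envelope is band-limited far
below audio rates) and is resampled to audio rate by exact trigonometric
interpolation; FFT lengths are kept 2-3-5-smooth. These are implementation
choices that change nothing statistical.

**Trials.** A trial is 4 s: incoherent (1 s), coherent (1 s), incoherent
(1 s), coherent (1 s), giving coherence-change events at t = 1 s and 3 s.
During coherent segments the scheduled subset of tones shares one fresh
envelope realization; the subset is redrawn across trials, and the two
coherent periods of one trial use the same subset with independent shared
realizations (the design fixes randomization "trial to trial" only; we
chose the same-subset reading and expose the schedule object if the other
is wanted). Segments join through a 10-ms raised-cosine crossfade (on by
default) to avoid spectral splatter introducing a within-channel transient
cue; statistics, not sample continuity, are the fixed quantity. Carrier
phases are randomized per trial. Sessions interleave N = 6, 12, 18
pseudo-randomly, 240 trials per condition, ISI uniform on 1.2-1.3 s.

**Separation variants.** For the behavioral-control design, `narrow` mode
places the coherent tones contiguously (~1.445 ERB apart) and `wide` mode
maximally intersperses them (`round(seq(1, 20, length.out = n))`), giving
adjacent separations of at least 4 ERB (mean ~5.5 ERB for n = 6). A
six-tone figure at integer stride 4 does not fit on a 20-tone grid, so the
realized separation is reported rather than forced to a nominal value.
Under one seed the two modes share their envelope and phase realizations,
so comparisons are paired and differ only in which tones carry the figure.

## Periphery validation

The filterbank is a 4th-order gammatone magnitude response
$(1 + ((f - f_c)/b)^2)^{-2}$ with $b = 1.019\,\mathrm{ERB}(f_c)$, one
channel per tone, applied zero-phase in the frequency domain to positive
frequencies only; each channel output is an analytic signal whose
magnitude is the channel envelope (no group delay to compensate, one of
the advantages of the frequency-domain form). Envelopes are smoothed at
64 Hz, far above the 4-24 Hz modulation band. An optional exact
complex-demodulation decimation evaluates envelopes at a reduced rate for
Monte-Carlo work. Segment statistics drop 50 ms after each boundary to
exclude transition samples.

`validate_trial()` checks the design's central claim: per-channel envelope
RMS ratios (coherent/incoherent) center at 1 - the within-channel
statistics carry no information - while coherent-pair envelope
correlations (~0.99 at the filterbank output) separate sharply from
incoherent pairs (|r| ~ 0.15 over 1-s segments, the natural sampling floor
of a 4-24 Hz process). The broadband (summed) envelope *variance* rises
during coherent segments - envelope alignment raises the crest factor
without changing RMS - which is why the separation-variant control matters:
narrow and wide figures share that broadband signature and differ only in
coherence topology. `model_observer_detect()` provides a simple
correlation observer: the maximum over sliding 1-s windows and greedily
grown channel subsets of the mean pairwise envelope correlation.

## Synthetic cohort generator

Each participant's trial-level ROI time course is

$$x(t) = \sigma_b\,n_{1/f}(t) + A\,[M_1(t) + \mu_g\,M_2(t)] + \gamma_i\,g(t),$$

with $n_{1/f}$ a 1/f background (spectrum flattened below 1 Hz), $M_1$ a
Gaussian pulse (peak 100 ms, SD 20 ms), $M_2$ a slow half-sine over
250-450 ms scaled by $\mu_g$ (1 in TD, 0.2 in ASD: the M2 component is
nearly absent in the ASD group), and $g(t)$ a 30-70 Hz noise burst gated
over 400-900 ms with a fresh realization per epoch, so its phase is random
and it cancels in the trial average while surviving per-trial spectral
analysis. The evoked amplitude is

$$A = \mathrm{gain}_i\,(a_0 + s_g\,r) + \varepsilon_t,\qquad
\mathrm{gain}_i = e^{\sigma_p u_i},\ u_i \sim \mathcal N(0,1),$$

where $r \in \{1,2,3\}$ is the coherence rank of N = 6/12/18 and $s_g$ is
the group growth slope (0.30 TD vs 0.10 ASD per rank: the ASD growth is
sluggish). The participant effect is a multiplicative lognormal gain -
source amplitudes vary strongly but never change sign across people, which
keeps polarity alignment meaningful. Gamma is present only for TD at
N = 18 (amplitude 0.8, lognormal participant spread, correlated 0.5 with
the latent gain).

Defaults were chosen once as the study conditions: background SD 5 puts
the single-trial M1 near -10 dB SNR (a typical source-level MEG regime);
$\sigma_p = 0.8$ calibrates the expected N = 18 between-group contrast to
t(45) ≈ 3.5 at the full 240 trials/condition - a calibration aid tied to
the paradigm's reference effect size, not a fitted quantity. Behavioral scores follow
the reference phenotype profile: within ASD, SRS-SCI (mean 74.6, SD 11.5)
loads negatively on $u_i$ (r = -0.6), SPQ-APS (mean 15.35, SD 4.5) loads
positively (weaker responses go with lower, i.e. more abnormal, sensory
scores) and declines weakly with age, and ICSS-I is independent of the
neural effect by construction - it is the attention-confound control.
Epoch geometry: 1000 Hz, -0.5 to +1.0 s around each coherence-change
event, two events per trial, two hemispheres with no systematic
difference. The desk-scale default is 60 trials/condition; the full
experiment's 240 is a flag away.

What the generator does *not* emulate: sensor-level physics, artifacts,
source-localization error, latency jitter between participants, or any
group difference in the M1 *latency* - so passing tests validate the
analysis chain and its calibration, not claims about real MEG data.

## Analysis chain

**Evoked.** The two events of each trial are collapsed by averaging;
polarity alignment flips a hemisphere's sign when its average M1-window
response is negative (source current direction is arbitrary). The
trial-average trace is z-scored against the 200 ms immediately preceding
the event, per hemisphere. Component scores are window means of z: M1 =
[50, 150) ms, M2 = [250, 450) ms, combined = [50, 450) ms (all half-open
on the 1-ms grid, which makes the boxcar arithmetic exact); hemispheres
are averaged at the score level.

**Induced.** Per-trial multitaper spectrograms: 200-ms windows, 50%
overlap, full time-bandwidth product 4. A taper count of 3 is
consistent only with half-bandwidth product NW = 2 (K = 2NW - 1 = 3), so
that is the implemented plan; both numbers are arguments. Slepian tapers
come from the exact symmetric-tridiagonal eigenproblem. Power is averaged
over trials *before* the base-10 log (the choice of log base only scales
the reported log-ratios); the time axis is collapsed by averaging; the
spectrum is expressed as a log-ratio against the windows wholly inside the
pre-event (incoherent) portion, and gamma power is the mean log-ratio over
30-70 Hz in the late (0.4-1.0 s) windows, where the burst lives. The
order matters: averaging trials before squaring would cancel the
random-phase gamma; the test suite checks both routes explicitly.

**Inference.** The group x condition model is
`response ~ group * condition + (1 | participant)`, REML via `lme4`, with
Satterthwaite-F fixed-effect tests (`lmerTest`) - for this balanced
single-random-intercept design the F statistics and degrees of freedom
(1/45, 2/90, 2/90 at full cohort size) coincide exactly with classical
repeated-measures ANOVA, which the tests verify against `aov()`. The
random structure is a single condition-independent participant intercept -
the structure an information-criterion pruning of richer covariance models
selects for this design; for unbalanced tables the function
falls back to a label-permutation test rather than fitting covariance
structures it cannot honestly identify. Per-condition contrasts are
pooled-variance two-sample t tests (df = 45). No multiplicity adjustment
is applied - these are the paradigm's planned contrasts - and the report
says so.

**Classification and behavior.** Diagnosis decoding is a linear SVM
(cost 1, `e1071`), features = combined evoked z and gamma log-ratio at
N = 18, features standardized on the training fold only, 90/10 split
repeated 50 times. "Repeated with replacement" is read as 50 independent
random re-partitions (a participant never appears twice within one split);
the split plan is recorded in the output. Behavioral prediction regresses
SRS-SCI (or age-corrected SPQ-APS, the residuals from a least-squares
regression of SPQ-APS on age) on the same two features within the ASD
group and reports Pearson r between fitted and observed scores - in-sample
by design, so the r equals the multiple correlation coefficient and is
optimistically biased under the null (E[R²] = p/(n-1) ≈ 0.1 here); the
documentation and a dedicated test quantify that bias rather than hiding
it. A cross-validated variant would be the obvious extension.

## Numerical and reproducibility choices

* Every stochastic stage derives its seed from one master seed via a
  31-bit string hash (`derive_seed()`); the whole pipeline, including the
  classifier splits, is bit-reproducible, and `run_pipeline()` writes an
  MD5 manifest so reruns can be compared file by file.
* Half-open time windows on exact sample grids avoid double-counting
  boundary samples; segment statistics exclude 50 ms after each boundary.
* Zero baseline variance, missing events, windows outside the epoch,
  infeasible wide figures, and single-class training folds all fail fast
  (or, for the folds, redraw) rather than propagating NaNs.
* Degenerate inputs are defined: N = 0 trials are fully incoherent,
  N = 20 fully coherent; constant age vectors residualize to centered
  scores with a warning.

## Problem sizes used by the test suite

The suite validates the periphery claims over 100 trials per coherence
level at a 20 kHz audio rate; calibrates the mixed model's type-I error
over 500 null cohorts (8 + 8 participants, 12 trials/condition, 250 Hz
epochs); and measures parameter recovery over 100 replicate cohorts at the
full 240 trials/condition with 250 Hz epochs and a -0.2 to +0.46 s window
(the minimal window containing baseline and all component windows).
Reduced epoch rates leave the window scores' distribution essentially
unchanged - the z-scores depend on band-limited noise statistics, not on
the sampling grid - and were chosen so the whole suite runs on a laptop
core in minutes. Classification checks run at the desk-scale default of
60 trials/condition.

## Known limitations

* The periphery model is a linear gammatone magnitude response: no
  compression, adaptation, or rate-level nonlinearity, and the "1 ERB"
  bandwidth is itself a modeling convention for "cochlear-filter scale".
* The generator's effect sizes are calibrated, not discovered; recovery
  tests demonstrate internal consistency of generator + analysis, which is
  the design goal of a synthetic cohort.
* The evoked and induced components share one latent gain; real data
  likely have richer (and noisier) coupling between evoked amplitude,
  gamma power and behavior.
* In-sample behavior prediction follows the paradigm's procedure as
  defined, including its optimism; treat the reported r as descriptive.
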