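---
title: "Measuring ILD sensitivity in bilateral cochlear-implant experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ILD sensitivity in bilateral cochlear-implant experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ildsense)
library(dplyr)
```

## The problem

Bilateral cochlear-implant (CI) users localize sound mostly through
interaural level differences (ILDs): the difference, in dB of electric pulse
amplitude, between the stimulation delivered to the two ears. In animal
psychophysics this is measured with a two-alternative forced-choice (2AFC)
lateralization task: on each trial a binaural pulse train with some ILD is
presented, the animal responds "left" or "right", and the proportion of
"right" responses as a function of ILD — the psychometric function — tells us
how sensitive the animal is to the cue.

`ildsense` implements the full analysis chain for such experiments: electric
stimulus synthesis and clinical-unit arithmetic, a seeded trial-level
simulator for testing the chain end to end, maximum-likelihood psychometric
fitting with model selection, sensitivity metrics, and the dependence of
sensitivity on stimulation pulse rate.

## The stimulus model

Electric stimuli are unmodulated trains of charge-balanced biphasic current
pulses, as used clinically. At the stimulator's fixed sample rate of
48,828.125 Hz each pulse occupies six samples in three 2-sample phases
(`+A, +A, 0, 0, -A, -A`), so a phase lasts exactly 40.96 µs and every pulse
sums to zero charge. Amplitudes are capped at 300 µA. Only whole pulses are
emitted (`floor(rate × duration)` of them), which keeps the train
charge-balanced; pulse periods are rounded to whole samples, so the realized
rate can differ from the nominal rate by under half a sample per period and
is reported in the `pulse_train` object.

An ILD is applied symmetrically around the average binaural level (ABL):
left = ABL − ILD/2, right = ABL + ILD/2, in amplitude dB
(`20·log10` of the peak-current ratio). The experimental literature does not
pin down whether one ear is held fixed instead; the symmetric split is our
choice because it holds the ABL — the loudness-controlling variable — constant
across ILDs, and it is recorded in the stimulus metadata. Interaural time
differences are always zero: the two channels are sample-aligned.

Clinical papers often report ILDs in Cochlear Ltd current-level (CL) units.
Since `I(µA) = 17.5 × 100^(CL/255)`, a CL difference maps to dB linearly at
`40/255 ≈ 0.15686` dB per CL unit; `cl_to_microamps()` and `cl_ild_to_db()`
implement both directions of this arithmetic.

```{r stimulus}
stim <- make_binaural(900, 0.02, abl_db = 0, ild_db = 6)
measure_ild(stim)
cl_ild_to_db(5)
```

## The psychometric models

The proportion of "right" responses is modelled as a function of ILD by three
candidate models:

* **probit with lapses**: `pR = Φ(ILD·α + β)(1 − γ) + γ/2 + δ`. `α` is the
  sensitivity (probit units per dB); `β` an *ear bias* (zero ILD heard
  off-centre shifts the curve horizontally); `γ ∈ [0, 1]` a *lapse rate* — the
  proportion of trials answered without regard to the stimulus, which
  compresses both asymptotes toward chance symmetrically; `δ` a *spout bias*,
  a vertical offset from an idiosyncratic preference for one response side.
* **bounded linear**: `pR = ILD·α + 1/2 + δ`, clipped to `[0, 1]` — adequate
  when performance never saturates within the tested range.
* **null**: `pR = δ`, a constant. Note that the null model's `δ` is an
  absolute probability in `[0, 1]`, not an offset around 1/2; we keep that
  reading because the constant is the model.

Fitting maximizes the binomial log-likelihood of per-ILD right-response
counts, which equals the trial-level Bernoulli likelihood up to a
parameter-free constant. Numerical choices:

* probabilities are clamped to `[1e-9, 1 − 1e-9]` inside the likelihood;
* the probit fit runs L-BFGS-B from a fixed lattice of 16 starting points
  (`α ∈ {±0.05, ±0.5} × β ∈ {±0.25} × γ ∈ {0.02, 0.2}`, `δ = 0`), because
  lapse models have local optima. The lattice is sign-symmetric, so mirrored
  datasets (ILD → −ILD, responses swapped) produce exactly mirrored fits, and
  it contains no random jitter, keeping fits free of hidden RNG state;
* constraints are a box (`γ ∈ [0, 1]`, `δ ∈ [−0.5, 0.5]`, generous bounds on
  `α, β`) plus a quadratic penalty keeping predictions inside `[0, 1]` over
  the observed ILD range — simpler and more testable than deriving analytic
  joint bounds on `(β, γ, δ)`;
* one-sided data (every response the same) is fit to the boundary with a
  warning, and non-convergence is flagged, never silently dropped.

**Model selection** runs sequential deviance (likelihood-ratio) tests along
null → linear → probit, accepting the richer model when `2·ΔLL` exceeds the
χ² critical value with df = Δ(free parameters) at a configurable 0.05 level;
a statistic exactly at the threshold resolves to the simpler model. The
bounded-linear model is not strictly nested in the probit, so the chain is a
pragmatic ordering of the three candidates rather than exact theory; an
AIC comparison is available (`select_model(..., method = "aic")`) for users
who prefer a non-nested criterion.

```{r fit}
subject <- virtual_subject("demo", alpha = 0.45, beta = 0.1, gamma = 0.05)
trials <- simulate_trials(subject, session_design(seed = 7))
sel <- fit_and_select(binomial_summary(trials))
sel$model
tidy(sel$selected)
```

## Sensitivity metrics

Two measures summarize a fitted curve:

* **JND** — the ILD change raising `pR` from 50% to 75% on the
  spout-bias-corrected curve. For the probit this is
  `Φ⁻¹((0.75 − γ/2)/(1 − γ)) / |α|` (the ear bias cancels); for the linear
  model `0.25/|α|`. We remove only `δ` and *retain* the lapse term by
  default, since the published definition corrects for spout bias and says
  nothing about lapses; `jnd(fit, lapse_corrected = TRUE)` gives the other
  convention. When `γ ≥ 0.5` the lapse-retained curve never reaches 75% and
  the JND is reported as undefined rather than extrapolated. `|α|` keeps the
  JND positive for left-preferring fits; direction is carried by the slope's
  sign.
* **slope at ILD = 0** — `100·α·φ(β)(1 − γ)` %/dB for the probit, `100·α`
  for the linear model (zero if the linear fit is clipped at zero ILD).

Raw per-ILD proportions get Wilson score intervals (the critical value is
computed from the normal quantile, so any confidence level works). Pulse-rate
dependence is quantified by pooled ordinary least squares of each measure on
`log10(pps)` across all (subject, rate) points — a single regression line, not
per-animal fits or a mixed model, matching how a single R² per measure is
reported in this literature; undefined JNDs are excluded listwise with the
count reported. Base 10 is a display choice: R² and the p-value are invariant
to the base.

## What the synthetic generator emulates — and what it does not

Because trial-level data from such experiments are typically not deposited,
the package ships a first-class generator. It emulates the study design: 24
subjects, ILDs ±{0.5, 1, 2, 3, 4, 5, 6} dB (zero excluded, as in the tested
set; if a user adds it, the `correct` flag is a fair coin), ~200 trials per
session, 4 sessions per curve (~800 trials), pulse rates 50–2400 pps, and
Bernoulli responses from a probit-with-lapse ground truth. Trials are
allocated to ILDs in balanced shuffled blocks, approximating the near-equal
per-ILD counts visible in published data; the true allocation schedule of any
given lab is unknown, and this is our assumption. Each (subject, rate) cell
draws from its own stream derived from the master seed by a stable string
hash, so runs are bit-reproducible and adding subjects never perturbs
existing ones.

Default cohort calibration (chosen once): `α` at 900 pps is log-normal with
median 0.42 (sdlog 0.40), `β ~ N(0, 0.35)`, `γ ~ Beta(1.5, 20)`,
`δ ~ N(0, 0.02)` clamped into the interval that keeps predictions in
`[0, 1]`. These values put the implied cohort medians near the anchors
reported for real implanted rats (median JND ≈ 1.7 dB, median slope
≈ 15 %/dB at 900 pps); the two anchors are not exactly jointly attainable
with a zero-centred ear bias, so both sit within a few percent rather than
exactly. Across rates, each subject's true JND scales as
`−0.6715 + 0.5657·log10(pps)` (normalized to 1 at 900 pps), chosen to
reproduce the roughly twofold mean-JND increase from 300 to 2400 pps.
The generator also implements the monaural-audibility control: when the
quieter ear falls below a subject's audibility threshold, the response
probability collapses to the guessing mixture `0.5 + δ`, which is what makes
performance collapse for near-threshold or unilaterally suprathreshold
stimuli.

The generator does **not** model session-to-session learning, reaction
times, reward or timeout dynamics, serial dependence between trials, or
electrode-specific loudness growth. Passing tests on synthetic cohorts
therefore demonstrate that the analysis chain is correct and calibrated
under its own assumptions — not that real animals satisfy those assumptions.

## Reproducible pipeline

`run_pipeline(run_config(...))` chains simulate → summarize → fit → select →
metrics → regression → figures, writing tidy CSV/JSON artifacts plus a
manifest of MD5 hashes. A single master seed in the config derives every
stage stream; the output directory is excluded from the serialized config so
identical configs give hash-identical bundles wherever they are written.
Figures are pure views, regenerable from the CSV/JSON artifacts alone. A thin
command-line wrapper over `run_pipeline()` is installed at
`system.file("scripts", "run_pipeline.R", package = "ildsense")`.

Problem sizes used in the shipped checks: cohort analyses use the full
design (24 subjects × ~800 trials); replicated calibration checks use 200
recovery replicates and 500 model-selection replicates at 800 trials per
curve, and Wilson coverage uses 10,000 draws at n = 100.

## Known limitations

* The deviance chain treats the bounded-linear model as nested between null
  and probit; this is an approximation (see above).
* The probit δ constraint is enforced over the *observed* ILD range, so a fit
  extrapolated far outside that range can leave `[0, 1]`.
* JND conventions differ across labs (lapse retained vs removed); both are
  implemented, and the default is the lapse-retained reading.
* The pooled rate regression ignores within-subject correlation; with few
  animals a mixed model would be more efficient but is deliberately out of
  scope.
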