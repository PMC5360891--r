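---
title: "Identifying and predicting COPD exacerbations from telemonitoring data"
author: "copdwatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and predicting COPD exacerbations from telemonitoring data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copdwatch)
```

## The problem

Patients with chronic obstructive pulmonary disease (COPD) suffer
exacerbations — sustained worsenings of symptoms that often lead to
hospitalisation. In home telemonitoring, a patient completes a short
self-monitoring *session* several times a week: an interactive symptom diary
(six questions answered *improved* / *no change* / *worse* relative to what
is usual for them), medication usage flags, and a ~30-second pulse-oximeter
recording that yields oxygen saturation (SpO2), pulse rate, and — via the
photoplethysmogram (PPG) waveform — respiratory rate.

`copdwatch` does two things with such data:

1. **Identification.** A deterministic three-state finite-state machine (FSM)
   turns the session stream into a state timeline (NORMAL, TRANSITIONAL,
   EXACERBATION) and a list of exacerbation events.
2. **Prediction.** Labelled 7-day windows — *stable* (all-normal, isolated by
   guard bands) and *prodromal* (the 7 days before an event) — are summarised
   by per-vital linear-trend features and classified with logistic
   regression, evaluated by repeated 10-fold cross-validation.

## The finite-state machine

Each session is encoded as a 3-bit input. The first bit is 1 when a
*medication event* occurs — starting oral steroids and/or antibiotics
(a rising edge relative to the previous session, or resumption after at
least 7 flag-free days), or increased reliever-inhaler use sustained for at
least 48 hours — or when the patient reports contact with a health-care
professional. The remaining two bits code the symptom change: `00` no
change, `10` significant worsening, `11` improvement. A *significant
worsening* requires at least two `worse` answers, at least one of them for a
major symptom (chest tightness, breathlessness, sputum volume, sputum
purulence). Improvement mirrors this definition and is evaluated against the
previous diary session: an answer counts toward improvement when it is
`improved`, or when it was `worse` at the previous session and is
`no change` now. If a session satisfies both definitions simultaneously,
worsening wins — the conservative choice for detecting deterioration.

The transition rules: patients stay NORMAL unless symptoms worsen; worsening
moves them to TRANSITIONAL (no medication event) or directly to EXACERBATION
(with one). From TRANSITIONAL, improvement always returns to NORMAL, and a
medication event without improvement escalates to EXACERBATION. From
EXACERBATION the only exit is improvement, back to NORMAL. The state machine
is a pure total function over 3 states x 6 legal inputs; the test suite
checks all 18 pairs against a hand-transcribed table and verifies by
exhaustion that no path leads from EXACERBATION to TRANSITIONAL.

```{r fsm-demo}
fsm_step("NORMAL", list(event_bit = 1L, symptom_code = "10"))
```

Between sessions a patient inherits the state of the most recent session (a
step function in time); everyone starts in NORMAL. Event lengths are the day
span from the entering session to the session that exits to NORMAL, rounded
up, with a minimum of one day (so event-length histograms can start at the
1–7-day bin).

Two readings of the definitions were genuinely open and are package design
choices: the 48-hour reliever rule is a contiguous run of
`reliever_increased` sessions spanning at least 2 days, broken by a
non-flagged session or by a gap of more than 2 days without any session; and
each session's worsening is re-evaluated independently (the diary answers
are already self-relative).

## Period selection

*Stable* windows are 7-day windows lying wholly inside a NORMAL stretch,
with a 7-day guard band after the return to NORMAL and before the next
departure — so a stable window is never within 7 days of a transitional or
exacerbation state. The trimmed stretch is tiled with disjoint 7-day windows
from its left edge (deterministic, and maximises early windows); leftover
days are discarded. No guard is applied against enrollment or the end of
monitoring, since guards are defined relative to episodes only. *Prodromal*
windows are the 7 days immediately before an event, kept only when the
patient was NORMAL or TRANSITIONAL throughout (which excludes events
following a previous event within 7 days).

Both labels require at least two member sessions — a line fit needs two
points. (For prodromal windows this also reproduces the exclusion of events
with a single in-window diary session; for stable windows it is an
extrapolation of the same requirement.)

## Respiratory rate from the PPG

Breathing modulates the PPG in amplitude (mechanical effect) and in beat
timing (respiratory sinus arrhythmia). The estimator targets the amplitude
modulation, since sinus arrhythmia declines with age and medication:

1. remove the mean;
2. low-pass filter with a heart-rate-adaptive linear-phase FIR whose
   transition band runs from 0.5 x to 1.2 x the cardiac frequency
   (Kaiser design, passband ripple <= 1 dB, stopband attenuation >= 40 dB;
   the paper-style adaptive band leaves the respiratory baseband intact
   while suppressing the cardiac line);
3. decimate to ~4 Hz (anti-aliased), concentrating AR poles in the
   respiratory band for 30-s segments;
4. fit Burg autoregressive models at orders 4–12 and take the pointwise
   median of their power spectra on a 0–1 Hz grid (5 mHz step) — the median
   is robust to an occasional poorly conditioned order;
5. report 60 x the peak frequency within the respiratory band, default
   4–40 breaths/min for adults.

If the in-band peak rises less than 3 dB above the median in-band power the
estimate is flagged `low_confidence`; degenerate inputs give `failed`. The
estimate is scale-invariant, and always lies inside the band unless flagged.
When the device pulse rate is missing, `estimate_pulse_rate()` recovers it
from systolic peaks of the 0.5–3 Hz band-passed waveform (median inter-beat
interval; fewer than 10 beats fails).

```{r rr-demo}
seg <- generate_ppg(ppg_config(fs_hz = 100, hr_bpm = 75, rr_brpm = 18,
                               am_depth = 0.2))
est <- estimate_respiratory_rate(seg, hr_bpm = 75)
c(rr = est$rr_brpm, quality = est$quality)
```

On a noise-free grid of RR 8–30 brpm x HR 60–100 bpm the mean absolute
error is well under 1 brpm (the suite requires <= 1.5), and the error is
non-decreasing in additive noise.

## Trend features

Traditional time-series methods assume regular sampling; diary data are
irregular with missing days. Instead of imputing, each vital sign in each
7-day window is summarised by an ordinary least-squares straight line fitted
to whatever sessions exist: the window's times are shifted so the first
session is at 0, and the gradient *m* (units/day) plus the unweighted session
mean form the two features per vital — six features per window. The mean is
the raw session mean, not the fitted midpoint, matching how per-period means
are usually reported; the y-intercept and standard deviation are available
behind a flag but excluded by default, as they have not been found to add
information. Multiple sessions within one day are kept as distinct points.

## Classification and validation

A logistic classifier maps the six features to the probability that a window
is prodromal. The implementation standardises features internally (training
folds only), minimises the convex mean cross-entropy by damped Newton steps
from a zero start (gradient-norm tolerance 1e-6), and reports coefficients
and Wald covariance on the original feature scale. Probabilities are clipped
at 1e-15 in the cost so saturated predictions cannot produce infinities.
There is no regularisation by default; an optional ridge penalty sits behind
a flag.

Validation follows the repeated-cross-validation design: the windows are
randomly split into 10 folds (unstratified; degenerate partitions that leave
a training split single-class are resampled and logged), out-of-fold
probabilities are pooled so every window is scored once per repeat, and one
ROC curve is computed per repeat. Curves are averaged vertically on a fixed
101-point false-positive-rate grid; the 95% band is the 2.5/97.5 percentile
envelope, and the headline AUC is the mean of per-repeat trapezoidal AUCs
(the AUC of the mean curve is also reported). Specificity at 60%–80%
sensitivity is read off the mean curve at the smallest grid FPR whose mean
TPR reaches the level. `compare_feature_sets()` evaluates all seven subsets
of {pulse rate, SpO2, respiratory rate} with identical fold partitions per
repeat, so subset comparisons are paired.

Folds are over windows, not patients, matching the original design; windows
from one patient can land in both train and test. A `group` argument (or
`group_by_patient` in the pipeline) provides the methodologically stricter
variant for sensitivity analyses; it is off by default.

## The synthetic cohort generator

The trial data behind this kind of analysis are not publicly deposited, so
the package ships a generator that emulates their statistical structure with
known ground truth; it is what the test suite and the acceptance script run
on.

* **Compliance**: each day holds a session with probability 5.3/7, at a
  uniformly random time in a 12-hour daytime window (patients record at a
  time of their choosing).
* **Episodes**: onsets are a Poisson process at 3.6 events/patient/year;
  lengths are log-normal parameterised by mean 8.8 and median 4 days (the
  two printed moments of the reference distribution fix both log-normal
  parameters); overlapping onsets are thinned.
* **Diaries**: at each realized onset the first session reports two major
  symptoms worse, with medication starting at the same session with
  probability 0.64 (the direct NORMAL-to-EXACERBATION route) and one session
  later otherwise (the route through TRANSITIONAL); worsening persists until
  the first post-episode session reports improvement. Outside episodes,
  transient symptom worsenings occur at 0.02/session (0.35/session in the
  prodromal week) and recover with probability 0.5 per subsequent session,
  exercising both recovery codings (explicit `improved` answers and
  `no change` after `worse`). Occasional isolated reliever flags are
  injected; they never span 48 hours.
* **Vitals**: stable sessions draw from Gaussians around (SpO2 94%, PR
  80 bpm, RR 22 brpm) with SDs (2, 8, 3) — deliberately heavy class overlap.
  Over the 7 days before an onset the means drift linearly with gradient
  2 x (prodromal - stable)/7 per vital, so the drift starts at the stable
  mean and the 7-day *window mean* equals the prodromal means (93, 83, 24).
  Within-class SDs and cross-vital correlations are not published for this
  setting, so the SDs are exposed as parameters rather than fixed truths.
* **PPG**: a raised-cosine pulse train at the session's pulse rate, amplitude
  modulated at the respiratory frequency, optionally frequency-modulated
  (sinus arrhythmia) and noise-corrupted. Only the modulation structure
  matters for the estimator; the morphology is deliberately not
  physiological (no dicrotic notch).

Everything is driven by one root seed through a deterministic per-stream
seed derivation, so identical configurations reproduce cohorts bit for bit.

What the generator does **not** emulate: within-patient baseline
heterogeneity and autocorrelated vitals, missing-not-at-random compliance,
cross-vital correlation, motion artifacts in the PPG, and symptom reporting
noise. Consequently, passing tests demonstrate the pipeline's correctness
and calibration on data with the assumed structure — not the clinical
performance level to expect on real patients, where class overlap is worse
(cross-validated AUCs on the synthetic cohorts run higher than on trial
data for exactly this reason).

## Problem sizes and numerical choices

The shipped test suite and acceptance script keep simulations at desk scale
as the package's own defaults: cohorts of 20–100 patients over 180–365 days,
100 cross-validation repeats, 50-seed noise sweeps for the respiratory-rate
estimator, and 200-replicate coverage simulations at n = 1291 with a
1005:286 class imbalance. The full 1000-repeat cross-validation of the
original design is a single argument (`cv_reps = 1000`).

Numerical details worth knowing: the FIR filter is applied forward with its
constant group delay removed and start-up samples dropped (not
forward-backward, which would square the response); `ar.burg` is fitted
without AIC selection at each fixed order; ROC ties are grouped so the
trapezoidal AUC equals the concordant-pair probability with half-credit for
ties; and the Newton optimiser halves its step until the convex cost
decreases, making the fit deterministic from the zero start regardless of
row order.

## Limitations

The FSM can only see what patients report: unreported exacerbations (e.g. an
HCP contact while TRANSITIONAL, with no diary change) are missed, as in the
original definition. Event lengths for episodes still open at the end of
monitoring are measured to the last session and flagged `open`. The
respiratory-rate estimator assumes the amplitude-modulation pathway
dominates; PPGs whose respiratory information is purely in frequency
modulation return `low_confidence`/`failed` rather than an estimate.
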