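---
title: "Methods: from vertical ground reaction forces to asymmetry statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from vertical ground reaction forces to asymmetry statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rspgait)
```

## The problem

Athletes with a unilateral transtibial amputation run with a carbon-fibre
running-specific prosthesis (RSP). How the RSP is configured — which model,
which manufacturer stiffness category, what height — changes the mechanics of
each leg and the asymmetry between legs, and those changes may depend on
running speed. This package implements the standard analysis chain for that
question: treadmill vertical ground-reaction-force (GRF) signals are turned
into per-leg spatiotemporal metrics, per-trial symmetry indices, and finally
linear mixed-effects estimates of configuration effects across speeds.

## The model of a running step

A step is one ground-contact (stance) phase of a leg plus the following
aerial phase. With contact time $t_c$ and aerial time $t_a$:

$$f_{step} = \frac{1}{t_c + t_a}, \qquad
  L_c = v\, t_c, \qquad
  L_{step} = L_c \cdot F_{avg}, \qquad
  v = L_c \cdot F_{avg} \cdot f_{step},$$

where $v$ is the (constant) belt speed, $L_c$ the contact length, and
$F_{avg}$ the stance-average vertical GRF normalized to body weight.
The last identity follows from steady-running impulse balance: over a full
step the vertical impulse must equal body weight times step time, so
$F_{avg} = (t_c + t_a)/t_c$ bodyweights and the product telescopes to $v$.

On a treadmill $L_c$ is estimated as `belt_speed * t_c`. This is the single
largest modelling assumption in the chain: contact length is defined as the
forward distance the centre of mass travels during contact, and the
belt-speed surrogate is exact only at constant speed. It is also what makes
$L_{step} = L_c\,F_{avg}$ an identity rather than an approximation.

Between-leg asymmetry of a metric $X$ uses the symmetry index

$$SI = \frac{X_{UL} - X_{AL}}{\tfrac12 (X_{UL} + X_{AL})} \times 100\%,$$

with $X_{UL}$ the unaffected-leg and $X_{AL}$ the affected-leg value: 0% is
perfect symmetry, positive means the unaffected leg is larger. Changes in SI
are reported in percentage points. The SI of a trial is computed from the
per-leg *means* — the index is defined on leg-level quantities — not by
averaging per-step indices.

## Signal conditioning

**Drift correction.** Force transducers drift over a trial. During an aerial
phase the true vertical force is zero, so any reported force there is
baseline. `correct_drift()` finds sub-threshold runs of at least 20 ms,
anchors each at its midpoint with the run's median force, interpolates
linearly between anchors (flat extension to the edges), and subtracts. The
median anchor makes the estimate robust to residual noise; tests pin the
behaviour to within ±0.5 N of a zero aerial baseline under a 10 N ramp.

**Filtering.** Force is low-pass filtered at 30 Hz and marker positions at
6 Hz, both with a fourth-order Butterworth filter applied forward and
backward (zero phase), which is the standard in biomechanics because it does
not shift event timings. `signal::butter()` supplies the coefficients; the
zero-phase application is implemented in-package with odd-reflection padding
and steady-state initial conditions, so a constant signal passes through
exactly and edge transients are suppressed (naive forward–backward filtering
without initial-condition handling produces edge excursions of hundreds of
newtons on a 700 N signal).

**Stance detection.** A 20 N threshold defines contact: touchdown is the
first sample at or above threshold, takeoff the first sample back below it
(half-open interval, 1-based indices). Sub-threshold gaps shorter than 20 ms
are merged into the surrounding stance and supra-threshold bursts shorter
than 50 ms are discarded; both constants are configurable and sit well below
the shortest plausible aerial time at 7 m s⁻¹. Stances touching a signal
edge are incomplete and dropped.

By default the threshold is applied to the **drift-corrected, unfiltered**
force, while $F_{avg}$ is averaged over the **filtered** force within the
detected stance. The choice was measured, not assumed: zero-phase 30 Hz
filtering smears the sharp stance onset, lifting the signal above 20 N two
to seven samples early on clean synthetic trials (worse at sprint speeds),
which breaks the edge-timing guarantee the rest of the chain relies on.
Thresholding the raw signal is sample-exact there; `run_config(detect_on =
"filtered")` restores the other convention.

**Leg labelling.** Reflective markers on the prosthesis and foot identify
which leg is on the belt: the event is attributed to the leg whose filtered
marker is lowest on average over the stance (nearest-sample matching between
the 200 Hz marker clock and the 1000 Hz force clock — labelling needs only
coarse alignment). Consecutive events must alternate legs; a violation is
labelled `unknown` with a warning rather than silently propagated. Trials
whose raw force sits at the transducer saturation level for ≥ 3 consecutive
samples are flagged and excluded from aggregation.

## The synthetic-data generator

`simulate_trial()` is first-class, tested code, not a fixture: it emulates
the features of treadmill GRF data the pipeline must survive, with the truth
recorded before corruption.

* Stance force bumps are half-sines, $F(t) = F_{peak}\sin(\pi t/t_c)$. The
  shape is the simplest one with the right impulse properties; every metric
  in the chain depends only on timing and the stance mean, not the shape.
  Unless overridden, $F_{peak}$ is set by impulse balance:
  $\frac{2}{\pi} F_{peak} = m g\,(t_c+t_a)/t_c$.
* Between-leg asymmetry is a signed fractional offset applied in opposite
  directions (unaffected ×(1+a), affected ×(1−a)), so closed-form SI values
  are available for every test (a = 0.1 on $t_c$ gives $SI_{L_c}$ = 20%).
* White noise, then linear or sinusoidal baseline drift, then saturation
  clipping are applied after the truth is captured, mirroring the physical
  signal path.
* Markers are scalar heights: 0.05 m during the leg's own stance, a
  sinusoidal arc to 0.15 m mid-swing — sufficient for labelling, nothing
  more.
* Defaults are the study conditions: 16 steps per trial (the success
  criterion for a treadmill trial), 1000 Hz force, 200 Hz markers. Contact
  and aerial times default to $t_c = 0.2$ s, $t_a = 0.12$ s, typical of
  running near 3 m s⁻¹; tests at faster speeds shorten them accordingly.
  Step-to-step variability within a trial has no published anchor, so noise
  levels are exposed as configuration with a zero default rather than baked
  in as constants.

What the generator does **not** emulate: anterior–posterior and mediolateral
force components, soft-tissue impact transients, marker dropout and
occlusion, belt-speed fluctuation, or within-trial fatigue drift of the gait
itself. Passing tests therefore certify the event logic, the metric algebra
and the statistics — not robustness to every artefact of real recordings.

`rsp_study_design()` reproduces the benchmark study's repeated-measures
design exactly: 10 subjects × (9 model-stiffness cells at recommended height
plus ±2 cm height cells for a subset), speeds 3–7 m s⁻¹, with the
documented per-subject deviations — individual height changes of 0.8–1.8 cm
where a full 2 cm was not possible, subjects missing the fastest trials, and
four saturated trials — yielding 704 analysable trials.
`simulate_trial_table()` lays a linear predictor with known coefficients, a
subject random intercept and residual noise over that design.

## The mixed models

Each of six responses (affected-leg $L_c$, $F_{avg}$, $f_{step}$ and their
symmetry indices) is modelled with fixed effects for RSP model, stiffness
category, height (cm relative to recommended, signed, non-integer allowed),
speed (m s⁻¹, uncentred), and the interaction of each of the first three
with speed, plus a subject random intercept, fitted by REML with
`lme4::lmer()`. Treatment coding uses Catapult and the −1 stiffness category
as references; speed is left uncentred because the published intercepts are
only consistent with a speed-zero reference point.

Confidence intervals are Wald intervals on a t distribution. Degrees of
freedom are the residual $n - p$ by default, with the Satterthwaite
approximation (via `lmerTest`) available as an option; with ~700 trials the
two differ materially only for the between-subject terms. Exact p-value
reproduction across df conventions is not a goal — estimates and standard
errors are. Singular (boundary) variance estimates are flagged in the result
rather than rejected: with 10 subjects and strong fixed effects a zero
subject-variance estimate is a legitimate outcome, and the fixed effects
then coincide with ordinary least squares (a property the tests exploit).
α = 0.05 with no multiple-testing correction, matching the original
analysis; significance markers are annotations only.

Verification of the statistics stage is two-route: simulated tables with
known coefficients are recovered (95% CI coverage ≥ 90% over 200 replicates
at the study design with subject s.d. = residual s.d. = 0.02), and balanced
designs without subject effects must match `lm()` to 10⁻⁶. One caveat
discovered while building the harness: a "mean absolute bias < 10% of
truth" criterion is meaningless for coefficients whose true value is far
below the design's sampling error (e.g. an interaction of 0.00036 m per
m s⁻¹ against a standard error of 0.0025) — for those terms the harness
checks that the *signed* bias is within Monte-Carlo error of zero instead.

## Numerical choices and conventions

* 1-based sample indices; stance intervals half-open `[touchdown, takeoff)`;
  threshold comparison ≥ on entry, < on exit — one deterministic convention.
* Seconds, newtons, metres and Hz throughout; g = 9.81 m s⁻² (configurable).
* The analysis window is the last 16 labelled steps of a trial
  (configurable to all steps), with at least 4 usable steps per leg.
* Analysis tables accept a user-supplied column mapping, and category labels
  are normalised on ingestion (typographic minus "−1" → "-1", case variants
  of "Rec"), because published tables use typographic glyphs.
* All randomness flows through explicit integer seeds; identical seeds give
  byte-identical trials and tables.

## Problem sizes used in the checks

The test-suite and the acceptance script run entirely from synthetic or
printed inputs: single trials of 16 steps at 3–7 m s⁻¹ for the signal-chain
properties, the 704-trial design for single fits, 200 replicate tables for
the coverage Monte Carlo, and a 1350-trial balanced factorial for the OLS
equivalence. The deposited per-trial table of the original study is not
redistributable here; `reproduce_study()` runs the per-speed summaries, all
six fits and the comparison against the published coefficient values for
any table laid out in (or mapped to) the canonical columns.

## Known limitations

* `L_c = belt_speed * t_c` is a surrogate, exact only at constant belt speed.
* Leg labelling needs markers or trust in strict alternation; there is no
  gap-filling of marker dropouts beyond the `unknown` fallback.
* The drift model is piecewise-linear between aerial anchors; drift with
  appreciable curvature *within* a single stance is not corrected.
* Random intercepts only — no random slopes, no Bayesian variants, and no
  stiffness-in-kN m⁻¹ analysis (that requires an external stiffness model).
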