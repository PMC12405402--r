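---
title: "Anonymizing time-continuous physiological data: models, metrics and attacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anonymizing time-continuous physiological data: models, metrics and attacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcanon)
```

## The problem

Physiological signals recorded in clinical settings — ECG, blood pressure,
oxygen saturation — are *time-continuous*: the generating process evolves
smoothly, and the clinical value of the record lies in its spatio-temporal
shape (wave amplitudes, intervals between deflections, sampling
character). Classical anonymization operators (generalization,
suppression, masking, swapping, perturbation) were designed for tabular
attributes and interact badly with this structure: some destroy the
ability to interpolate at all, some reorder samples, and all trade
clinical utility for privacy in ways that need measuring rather than
guessing. At the same time, the shape itself is identifying — a pacemaker
spike, a characteristic RR interval or a rare sequence of morphological
anomalies can link records back to a person even after direct identifiers
are removed.

`tcanon` makes this tension executable. It provides (i) a validated data
model with the two properties that matter — *continuity* and *sample
order* — as testable predicates; (ii) reference implementations of the
classical mechanism classes plus a pointwise ε-DP Laplace mechanism;
(iii) curve-level utility metrics; (iv) concrete linkage attacks and a
Monte-Carlo privacy estimator; and (v) a synthetic ECG/vitals generator
with exact ground truth that feeds every test in the package.

## Data model and continuity

A record is a strictly time-ordered sequence of `(t, v)` samples on a
declared channel domain. Continuity of sampled data cannot be checked
directly against the ε,δ criterion for continuous functions, so the
package operationalizes it as three testable conditions
(`check_continuity()`): the sampling rate is high enough (no gap above
`max_gap`), an interpolate exists between all samples, and the
interpolate introduces no jumps (no duplicate timestamps with differing
values, no per-step change above `max_jump`). Two interpolates ship with
the package: sample-and-hold, which necessarily creates a jump at every
value change and therefore disqualifies any non-constant record, and
chord (linear) interpolation, which is jump-free. The published form of
the linear interpolate is a self-referential average of neighbouring
interpolate values; the only non-circular reading consistent with
"linear interpolation between two samples" is the chord between the
bracketing stored samples, which is what `tc_interpolate(mode =
"linear")` computes.

Defaults: `max_gap` is 3x the median step (a purely structural choice: an
isolated dropped sample still passes, a real hole does not); `max_jump`
is channel-specific because jump plausibility is application-specific —
0.5 mV per step for ECG, scaled analogues for the other monitor
channels. Neither number is claimed to be canonical; both are config.

## The synthetic generator as a stated world

Each cardiac cycle is laid out as P, PQ, Q, R, S, ST, T, U, TP with
signed raised-cosine lobes on a zero baseline (the PQ segment is the
baseline reference). Raised cosines were chosen over Gaussians because
their support is compact, so annotated onsets and offsets are *exact*,
making the generator its own oracle for the detector and attack tests.
Two morphological constants are anchored in the clinical literature: the
P wave lasts 0.1 s, and the U wave (when present) has 25% of the T-wave
amplitude. The remaining defaults (P 0.15, Q −0.10, R 1.00, S −0.15,
T 0.30 mV; 60 bpm; 500 Hz) are package defaults in the usual clinical
ranges. Beat-to-beat variability is multiplicative Gaussian jitter on the
TP interval only (default 2%), so wave durations remain exact under
jitter. The pacemaker spike defaults to 0.3 mV and 8 ms — the literature
this package draws on names the feature but not its magnitude.

What the generator does *not* emulate: electrode noise, baseline wander,
respiration coupling, ectopic beats, multi-lead geometry, or any
dynamical heart model. A green test therefore establishes that an
algorithm behaves correctly on cleanly structured morphology, not that it
is robust to real-world ECG artefacts.

Multi-person databases (`generate_database()`) give each person a stable
heart rate, a stable U-wave flag and a stable injected event signature
across their records; with `distinct_rr = TRUE` the rates are spread
evenly so that inter-beat timing alone identifies every person. That
fixture is deliberately favourable to the attacker: it provides the
cleanest possible demonstration of timing linkage and a sharp baseline
against which anonymization should degrade it.

## Mechanisms

All mechanisms are index-stable except suppression/masking, which report
removals. Bounded perturbation uses truncated Laplace noise via rejection
sampling rather than clamping, so the in-bound density keeps the Laplace
shape; the caveat is that truncation changes formal ε accounting, and the
package reports nominal ε only. `order_safe_time_bound()` returns
`min(Δt)/2` (minus a machine tolerance): opposite-sign shifts of two
neighbours bounded by `b` close a gap of at most `2b`, so `b < min(Δt)/2`
provably preserves order — the property harness confirms it empirically
over seeds.

Time generalization emits one representative per non-overlapping bin
(midpoint, mean value). With a single bin the output degenerates to one
sample — returned unvalidated on purpose, as the information-loss
extreme of the mechanism rather than an error. Generalization to a
nominal diagnosis label is included purely as the executable
counterexample to continuity preservation: a nominal domain has no
subtraction or order, so no interpolate exists and `check_continuity()`
reports not-continuous by construction. The bundled labeler (MI iff an
ST-elevation event is present, CA iff jitter exceeds 10%, else Healthy)
exists to make that counterexample runnable, not as a clinical claim.

## The property harness

`theorem_matrix()` turns the mechanism-class safety statements into an
empirical verification matrix: "guaranteed" rows must show zero
violations over the trial budget, "not guaranteed" rows must produce at
least one constructed witness. Two calibration choices deserve note.
First, the harness's continuity check runs with `max_jump = Inf`: the
theoretical claim is that perturbation is an endomorphism of the domain
(an interpolate still exists), not that noisy data looks clinically
plausible — with a finite jump threshold, large bounded value noise
would "falsify" a true theorem. Second, step-characteristic preservation
is judged as mean Δt within 5%; the underlying requirement is stated
only qualitatively, so the 5% is an artifact choice, exposed as
`step_tol`.

## Utility metrics

The discrete Fréchet distance is the workhorse curve distance (dynamic
program in C++), with Hausdorff and STED as baselines. Axes carry
different units, so a `standardize` option rescales both axes by pooled
standard deviations; it is *off* by default because raw data units keep
the distance interpretable (a pure 0.2 mV offset measures exactly
0.2) and because the algebraic identities the test suite asserts hold in
raw units. This inverts a natural default — standardizing always — in
favour of interpretability; callers comparing curves of wildly different
scales should turn it on.

The composite curve difference is the literal composition
`F(G(E(c1, c2, τ, ω), c2), c2)`. `E` (mismatch correction) is described
only informally in the source literature; it is operationalized here as:
resample both curves to a shared grid, score sliding windows of width ≤ ω
by mean |Δv|, greedily excise the worst non-overlapping windows while the
total stays within τ of the common duration, and bridge the excised spans
linearly in both curves. `G` searches a restricted transform family
(time shift, value offset, value scale) by grid search plus local
refinement; rotation is excluded because rotating a time series mixes
axes with different units, and the full infimum over isometric embeddings
(the Gromov–Hausdorff idea) is not computable. `E` is applied to both
curves but `G` only to the first argument — as written in the
definition, implemented literally.

The Fourier curve norm resamples (linear interpolate, default 4x the
nominal rate) onto an equidistant grid, takes the unnormalized forward
DFT and applies a p-norm (p ≥ 2); for p = 2, Parseval pins the value to
`sqrt(n) * ||v||_2`, asserted to 1e-9 relative in the tests. The
time-continuous MRE divides each pair's curve difference by the raw
curve's norm and normalizes by the total difference mass `N = Σ d`. Two
degenerate corners are handled explicitly: `N = 0` (all pairs identical)
returns 0 with a flag, since the definition would divide by zero; and a
zero-norm raw curve is an error. The normalization also has a
documented algebraic quirk, implemented literally: a single pair with
`d > 0` yields exactly `1/|c1|` regardless of `d`.

Decision utility is the fraction of discrete decisions unchanged by
anonymization (a decision on raw data is correct by definition), and the
width information loss is the mean generalization-interval width over the
domain width — zero on raw data.

## Attacks and the privacy ratio

The event detector is rule-based and anchored on detected R peaks (local
maxima above 0.3x the record maximum with a 0.3 s refractory window; the
0.3 fraction keeps an injected shallow R wave of 0.4 mV detectable).
The infarction rule follows the clinical criterion: elevation of at
least 0.1 mV sustained for at least 80 ms, measured as the contiguous
elevated run starting at the J point (located where the S-wave recovery
slope flattens near baseline). The remaining thresholds are relative to
per-record R amplitude and are artifact defaults tuned to the
generator's injection magnitudes — the feasibility question for this
attack family is open, and these defaults are a working instantiation,
not a claim.

Timing linkage compares the median inter-R interval of a reference
record with every database record inside a tolerance band ε_Δ (the
published set definition uses an equality with an error term; the
symmetric band is its natural reading). The median was chosen over the
mean for robustness to single ectopic cycles. Verification by U-wave
presence narrows candidates to the verified subset. Signature linkage
builds the ordered sequence of detected event types per record and links
records whose signatures are within an edit-distance threshold.

The privacy ratio `P = Pr(S∖i, i) / Pr(S, i)` requires decision
probabilities that the source formalism leaves application-specific.
The estimator runs an explicit decision procedure (default: membership
inference via timing linkage against a raw reference) over repeated
anonymize-and-attack trials on `S` and on `S∖i`, and reports the ratio
of success frequencies with Wilson standard errors (chosen so the error
stays positive at frequency 0 or 1). Removing an individual cannot add
information about them, so the ratio must not exceed 1 beyond noise —
the acceptance suite asserts `ratio ≤ 1 + 3·SE` for the shipped attacks.

## Numerical choices and degenerate inputs

* Duplicate timestamps with equal values are collapsed with a warning at
  record validation; with differing values they are rejected (as a
  record) or reported as a `no_jumps` violation (as a raw sequence).
* Step-time classification compares every Δt to the first one with a
  relative tolerance (default 1e-6), treating floating-point grids as
  exact.
* Stored sample times return stored values exactly under both
  interpolates, bypassing interpolation round-off.
* All stochastic operations take an explicit seed and restore the RNG
  state (`withr::with_seed`); derived seeds keep parallel streams
  deterministic and below 2^31.
* Empty alignment families are the identity; a correction budget τ = 0
  disables excision regardless of mismatch.

## Limitations

The generator's realism bounds what the green matrix proves (see above).
The DP mechanism is pointwise and ignores temporal correlation — known
to leak more than its nominal ε suggests on correlated series; it is
included as the reference point the rest of the toolkit measures
against, not as a recommended mechanism. WFDB support is a minimal
format-16 single-signal reader/writer; EDF import is not provided
because no reader exists in the supported dependency stack. Attack
thresholds are tuned to the synthetic world; real ECG would need
re-tuning and a noise-robust detector.
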