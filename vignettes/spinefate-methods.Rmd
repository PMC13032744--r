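---
title: "Methods: event extraction and spine-fate analysis in spinefate"
author: "spinefate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event extraction and spine-fate analysis in spinefate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Two-photon imaging of GCaMP-expressing dendritic spines in organotypic
hippocampal slice cultures yields, per spine, short (60 s, 20 Hz)
fluorescence recordings before and after a treatment, plus a 24-h follow-up
session in which some spines have disappeared. The scientific questions
attached to such data are longitudinal: does the treatment change synaptic
event rates, which spines are eliminated, does astrocyte contact protect
them, and do eliminated spines expose more phosphatidylserine (an "eat-me"
signal, read out with the PsVue probe)?

`spinefate` implements the full chain from raw per-ROI intensity traces to
nested-design inference, together with a synthetic-data generator that
reproduces the statistical structure of such a study with known ground
truth, so that every stage can be validated by parameter recovery rather
than by eyeballing.

# Trace conditioning

The chain is fixed and recorded in every output object:
baseline subtraction, Okada denoising, dF/F conversion, z-scoring.

**Baseline.** A 10th-order polynomial is fit to each 1200-frame trace by
least squares and subtracted. The fit uses `stats::poly()` (orthogonal
polynomials on a centred abscissa): a raw Vandermonde design at order 10 and
n = 1200 is numerically singular. Order 10 over 60 s tracks slow drift and
bleaching without following individual transients; a lone transient on an
otherwise flat trace loses roughly 8% of its amplitude into the baseline,
which is why amplitude round-trip checks in the test-suite use a constant
baseline.

**Okada filter.** Any interior sample that is a strict single-point local
extremum is replaced by the mean of its two neighbours; the pass is repeated
`okada_iterations` times (4 in the main pipeline, 1 in the GECI-comparison
preset). Updates within a pass are synchronous (all extrema located on the
pre-pass array, then replaced at once), so the result is independent of scan
order; a sequential in-place variant is available for sensitivity checks.
Two properties matter and are tested: the filter never leaves the range of
its input, and repeated application contracts — the per-pass change decays
by orders of magnitude. It does *not* reach a literal fixed point in
finitely many passes on continuous data: each mean-replacement can create a
smaller extremum next door, so convergence is asymptotic.

**dF/F.** The pipeline divides the (denoised) detrended trace pointwise by
the fitted polynomial baseline — the only baseline estimate the chain
constructs — with the divisor floored at `0.01 * median(baseline)` so a
near-zero baseline sample cannot blow up a single frame. dF/F is therefore
invariant to rescaling the raw intensities.

**z-score.** Population (n-denominator) standard deviation of the full
trace; the convention is stored in the output metadata. z-scoring whole
traces has one consequence worth stating: the divisor includes signal
variance, so on an event-rich trace a unitary transient spans fewer z-units
than on a quiet one. The event-detection threshold accounts for this (next
section).

# Event detection

Events are recovered by sparse non-negative deconvolution under an AR(1)
decay model: calcium `c_t = g c_{t-1} + s_t` with impulses `s_t >= 0`,
minimising `||z - c||^2`, with impulses below an amplitude threshold
suppressed and their mass re-absorbed into the preceding decay. The solver
is the online pool-merging scheme: each new frame opens a pool; while the
newest pool's implied spike (its fitted height minus the decayed height of
its predecessor) fails the threshold, the two pools merge, with pool height
refit by decay-weighted least squares.

Three design points, each forced by an identifiable failure mode:

**Noise level and threshold.** The acceptance threshold is
`s_min * sn` with `s_min = 2.5`: events must exceed 2.5 noise standard
deviations. `sn` is estimated from the high-frequency half of the
periodogram — but on the trace *before* Okada filtering, where measurement
noise is still white. Estimating it after filtering is inconsistent: the
filter removes exactly the high-frequency power the estimator measures,
which collapses the threshold and floods the output with false positives.
`process_trace()` therefore measures the noise on the unfiltered dF/F trace
and expresses it in units of the final z-trace (`sn_z`); the pipeline
passes that value down. The division by the trace's own standard deviation
has a useful self-calibrating effect: on an event-free trace the z-scaling
is small, so the threshold in z-units rises and noise crossings are
rejected; on an event-rich trace the threshold falls toward the noise
floor. Standalone use of `deconvolve_oasis()` on an externally z-scored
trace estimates `sn` from that trace's own periodogram.

**The decay coefficient g.** The initial estimate is the lag-1/lag-2
autocovariance ratio (noise-free in expectation for AR(1)-plus-white-noise),
guarded: if the lag-1 autocovariance is not significantly positive the trace
carries no usable correlation and 0 is returned. The estimate is then
refined from the data — least squares on the decay after the largest
isolated supra-threshold peaks of the trace itself, run twice so the
isolation window reflects the refined decay constant. Both the estimate and
the refinement are constrained to the physiological indicator range
(decay time constants 0.2–2 s): a fitted decay outside what a calcium
indicator can produce means the fit latched onto filter-induced noise
correlation. This constraint is what keeps pure-noise traces silent — with
a physiological g, an isolated noise crossing has no decay-consistent tail,
so pool merging absorbs it.

**Finite rise time.** An AR(1) impulse is instantaneous, but a real
indicator transient rises over several frames (~0.18 s to peak for a
7b-like kernel at 20 Hz). Two consequences and two mechanisms: (i) greedy
backward merging never revisits a pool, so a slow rise can be absorbed into
the baseline pool without any single frame clearing the threshold even
though placing a spike there is SSE-optimal — a split-refinement pass
therefore tests every interior split of every pool (O(length) per attempt
via forward/backward recurrences) and accepts the SSE-minimising split
whose spike clears the candidate threshold, recursing on the halves;
(ii) the rise spreads mass over neighbouring frames, so candidate impulses
are admitted at half the acceptance threshold, grouped within a 0.25-s
window anchored at the group onset (about one rise-to-peak time;
anchoring, rather than chaining, keeps nearby distinct transients
separate), and a grouped event is returned only if its total mass reaches
`s_min * sn`. Frame-level impulses remain available in the fit object;
event rates count grouped events.

On noiseless AR(1) toy traces the solver provably matches exhaustive
enumeration over all feasible event placements (tested up to 20 frames
against a brute-force oracle). Under noise the greedy solution can differ
from the exact optimum — typically a one-frame shift of the onset — which
is why oracle-equivalence claims in the tests are confined to the noiseless
case. Two further known limitations: two true events closer than the 0.25-s
grouping window are reported as one, and event onsets carry ±1-frame
jitter relative to ground truth.

**Presets.** Main pipeline: 20 Hz, Okada ×4, `s_min = 2.5`.
GECI-variant comparison: 10 Hz, Okada ×1, `s_min = 1.5`; peak amplitudes
are read off the dF/F trace in a 1-s window after each detected onset.

# Bleaching

The bleaching profile is the per-frame integrated intensity normalised to
the first frame. Its model is a biexponential
`A exp(-t/tau1) + B exp(-t/tau2)` — a fast component attributed to an
immobile fluorophore fraction plus a slow steady decline — fitted by
Levenberg–Marquardt (via `minpack.lm`) with a 27-point multi-start grid over
fast/slow time constants and amplitude splits; the converged start with the
lowest SSE wins, and components are reported in canonical order
`tau1 <= tau2`. No constant offset is included by default (one is available
behind a flag). Non-convergence across all starts yields a flagged fit with
`NA` parameters rather than an error.

The bleach-rate statistic needs no model: `F0 - F60`, where `F0` averages
frames 5–10 (read as 0-based inclusive indices — the indexing origin is not
universal, so the window is configurable) and `F60` averages the last five
frames. It is exactly zero on a constant profile and lies in [0, 1] for
monotone non-increasing profiles.

# Longitudinal annotation

**Matching.** Fields from the two imaging days are aligned by a single
rigid translation: candidate shifts are all day-2-minus-day-1 centroid
differences within `max_shift_px` (plus zero), scored by summed
nearest-neighbour distance, then refined by the mean displacement of
provisional within-radius matches. Spines are assigned one-to-one, nearest
pair first, ties broken by lowest ROI id — deterministic by construction. A
day-1 spine survives iff its assigned partner lies within the day-1 spine
radius after alignment, so `survived + lost = day-1 count` holds exactly.
Rotation is not modelled (re-imaging of an annotated field is
translation-dominant); the matching is translation-equivariant.

**Astrocyte proximity.** A spine is proximal if any astrocyte-positive
pixel lies within twice the spine radius of its centroid, boundary
inclusive — the ROI extent plus one further spine radius, covering both
signal superposition and near-contact. The radius multiple is exposed
(`reach_radii`) because the alternative reading (one radius measured from
the ROI boundary vs from the centroid) differs in edge cases. The
implementation scans only a window around the centroid; the test suite
checks it against an exhaustive whole-mask pixel-distance oracle and for
monotonicity under mask dilation.

**PsVue.** Intensities are measured on the background-subtracted sum
projection of the stack, averaged over the ROI disc (or the whole field).
Relative changes use `(POST - PRE)/PRE`; a spine with `PRE = 0` and
`POST > 0` yields the infinity sentinel, which group summaries exclude and
count rather than silently average.

# Nested-design statistics

Spines within a dendrite, dendrites within a slice, and slices within an
animal are not independent. Group summaries therefore average spines within
animal first and then average animal means without weighting by spine
count. Inference uses a hierarchical permutation test: the statistic is the
difference of animal-averaged group means, and the null distribution comes
from permuting treatment labels at the exchangeable-unit level — slices
within animal by default (treatments are assigned at the slice level, with
every animal receiving all arms), or whole animals. A design check refuses
a factor that varies within an exchange unit, since permuting such labels
would not respect exchangeability. P-values use the add-one convention
`(1 + #{|perm| >= |obs|}) / (1 + n_perm)`, so they are never below
`1/(1 + n_perm)`. Calibration is verified empirically: on 1000 null
datasets with animal- and slice-level random effects (6 animals x 4 slices
x 10 spines — a deliberately small size chosen so the whole calibration
runs in about a minute), the rejection rate at nominal 0.05 falls within
[0.03, 0.07].

The Tukey ladder-of-powers transform used before spine-level model
summaries shifts the sample to positivity if needed and picks the exponent
on the grid −2 to 2 (step 0.25) maximising the Shapiro–Wilk W statistic;
`x^lambda` for positive lambda, `log x` at zero, `-x^lambda` for negative
lambda, so the map is increasing and rank-preserving for every grid value.

Mass-to-molar conversion for ELISA results: `pg/mL / (g/mol)` is
`pmol/mL`; multiplying by 1000 mL/L gives pM. Defaults use average isotopic
masses 4329.8 g/mol (amyloid-beta 1-40) and 4514.1 g/mol (amyloid-beta
1-42).

# The synthetic-data generator

`sim_config()` bundles every generative parameter; `simulate_spine_population()`
draws the spine table and ground truth; `simulate_recordings()` renders the
fluorescence traces. The generator emulates:

* **Hierarchy and design.** 10 animals x 4 slices x 1 dendrite x 15 spines
  by default; the four treatment arms (amyloid-positive or depleted brain
  extract, crossed with the glutamate-transport blocker TBOA or vehicle)
  are assigned within each animal, one arm per slice, mirroring the
  within-animal control design.
* **Event trains.** Homogeneous Poisson per spine; the per-spine baseline
  rate is lognormal around 0.1 Hz (log-sd 0.4). Published per-spine rates
  for this preparation are not available; 0.05–0.2 Hz is the plausible
  range for spontaneous synaptic calcium events, and 0.1 Hz was fixed once
  as the median.
* **Treatment effects.** The amyloid arms double the event rate after
  treatment (`abeta_rate_multiplier = 2`); spines headed for elimination
  hyperactivate by a further factor 1.5 (`lost_rate_multiplier`),
  reproducing the observation that to-be-lost spines show the larger
  activity increase. Survivors keep their elevated rate at 24 h; lost
  spines simply have no 24-h recording.
* **Transients.** Difference-of-exponentials kernels with unit-normalised
  peak scaled by `amplitude_dff`; presets 6s-like (1.0, 0.18/1.0 s),
  7b-like (1.5, 0.07/0.7 s — the brighter variant), 8s-like (1.0,
  0.02/0.2 s).
* **Nuisance structure.** Order-4 random polynomial drift (8% of F0),
  multiplicative biexponential bleaching applied to baseline and transients
  alike (fluorophore-level photophysics), additive Gaussian noise (5% of
  F0).
* **Survival.** Logistic model on treatment, proximity, their interaction
  and a TBOA x amyloid x proximity term. Default coefficients
  (2.197, −1.792, 0, 1.329, −1.329) encode: control survival 0.90,
  amyloid-challenged non-proximal 0.60, amyloid-challenged proximal 0.85,
  and full abolition of the astrocyte protection under TBOA.
* **PsVue.** Fractional intensity change with mean
  `0.05 + abeta*(0.25 + 0.45*lost + 0.25*nonproximal)` and sd 0.15: larger
  phosphatidylserine exposure on challenged spines, largest on those about
  to be lost and on those without astrocyte contact.
* **Proximity stacks.** Two-channel synthetic fields with non-overlapping
  spine discs and a blob-built astrocyte mask at a target coverage;
  ground-truth labels are computed by an exhaustive pixel scan at
  generation time.

What the generator does **not** emulate: photon shot noise scaling with
intensity, detector artefacts, motion or focus drift requiring registration,
a realistic point-spread function, astrocyte morphology beyond coverage
fraction, and any coupling between activity and survival beyond the
configured effects. Passing recovery tests on these simulations therefore
demonstrates that the pipeline is a consistent estimator of its own forward
model under realistic rates, SNR and nesting — not that it is robust to
every artefact of real two-photon data.

# Problem sizes and numerical choices

The validation suite runs at sizes chosen to finish in a few minutes while
keeping binomial/Poisson standard errors meaningful: 2000 seeds for
dispersion checks, 200 traces for rate recovery and false positives, 500
spines for the proximity oracle, the full 10-animal default study for
directional recovery, and 1000 null datasets (199 permutations each) for
test calibration. Tolerances follow the quantity: exact identities at
1e-9–1e-12, recovery of continuous parameters at 5%, stochastic recoveries
at 3 standard errors or the stated acceptance band. All randomness flows
through explicit seeds; identical configuration and seed reproduce
byte-identical tables.

# Known limitations

* The AR(1) model has no rise component; onset times carry ±1 frame jitter
  and events closer than the grouping window merge. An AR(2) kernel would
  remove both at the cost of a substantially harder constrained solver.
* The greedy pooled solution is exact only in the noiseless limit.
* Mixed-effects REML models are deliberately out of the inferential
  surface; the permutation test is the package's own inference, and
  `lme4`-style models can be fit externally on the exported tables.
* Real-image registration (rotation, non-rigid) is not implemented; the
  matcher assumes translation-dominant re-alignment of an annotated field.
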