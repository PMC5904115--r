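---
title: "Proscriptive integration: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proscriptive integration: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(proscribe)
```

This vignette is the package's account of the science it implements: the
population-code model of slant-cue integration by suppression, the choices we
made where the architecture left freedom, the calibrations behind the default
parameters, and what the simulations do and do not establish.

## The model and its assumptions

Surface slant is signalled by two cues — binocular disparity and texture
perspective — each encoded by a bank of slant-tuned units with von Mises
receptive fields over the ±90° slant range. The factor 2 in
`exp(k[cos 2(θ − θ_pref) − 1])` maps that range onto one cycle, and the
response is normalised so the peak rate equals `A · rate_scale`: intensity
`A` is then interpretable, and single-cue output peaks scale exactly as √A
after the combination stage. Every disparity–texture pairing drives one
combination unit via the sublinear sum `E = √(f_δ + f_χ)`; the square root
stands in for synaptic depression or normalization and is what makes the
congruent-cue combination land exactly on the quadratic-summation ceiling
(point for point, the congruent profile is √2 times the single-cue profile).

The readout is where proscription lives. Output unit *i* pools combination
units along the anti-diagonal through its own preference with weights
`cos 4j − c` for offsets up to a quarter cycle. A combination unit whose two
preferences disagree by more than ~45° therefore votes *against* the
intermediate slant: evidence for a large cue conflict suppresses the fused
interpretation and, because the stronger cue's energy lands (with negative
weight) on the weaker cue's preferred slant, also extinguishes the weaker
cue's candidate percept. This single mechanism produces near-optimal fusion
at small conflicts and reversion to the more reliable cue at large ones.
The tonic offset `c = 0.05` models inhibitory dominance of sensory cortex.

Assumptions worth stating explicitly: independent Poisson spiking across
units and trials; a purely feedforward readout (no recurrence except in the
rivalry extension); one-dimensional slant (no tilt); and cue intensity as the
only reliability channel.

## Decoding: reliability versus sensitivity

Raw output is rectified at zero and treated as a likelihood function over
slant. Three summaries are reported per trial:

* the grid argmax and a parabolically interpolated peak position (the slant
  estimate; interpolation prevents the 5° grid from quantising estimate
  statistics);
* the **reliability proxy**: the height of the peak. For single cues this
  scales as √A and it obeys quadratic summation exactly in the noise-free
  limit, so it anchors the intensity calibration;
* the **sensitivity proxy**: peak height divided by the standard deviation of
  the rectified profile (height relative to spread). This is the quantity a
  discrimination experiment measures. The distinction matters: suppressive
  weights can only *subtract* activity, so every raw peak decreases
  monotonically as suppression grows — a peak-height-only reading of
  sensitivity would make suppression uniformly harmful. What suppression
  actually buys is a *sharper* likelihood: it removes the skirt of
  unsuppressed conflicting evidence that otherwise broadens the profile for
  incongruent stimuli. Height-over-spread captures exactly that, leaves
  single/congruent profiles (whose shape the negative weights barely touch)
  nearly invariant, and preserves the √A single-cue scaling because the
  noise-free profile width is intensity-invariant.

Degenerate trials (profile rectified to zero everywhere) are errors at the
single-decode level and are counted and propagated in condition summaries.
Profiles whose secondary local maximum exceeds 70% of the global peak are
flagged bimodal (`bimodal_frac`, exposed in `model_config()`).

## Numerical and calibration choices

**Circular readout.** Out-of-range offsets are wrapped rather than zeroed.
Under the factor-2 angle convention every tuning curve and weight profile is
exactly π-periodic, so the ±90° endpoints alias to the same physical unit.
Zero-padding instead creates large rim artefacts — spurious output bumps near
±65–70° that capture the argmax for conflicts above ~25° — which destroy the
reversion behaviour the model exists to produce. Physical slant is of course
not circular; estimates decoded in the outer two grid points are flagged.

**Tuning concentration (k = 40).** The architecture states both a nominal
concentration and a ~10° tuning bandwidth, and the two are inconsistent under
any reading of the (garbled) tuning equation: a concentration of 2 gives a
~40° half-width at which the suppression phenomenology collapses (the
conflicting cues' profiles merge and the suppressive gain correlates
*negatively* with incongruent sensitivity). We therefore treat the stated
bandwidth as the operative parameter. Within the range the two common
bandwidth conventions span (half-width 10° → k ≈ 11.5; full width 10° →
k ≈ 45.6) we fixed k = 40 (FWHM ≈ 10.7°) once: at substantially smaller k the
single/congruent conditions inherit a spurious dependence on the suppressive
gain through their profile skirts, and at k ≈ 45 the tuning becomes so narrow
relative to the 5° preference grid that the congruent profile develops a
square-root mixing artefact (a double peak around the true slant) inflating
the quadratic-sum benefit by ~5–7%.

**Rates and trials.** `rate_scale = 100` peak spikes per interval per unit
intensity and `n_trials = 100` Poisson repetitions per condition are the
default study conditions; the intensity calibration (A = 8 versus 1 giving a
~3:1 sensitivity ratio, A = 4 giving ~2:1 with the same constant) is
scale-invariant by construction, so these choices trade Monte-Carlo noise
against runtime only.

**Stimulus geometry.** Single and congruent conditions sit at 30°; the
incongruent condition pairs disparity at 20° with texture at 50° (a 30°
conflict with the texture cue engineered to twice the sensitivity via
A = 4), matching the behavioural design the simulations accompany. Conflict
sweeps centre the cue pair on 0° and avoid stimuli near the range ends.

## The suppression sweep and a known discrepancy

`suppression_sweep()` draws β ~ N(0.75, 0.1) (clipped to [0, 1]; clipping is
logged in the returned table implicitly via the stored values) and jitters
every intensity with SD 0.1, then measures per-condition sensitivity and the
reliable-cue weight `1 − |bias| / |S_reliable − S_unreliable|`. At the
default calibration the suppressive gain strongly predicts incongruent-cue
sensitivity, barely predicts single/congruent sensitivity, and the mean
reliable-cue weight is ≈ 0.86.

One reported relationship we could not reproduce under any reading of the
printed architecture: a strong *positive* correlation between the suppressive
gain and the reliable-cue weight. In this implementation the gradient of the
suppressive field around the decoded peak points *away* from the reliable
cue (the conflicting cue's energy, seen through the negative flank of the
readout, cuts the near side of the peak harder than the far side), so the
estimate drifts slightly toward fusion as β grows and the β–weight
correlation comes out negative, at an unchanged mean weight. We examined
argmax, interpolated-argmax, centroid, thresholded-centroid and
height-weighted multi-peak position readouts; none reverses the sign. The
corresponding acceptance expectation is left failing rather than redefining
the weight to manufacture agreement.

## The stimulation (tDCS-analogue) protocol

Nominally single-cue stimuli are modelled as containing a *latent*
frontoparallel residual of the other modality, whose intensity is fitted by
bounded one-dimensional search (grid bracket, then local refinement — the
objective is not unimodal over wide latent ranges) so that the model's
congruent:single sensitivity ratios match the observed ones; the same latent
intensity serves both single-cue conditions. Stimulation is then two free
factors `p_pos, p_neg ∈ [0, 1]` on the positive and negative readout weights,
fitted by a 41×41 grid search with quasi-Newton refinement on the noise-free
forward model — **using single- and congruent-cue data only** — and frozen
before predicting the incongruent condition. Sensitivities are expressed in
sham-calibrated units (sham single-disparity = 1). An identity perturbation
reproduces sham within Monte-Carlo error; a cathodal-like dataset (weakened
suppressive weights) yields fitted parameters that reduce congruent *and*
incongruent sensitivity while leaving the single-cue conditions within
Monte-Carlo tolerance of sham, which is the generalisation test the protocol
exists for.

## Rivalry dynamics

The output layer is given mutual inhibition (γ = 7) through a
half-wave-rectified cosine kernel, slow shunting adaptation (α = 7,
τ_A = 125) and additive noise (σ = 0.005), integrated by Euler–Maruyama with
dt = 0.05·τ. Design notes:

* The printed lateral kernel is implemented as `[−cos 2(θ_j − θ_i)]₊`:
  rectified, maximal between maximally different slants, zero between
  neighbours (the printed argument appears to drop a factor of 2 and a sign).
* The lateral sum is scaled by the preference-grid spacing (a Riemann sum),
  making the dynamical regime independent of `n_units`. Without this, the
  hill of co-active units multiplies the effective inhibition several-fold at
  γ = 7 and the shunting adaptation — whose single-unit fixed point is always
  stable — can never release the suppressed percept: no sigmoid setting
  produces alternation.
* The Naka–Rushton nonlinearity is unspecified in the source architecture; we
  use exponent 2 with half-saturation at 50% of the normalised single-cue
  drive peak. The calibration criterion was qualitative: alternation at the
  stated γ, α, τ_A for equal-reliability conflict, winner-take-all without
  adaptation, coexistence without inhibition, and no rivalry for strongly
  unequal reliabilities. All four regimes hold at the defaults.
* The drive is the rectified noise-free output profile normalised by the
  single-cue peak; the equal-cue rivalry stimulus used in examples and tests
  places the cues at ±30°.
* The symmetric noise-free state is dynamically unstable; rounding noise
  breaks it on a timescale of tens of τ, which the symmetry test respects by
  using a short horizon.

Dominance is labelled when one cue-consistent unit's activity exceeds the
other's by 1.5× with a one-τ debounce; the bistability index is the
difference between the mean decoded slants of the two percepts' episodes
(zero under fusion or winner-take-all).

## Baselines

The maximum-likelihood module is the closed-form Gaussian-fusion baseline;
its bias grows linearly with conflict and never reverts. The
divisive-normalization comparator is deliberately simplified and labelled as
such: congruent-only combination units, activity divided by summed population
activity, slant read out as the population vector. We decode it by population
vector rather than argmax because the argmax of a congruent-only summed grid
trivially jumps to the taller mode at large conflict, which would mask the
averaging failure the comparator is meant to illustrate; no quantitative
conclusion rests on its numbers.

## Psychophysics

* Psychometric family: cumulative Gaussian with a lapse parameter bounded at
  0.1, fitted by maximum likelihood on per-level binomial counts; PSE at the
  50% point; j.n.d. = one SD of the underlying Gaussian (the 50→84%
  convention, exposed as `jnd_convention`); sensitivity = 1/j.n.d. Fits that
  fail a likelihood-ratio test against the intercept-only model error out as
  degenerate; slope parameters at the lower bound (step-function data) are
  flagged, not errors.
* The 2IFC simulator draws both intervals with independent Gaussian noise, so
  the √2 in `s = σ⁻¹/√2` emerges from the task structure and the
  simulate-then-fit loop closes on the conversion formula.
* Bayes factors from t statistics use the default Cauchy (scale √2/2) prior
  on effect size, computed by numerical integration and cross-checked in the
  test suite against an independent Monte-Carlo integration.
* The bivariate outlier rule for robust correlations is the boxplot rule
  applied marginally (1.5 IQR fences per variable, union). A four-projection
  variant was tried and rejected: at n = 18 it discards up to a third of
  well-behaved correlated points and can flip the sign of a strong sample
  correlation.
* The log-3SD screen and the quadratic-sum cap are one-pass operations, as in
  the re-analysis they implement.

## The synthetic cohort

`generate_cohort()` emulates the statistical structure of a between-observer
suppression study: a latent gain trait β drives behaviour through the full
model; a noisy linear transform of β plays the role of a neurochemical
measurement (the mapping's slope and intercept are arbitrary — correlations
are scale-free); per-observer cue-intensity jitter adds trait-unrelated
variance; and 2IFC trial tables are generated from each observer's
model-derived sensitivities (calibrated so a typical disparity single-cue
sensitivity is 0.16 per degree) with test levels spanning ~0.5–3
discrimination SDs, mirroring the per-participant range calibration of real
designs. What it does *not* emulate: lapses, learning, serial dependence,
criterion drift, or any mechanistic link between the neurochemical
measurement and cortex — so recovery results validate the analysis pipeline,
not the physiological claim.

The between-observer spread of incongruent sensitivity induced by
β ~ N(0.75, 0.1) is only a few percent, so recovering it demands many trials:
the recovery tests use 12,000 trials per condition (the criterion floor is
400, at which psychometric-fit noise dominates the trait signal and recovery
is unreliable) and compare rank correlations of the latent trait with
recovered incongruent versus congruent sensitivity across 20 seeded
replicates of 18 observers.

## Problem sizes in the test suite

Unit and property tests run on the 37-unit model with 20–100 Poisson trials,
rivalry horizons of 25–1500 τ, and sweeps of 5–100 simulations; the
acceptance tests use the full study conditions (100-simulation sweep,
50·τ_A rivalry run, 20 cohort replicates). These sizes were chosen as the
smallest at which the Monte-Carlo tolerances quoted in the tests are
comfortably met.

## Limitations

One-dimensional slant only; no recalibration or readout plasticity; the
comparator is illustrative; the β–weight correlation discrepancy above;
quantitative agreement with human effect sizes (neurochemical correlations,
stimulation effect sizes, Bayes factors on behavioural contrasts) is out of
scope because it requires the human dataset — the machinery is instead
exercised on synthetic data with known ground truth.
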