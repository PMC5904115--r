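# proscribe

Robust integration of depth cues by suppression: a population-code model of
surface-slant perception from binocular disparity and texture, built around
"what not" detectors — combination units tuned to *incongruent* cue pairs
whose activity is read out with negative weights and so vetoes unlikely
interpretations of the scene.

The package is for computational and visual neuroscientists who want to
simulate and probe this proscriptive integration scheme: how it fuses
consistent cues near-optimally, reverts to the more reliable cue under large
conflict, degrades when its suppressive gain is attenuated (a GABA analogue),
responds to perturbation of its excitatory/inhibitory readout (a
direct-current-stimulation analogue), and turns cue conflict into perceptual
rivalry when a competition stage is added. The psychophysical machinery used
to evaluate such models against behaviour — two-interval forced-choice (2IFC)
simulation, psychometric fitting, robust correlation, Bayes factors — is
included, together with a synthetic-cohort generator for end-to-end
parameter-recovery studies.

## The model

Each cue (disparity δ, texture χ) drives a bank of slant-tuned units with von
Mises receptive fields,

    f_cue(θ) = A_cue · r · exp{ k [cos 2(θ − θ_pref) − 1] },

with preferences θ_pref on a 37-point grid spanning ±90°, intensity A_cue
scaling rates linearly, and k set so the tuning bandwidth (FWHM) is ≈10°.
Every pair of unimodal units converges on a combination unit that sums its
inputs sublinearly,

    E(θ_δ, θ_χ) = √( f_δ(θ_δ) + f_χ(θ_χ) ),

so most combination units are *incongruent* (θ_δ ≠ θ_χ). Output units pool
combination units along the diagonal through their own preference with a
cosine weight profile,

    F_i = Σ_j E(θ_{i−j}, θ_{i+j}) · (cos 4j − c),      |j| ≤ π/4,

where the temperature offset c = 0.05 makes units tuned to large internal
conflict suppressive: evidence for "disparity says a, texture says b" counts
*against* the intermediate interpretation. Negative activity is rectified to
zero; the peak of the profile gives the slant estimate (reliability from its
height, sensitivity from its height relative to its spread), and unimodal
responses are generated by Poisson sampling. Attenuating the negative weights
by a gain β ∈ [0, 1] weakens proscription; scaling the positive and negative
weights independently emulates excitatory/inhibitory perturbation. A
mutual-inhibition + adaptation stage on the output layer
(τ dX/dt = F − (1+A)X + noise − γ Σ S[X] [−cos 2Δθ]₊,
τ_A dA/dt = −A + α S[X]) produces perceptual rivalry for conflicting cues of
equal reliability.

Maximum-likelihood fusion (σ²-weighted averaging, σ_δχ = √(σ_δ²σ_χ²/(σ_δ²+σ_χ²)),
s = σ⁻¹/√2) and a simplified divisive-normalization comparator are provided
as baselines.

## Worked example

Decode an incongruent stimulus (disparity 20°, texture 50°, texture twice as
sensitive), then run the suppression sweep:

```r
library(proscribe)

cfg <- model_config(seed = 1)
simulate_condition(slant_stimulus(20, 50, A_delta = 1, A_chi = 4), cfg)
#>   mean_estimate_deg bias_deg rel_reliability rel_sensitivity bimodal_rate
#> 1            44.751    5.249           0.791           1.562            0
```

The estimate (44.8°) sits near the reliable texture cue: the model assigns it
a weight of `weight_from_bias(5.25, 50, 20)` = 0.825, and combined
reliability falls just below the reliable single cue, as expected at a 30°
conflict. Sweeping the suppressive gain across 100 simulated observers
(β ~ N(0.75, 0.1), intensity jitter SD 0.1):

```r
sw <- suppression_sweep(sweep_spec(n_sims = 100, seed = 1), model_config())
sw$correlations[, c("term", "n", "r", "p")]
#>                           term   n      r        p
#> 1      incongruent_sensitivity 100  0.840 9.92e-28
#> 2        congruent_sensitivity 100  0.340 5.38e-04
#> 3 single_disparity_sensitivity 100  0.254 1.07e-02
#> 4   single_texture_sensitivity 100  0.225 2.46e-02
#> 5 single_congruent_sensitivity 100  0.340 5.49e-04
#> 6          reliable_cue_weight 100 -0.928 7.37e-44
mean(sw$simulations$weight_reliable)
#> [1] 0.859
```

More suppression means markedly better incongruent-cue sensitivity
(r = 0.84) with only weak dependence for single or congruent cues, and a mean
reliable-cue weight of 0.86. `autoplot(sw)` draws the per-condition scatter;
see `?simulate_rivalry`, `?fit_tdcs`, `?generate_cohort`,
`?fit_psychometric` for the other workflows, and the methods vignette
(`vignettes/proscriptive-integration.Rmd`) for the model's assumptions,
calibrations and limitations.

A thin command-line wrapper is installed as `exec/proscribe`
(`proscribe <simulate|sweep|tdcs|rivalry|fit|cohort> --config cfg.yaml --out dir`);
every run writes a manifest (config hash, seed, output checksums) for exact
replay.

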