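# spinefate

Synaptic calcium event extraction and longitudinal spine-fate analysis for
two-photon imaging of dendritic spines in organotypic slice cultures.

When hippocampal slices are challenged with amyloid-beta-containing brain
extract, individual synapses hyperactivate, expose phosphatidylserine, and
some are eliminated within a day — unless an astrocyte process sits next to
them. Quantifying that story requires a chain of distinct computations:

* **Trace conditioning** — per-ROI fluorescence traces (60 s at 20 Hz) are
  detrended with a 10th-order polynomial baseline, denoised with the Okada
  filter (single-point extrema replaced by neighbour means), converted to
  ΔF/F against the fitted baseline, and z-scored.
* **Event detection** — sparse non-negative deconvolution under an AR(1)
  decay model, `c_t = g·c_{t−1} + s_t`, minimising `‖z − c‖²` by online
  pool merging; deconvolved events below `s_min·σ` (default 2.5 noise
  standard deviations) are suppressed and re-absorbed. Per-spine rates
  average repeat recordings.
* **Bleaching** — normalised intensity profiles fit with a biexponential
  `A·e^(−t/τ₁) + B·e^(−t/τ₂)`; the bleach-rate statistic is `F0 − F60`
  (mean of frames 5–10 minus mean of the last five).
* **Longitudinal annotation** — rigid-translation matching of spines across
  imaging days with one-to-one nearest assignment (survival ⇔ a day-2 match
  within the spine radius), astrocyte-proximity classification (astrocyte
  signal within two spine radii of the centroid), percent spine loss, and
  PsVue intensity from background-subtracted sum projections.
* **Nested statistics** — animal-first averaging, relative changes
  `ΔHz/Hz = (POST − PRE)/PRE` with an infinity sentinel for silent-then-active
  spines, a Tukey ladder-of-powers transform, hierarchical permutation tests
  that shuffle treatment labels at the slice-within-animal level, and
  pg/mL → pM conversions for ELISA results.
* **Synthetic data** — a generator producing the full study structure
  (Poisson event trains, GECI transient kernels, drift, biexponential
  bleaching, within-animal treatment arms, a logistic survival model with an
  astrocyte-protection interaction, PsVue effects) with complete ground
  truth, so every stage is validated by parameter recovery.

## Worked example

Simulate a small four-arm study, run the full pipeline, and test the
treatment effect with nesting-aware inference:

```r
library(spinefate)

cfg <- sim_config(n_animals = 4, spines_per_dendrite = 8, seed = 7)
pop <- simulate_spine_population(cfg)
rec <- simulate_recordings(pop, cfg, sessions = c("PRE", "POST"))
sp  <- analyze_spine_dataset(pop$spines, extract_event_rates(rec$traces))

animal_averages(sp, "rel_change_hz", "abeta")$groups
#>   abeta      mean n_animals n_spines n_excluded_infinite
#> 1     0 0.2378323         4       64                   0
#> 2     1 1.0391544         4       64                   0

perm <- hierarchical_permutation_test(sp[sp$tboa == 0, ], "rel_change_hz",
                                      "abeta", n_perm = 999, seed = 1)
c(observed = perm$observed, p = perm$p_value)
#> observed         p
#>    0.736     0.119
```

The amyloid-challenged arms show the configured rate increase (relative
change ≈ 1.0 versus ≈ 0.24 in controls — detection noise makes even null
spines fluctuate around a small positive change, which is why the control
mean is not zero). With only four animals the slice-level permutation test
is honest about uncertainty (p = 0.119); the default ten-animal design
detects the same effect at p < 0.01.

One spine's recording, processed and deconvolved:

```r
one <- subset(rec$traces, spine_id == sp$spine_id[1] &
                session == "PRE" & recording_idx == 1)
pt  <- process_trace(one$intensity)
p   <- deconv_params(); p$sn <- pt$sn_z
deconvolve_oasis(pt$z, p, frame_rate_hz = 20)
#> Sparse AR(1) deconvolution fit
#>   1200 frames (60.0 s at 20 Hz), g = 0.9325, sn = 0.2220, threshold = 0.555
#>   12 events (0.200 Hz); residual SS = 434.7868
```

And the ELISA conversion utility:

```r
pg_per_ml_to_pM(227.2, 4329.8, digits = 1)  # amyloid-beta 1-40
#> [1] 52.5
```

See `vignettes/spinefate-methods.Rmd` for the model details, parameter
semantics, and the design decisions behind the detector.

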