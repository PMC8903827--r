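# gazevis

Does a uniformly white sclera make gaze direction easier to read? Comparative
psychophysics answers this by asking human and chimpanzee observers to judge
where human-type eyes (white sclera, dark iris — *positive* contrast
polarity) and chimpanzee-type eyes (dark sclera, brighter iris — *negative*
polarity) are looking, while two manipulations probe the mechanism:
**polarity reversal**, which inverts the CIELAB lightness L\* of the eyeball
(L\* → 100 − L\*) with chromaticity (a\*, b\*) untouched — swapping which
species "has" the white sclera without altering the iris–sclera color
difference ΔE = √(ΔL² + Δa² + Δb²) — and **stimulus level** L1–L4, joint
size-and-brightness degradation (L1 = 400 px / 100% down to L4 = 50 px /
25%) that emulates distancing and shading.

`gazevis` is an R package for researchers designing, simulating or analysing
such experiments. It provides:

* **Stimuli** — parametric rendering of two-species eye images with aligned
  iris/sclera/eyeball ROI masks, polarity reversal, the seven-level
  width × brightness table, iris-diameter normalization (16 px standard),
  4:1 eye-region cropping, and ROI colorimetry (CIELAB means, ΔE, eye-shape
  metrics).
* **Schedules** — constraint-satisfying pseudorandom trial plans for a
  three-direction keypress task (96 trials, 8 species-alternating blocks)
  and a three-item visual-search task (48 trials, baseline/test split),
  plus the adaptive level-increment rule (above 85% in two successive
  sessions) and training-stage pass criteria.
* **Observer simulation** — a generative logistic observer with crossed
  uncorrelated random effects, guessing floor and lapse rate, producing
  trial-level correct/incorrect records.
* **Analysis** — binomial GLMMs with crossed random effects (Laplace, lme4),
  likelihood-ratio tests, interaction pruning, Bonferroni-corrected simple
  effects, Pearson dispersion checks, and nonparametric bootstrap CIs.

## Worked example

Simulate 25 participants on the polarity-crossed keypress design and run the
term-testing protocol:

```r
library(gazevis)

plan <- build_study1_exp2(seed = 1)        # 96 trials, N N R R N N R R blocks
resp <- simulate_responses(plan, observer_presets("full"),
                           n_participants = 25, seed = 2)
prune_and_test(resp, spec_study1_exp2(controls = FALSE))
#>   species:level:polarity       chisq =  12.941  df = 1  p = 0.0003215  -> retained (significant)
#> final terms: species, level, polarity, species:level, species:polarity, level:polarity, species:level:polarity
#> significant interaction: simple-effects follow-up required
```

The three-way species × level × polarity interaction the generator embeds is
detected and retained, so main effects are not interpreted; instead the
polarity effect is tested within each species × level stratum:

```r
simple_effects(resp, focal = "polarity", split_by = c("species", "level"),
               alpha = 0.05)
#>      species level     chisq df            p significant
#> 1 chimpanzee     3  5.736039  1 1.662023e-02        TRUE
#> 2 chimpanzee     4 43.662685  1 3.901401e-11        TRUE
#> 3      human     3  3.110897  1 7.777014e-02       FALSE
#> 4      human     4 94.160837  1 2.908996e-22        TRUE
```

Reversal (which whitens the chimpanzee sclera) changes accuracy most where
stimuli are most degraded (L4), in opposite directions for the two stimulus
species — the signature pattern of the white-sclera advantage. Accompany
such tables with a unit-level uncertainty summary:

```r
bootstrap_ci(resp, "participant_id", seed = 3)
#> proportion correct 0.724, 95% CI [0.690, 0.756] (2000 resamples by participant_id)
```

On the stimulus side, a rendered chimpanzee-type eye reports its colorimetry:

```r
stim <- render_eye_stimulus(geometry_preset("chimpanzee"),
                            appearance_preset("chimpanzee"))
measure_colorimetry(stim$image, stim$masks)
#> iris  mean Lab:  64.98  10.20  24.75   (area 176 px)
#> sclera mean Lab:  18.10   5.66   7.97   (area 492 px)
#> iris-sclera delta E: 50.00
#> eye opening: 44 x 20 px (ratio 2.20)
```

The iris is brighter than the sclera (negative polarity), the iris–sclera
ΔE ≈ 50 is comparable to the human preset's ≈ 52, and the eye opening is
less elongated than the human 3:1 — the three stimulus properties the design
controls.

See `vignettes/gaze-visibility-methods.Rmd` for the full account of the
model, the schedule constraints, the generative observer and the numerical
choices, and `run_pipeline()` for the orchestrated
stimuli → schedule → simulate → analyze pipeline with a hashed run manifest.

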