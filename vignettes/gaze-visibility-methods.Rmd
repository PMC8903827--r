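---
title: "Methods: stimuli, schedules, observers and mixed models in gazevis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimuli, schedules, observers and mixed models in gazevis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazevis)
```

## The scientific problem

Whether the uniformly white human sclera evolved to advertise gaze direction
is tested experimentally by asking human and chimpanzee observers to judge
the gaze direction of human-type eyes (light sclera, dark iris: positive
contrast polarity) and chimpanzee-type eyes (dark sclera, brighter iris:
negative polarity), under two manipulations:

* **Polarity reversal** — inverting the lightness of the eyeball region while
  leaving chromaticity untouched, which gives a chimpanzee eye a white sclera
  (and a human eye a dark one) *without changing the iris–sclera color
  difference*. Any performance change therefore isolates the contribution of
  the white sclera itself from that of local color contrast.
* **Stimulus level** — joint shrinking and darkening of the image (L1 the
  original, L4 an eighth the width at a quarter the brightness) emulating
  distancing and shading, the natural degradations a gaze signal must
  survive.

`gazevis` implements this experiment end to end as testable code: parametric
stimulus rendering and colorimetry, constraint-satisfying trial schedules,
a generative observer that produces trial-level correct/incorrect data, and
the binomial mixed-model analysis chain.

## Stimulus rendering and colorimetry

`render_eye_stimulus()` draws a single eye — an elliptical opening holding a
sclera field, an iris disc with a concentric pupil — on a skin-colored patch
over a 50% gray (sRGB 128) canvas, and returns pixel-aligned iris, sclera
and eyeball masks. Rendering is deterministic; all variation enters through
parameters. The presets encode the two species as their field descriptions
dictate: a human-like eye with high-lightness sclera, darker iris and a 3:1
opening (horizontally elongated), and a chimpanzee-like eye with dark sclera,
brighter iris and a 2.2:1 opening. Preset CIELAB values were chosen so the
iris–sclera color difference is comparable across species (ΔE ≈ 52 vs ≈ 50),
mirroring the empirical finding that this difference does not separate the
species — the experiment's point is that the *arrangement* (uniform
whiteness), not the local difference, carries the signal.

Geometric conventions: the iris is 16 px in diameter — the normalization
standard every stimulus is rescaled to (`normalize_by_iris()`), so eye shape
and sclera exposure are compared independently of absolute image scale.
Averted gaze displaces the iris 6 px horizontally, corresponding to an
eyeball rotation of about 20° for an eyeball radius of 6/sin 20° ≈ 17.54 px;
`gaze_shift_for_angle()` maps the 38° and 30° training eccentricities to
11 px and 9 px through the same radius, keeping the printed 6 px ↔ 20° pair
self-consistent. The sclera fills whatever the shifted iris uncovers, the
synthetic analogue of clone-stamping sclera color into the blank left by
shifting a photographed eyeball. Coordinates are 0-based, origin top-left,
with "left/right" read from the viewer's side.

Color machinery: sRGB ↔ CIELAB conversions use D65 and the 2° observer
(`grDevices::convertColor`); the test suite checks them against an
independently coded implementation of the published transfer and CIELAB
equations. `reverse_polarity()` maps L* → 100 − L* inside the eyeball mask
with (a\*, b\*) untouched and clips back to the sRGB gamut. Because the map
is an isometry in L\*, it provably conserves the Euclidean (ΔE) difference
between ROI means up to quantization — the property the suite asserts to
0.5 ΔE, with the double-reversal involution holding to 1 ΔE per pixel. An
8-bit grayscale inversion mode is available as an option flag for comparison
with editors that invert luma rather than L\*.

Two open choices were resolved as follows. *Brightness scaling* ("50%
brightness") is multiplicative on the stored sRGB channels — image-editor
semantics — because the level table originates from image-editing software;
a linear-light mode is provided (`brightness_space = "linear"`) for
photometric use. *Resampling* is exact area-averaging (box integration) with
re-quantization to 8 bits after every transform: deterministic and
alias-resistant at the 8× downscale L4 requires, where interpolating filters
shimmer. The half-level L2.5 uses the printed 42% brightness rather than the
arithmetic midpoint 41.5%.

`crop_eye_region()` reconciles two readings of the 4:1 eye-region format:
with `width = NULL` it returns the minimal 4:1 window containing the eyeball
mask (idempotent, useful for tight synthetic eyes); `width = 400` reproduces
the 400 × 100 px face-scale crop used in the visual-search task.

## Trial schedules

Three builders generate pseudorandomized, constraint-satisfying plans:

* `build_study1_exp1()` — 96 keypress trials, 8 species-alternating blocks
  of 12, levels stepping L1→L4 every three trials within a block; 32 trials
  per gaze direction; stimulus individuals balanced to 4–5 appearances
  (mean 4.8 — 48 trials per species cannot divide evenly over 10
  individuals).
* `build_study1_exp2()` — same frame with six L3 then six L4 trials per
  block and the block polarity pattern N N R R N N R R, giving 12 trials per
  species × level × polarity cell.
* `build_study2_session()` — 48 visual-search trials in 4 alternating
  blocks; at level ≥ 1.5 each block is six L1 baseline trials then six test
  trials; 16 trials per target location and exactly 4 per stimulus
  individual.

Sequential constraints (no direction/location more than twice in a row, no
stimulus individual twice running) are enforced by a sequential sampler that
draws uniformly among count-feasible symbols and restarts on dead ends, with
a hard cap of 10,000 attempts — constraints fail loudly, never silently
relax. In practice plans succeed within a handful of attempts; the property
suite validates every contract over 1000 seeds and byte-level replayability
under a fixed seed. Species-individual balance is enforced at the session
level (the design text does not constrain it within blocks), and which
species opens a session is a caller-supplied counterbalancing parameter.

The adaptive machinery mirrors the chimpanzee testing protocol:
`update_level()` raises the level by 0.5 only after target accuracy exceeds
85% (strictly) in two successive sessions at the current level, never
lowers it, and caps at L4; target accuracy counts all L1 trials plus test
trials above L1. Sessions at level ≥ 2.5 constitute the test phase.
`evaluate_training()` implements the stage-passing rule — over 90% in one
session or at least 80% in two consecutive sessions, required for each
stimulus species separately — reading "over" as strict and "80%" as
inclusive, the literal wording.

## The generative observer

`simulate_responses()` is the package's synthetic-data generator: a logistic
observer whose logit-scale linear predictor carries an intercept, a
human-stimulus effect, categorical level effects, a polarity effect and all
interactions (treatment coding, references: chimpanzee, lowest level
present, normal polarity — identical to the fitted models), plus
uncorrelated centered-normal random effects: a participant intercept,
optional participant slopes per factor, and a stimulus-individual intercept.
The success probability is

$$p = g + (1 - g - \lambda)\,\mathrm{logit}^{-1}(\eta)$$

with guessing floor $g$ (default 1/3, the three-alternative chance rate) and
lapse rate $\lambda$ (default 0). The floor belongs in the generator because
a three-alternative task cannot fall below chance; it is deliberately *not*
in the fitted model, which stays a plain binomial GLMM as in the analysis it
mirrors. Recovery tests therefore target the $g = 0$ configuration; with
$g > 0$ the fitted fixed effects are attenuated toward zero (the model
ascribes floor-induced successes to the linear predictor), which is the
honest statement of that mismatch.

The `"full"` preset encodes the qualitative result pattern: accuracy falls
with level; the human-stimulus advantage grows as stimuli degrade; and
polarity reversal — which gives the chimpanzee eye a white sclera — helps
chimpanzee stimuli and hurts human stimuli, increasingly so at higher
levels (a species × level × polarity interaction). Magnitudes are the
package's own choices for plausible psychophysics (reference-cell accuracy
≈ 0.90 at L1, falling to ≈ 0.45 for the hardest normal-polarity chimpanzee
cell), not fitted values. Moderate heterogeneity defaults (participant SD
0.5, slope SDs 0.3, stimulus SD 0.3 on the logit scale) give
participant-level accuracy spreads of roughly ±10 points, typical of trained
observers. The generator does not emulate image-computable vision (no link
from pixel contrast to accuracy), serial dependencies, learning or fatigue
within sessions, or reaction times — so passing tests certify the
statistical machinery, not any claim about real observers.

## The mixed-model analysis chain

`fit_glmm()` fits a binomial GLMM by maximum likelihood with the Laplace
approximation over crossed random effects (lme4 with the bobyqa optimizer),
or an ordinary logistic regression when the random-factor set is empty —
that zero-variance limit is checked against direct likelihood maximization
to 10⁻⁶. Model structure follows the analysis design: test factors with all
interactions; control fixed factors block (categorical) and within-block
trial nested in block, encoded as a per-block linear slope on the centered
trial index — a fully categorical nested trial term would saturate a
96-trial design; random factors participant and stimulus individual
(keypress designs) or stimulus individual and session (visual-search
designs, where level is adapted within sessions and deliberately not
modeled). Random slopes, when requested, are dummy-coded and entered as
separate uncorrelated terms, never estimating slope–intercept correlations.

Inference is by likelihood-ratio test (`lrt()`): χ² = 2Δℓ with the
parameter-count difference as df. `prune_and_test()` implements the term
protocol — test the highest-order interaction first; drop it if
nonsignificant and test lower-order terms in the reduced model; if
significant, retain it, stop testing the terms it contains, and flag a
simple-effects follow-up (`simple_effects()`, which re-tests the focal
factor within each stratum at a caller-supplied α such as 0.05/3 for three
individually analysed chimpanzees). Overdispersion is monitored as Pearson
χ²/df (`dispersion()`); well-specified simulations sit near 1, consistent
with the 0.77–1.12 range reported for the original fits. `bootstrap_ci()`
gives percentile intervals from 2000 resamples of whole units —
participants for keypress data, sessions for visual-search data; both the
count and the unit are package defaults, as the source analysis names
neither.

Numerical choices: treatment contrasts throughout; glm separation is
flagged when coefficients exceed ±15; an LRT statistic below −10⁻⁶ raises
an error (the "reduced" model fitted better — refit needed) while smaller
negative noise clamps to 0; degenerate simple-effect strata (one outcome
value or one focal level) are skipped with a warning rather than fitted.

## Problem sizes used in validation

The validation suite works at the study's own scale where that is cheap and
at reduced replication where it is not, as a deliberate design choice:
schedule contracts are property-checked over 1000 seeds; the type-I error
of the species LRT is estimated from 1000 null-generator replications of a
two-participant design; fixed-effect recovery uses 100 replications of the
full 25-participant × 96-trial design with intercept-only random structure
(each generating coefficient must land inside ±2 estimated SEs in ≥ 90% of
replicates — observed coverage 0.94–0.98); dispersion is checked on a single
2400-trial fit. Fitting the maximal random-slope structure inside the
recovery loop would add nothing to the coverage question while multiplying
its cost; the slope machinery is exercised separately.

## Known limitations

* Synthetic stimuli are flat-shaded ellipses: no eyelids, lashes,
  highlights, or texture, and no automatic segmentation of photographs —
  real images are accepted only with user-supplied ROI masks.
* The observer is not image-computable; stimulus level influences accuracy
  only through its categorical coefficient, not through the rendered pixels.
* Laplace-approximate likelihoods make LRT χ² values implementation-shaded
  in the third significant figure across mixed-model software; exact
  agreement is only guaranteed for the zero-variance logistic limit.
* The ABA phase comparison is supported through the `phase` factor in
  `spec_study2(phase = TRUE)`, but no session-ordering machinery beyond
  that is provided.

## Worked example

```{r example, eval = FALSE}
plan <- build_study1_exp2(seed = 1)
resp <- simulate_responses(plan, observer_presets("full"),
                           n_participants = 25, seed = 2)
pr <- prune_and_test(resp, spec_study1_exp2(controls = FALSE))
pr
simple_effects(resp, focal = "polarity", split_by = c("species", "level"),
               alpha = 0.05)
```
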