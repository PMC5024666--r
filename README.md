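# illumdisc

A fully synthetic pipeline for illumination-discrimination psychophysics:
how large an illumination change (and in which chromatic direction) does an
observer need before a scene no longer looks like it is under the reference
light?

The package simulates the complete experiment in software:

- **Stimuli.** The target illumination is a metamer of a 6700 K CIE-daylight
  spectrum ("D67"), synthesized as a spectrally smooth nonnegative combination
  of 13 simulated Gaussian LED channels (a nonnegative least-squares quadratic
  program with a curvature penalty, weights snapped to a 16-bit hardware
  lattice). Four comparison series of 51 illuminants each step away from the
  target at nominal CIELUV colour differences 0–50: *blue* and *yellow* move
  along the Planckian locus (toward higher and lower correlated colour
  temperature), *red* and *green* move along the orthogonal iso-CCT line.
  All comparisons are luminance-matched to the target, so the colour
  difference is purely chromatic.
- **Scenes.** Mondrian patterns of 2000 overlapping rectangles drawn from a
  16-surface reflectance ensemble, rendered as 31-band (400–700 nm)
  hyperspectral images under any illuminant. Ensemble variants bias the
  sampling toward reddish-blue or yellowish-green surfaces; candidate scenes
  are generated and the one whose mean chromaticity best matches the variant
  target is selected.
- **Observers.** A *Weibull observer* answers the three-interval task directly
  from the comparison's colour difference through a cumulative-Weibull
  percent-correct function. A *mechanistic observer* actually looks at the
  scene: it summarizes each interval's image in CIELUV (global mean or a
  single tracked surface), perturbs each summary with isotropic Gaussian
  internal noise, and picks the candidate interval nearest the noisy
  reference. Only the mechanistic observer can reproduce scene-ensemble
  effects on thresholds.
- **Procedure.** Twelve interleaved 1-up–2-down staircases per block (three
  per direction, step schedule 15/10/5/3/1, terminating at the sixth reversal
  or 50 trials). Trials are pooled per direction, sorted by achieved colour
  difference, binned by 10, fit by binomial maximum likelihood with a
  cumulative Weibull (guess 0.5, lapse in [0, 0.05]) and inverted at the
  staircase equilibrium of 70.71% correct. Observers with any
  out-of-range fit are excluded from the group summary.
- **Image metric.** An S-CIELAB implementation (opponent-channel spatial
  filtering before pixelwise CIELAB differences) measures how large the image
  difference is at threshold.

## Worked example

```r
library(illumdisc)

basis  <- make_led_basis()                 # 13 Gaussian LED channels
series <- generate_series("blue", basis)   # 51 comparisons toward higher CCT
series
#> <comparison_series> blue | 51 comparisons | achieved dE 0.02..49.99 | mean |achieved-nominal| = 0.003

head(series$table[, c("nominal_de", "achieved_de", "x", "y", "cct")], 4)
#>   nominal_de achieved_de         x         y      cct
#> 1          0   0.0174044 0.3096039 0.3264295 6718.575
#> 2          1   0.9996367 0.3085948 0.3254187 6786.923
#> 3          2   2.0009373 0.3075894 0.3244067 6856.669
#> 4          3   3.0005549 0.3065914 0.3233967 6927.606

cfg <- experiment_config(seed = 42, dialect = "simulated",
                         observer = weibull_observer(alpha = 10, beta = 3),
                         n_observers = 3)
bundle <- run_experiment(cfg)
bundle$group_summary
#>   direction     mean       sem n
#> 1      blue 6.892957 1.0575464 3
#> 2     green 8.232762 0.9758385 3
#> 3       red 8.704929 0.5145665 3
#> 4    yellow 6.912375 0.1374186 3

# the simulated observer's true 70.71%-correct threshold, for comparison:
threshold_at(list(alpha = 10, beta = 3, lapse = 0, guess = 0.5))
#> [1] 8.116913
```

## Analysis workflow

Numbered driver scripts under `analysis/` run the full study and write tables
under `results/` (run them from the repository root, in order):

1. `01_build_stimuli.R` — target metamer and the four comparison series.
2. `02_select_scenes.R` — the three Mondrian ensemble variants and their
   selected scenes.
3. `03_run_experiment.R` — ten observers × two blocks of interleaved
   staircases, Weibull fits, group thresholds.
4. `04_scene_effects.R` — the surface-ensemble manipulation with a
   mechanistic observer (thresholds per scene variant and contrasts vs the
   neutral ensemble).
5. `05_scielab_at_threshold.R` — mean S-CIELAB image difference at the fitted
   thresholds (requires the output of step 3).

## Reproduction

`scripts/acceptance.R` recomputes the package's headline quantities from
scratch against the installed package and writes them as a flat JSON object:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

- `t2` — proportion correct of a noisy mechanistic observer over 10,000
  three-interval trials with zero illumination change (chance anchoring).
- `t3` — the CIELUV colour difference of one just-noticeable difference,
  from the embedded MacAdam (1942) ellipses scaled to 1.96 SD.

The random components derive all their seeds from `--seed`; `t3` is
deterministic.

## Package layout

- `R/constants.R` — embedded CIE tables (colour-matching functions, daylight
  components, MacAdam ellipses, S-CIELAB kernels).
- `R/spectrum.R`, `R/colorimetry.R` — spectral types and colorimetry
  (CIELUV/CIELAB, Planckian locus, CCT, daylight model, JND calibration).
- `R/illuminants.R` — LED basis, metamer fitting, comparison series.
- `R/scene.R` — reflectance ensembles, Mondrian generation, rendering,
  display mapping.
- `R/observer.R`, `R/staircase.R`, `R/psychometrics.R` — simulated observers,
  adaptive procedure, threshold extraction.
- `R/scielab.R` — the spatial colour-difference metric.
- `R/experiment.R` — configuration presets and the end-to-end experiment.

See `vignettes/illumination-discrimination.Rmd` for the modelling choices and
their limitations.
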