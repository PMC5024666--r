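---
title: "Simulated illumination-discrimination experiments: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated illumination-discrimination experiments: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(illumdisc)
```

This vignette documents what the package models, the parameter choices and
their defaults, the numerical decisions behind the implementation, and what
the synthetic pipeline can and cannot tell you. Code chunks are illustrative
and not evaluated when the vignette is built.

## The task being modelled

An observer views a scene under a reference ("target") illumination, then two
candidate intervals: one repeats the target, the other shows the scene under a
comparison illumination displaced from the target by a controlled chromatic
step. The observer reports which candidate changed. The illumination
discrimination threshold is the displacement, measured as a CIELUV colour
difference, at which the observer is right 70.71% of the time — the
convergence point of a 1-up–2-down staircase, since a level is stationary
when the probability of two consecutive correct responses equals one half
(p² = 0.5).

Thresholds are measured along four chromatic directions. *Blue* and *yellow*
displace the chromaticity along the Planckian locus, toward higher and lower
correlated colour temperature (CCT); *red* and *green* displace it along the
iso-CCT line, the direction orthogonal to the locus in the CIE 1960 uv
diagram. The target illumination is a metamer of the CIE daylight spectrum at
6700 K.

## Stimulus synthesis

`make_led_basis()` models a 13-channel tunable LED luminaire as Gaussian
spectral channels (peaks every 23 nm or so from 410 to 690 nm, 30 nm full
width at half maximum) on the canonical 400–700 nm, 10 nm grid. The real
luminaire's channel spectra are not published; Gaussians of this width are a
standard stand-in for narrowband phosphor-free LEDs. Every synthesized
illuminant is a nonnegative combination of these channels.

Metamer fitting is a quadratic program solved as nonnegative least squares on
a stacked system (`pracma::lsqnonneg`): minimize the spectral (or
tristimulus) mismatch plus a second-difference curvature penalty
(`smoothness = 1e-3`) that selects the smoothest spectrum among the many
nonnegative combinations matching the target. For comparison illuminants the
tristimulus match is enforced through a large quadratic penalty
(`match_weight = 1e4`) rather than a hard constraint, which keeps the whole
problem inside one NNLS call; the residual chromaticity error this leaves is
orders of magnitude below one just-noticeable difference. Channel weights are
snapped to a 16-bit lattice, mimicking hardware drive levels, and every
comparison is rescaled to the target's luminance so that only chromaticity
carries the signal.

Two numerical choices in the series geometry deserve explanation:

- **The blue/yellow path is the Planckian locus rigidly translated to pass
  through the target chromaticity.** The daylight chromaticity at 6700 K sits
  slightly above the Planckian locus (a Duv of about +0.003). A series that
  started exactly at the target and also lay exactly on the locus is
  geometrically impossible; translating the locus keeps the series anchored
  at the target (the zero-step comparison differs from it by a colour
  difference of ~0.02) while preserving the locus's curvature, so CCT rises
  along the blue series and falls along the yellow one as intended. The
  series consequently runs parallel to the locus at a distance of ~0.003 uv
  rather than on it.
- **The red/green line is the locus normal evaluated at the target's own
  CCT.** A straight line through a chromaticity is an iso-CCT line exactly
  when it is the normal from the nearest locus point. Using the normal at the
  target's CCT keeps every red/green comparison within a few kelvin of the
  target's correlated colour temperature; using the normal at nominal 6700 K
  instead lets the CCT drift by ~30 K across the series.

The path parameter along the locus is reciprocal temperature (mireds), which
spaces steps much more evenly than kelvins; the point at a requested colour
difference is found by root bisection on the luminance-matched CIELUV
distance from the target, with the target itself as the reference white. With
that white the target maps to (L*, u*, v*) = (100, 0, 0) and the colour
difference reduces to its chromatic terms.

## Calibration of the colour-difference unit

`jnd_in_delta_e()` converts the embedded MacAdam (1942) chromaticity
discrimination ellipses into a CIELUV colour difference per just-noticeable
difference: each ellipse is scaled to 1.96 standard deviations, its boundary
sampled, centre and boundary converted to CIELUV at equal luminance with
illuminant C (the adapting field of the original measurements) as reference
white, and the distances averaged over boundary points and ellipses. This
yields 3.99 ΔE per JND. The averaging convention matters: averaging the two
semi-axis lengths instead gives 3.85, the major axis alone 5.04, the minor axis
alone 2.66. We report the boundary mean, the convention that uses the whole
ellipse shape.

## Scenes and rendering

Scenes are Mondrians: `n_rects = 2000` axis-aligned rectangles with uniformly
random positions and sizes (4–64 px sides), painted in order so later
rectangles overpaint earlier ones, each drawing a surface from a 16-member
reflectance ensemble. The default ensemble (`default_reflectance_set()`) is
synthetic — smooth sums of Gaussians spanning the hue circle plus four
neutrals — standing in for a printed poster's measured reflectances, which
are not published. Ensemble variants double the sampling weight of red+blue
or yellow+green surfaces. Because overpainting makes the realized surface
shares highly variable, the pipeline generates `n_candidates = 20` candidate
scenes and keeps the one whose mean chromaticity under the target
illumination is closest to the variant's target chromaticity; this candidate
selection, not the bias alone, is what pins the scene statistics.

Rendering is deliberately minimal: each pixel's spectrum is the product of
its surface reflectance and the illuminant (a flat, diffuse, shadowless
world). The default experiment canvas is 128×128 px — large enough for stable
surface shares, small enough that a full simulated experiment runs in
seconds. For the mechanistic observer the pipeline never renders per-pixel at
all: with a flat renderer the image mean tristimulus values equal the
area-share-weighted sum of per-surface tristimulus values, which is computed
analytically.

## Observers

`weibull_observer(alpha, beta, lapse)` responds correct with probability
p(ΔE) = 0.5 + (0.5 − λ)(1 − exp(−(ΔE/α)^β)): a scene-blind observer with a
known ground-truth threshold, used to validate the staircase-to-fit pipeline
end to end.

`mechanistic_observer(strategy, noise_sd)` implements a minimal
signal-detection account: each interval is summarized as a CIELUV point
(the image's global mean, or one tracked surface), each summary is perturbed
by isotropic Gaussian noise of `noise_sd` CIELUV units (default 3,
i.e. internal noise slightly below one JND per interval), and the observer
picks the candidate nearest the noisy reference. Isotropy in a roughly
perceptually uniform space is the simplest defensible noise model; it makes
percent correct depend only on the summary separation over the noise scale.
Only this observer "sees" the scene, so only it can express surface-ensemble
effects on thresholds — with a global-mean strategy, an ensemble lacking
long-wavelength reflectance mutes the image-level signal of a reddish
illumination shift and raises the red-direction threshold.

## Procedure and threshold extraction

Each block interleaves twelve staircases (three per direction, starting
levels drawn uniformly from 11–20, 21–30 and 31–40), choosing the next trial
uniformly at random among unfinished staircases. The step schedule is
15/10/5/3/1, advancing at each of the first four reversals; a staircase ends
at its sixth reversal or 50 trials. Movements clamped at the level floor or
ceiling do not count as reversals (nothing reversed). The level floor is 0 in
the real-scene dialect and 1 in the simulated-scene dialect; the dialects
also differ in blocks per observer (1 vs 2) and interval timing metadata.

All of a direction's trials are pooled, sorted by achieved colour difference
(stable sort, chronological tie-break), binned in tens (remainder in the last
bin), and fit with a cumulative Weibull by binomial maximum likelihood with
guess fixed at 0.5 and lapse bounded in [0, 0.05]. The likelihood surface has
local optima for near-degenerate data, so the optimizer (L-BFGS-B on
(log α, log β, λ)) is run from 48 starts — eight log-spaced α spanning the
data range × β ∈ {1, 2, 4} × λ ∈ {0, 0.025} — and the best optimum kept. The
threshold is the closed-form inverse at 70.71%; fits whose threshold leaves
the (1, 50) stimulus range are flagged invalid, and an observer with any
invalid fit is excluded from the group summary. Significance levels for
planned comparisons use Bonferroni correction (`bonferroni_alpha()`).

## S-CIELAB

`scielab_map()` implements the standard S-CIELAB pipeline: per-pixel XYZ →
opponent channels → per-channel spatial filtering with sums of Gaussians
whose widths scale with viewing resolution (default `ppd = 17` pixels per
degree) → back to XYZ → CIELAB → pixelwise ΔE. The separable convolutions
use symmetric edge padding, kernels are truncated at ±0.5° (or 4 SD,
whichever is smaller) and renormalized so each channel has exactly unit DC
gain — which guarantees the metric reduces to plain CIELAB on uniform fields,
one of its defining degeneracies. The reference white defaults to the mean
filtered chromaticity of the first image at the pair's maximum luminance, so
the metric is usable on images in arbitrary linear units.

## What the synthetic pipeline does and does not show

Everything here is simulation. The package demonstrates that the machinery is
correct — the staircase converges where theory says, known observers are
recovered end to end, the geometry of the stimulus series holds, ensemble
manipulations move a mechanistic observer's thresholds in the expected
direction. It cannot show anything about human vision: no simulated observer
validates the "blue bias" or any other empirical asymmetry between chromatic
directions, and none of the group thresholds produced by the analysis scripts
are predictions of human data. The generator's realism is limited in known
ways: Gaussian LED channels and a synthetic reflectance ensemble replace
unpublished measured spectra; the renderer has no geometry, shading,
interreflections or chromatic adaptation dynamics; the mechanistic observer's
two summary strategies bracket, but do not span, plausible human strategies;
and timing metadata is carried but unused, because simulated observers are
timing-blind.

Problem sizes (31 spectral bands, 51 series members, 13 channels, 16
surfaces, 2000 rectangles, 20 candidates, 128×128 canvas) are the package's
own defaults, chosen so the full pipeline runs on a desktop in well under a
minute; all of them are arguments, not constants.
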