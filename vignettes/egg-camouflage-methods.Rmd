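---
title: "Quantifying egg camouflage through predator eyes: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying egg camouflage through predator eyes: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ground-nesting shorebirds lay open nests whose only passive defence is
camouflage. Whether eggs actually match their background must be judged in
the eyes of the likely predators — birds (tetrachromats with a double-cone
luminance channel), mammalian carnivores (dichromats) and, for comparison,
humans — and separately for colour (which dominates detection at a
distance, where pattern cannot be resolved) and visual texture (which
matters close up). `ovicrypt` implements this analysis end to end: from a
calibrated nest photograph plus a colour-keyed mask image to
predator-specific colour/texture features, and from those to
discriminability statistics. A synthetic scene generator stands in for
field photographs so that every stage is testable against known ground
truth.

## Pipeline overview

1. **Scenes** (`generateDataset()` or `readScene()`): a linear-RGB raster
   in [0, 1] with masks for three eggs (cyan/magenta/yellow colour key), a
   40 mm ruler segment (green), a 20 %-reflectance grey square (red) and an
   exclusion zone.
2. **Calibration** (`greyCalibrate()`, `rescaleToStandard()`): per-channel
   gains `target / mean(grey pixels)` normalise exposure and white point at
   once; the ruler fixes the pixel scale and scenes are resampled by
   nearest neighbour to a common resolution (native scale 12 px/mm).
3. **Receptor catches** (`spectralSystem()`, `fitRgbToConeMap()`,
   `applyMap()`): a polynomial mapping from camera RGB to cone quantum
   catches, trained on a bank of smooth reflectance spectra.
4. **Colour metrics** (`regionColour()`): per region, luminance plus
   red-green and yellow-blue opponent values (CIE L\*a\*b\* for humans).
5. **Texture** (`buildBank()`, `filterEnergies()`, `fitPca()`): 6 scales x
   8 orientations of log-Gabor filters on the luminance plane — 48 log
   mean-magnitude features — reduced by correlation-matrix PCA.
6. **Sampling** (`planBackgroundSamples()`, `buildFeatureTable()`): per
   scene, the 3 eggs plus 27 egg-shaped background samples (translated
   copies of a randomly chosen egg mask, orientation preserved, avoiding
   the exclusion zone) give 30 rows; the random-guess egg rate is 3/30 =
   0.1 by design.
7. **Statistics** (`runTableSuite()`, `runDiscriminationSuite()`): linear
   mixed models with a per-photograph random intercept and Satterthwaite
   t-tests; MANOVA with Pillai's trace over the joint texture PCs;
   leave-one-nest-out cross-validated binomial mixed-model classifiers
   summarised by confusion matrices against the 0.9 no-information rate
   and by empirical ROC curves.
8. **Acuity** (`resolvableDistance()`): converts feature size and acuity
   to the farthest distance at which a pattern element is resolvable,
   under a one-cycle convention (d = size/1000 x cpd x 180/pi metres).

## Spectral model

The wavelength grid is 400–700 nm in 5 nm steps (finer than the 10 nm
bandpass filters such calibrations are built from; negligible cost). The
illuminant is CIE D65 (open-field daylight), embedded as the standard
10 nm table and interpolated. Receptor sensitivities come from a
Govardovskii-style A1 visual-pigment template (alpha + beta band)
parameterised by the wavelength of peak absorbance:

* avian (violet-sensitive type): double cone D 570 nm, single cones
  L 605, M 537, S 477 nm, each with a configurable long-pass "oil-droplet"
  cut-off (smooth logistic; defaults D/S 440, M 500, L 560 nm);
* carnivore (dichromat): L 558, S 430 nm;
* human: L 566, M 541, S 441 nm.

No ultraviolet/violet cone is modelled: a three-sensor camera cannot
separate a UV/V channel from the short-wave channel, and the analysis is
restricted to the human-visible range. Peak values are conventions, set
as constructor arguments, not estimates from this package.

The camera is modelled with Gaussian sensor sensitivities (R 600/50,
G 535/45, B 450/55 nm peak/sd). The broad blue sensor matters: cone
catches are predicted from camera catches by a quadratic polynomial, and
the short-wave cones are only recoverable if the camera carries
information below 460 nm. The mapping uses the full 10-term quadratic
design {1, R, G, B, R², G², B², RG, RB, GB} — with/without cross-terms is
genuinely open; the full set is the most general quadratic and the
held-out fit reports whatever it earns. Quantum catches are normalised so
a perfect reflector scores 1. The training bank is 200 synthetic spectra
(1–3 broad Gaussians of 60–140 nm width plus a linear ramp, clipped to
[0, 1]) — a low-dimensional smooth family standing in for natural
reflectance spectra, which are themselves well described by very few
basis functions. A fixed, seeded 75/25 split supplies held-out R² per
cone. The human pathway bypasses the fitted map: linear sRGB converts
exactly to CIE XYZ (and Y is the human luminance plane).

## Colour metrics

Opponent channels use the Michelson contrast form (A − B)/(A + B):
intensity-invariant and bounded in [−1, 1]. For the avian system,
luminance is the double-cone catch, red-green is (L − M)/(L + M) and
yellow-blue contrasts the mean of L and M against S. The dichromat's
yellow-blue is (L − S)/(L + S) and its luminance is taken as the L-cone
catch (the long-wave mechanism dominates dichromat achromatic vision; a
stated convention). The contrast form itself is swappable — it is isolated
in one internal function — because the literature also uses log-ratio
forms. Region colour pools first and transforms second (mean catches,
then opponency): at the distances where colour drives detection the
region is spatially pooled before opponency, and this order also keeps
region values consistent with the bounded channel definitions.

## Texture model

Log-Gabor filters are defined in the frequency domain: a Gaussian profile
on log radial frequency (sigma/f = 0.55, about two octaves) times a
Gaussian angular profile (orientation spacing 22.5°, spacing/sigma = 1.5),
single-sided so the spatial response is complex and its modulus is the
local energy envelope. They have no DC response, so a constant image
scores zero everywhere. Six scales start at a 3 px minimum wavelength and
double per scale (3–96 px; 0.25–8 mm at 12 px/mm — maculation dots up to
pebble-scale objects). Orientation o1 is horizontal, turning
anticlockwise. Only the 6 x 8 geometry is canonical; the bandwidths and
wavelength range are declared conventions, all exposed as `buildBank()`
arguments for sensitivity analysis.

Filtering is done once per scene over the whole image; the region mask is
applied to the response magnitude, not to the input, so mask edges cannot
inject spurious spectral energy. Per filter, the mean magnitude over the
region is logged (natural log) with a floor of 1e-8 — plain Gabor energy
is non-negative and correlates with mean luminance, while logged values
can go negative and decorrelate from brightness. Logging the pooled mean
(rather than pooling per-pixel logs) is a choice; the alternative is one
switch away in the code (`filterEnergies()` is the single place the
pooling order lives). A region closer to the border than half the largest
wavelength is flagged with a non-fatal boundary note.

Because computed luminance planes of the three visual systems are nearly
proportional (the test suite asserts per-feature correlations above 0.95
between avian double-cone and human-Y texture vectors on synthetic
scenes), one shared texture space is used for all systems, computed from
the avian double-cone plane.

The 48 features are reduced by PCA on the correlation matrix, fitted once
on the pooled egg + background table across both habitats (refitting per
stratum would break score comparability). Components with eigenvalue > 1
are retained (they explain more than any single original feature), each
oriented so its loading sum is non-negative; the feature table always
carries at least PC1–PC4 so the downstream grids have a fixed shape.

## Statistical machinery

With 30 samples per photograph, "photograph" (= nest) is a random
intercept in every model. `fitLmm()` wraps a REML `lmer` fit and reports
Satterthwaite degrees of freedom; the degrees of freedom reported are the
ones this machinery produces — no attempt is made to reproduce any
specific published df value, which depends on unknowable details of the
original data layout. Standardised effects z-score the response over the
analysed stratum first, so a two-level factor's coefficient is a
difference of standardised means (negative = eggs below backgrounds). A
constant response is returned flagged `singular` with a zero effect
rather than erroring, so metric grids stay rectangular.

`manovaPillai()` reports Pillai's trace — trace(H(H+E)⁻¹), a multivariate
R²-like effect size — with the standard approximate-F transformation (the
stock transformation in `summary.manova`; an ambiguity about a bespoke
variance-ratio F is resolved in favour of the standard one). Two modes
exist because the three analysis splits need different units: raw
samples (object-type questions, where within-nest replication carries the
signal) or nest means (habitat questions, where the nest is the unit).
`runTableSuite()` produces the three splits — object x habitat
interaction on everything; beach vs salt marsh separately for eggs and
backgrounds (nest-level MANOVA); egg vs background per habitat with
standardised effects — each over the same 10-metric grid (5 colour
metrics, PC1–4 jointly, PC1–4 singly). No multiplicity correction is
applied; the joint MANOVA is the type-I protection for the texture block.

`looCrossValidate()` fits a binomial GLMM (logit link, nest random
intercept) on all-but-one nest and predicts the held-out nest with the
fixed effects only — the random intercept of an unseen group has
expectation zero, and that is the only coherent prediction for a new
nest. Features are standardised per training fold. Folds that fail or
separate (runaway slopes, common when colour + texture classify
perfectly) are refitted with a ridge-stabilised logistic regression
(lambda 1e-4 on slopes, intercept unpenalised) and flagged. Confusion
summaries threshold at 0.5 and test accuracy against the no-information
rate (0.9 under the 3:27 design) with a one-sided exact binomial test.
The ROC is the empirical curve over all distinct probability thresholds;
its trapezoidal AUC equals the Mann–Whitney concordance probability,
which the tests assert against a brute-force pair count and against
pROC.

## The synthetic scene generator

`generateDataset()` emulates the statistical structure the analysis
assumes, not photorealism:

* **Backgrounds**: band-limited Gaussian luminance noise (log-Gaussian
  spectral shaping around a characteristic grain wavelength) modulating a
  mean habitat colour, plus explicit pebble ellipses with independent
  luminance offsets. Noise and pebbles separately control the
  contrast-like and grain-like texture axes. Beach defaults: linear RGB
  (0.66, 0.58, 0.40), luminance sd 0.05, grain 0.5 mm, sparse small
  pebbles. Salt marsh: darker and browner (0.42, 0.34, 0.26), higher
  contrast (sd 0.09), coarser grain (1.6 mm), many larger pebbles.
* **Eggs**: three filled ellipses (default 33 x 22 mm at the working
  resolution, within the species' 30–36 mm length range) of a brown
  ground colour placed between the two habitat means — darker on average
  than the beach background — with dark maculation: spots (quantile-drawn
  Poisson counts so coverage is monotone in density at a fixed seed) and
  wispy 1–2 px random-walk polylines. No quantitative maculation
  statistics exist for these eggs; spot density and size are free
  conventions.
* **Between-nest variation**: each nest draws a log-normal colour jitter
  (sd 0.12 beach, 0.20 salt marsh — the marsh is the more variable
  habitat) applied to the background hue with noise scaled
  proportionally, and a clutch-level lightness jitter (sd 0.08) applied
  to all three eggs. This is what makes egg and background colour
  distributions overlap across nests — the phenomenon the discrimination
  analysis is about — instead of separating on a fixed offset.
* **Fiducials**: grey square (exact 0.20 reflectance pre-noise) and a
  40 mm ruler in fixed corners; deterministic layout keeps mask-decoding
  tests simple. The exclusion zone is the union of eggs, ruler and grey
  patch, each dilated by 5 px (the nest-scrape margin is not specified
  anywhere; 5 px is a declared convention).
* **Determinism**: every output is a pure function of (parameters, seed);
  per-scene seeds derive from the global seed and the nest id, so results
  do not depend on processing order.
* A `composeScene(eggOffset=)` control can force the egg-minus-background
  difference of means to an exact configured value (scalar luminance or
  per-channel), which is how parameter-recovery and
  "texture-differs-but-colour-matches" experiments are set up.

What the generator does **not** emulate: 3-D shading, cast shadows,
egg-outline cues, vegetation structure, illumination changes between
photographs, or camera noise (a Gaussian sensor-noise flag exists but
defaults to off). Passing tests on synthetic scenes therefore validate
the machinery and its contracts, not any claim about real nests.

## Numerical choices and problem sizes

* Coordinates: 0-based row-major with origin top-left in all documentation
  (R's 1-based indexing is an implementation detail); rectangles half-open.
* Mask decoding is by exact 8-bit palette match; anti-aliased masks are
  rejected (masks are labels, not photographs).
* Nearest-neighbour resampling everywhere a mask is involved, preserving
  boolean labels and sharp maculation edges; upscaling needs an explicit
  override since the standard workflow only downscales.
* Log floor 1e-8 before logging energies; opponent channels error on a
  zero denominator rather than returning NaN.
* Ridge lambda 1e-4; IRLS capped at 100 iterations; probabilities clamped
  to (1e-9, 1 − 1e-9).
* Background-sample rejection budget 1e5 draws, with an early area
  feasibility check (background area at least 27 egg areas).
* The test-suite and example runs generate scenes at 2 px/mm (eggs 66 x
  44 px, scenes roughly 330 px square) rather than the native 12 px/mm;
  the analysis is resolution-agnostic and this keeps an 88-scene run with
  full texture analysis to a few minutes. Simulation-based checks use 200
  replicates (offset recovery) and 400 replicates (null calibration) of
  30-nest tables.

## Known limitations

* The generator's habitat and maculation parameters are plausibility
  conventions, not field estimates; only their orderings (marsh darker,
  more variable, coarser; eggs darker than beach) are anchored.
* The texture bank's bandwidths and wavelength range are conventions; PC
  interpretations (contrast-like PC1, grain-like PC2) should be checked on
  any new dataset from the loadings, not assumed.
* Dichromat luminance = L-catch and the Michelson contrast form are
  conventions kept behind single functions so alternatives can be swapped.
* Real-mode inputs are assumed already linearised; RAW demosaicing and
  camera response estimation are out of scope.
* Receptor-noise (JND) discrimination models are deliberately absent: the
  analysis is distributional (signal detection over feature
  distributions), not threshold-based.
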