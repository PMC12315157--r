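---
title: "Evolving wavelength-interval feature extractors: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving wavelength-interval feature extractors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsigp)
```

## The problem

Field hyperspectral cameras record hundreds of narrow reflectance bands
per pixel, but a deployable multispectral sensor can afford only a
handful of filters. Choosing which wavelengths (and how wide a bandpass
around each) best predict a sediment attribute such as organic-matter
content is therefore both a feature-selection and a sensor-design
question. `hsigp` treats it as a program-synthesis problem: strongly
typed genetic programming (STGP) evolves feature-extraction trees whose
leaves choose *variable-width wavelength intervals* — contiguous windows
of adjacent bands aggregated into one value — rather than isolated
bands, exploiting the strong correlation between neighbouring channels.

## From raw counts to analysable spectra

The calibration pipeline mirrors standard field practice:

1. **White-reference correction.** In bright conditions the visible
   part of the in-scene white tile saturates. Saturated entries carry no
   information and are replaced by `a * seed^b + c` applied to a seed
   white spectrum from a non-overexposed acquisition, with `(a, b, c)`
   fitted by unconstrained least squares on the non-saturated bands
   (`b` initialised at 1, the linear solution as the starting point).
   Non-saturated entries pass through untouched, so the operation is
   idempotent on clean references.
2. **Reflectance calibration.** `Rc = (RR - RD) / (RW - RD)` per pixel
   and band, with raw counts `RR`, white `RW` and dark `RD`.
3. **Shell segmentation.** Specular shell fragments reflect strongly in
   the NIR where wet sediment is dark; pixels above a threshold at the
   band nearest 873 nm are dropped from the region of interest, and the
   surviving mask is eroded by a disc (radius 1 pixel by default) to
   trim mixed boundary pixels. The numeric threshold is data dependent,
   so the default is Otsu's threshold on that band, both it and the
   radius being configuration.
4. **Gridding.** Each 25 cm quadrat is split into a 5 x 5 grid of cells,
   the modelling unit; ground-truth cores come from the four corners
   and the centre cell.
5. **Pretreatment.** Per-pixel standard normal variate (SNV) and
   Savitzky-Golay smoothing; the mean ROI spectrum of a cell is the
   spectra-based model input. The smoothing window (9) and polynomial
   order (2) are conventional defaults and configurable — neither the
   order of the two pretreatments nor their parameters is canonical in
   the field, so `preprocess_cube()` exposes them.

## The two program structures

Trees are typed: HSI (hyperspectral cube), GSI (grayscale image),
SPECTRA (reflectance spectrum), SF (scalar spectral feature) and FV
(feature vector), plus the parameter terminals (centre band, window
width in {1,3,5,7,9,11}, Gaussian width in (0,5], kernel size in
{3,5,7,9,11}, Gabor orientation k·pi/4 and frequency pi·2^-(1+0.5v),
co-occurrence angle and distance). The **spectra-based** structure maps
a preprocessed mean spectrum through interval selections (mean or
median), optional SF arithmetic with protected division, a conversion
`=` to FV, and a concatenation root of arity 2-4. The **image-based**
structure additionally extracts grayscale images from band windows
(mean/median/Gaussian weights, renormalised over surviving bands at the
spectrum edges), filters them (Gaussian, derivative-of-Gaussian
magnitude, median, min, max, Gabor at 7x7 and 9x9 with fixed envelope
sigma = 2, gamma = 0.3, psi = 1, min-max scaling), and summarises them
either by ROI averaging (a spectral feature) or by texture descriptors:
the five co-occurrence features (homogeneity, entropy, contrast,
correlation, energy) and four histogram moments. Disabling the texture
primitives makes the image structure express exactly the spectra-based
extractors, which the tests verify numerically.

Concatenation primitives are root-only: they may not nest, mirroring
the single feature-concatenation layer of both structures. Crossover
and mutation respect this (a concatenation node can only move to
another root position).

### Initialisation under per-type height budgets

Many primitives have arity 2+ and the type system forces mandatory
chains (FV <- SF <- SPECTRA, or FV <- SF <- GSI <- HSI), so naive
ramped half-and-half either explodes or fails. Generation therefore
tracks, for every type, the minimum number of levels needed to finish a
subtree of that type (a fixpoint over the primitive signatures) and
only ever picks primitives whose arguments still fit in the remaining
budget; each branch is thereby forced to transition toward terminals
before the cap. For the *full* method, primitives that consume the
program input are only eligible one level above the target depth,
keeping trees as full as the type system allows. Defaults follow common
GP practice at field scale: initial depth 3-6 (spectra) or 4-7 (image),
caps 8 and 9 — the image structure needs one extra mandatory
transition — population 2048, 50 generations, tournament size 4,
crossover 0.8, mutation 0.2 (the mutation point is a non-leaf with
probability 0.75), elitism 0.01.

### Fitness

Each tree maps every calibration sample to a feature vector; features
are z-scored with statistics estimated across **all** extracted
calibration vectors (the prediction set never contributes), and a
linear-kernel support vector regression with fixed cost 1 and epsilon
0.1 is fitted on a 70:30 train/evaluation split of the calibration set,
drawn once per run and shared by all individuals. Fitness is the
evaluation-portion R-squared (maximised) or MSE (minimised). Per-
individual hyperparameter search would multiply the cost of every
generation for little ranking benefit, so the grid-searched SVR is
reserved for the final reported models. Evaluation failures (empty ROI,
out-of-range index, non-finite feature) earn the worst-possible
sentinel rather than aborting the run. Offspring are built DEAP-style:
crossover *or* reproduction at rate 0.8, then mutation at rate 0.2 —
the composition order is a genuine open choice; this one keeps the
expected operator application counts at their nominal rates.

## The chemometric toolchain

* **SPXY** partitions samples 2:1 into calibration and prediction sets
  by greedy maximin selection on the joint x-y distance
  `d = dX/max(dX) + dY/max(dY)` — deterministic, spread-maximising.
* **PLSR** chooses its latent-variable count by minimising RMSECV under
  five-fold cross-validation with two repeats, then refits on all rows
  (the factorisation itself is delegated to `mixOmics::pls`).
* **SVR** hyperparameters come from a grid search (cost {0.1,1,10,100},
  epsilon {0.01,0.1,1}, and for RBF a gamma band around the scale
  heuristic `1/(p * var(X))`) scored by cross-validated MSE.
* The **evaluation protocol** reports six numbers: training-fold and
  held-out-fold R-squared/MSE under five-fold cross-validation of the
  calibration set, and the prediction-set metrics of each fold's model,
  all averaged over folds. R-squared is `1 - SSE/SST` and can be
  negative when a model underperforms the mean predictor.
* **Baseline selectors.** SPA builds candidate chains by successive
  orthogonal projections (largest residual norm first) from every
  start, scoring subsets by cross-validated least-squares RMSE; CARS
  runs Monte-Carlo row sampling with an exponentially decaying enforced
  retention ratio and adaptive reweighted sampling by absolute PLS
  coefficients, returning the subset with minimal RMSECV; RC keeps
  local maxima of the absolute PLS coefficients under non-maximum
  suppression (window +/-5 bands, floor 20 % of the global maximum —
  both configurable, since no canonical values exist).

## The synthetic scene generator

Real field cubes are large and external, so every stage is validated on
synthetic scenes with known ground truth: a smooth low-order polynomial
base spectrum shaped like wet sediment reflectance; planted Gaussian
absorption features (defaults at 675 and 940 nm, widths 15 and 20 nm)
whose depths are proportional to the target attribute (0.04 reflectance
per unit over a 0.5-2.1 attribute range — at mid-range the dip depth is
five times the per-pixel noise sd of 0.01); multiplicative smoothed-
noise texture (3 % amplitude, 3-pixel correlation length); bright flat
"shell" blobs at 0.9 reflectance; per-sample multiplicative
illumination drift (+/-5 %); and Gaussian pixel noise. What the
generator does **not** emulate: atmospheric water-vapour absorption
structure, inter-band noise correlation, spatially organised sediment
features, and reference-measurement error — passing recovery tests
therefore demonstrate algorithmic correctness, not field performance.

Two design notes on the recovery experiments. First, band means are
taken after shell segmentation — shells can cover a large fraction of a
small synthetic scene and attenuate the dip signal by a sample-varying
factor, exactly the artefact segmentation exists to remove. Second,
recovery runs use calibrated reflectance *without* SNV: SNV divides
each spectrum by its own standard deviation, which in these scenes is
itself a function of dip depth, so after SNV every band carries the
target signal and the question "did the tree select the planted
interval?" stops being identified. SNV remains exercised by its own
unit tests and by the pretreatment path.

## Problem sizes used by the test suite

Validation runs at desk scale, chosen so the full suite completes
comfortably on one CPU: co-occurrence oracles sweep 100 random 16x16
images over all 20 (distance, angle) pairs; typed-generation checks
draw 5,000 trees plus 1,000 crossovers and 1,000 mutations per
structure; determinism/elitism checks use population 64 for 10
generations; recovery experiments use n = 60 samples of 12x12x204
cubes, population 128, 20 generations, 5 seeds. The headline field
configuration (population 2048, 50 generations, 50 repeated runs)
is what `gp_config()` defaults encode.

## Numerical conventions and degenerate inputs

* Sample (n-1) standard deviations everywhere; kurtosis is excess by
  default.
* Interval windows truncated at spectrum edges renormalise their
  weights over the surviving bands; medians of even-count windows take
  the midpoint of the central pair.
* Protected division returns 0 when |denominator| < 1e-9; min-max
  scaling of a constant ROI returns zeros; zero-variance feature
  columns standardise to 0; co-occurrence correlation of a degenerate
  (single-level) matrix is 0. Each rule keeps the evolutionary search
  total instead of aborting on a degenerate individual.
* 2-D filters use symmetric (reflect) border padding and are computed
  over the full rectangle; features only ever read ROI pixels, so
  convolution near mask holes stays well defined.
* Band lookup by wavelength is nearest-neighbour; band indices are
  1-based throughout the R API.
* Grey-level quantisation for co-occurrence matrices is min-max over
  ROI pixels into 32 levels by default (configurable); this makes all
  texture features invariant to affine intensity rescaling.
* Tournament ties break toward the smaller tree; crossover retries up
  to 5 times before returning the parents unchanged; identical parents
  are returned as-is.

## Known limitations

The evolutionary loop is single-threaded; image-based fitness evaluates
cubes per sample and is markedly slower than the vectorised spectra
path. The SPA implementation scores every (start, size) chain by
cross-validated least squares, which is quadratic in band count and
meant for a few hundred bands. PLSR delegates to `mixOmics`, whose
internal autoscaling differs from mean-centred-only conventions in some
chemometrics texts; RMSECV curves are comparable but not bit-identical
to other PLS implementations. The white-reference power-law fit assumes
the seed spectrum is strictly positive. None of the reported numbers
here or in the README are asserted beyond what the test suite and
`scripts/acceptance.R` recompute at run time.
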