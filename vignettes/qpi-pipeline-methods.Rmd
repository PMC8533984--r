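---
title: "Methods: from off-axis hologram to cell-state fractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from off-axis hologram to cell-state fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(holocell)
```

This vignette is the package's own account of the models and numerical
choices behind each stage of the pipeline. It states no empirical results;
quantitative claims about the implementation are made (and checked) by the
test suite and by `scripts/acceptance.R`.

## Physical model

A transparent cell in medium delays the optical field by a phase

$$\varphi(x, y) = \frac{2\pi}{\lambda}\,\big(n_\mathrm{cell} -
n_\mathrm{medium}\big)\, h(x, y),$$

where $h$ is the physical thickness, under the assumption that the
intracellular refractive index is spatially constant. `optical_constants()`
bundles the four physical parameters:

* `wavelength_nm` (default 633): the recording wavelength of a HeNe-based
  off-axis interferometer.
* `n_cell` (default 1.380) and `n_medium` (default 1.337): literature-typical
  values for adherent mammalian cells and culture medium; the refractive
  contrast $\Delta n = 0.043$ is the single most uncertain constant in any
  QPI morphology computation, and `relative_errors()` exists precisely to
  quantify what its misspecification does to recovered volumes.
* `alpha_ml_per_g` (default 0.19 mL/g): the specific refraction increment
  converting integrated optical path difference to dry mass,
  $\mathrm{DM} = \frac{\lambda}{2\pi\alpha} \sum \varphi\, p^2$ with $p$ the
  pixel pitch. In these units 1 mL/g equals 1 µm³/pg, so the result is in
  picograms.

An off-axis hologram superposes the object wave with a tilted reference,
$I = B\,[1 + m\cos(2\pi(f_x x + f_y y) + \varphi)]$. The default carrier
$(f_x, f_y) = (0.2, 0.1)$ cycles/px is far enough from DC to be resolved by
a 12 px window and comfortably below Nyquist.

## Demodulation

`demodulate_lse()` fits, at every pixel, the local three-parameter model
$I \approx a + c\cos\psi + s\sin\psi$ with $\psi = 2\pi(f_x x + f_y y)$ over
a centred 12 × 12 px window by linear least squares and reports
$\varphi = \operatorname{atan2}(-s, c)$, wrapped to $(-\pi, \pi]$. Design
choices:

* **The carrier is supplied externally** (normally from
  `estimate_carrier()`, which interpolates the spectral peak to sub-pixel
  precision), not refitted per window: a 12 px window is too small for a
  stable joint frequency-and-phase fit.
* **The sign convention** $\varphi = \operatorname{atan2}(-s, c)$ makes
  increasing optical thickness increase $\varphi$ under the forward model of
  `synthesize_hologram()`.
* **Borders are handled by window clipping**, never by padding: padding
  would invent fringes. The normal equations reduce to nine sliding box
  sums, evaluated with integral images, so the whole fit is vectorised; a
  window whose fringe basis is numerically singular (a flat corner, say)
  yields phase 0 with quality 0 rather than noise.
* The per-pixel **quality** is $1 -$ the normalised fit residual, and later
  selects the unwrapping seed.

`demodulate_fourier()` — conjugate-carrier multiplication, a raised-cosine
radial low-pass of the recentred +1 order (passband up to 0.5 of the carrier
modulus, rolled off to 0.9), inverse transform, argument — is deliberately a
*different* algorithm. The two demodulators cross-validate each other in the
tests; spectral leakage makes the Fourier route slightly less accurate near
image borders, which is why its checks evaluate the interior.

## Unwrapping

`compute_residues()` sums the four wrapped differences around every 2 × 2
loop; sums of $\pm 2\pi$ mark residues. `place_branch_cuts()` implements the
classic box-grow pairing: the search box around an unbalanced residue
doubles in radius until it contains an opposite unbalanced charge or the
border is nearer, and the straight rasterised segment is added to the cut
mask. The variant is deliberately the plain nearest-neighbour one — no
quality-guided hybrid — and both the seed pixel (highest demodulation
quality, else the image centre) and the integration order (breadth-first
flood fill, implemented in C++) are deterministic, so identical inputs give
identical unwrapped surfaces. Pixels lying on cuts are assigned a value from
an unwrapped neighbour afterwards but stay flagged invalid in `valid_mask`;
cells whose mask overlaps invalid pixels are excluded from feature
extraction rather than silently measured. `itoh_unwrap()` (cumulative row /
column unwrapping) is kept as an exact oracle and *enforces* its
residue-free precondition, so it cannot be misused where it is not valid.

The global phase offset is not fixed here: `subtract_background()` removes
the empty-field reference, a robust plane (least squares on the
lowest-quartile pixels), and shifts the background mode to zero. Aberration
correction beyond a plane is out of scope by design: the modelled instrument
subtracts an empty-field phase.

## Segmentation

Phase images of adherent cells have a near-bimodal histogram (background
near 0 vs. cell), but the background bin dominates and plain Otsu then
over-thresholds optically tall cells. `segment_cells()` therefore uses
hysteresis: Otsu (never below the 0.3 rad floor) defines *seed* regions,
the 0.3 rad floor defines the *support*, and a cell is a support component
containing a seed. 0.3 rad is six standard deviations above the default
synthetic speckle level. Then 3 × 3 opening, hole filling, optional
watershed on the distance transform (tolerance 0.3 × the maximum distance,
so shallow boundary dimples do not fragment single cells while a pronounced
neck still splits), an area floor of 50 µm², and optional exclusion of
border-touching cells, whose area and volume would be truncated. Whether
touching cells are split or merged is a configuration switch
(`split_touching`), since either convention is defensible for monolayer
monitoring.

## Features

`qpi_features()` computes all moments over in-mask pixels. Unit conventions
worth stating explicitly:

* Before any surface or sphericity computation the phase is converted to
  optical path difference $z = \varphi \lambda / 2\pi$ (µm) so both axes of
  the surface share units. `v_phase` is reported in rad·µm² (the quantity
  proportional to dry mass) and `v_opd_um3` in µm³.
* The **top surface** is the area of the piecewise-linear graph of $z$ over
  the mask. Two boundary conventions are implemented: `"rim"` (default) ends
  the surface at the boundary rim — no skirt down to $z = 0$, so a flat
  pancake has top surface exactly equal to its projected area — and
  `"closed"` triangulates boundary cells down to the zero level, which is
  the right convention for steep-edged bodies (a hemisphere's flank) whose
  graph has a near-vertical zone inside the last pixel ring. The membrane
  area adds the projected (attachment) area; sphericity
  $\psi = \pi^{1/3}(6V)^{2/3}/S$ is normalised so a sphere gives exactly 1.
* **Kurtosis is Pearson** (normal → 3), variance is the population second
  central moment; a zero-variance phase distribution returns kurtosis and
  skewness 0 with a `degenerate_phase` flag instead of NaN.
* Eccentricity derives from the mask's second central moments with the
  $p^2/12$ per-pixel correction, which makes rectangle and disk moments
  match their continuous values.

`amplitude_features()` is the bright-field baseline: everything computable
from the binary mask alone. The perimeter uses a 4-direction Cauchy–Crofton
intercept estimator (a raw boundary-pixel count overestimates a disk's
perimeter by ~27%); solidity compares against the convex hull of pixel
centres dilated by half a pixel, without which a perfect disk would score
below 1 for purely digital reasons.

## Morphology and its errors

`height_map()` inverts the physical model (negative phase clipped to zero,
with the clipped fraction reported); `morphology_summary()` gives mean
height, volume and membrane surface. `relative_errors()` computes per-cell
signed relative errors against reference morphology and splits them into a
systematic component (cohort mean) and a random component (cohort sd), with
Figure-style histograms (default 10 bins over ±40%). The reference here is
phantom ground truth: a confocal reference stack is instrument-bound and out
of scope, but the error-analysis *procedure* is preserved, and the tests
drive it with the two mechanisms that dominate in practice — correlated
phase speckle (which ripples the recovered surface and systematically
inflates membrane area) and refractive-contrast misspecification (volume
errors of $-\delta(\Delta n)/\Delta n$ to first order).

## Classifiers

"Quadratic kernel" is read as the polynomial kernel of degree 2 (`coef0 = 1`,
one-vs-one multiclass) on z-scored features; "cubic distance" as Minkowski
$p = 3$. Hyperparameters the underlying study leaves unstated are explicit
configuration with defaults chosen once: SVM cost 1, $k = 7$ neighbours,
200 trees. The distance-weighted k-NN (weights $1/d$) with cosine and
Minkowski-3 metrics is implemented in the package because no installed
library offers that combination; SVMs come from e1071 and the random forest
from randomForest, with a SAMME AdaBoost on shallow rpart trees as the
second ensemble option. Dry mass is an affine rescaling of `v_phase`, which
standardisation absorbs; the feature table carries both, and classification
uses `dm_pg` alongside the ten optical parameters.

`split_train_test()` stratifies by the joint (line, state) label at a 20%
test fraction. `feature_subset_analysis()` evaluates nested prefixes of a
feature ranking on one fixed split, and computes a greedy-forward ranking
when none is given — the accuracy-vs-subset-size curve mirrors how much each
parameter contributes. `classify_time_series()` chains segmentation,
feature extraction and state prediction per timepoint and reports counts
and fractions, leaving timepoints with no detected cells as missing rather
than inventing zeros.

## The synthetic-data generator

`make_cell_phantom()` builds superellipsoid-cap bodies
$h = h_0 (1 - \rho_e^{\,q})^{1/2}$ on an elliptical support, with
archetypes per state: live cells are spread moderate domes ($q = 3.5$),
apoptotic cells are compact, tall, rounded caps ($q = 2$, radius halved,
height ×2.8) carrying 4–8 Gaussian blebs, and necrotic cells are broad, low,
flat-topped ($q = 8$) with strong multiplicative surface texture. Cell lines
differ in footprint, height and elongation (3T3 markedly eccentric with
aspect 0.5); radii and heights are log-normal with CVs of 12% and 8%. The
class table was calibrated once so that the nine classes are separable
primarily through *optical* parameters — lines differ mainly in thickness
and density, with strongly overlapping footprints — because that is the
regime in which phase imaging earns its keep over bright-field morphology;
it is also why the mask-only baseline features trail the QPI features on
this data. Texture and speckle (correlated Gaussian fields, correlation
length 2 px, $\sigma$ = 0.05 rad by default) are generated on a 3×
supersampled grid from which the pixel raster is the exact centre subsample,
so the ground truth (volume, mean height, surface area integrated on the
fine grid) and the sampled image describe the same realised surface.

What the generator does **not** emulate: diffraction and defocus (the
forward model is a pure projection), shot-noise statistics tied to intensity
(noise is additive Gaussian), subcellular refractive-index structure,
cell-to-cell contact in the single-cell dataset, and motility between
timepoints of a monitoring series. Passing tests therefore demonstrate that
the *pipeline* is correct and that class-separable optical signatures are
recovered end-to-end — not that real HeLa cultures will yield the same
accuracies.

The treatment-series simulator shifts the state mixture linearly between
endpoints with largest-remainder rounding, so the *composition* of each
frame is deterministic while individual cell shapes remain random; recovered
fraction curves can thus be compared against exact per-frame truth.

## Numerical choices and problem sizes

* Wrapping maps to $(-\pi, \pi]$ throughout (the closed end at $+\pi$).
* The LSE window default is 12 px; windows are clipped at borders.
* Residue loop sums are compared to $\pm 2\pi$ by rounding, immune to
  $10^{-9}$-level float noise.
* The default validation sizes — a 512² frame for the holography loop, 50
  cells per class (450 total) for the classification experiment, 50-cell
  Monte-Carlo cohorts for the error analysis, 13 timepoints × 16 cells for
  the dynamics — were chosen as the smallest sizes at which the statistical
  checks (moment tolerances, accuracy bounds, rank correlations) are stable
  across seeds.
* Phase rasters are written as 32-bit TIFF normalised to [0, 1] with the
  scale recorded in a JSON sidecar, restoring values exactly on read.

## Known limitations

* The Goldstein cut placement is the classic greedy pairing; pathological
  residue constellations can produce longer cuts than a global optimiser
  would, and heavily residue-laden inputs (strong speckle at low fringe
  contrast) will lose valid area.
* The `"rim"` surface convention underestimates the membrane area of bodies
  with near-vertical flanks; use `"closed"` for such geometry. Real
  segmented cells sit between the two conventions, closer to `"rim"`.
* Morphology is only as good as $\Delta n$: a 0.01 misspecification of
  `n_cell` moves volumes by ~23% at the default contrast. That sensitivity
  is a property of single-wavelength QPI, not of the implementation.
* The classifiers are deliberately shallow (no learned representations);
  with overlapping class distributions their accuracy is bounded by the
  feature set, as the bright-field baseline illustrates.
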