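# holocell

Label-free cytometry from quantitative phase imaging (QPI): **holocell**
implements the full computational pipeline of an off-axis digital holographic
microscope, from the raw interferogram to the classification of individual
cells by line (HeLa / A549 / 3T3) and physiological state (live / apoptotic /
necrotic), including the time-resolved fractions of dying cells after a
cytotoxic treatment. It is aimed at researchers who study cell death and
drug response with digital holographic or other quantitative phase
microscopes and want a fully scriptable, testable analysis chain.

Because no public experimental dataset accompanies this problem, the package
ships a first-class synthetic-data generator: parametric adherent-cell
phantoms with closed-to-numerical ground-truth morphology, their projection
to phase images, and off-axis hologram synthesis. Every stage of the
pipeline can therefore be validated against known truth.

## The pipeline

1. **Demodulation** — an off-axis hologram
   `I = B (1 + m cos(2π(fx·x + fy·y) + φ))` is demodulated by a windowed
   least-squares fit of the local three-parameter fringe model
   `I ≈ a + c·cos ψ + s·sin ψ` over a scanning 12 × 12 px window
   (`demodulate_lse()`), giving the wrapped phase `φ = atan2(−s, c)`.
   An independent Fourier sideband method (`demodulate_fourier()`) serves as
   a cross-check, and `estimate_carrier()` locates the carrier sub-pixel.
2. **Unwrapping** — Goldstein's branch-cut algorithm: residue detection on
   2 × 2 loops (`compute_residues()`), nearest-neighbour cut placement
   (`place_branch_cuts()`), and flood-fill integration that never crosses a
   cut (`goldstein_unwrap()`); `itoh_unwrap()` is the exact oracle for
   residue-free fields. Empty-field background subtraction and plane removal
   follow (`subtract_background()`).
3. **Segmentation** — hysteresis thresholding (Otsu seed over a 0.3 rad
   support floor), morphological cleanup, optional watershed splitting
   (`segment_cells()`).
4. **Features** — the 10-parameter optical feature vector per cell
   (`qpi_features()`): average phase shift φ_av, phase volume
   V_phase = Σφ·p² (proportional to dry mass
   `DM = λ/(2πα) · Σφ·p²`, `dry_mass()`), projected area S_pr, top phase
   surface area, phase membrane area, phase sphericity
   `ψ = π^(1/3) (6V)^(2/3) / S`, variance / kurtosis (Pearson, normal → 3) /
   skewness of the in-cell phase, and eccentricity — plus a 7-parameter
   bright-field baseline computed from the mask alone
   (`amplitude_features()`).
5. **Morphology** — under the constant-refractive-index assumption the
   height map is `h = φ·λ / (2π (n_cell − n_medium))` (`height_map()`), from
   which mean height, volume and membrane surface area are summarised
   (`morphology_summary()`) and compared against reference morphology as
   signed relative errors with systematic (mean) and random (sd) components
   (`relative_errors()`).
6. **Classification** — SVM (quadratic/cubic polynomial, linear, Gaussian
   kernels), distance-weighted k-NN (cosine or Minkowski p = 3), and
   decision-tree ensembles (Breiman random forest, SAMME AdaBoost) on the
   feature tables (`train_classifier()`, `evaluate()`), feature-importance
   progression over nested subsets (`feature_subset_analysis()`), and
   per-timepoint live/apoptotic/necrotic fractions for monitoring series
   (`classify_time_series()`).

All tabular results are tibbles; fitted models and reports have `tidy()` /
`glance()` methods and every result type has an `autoplot()`.

## Worked example

Simulate one apoptotic HeLa cell, record its hologram, reconstruct and
measure it:

```r
library(holocell)
oc <- optical_constants()              # 633 nm, n_cell 1.380, n_medium 1.337
cell <- make_cell_phantom("HeLa", "apoptotic", seed = 7)
truth <- phantom_to_phase(cell, oc)
holo  <- synthesize_hologram(truth, carrier_spec(), noise_sigma = 20, seed = 7)
wrapped <- demodulate_lse(holo, estimate_carrier(holo), window_px = 12)
phase <- subtract_background(goldstein_unwrap(wrapped, cell$pixel_pitch_um))
seg   <- segment_cells(phase)
extract_features(phase, seg, oc)[, c("phi_av", "s_pr", "psi", "dm_pg")]
#> # A tibble: 1 × 4
#>   phi_av  s_pr   psi dm_pg
#>    <dbl> <dbl> <dbl> <dbl>
#> 1   1.95  234. 0.132  242.
morphology_summary(height_map(phase, seg$labels == 1, oc))
#> # A tibble: 1 × 4
#>    h_av volume s_surf  s_pr
#>   <dbl>  <dbl>  <dbl> <dbl>
#> 1  4.57  1070.   602.  234.
cell$true_volume
#> [1] 1180.5
```

The cell reads as optically dense (mean phase 1.95 rad, dry mass ≈ 242 pg)
with a small footprint (234 µm²) — the apoptotic signature. The recovered
volume (1070 µm³) sits 9% below the phantom's ground truth because
segmentation at the 0.3 rad support floor trims the thin rim, a bias the
`relative_errors()` machinery quantifies cohort-wide.

A full classification experiment:

```r
ds    <- make_labeled_dataset(synthetic_dataset_spec(n_cells_per_class = 50,
                                                     seed = 1))
feats <- dataset_features(ds)
split <- split_train_test(feats, 0.2, seed = 101)
model <- train_classifier(split$train, classifier_spec("svm", "quadratic"),
                          task = "9class",
                          feature_names = c(qpi_feature_names(), "dm_pg"))
evaluate(model, split$test)        # 9-class accuracy on held-out cells
```

A thin command-line dispatcher over the same functions is installed at
`inst/cli/holocell.R` (subcommands `simulate`, `reconstruct`, `unwrap`,
`segment`, `features`, `morphology`, `train`, `evaluate`, `dynamics`).

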