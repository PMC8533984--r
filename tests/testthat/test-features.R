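test_that("constant disk gives exact mean, zero variance, round shape", {
  mask <- disk_mask(128, 50)
  ph <- matrix(0, 128, 128); ph[mask] <- 1.0
  pim <- phase_image(ph, 0.5)
  f <- qpi_features(pim, mask)
  expect_equal(f$phi_av, 1.0, tolerance = 1e-9)
  expect_lt(f$var_phi, 1e-12)
  expect_true(f$degenerate_phase)
  expect_equal(f$kurtosis_phi, 0)      # degenerate-distribution convention
  expect_lt(f$eccentricity, 0.05)
  # definitional identity
  expect_equal(f$s_membr, f$s_top_surf + f$s_pr, tolerance = 1e-12)
  expect_equal(f$s_pr, sum(mask) * 0.25, tolerance = 1e-12)
})

test_that("phase moments match their sampling distributions", {
  set.seed(2024)
  mask <- matrix(TRUE, 100, 100)
  ph <- matrix(rnorm(1e4), 100, 100)
  f <- qpi_features(phase_image(ph, 0.5), mask)
  expect_equal(f$kurtosis_phi, 3, tolerance = 0.15 / 3)
  expect_lt(abs(f$skewness_phi), 0.1)
  expect_equal(f$var_phi, mean((ph - mean(ph))^2), tolerance = 1e-12)
})

test_that("features scale correctly with phase amplitude", {
  ds <- small_dataset()
  oc <- optical_constants()
  pim <- ds$phase[[3]]; mask <- ds$phantom[[3]]$mask
  f1 <- qpi_features(pim, mask, oc)
  pim2 <- pim; pim2$phase <- 2.5 * pim$phase
  f2 <- qpi_features(pim2, mask, oc)
  expect_equal(f2$phi_av, 2.5 * f1$phi_av, tolerance = 1e-12)
  expect_equal(f2$v_phase, 2.5 * f1$v_phase, tolerance = 1e-12)
  expect_equal(f2$s_pr, f1$s_pr)
  expect_equal(f2$eccentricity, f1$eccentricity)
  expect_equal(dry_mass(pim2, mask, oc), 2.5 * dry_mass(pim, mask, oc),
               tolerance = 1e-12)
})

test_that("sphericity is bounded by the sphere", {
  ds <- small_dataset()
  oc <- optical_constants()
  for (k in seq_len(nrow(ds))) {
    f <- qpi_features(ds$phase[[k]], ds$phantom[[k]]$mask, oc)
    expect_lte(f$psi, 1.02)
    expect_gt(f$psi, 0)
  }
  # hemisphere completed to a full sphere reaches psi = 1
  r <- 10
  hp <- hemisphere_phantom(r, pixel_pitch_um = 0.1)
  oc2 <- optical_constants()
  pim <- phantom_to_phase(hp, oc2)
  # express the surface in OPD units equal to physical height
  pim$phase <- hp$height_map * 2 * pi / wavelength_um(oc2)
  f <- qpi_features(pim, hp$mask, oc2, surface_boundary = "closed")
  psi_sphere <- sphericity(2 * f$v_opd_um3, 2 * f$s_top_surf)
  expect_equal(psi_sphere, 1.0, tolerance = 0.02)
})

test_that("top surface converges under grid refinement", {
  # a smooth (gaussian-profile) dome: no vertical tangent at the rim
  sp <- list(profile = "gaussian", radius_um = 6, height_um = 5, pexp = 2,
             aspect = 1, theta = 0, blebs = NULL, texture = NULL)
  oc <- optical_constants()
  f_at <- function(pitch) {
    hp <- make_cell_phantom("HeLa", "live", shape_params = sp,
                            pixel_pitch_um = pitch)
    qpi_features(phantom_to_phase(hp, oc), hp$mask, oc)
  }
  f_coarse <- f_at(0.2)
  f_fine <- f_at(0.1)
  expect_lt(abs(f_fine$s_top_surf - f_coarse$s_top_surf) / f_fine$s_top_surf,
            0.01)
})

test_that("amplitude features recover disk and rectangle geometry", {
  mask <- disk_mask(128, 50)
  f <- amplitude_features(mask, 0.5)
  expect_equal(f$amp_circularity, 1.0, tolerance = 0.05)
  expect_gte(f$amp_solidity, 0.98)
  expect_lte(f$amp_solidity, 1)
  expect_lt(f$amp_eccentricity, 0.05)
  expect_equal(f$amp_p_pr, 2 * pi * 50 * 0.5, tolerance = 0.05 * 2 * pi * 25)
  # 100 x 20 px rectangle: axis ratio 5, eccentricity sqrt(1 - 1/25)
  rect <- matrix(FALSE, 120, 140)
  rect[11:30, 21:120] <- TRUE
  fr <- amplitude_features(rect, 1)
  expect_equal(fr$amp_major_axis_um / fr$amp_minor_axis_um, 5.0,
               tolerance = 0.04)
  expect_equal(fr$amp_eccentricity, sqrt(1 - 1 / 25), tolerance = 0.01)
  # single-row mask is degenerate
  line <- matrix(FALSE, 20, 20); line[10, 3:18] <- TRUE
  expect_error(amplitude_features(line, 1), "degenerate")
})

test_that("dry mass follows the unit-checked conversion", {
  oc <- optical_constants(wavelength_nm = 633, alpha_ml_per_g = 0.19)
  mask <- matrix(TRUE, 20, 20)
  ph <- matrix(2, 20, 20)                       # 2 rad over 100 um^2
  pim <- phase_image(ph, 0.5, wavelength_nm = 633)
  dm <- dry_mass(pim, mask, oc)
  # hand calculation: 0.633 um * 200 rad um^2 / (2 pi * 0.19 um^3/pg)
  expect_equal(dm, 0.633 * 200 / (2 * pi * 0.19), tolerance = 1e-9)
  expect_equal(dm, 106.05, tolerance = 0.001)
  # zero phase -> zero mass; alpha doubling halves mass
  expect_equal(dry_mass(phase_image(ph * 0, 0.5), mask, oc), 0)
  oc2 <- optical_constants(alpha_ml_per_g = 0.38)
  expect_equal(dry_mass(pim, mask, oc2), dm / 2, tolerance = 1e-12)
})

test_that("tiny masks and invalid phase are rejected", {
  pim <- phase_image(matrix(1, 16, 16), 0.5)
  small <- matrix(FALSE, 16, 16); small[8, 8:10] <- TRUE
  expect_error(qpi_features(pim, small), "fewer than 8")
  mask <- matrix(TRUE, 16, 16)
  bad <- pim; bad$phase[3, 3] <- Inf
  expect_error(qpi_features(bad, mask), "finite")
})

test_that("feature extraction tables are complete and labelled", {
  ds <- small_dataset()[1:6, ]
  feats <- dataset_features(ds)
  expect_true(all(c("cell_id", "line", "state", qpi_feature_names(),
                    "dm_pg", amplitude_feature_names()) %in% names(feats)))
  expect_true(all(stats::complete.cases(
    feats[, c(qpi_feature_names(), amplitude_feature_names())])))
  # truth-mask route agrees on projected area within segmentation tolerance
  ft <- dataset_features(ds, use_truth_mask = TRUE)
  shared <- intersect(feats$cell_id, ft$cell_id)
  a <- feats$s_pr[match(shared, feats$cell_id)]
  b <- ft$s_pr[match(shared, ft$cell_id)]
  expect_true(all(abs(a - b) / b < 0.25))
})
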