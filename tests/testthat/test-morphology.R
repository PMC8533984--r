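test_that("height formula converts phase to physical height", {
  oc <- optical_constants(wavelength_nm = 633, n_cell = 1.337 + 0.0633,
                          n_medium = 1.337)
  pim <- phase_image(matrix(2 * pi, 32, 32), 0.5, 633)
  hm <- height_map(pim, constants = oc)
  expect_equal(hm$height[16, 16], 10.0, tolerance = 1e-9)
  # zero in, zero out; clipping of negative phase is reported
  z <- height_map(phase_image(matrix(0, 32, 32), 0.5), constants = oc)
  expect_true(all(z$height == 0))
  neg <- phase_image(matrix(c(-1, rep(1, 99)), 10, 10), 0.5)
  hneg <- height_map(neg, constants = oc)
  expect_true(all(hneg$height >= 0))
  expect_equal(attr(hneg, "clip_fraction"), 0.01)
  bad <- optical_constants()
  bad$n_cell <- 1.2
  expect_error(height_map(pim, constants = bad), "n_cell")
})

test_that("morphology summary matches closed forms for the hemisphere", {
  r <- 10
  hp <- hemisphere_phantom(r, pixel_pitch_um = 0.1)
  hm <- structure(list(height = hp$height_map, mask = hp$mask,
                       pitch_um = hp$pixel_pitch_um), class = "height_map")
  ms <- morphology_summary(hm)
  expect_equal(ms$volume, 2 / 3 * pi * r^3, tolerance = 0.01)
  expect_equal(ms$h_av, 2 * r / 3, tolerance = 0.02)
  expect_equal(ms$volume, ms$h_av * ms$s_pr, tolerance = 1e-9)
})

test_that("flat pancake surface follows the rim-excluded convention", {
  mask <- matrix(FALSE, 30, 30); mask[6:25, 6:25] <- TRUE  # 10x10 um
  h <- matrix(0, 30, 30); h[mask] <- 2
  hm <- structure(list(height = h, mask = mask, pitch_um = 0.5),
                  class = "height_map")
  ms <- morphology_summary(hm)
  expect_equal(ms$volume, 200, tolerance = 1e-12)
  expect_equal(ms$s_surf, 200, tolerance = 1e-9)   # top 100 + base 100, no rim
  # doubling the height doubles volume and mean height exactly
  hm2 <- hm; hm2$height <- 2 * hm$height
  ms2 <- morphology_summary(hm2)
  expect_equal(ms2$volume, 2 * ms$volume)
  expect_equal(ms2$h_av, 2 * ms$h_av)
  expect_error(morphology_summary(structure(
    list(height = h, mask = mask & FALSE, pitch_um = 0.5),
    class = "height_map")), "empty")
})

test_that("relative-error analysis recovers constructed biases exactly", {
  ref <- tibble::tibble(cell_id = 1:20, h_av = runif(20, 2, 6),
                        volume = runif(20, 500, 3000),
                        s_surf = runif(20, 300, 1500))
  ident <- relative_errors(ref, ref)
  expect_true(all(abs(ident$per_cell$delta_v) < 1e-12))
  expect_true(all(ident$summary$mean_pct == 0))
  expect_true(all(ident$summary$sd_pct == 0))
  est <- ref; est$s_surf <- ref$s_surf * 1.07
  biased <- relative_errors(est, ref)
  s <- biased$summary[biased$summary$parameter == "delta_s_surf", ]
  expect_equal(s$mean_pct, 7, tolerance = 1e-9)
  expect_equal(s$sd_pct, 0, tolerance = 1e-9)
  # nonpositive reference cells are skipped with a message
  ref2 <- ref; ref2$volume[3] <- 0
  expect_message(out <- relative_errors(est, ref2), "skipped")
  expect_equal(nrow(out$per_cell), 19)
})

test_that("positive-mean surface ripple inflates the membrane area", {
  oc <- optical_constants()
  ph <- make_cell_phantom("HeLa", "live", seed = 8)
  pim <- phantom_to_phase(ph, oc)
  base <- morphology_summary(height_map(pim, ph$mask, oc))
  rip <- add_phase_speckle(pim, sigma_rad = 0.10, corr_px = 2,
                           mean_rad = 0.05, seed = 4)
  rippled <- morphology_summary(height_map(rip, ph$mask, oc))
  expect_gt(rippled$s_surf, base$s_surf)
})

test_that("volume error follows refractive-index misspecification to first order", {
  oc_true <- optical_constants(n_cell = 1.380)
  ph <- make_cell_phantom("A549", "live", seed = 9)
  pim <- phantom_to_phase(ph, oc_true)
  for (eps in c(-0.1, 0.05, 0.1)) {
    dn_used <- delta_n(oc_true) * (1 + eps)
    oc_used <- optical_constants(n_cell = 1.337 + dn_used)
    v <- morphology_summary(height_map(pim, ph$mask, oc_used))$volume
    v0 <- morphology_summary(height_map(pim, ph$mask, oc_true))$volume
    dv <- v / v0 - 1
    expect_equal(dv, 1 / (1 + eps) - 1, tolerance = 1e-9)  # exact relation
    expect_lt(abs(dv + eps), 1.5 * eps^2 + 1e-12)          # first-order term
  }
})
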