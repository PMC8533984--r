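test_that("hemisphere phantom reproduces closed-form morphology", {
  r <- 10
  hp <- hemisphere_phantom(r, pixel_pitch_um = 0.1)
  expect_lt(abs(hp$true_volume - 2 / 3 * pi * r^3) / (2 / 3 * pi * r^3), 0.005)
  expect_lt(abs(hp$true_mean_height - 2 * r / 3) / (2 * r / 3), 0.01)
  # discrete integral of the sampled height map matches the reference volume
  vol_disc <- sum(hp$height_map) * hp$pixel_pitch_um^2
  expect_lt(abs(vol_disc - hp$true_volume) / hp$true_volume, 0.005)
})

test_that("phantom generation is deterministic under a seed", {
  p1 <- make_cell_phantom("HeLa", "apoptotic", seed = 11)
  p2 <- make_cell_phantom("HeLa", "apoptotic", seed = 11)
  expect_identical(p1$height_map, p2$height_map)
  expect_identical(p1$true_volume, p2$true_volume)
  p3 <- make_cell_phantom("HeLa", "apoptotic", seed = 12)
  expect_false(identical(p1$height_map, p3$height_map))
})

test_that("unknown class labels are rejected with a clear message", {
  expect_error(make_cell_phantom("CHO", "live"), "unknown cell line")
  expect_error(make_cell_phantom("HeLa", "zombie"), "unknown cell state")
})

test_that("ground-truth volume matches the sampled raster for all classes", {
  set.seed(5)
  combos <- expand.grid(line = c("HeLa", "A549", "3T3"),
                        state = c("live", "apoptotic", "necrotic"),
                        stringsAsFactors = FALSE)
  for (k in seq_len(nrow(combos))) {
    ph <- make_cell_phantom(combos$line[k], combos$state[k])
    vol <- sum(ph$height_map) * ph$pixel_pitch_um^2
    expect_lt(abs(vol - ph$true_volume) / ph$true_volume, 0.005)
    expect_true(all(ph$height_map >= 0))
    expect_true(all(ph$height_map[!ph$mask] == 0))
    # support must not touch the grid border
    expect_false(any(ph$mask[1, ]) || any(ph$mask[nrow(ph$mask), ]) ||
                   any(ph$mask[, 1]) || any(ph$mask[, ncol(ph$mask)]))
  }
})

test_that("archetypes order as expected: phase, footprint, sphericity", {
  set.seed(7)
  oc <- optical_constants()
  per_state <- function(state, n) {
    lines <- rep(c("HeLa", "A549", "3T3"), length.out = n)
    t(vapply(seq_len(n), function(i) {
      ph <- make_cell_phantom(lines[i], state)
      pim <- phantom_to_phase(ph, oc)
      f <- qpi_features(pim, ph$mask, oc)
      c(phi_av = f$phi_av, area = f$s_pr, psi = f$psi)
    }, numeric(3)))
  }
  n <- 51
  live <- per_state("live", n)
  apop <- per_state("apoptotic", n)
  necr <- per_state("necrotic", n)
  expect_gt(mean(apop[, "phi_av"]), mean(live[, "phi_av"]))
  expect_gt(mean(live[, "area"]), mean(apop[, "area"]))
  expect_gt(mean(apop[, "psi"]), mean(necr[, "psi"]))
})

test_that("forward phase model is the exact inverse of the height map", {
  oc <- optical_constants()
  ph <- make_cell_phantom("A549", "live", seed = 3)
  pim <- phantom_to_phase(ph, oc)
  # delta_n * h = lambda  =>  phi = 2 pi
  h_2pi <- wavelength_um(oc) / delta_n(oc)
  sp <- list(profile = "cap", radius_um = 5, height_um = h_2pi, pexp = 2,
             aspect = 1, theta = 0, blebs = NULL, texture = NULL)
  flat <- make_cell_phantom("HeLa", "live", shape_params = sp,
                            pixel_pitch_um = 0.2)
  pflat <- phantom_to_phase(flat, oc)
  expect_equal(max(pflat$phase), 2 * pi, tolerance = 1e-9)
  # zero phantom -> zero phase
  z <- ph; z$height_map <- ph$height_map * 0
  expect_true(all(phantom_to_phase(z, oc)$phase == 0))
  # round trip through the height-map reconstruction
  hm <- height_map(pim, ph$mask, oc)
  expect_lt(max(abs(hm$height - ph$height_map)), 1e-9)
})

test_that("hologram synthesis produces carrier fringes and clips noise", {
  pim <- phase_image(matrix(0, 128, 128), 0.25)
  # grid-commensurate carrier: the spectrum has exactly two conjugate peaks
  h <- synthesize_hologram(pim, carrier_spec(0.25, 0.125, 0.8, 1000))
  Fm <- Mod(stats::fft(h$intensity - mean(h$intensity)))
  ord <- order(Fm, decreasing = TRUE)
  nr <- 128
  bins <- cbind((ord - 1) %% nr, (ord - 1) %/% nr)
  expect_setequal(bins[1:2, 1], c(0.125 * nr, nr - 0.125 * nr))
  expect_setequal(bins[1:2, 2], c(0.25 * nr, nr - 0.25 * nr))
  # all remaining spectral energy is negligible
  expect_lt(Fm[ord[3]] / Fm[ord[1]], 1e-9)
  # zero modulation -> constant frame
  expect_error(carrier_spec(fx = 0.2, fy = 0.1, modulation_depth = 0),
               "modulation_depth")
  h0 <- synthesize_hologram(pim, carrier_spec(0.2, 0.1, 1e-9, 500))
  expect_lt(diff(range(h0$intensity)), 1e-3)
  # carrier at/above Nyquist rejected
  expect_error(carrier_spec(0.4, 0.4), "Nyquist")
  # determinism of the noise
  h1 <- synthesize_hologram(pim, carrier_spec(), noise_sigma = 10, seed = 4)
  h2 <- synthesize_hologram(pim, carrier_spec(), noise_sigma = 10, seed = 4)
  expect_identical(h1$intensity, h2$intensity)
  expect_true(all(h1$intensity >= 0))
})

test_that("labelled dataset is balanced and reproducible", {
  spec <- synthetic_dataset_spec(n_cells_per_class = 2, seed = 9)
  ds1 <- make_labeled_dataset(spec)
  expect_equal(nrow(ds1), 18)
  counts <- table(ds1$line, ds1$state)
  expect_true(all(counts == 2))
  ds2 <- make_labeled_dataset(spec)
  expect_identical(ds1$phase[[5]]$phase, ds2$phase[[5]]$phase)
  expect_identical(ds1$phantom[[17]]$height_map, ds2$phantom[[17]]$height_map)
})

test_that("treatment series has deterministic composition and geometry", {
  fr <- simulate_treatment_series(n_timepoints = 3, n_cells = 4, seed = 2,
                                  noise = FALSE)
  expect_equal(nrow(fr), 3)
  expect_equal(fr$true_live + fr$true_apoptotic + fr$true_necrotic,
               rep(4L, 3))
  expect_equal(fr$true_live[1], 4L)        # starts fully live
  expect_gt(fr$true_necrotic[3], fr$true_necrotic[1])
  fr2 <- simulate_treatment_series(n_timepoints = 3, n_cells = 4, seed = 2,
                                   noise = FALSE)
  expect_identical(fr$phase[[2]]$phase, fr2$phase[[2]]$phase)
})
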