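## Parametric cell phantoms with ground-truth morphology, the forward phase
## model, and off-axis hologram synthesis. Every downstream stage of the
## pipeline is testable against these generators.

CELL_LINES  <- c("HeLa", "A549", "3T3")
CELL_STATES <- c("live", "apoptotic", "necrotic")

# run code under a temporary RNG state; NULL seed = use ambient stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Default per-class phantom shape distributions
#'
#' One row per (line, state) pair. Cell lines differ in overall footprint,
#' dome height and elongation (3T3 fibroblasts are markedly eccentric);
#' states modulate the archetype: live cells are smooth spread domes,
#' apoptotic cells are compact tall rounded caps carrying small blebs, and
#' necrotic cells are broad, low, flat-topped and irregular. Radii and
#' heights are drawn log-normally with the stated coefficient of variation.
#'
#' @return A tibble with one row per (line, state) combination.
#' @export
class_parameter_table <- function() {
  lines <- tibble::tibble(
    line = CELL_LINES,
    base_radius_um = c(14, 15.5, 13),
    base_height_um = c(2.8, 1.9, 3.8),
    base_aspect    = c(0.72, 0.80, 0.50)
  )
  states <- tibble::tibble(
    state = CELL_STATES,
    radius_mult  = c(1.00, 0.50, 1.45),
    height_mult  = c(1.00, 2.80, 0.80),
    pexp         = c(3.5, 2.0, 8.0),
    aspect_override = c(NA, 0.90, NA),
    n_blebs_min  = c(0L, 4L, 0L),
    n_blebs_max  = c(0L, 8L, 0L),
    bleb_sigma_um = c(0, 1.0, 0),
    bleb_amp_um   = c(0, 1.2, 0),
    texture_amp   = c(0.05, 0.08, 0.15),
    texture_scale_um = c(4, 2, 3)
  )
  out <- tidyr::crossing(lines, states)
  out$radius_um <- out$base_radius_um * out$radius_mult
  out$height_um <- out$base_height_um * out$height_mult
  out$aspect <- ifelse(is.na(out$aspect_override), out$base_aspect,
                       out$aspect_override)
  out$radius_cv <- 0.12
  out$height_cv <- 0.08
  out$noise_sigma_rad <- 0.05
  dplyr::select(out, "line", "state", "radius_um", "radius_cv", "height_um",
                "height_cv", "pexp", "aspect", "n_blebs_min", "n_blebs_max",
                "bleb_sigma_um", "bleb_amp_um", "texture_amp",
                "texture_scale_um", "noise_sigma_rad")
}

# draw one concrete shape-parameter set from the class table
draw_shape_params <- function(line, state, table = class_parameter_table()) {
  row <- table[table$line == line & table$state == state, ]
  stopifnot(nrow(row) == 1L)
  rlnorm1 <- function(mean, cv) {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(1, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
  }
  radius <- rlnorm1(row$radius_um, row$radius_cv)
  height <- rlnorm1(row$height_um, row$height_cv)
  aspect <- min(0.98, max(0.25, row$aspect * stats::rnorm(1, 1, 0.06)))
  theta  <- stats::runif(1, 0, pi)
  n_blebs <- if (row$n_blebs_max > 0)
    sample(row$n_blebs_min:row$n_blebs_max, 1) else 0L
  blebs <- NULL
  if (n_blebs > 0) {
    rho <- stats::runif(n_blebs, 0.25, 0.60)
    ang <- stats::runif(n_blebs, 0, 2 * pi)
    a <- radius; b <- radius * aspect
    # positions in unrotated ellipse frame
    blebs <- tibble::tibble(
      x = rho * a * cos(ang), y = rho * b * sin(ang),
      sigma = row$bleb_sigma_um * stats::runif(n_blebs, 0.7, 1.3),
      amp = row$bleb_amp_um * stats::runif(n_blebs, 0.7, 1.3)
    )
  }
  texture <- NULL
  if (row$texture_amp > 0) {
    texture <- list(amp = row$texture_amp,
                    scale_um = row$texture_scale_um,
                    seed = sample.int(.Machine$integer.max, 1))
  }
  list(profile = "cap", radius_um = radius, height_um = height,
       pexp = row$pexp, aspect = aspect, theta = theta,
       blebs = blebs, texture = texture)
}

# analytic height function h(x, y) in um; x, y in um relative to cell center,
# in the unrotated frame handled internally via theta
phantom_height_fun <- function(sp) {
  a <- sp$radius_um
  b <- sp$radius_um * sp$aspect
  ct <- cos(sp$theta); st <- sin(sp$theta)
  support_rho <- if (identical(sp$profile, "gaussian")) 3 else 1
  function(x, y, what = c("height", "support")) {
    what <- match.arg(what)
    xr <- ct * x + st * y
    yr <- -st * x + ct * y
    rho <- sqrt((xr / a)^2 + (yr / b)^2)
    inside <- rho <= support_rho
    if (what == "support") return(inside)
    h <- numeric(length(rho))
    if (identical(sp$profile, "gaussian")) {
      h[inside] <- sp$height_um * exp(-rho[inside]^2 / 2)
    } else {
      h[inside] <- sp$height_um * sqrt(pmax(0, 1 - rho[inside]^sp$pexp))
    }
    if (!is.null(sp$blebs) && nrow(sp$blebs) > 0) {
      taper <- pmax(0, 1 - rho^2)
      bl <- numeric(length(rho))
      for (i in seq_len(nrow(sp$blebs))) {
        d2 <- (xr - sp$blebs$x[i])^2 + (yr - sp$blebs$y[i])^2
        bl <- bl + sp$blebs$amp[i] * exp(-d2 / (2 * sp$blebs$sigma[i]^2))
      }
      h <- h + bl * taper * inside
    }
    pmax(h, 0)
  }
}

# stationary Gaussian random field: unit-variance white noise smoothed by a
# Gaussian kernel of the given correlation length (cyclic FFT convolution)
smooth_noise_field <- function(nr, nc, corr_px, seed) {
  field <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  gy <- stats::dnorm(seq_len(nr) - 1 - nr %/% 2, sd = corr_px)
  gx <- stats::dnorm(seq_len(nc) - 1 - nc %/% 2, sd = corr_px)
  K <- outer(gy, gx); K <- K / sum(K)
  field <- Re(stats::fft(stats::fft(field) * stats::fft(K), inverse = TRUE)) /
    (nr * nc)
  field / stats::sd(field)
}

#' Generate a single cell phantom with ground-truth morphology
#'
#' Builds a parametric adherent-cell phantom (superellipsoid-cap body with
#' optional Gaussian blebs and multiplicative surface texture), samples it on
#' a pixel grid, and computes reference morphology (volume, mean height, top +
#' base surface area) by numerical integration of the same analytic geometry
#' on a 3x supersampled grid -- independent of the feature-extraction code
#' that is later validated against it.
#'
#' @param line Cell line label: "HeLa", "A549" or "3T3".
#' @param state Cell state label: "live", "apoptotic" or "necrotic".
#' @param shape_params Optional list overriding the random class draw:
#'   `profile` ("cap" or "gaussian"), `radius_um`, `height_um`, `pexp`,
#'   `aspect`, `theta`, `blebs`, `texture`.
#' @param pixel_pitch_um Lateral sampling (um/px).
#' @param seed Optional integer seed; identical seeds give identical phantoms.
#' @param table Class parameter table, see [class_parameter_table()].
#' @return An object of class `phantom_cell` with fields `height_map` (um),
#'   `mask`, `true_volume` (um^3), `true_mean_height` (um),
#'   `true_surface_area` (um^2, top + base), labels and the pixel pitch.
#' @examples
#' ph <- make_cell_phantom("HeLa", "live", seed = 1)
#' ph$true_volume
#' @export
make_cell_phantom <- function(line, state, shape_params = NULL,
                              pixel_pitch_um = 0.25, seed = NULL,
                              table = class_parameter_table()) {
  if (!line %in% CELL_LINES) {
    stop("unknown cell line '", line, "'; expected one of: ",
         paste(CELL_LINES, collapse = ", "))
  }
  if (!state %in% CELL_STATES) {
    stop("unknown cell state '", state, "'; expected one of: ",
         paste(CELL_STATES, collapse = ", "))
  }
  stopifnot(pixel_pitch_um > 0)
  sp <- with_seed(seed, {
    if (is.null(shape_params)) draw_shape_params(line, state, table)
    else shape_params
  })
  hfun <- phantom_height_fun(sp)
  support_r <- sp$radius_um * (if (identical(sp$profile, "gaussian")) 3 else 1)
  half <- support_r * 1.08 + 3 * pixel_pitch_um
  n <- 2L * ceiling(half / pixel_pitch_um) + 1L

  # the geometry is realised once on a 3x supersampled grid: ground truth is
  # integrated there, and the pixel raster is the exact centre subsample of
  # the same surface
  s <- 3L
  fine_pitch <- pixel_pitch_um / s
  nf <- n * s
  axf <- (seq_len(nf) - (nf + 1) / 2) * fine_pitch
  Xf <- matrix(axf, nf, nf, byrow = TRUE)  # x varies along columns
  Yf <- matrix(axf, nf, nf)                # y varies along rows
  hf <- matrix(hfun(as.vector(Xf), as.vector(Yf)), nf, nf)
  maskf <- matrix(hfun(as.vector(Xf), as.vector(Yf), what = "support"), nf, nf)
  if (!is.null(sp$texture)) {
    tx <- sp$texture$amp *
      smooth_noise_field(nf, nf, sp$texture$scale_um / fine_pitch,
                         sp$texture$seed %||% seed)
    hf <- hf * (1 + pmin(0.8, pmax(-0.8, tx)))
  }
  hf[!maskf] <- 0
  ctr <- seq(2L, nf, by = s)               # fine samples at pixel centres
  h <- hf[ctr, ctr]
  mask <- maskf[ctr, ctr]
  true_volume <- sum(hf) * fine_pitch^2
  true_area <- sum(maskf) * fine_pitch^2
  true_surface <- graph_surface_area(hf, maskf, fine_pitch,
                                     boundary = "closed") + true_area

  structure(
    list(height_map = h, mask = mask,
         true_volume = true_volume,
         true_mean_height = true_volume / true_area,
         true_projected_area = true_area,
         true_surface_area = true_surface,
         class_line = line, class_state = state,
         pixel_pitch_um = pixel_pitch_um, shape_params = sp),
    class = "phantom_cell"
  )
}

#' @export
print.phantom_cell <- function(x, ...) {
  cat(sprintf(
    "phantom_cell %s/%s %dx%d px @ %g um/px; V = %.1f um^3, h_av = %.2f um, S = %.1f um^2\n",
    x$class_line, x$class_state, nrow(x$height_map), ncol(x$height_map),
    x$pixel_pitch_um, x$true_volume, x$true_mean_height, x$true_surface_area))
  invisible(x)
}

#' Hemispherical reference phantom
#'
#' A hemisphere of radius `radius_um` (a sphere truncated at the equator),
#' for which volume (2/3) pi r^3, mean height 2r/3 and surface areas are
#' known in closed form.
#'
#' @param radius_um Sphere radius (um).
#' @param pixel_pitch_um Lateral sampling (um/px).
#' @return A `phantom_cell`.
#' @export
hemisphere_phantom <- function(radius_um = 10, pixel_pitch_um = 0.1) {
  make_cell_phantom(
    "HeLa", "apoptotic",
    shape_params = list(profile = "cap", radius_um = radius_um,
                        height_um = radius_um, pexp = 2, aspect = 1,
                        theta = 0, blebs = NULL, texture = NULL),
    pixel_pitch_um = pixel_pitch_um
  )
}

#' Forward phase model: phantom to phase image
#'
#' Projects a phantom's physical height to optical phase,
#' phi(x, y) = 2 pi (n_cell - n_medium) h(x, y) / lambda, the forward
#' counterpart of the height-map reconstruction in [height_map()].
#'
#' @param phantom A `phantom_cell`.
#' @param constants [optical_constants()].
#' @return A [phase_image()].
#' @export
phantom_to_phase <- function(phantom, constants = optical_constants()) {
  stopifnot(inherits(phantom, "phantom_cell"),
            inherits(constants, "optical_constants"))
  phi <- 2 * pi * delta_n(constants) * phantom$height_map /
    wavelength_um(constants)
  phase_image(phi, phantom$pixel_pitch_um, constants$wavelength_nm)
}

#' Correlated phase speckle
#'
#' Adds a zero-mean Gaussian random field with the given correlation length
#' to a phase matrix, emulating coherent noise on reconstructed phase maps.
#'
#' @param phase A [phase_image()] or numeric matrix.
#' @param sigma_rad Marginal standard deviation of the field (radians).
#' @param corr_px Correlation length (pixels, Gaussian kernel sigma).
#' @param mean_rad Mean level of the field (radians); positive values emulate
#'   one-sided ripple.
#' @param seed Optional seed.
#' @return Same type as the input, with the noise field added.
#' @export
add_phase_speckle <- function(phase, sigma_rad, corr_px = 2, mean_rad = 0,
                              seed = NULL) {
  mat <- if (inherits(phase, "phase_image")) phase$phase else phase
  nr <- nrow(mat); nc <- ncol(mat)
  field <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  if (corr_px > 0) {
    gy <- stats::dnorm(seq_len(nr) - 1 - nr %/% 2, sd = corr_px)
    gx <- stats::dnorm(seq_len(nc) - 1 - nc %/% 2, sd = corr_px)
    K <- outer(gy, gx)
    K <- K / sum(K)
    field <- Re(stats::fft(stats::fft(field) * stats::fft(K), inverse = TRUE)) /
      (nr * nc)
  }
  field <- field / stats::sd(field) * sigma_rad + mean_rad
  out <- mat + field
  if (inherits(phase, "phase_image")) {
    phase$phase <- out
    phase
  } else {
    out
  }
}

#' Synthesize an off-axis hologram from a phase image
#'
#' Forward model of off-axis recording:
#' I(x, y) = B (1 + m cos(2 pi (fx x + fy y) + phi(x, y))) + gaussian noise,
#' clipped at zero. The true carrier is kept in the frame's `carrier_hint`
#' for test use.
#'
#' @param phase A [phase_image()].
#' @param carrier A [carrier_spec()].
#' @param noise_sigma Additive Gaussian noise sigma in counts.
#' @param seed Optional seed for the noise.
#' @return An [interferogram()].
#' @export
synthesize_hologram <- function(phase, carrier = carrier_spec(),
                                noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(phase, "phase_image"), inherits(carrier, "carrier_spec"),
            noise_sigma >= 0)
  nr <- nrow(phase$phase); nc <- ncol(phase$phase)
  X <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  Y <- matrix(seq_len(nr) - 1, nr, nc)
  B <- carrier$background_level
  m <- carrier$modulation_depth
  I <- B * (1 + m * cos(2 * pi * (carrier$fx * X + carrier$fy * Y) +
                          phase$phase))
  if (noise_sigma > 0) {
    I <- I + with_seed(seed, matrix(stats::rnorm(nr * nc, 0, noise_sigma),
                                    nr, nc))
  }
  I[I < 0] <- 0
  interferogram(I, phase$pixel_pitch_um, phase$wavelength_nm,
                carrier_hint = carrier)
}

#' Specification of a synthetic labeled dataset
#'
#' @param n_cells_per_class Cells per (line, state) pair.
#' @param class_parameter_table Per-class shape distributions,
#'   see [class_parameter_table()].
#' @param pixel_pitch_um Lateral sampling (um/px).
#' @param noise If `TRUE`, correlated phase speckle (per-class
#'   `noise_sigma_rad`) is added to each phase image.
#' @param seed RNG seed making the dataset reproducible.
#' @return An object of class `synthetic_dataset_spec`.
#' @export
synthetic_dataset_spec <- function(n_cells_per_class = 50,
                                   class_parameter_table = NULL,
                                   pixel_pitch_um = 0.25,
                                   noise = TRUE, seed = 1) {
  if (is.null(class_parameter_table)) {
    class_parameter_table <- class_parameter_table()
  }
  stopifnot(n_cells_per_class >= 1, pixel_pitch_um > 0)
  structure(
    list(n_cells_per_class = as.integer(n_cells_per_class),
         class_parameter_table = class_parameter_table,
         pixel_pitch_um = pixel_pitch_um, noise = noise,
         seed = as.integer(seed)),
    class = "synthetic_dataset_spec"
  )
}

#' Generate a balanced labeled phantom dataset
#'
#' Draws `n_cells_per_class` phantoms for every (line, state) pair, projects
#' each to a phase image (optionally with correlated speckle noise), and
#' returns everything with ground truth attached. Stands in for an
#' experimental database of segmented single-cell phase images.
#'
#' @param spec A [synthetic_dataset_spec()].
#' @param constants [optical_constants()].
#' @return A tibble with columns `cell_id`, `line`, `state`, and list-columns
#'   `phantom` and `phase`.
#' @export
make_labeled_dataset <- function(spec = synthetic_dataset_spec(),
                                 constants = optical_constants()) {
  stopifnot(inherits(spec, "synthetic_dataset_spec"))
  classes <- unique(spec$class_parameter_table[, c("line", "state")])
  with_seed(spec$seed, {
    rows <- list()
    id <- 0L
    for (k in seq_len(nrow(classes))) {
      line <- classes$line[k]; state <- classes$state[k]
      nsig <- spec$class_parameter_table$noise_sigma_rad[
        spec$class_parameter_table$line == line &
          spec$class_parameter_table$state == state][1]
      for (i in seq_len(spec$n_cells_per_class)) {
        id <- id + 1L
        phant <- make_cell_phantom(line, state,
                                   pixel_pitch_um = spec$pixel_pitch_um,
                                   table = spec$class_parameter_table)
        phase <- phantom_to_phase(phant, constants)
        if (spec$noise && nsig > 0) {
          phase <- add_phase_speckle(phase, nsig, corr_px = 2)
        }
        rows[[id]] <- tibble::tibble(
          cell_id = id, line = line, state = state,
          phantom = list(phant), phase = list(phase))
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Simulate a photodynamic-treatment time series
#'
#' Builds one multi-cell phase frame per timepoint. The composition of states
#' shifts linearly from `mixture_start` to `mixture_end` over the series
#' (largest-remainder rounding of the expected counts, so the composition
#' itself is deterministic); individual cell shapes are random draws.
#'
#' @param n_timepoints Number of frames.
#' @param dt_min Time step between frames (minutes).
#' @param n_cells Cells per frame (placed on a jittered grid; frames contain
#'   no overlapping cells).
#' @param line Cell line used for every cell.
#' @param mixture_start,mixture_end Length-3 state mixtures
#'   (live, apoptotic, necrotic) at the first and last timepoint.
#' @param pixel_pitch_um Lateral sampling (um/px).
#' @param noise If TRUE, per-class speckle noise is added to each frame.
#' @param seed RNG seed.
#' @param constants [optical_constants()].
#' @return A tibble with columns `time_min`, `phase` (list of
#'   [phase_image()]), `true_live`, `true_apoptotic`, `true_necrotic`.
#' @export
simulate_treatment_series <- function(n_timepoints = 13, dt_min = 5,
                                      n_cells = 16, line = "HeLa",
                                      mixture_start = c(1, 0, 0),
                                      mixture_end = c(0, 0.2, 0.8),
                                      pixel_pitch_um = 0.35,
                                      noise = TRUE, seed = 1,
                                      constants = optical_constants()) {
  stopifnot(length(mixture_start) == 3, length(mixture_end) == 3,
            abs(sum(mixture_start) - 1) < 1e-9,
            abs(sum(mixture_end) - 1) < 1e-9)
  table <- class_parameter_table()
  grid_k <- ceiling(sqrt(n_cells))
  spacing <- 50                                     # um between cell centers
  fov <- grid_k * spacing + 24
  npix <- ceiling(fov / pixel_pitch_um)
  with_seed(seed, {
    out <- vector("list", n_timepoints)
    for (t in seq_len(n_timepoints)) {
      frac <- if (n_timepoints == 1) 1 else (t - 1) / (n_timepoints - 1)
      mix <- (1 - frac) * mixture_start + frac * mixture_end
      counts <- largest_remainder_round(mix * n_cells)
      states <- rep(CELL_STATES, counts)
      states <- sample(states)                       # shuffle positions
      frame <- matrix(0, npix, npix)
      centers <- expand.grid(
        gx = seq_len(grid_k), gy = seq_len(grid_k))[seq_len(n_cells), ]
      for (i in seq_along(states)) {
        phant <- make_cell_phantom(line, states[i],
                                   pixel_pitch_um = pixel_pitch_um,
                                   table = table)
        patch <- phantom_to_phase(phant, constants)$phase
        cx <- (centers$gx[i] - 0.5) * spacing + 12 +
          stats::runif(1, -2, 2)
        cy <- (centers$gy[i] - 0.5) * spacing + 12 +
          stats::runif(1, -2, 2)
        ci <- round(cy / pixel_pitch_um); cj <- round(cx / pixel_pitch_um)
        pr <- nrow(patch); pc <- ncol(patch)
        i0 <- ci - pr %/% 2; j0 <- cj - pc %/% 2
        ii <- pmax(1, i0):pmin(npix, i0 + pr - 1)
        jj <- pmax(1, j0):pmin(npix, j0 + pc - 1)
        frame[ii, jj] <- frame[ii, jj] +
          patch[ii - i0 + 1, jj - j0 + 1]
      }
      if (noise) frame <- add_phase_speckle(frame, 0.05, corr_px = 2)
      out[[t]] <- tibble::tibble(
        time_min = (t - 1) * dt_min,
        phase = list(phase_image(frame, pixel_pitch_um,
                                 constants$wavelength_nm)),
        true_live = counts[1], true_apoptotic = counts[2],
        true_necrotic = counts[3])
    }
    dplyr::bind_rows(out)
  })
}

largest_remainder_round <- function(x) {
  n <- round(sum(x))
  fl <- floor(x)
  rem <- n - sum(fl)
  if (rem > 0) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}
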