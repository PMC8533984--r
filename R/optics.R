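#' Optical constants of the imaging experiment
#'
#' Bundles the physical constants needed to convert phase to physical
#' quantities: the recording wavelength, the (assumed constant) intracellular
#' refractive index, the refractive index of the culture medium, and the
#' specific refraction increment used for the dry-mass conversion.
#'
#' @param wavelength_nm Recording light wavelength in nanometres.
#' @param n_cell Intracellular refractive index (assumed spatially constant).
#' @param n_medium Refractive index of the culture medium.
#' @param alpha_ml_per_g Specific refraction increment in mL/g
#'   (numerically equal to um^3/pg), the proportionality between integrated
#'   optical path difference and dry mass.
#'
#' @return An object of class `optical_constants`.
#' @examples
#' oc <- optical_constants()
#' delta_n(oc)
#' @export
optical_constants <- function(wavelength_nm = 633, n_cell = 1.380,
                              n_medium = 1.337, alpha_ml_per_g = 0.19) {
  stopifnot(
    is.numeric(wavelength_nm), length(wavelength_nm) == 1L, wavelength_nm > 0,
    is.numeric(n_cell), is.numeric(n_medium),
    n_cell > n_medium, n_medium > 1,
    is.numeric(alpha_ml_per_g), alpha_ml_per_g > 0
  )
  structure(
    list(wavelength_nm = wavelength_nm, n_cell = n_cell,
         n_medium = n_medium, alpha_ml_per_g = alpha_ml_per_g),
    class = "optical_constants"
  )
}

#' @export
print.optical_constants <- function(x, ...) {
  cat("Optical constants:\n")
  cat(sprintf("  wavelength      %g nm\n", x$wavelength_nm))
  cat(sprintf("  n_cell          %g\n", x$n_cell))
  cat(sprintf("  n_medium        %g (delta n = %g)\n", x$n_medium, delta_n(x)))
  cat(sprintf("  alpha           %g mL/g\n", x$alpha_ml_per_g))
  invisible(x)
}

#' Refractive-index contrast n_cell - n_medium
#' @param constants An [optical_constants()] object.
#' @return Numeric scalar.
#' @export
delta_n <- function(constants) constants$n_cell - constants$n_medium

wavelength_um <- function(constants) constants$wavelength_nm / 1000

#' Wrap phase values into (-pi, pi]
#'
#' @param x Numeric vector, matrix or array of phase values (radians).
#' @return Same shape as `x`, every value in (-pi, pi].
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi))
#' @export
wrap_phase <- function(x) {
  w <- x %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

## ---- raster containers ----------------------------------------------------

#' Construct a phase image
#'
#' The pipeline's central raster: an (unwrapped) phase map in radians on a
#' calibrated pixel grid.
#'
#' @param phase Numeric matrix of phase values (radians).
#' @param pixel_pitch_um Lateral sampling in micrometres per pixel.
#' @param wavelength_nm Recording wavelength (nm).
#' @param valid_mask Logical matrix flagging pixels carrying a trustworthy
#'   phase value (e.g. reached by the unwrapping integration). Default: all.
#' @return An object of class `phase_image`.
#' @export
phase_image <- function(phase, pixel_pitch_um, wavelength_nm = 633,
                        valid_mask = NULL) {
  stopifnot(is.matrix(phase), is.numeric(phase), pixel_pitch_um > 0)
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, nrow(phase), ncol(phase))
  }
  stopifnot(identical(dim(valid_mask), dim(phase)))
  structure(
    list(phase = phase, pixel_pitch_um = pixel_pitch_um,
         wavelength_nm = wavelength_nm, valid_mask = valid_mask),
    class = "phase_image"
  )
}

#' @export
print.phase_image <- function(x, ...) {
  rng <- range(x$phase[x$valid_mask])
  cat(sprintf(
    "phase_image %dx%d px, pitch %g um, lambda %g nm, phase in [%.3f, %.3f] rad (%.1f%% valid)\n",
    nrow(x$phase), ncol(x$phase), x$pixel_pitch_um, x$wavelength_nm,
    rng[1], rng[2], 100 * mean(x$valid_mask)))
  invisible(x)
}

#' Construct a wrapped-phase raster
#'
#' @param phase Numeric matrix with all values in (-pi, pi].
#' @param quality Optional matrix in `[0, 1]` scoring per-pixel fit quality.
#' @return An object of class `wrapped_phase`.
#' @export
wrapped_phase <- function(phase, quality = NULL) {
  stopifnot(is.matrix(phase), all(is.finite(phase)),
            all(phase > -pi - 1e-12), all(phase <= pi + 1e-12))
  if (!is.null(quality)) stopifnot(identical(dim(quality), dim(phase)))
  structure(list(phase = phase, quality = quality), class = "wrapped_phase")
}

#' Construct an interferogram frame
#'
#' @param intensity Nonnegative numeric matrix of recorded counts.
#' @param pixel_pitch_um Lateral sampling (um/px).
#' @param wavelength_nm Recording wavelength (nm).
#' @param carrier_hint Optional [carrier_spec()] with the true carrier
#'   (kept by the simulator for testing; real frames have `NULL`).
#' @return Object of class `interferogram`.
#' @export
interferogram <- function(intensity, pixel_pitch_um, wavelength_nm = 633,
                          carrier_hint = NULL) {
  stopifnot(is.matrix(intensity), all(is.finite(intensity)),
            all(intensity >= 0), nrow(intensity) >= 32, ncol(intensity) >= 32)
  structure(
    list(intensity = intensity, pixel_pitch_um = pixel_pitch_um,
         wavelength_nm = wavelength_nm, carrier_hint = carrier_hint),
    class = "interferogram"
  )
}

#' Off-axis carrier specification
#'
#' @param fx,fy Carrier spatial frequency in cycles/pixel along image columns
#'   (x) and rows (y). The modulus must lie strictly below Nyquist (0.5).
#' @param modulation_depth Fringe visibility in (0, 1].
#' @param background_level Mean intensity in counts.
#' @return Object of class `carrier_spec`.
#' @export
carrier_spec <- function(fx = 0.2, fy = 0.1, modulation_depth = 0.8,
                         background_level = 1000) {
  fmod <- sqrt(fx^2 + fy^2)
  if (!(fmod > 0 && fmod < 0.5)) {
    stop("carrier frequency must satisfy 0 < |f| < 0.5 cycles/px (Nyquist)")
  }
  stopifnot(modulation_depth > 0, modulation_depth <= 1, background_level > 0)
  structure(
    list(fx = fx, fy = fy, modulation_depth = modulation_depth,
         background_level = background_level),
    class = "carrier_spec"
  )
}

## ---- shared numerics ------------------------------------------------------

# Sliding box sum with clipped (not padded) windows, via integral image.
# For even w the window spans offsets -(w/2 - 1) .. +w/2.
box_sum <- function(m, w) {
  lo <- floor((w - 1) / 2)
  hi <- floor(w / 2)
  nr <- nrow(m); nc <- ncol(m)
  cs <- apply(m, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  cs <- rbind(0, cbind(0, cs))           # cs[i+1, j+1] = sum m[1:i, 1:j]
  i1 <- pmax(seq_len(nr) - lo, 1L); i2 <- pmin(seq_len(nr) + hi, nr)
  j1 <- pmax(seq_len(nc) - lo, 1L); j2 <- pmin(seq_len(nc) + hi, nc)
  cs[i2 + 1L, j2 + 1L, drop = FALSE] - cs[i1, j2 + 1L, drop = FALSE] -
    cs[i2 + 1L, j1, drop = FALSE] + cs[i1, j1, drop = FALSE]
}

# Area of the piecewise-linear graph z(x, y) over a pixel mask.
# boundary = "rim": each grid cell whose four corners lie in the mask
# contributes two triangles of the interpolated surface; mask pixels not
# covered by any such cell (a one-pixel boundary band) contribute their flat
# pixel area, and no skirt to z = 0 is added -- the top surface ends at the
# boundary rim. boundary = "closed": cells with at least one in-mask corner
# are triangulated too, using the out-of-mask z values (zero for a masked
# raster), so the surface descends to the zero level at the cell edge --
# appropriate for steep-edged bodies whose true surface has a near-vertical
# flank inside the last pixel ring.
graph_surface_area <- function(z, mask, pitch, boundary = c("rim", "closed")) {
  boundary <- match.arg(boundary)
  stopifnot(identical(dim(z), dim(mask)))
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 2 || nc < 2) return(sum(mask) * pitch^2)
  m00 <- mask[-nr, -nc]; m10 <- mask[-1, -nc]
  m01 <- mask[-nr, -1];  m11 <- mask[-1, -1]
  full <- if (boundary == "rim") m00 & m10 & m01 & m11 else
    m00 | m10 | m01 | m11
  z00 <- z[-nr, -nc][full]; z10 <- z[-1, -nc][full]
  z01 <- z[-nr, -1][full];  z11 <- z[-1, -1][full]
  p <- pitch
  a1 <- 0.5 * p * sqrt((z10 - z00)^2 + (z01 - z00)^2 + p^2)
  a2 <- 0.5 * p * sqrt((z01 - z11)^2 + (z10 - z11)^2 + p^2)
  tri_area <- sum(a1) + sum(a2)
  # projected coverage of the triangulated cells: each full cell covers one
  # quarter of each of its four corner pixels
  cover <- matrix(0, nr, nc)
  fullnum <- matrix(0, nr - 1, nc - 1); fullnum[full] <- 0.25
  cover[-nr, -nc] <- cover[-nr, -nc] + fullnum
  cover[-1, -nc]  <- cover[-1, -nc]  + fullnum
  cover[-nr, -1]  <- cover[-nr, -1]  + fullnum
  cover[-1, -1]   <- cover[-1, -1]   + fullnum
  flat_area <- sum((1 - cover)[mask]) * p^2
  tri_area + flat_area
}
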