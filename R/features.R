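## The ten-parameter optical (QPI) feature vector, the seven-parameter
## bright-field baseline, and the dry-mass conversion.

#' Names of the QPI feature columns
#' @return Character vector of the ten phase-derived feature names plus
#'   `dm_pg`.
#' @export
qpi_feature_names <- function() {
  c("phi_av", "v_phase", "s_pr", "s_top_surf", "s_membr", "psi",
    "var_phi", "kurtosis_phi", "skewness_phi", "eccentricity")
}

#' Names of the bright-field (amplitude) baseline feature columns
#' @return Character vector of the seven mask-derived feature names
#'   (prefixed `amp_`).
#' @export
amplitude_feature_names <- function() {
  c("amp_s_pr", "amp_p_pr", "amp_circularity", "amp_eccentricity",
    "amp_solidity", "amp_minor_axis_um", "amp_major_axis_um")
}

# eigenvalues of the second central moment matrix of mask pixel coords (um^2)
mask_moments <- function(mask, pitch) {
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2] * pitch; y <- idx[, 1] * pitch
  n <- length(x)
  cxx <- sum((x - mean(x))^2) / n + pitch^2 / 12
  cyy <- sum((y - mean(y))^2) / n + pitch^2 / 12
  cxy <- sum((x - mean(x)) * (y - mean(y))) / n
  tr <- cxx + cyy
  dt <- cxx * cyy - cxy^2
  disc <- sqrt(max(0, (tr / 2)^2 - dt))
  c(lmax = tr / 2 + disc, lmin = tr / 2 - disc)
}

mask_eccentricity <- function(mask, pitch) {
  l <- mask_moments(mask, pitch)
  if (l["lmax"] <= 0) return(0)
  e <- sqrt(max(0, 1 - l["lmin"] / l["lmax"]))
  unname(min(e, 1 - 1e-9))
}

#' Sphericity index
#'
#' psi = pi^(1/3) (6 V)^(2/3) / S: the surface-normalised shape index, equal
#' to 1 for a sphere and below 1 for any other body.
#'
#' @param volume Volume (um^3).
#' @param surface Total surface area (um^2).
#' @return Numeric scalar.
#' @export
sphericity <- function(volume, surface) {
  pi^(1 / 3) * (6 * volume)^(2 / 3) / surface
}

#' Ten-parameter QPI feature vector of one cell
#'
#' Computes, over the in-mask pixels of a phase image: average phase shift,
#' phase volume (rad um^2, proportional to dry mass), projected area, top
#' phase-surface and phase-membrane areas, phase sphericity, variance /
#' kurtosis / skewness of the in-cell phase distribution, and the
#' equivalent-ellipse eccentricity of the mask. Before any surface or
#' sphericity computation the phase is converted to optical path difference
#' z = phi lambda / (2 pi) (um), so lateral and axial axes share units; the
#' top surface is the triangulated graph of z over the mask (no skirt to
#' z = 0), and the membrane area adds the projected (attachment) area.
#' Kurtosis uses the Pearson convention (normal distribution -> 3), variance
#' is the population second central moment.
#'
#' @param phase A [phase_image()].
#' @param cell_mask Logical matrix selecting the cell's pixels.
#' @param constants [optical_constants()].
#' @param surface_boundary `"rim"` (default; the top surface ends at the
#'   boundary rim) or `"closed"` (boundary cells are triangulated down to the
#'   zero level, capturing the near-vertical flank of steep-edged bodies).
#' @return A one-row tibble with columns [qpi_feature_names()], `v_opd_um3`
#'   (the OPD-converted phase volume) and `degenerate_phase` (TRUE when the
#'   in-cell phase has zero variance, in which case kurtosis and skewness are
#'   reported as 0).
#' @export
qpi_features <- function(phase, cell_mask, constants = optical_constants(),
                         surface_boundary = "rim") {
  stopifnot(inherits(phase, "phase_image"), is.logical(cell_mask),
            identical(dim(cell_mask), dim(phase$phase)))
  npx <- sum(cell_mask)
  if (npx < 8) stop("cell mask has fewer than 8 pixels; moments unstable")
  phi <- phase$phase[cell_mask]
  if (!all(is.finite(phi))) stop("phase not finite on the cell mask")
  p <- phase$pixel_pitch_um
  lam <- phase$wavelength_nm / 1000
  phi_av <- mean(phi)
  m2 <- mean((phi - phi_av)^2)
  degenerate <- m2 < 1e-12
  if (degenerate) {
    kurt <- 0; skew <- 0
  } else {
    kurt <- mean((phi - phi_av)^4) / m2^2
    skew <- mean((phi - phi_av)^3) / m2^1.5
  }
  v_phase <- sum(phi) * p^2
  s_pr <- npx * p^2
  z <- matrix(0, nrow(cell_mask), ncol(cell_mask))
  z[cell_mask] <- phi * lam / (2 * pi)
  s_top <- graph_surface_area(z, cell_mask, p, boundary = surface_boundary)
  s_membr <- s_top + s_pr
  v_opd <- sum(z[cell_mask]) * p^2
  tibble::tibble(
    phi_av = phi_av, v_phase = v_phase, s_pr = s_pr,
    s_top_surf = s_top, s_membr = s_membr,
    psi = sphericity(max(v_opd, 0), s_membr),
    var_phi = m2, kurtosis_phi = kurt, skewness_phi = skew,
    eccentricity = mask_eccentricity(cell_mask, p),
    v_opd_um3 = v_opd, degenerate_phase = degenerate
  )
}

# Cauchy-Crofton perimeter from intercept counts in 4 directions
crofton_perimeter <- function(mask, pitch) {
  m <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  nr <- nrow(m); nc <- ncol(m)
  t0  <- sum(m[, -1] != m[, -nc])                    # along x (rows scanned)
  t90 <- sum(m[-1, ] != m[-nr, ])                    # along y
  t45  <- sum(m[-1, -1] != m[-nr, -nc])              # diagonal
  t135 <- sum(m[-1, -nc] != m[-nr, -1])              # antidiagonal
  (pi / 8) * (t0 + t90 + (t45 + t135) / sqrt(2)) * pitch
}

#' Seven-parameter bright-field baseline features of one cell
#'
#' Mask-only descriptors computable from a segmented amplitude (bright-field)
#' image, ignoring phase values: projected area, Crofton-estimated perimeter,
#' circularity 4 pi S / P^2, equivalent-ellipse eccentricity, solidity
#' (area over convex-hull area), and equivalent-ellipse minor/major axes.
#'
#' @param cell_mask Logical matrix selecting the cell's pixels.
#' @param pitch Pixel pitch (um/px).
#' @return A one-row tibble with columns [amplitude_feature_names()].
#' @export
amplitude_features <- function(cell_mask, pitch) {
  stopifnot(is.logical(cell_mask), pitch > 0)
  npx <- sum(cell_mask)
  if (npx < 8) stop("cell mask has fewer than 8 pixels; moments unstable")
  l <- mask_moments(cell_mask, pitch)
  if (l["lmin"] <= pitch^2 / 12 + 1e-12) stop("degenerate (line-like) cell mask")
  s_pr <- npx * pitch^2
  p_pr <- crofton_perimeter(cell_mask, pitch)
  idx <- which(cell_mask, arr.ind = TRUE)
  pts <- cbind(idx[, 2] * pitch, idx[, 1] * pitch)
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  k <- nrow(hp)
  x <- hp[, 1]; y <- hp[, 2]
  polyarea <- abs(sum(x * y[c(2:k, 1)] - x[c(2:k, 1)] * y)) / 2
  hull_perim <- sum(sqrt(diff(x[c(1:k, 1)])^2 + diff(y[c(1:k, 1)])^2))
  # dilate the pixel-centre hull by half a pixel (Minkowski sum with a disk)
  hull_area <- polyarea + 0.5 * pitch * hull_perim + pi * (pitch / 2)^2
  tibble::tibble(
    amp_s_pr = s_pr, amp_p_pr = p_pr,
    amp_circularity = 4 * pi * s_pr / p_pr^2,
    amp_eccentricity = mask_eccentricity(cell_mask, pitch),
    amp_solidity = min(1, s_pr / hull_area),
    amp_minor_axis_um = 4 * sqrt(unname(l["lmin"])),
    amp_major_axis_um = 4 * sqrt(unname(l["lmax"]))
  )
}

#' Cell dry mass from integrated phase
#'
#' DM = lambda / (2 pi alpha) * sum(phi) * pitch^2, in picograms, with the
#' specific refraction increment alpha in mL/g (= um^3/pg).
#'
#' @param phase A [phase_image()].
#' @param cell_mask Logical matrix selecting the cell's pixels.
#' @param constants [optical_constants()].
#' @return Dry mass in picograms (scalar).
#' @export
dry_mass <- function(phase, cell_mask, constants = optical_constants()) {
  stopifnot(constants$alpha_ml_per_g > 0)
  p <- phase$pixel_pitch_um
  lam <- phase$wavelength_nm / 1000
  v_phase <- sum(phase$phase[cell_mask]) * p^2
  lam / (2 * pi * constants$alpha_ml_per_g) * v_phase
}

#' Feature table for all cells of a segmented phase image
#'
#' Applies [qpi_features()], [amplitude_features()] and [dry_mass()] to every
#' labelled cell; cells flagged as containing invalid phase or failing the
#' minimum-size guard are skipped.
#'
#' @param phase A [phase_image()].
#' @param segmentation A [segment_cells()] result.
#' @param constants [optical_constants()].
#' @param image_id Provenance string stored with each row.
#' @return Tibble with one row per cell: provenance (`image_id`, `label`),
#'   the ten QPI features, `dm_pg`, `v_opd_um3`, and the seven amplitude
#'   features.
#' @export
extract_features <- function(phase, segmentation,
                             constants = optical_constants(),
                             image_id = "image") {
  stopifnot(inherits(segmentation, "segmentation_result"))
  rows <- list()
  for (k in seq_len(nrow(segmentation$cells))) {
    rec <- segmentation$cells[k, ]
    if (rec$contains_invalid_phase) next
    mask <- segmentation$labels == rec$label
    if (sum(mask) < 8) next
    qf <- qpi_features(phase, mask, constants)
    af <- amplitude_features(mask, phase$pixel_pitch_um)
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(image_id = image_id, label = rec$label),
      qf,
      tibble::tibble(dm_pg = dry_mass(phase, mask, constants)),
      af)
  }
  if (!length(rows)) {
    return(tibble::tibble())
  }
  dplyr::bind_rows(rows)
}

#' Feature table for a labelled synthetic dataset
#'
#' Runs segmentation (largest cell per single-cell image) and feature
#' extraction over a [make_labeled_dataset()] tibble, attaching the class
#' labels.
#'
#' @param dataset Tibble from [make_labeled_dataset()].
#' @param constants [optical_constants()].
#' @param config [segmentation_config()]; single-cell images keep the default.
#' @param use_truth_mask Use the phantom's ground-truth mask instead of
#'   segmenting (for isolating feature behaviour from segmentation).
#' @return Tibble of features with `cell_id`, `line`, `state` attached;
#'   cells whose segmentation fails are dropped.
#' @export
dataset_features <- function(dataset, constants = optical_constants(),
                             config = segmentation_config(exclude_border = FALSE),
                             use_truth_mask = FALSE) {
  rows <- list()
  for (k in seq_len(nrow(dataset))) {
    phase <- dataset$phase[[k]]
    if (use_truth_mask) {
      mask <- dataset$phantom[[k]]$mask
      qf <- qpi_features(phase, mask, constants)
      af <- amplitude_features(mask, phase$pixel_pitch_um)
      feats <- dplyr::bind_cols(
        qf, tibble::tibble(dm_pg = dry_mass(phase, mask, constants)), af)
    } else {
      seg <- suppressWarnings(segment_cells(phase, config))
      if (nrow(seg$cells) == 0) next
      big <- seg$cells$label[which.max(seg$cells$area_um2)]
      seg$cells <- seg$cells[seg$cells$label == big, ]
      feats <- extract_features(phase, seg, constants,
                                image_id = as.character(dataset$cell_id[k]))
      if (nrow(feats) == 0) next
      feats <- dplyr::select(feats, -"image_id", -"label")
    }
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(cell_id = dataset$cell_id[k],
                     line = dataset$line[k], state = dataset$state[k]),
      feats)
  }
  dplyr::bind_rows(rows)
}
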