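## Phase-to-height conversion under the constant-refractive-index assumption,
## 3D morphology summaries, and the relative-error analysis against reference
## morphology.

#' Height map from phase under constant intracellular refractive index
#'
#' h(x, y) = phi lambda / (2 pi (n_cell - n_medium)), with lambda in um.
#' Negative phase values inside the mask are clipped to zero; the clipped
#' fraction is reported as an attribute.
#'
#' @param phase A [phase_image()].
#' @param mask Logical matrix: cell support. Default: whole image.
#' @param constants [optical_constants()]; requires `n_cell > n_medium`.
#' @return Object of class `height_map`: list with `height` (um, zero outside
#'   the mask), `mask`, `pitch_um`; attribute `clip_fraction`.
#' @export
height_map <- function(phase, mask = NULL, constants = optical_constants()) {
  stopifnot(inherits(phase, "phase_image"))
  if (constants$n_cell <= constants$n_medium) {
    stop("n_cell must exceed n_medium")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(phase$phase), ncol(phase$phase))
  lam <- wavelength_um(constants)
  h <- phase$phase * lam / (2 * pi * delta_n(constants))
  h[!mask] <- 0
  clip_frac <- if (any(mask)) mean(h[mask] < 0) else 0
  h[h < 0] <- 0
  structure(list(height = h, mask = mask, pitch_um = phase$pixel_pitch_um),
            class = "height_map", clip_fraction = clip_frac)
}

#' Morphological summary of a height map
#'
#' Average height over the mask, volume (discrete integral), and membrane
#' surface area (triangulated top surface plus the projected base area).
#'
#' @param height A [height_map()].
#' @param surface_boundary Boundary convention for the top-surface
#'   triangulation; see [qpi_features()].
#' @return One-row tibble: `h_av` (um), `volume` (um^3), `s_surf` (um^2),
#'   `s_pr` (um^2).
#' @export
morphology_summary <- function(height, surface_boundary = "rim") {
  stopifnot(inherits(height, "height_map"))
  if (!any(height$mask)) stop("empty mask")
  p <- height$pitch_um
  hvals <- height$height[height$mask]
  s_pr <- sum(height$mask) * p^2
  vol <- sum(hvals) * p^2
  s_top <- graph_surface_area(height$height, height$mask, p,
                              boundary = surface_boundary)
  tibble::tibble(h_av = mean(hvals), volume = vol,
                 s_surf = s_top + s_pr, s_pr = s_pr)
}

#' Per-cell relative errors of morphology estimates against a reference
#'
#' Signed relative errors (%) of average height, volume and membrane surface
#' area for matched cells, with the cohort mean (systematic component),
#' standard deviation (random component) and histograms.
#'
#' @param estimated Tibble with columns `cell_id`, `h_av`, `volume`, `s_surf`
#'   (e.g. stacked [morphology_summary()] rows).
#' @param reference Tibble with the same columns holding reference values
#'   (e.g. phantom ground truth).
#' @param bins Histogram bin edges (%); default 10 bins over -40..40.
#' @return Object of class `morphology_errors`: list with `per_cell` (tibble
#'   of `delta_h_av`, `delta_v`, `delta_s_surf` in %), `summary` (tibble of
#'   mean and sd per parameter) and `histograms`.
#' @export
relative_errors <- function(estimated, reference,
                            bins = seq(-40, 40, length.out = 11)) {
  need <- c("cell_id", "h_av", "volume", "s_surf")
  stopifnot(all(need %in% names(estimated)), all(need %in% names(reference)))
  m <- dplyr::inner_join(estimated, reference, by = "cell_id",
                         suffix = c("_est", "_ref"))
  ok <- m$h_av_ref > 0 & m$volume_ref > 0 & m$s_surf_ref > 0
  if (any(!ok)) {
    message(sum(!ok), " cell(s) skipped: nonpositive reference values")
  }
  m <- m[ok, ]
  per_cell <- tibble::tibble(
    cell_id = m$cell_id,
    delta_h_av = 100 * (m$h_av_est - m$h_av_ref) / m$h_av_ref,
    delta_v = 100 * (m$volume_est - m$volume_ref) / m$volume_ref,
    delta_s_surf = 100 * (m$s_surf_est - m$s_surf_ref) / m$s_surf_ref
  )
  long <- tidyr::pivot_longer(per_cell, -"cell_id",
                              names_to = "parameter", values_to = "error_pct")
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$parameter),
    mean_pct = mean(.data$error_pct),
    sd_pct = stats::sd(.data$error_pct),
    n = dplyr::n(), .groups = "drop")
  histograms <- lapply(split(long$error_pct, long$parameter), function(v) {
    b <- bins
    if (any(v < min(b)) || any(v > max(b))) {
      b <- seq(min(min(v), min(b)), max(max(v), max(b)),
               length.out = length(bins))
    }
    graphics::hist(v, breaks = b, plot = FALSE)
  })
  structure(list(per_cell = per_cell, summary = summary,
                 histograms = histograms),
            class = "morphology_errors")
}

#' @export
print.morphology_errors <- function(x, ...) {
  cat("Relative morphology errors (%):\n")
  print(x$summary)
  invisible(x)
}
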