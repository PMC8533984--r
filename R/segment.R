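## Single-cell segmentation on unwrapped, background-subtracted phase images.

#' Segmentation configuration
#'
#' @param threshold_method `"otsu"` (Otsu's threshold on positive phase,
#'   never below `otsu_floor_rad`) or `"fixed"`.
#' @param fixed_threshold_rad Threshold (radians) used when
#'   `threshold_method = "fixed"`.
#' @param otsu_floor_rad Lower bound applied to the Otsu threshold; phase
#'   backgrounds are flat near zero, so a small absolute floor guards against
#'   degenerate histograms.
#' @param min_area_um2 Components below this area are discarded.
#' @param split_touching Split touching cells by watershed on the distance
#'   transform.
#' @param exclude_border Drop cells touching the image border (their area and
#'   volume are truncated).
#' @param fill_holes Fill interior holes of each component.
#' @return Object of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold_rad = 0.3,
                                otsu_floor_rad = 0.3,
                                min_area_um2 = 50,
                                split_touching = TRUE,
                                exclude_border = TRUE,
                                fill_holes = TRUE) {
  stopifnot(min_area_um2 > 0)
  structure(
    list(threshold_method = match.arg(threshold_method),
         fixed_threshold_rad = fixed_threshold_rad,
         otsu_floor_rad = otsu_floor_rad,
         min_area_um2 = min_area_um2,
         split_touching = split_touching,
         exclude_border = exclude_border,
         fill_holes = fill_holes),
    class = "segmentation_config"
  )
}

#' Segment single cells on a phase image
#'
#' Threshold (Otsu on positive phase by default), 3x3 morphological opening,
#' hole filling, optional watershed splitting of touching cells on the
#' distance transform, then removal of small and (optionally) border-touching
#' components. Cells overlapping invalid phase pixels are flagged.
#'
#' @param phase A background-subtracted [phase_image()] (background mode
#'   near 0).
#' @param config A [segmentation_config()].
#' @return Object of class `segmentation_result`: list with `labels`
#'   (integer matrix, 0 = background), `cells` (tibble with per-cell `label`,
#'   `area_um2`, `centroid_row`, `centroid_col`, `touches_border`,
#'   `contains_invalid_phase`), and `pixel_pitch_um`.
#' @export
segment_cells <- function(phase, config = segmentation_config()) {
  stopifnot(inherits(phase, "phase_image"),
            inherits(config, "segmentation_config"))
  ph <- phase$phase
  if (!all(is.finite(ph))) stop("phase contains non-finite values")
  p <- phase$pixel_pitch_um
  if (config$threshold_method == "otsu") {
    # hysteresis: Otsu gives the strong (seed) threshold, the floor gives the
    # weak (support) threshold; a cell is the weak region around a strong
    # seed. Plain Otsu over-thresholds optically tall cells whose histogram
    # is dominated by the zero background.
    if (max(ph) <= 0) {
      strong <- weak <- config$otsu_floor_rad
    } else {
      rng <- max(ph)
      strong <- EBImage::otsu(EBImage::Image(pmax(ph, 0) / rng),
                              range = c(0, 1)) * rng
      strong <- max(strong, config$otsu_floor_rad)
      weak <- config$otsu_floor_rad
    }
  } else {
    strong <- weak <- config$fixed_threshold_rad
  }
  bw <- ph > weak
  if (weak < strong) {
    lab <- EBImage::bwlabel(EBImage::Image(bw))
    lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(ph), ncol(ph))
    seeded <- setdiff(unique(lab[ph >= strong]), 0L)
    bw <- lab %in% seeded & bw
    dim(bw) <- dim(ph)
  }
  if (sum(bw) == 0) {
    warning("segmentation found no cells")
    return(empty_segmentation(dim(ph), p))
  }
  bw <- EBImage::opening(EBImage::Image(bw), EBImage::makeBrush(3, shape = "box"))
  if (config$fill_holes) bw <- EBImage::fillHull(bw)
  if (config$split_touching) {
    dm <- EBImage::distmap(bw)
    tol <- max(1, 0.3 * max(dm))
    labels <- EBImage::watershed(dm, tolerance = tol, ext = 1)
  } else {
    labels <- EBImage::bwlabel(bw)
  }
  labels <- matrix(as.integer(EBImage::imageData(labels)),
                   nrow(ph), ncol(ph))
  keep_and_summarize(labels, phase, config)
}

empty_segmentation <- function(dims, pitch) {
  structure(
    list(labels = matrix(0L, dims[1], dims[2]),
         cells = tibble::tibble(
           label = integer(), area_um2 = numeric(),
           centroid_row = numeric(), centroid_col = numeric(),
           touches_border = logical(), contains_invalid_phase = logical()),
         pixel_pitch_um = pitch),
    class = "segmentation_result"
  )
}

keep_and_summarize <- function(labels, phase, config) {
  p <- phase$pixel_pitch_um
  nr <- nrow(labels); nc <- ncol(labels)
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  rows <- list(); newlab <- matrix(0L, nr, nc); next_id <- 0L
  for (id in ids) {
    sel <- labels == id
    npx <- sum(sel)
    area <- npx * p^2
    if (area < config$min_area_um2) next
    idx <- which(sel, arr.ind = TRUE)
    touches <- any(idx[, 1] == 1L | idx[, 1] == nr |
                     idx[, 2] == 1L | idx[, 2] == nc)
    if (config$exclude_border && touches) next
    invalid <- any(!phase$valid_mask[sel])
    next_id <- next_id + 1L
    newlab[sel] <- next_id
    rows[[next_id]] <- tibble::tibble(
      label = next_id, area_um2 = area,
      centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]),
      touches_border = touches, contains_invalid_phase = invalid)
  }
  if (next_id == 0L) {
    warning("segmentation found no cells after filtering")
    return(empty_segmentation(c(nr, nc), p))
  }
  structure(
    list(labels = newlab, cells = dplyr::bind_rows(rows),
         pixel_pitch_um = p),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result: %d cells on %dx%d px (pitch %g um)\n",
              nrow(x$cells), nrow(x$labels), ncol(x$labels),
              x$pixel_pitch_um))
  invisible(x)
}
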