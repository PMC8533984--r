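## Raster and table input/output. Phase and height rasters travel as TIFF
## with a JSON sidecar carrying calibration and the normalisation scale
## (TIFF stores [0,1]); feature tables and reports as CSV/JSON.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a phase image as TIFF + JSON sidecar
#'
#' The raster is stored 32-bit normalised to `[0, 1]`; the sidecar records
#' `phase_min`/`phase_max` for exact restoration, plus pixel pitch and
#' wavelength.
#'
#' @param phase A [phase_image()].
#' @param path Output TIFF path; the sidecar goes next to it.
#' @return `path`, invisibly.
#' @export
write_phase_tiff <- function(phase, path) {
  stopifnot(inherits(phase, "phase_image"))
  lo <- min(phase$phase); hi <- max(phase$phase)
  scl <- if (hi > lo) (phase$phase - lo) / (hi - lo) else phase$phase * 0
  tiff::writeTIFF(scl, path, bits.per.sample = 32L)
  meta <- list(kind = "phase_image", phase_min = lo, phase_max = hi,
               pixel_pitch_um = phase$pixel_pitch_um,
               wavelength_nm = phase$wavelength_nm)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a phase image written by [write_phase_tiff()]
#' @param path TIFF path (sidecar JSON expected next to it).
#' @return A [phase_image()].
#' @export
read_phase_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  ph <- m * (meta$phase_max - meta$phase_min) + meta$phase_min
  phase_image(ph, meta$pixel_pitch_um, meta$wavelength_nm)
}

#' Write an interferogram as 16-bit TIFF + JSON sidecar
#' @param frame An [interferogram()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_interferogram_tiff <- function(frame, path) {
  stopifnot(inherits(frame, "interferogram"))
  hi <- max(frame$intensity)
  tiff::writeTIFF(frame$intensity / max(hi, 1), path, bits.per.sample = 16L)
  meta <- list(kind = "interferogram", intensity_max = hi,
               pixel_pitch_um = frame$pixel_pitch_um,
               wavelength_nm = frame$wavelength_nm)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an interferogram from TIFF/PNG plus metadata sidecar
#'
#' @param path Image path (8/16-bit grayscale TIFF or PNG).
#' @param meta_path JSON with `pixel_pitch_um` and `wavelength_nm`
#'   (default: sidecar next to the image).
#' @return An [interferogram()].
#' @export
read_interferogram <- function(path, meta_path = sidecar_path(path)) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  if (!is.null(meta$intensity_max)) m <- m * meta$intensity_max
  interferogram(m, meta$pixel_pitch_um, meta$wavelength_nm %||% 633)
}

#' Write a labelled synthetic dataset to disk
#'
#' Phase images as TIFF + sidecars, ground truth and labels as one CSV row
#' per cell, and a JSON manifest with the generating spec and seed.
#'
#' @param dataset Tibble from [make_labeled_dataset()].
#' @param dir Output directory (created if needed).
#' @param spec The [synthetic_dataset_spec()] used (stored in the manifest).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- lapply(seq_len(nrow(dataset)), function(k) {
    ph <- dataset$phantom[[k]]
    file <- sprintf("cell_%04d.tif", dataset$cell_id[k])
    write_phase_tiff(dataset$phase[[k]], file.path(dir, file))
    tibble::tibble(
      cell_id = dataset$cell_id[k], file = file,
      line = dataset$line[k], state = dataset$state[k],
      true_volume_um3 = ph$true_volume,
      true_mean_height_um = ph$true_mean_height,
      true_surface_area_um2 = ph$true_surface_area,
      pixel_pitch_um = ph$pixel_pitch_um)
  })
  utils::write.csv(dplyr::bind_rows(truth), file.path(dir, "cells.csv"),
                   row.names = FALSE)
  manifest <- list(n_cells = nrow(dataset),
                   seed = if (!is.null(spec)) spec$seed else NA,
                   n_cells_per_class = if (!is.null(spec))
                     spec$n_cells_per_class else NA,
                   pixel_pitch_um = if (!is.null(spec))
                     spec$pixel_pitch_um else NA)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write / read a feature table as CSV
#' @param features Tibble from [extract_features()] or [dataset_features()].
#' @param path CSV path.
#' @return `path` / the tibble.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Persist / restore a trained classifier
#'
#' The model is serialised as RDS with a JSON sidecar recording the spec,
#' task, feature names and training seed for provenance.
#'
#' @param model A [train_classifier()] fit.
#' @param path Output `.rds` path.
#' @return `path` / the model.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "trained_classifier"))
  saveRDS(model, path)
  meta <- list(family = model$spec$family, task = model$task,
               feature_names = model$feature_names,
               levels = model$levels, seed = model$spec$seed,
               package_version = as.character(utils::packageVersion("holocell")))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "trained_classifier"))
  model
}
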