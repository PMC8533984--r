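## Goldstein branch-cut phase unwrapping: residue detection, box-grow
## nearest-neighbour cut placement, and masked flood-fill integration, plus
## Itoh row/column unwrapping as an oracle for residue-free images.

#' Detect phase residues on the dual grid
#'
#' Sums the four wrapped phase differences counterclockwise around every
#' 2x2 pixel loop. Loops summing to +-2 pi are recorded as residues of
#' charge +1/-1; a site `(row, col)` denotes the loop whose top-left pixel is
#' `(row, col)`.
#'
#' @param wrapped A [wrapped_phase()].
#' @return Object of class `residue_map`: a tibble with columns `row`, `col`,
#'   `charge`, plus a `shape` attribute.
#' @export
compute_residues <- function(wrapped) {
  stopifnot(inherits(wrapped, "wrapped_phase"))
  ph <- wrapped$phase
  nr <- nrow(ph); nc <- ncol(ph)
  p00 <- ph[-nr, -nc]; p01 <- ph[-nr, -1]
  p11 <- ph[-1, -1];   p10 <- ph[-1, -nc]
  s <- wrap_phase(p01 - p00) + wrap_phase(p11 - p01) +
    wrap_phase(p10 - p11) + wrap_phase(p00 - p10)
  q <- round(s / (2 * pi))
  idx <- which(q != 0, arr.ind = TRUE)
  out <- tibble::tibble(
    row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
    charge = as.integer(q[idx]))
  attr(out, "shape") <- c(nr, nc)
  class(out) <- c("residue_map", class(out))
  out
}

# Bresenham rasterization between two pixel coordinates (inclusive)
raster_segment <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1L
  cbind(round(seq(r0, r1, length.out = n)),
        round(seq(c0, c1, length.out = n)))
}

#' Place Goldstein branch cuts
#'
#' Nearest-neighbour box-grow pairing: around every unbalanced residue a
#' search box is grown (radius doubling); the residue is connected by a
#' rasterised cut to the nearest opposite-charge unbalanced residue, or to
#' the image border when that is closer. Every residue ends balanced.
#'
#' @param residues A `residue_map` from [compute_residues()].
#' @param shape Optional `c(nrow, ncol)` of the image; defaults to the
#'   residue map's own shape attribute.
#' @return Object of class `branch_cut_mask`: list with `cut_pixels`
#'   (logical matrix) and `pairing` (tibble of drawn connections).
#' @export
place_branch_cuts <- function(residues, shape = attr(residues, "shape")) {
  stopifnot(!is.null(shape), length(shape) == 2)
  nr <- shape[1]; nc <- shape[2]
  cut <- matrix(FALSE, nr, nc)
  pairing <- list()
  n <- nrow(residues)
  if (n == 0) {
    return(structure(list(cut_pixels = cut,
                          pairing = tibble::tibble(
                            from_row = integer(), from_col = integer(),
                            to_row = integer(), to_col = integer(),
                            to = character())),
                     class = "branch_cut_mask"))
  }
  balanced <- rep(FALSE, n)
  rows <- residues$row; cols <- residues$col; charges <- residues$charge
  draw <- function(r0, c0, r1, c1) {
    seg <- raster_segment(r0, c0, r1, c1)
    cut[cbind(pmin(pmax(seg[, 1], 1L), nr), pmin(pmax(seg[, 2], 1L), nc))] <<- TRUE
  }
  for (i in seq_len(n)) {
    if (balanced[i]) next
    # distance to nearest border (a residue site (r,c) sits between pixels)
    bdist <- min(rows[i], cols[i], nr - rows[i], nc - cols[i])
    k <- 2L
    repeat {
      cand <- which(!balanced & charges == -charges[i])
      if (length(cand)) {
        d <- pmax(abs(rows[cand] - rows[i]), abs(cols[cand] - cols[i]))
        cand <- cand[d <= k]
        d <- d[d <= k]
      } else {
        d <- numeric()
      }
      if (length(cand) && (min(d) <= bdist)) {
        j <- cand[which.min(d)]
        draw(rows[i], cols[i], rows[j], cols[j])
        balanced[c(i, j)] <- TRUE
        pairing[[length(pairing) + 1]] <- tibble::tibble(
          from_row = rows[i], from_col = cols[i],
          to_row = rows[j], to_col = cols[j], to = "residue")
        break
      }
      if (bdist <= k) {
        # connect straight to the nearest border
        tr <- rows[i]; tc <- cols[i]
        dists <- c(rows[i], nr - rows[i], cols[i], nc - cols[i])
        side <- which.min(dists)
        if (side == 1) tr <- 1L else if (side == 2) tr <- nr
        if (side == 3) tc <- 1L else if (side == 4) tc <- nc
        draw(rows[i], cols[i], tr, tc)
        balanced[i] <- TRUE
        pairing[[length(pairing) + 1]] <- tibble::tibble(
          from_row = rows[i], from_col = cols[i],
          to_row = tr, to_col = tc, to = "border")
        break
      }
      k <- k * 2L
      if (k > 2L * max(nr, nc)) {
        stop("branch-cut placement failed to balance a residue")
      }
    }
  }
  structure(list(cut_pixels = cut, pairing = dplyr::bind_rows(pairing)),
            class = "branch_cut_mask")
}

#' Goldstein branch-cut phase unwrapping
#'
#' Detects residues, places branch cuts ([place_branch_cuts()]), then
#' integrates wrapped neighbour differences by flood fill from a seed pixel
#' (the highest-quality pixel if the input carries a quality map, else the
#' image centre), never crossing a cut. Cut pixels are afterwards assigned a
#' value from an unwrapped neighbour but stay flagged invalid, as do pixels
#' isolated by cuts.
#'
#' @param wrapped A [wrapped_phase()].
#' @param pixel_pitch_um,wavelength_nm Calibration forwarded to the output.
#' @return A [phase_image()] whose `valid_mask` marks pixels reached by the
#'   integration; on it, output minus input is a multiple of 2 pi.
#' @export
goldstein_unwrap <- function(wrapped, pixel_pitch_um = 1,
                             wavelength_nm = 633) {
  stopifnot(inherits(wrapped, "wrapped_phase"))
  ph <- wrapped$phase
  nr <- nrow(ph); nc <- ncol(ph)
  res <- compute_residues(wrapped)
  cuts <- place_branch_cuts(res, c(nr, nc))
  cut <- cuts$cut_pixels
  if (all(cut)) stop("unwrap failed: all pixels are isolated by branch cuts")
  if (!is.null(wrapped$quality)) {
    q <- wrapped$quality
    q[cut] <- -Inf
    seed <- which.max(q)
  } else {
    seed <- (nc %/% 2) * nr + nr %/% 2 + 1
    if (cut[seed]) seed <- which(!cut)[1]
  }
  resl <- .bfs_unwrap(ph, cut, as.integer(seed - 1L))
  un <- resl$unwrapped
  valid <- resl$valid
  if (!any(valid)) stop("unwrap failed: no pixel reachable from seed")
  # post-fill cut/isolated pixels from a valid 4-neighbour (flagged invalid)
  todo <- which(!valid)
  guard <- 0L
  while (length(todo) && guard < nr + nc) {
    guard <- guard + 1L
    filled <- logical(length(todo))
    for (t in seq_along(todo)) {
      idx <- todo[t]
      i <- (idx - 1L) %% nr + 1L; j <- (idx - 1L) %/% nr + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] < 1 || nb[1] > nr || nb[2] < 1 || nb[2] > nc) next
        if (valid[nb[1], nb[2]]) {
          d <- wrap_phase(ph[i, j] - ph[nb[1], nb[2]])
          un[i, j] <- un[nb[1], nb[2]] + d
          filled[t] <- TRUE
          break
        }
      }
    }
    # newly filled pixels can seed further fills but remain invalid
    newly <- todo[filled]
    if (!length(newly)) break
    valid[newly] <- TRUE
    todo <- todo[!filled]
  }
  # restore: post-filled pixels are not "reached by integration"
  final_valid <- resl$valid
  phase_image(un, pixel_pitch_um, wavelength_nm, valid_mask = final_valid)
}

#' Itoh row/column unwrapping (residue-free oracle)
#'
#' Classical cumulative unwrapping: first column, then every row. Exact up to
#' a global constant, but only defined for residue-free inputs; the
#' precondition is enforced.
#'
#' @param wrapped A [wrapped_phase()] with no residues.
#' @param pixel_pitch_um,wavelength_nm Calibration forwarded to the output.
#' @return A [phase_image()].
#' @export
itoh_unwrap <- function(wrapped, pixel_pitch_um = 1, wavelength_nm = 633) {
  stopifnot(inherits(wrapped, "wrapped_phase"))
  if (nrow(compute_residues(wrapped)) > 0) {
    stop("itoh_unwrap requires a residue-free input (oracle misuse)")
  }
  ph <- wrapped$phase
  nr <- nrow(ph); nc <- ncol(ph)
  col1 <- cumsum(c(ph[1, 1], wrap_phase(diff(ph[, 1]))))
  D <- wrap_phase(ph[, -1, drop = FALSE] - ph[, -nc, drop = FALSE])
  un <- cbind(0, t(apply(D, 1, cumsum))) + col1
  phase_image(un, pixel_pitch_um, wavelength_nm)
}
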