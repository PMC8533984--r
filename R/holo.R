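## Off-axis interferogram demodulation: carrier estimation, windowed
## least-squares phase extraction, Fourier sideband filtering (independent
## oracle), and reference-phase background subtraction.

# centered FFT frequency axis in cycles/sample
fft_freqs <- function(n) {
  f <- (seq_len(n) - 1) / n
  f[f >= 0.5] <- f[f >= 0.5] - 1
  f
}

#' Estimate the off-axis carrier of an interferogram
#'
#' Locates the dominant off-axis peak of the 2D intensity spectrum with
#' sub-pixel (quadratic) interpolation, excluding a DC neighbourhood, and
#' estimates fringe visibility from the peak/DC magnitude ratio.
#'
#' @param frame An [interferogram()].
#' @param dc_exclude_cyc Radius (cycles/px) of the DC exclusion zone.
#' @return A [carrier_spec()] with `fx > 0` (sign convention: of the two
#'   conjugate sidebands the one in the right half-plane is reported).
#' @export
estimate_carrier <- function(frame, dc_exclude_cyc = 0.04) {
  stopifnot(inherits(frame, "interferogram"))
  I <- frame$intensity
  nr <- nrow(I); nc <- ncol(I)
  Fm <- Mod(stats::fft(I - mean(I)))
  fy <- fft_freqs(nr); fx <- fft_freqs(nc)
  FR <- matrix(fy, nr, nc)
  FC <- matrix(fx, nr, nc, byrow = TRUE)
  frad <- sqrt(FR^2 + FC^2)
  half <- FC > 0 | (abs(FC) < 1e-12 & FR > 0)     # one of the two sidebands
  cand <- half & frad > dc_exclude_cyc
  noise_floor <- stats::median(Fm[cand])
  peak_val <- max(Fm[cand])
  if (!(peak_val > 5 * noise_floor) || peak_val <= 0) {
    stop("no carrier detected: off-axis spectrum shows no peak above the noise floor")
  }
  idx <- which(cand & Fm == peak_val)[1]
  pi0 <- (idx - 1) %% nr + 1
  pj0 <- (idx - 1) %/% nr + 1
  # 3-point parabolic interpolation on log magnitude, per axis
  interp <- function(vals) {
    l <- log(pmax(vals, .Machine$double.xmin))
    den <- l[1] - 2 * l[2] + l[3]
    if (abs(den) < 1e-12) 0 else {
      d <- 0.5 * (l[1] - l[3]) / den
      max(-0.5, min(0.5, d))
    }
  }
  iwrap <- function(i, n) (i - 1) %% n + 1
  di <- interp(Fm[cbind(iwrap(pi0 + c(-1, 0, 1), nr), pj0)])
  dj <- interp(Fm[cbind(pi0, iwrap(pj0 + c(-1, 0, 1), nc))])
  fy_est <- fy[pi0] + di / nr
  fx_est <- fx[pj0] + dj / nc
  dc_mag <- Mod(sum(I))
  depth <- min(1, 2 * peak_val / max(dc_mag, .Machine$double.eps))
  carrier_spec(fx = fx_est, fy = fy_est,
               modulation_depth = max(depth, 1e-3),
               background_level = mean(I))
}

#' Windowed least-squares demodulation of an off-axis interferogram
#'
#' For every pixel, fits the local three-parameter fringe model
#' I = a + c cos(psi) + s sin(psi), psi = 2 pi (fx x + fy y), by linear least
#' squares over the centred `window_px` x `window_px` neighbourhood (windows
#' are clipped at image borders, never padded) and reports
#' phi = atan2(-s, c) at the window centre, wrapped to (-pi, pi]. The sign
#' convention makes increasing optical thickness increase phi under the
#' forward model of [synthesize_hologram()]. The normal equations reduce to
#' sliding box sums, so the fit is evaluated at all pixels in a handful of
#' vectorised passes.
#'
#' @param frame An [interferogram()].
#' @param carrier A [carrier_spec()]; see [estimate_carrier()].
#' @param window_px Scanning window size in pixels (>= 4).
#' @return A [wrapped_phase()] whose `quality` is 1 minus the normalised fit
#'   residual (0 where the local normal equations are singular).
#' @export
demodulate_lse <- function(frame, carrier = NULL, window_px = 12) {
  stopifnot(inherits(frame, "interferogram"), window_px >= 4)
  if (is.null(carrier)) carrier <- estimate_carrier(frame)
  if (sqrt(carrier$fx^2 + carrier$fy^2) >= 0.5) {
    stop("carrier at or above Nyquist")
  }
  I <- frame$intensity
  nr <- nrow(I); nc <- ncol(I)
  X <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  Y <- matrix(seq_len(nr) - 1, nr, nc)
  psi <- 2 * pi * (carrier$fx * X + carrier$fy * Y)
  C <- cos(psi); S <- sin(psi)
  w <- as.integer(window_px)
  bs <- function(m) box_sum(m, w)
  N   <- bs(matrix(1, nr, nc))
  Sc  <- bs(C);      Ss  <- bs(S)
  Scc <- bs(C * C);  Sss <- bs(S * S); Scs <- bs(C * S)
  Si  <- bs(I);      Sic <- bs(I * C); Sis <- bs(I * S)
  Sii <- bs(I * I)
  # Cramer's rule on the 3x3 normal system [N Sc Ss; Sc Scc Scs; Ss Scs Sss]
  det <- N * (Scc * Sss - Scs^2) - Sc * (Sc * Sss - Scs * Ss) +
    Ss * (Sc * Scs - Scc * Ss)
  det_a <- Si * (Scc * Sss - Scs^2) - Sc * (Sic * Sss - Scs * Sis) +
    Ss * (Sic * Scs - Scc * Sis)
  det_c <- N * (Sic * Sss - Scs * Sis) - Si * (Sc * Sss - Scs * Ss) +
    Ss * (Sc * Sis - Sic * Ss)
  det_s <- N * (Scc * Sis - Sic * Scs) - Sc * (Sc * Sis - Sic * Ss) +
    Si * (Sc * Scs - Scc * Ss)
  ok <- abs(det) > 1e-8 * N^3   # Gram determinant of the basis, scale-free in I
  a <- ifelse(ok, det_a / det, 0)
  cc <- ifelse(ok, det_c / det, 0)
  ss <- ifelse(ok, det_s / det, 0)
  phi <- atan2(-ss, cc)
  rss <- pmax(0, Sii - (a * Si + cc * Sic + ss * Sis))
  tss <- pmax(0, Sii - Si^2 / N)
  quality <- ifelse(ok & tss > 1e-12, pmax(0, pmin(1, 1 - rss / tss)), 0)
  phi[!ok] <- 0
  wrapped_phase(wrap_phase(phi), quality)
}

#' Fourier-filtering demodulation (sideband method)
#'
#' Independent reference method for [demodulate_lse()]: multiplies the frame
#' by the conjugate carrier wave (shifting the +1 diffraction order to DC),
#' applies a soft radial low-pass in the Fourier domain, and takes the
#' argument of the filtered analytic signal.
#'
#' @param frame An [interferogram()].
#' @param carrier Optional [carrier_spec()]; estimated from the frame when
#'   `NULL`.
#' @return A [wrapped_phase()]; `quality` is the normalised magnitude of the
#'   filtered analytic signal.
#' @export
demodulate_fourier <- function(frame, carrier = NULL) {
  stopifnot(inherits(frame, "interferogram"))
  if (is.null(carrier)) carrier <- estimate_carrier(frame)
  I <- frame$intensity
  nr <- nrow(I); nc <- ncol(I)
  X <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  Y <- matrix(seq_len(nr) - 1, nr, nc)
  demod <- I * exp(-2i * pi * (carrier$fx * X + carrier$fy * Y))
  Fd <- stats::fft(demod)
  FR <- matrix(fft_freqs(nr), nr, nc)
  FC <- matrix(fft_freqs(nc), nr, nc, byrow = TRUE)
  frad <- sqrt(FR^2 + FC^2)
  fcn <- sqrt(carrier$fx^2 + carrier$fy^2)
  r1 <- 0.5 * fcn; r2 <- 0.9 * fcn
  H <- ifelse(frad <= r1, 1,
              ifelse(frad >= r2, 0, 0.5 * (1 + cos(pi * (frad - r1) / (r2 - r1)))))
  analytic <- stats::fft(Fd * H, inverse = TRUE) / (nr * nc)
  amp <- Mod(analytic)
  wrapped_phase(wrap_phase(Arg(analytic)), amp / max(amp))
}

#' Subtract a reference (empty-field) phase and flatten the background
#'
#' Pixelwise difference of object and reference phase, followed by a robust
#' plane fit over the lowest-phase quartile of pixels (taken as background)
#' and an offset shift placing the background mode at zero. Mirrors the
#' empty-field aberration-subtraction step of off-axis reconstruction.
#'
#' @param phase Object [phase_image()].
#' @param reference Reference [phase_image()] of identical shape, or `NULL`
#'   to only remove a plane and offset.
#' @return A background-flattened [phase_image()].
#' @export
subtract_background <- function(phase, reference = NULL) {
  stopifnot(inherits(phase, "phase_image"))
  d <- phase$phase
  if (!is.null(reference)) {
    if (inherits(reference, "phase_image")) reference <- reference$phase
    if (!identical(dim(reference), dim(d))) {
      stop("reference shape ", paste(dim(reference), collapse = "x"),
           " does not match phase shape ", paste(dim(d), collapse = "x"))
    }
    d <- d - reference
  }
  nr <- nrow(d); nc <- ncol(d)
  bg <- d <= stats::quantile(d, 0.25)
  X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  Y <- matrix(seq_len(nr), nr, nc)
  df <- data.frame(z = d[bg], x = X[bg], y = Y[bg])
  if (nrow(df) > 20000) df <- df[seq(1, nrow(df), length.out = 20000), ]
  fit <- stats::lm(z ~ x + y, data = df)
  plane <- fit$coefficients[1] + fit$coefficients[2] * X +
    fit$coefficients[3] * Y
  out <- d - plane
  # background mode -> 0
  bgvals <- out[bg]
  if (stats::sd(bgvals) < 1e-12) {
    offset <- bgvals[1]
  } else {
    dens <- stats::density(bgvals, n = 512)
    offset <- dens$x[which.max(dens$y)]
  }
  out <- out - offset
  phase_image(out, phase$pixel_pitch_um, phase$wavelength_nm,
              phase$valid_mask)
}
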