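#' Raw frame stack for one illumination band
#'
#' @param wavelength_nm integer band centre in nanometres.
#' @param frames list of integer-count grayscale matrices (repeat exposures of
#'   the same field), all of one shape.
#' @param bit_depth sensor bit depth; pixel values must lie in
#'   \[0, 2^bit_depth - 1\].
#' @return An object of class `raw_band_stack`.
#' @export
raw_band_stack <- function(wavelength_nm, frames, bit_depth = 8L) {
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) < 1L) stop("no frames")
  shp <- dim(frames[[1L]])
  maxc <- 2^bit_depth - 1
  for (f in frames) {
    if (!identical(dim(f), shp)) stop("frame shape mismatch")
    if (min(f) < 0 || max(f) > maxc) {
      stop("pixel counts must lie in [0, ", maxc, "]")
    }
  }
  structure(list(wavelength_nm = as.integer(wavelength_nm), frames = frames,
                 bit_depth = as.integer(bit_depth)),
            class = "raw_band_stack")
}

#' Dark and reference frames for reflectance calibration
#'
#' The dark frame records the sensor signal without illumination; each
#' reference frame records a blank region of the slide under one band's
#' illumination. Pixels where `reference < dark + eps` cannot support the
#' reflectance division and are flagged downstream.
#'
#' @param dark grayscale matrix of dark counts.
#' @param references named list of grayscale matrices, one per wavelength,
#'   names coercible to integer nanometres.
#' @return An object of class `calibration_frames`.
#' @export
calibration_frames <- function(dark, references) {
  shp <- dim(dark)
  if (is.null(names(references)) || anyNA(as.integer(names(references)))) {
    stop("references must be a named list, names = wavelength in nm")
  }
  for (r in references) {
    if (!identical(dim(r), shp)) stop("reference/dark shape mismatch")
  }
  structure(list(dark = dark, references = references),
            class = "calibration_frames")
}

#' Average repeat frames
#'
#' Per-pixel arithmetic mean over a group of repeat exposures; suppresses
#' random sensor noise by sqrt(number of frames).
#'
#' @param stack a [raw_band_stack()], a list of matrices, or a single matrix.
#' @return numeric matrix of mean counts (same shape as the input frames).
#' @export
average_frames <- function(stack) {
  frames <- if (inherits(stack, "raw_band_stack")) stack$frames else stack
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) < 1L) stop("no frames")
  shp <- dim(frames[[1L]])
  for (f in frames) if (!identical(dim(f), shp)) stop("frame shape mismatch")
  Reduce(`+`, frames) / length(frames)
}

#' Reflectance correction against dark and reference frames
#'
#' Computes `R = (raw - dark) / (ref - dark)` per pixel and clips to
#' \[0, 1\]. Pixels whose denominator falls below `eps` counts are unusable
#' (no effective illumination there): they are set to 0 and their count is
#' returned in the `n_flagged` attribute so [calibrate_cube()] can record
#' them in the cube provenance.
#'
#' @param raw,dark,ref grayscale count matrices of one shape.
#' @param eps minimum usable denominator, in counts.
#' @return reflectance matrix in \[0, 1\] with attribute `n_flagged`.
#' @export
#' @examples
#' reflectance_correct(matrix(150, 2, 2), matrix(10, 2, 2), matrix(210, 2, 2))
reflectance_correct <- function(raw, dark, ref, eps = 1) {
  if (!identical(dim(raw), dim(dark)) || !identical(dim(raw), dim(ref))) {
    stop("shape mismatch between raw, dark and reference frames")
  }
  den <- ref - dark
  flagged <- den < eps
  if (all(flagged)) stop("reference unusable: no pixel exceeds the dark frame")
  den[flagged] <- 1 # placeholder; flagged pixels are zeroed below
  r <- (raw - dark) / den
  r[flagged] <- 0
  r <- .clip01(r)
  attr(r, "n_flagged") <- sum(flagged)
  r
}

#' Parameters of the adaptive two-dimensional gamma illumination correction
#'
#' @param sigma_px Gaussian scale (pixels) of the low-pass illumination
#'   estimate. `NULL` (default) resolves to image width / 8 at use.
#' @param base base of the per-pixel gamma exponent, in (0, 1). 0.5 gives the
#'   widely used form `gamma(x,y) = 0.5^((m - F(x,y)) / m)`.
#' @return An object of class `gamma_params`.
#' @export
gamma_params <- function(sigma_px = NULL, base = 0.5) {
  if (!is.null(sigma_px) && sigma_px < 1) stop("sigma_px must be >= 1")
  if (base <= 0 || base >= 1) stop("base must lie in (0, 1)")
  structure(list(sigma_px = sigma_px, base = base), class = "gamma_params")
}

# Wide Gaussian low-pass of the image. For large scales the blur is computed
# on a decimated copy (sigma scaled accordingly) and bilinearly upsampled:
# numerically indistinguishable for an illumination-scale surface, an order
# of magnitude cheaper.
# Gaussian blur with the kernel radius capped so it never exceeds the image
.gblur_safe <- function(x, sigma) {
  radius <- 2L * ceiling(3 * sigma) + 1L
  maxr <- min(dim(x)[1:2])
  if (maxr %% 2L == 0L) maxr <- maxr - 1L
  EBImage::gblur(x, sigma = sigma, radius = min(radius, maxr),
                 boundary = "replicate")
}

.illumination_field <- function(image, sigma_px) {
  H <- nrow(image); W <- ncol(image)
  if (sigma_px >= 16) {
    dec <- 8
    small <- EBImage::resize(image, w = ceiling(H / dec), h = ceiling(W / dec))
    small <- .gblur_safe(small, sigma_px / dec)
    f <- EBImage::resize(small, w = H, h = W)
  } else {
    f <- .gblur_safe(image, sigma_px)
  }
  matrix(as.numeric(f), H, W)
}

# exponent application given a precomputed illumination field
.apply_gamma <- function(image, field, base = 0.5) {
  m <- mean(field)
  if (m <= 0) stop("black image")
  g <- base^((m - field) / m)
  .clip01(image^g)
}

#' Adaptive two-dimensional gamma illumination correction
#'
#' Estimates the illumination surface `F(x,y)` as a wide Gaussian blur of the
#' image, then raises each pixel to the exponent
#' `gamma(x,y) = base^((m - F(x,y)) / m)` where `m = mean(F)`. Dark regions
#' (`F < m`) get `gamma < 1` and are brightened; bright regions are darkened;
#' pixels where `F == m` are untouched, so a uniformly lit image passes
#' through unchanged.
#'
#' @param image reflectance matrix with values in \[0, 1\].
#' @param params a [gamma_params()].
#' @return corrected reflectance matrix in \[0, 1\].
#' @export
correct_illumination <- function(image, params = gamma_params()) {
  .check01(image)
  sigma <- params$sigma_px %||% (ncol(image) / 8)
  f <- .illumination_field(image, sigma)
  .apply_gamma(image, f, params$base)
}

#' Calibrate raw band stacks into a reflectance cube
#'
#' Per band, in acquisition-pipeline order: average the repeat frames,
#' apply the reflectance correction against dark and reference frames, then
#' (optionally) correct residual illumination nonuniformity with the
#' adaptive 2D gamma method. Bands are ordered by ascending wavelength.
#'
#' @param stacks list of [raw_band_stack()] objects, one per wavelength.
#' @param cal a [calibration_frames()] covering every required wavelength.
#' @param gamma a [gamma_params()], or `NULL` to skip the illumination step
#'   (e.g. when the optical train is known to be flat).
#' @param wavelengths_nm required band grid; defaults to the instrument's
#'   13-band 420-660 nm grid. A stack or reference missing from this grid is
#'   an error naming the wavelength.
#' @param eps minimum usable reference-minus-dark denominator, in counts.
#' @return A [spectral_cube()] whose provenance records, per band, the number
#'   of frames averaged and of flagged reference pixels.
#' @export
calibrate_cube <- function(stacks, cal, gamma = gamma_params(),
                           wavelengths_nm = seq(420L, 660L, by = 20L),
                           eps = 1) {
  wl_have <- vapply(stacks, function(s) s$wavelength_nm, integer(1))
  if (is.null(wavelengths_nm)) wavelengths_nm <- sort(wl_have)
  wavelengths_nm <- sort(as.integer(wavelengths_nm))
  miss <- setdiff(wavelengths_nm, wl_have)
  if (length(miss)) stop("missing band ", paste(miss, collapse = ", "))
  wl_ref <- as.integer(names(cal$references))
  miss_ref <- setdiff(wavelengths_nm, wl_ref)
  if (length(miss_ref)) {
    stop("missing reference frame for band ", paste(miss_ref, collapse = ", "))
  }

  shp <- dim(stacks[[1L]]$frames[[1L]])
  data <- array(NA_real_, c(shp, length(wavelengths_nm)))
  prov <- list(eps = eps,
               gamma = if (is.null(gamma)) NULL else unclass(gamma),
               bands = list())
  for (k in seq_along(wavelengths_nm)) {
    wl <- wavelengths_nm[k]
    stack <- stacks[[which(wl_have == wl)[1L]]]
    avg <- average_frames(stack)
    refl <- reflectance_correct(avg, cal$dark,
                                cal$references[[as.character(wl)]], eps = eps)
    n_flagged <- attr(refl, "n_flagged")
    if (!is.null(gamma)) refl <- correct_illumination(refl, gamma)
    data[, , k] <- refl
    prov$bands[[as.character(wl)]] <-
      list(n_frames = length(stack$frames), n_flagged = n_flagged)
  }
  spectral_cube(data, wavelengths_nm, provenance = prov)
}
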