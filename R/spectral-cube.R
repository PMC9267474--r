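#' Calibrated reflectance cube
#'
#' Container for a co-registered stack of reflectance images, one plane per
#' narrow illumination band, with values bounded in \[0, 1\]. This is the
#' common currency between calibration, segmentation and quantification.
#'
#' @param data numeric array `H x W x B` (or a single `H x W` matrix) of
#'   reflectance values in \[0, 1\].
#' @param wavelengths_nm integer vector of band centre wavelengths in
#'   nanometres, strictly increasing, one per band plane.
#' @param provenance list recording the corrections applied per band
#'   (frame counts averaged, flagged reference pixels, illumination
#'   parameters). Free-form; carried along unmodified.
#'
#' @return An object of class `spectral_cube` with fields `data`,
#'   `wavelengths_nm` and `provenance`.
#' @export
#' @examples
#' cube <- spectral_cube(array(0.5, c(8, 8, 2)), c(520, 660))
#' dim(get_band(cube, 660))
spectral_cube <- function(data, wavelengths_nm, provenance = list()) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (length(dim(data)) != 3L) stop("data must be an H x W x B array")
  wavelengths_nm <- as.integer(wavelengths_nm)
  if (length(wavelengths_nm) != dim(data)[3L]) {
    stop("number of wavelengths (", length(wavelengths_nm),
         ") does not match number of band planes (", dim(data)[3L], ")")
  }
  if (is.unsorted(wavelengths_nm, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing")
  }
  .check01(data, "reflectance")
  structure(
    list(data = data, wavelengths_nm = wavelengths_nm, provenance = provenance),
    class = "spectral_cube"
  )
}

#' Extract one band plane from a cube
#'
#' @param cube a [spectral_cube()].
#' @param wavelength_nm band centre to extract.
#' @return `H x W` numeric matrix of reflectance.
#' @export
get_band <- function(cube, wavelength_nm) {
  i <- match(as.integer(wavelength_nm), cube$wavelengths_nm)
  if (is.na(i)) stop("missing band ", wavelength_nm)
  cube$data[, , i]
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat("<spectral_cube> ", d[1], " x ", d[2], " px, ", d[3], " bands (",
      min(x$wavelengths_nm), "-", max(x$wavelengths_nm), " nm)\n", sep = "")
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

#' Aligned binary masks for the segmented structure classes
#'
#' Validates and bundles the per-structure masks produced by
#' [segment_structures()]: masks must share one shape, be pairwise disjoint,
#' and lie inside the tissue mask.
#'
#' @param nuclei,keratin,collagen,tissue logical matrices of one shape.
#'   `keratin` holds keratin pearls in carcinoma sections and large lipid
#'   droplets in normal ones (the two share a band and a mask).
#' @param band_used named integer vector mapping structure to the wavelength
#'   it was segmented from.
#' @return An object of class `structure_masks`.
#' @export
structure_masks <- function(nuclei, keratin, collagen, tissue,
                            band_used = c(nuclei = 660L, keratin = 600L,
                                          collagen = 520L)) {
  masks <- list(nuclei = nuclei, keratin = keratin, collagen = collagen,
                tissue = tissue)
  shp <- dim(nuclei)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), shp)) {
      stop("mask '", nm, "' must be a logical matrix of shape ",
           paste(shp, collapse = " x "))
    }
  }
  if (any(nuclei & keratin) || any(nuclei & collagen) || any(keratin & collagen)) {
    stop("structure masks must be pairwise disjoint")
  }
  if (any((nuclei | keratin | collagen) & !tissue)) {
    stop("structure masks must lie inside the tissue mask")
  }
  structure(c(masks, list(shape = shp, band_used = band_used)),
            class = "structure_masks")
}

#' @export
print.structure_masks <- function(x, ...) {
  cat("<structure_masks> ", x$shape[1], " x ", x$shape[2], " px; px counts: ",
      "nuclei ", sum(x$nuclei), ", keratin ", sum(x$keratin),
      ", collagen ", sum(x$collagen), ", tissue ", sum(x$tissue), "\n",
      sep = "")
  invisible(x)
}
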