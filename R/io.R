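#' Write / read a raw frame stack as multi-page TIFF
#'
#' Integer counts are stored as 8- or 16-bit pages (one page per repeat
#' frame) and recovered exactly on read.
#'
#' @param stack a [raw_band_stack()].
#' @param path output `.tif` path.
#' @export
write_stack_tiff <- function(stack, path) {
  maxc <- 2^stack$bit_depth - 1
  pages <- lapply(stack$frames, function(f) f / maxc)
  tiff::writeTIFF(pages, path,
                  bits.per.sample = if (stack$bit_depth <= 8) 8L else 16L,
                  compression = "LZW")
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param wavelength_nm band centre recorded on the returned stack.
#' @param bit_depth sensor bit depth used when writing.
#' @export
read_stack_tiff <- function(path, wavelength_nm, bit_depth = 8L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  maxc <- 2^bit_depth - 1
  frames <- lapply(pages, function(p) round(p * maxc))
  raw_band_stack(wavelength_nm, frames, bit_depth)
}

#' Write / read a calibrated reflectance cube as 32-bit float TIFF
#'
#' One page per band, ascending wavelength; a JSON sidecar carries the
#' wavelengths and provenance.
#'
#' @param cube a [spectral_cube()].
#' @param path output `.tif` path; the sidecar is `<path>.json`.
#' @export
write_cube_tiff <- function(cube, path) {
  pages <- lapply(seq_along(cube$wavelengths_nm),
                  function(b) cube$data[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(wavelengths_nm = cube$wavelengths_nm,
                            provenance = cube$provenance),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cube_tiff
#' @export
read_cube_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
  spectral_cube(data, meta$wavelengths_nm,
                provenance = as.list(meta$provenance))
}

#' Write / read a binary mask as PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path output `.png` path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}

#' Write one section's acquisition to a directory
#'
#' Layout: `band_<wl>.tif` (multi-page, one page per repeat frame),
#' `dark.tif`, `ref_<wl>.tif`, and — when ground truth is available —
#' `truth.json` (scalars) plus `class_map.png`.
#'
#' @param dir section directory (created).
#' @param stacks list of [raw_band_stack()].
#' @param cal a [calibration_frames()].
#' @param scene optional [make_scene()] ground truth.
#' @export
write_section <- function(dir, stacks, cal, scene = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bit_depth <- stacks[[1L]]$bit_depth
  maxc <- 2^bit_depth - 1
  for (s in stacks) {
    write_stack_tiff(s, file.path(dir, sprintf("band_%d.tif", s$wavelength_nm)))
  }
  tiff::writeTIFF(cal$dark / maxc, file.path(dir, "dark.tif"),
                  bits.per.sample = 8L, compression = "LZW")
  for (wl in names(cal$references)) {
    tiff::writeTIFF(cal$references[[wl]] / maxc,
                    file.path(dir, sprintf("ref_%s.tif", wl)),
                    bits.per.sample = 8L, compression = "LZW")
  }
  jsonlite::write_json(
    list(wavelengths_nm = vapply(stacks, function(s) s$wavelength_nm,
                                 integer(1)),
         bit_depth = bit_depth),
    file.path(dir, "meta.json"), digits = NA, auto_unbox = TRUE)
  if (!is.null(scene)) {
    jsonlite::write_json(
      list(label = scene$label,
           realized_nuclear_fraction = scene$realized_nuclear_fraction,
           jittered_target = scene$jittered_target,
           seed = scene$seed),
      file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
    png::writePNG(scene$class_map / 4, file.path(dir, "class_map.png"))
  }
  invisible(dir)
}

#' @rdname write_section
#' @return `read_section` returns a list with `stacks` and `cal`.
#' @export
read_section <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  maxc <- 2^meta$bit_depth - 1
  stacks <- lapply(meta$wavelengths_nm, function(wl) {
    read_stack_tiff(file.path(dir, sprintf("band_%d.tif", wl)), wl,
                    meta$bit_depth)
  })
  names(stacks) <- meta$wavelengths_nm
  dark <- round(tiff::readTIFF(file.path(dir, "dark.tif")) * maxc)
  refs <- lapply(meta$wavelengths_nm, function(wl) {
    p <- file.path(dir, sprintf("ref_%d.tif", wl))
    if (!file.exists(p)) stop("missing reference frame for band ", wl)
    round(tiff::readTIFF(p) * maxc)
  })
  names(refs) <- meta$wavelengths_nm
  list(stacks = stacks, cal = calibration_frames(dark, refs))
}
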