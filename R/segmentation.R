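#' Enhancement parameters for band images
#'
#' @param tile_grid integer pair: contrast-equalization tiles along
#'   (rows, columns).
#' @param clip_limit contrast-limiting clip fraction in (0, 1\]; the fraction
#'   of a tile's pixels any single histogram bin may hold before the excess
#'   is redistributed.
#' @param median_kernel odd integer >= 3, side of the median-filter window.
#' @return An object of class `enhance_params`.
#' @export
enhance_params <- function(tile_grid = c(8L, 8L), clip_limit = 0.01,
                           median_kernel = 3L) {
  tile_grid <- as.integer(tile_grid)
  if (length(tile_grid) != 2L || any(tile_grid < 1L)) {
    stop("tile_grid must be two integers >= 1")
  }
  if (clip_limit <= 0 || clip_limit > 1) stop("clip_limit must lie in (0, 1]")
  median_kernel <- as.integer(median_kernel)
  if (median_kernel < 3L || median_kernel %% 2L == 0L) {
    stop("median_kernel must be an odd integer >= 3")
  }
  structure(list(tile_grid = tile_grid, clip_limit = clip_limit,
                 median_kernel = median_kernel), class = "enhance_params")
}

#' Adaptive-threshold parameters
#'
#' @param block_size odd integer >= 3: side of the square neighbourhood whose
#'   mean serves as the local threshold.
#' @param offset margin (reflectance units) a pixel must clear beyond its
#'   local mean to enter the mask.
#' @param polarity `"dark_foreground"` selects pixels darker than their
#'   neighbourhood (absorbing, stained structures); `"bright_foreground"`
#'   the converse.
#' @return An object of class `threshold_params`.
#' @export
threshold_params <- function(block_size = 51L, offset = 0.02,
                             polarity = c("dark_foreground",
                                          "bright_foreground")) {
  block_size <- as.integer(block_size)
  if (block_size < 3L || block_size %% 2L == 0L) {
    stop("block_size must be an odd integer >= 3")
  }
  polarity <- match.arg(polarity)
  structure(list(block_size = block_size, offset = offset,
                 polarity = polarity), class = "threshold_params")
}

# symmetric-pad an image on the bottom/right so dims become multiples of tiles
.pad_to_multiple <- function(image, ny, nx) {
  H <- nrow(image); W <- ncol(image)
  ph <- (-H) %% ny
  pw <- (-W) %% nx
  if (ph > 0L) image <- image[c(seq_len(H), H:(H - ph + 1L)), , drop = FALSE]
  if (pw > 0L) image <- image[, c(seq_len(W), W:(W - pw + 1L)), drop = FALSE]
  image
}

#' Contrast-limited local histogram equalization
#'
#' Tile-based (CLAHE) equalization: each tile's histogram is equalized with
#' the clip limit bounding contrast amplification, and per-pixel mappings are
#' bilinearly interpolated between tile centres. Flat (constant) images pass
#' through unchanged. Images whose size is not a multiple of the tile grid
#' are symmetrically padded for the transform and cropped back.
#'
#' @param image reflectance matrix in \[0, 1\].
#' @param params an [enhance_params()].
#' @return equalized matrix in \[0, 1\].
#' @export
equalize_local <- function(image, params = enhance_params()) {
  .check01(image)
  ny <- params$tile_grid[1L]; nx <- params$tile_grid[2L]
  if (nrow(image) < ny || ncol(image) < nx) {
    stop("image smaller than tile grid")
  }
  if (diff(range(image)) < 1e-12) return(image)
  padded <- .pad_to_multiple(image, ny, nx)
  bins <- 256L
  out <- EBImage::clahe(padded, nx = ny, ny = nx, bins = bins,
                        limit = params$clip_limit * bins)
  out <- matrix(as.numeric(out), nrow(padded), ncol(padded))
  .clip01(out[seq_len(nrow(image)), seq_len(ncol(image)), drop = FALSE])
}

#' Median filtering
#'
#' Per-pixel median over an odd square window, with reflective (symmetric)
#' edge padding; removes salt-and-pepper noise while keeping edges.
#'
#' @param image numeric matrix.
#' @param kernel odd window side, or an [enhance_params()] whose
#'   `median_kernel` is used.
#' @return filtered matrix.
#' @export
median_denoise <- function(image, kernel = 3L) {
  if (inherits(kernel, "enhance_params")) kernel <- kernel$median_kernel
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L || kernel < 1L) stop("median kernel must be odd")
  cpp_median_filter(image, kernel)
}

#' Adaptive mean thresholding
#'
#' Binarizes against a moving local threshold: `T(x,y)` is the mean of the
#' `block_size` x `block_size` neighbourhood (reflective padding). With
#' `dark_foreground` polarity the mask is `image < T - offset`; with
#' `bright_foreground`, `image > T + offset`.
#'
#' When a `support` mask is supplied, the local mean is computed over the
#' supported pixels of the neighbourhood only, and unsupported pixels stay
#' out of the mask. This keeps the threshold from being dragged by
#' out-of-specimen material — most visibly the bright blank glass bordering
#' a section, which otherwise paints a spurious dark halo along the tissue
#' edge.
#'
#' @param image reflectance matrix in \[0, 1\].
#' @param params a [threshold_params()].
#' @param support optional logical matrix: restrict both the threshold
#'   statistics and the mask to these pixels.
#' @return logical mask matrix.
#' @export
adaptive_threshold <- function(image, params = threshold_params(),
                               support = NULL) {
  .check01(image)
  if (params$block_size >= min(dim(image))) {
    stop("block_size must be smaller than the image")
  }
  if (is.null(support)) {
    thr <- cpp_local_mean(image, params$block_size)
  } else {
    if (!identical(dim(support), dim(image))) {
      stop("support/image shape mismatch")
    }
    s <- support * 1
    wsum <- cpp_local_mean(s, params$block_size)
    thr <- cpp_local_mean(image * s, params$block_size) / wsum
    thr[wsum == 0] <- NA_real_
  }
  mask <- if (params$polarity == "dark_foreground") {
    image < thr - params$offset
  } else {
    image > thr + params$offset
  }
  mask[is.na(mask)] <- FALSE
  if (!is.null(support)) mask <- mask & support
  mask
}

#' Segment nuclei, keratin/lipid and collagen from their working bands
#'
#' Runs the enhancement chain (local equalization, then median filtering,
#' then adaptive dark-foreground thresholding restricted to tissue)
#' independently on the 660, 600 and 520 nm band images — the bands at which
#' nuclei, keratin pearls (lipid droplets in normal tissue) and collagen
#' absorb most strongly. A pixel captured at more than one working band is
#' assigned the class at whose band it reflects least (stained chromophores
#' absorb most strongly at their signature band), with ties broken by
#' precedence nuclei > keratin > collagen. All masks are intersected with
#' the tissue mask.
#'
#' @param cube a [spectral_cube()] containing the 520, 600 and 660 nm bands.
#' @param enhance an [enhance_params()].
#' @param thresh a [threshold_params()].
#' @param tissue optional precomputed tissue mask; defaults to
#'   [tissue_mask()] on the cube.
#' @param blank_threshold forwarded to [tissue_mask()] when `tissue` is NULL.
#' @return A [structure_masks()].
#' @export
segment_structures <- function(cube, enhance = enhance_params(),
                               thresh = threshold_params(), tissue = NULL,
                               blank_threshold = 0.95) {
  bands <- c(nuclei = 660L, keratin = 600L, collagen = 520L)
  for (wl in bands) {
    if (!(wl %in% cube$wavelengths_nm)) stop("missing band ", wl)
  }
  if (is.null(tissue)) {
    tissue <- tissue_mask(cube, blank_threshold = blank_threshold,
                          median_kernel = enhance$median_kernel)
  }
  seg_band <- function(wl) {
    img <- get_band(cube, wl)
    img <- equalize_local(img, enhance)
    img <- median_denoise(img, enhance$median_kernel)
    adaptive_threshold(img, thresh, support = tissue)
  }
  cand <- lapply(bands, seg_band)
  # per-pixel class score: the raw band reflectance where captured, else Inf
  score <- lapply(names(bands), function(nm) {
    s <- get_band(cube, bands[[nm]])
    s[!cand[[nm]]] <- Inf
    s
  })
  names(score) <- names(bands)
  nuclei <- cand$nuclei & score$nuclei <= score$keratin &
    score$nuclei <= score$collagen
  keratin <- cand$keratin & !nuclei & score$keratin <= score$collagen
  collagen <- cand$collagen & !nuclei & !keratin
  structure_masks(nuclei, keratin, collagen, tissue, band_used = bands)
}

#' Compose a pseudo-color overlay of the segmentation
#'
#' Renders the grayscale background with each structure class painted in its
#' own colour, precedence nuclei > keratin > collagen (applied by painting
#' collagen first and nuclei last).
#'
#' @param masks a [structure_masks()] (or any list with logical `nuclei`,
#'   `keratin`, `collagen` matrices).
#' @param background grayscale matrix in \[0, 1\] (e.g. one band image).
#' @param colors named list of RGB triplets in \[0, 1\].
#' @return numeric `H x W x 3` RGB array in \[0, 1\].
#' @export
compose_pseudocolor <- function(masks, background,
                                colors = list(nuclei = c(0.54, 0.17, 0.89),
                                              keratin = c(1, 0, 0),
                                              collagen = c(0, 0.8, 0))) {
  if (!identical(dim(background), dim(masks$nuclei))) {
    stop("background/mask shape mismatch")
  }
  .check01(background, "background")
  rgb <- array(rep(background, 3L), c(dim(background), 3L))
  for (nm in c("collagen", "keratin", "nuclei")) { # ascending precedence
    m <- masks[[nm]]
    col <- colors[[nm]]
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[m] <- col[ch]
      rgb[, , ch] <- plane
    }
  }
  rgb
}
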