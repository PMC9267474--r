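#' Tissue presets for the synthetic scene generator
#'
#' Defaults encode the two study conditions: normal skin with a 4.239%
#' nuclear area fraction of tissue and small nuclei, and cutaneous squamous
#' cell carcinoma (cSCC) with a 15.607% fraction, larger and darker nuclei,
#' and keratin pearls (absent from normal tissue). `section_sd` is the
#' relative between-section jitter applied to the nuclear fraction target,
#' emulating biological section-to-section variability.
#'
#' @param name `"normal"`, `"cscc"`, or `"custom"` (then
#'   `nuclear_fraction_target` must be given).
#' @param nuclear_fraction_target target nuclei / tissue pixel fraction.
#' @param nucleus_radius_px two-element range of nucleus ellipse semi-axes.
#' @param n_keratin_pearls two-element integer range of pearl counts.
#' @param pearl_radius_px two-element range of pearl radii.
#' @param collagen_fraction fraction of the non-nuclear, non-keratin tissue
#'   assigned collagen texture.
#' @param section_sd relative SD of the per-section jitter on the target.
#' @param nuclei_absorbance_mult multiplier on nuclear absorbance (cSCC
#'   nuclei stain darker; default 1.3 for the cscc preset).
#' @return An object of class `tissue_preset`.
#' @export
tissue_preset <- function(name = c("normal", "cscc", "custom"),
                          nuclear_fraction_target = NULL,
                          nucleus_radius_px = NULL,
                          n_keratin_pearls = NULL,
                          pearl_radius_px = c(15, 40),
                          collagen_fraction = 0.30,
                          section_sd = 0.15,
                          nuclei_absorbance_mult = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    normal = list(target = 0.04239, radius = c(3, 6), pearls = c(0L, 0L),
                  mult = 1),
    cscc = list(target = 0.15607, radius = c(5, 10), pearls = c(2L, 5L),
                mult = 1.3),
    custom = list(target = NULL, radius = c(3, 6), pearls = c(0L, 0L),
                  mult = 1)
  )
  target <- nuclear_fraction_target %||% defaults$target
  if (is.null(target)) stop("custom preset needs nuclear_fraction_target")
  if (target <= 0 || target >= 1) {
    stop("nuclear_fraction_target must lie in (0, 1)")
  }
  radius <- nucleus_radius_px %||% defaults$radius
  pearls <- as.integer(n_keratin_pearls %||% defaults$pearls)
  mult <- nuclei_absorbance_mult %||% defaults$mult
  if (any(radius <= 0) || any(pearl_radius_px <= 0)) {
    stop("radii must be positive")
  }
  if (name == "normal" && any(pearls != 0L)) {
    stop("normal preset must have zero keratin pearls")
  }
  if (collagen_fraction < 0 || collagen_fraction >= 1) {
    stop("collagen_fraction must lie in [0, 1)")
  }
  structure(list(name = name, nuclear_fraction_target = target,
                 nucleus_radius_px = radius, n_keratin_pearls = pearls,
                 pearl_radius_px = pearl_radius_px,
                 collagen_fraction = collagen_fraction,
                 section_sd = section_sd,
                 nuclei_absorbance_mult = mult),
            class = "tissue_preset")
}

#' Band-dependent absorbance model of the stained structure classes
#'
#' Each structure class absorbs most strongly near one band — nuclei near
#' 660 nm, keratin/lipid near 600 nm, collagen near 520 nm — realized as a
#' Gaussian absorbance peak over a flat baseline shared with cytoplasm;
#' background (blank glass) absorbs nothing. Reflectance follows
#' Beer-Lambert: `R = exp(-A)`.
#'
#' @param wavelengths_nm band grid (13 bands, 420-660 nm by default).
#' @param peak_nm named vector of class peak positions.
#' @param peak_height,peak_width_nm,baseline Gaussian peak height, SD width
#'   (nm) and baseline absorbance.
#' @return An object of class `spectral_model` with an `absorbance` matrix
#'   (rows background, cytoplasm, nuclei, keratin, collagen; one column per
#'   band).
#' @export
spectral_model <- function(wavelengths_nm = seq(420L, 660L, by = 20L),
                           peak_nm = c(nuclei = 660, keratin = 600,
                                       collagen = 520),
                           peak_height = 1.2, peak_width_nm = 40,
                           baseline = 0.1) {
  wavelengths_nm <- as.integer(wavelengths_nm)
  classes <- c("background", "cytoplasm", "nuclei", "keratin", "collagen")
  A <- matrix(0, length(classes), length(wavelengths_nm),
              dimnames = list(classes, wavelengths_nm))
  A["cytoplasm", ] <- baseline
  for (cl in names(peak_nm)) {
    A[cl, ] <- baseline +
      peak_height * exp(-(wavelengths_nm - peak_nm[[cl]])^2 /
                          (2 * peak_width_nm^2))
  }
  for (cl in names(peak_nm)) {
    if (wavelengths_nm[which.max(A[cl, ])] !=
        wavelengths_nm[which.min(abs(wavelengths_nm - peak_nm[[cl]]))]) {
      stop("class '", cl, "' does not peak at its designated band")
    }
  }
  structure(list(wavelengths_nm = wavelengths_nm, absorbance = A,
                 peak_nm = peak_nm, peak_height = peak_height,
                 peak_width_nm = peak_width_nm, baseline = baseline),
            class = "spectral_model")
}

#' Imaging model for rendering raw frames
#'
#' @param dark_level sensor dark offset, counts.
#' @param ref_level blank-slide signal above dark at the field centre,
#'   counts.
#' @param vignette_strength fractional corner falloff of the cos^4-style
#'   radial vignette, in \[0, 1).
#' @param noise_sd Gaussian read-noise SD, counts.
#' @param n_frames repeat exposures per band.
#' @param bit_depth sensor bit depth.
#' @return An object of class `imaging_model`.
#' @export
imaging_model <- function(dark_level = 8, ref_level = 230,
                          vignette_strength = 0.25, noise_sd = 2,
                          n_frames = 5L, bit_depth = 8L) {
  if (dark_level >= ref_level) stop("dark_level must be below ref_level")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (vignette_strength < 0 || vignette_strength >= 1) {
    stop("vignette_strength must lie in [0, 1)")
  }
  structure(list(dark_level = dark_level, ref_level = ref_level,
                 vignette_strength = vignette_strength, noise_sd = noise_sd,
                 n_frames = as.integer(n_frames),
                 bit_depth = as.integer(bit_depth)),
            class = "imaging_model")
}

# classes are encoded in the class map as integers
.CLS <- c(background = 0L, cytoplasm = 1L, nuclei = 2L, keratin = 3L,
          collagen = 4L)

# paint a rotated ellipse; returns matrix indices, or NULL if out of frame
.ellipse_idx <- function(cy, cx, r1, r2, theta, H, W) {
  rmax <- max(r1, r2)
  y0 <- floor(cy - rmax); y1 <- ceiling(cy + rmax)
  x0 <- floor(cx - rmax); x1 <- ceiling(cx + rmax)
  if (y0 < 1 || x0 < 1 || y1 > H || x1 > W) return(NULL)
  yy <- y0:y1; xx <- x0:x1
  dy <- matrix(yy - cy, length(yy), length(xx))
  dx <- matrix(xx - cx, length(yy), length(xx), byrow = TRUE)
  u <- (dx * cos(theta) + dy * sin(theta)) / r1
  v <- (-dx * sin(theta) + dy * cos(theta)) / r2
  inside <- which(u^2 + v^2 <= 1, arr.ind = TRUE)
  if (nrow(inside) == 0L) return(NULL)
  cbind(yy[inside[, 1L]], xx[inside[, 2L]])
}

#' Generate a ground-truthed synthetic section scene
#'
#' Lays a tissue slab covering most of the frame, places keratin pearls
#' (discs) per the preset, then adds randomly oriented nuclear ellipses —
#' rejecting any that would overlap a pearl or leave the tissue — until the
#' realized nuclear fraction of tissue reaches the section's jittered
#' target. The remaining tissue is split into a smooth collagen texture and
#' cytoplasm. All randomness flows from `seed`.
#'
#' @param preset a [tissue_preset()].
#' @param shape frame (rows, cols); at least 200 x 200 so 100-pixel analysis
#'   windows fit with margin.
#' @param seed integer RNG seed.
#' @param model a [spectral_model()].
#' @param label section label stored on the scene; defaults to the preset
#'   name (custom presets count as `"normal"` unless told otherwise).
#' @return An object of class `synthetic_scene`: `class_map` (integer matrix,
#'   0 background / 1 cytoplasm / 2 nuclei / 3 keratin / 4 collagen),
#'   `realized_nuclear_fraction`, `jittered_target`, `label`, `seed`, plus
#'   the preset and model for rendering.
#' @export
make_scene <- function(preset = tissue_preset("normal"),
                       shape = c(512L, 640L), seed = 1L,
                       model = spectral_model(),
                       label = NULL) {
  if (any(shape < 200L)) stop("shape must be at least 200 x 200")
  set.seed(seed)
  H <- as.integer(shape[1L]); W <- as.integer(shape[2L])
  cm <- matrix(.CLS[["background"]], H, W)
  mh <- max(1L, round(0.03 * H)); mw <- max(1L, round(0.03 * W))
  cm[(mh + 1L):(H - mh), (mw + 1L):(W - mw)] <- .CLS[["cytoplasm"]]
  n_tissue <- sum(cm != .CLS[["background"]])

  pr <- preset$n_keratin_pearls
  n_pearls <- if (pr[2L] > pr[1L]) sample(pr[1L]:pr[2L], 1L) else pr[1L]
  for (k in seq_len(n_pearls)) {
    r <- runif(1, preset$pearl_radius_px[1L], preset$pearl_radius_px[2L])
    cy <- runif(1, mh + r + 1, H - mh - r)
    cx <- runif(1, mw + r + 1, W - mw - r)
    idx <- .ellipse_idx(cy, cx, r, r, 0, H, W)
    if (!is.null(idx)) cm[idx] <- .CLS[["keratin"]]
  }

  jitter <- max(0.4, 1 + preset$section_sd * rnorm(1))
  target <- preset$nuclear_fraction_target * jitter
  rad <- preset$nucleus_radius_px
  nuc_px <- 0L
  rejects <- 0L
  while (nuc_px / n_tissue < target) {
    if (rejects > 5000L) stop("unreachable nuclear fraction target")
    # near the target, cap the radius so the final nucleus cannot push the
    # realized fraction beyond the +/- 0.003 bookkeeping tolerance
    rcap <- sqrt((target - nuc_px / n_tissue + 0.0025) * n_tissue / pi)
    hi <- min(rad[2L], max(rad[1L] / 2, rcap))
    lo <- min(rad[1L], hi)
    r1 <- runif(1, lo, hi); r2 <- runif(1, lo, hi)
    theta <- runif(1, 0, pi)
    cy <- runif(1, 1, H); cx <- runif(1, 1, W)
    idx <- .ellipse_idx(cy, cx, r1, r2, theta, H, W)
    if (is.null(idx)) { rejects <- rejects + 1L; next }
    vals <- cm[idx]
    if (any(vals == .CLS[["keratin"]])) { # never into a pearl
      rejects <- rejects + 1L
      next
    }
    # clip at the tissue boundary rather than reject, so nuclear density
    # stays homogeneous right up to the section edge
    keep <- vals == .CLS[["cytoplasm"]]
    if (!any(keep)) { rejects <- rejects + 1L; next }
    cm[idx[keep, , drop = FALSE]] <- .CLS[["nuclei"]]
    nuc_px <- nuc_px + sum(keep)
    rejects <- 0L
  }
  realized <- nuc_px / n_tissue
  if (abs(realized - target) > 0.003) {
    stop("nuclear fraction overshoot beyond tolerance") # should not happen
  }

  # smooth random field -> collagen texture over part of the leftover tissue
  f0 <- matrix(runif(ceiling(H / 16) * ceiling(W / 16)),
               ceiling(H / 16), ceiling(W / 16))
  f <- EBImage::resize(f0, w = H, h = W)
  f <- matrix(as.numeric(EBImage::gblur(f, sigma = 4,
                                        boundary = "replicate")), H, W)
  rem <- which(cm == .CLS[["cytoplasm"]])
  k <- round(preset$collagen_fraction * length(rem))
  if (k > 0L) {
    sel <- rem[order(f[rem], decreasing = TRUE)[seq_len(k)]]
    cm[sel] <- .CLS[["collagen"]]
  }

  structure(list(class_map = cm,
                 label = label %||%
                   (if (preset$name == "cscc") "cscc" else "normal"),
                 realized_nuclear_fraction = realized,
                 jittered_target = target,
                 preset = preset, model = model, seed = seed,
                 shape = c(H, W)),
            class = "synthetic_scene")
}

#' True reflectance cube of a synthetic scene
#'
#' Beer-Lambert rendering of the class map: `R = exp(-A(class, band))`, with
#' the preset's nuclear absorbance multiplier applied (darker carcinoma
#' nuclei). This is the ground truth that calibration round-trip tests
#' compare against.
#'
#' @param scene a [make_scene()] result.
#' @return A [spectral_cube()] (provenance notes it is synthetic truth).
#' @export
scene_reflectance <- function(scene) {
  A <- scene$model$absorbance
  A["nuclei", ] <- A["nuclei", ] * scene$preset$nuclei_absorbance_mult
  cls <- as.integer(scene$class_map) + 1L # 1..5 indexes the absorbance rows
  H <- scene$shape[1L]; W <- scene$shape[2L]
  wl <- scene$model$wavelengths_nm
  data <- array(NA_real_, c(H, W, length(wl)))
  for (b in seq_along(wl)) {
    refl_by_class <- exp(-A[, b])
    data[, , b] <- matrix(refl_by_class[cls], H, W)
  }
  spectral_cube(data, wl, provenance = list(synthetic_truth = TRUE,
                                            seed = scene$seed))
}

# radial cos^4-style vignette, 1 at centre, (1 - strength) at the far corner
.vignette_field <- function(H, W, strength) {
  if (strength == 0) return(matrix(1, H, W))
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  dy <- matrix((seq_len(H) - cy), H, W)
  dx <- matrix((seq_len(W) - cx), H, W, byrow = TRUE)
  d <- sqrt(dy^2 + dx^2) / sqrt(cy^2 + cx^2)
  a <- acos((1 - strength)^(1 / 4))
  cos(a * pmin(d, 1))^4
}

#' Render raw frame stacks and calibration frames from a scene
#'
#' Forward model of the acquisition: per band and repeat frame,
#' `raw = round(clip(ref_level * R_true * V + dark_level + noise))` with `V`
#' the radial vignette field and Gaussian read noise; reference frames are
#' the noiseless blank response `round(ref_level * V + dark_level)` (one per
#' band), and the dark frame is `dark_level` plus noise. This is exactly the
#' model [calibrate_cube()] inverts.
#'
#' @param scene a [make_scene()] result.
#' @param imaging an [imaging_model()].
#' @param seed RNG seed for the noise draws.
#' @return list with `stacks` (list of [raw_band_stack()]) and `cal`
#'   (a [calibration_frames()]).
#' @export
render_cube <- function(scene, imaging = imaging_model(), seed = 1L) {
  set.seed(seed)
  H <- scene$shape[1L]; W <- scene$shape[2L]
  maxc <- 2^imaging$bit_depth - 1
  V <- .vignette_field(H, W, imaging$vignette_strength)
  truth <- scene_reflectance(scene)
  noise <- function() {
    if (imaging$noise_sd == 0) 0 else rnorm(H * W, 0, imaging$noise_sd)
  }
  quantize <- function(x) round(pmin(pmax(x, 0), maxc))
  stacks <- list()
  refs <- list()
  for (b in seq_along(truth$wavelengths_nm)) {
    wl <- truth$wavelengths_nm[b]
    signal <- imaging$ref_level * truth$data[, , b] * V + imaging$dark_level
    frames <- lapply(seq_len(imaging$n_frames), function(i) {
      quantize(signal + noise())
    })
    stacks[[as.character(wl)]] <-
      raw_band_stack(wl, frames, imaging$bit_depth)
    refs[[as.character(wl)]] <-
      quantize(imaging$ref_level * V + imaging$dark_level)
  }
  dark <- quantize(matrix(imaging$dark_level, H, W) + noise())
  list(stacks = stacks, cal = calibration_frames(dark, refs))
}

#' Generate a labelled two-group cohort of synthetic sections
#'
#' Draws per-section scene and render seeds from the master seed, generates
#' `n_per_group` sections per label, and asserts that the true nuclear
#' fractions of the two groups separate completely (`max(normal) <
#' min(cscc)`); if a seed draw violates this, the cohort is regenerated from
#' a derived seed (bounded retries) so that downstream discrimination tests
#' exercise the pipeline rather than a data accident.
#'
#' @param n_per_group sections per label (>= 2).
#' @param seed master seed; all per-section seeds derive from it.
#' @param presets named list with `normal` and `cscc` [tissue_preset()]s.
#' @param shape per-section frame size.
#' @param imaging an [imaging_model()] (stored; used when writing).
#' @param model a [spectral_model()].
#' @param dir optional directory: when given, every section's raw stacks,
#'   calibration frames and ground truth are written there (see
#'   [write_section()]) under a JSON manifest.
#' @return An object of class `synthetic_cohort`: `manifest` (data frame
#'   with section_id, label, scene_seed, render_seed,
#'   realized_nuclear_fraction), `scenes` (list of [make_scene()] objects),
#'   plus the models, and `dir`/`manifest_path` when written.
#' @export
generate_cohort <- function(n_per_group = 21L, seed = 1L,
                            presets = list(normal = tissue_preset("normal"),
                                           cscc = tissue_preset("cscc")),
                            shape = c(512L, 640L),
                            imaging = imaging_model(),
                            model = spectral_model(),
                            dir = NULL) {
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  base_seed <- as.integer(seed %% (2^31 - 64))
  labels <- rep(c("normal", "cscc"), each = n_per_group)
  for (attempt in 0:20) {
    set.seed(base_seed + attempt)
    seeds <- matrix(sample.int(2^31 - 2, 4L * n_per_group), ncol = 2L)
    scenes <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      scenes[[i]] <- make_scene(presets[[labels[i]]], shape = shape,
                                seed = seeds[i, 1L], model = model)
    }
    fr <- vapply(scenes, function(s) s$realized_nuclear_fraction, numeric(1))
    if (max(fr[labels == "normal"]) < min(fr[labels == "cscc"])) break
    if (attempt == 20L) stop("could not realize separated groups")
  }
  manifest <- data.frame(
    section_id = sprintf("%s_%02d", labels,
                         c(seq_len(n_per_group), seq_len(n_per_group))),
    label = labels,
    scene_seed = seeds[, 1L],
    render_seed = seeds[, 2L],
    realized_nuclear_fraction = vapply(scenes, function(s)
      s$realized_nuclear_fraction, numeric(1)),
    stringsAsFactors = FALSE
  )
  cohort <- structure(list(manifest = manifest, scenes = scenes,
                           imaging = imaging, model = model, shape = shape,
                           seed = seed),
                      class = "synthetic_cohort")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest))) {
      rendered <- render_cube(scenes[[i]], imaging, manifest$render_seed[i])
      write_section(file.path(dir, manifest$section_id[i]),
                    rendered$stacks, rendered$cal, scene = scenes[[i]])
    }
    cohort$dir <- dir
    cohort$manifest_path <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, cohort$manifest_path, dataframe = "rows",
                         digits = NA, auto_unbox = TRUE)
  }
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d sections (%s), %d x %d px%s\n",
              nrow(x$manifest),
              paste(names(table(x$manifest$label)), table(x$manifest$label),
                    sep = ": ", collapse = ", "),
              x$shape[1], x$shape[2],
              if (is.null(x$dir)) "" else paste0(", written to ", x$dir)))
  invisible(x)
}
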