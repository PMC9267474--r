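#' Sliding-window criteria for nucleocytoplasmic-ratio quantification
#'
#' @param window_px window side in pixels (the analysis unit).
#' @param stride_px scan stride; half-window by default so the scan covers
#'   junctions between grid cells.
#' @param min_mean_reflectance,max_mean_reflectance bounds on the window's
#'   mean 660 nm reflectance; windows below the floor are underexposed, above
#'   the ceiling mostly blank glass.
#' @param max_keratin_fraction windows with more than this fraction of
#'   keratin pixels sit on nucleus/keratin-pearl junctions and are excluded.
#' @param min_tissue_fraction minimum fraction of window pixels on tissue.
#' @param n_select number of non-overlapping windows retained per section.
#' @param denominator `"tissue"` computes the ratio as nuclear area over all
#'   tissue pixels in the window; `"cytoplasm"` uses the strict
#'   nuclear/(tissue - nuclear) variant.
#' @return An object of class `window_criteria`.
#' @export
window_criteria <- function(window_px = 100L, stride_px = 50L,
                            min_mean_reflectance = 0.15,
                            max_mean_reflectance = 0.95,
                            max_keratin_fraction = 0.10,
                            min_tissue_fraction = 0.50,
                            n_select = 5L,
                            denominator = c("tissue", "cytoplasm")) {
  window_px <- as.integer(window_px); stride_px <- as.integer(stride_px)
  if (stride_px < 1L || stride_px > window_px) {
    stop("stride_px must satisfy 0 < stride_px <= window_px")
  }
  for (v in c(min_mean_reflectance, max_mean_reflectance,
              max_keratin_fraction, min_tissue_fraction)) {
    if (v < 0 || v > 1) stop("window thresholds must lie in [0, 1]")
  }
  n_select <- as.integer(n_select)
  if (n_select < 1L) stop("n_select must be >= 1")
  structure(list(window_px = window_px, stride_px = stride_px,
                 min_mean_reflectance = min_mean_reflectance,
                 max_mean_reflectance = max_mean_reflectance,
                 max_keratin_fraction = max_keratin_fraction,
                 min_tissue_fraction = min_tissue_fraction,
                 n_select = n_select,
                 denominator = match.arg(denominator)),
            class = "window_criteria")
}

#' Tissue mask from the 520 nm band
#'
#' Tissue is wherever the median-filtered 520 nm reflectance falls below the
#' blank threshold; blank glass reflects essentially all light and is
#' excluded. This is the denominator support for the nucleocytoplasmic
#' ratio.
#'
#' @param cube a [spectral_cube()] with a 520 nm band.
#' @param blank_threshold reflectance above which a pixel counts as blank
#'   (default 0.95: safely above stained tissue, below the ~1.0 of glass).
#' @param median_kernel kernel for the pre-threshold median filter.
#' @return logical tissue mask.
#' @export
tissue_mask <- function(cube, blank_threshold = 0.95, median_kernel = 3L) {
  img <- median_denoise(get_band(cube, 520L), median_kernel)
  img < blank_threshold
}

# integral-image window sums of M for all (row0, col0) in the 0-based grids
.window_sums <- function(M, rows0, cols0, w) {
  S <- matrix(0, nrow(M) + 1L, ncol(M) + 1L)
  S[-1L, -1L] <- t(apply(apply(M, 2L, cumsum), 1L, cumsum))
  # sum over rows (r0+1)..(r0+w), cols (c0+1)..(c0+w)
  outer(rows0, cols0, function(r0, c0) {
    S[cbind(r0 + w + 1L, c0 + w + 1L)] - S[cbind(r0 + 1L, c0 + w + 1L)] -
      S[cbind(r0 + w + 1L, c0 + 1L)] + S[cbind(r0 + 1L, c0 + 1L)]
  })
}

#' Scan a section with sliding windows
#'
#' Places `window_px`-square windows at every stride position fully inside
#' the frame (row-major order) and computes, per window, the nuclear and
#' tissue pixel counts, the keratin fraction of window area, the mean 660 nm
#' reflectance, and the nucleocytoplasmic ratio in percent (NA where the
#' window holds no tissue).
#'
#' @param masks a [structure_masks()].
#' @param cube the calibrated [spectral_cube()] (660 nm band used for the
#'   exposure statistic).
#' @param crit a [window_criteria()].
#' @return data frame with one row per window: `row0`, `col0` (0-based
#'   top-left), `nuclear_px`, `tissue_px`, `keratin_fraction`,
#'   `mean_reflectance`, `ratio_pct`.
#' @export
window_scan <- function(masks, cube, crit = window_criteria()) {
  H <- masks$shape[1L]; W <- masks$shape[2L]
  w <- crit$window_px; s <- crit$stride_px
  if (H < w || W < w) stop("frame smaller than window")
  rows0 <- seq.int(0L, H - w, by = s)
  cols0 <- seq.int(0L, W - w, by = s)
  nuc <- .window_sums(masks$nuclei * 1, rows0, cols0, w)
  tis <- .window_sums(masks$tissue * 1, rows0, cols0, w)
  ker <- .window_sums(masks$keratin * 1, rows0, cols0, w)
  refl <- .window_sums(get_band(cube, 660L), rows0, cols0, w)
  # row-major: row0 varies slowest
  grid <- expand.grid(col0 = cols0, row0 = rows0,
                      KEEP.OUT.ATTRS = FALSE)[, c("row0", "col0")]
  ri <- match(grid$row0, rows0); ci <- match(grid$col0, cols0)
  idx <- cbind(ri, ci)
  out <- data.frame(
    row0 = grid$row0, col0 = grid$col0,
    nuclear_px = as.integer(round(nuc[idx])),
    tissue_px = as.integer(round(tis[idx])),
    keratin_fraction = ker[idx] / w^2,
    mean_reflectance = refl[idx] / w^2
  )
  out$ratio_pct <- ifelse(out$tissue_px > 0L,
                          100 * out$nuclear_px / out$tissue_px, NA_real_)
  out
}

#' Exclude underexposed, blank, junction and off-tissue windows
#'
#' @param stats window table from [window_scan()].
#' @param crit a [window_criteria()].
#' @return the retained rows (possibly none).
#' @export
filter_windows <- function(stats, crit = window_criteria()) {
  w2 <- crit$window_px^2
  keep <- stats$mean_reflectance >= crit$min_mean_reflectance &
    stats$mean_reflectance <= crit$max_mean_reflectance &
    stats$keratin_fraction <= crit$max_keratin_fraction &
    stats$tissue_px / w2 >= crit$min_tissue_fraction
  stats[which(keep), , drop = FALSE]
}

#' Select the analysis windows
#'
#' Deterministic greedy selection: candidates ordered by descending tissue
#' coverage, ties broken row-major by (row0, col0); a candidate whose area
#' overlaps an already-selected window is skipped. Exactly `n_select`
#' windows are returned.
#'
#' @param eligible filtered window table from [filter_windows()].
#' @param crit a [window_criteria()].
#' @return data frame of `n_select` rows in selection order.
#' @export
select_windows <- function(eligible, crit = window_criteria()) {
  w <- crit$window_px
  ord <- order(-eligible$tissue_px, eligible$row0, eligible$col0)
  chosen <- integer(0)
  for (i in ord) {
    if (length(chosen) &&
        any(abs(eligible$row0[chosen] - eligible$row0[i]) < w &
            abs(eligible$col0[chosen] - eligible$col0[i]) < w)) {
      next
    }
    chosen <- c(chosen, i)
    if (length(chosen) == crit$n_select) break
  }
  if (length(chosen) < crit$n_select) stop("insufficient eligible windows")
  eligible[chosen, , drop = FALSE]
}

#' Nucleocytoplasmic ratio of a window, in percent
#'
#' @param nuclear_px,tissue_px pixel counts (vectorized).
#' @param denominator see [window_criteria()].
#' @return ratio in percent.
#' @export
#' @examples
#' nc_ratio(250, 10000) # 2.5
nc_ratio <- function(nuclear_px, tissue_px, denominator = "tissue") {
  if (any(tissue_px == 0)) stop("empty window")
  if (denominator == "tissue") {
    100 * nuclear_px / tissue_px
  } else {
    cyt <- tissue_px - nuclear_px
    if (any(cyt == 0)) stop("no cytoplasm in window")
    100 * nuclear_px / cyt
  }
}

#' Summarize a section's selected windows
#'
#' @param section_id identifier.
#' @param label one of `"normal"`, `"cscc"`, `"unknown"`.
#' @param selected window table from [select_windows()] (its `ratio_pct`
#'   column is summarized).
#' @return An object of class `section_summary` with the per-window ratios
#'   and their mean/max/min in percent.
#' @export
summarize_section <- function(section_id, label, selected) {
  label <- match.arg(label, c("normal", "cscc", "unknown"))
  ratios <- if (is.data.frame(selected)) selected$ratio_pct else selected
  if (length(ratios) == 0L) stop("empty selection")
  if (anyNA(ratios)) stop("selection contains windows without tissue")
  structure(list(section_id = section_id, label = label,
                 ratios_pct = as.numeric(ratios),
                 mean_pct = mean(ratios), max_pct = max(ratios),
                 min_pct = min(ratios)),
            class = "section_summary")
}

#' @export
print.section_summary <- function(x, ...) {
  cat(sprintf("<section_summary> %s [%s]: mean %.3f%%, min %.3f%%, max %.3f%% over %d windows\n",
              x$section_id, x$label, x$mean_pct, x$min_pct, x$max_pct,
              length(x$ratios_pct)))
  invisible(x)
}

#' Bind section summaries into a cohort table
#'
#' @param summaries list of [summarize_section()] objects.
#' @return data frame with one row per section: `section_id`, `label`,
#'   `mean_pct`, `max_pct`, `min_pct`.
#' @export
summaries_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(section_id = s$section_id, label = s$label,
               mean_pct = s$mean_pct, max_pct = s$max_pct,
               min_pct = s$min_pct, stringsAsFactors = FALSE)
  }))
}
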