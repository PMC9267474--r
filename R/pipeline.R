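#' Full pipeline configuration
#'
#' One validated bundle of every stage's parameters; unknown arguments are
#' rejected.
#'
#' @param wavelengths_nm required band grid.
#' @param eps minimum reference-minus-dark denominator (counts).
#' @param gamma a [gamma_params()] or NULL to skip illumination correction.
#' @param enhance an [enhance_params()].
#' @param thresh a [threshold_params()].
#' @param window a [window_criteria()].
#' @param blank_threshold tissue-mask reflectance ceiling.
#' @param var_equal pooled-variance t-test if TRUE (classical Student).
#' @param positive positive class label for ROC analysis.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(wavelengths_nm = seq(420L, 660L, by = 20L),
                            eps = 1,
                            gamma = gamma_params(),
                            enhance = enhance_params(),
                            thresh = threshold_params(),
                            window = window_criteria(),
                            blank_threshold = 0.95,
                            var_equal = TRUE,
                            positive = "cscc") {
  stopifnot(is.null(gamma) || inherits(gamma, "gamma_params"),
            inherits(enhance, "enhance_params"),
            inherits(thresh, "threshold_params"),
            inherits(window, "window_criteria"))
  if (blank_threshold <= 0 || blank_threshold > 1) {
    stop("blank_threshold must lie in (0, 1]")
  }
  structure(list(wavelengths_nm = as.integer(wavelengths_nm), eps = eps,
                 gamma = gamma, enhance = enhance, thresh = thresh,
                 window = window, blank_threshold = blank_threshold,
                 var_equal = var_equal, positive = positive),
            class = "pipeline_config")
}

#' Process one section: calibrate, segment, quantify
#'
#' @param stacks list of [raw_band_stack()], one per band.
#' @param cal a [calibration_frames()].
#' @param config a [pipeline_config()].
#' @param section_id,label identification carried into the summary.
#' @param keep_images retain the cube and masks in the result (they are
#'   large; the summary tables are usually all that is needed).
#' @return list with `summary` (a `section_summary`), `selected` and
#'   `windows` tables, and (if `keep_images`) `cube` and `masks`.
#' @export
process_section <- function(stacks, cal, config = pipeline_config(),
                            section_id = "section", label = "unknown",
                            keep_images = FALSE) {
  cube <- calibrate_cube(stacks, cal, gamma = config$gamma,
                         wavelengths_nm = config$wavelengths_nm,
                         eps = config$eps)
  tiss <- tissue_mask(cube, blank_threshold = config$blank_threshold,
                      median_kernel = config$enhance$median_kernel)
  masks <- segment_structures(cube, config$enhance, config$thresh,
                              tissue = tiss)
  windows <- window_scan(masks, cube, config$window)
  selected <- select_windows(filter_windows(windows, config$window),
                             config$window)
  summary <- summarize_section(section_id, label, selected)
  out <- list(summary = summary, selected = selected, windows = windows)
  if (keep_images) {
    out$cube <- cube
    out$masks <- masks
  }
  out
}

#' Simulate and analyze a full two-group cohort in memory
#'
#' Generates the synthetic cohort, then streams each section through
#' rendering, calibration, segmentation and window quantification
#' (discarding pixel data as it goes), and finishes with the group
#' comparison and ROC analysis. This is the one-call version of the whole
#' study.
#'
#' @param n_per_group sections per label.
#' @param seed master seed; every random draw derives from it.
#' @param config a [pipeline_config()].
#' @param presets,shape,imaging,model forwarded to [generate_cohort()].
#' @param verbose print one line per section.
#' @return An object of class `cohort_results`: `manifest` (with the true
#'   per-section nuclear fractions), `summaries` (per-section recovered
#'   mean/max/min ratios, percent), `selected` (all selected windows),
#'   `evaluation` (a `cohort_evaluation`).
#' @export
run_cohort <- function(n_per_group = 21L, seed = 1L,
                       config = pipeline_config(),
                       presets = list(normal = tissue_preset("normal"),
                                      cscc = tissue_preset("cscc")),
                       shape = c(512L, 640L),
                       imaging = imaging_model(),
                       model = spectral_model(),
                       verbose = FALSE) {
  cohort <- generate_cohort(n_per_group = n_per_group, seed = seed,
                            presets = presets, shape = shape,
                            imaging = imaging, model = model)
  summaries <- vector("list", nrow(cohort$manifest))
  selected <- vector("list", nrow(cohort$manifest))
  for (i in seq_len(nrow(cohort$manifest))) {
    m <- cohort$manifest[i, ]
    rendered <- render_cube(cohort$scenes[[i]], imaging, m$render_seed)
    res <- process_section(rendered$stacks, rendered$cal, config,
                           section_id = m$section_id, label = m$label)
    summaries[[i]] <- res$summary
    sel <- res$selected
    sel$section_id <- m$section_id
    sel$label <- m$label
    selected[[i]] <- sel
    if (verbose) {
      message(sprintf("%s [%s]: true %.3f%%, recovered mean %.3f%%",
                      m$section_id, m$label,
                      100 * m$realized_nuclear_fraction,
                      res$summary$mean_pct))
    }
  }
  summaries_df <- summaries_table(summaries)
  structure(list(manifest = cohort$manifest,
                 summaries = summaries_df,
                 selected = do.call(rbind, selected),
                 evaluation = evaluate_cohort(summaries_df,
                                              positive = config$positive,
                                              var_equal = config$var_equal),
                 seed = seed, shape = shape),
            class = "cohort_results")
}

#' @export
print.cohort_results <- function(x, ...) {
  cat(sprintf("<cohort_results> %d sections, seed %s\n",
              nrow(x$summaries), format(x$seed)))
  print(x$evaluation)
  invisible(x)
}

#' Analyze an on-disk cohort directory
#'
#' Reads a cohort written by [generate_cohort()] (or laid out the same way:
#' a `manifest.json` listing `section_id` and `label`, one directory per
#' section with band/dark/reference TIFFs), runs every section through the
#' pipeline, and writes `windows.csv`, `summaries.csv` and `stats.json`
#' into `out_dir`. Optionally writes the per-section masks and pseudo-color
#' overlay as PNG.
#'
#' @param dir cohort directory.
#' @param config a [pipeline_config()].
#' @param out_dir results directory (created); defaults to
#'   `file.path(dir, "results")`.
#' @param write_images also write mask/overlay PNGs per section.
#' @return An object of class `cohort_results` (invisibly); files under
#'   `out_dir`.
#' @export
run_directory <- function(dir, config = pipeline_config(),
                          out_dir = file.path(dir, "results"),
                          write_images = FALSE) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json under ", dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- list(); selected <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$section_id[i]
    sec <- read_section(file.path(dir, sid))
    res <- process_section(sec$stacks, sec$cal, config,
                           section_id = sid, label = manifest$label[i],
                           keep_images = write_images)
    if (write_images) {
      sdir <- file.path(out_dir, sid)
      dir.create(sdir, showWarnings = FALSE)
      for (nm in c("nuclei", "keratin", "collagen", "tissue")) {
        write_mask_png(res$masks[[nm]], file.path(sdir, paste0(nm, ".png")))
      }
      overlay <- compose_pseudocolor(res$masks, get_band(res$cube, 660L))
      png::writePNG(overlay, file.path(sdir, "pseudocolor.png"))
    }
    summaries[[i]] <- res$summary
    sel <- res$selected
    sel$section_id <- sid
    sel$label <- manifest$label[i]
    selected[[i]] <- sel
  }
  summaries_df <- summaries_table(summaries)
  selected_df <- do.call(rbind, selected)
  evaluation <- evaluate_cohort(summaries_df, positive = config$positive,
                                var_equal = config$var_equal)
  write.csv(selected_df, file.path(out_dir, "windows.csv"),
            row.names = FALSE)
  write.csv(summaries_df, file.path(out_dir, "summaries.csv"),
            row.names = FALSE)
  jsonlite::write_json(evaluation$table, file.path(out_dir, "stats.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(structure(list(manifest = manifest, summaries = summaries_df,
                           selected = selected_df, evaluation = evaluation,
                           out_dir = out_dir),
                      class = "cohort_results"))
}

#' Plain-text report of a cohort analysis
#'
#' Prints (and returns invisibly) the group mean ratios and, per summary
#' statistic, the t-test and AUC. Deterministic for fixed results.
#'
#' @param results a `cohort_results` (from [run_cohort()] or
#'   [run_directory()]) or a `cohort_evaluation`.
#' @return character vector of report lines, invisibly.
#' @export
report_cohort <- function(results) {
  ev <- if (inherits(results, "cohort_evaluation")) results
        else results$evaluation
  tb <- ev$table
  lines <- c(
    sprintf("Sections: %d normal, %d cSCC", ev$n_normal, ev$n_cscc),
    sprintf("Group mean nucleocytoplasmic ratio (mean statistic): normal %.3f%%, cSCC %.3f%%",
            tb$mean_normal[tb$statistic == "mean"],
            tb$mean_cscc[tb$statistic == "mean"]),
    vapply(seq_len(nrow(tb)), function(i) {
      sprintf("%-4s ratio: t = %8.3f, p = %.3g, AUC = %.3f",
              tb$statistic[i], tb$t_stat[i], tb$p_value[i], tb$auc[i])
    }, character(1))
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
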