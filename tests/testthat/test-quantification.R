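make_cube_const <- function(value, H = 120, W = 140,
                            wl = c(520L, 600L, 660L)) {
  spectral_cube(array(value, c(H, W, length(wl))), wl)
}

test_that("tissue mask separates tissue from blank glass", {
  blank <- make_cube_const(0.96)
  expect_false(any(tissue_mask(blank)))
  expect_true(all(tissue_mask(blank, blank_threshold = 1.0)))

  sc <- make_scene(tissue_preset("cscc"), shape = c(256, 320), seed = 51)
  tm <- tissue_mask(truth_cube(sc))
  structures <- sc$class_map %in% c(2L, 3L, 4L)
  expect_gte(sum(tm & structures) / sum(structures), 0.99)
})

test_that("window grid covers every full-fit stride position in row-major order", {
  masks <- structure_masks(matrix(FALSE, 300, 300), matrix(FALSE, 300, 300),
                           matrix(FALSE, 300, 300), matrix(TRUE, 300, 300))
  cube <- make_cube_const(0.5, 300, 300)
  w <- window_scan(masks, cube, window_criteria(stride_px = 100))
  expect_equal(nrow(w), 9L)
  expect_equal(w$row0, rep(c(0L, 100L, 200L), each = 3))
  expect_equal(w$col0, rep(c(0L, 100L, 200L), times = 3))
  expect_true(all(w$tissue_px == 10000L))
  expect_true(all(w$mean_reflectance == 0.5))
  expect_error(window_scan(masks, cube, window_criteria(window_px = 400)),
               "smaller than window")
})

test_that("window counts match exhaustive enumeration on a toy frame", {
  nuc <- matrix(c(TRUE, FALSE, FALSE, FALSE,
                  TRUE, TRUE, FALSE, FALSE,
                  FALSE, FALSE, FALSE, TRUE,
                  FALSE, FALSE, TRUE, TRUE), 4, 4, byrow = TRUE)
  ker <- matrix(FALSE, 4, 4); ker[1, 4] <- TRUE
  tis <- matrix(TRUE, 4, 4); tis[4, 1] <- FALSE
  masks <- structure_masks(nuc, ker, matrix(FALSE, 4, 4), tis,
                           band_used = c(nuclei = 660L, keratin = 600L,
                                         collagen = 520L))
  cube <- spectral_cube(array(0.25, c(4, 4, 3)), c(520L, 600L, 660L))
  crit <- window_criteria(window_px = 2, stride_px = 2, n_select = 1)
  w <- window_scan(masks, cube, crit)
  # hand enumeration of the four 2x2 windows, row-major
  expect_equal(w$row0, c(0L, 0L, 2L, 2L))
  expect_equal(w$col0, c(0L, 2L, 0L, 2L))
  expect_equal(w$nuclear_px, c(3L, 0L, 0L, 3L))
  expect_equal(w$keratin_fraction, c(0, 0.25, 0, 0))
  expect_equal(w$tissue_px, c(4L, 4L, 3L, 4L))
  expect_equal(w$ratio_pct, c(75, 0, 0, 75))
})

test_that("non-overlapping window counts conserve the frame totals", {
  set.seed(52)
  H <- 250L; W <- 310L
  nuc <- matrix(runif(H * W) < 0.1, H, W)
  tis <- matrix(runif(H * W) < 0.9, H, W)
  masks <- structure_masks(nuc & tis, matrix(FALSE, H, W),
                           matrix(FALSE, H, W), tis)
  cube <- make_cube_const(0.5, H, W)
  crit <- window_criteria(window_px = 50, stride_px = 50)
  w <- window_scan(masks, cube, crit)
  covered_r <- seq_len(250); covered_c <- seq_len(300)
  expect_equal(sum(w$nuclear_px), sum((nuc & tis)[covered_r, covered_c]))
  expect_equal(sum(w$tissue_px), sum(tis[covered_r, covered_c]))
})

test_that("window exclusion drops junction, underexposed and off-tissue windows", {
  base <- data.frame(row0 = 0L, col0 = 0L, nuclear_px = 100L,
                     tissue_px = 9000L, keratin_fraction = 0.01,
                     mean_reflectance = 0.8, ratio_pct = 1.1)
  crit <- window_criteria()
  expect_equal(nrow(filter_windows(base, crit)), 1L)
  junction <- transform(base, keratin_fraction = 0.5)
  expect_equal(nrow(filter_windows(junction, crit)), 0L)
  under <- transform(base, mean_reflectance = 0.05)
  expect_equal(nrow(filter_windows(under, crit)), 0L)
  blank <- transform(base, mean_reflectance = 0.99)
  expect_equal(nrow(filter_windows(blank, crit)), 0L)
  sparse <- transform(base, tissue_px = 4000L)
  expect_equal(nrow(filter_windows(sparse, crit)), 0L)
})

test_that("window selection is greedy, overlap-free and tie-broken row-major", {
  mk <- function(row0, col0, tissue) {
    data.frame(row0 = row0, col0 = col0, nuclear_px = 0L,
               tissue_px = tissue, keratin_fraction = 0,
               mean_reflectance = 0.8, ratio_pct = 0)
  }
  crit <- window_criteria(n_select = 2)
  # ties on tissue: the upper-left window must be taken first
  tied <- rbind(mk(100L, 100L, 9000L), mk(0L, 0L, 9000L),
                mk(0L, 300L, 9000L))
  sel <- select_windows(tied, crit)
  expect_equal(sel$row0, c(0L, 0L))
  expect_equal(sel$col0, c(0L, 300L))
  # an overlapping higher-coverage candidate blocks its neighbourhood
  over <- rbind(mk(0L, 0L, 10000L), mk(0L, 50L, 9900L), mk(0L, 200L, 9000L))
  sel2 <- select_windows(over, crit)
  expect_equal(sel2$col0, c(0L, 200L))
  expect_error(select_windows(over, window_criteria(n_select = 3)),
               "insufficient eligible windows")
  five <- do.call(rbind, lapply(0:4, function(k) mk(0L, 100L * k, 9000L)))
  sel5 <- select_windows(five, window_criteria(n_select = 5))
  expect_equal(nrow(sel5), 5L)
})

test_that("nucleocytoplasmic ratio arithmetic and its variants", {
  expect_equal(nc_ratio(0, 10000), 0)
  expect_equal(nc_ratio(250, 10000), 2.5)
  expect_equal(nc_ratio(10000, 10000), 100)
  expect_equal(nc_ratio(2000, 10000, denominator = "cytoplasm"), 25)
  expect_error(nc_ratio(5, 0), "empty window")
  expect_error(nc_ratio(10, 10, denominator = "cytoplasm"), "no cytoplasm")
})

test_that("section summaries report mean, max and min of the window ratios", {
  s <- summarize_section("s1", "normal", c(2, 4, 6, 8, 10))
  expect_equal(c(s$mean_pct, s$max_pct, s$min_pct), c(6, 10, 2))
  s1 <- summarize_section("s2", "cscc", 7.5)
  expect_equal(c(s1$mean_pct, s1$max_pct, s1$min_pct), c(7.5, 7.5, 7.5))
  set.seed(53)
  r <- runif(5, 0, 30)
  s2 <- summarize_section("s3", "unknown", r)
  expect_lte(s2$min_pct, s2$mean_pct)
  expect_lte(s2$mean_pct, s2$max_pct)
  expect_error(summarize_section("s4", "normal", numeric(0)),
               "empty selection")
  tbl <- summaries_table(list(s, s1))
  expect_equal(tbl$label, c("normal", "cscc"))
  expect_equal(tbl$mean_pct, c(6, 7.5))
})
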