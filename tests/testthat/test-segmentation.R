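test_that("local equalization: flat images pass, bimodal contrast expands", {
  flat <- matrix(0.62, 64, 64)
  expect_identical(equalize_local(flat), flat)

  set.seed(21)
  img <- matrix(sample(c(0.4, 0.6), 64 * 80, replace = TRUE), 64, 80)
  out <- equalize_local(img)
  expect_true(all(out >= 0 & out <= 1))
  expect_gt(max(out), max(img))
  expect_gt(diff(range(out)), diff(range(img)))
  expect_gt(sd(out), sd(img))
})

test_that("local equalization pads non-multiple shapes and checks size", {
  set.seed(22)
  img <- matrix(runif(100 * 110), 100, 110) # not divisible by 8
  out <- equalize_local(img)
  expect_identical(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 1))
  expect_error(equalize_local(matrix(runif(30), 5, 6)),
               "smaller than tile grid")
})

test_that("median filter agrees with the brute-force sort oracle", {
  flat <- matrix(0.5, 9, 9)
  expect_equal(median_denoise(flat, 3), flat)

  salt <- matrix(0, 7, 7); salt[4, 4] <- 1
  expect_equal(median_denoise(salt, 3), matrix(0, 7, 7))

  m <- matrix(c(9, 2, 7, 4, 5, 6, 3, 8, 1) / 10, 3, 3)
  expect_equal(median_denoise(m, 3)[2, 2], sort(as.numeric(m))[5])

  set.seed(23)
  for (k in c(3L, 5L)) {
    x <- matrix(runif(11 * 13), 11, 13)
    expect_equal(median_denoise(x, k), oracle_median_filter(x, k))
  }
  expect_error(median_denoise(flat, 4), "odd")
})

test_that("adaptive threshold matches the local-mean oracle and its symmetry", {
  flat <- matrix(0.5, 16, 16)
  expect_false(any(adaptive_threshold(flat, threshold_params(block_size = 7))))

  img <- matrix(0.8, 16, 16)
  img[7:10, 7:10] <- 0.2
  p <- threshold_params(block_size = 7, offset = 0.02)
  mask <- adaptive_threshold(img, p)
  expect_identical(mask, oracle_threshold_mask(img, 7L, 0.02))
  expect_true(all(mask[7:10, 7:10]))

  inv <- adaptive_threshold(1 - img,
                            threshold_params(block_size = 7, offset = 0.02,
                                             polarity = "bright_foreground"))
  expect_identical(inv, mask)

  expect_error(adaptive_threshold(img, threshold_params(block_size = 17)),
               "smaller than the image")
})

test_that("adaptive threshold oracle equivalence holds on random images", {
  set.seed(24)
  for (rep in 1:25) {
    H <- sample(8:32, 1); W <- sample(8:32, 1)
    img <- matrix(runif(H * W), H, W)
    bmax <- min(H, W) - 1L
    block <- sample(seq(3L, max(3L, bmax - !(bmax %% 2L)), by = 2L), 1)
    off <- runif(1, 0, 0.1)
    expect_identical(
      adaptive_threshold(img, threshold_params(block, off)),
      oracle_threshold_mask(img, block, off)
    )
  }
})

test_that("support-restricted thresholding ignores excluded pixels", {
  img <- matrix(0.9, 20, 30)
  img[, 21:30] <- 1.0   # bright blank region
  img[10, 5] <- 0.5     # one dark structure inside the supported area
  support <- matrix(FALSE, 20, 30); support[, 1:20] <- TRUE
  p <- threshold_params(block_size = 9, offset = 0.02)
  m_support <- adaptive_threshold(img, p, support = support)
  expect_true(m_support[10, 5])
  expect_false(any(m_support & !support))
  # with all pixels supported the result equals the unrestricted rule
  expect_identical(adaptive_threshold(img, p, matrix(TRUE, 20, 30)),
                   adaptive_threshold(img, p))
})

test_that("a nuclei-only scene yields empty keratin and collagen masks", {
  preset <- tissue_preset("custom", nuclear_fraction_target = 0.05,
                          collagen_fraction = 0)
  sc <- make_scene(preset, shape = c(256, 320), seed = 31)
  cube <- truth_cube(sc)
  masks <- segment_structures(cube)
  tiss <- sum(masks$tissue)
  expect_lt(sum(masks$keratin) / tiss, 0.005)
  expect_lt(sum(masks$collagen) / tiss, 0.005)
})

test_that("default cSCC scene nuclei area is recovered within 15 percent", {
  sc <- make_scene(tissue_preset("cscc"), seed = 32)
  r <- render_cube(sc, imaging_model(), seed = 33)
  cube <- calibrate_cube(r$stacks, r$cal)
  masks <- segment_structures(cube)
  true_px <- sum(sc$class_map == 2L)
  expect_lt(abs(sum(masks$nuclei) - true_px) / true_px, 0.15)
})

test_that("segmentation masks are disjoint, tissue-bound and deterministic", {
  sc <- make_scene(tissue_preset("cscc"), shape = c(256, 320), seed = 34)
  r <- render_cube(sc, imaging_model(), seed = 35)
  cube <- calibrate_cube(r$stacks, r$cal)
  m1 <- segment_structures(cube)
  m2 <- segment_structures(cube)
  expect_identical(m1, m2)
  expect_false(any(m1$nuclei & m1$keratin))
  expect_false(any(m1$nuclei & m1$collagen))
  expect_false(any(m1$keratin & m1$collagen))
  expect_true(all(m1$tissue[m1$nuclei | m1$keratin | m1$collagen]))

  cube12 <- spectral_cube(cube$data[, , cube$wavelengths_nm != 600L],
                          setdiff(cube$wavelengths_nm, 600L))
  expect_error(segment_structures(cube12), "missing band 600")
})

test_that("nuclei mask area tracks true nuclear fraction across scenes", {
  targets <- seq(0.02, 0.20, length.out = 10)
  est <- true <- numeric(10)
  for (i in seq_along(targets)) {
    preset <- tissue_preset("custom", nuclear_fraction_target = targets[i],
                            section_sd = 0)
    sc <- make_scene(preset, shape = c(256, 320), seed = 40 + i)
    masks <- segment_structures(truth_cube(sc))
    est[i] <- sum(masks$nuclei) / sum(masks$tissue)
    true[i] <- sc$realized_nuclear_fraction
  }
  expect_gte(cor(est, true, method = "spearman"), 0.9)
})

test_that("pseudo-color overlay paints classes with stated precedence", {
  bg <- matrix(0.5, 4, 4)
  empty <- matrix(FALSE, 4, 4)
  masks0 <- list(nuclei = empty, keratin = empty, collagen = empty)
  out <- compose_pseudocolor(masks0, bg)
  expect_equal(out, array(0.5, c(4, 4, 3)))

  nuc <- empty; nuc[2, 3] <- TRUE
  out1 <- compose_pseudocolor(list(nuclei = nuc, keratin = empty,
                                   collagen = empty), bg)
  expect_equal(out1[2, 3, ], c(0.54, 0.17, 0.89))
  expect_equal(sum(out1 != 0.5), 3)

  both <- empty; both[1, 1] <- TRUE
  out2 <- compose_pseudocolor(list(nuclei = empty, keratin = both,
                                   collagen = both), bg)
  expect_equal(out2[1, 1, ], c(1, 0, 0)) # keratin beats collagen

  expect_error(compose_pseudocolor(masks0, matrix(0.5, 5, 4)),
               "shape mismatch")
})
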