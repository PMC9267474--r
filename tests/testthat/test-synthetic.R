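test_that("scenes are seed-deterministic and preset-faithful", {
  s1 <- make_scene(tissue_preset("normal"), shape = c(200, 200), seed = 71)
  s2 <- make_scene(tissue_preset("normal"), shape = c(200, 200), seed = 71)
  expect_identical(s1$class_map, s2$class_map)
  expect_identical(s1$realized_nuclear_fraction, s2$realized_nuclear_fraction)

  expect_equal(sum(s1$class_map == 3L), 0L) # no pearls in normal skin
  s3 <- make_scene(tissue_preset("cscc"), shape = c(256, 320), seed = 72)
  expect_gt(sum(s3$class_map == 3L), 0L)
  expect_error(tissue_preset("normal", n_keratin_pearls = c(1, 2)),
               "zero keratin pearls")
  expect_error(make_scene(shape = c(150, 640)), "at least 200")
})

test_that("scene bookkeeping is exact and placement hits the target", {
  preset <- tissue_preset("custom", nuclear_fraction_target = 0.10,
                          section_sd = 0)
  sc <- make_scene(preset, shape = c(256, 320), seed = 73)
  expect_gte(sc$realized_nuclear_fraction, 0.097)
  expect_lte(sc$realized_nuclear_fraction, 0.103)
  recount <- sum(sc$class_map == 2L) / sum(sc$class_map != 0L)
  expect_identical(recount, sc$realized_nuclear_fraction)
  expect_lte(abs(sc$realized_nuclear_fraction - sc$jittered_target), 0.003)
  # tissue slab covers at least 80% of the frame
  expect_gte(mean(sc$class_map != 0L), 0.80)
})

test_that("spectral model peaks at the designated bands", {
  m <- spectral_model()
  expect_equal(ncol(m$absorbance), 13L)
  for (cl in c("nuclei", "keratin", "collagen")) {
    expect_equal(m$wavelengths_nm[which.max(m$absorbance[cl, ])],
                 as.integer(m$peak_nm[[cl]]))
  }
  expect_true(all(m$absorbance >= 0))
  sc <- make_scene(tissue_preset("cscc"), shape = c(200, 200), seed = 74)
  truth <- scene_reflectance(sc)
  # nuclei are darkest at 660 nm, keratin at 600, collagen at 520
  for (pair in list(c(2L, 660L), c(3L, 600L), c(4L, 520L))) {
    px <- which(sc$class_map == pair[1])[1]
    prof <- vapply(seq_len(13), function(b) truth$data[, , b][px], numeric(1))
    expect_equal(truth$wavelengths_nm[which.min(prof)], pair[2])
  }
})

test_that("rendering respects sensor bounds and the exact forward model", {
  sc <- make_scene(tissue_preset("cscc"), shape = c(200, 200), seed = 75)
  r <- render_cube(sc, imaging_model(), seed = 76)
  allvals <- unlist(lapply(r$stacks, function(s) range(s$frames[[1]])))
  expect_true(all(allvals >= 0 & allvals <= 255))
  for (wl in c("420", "540", "660")) {
    expect_true(all(r$cal$references[[wl]] >= r$cal$dark))
  }
  # noiseless, unvignetted glass pixels carry exactly ref_level + dark_level
  r0 <- render_cube(sc, imaging_model(noise_sd = 0, vignette_strength = 0),
                    seed = 77)
  glass <- sc$class_map == 0L
  expect_true(all(r0$stacks[["660"]]$frames[[1]][glass] == 238))
  expect_true(all(r0$cal$dark == 8))
})

test_that("darker nuclei absorb more: raw 660 nm counts drop monotonically", {
  p1 <- tissue_preset("custom", nuclear_fraction_target = 0.08,
                      nuclei_absorbance_mult = 1)
  p2 <- tissue_preset("custom", nuclear_fraction_target = 0.08,
                      nuclei_absorbance_mult = 1.5)
  s1 <- make_scene(p1, shape = c(200, 200), seed = 78)
  s2 <- make_scene(p2, shape = c(200, 200), seed = 78)
  expect_identical(s1$class_map, s2$class_map)
  r1 <- render_cube(s1, imaging_model(), seed = 79)
  r2 <- render_cube(s2, imaging_model(), seed = 79)
  nuc <- s1$class_map == 2L
  expect_lt(mean(r2$stacks[["660"]]$frames[[1]][nuc]),
            mean(r1$stacks[["660"]]$frames[[1]][nuc]))
})

test_that("cohort generation is deterministic, labelled and separated", {
  c1 <- generate_cohort(n_per_group = 3, seed = 80, shape = c(200, 200))
  c2 <- generate_cohort(n_per_group = 3, seed = 80, shape = c(200, 200))
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$scenes[[2]]$class_map, c2$scenes[[2]]$class_map)
  expect_equal(nrow(c1$manifest), 6L)
  expect_equal(as.numeric(table(c1$manifest$label)), c(3, 3))
  r1 <- render_cube(c1$scenes[[1]], c1$imaging, c1$manifest$render_seed[1])
  r2 <- render_cube(c2$scenes[[1]], c2$imaging, c2$manifest$render_seed[1])
  expect_identical(r1$stacks[["660"]]$frames, r2$stacks[["660"]]$frames)
  # true fractions separate completely between the groups
  fr <- c1$manifest$realized_nuclear_fraction
  expect_lt(max(fr[c1$manifest$label == "normal"]),
            min(fr[c1$manifest$label == "cscc"]))
  expect_error(generate_cohort(n_per_group = 1), ">= 2")
})

test_that("normal-group realized fractions are centred on the preset target", {
  coh <- generate_cohort(n_per_group = 21, seed = 81, shape = c(200, 200))
  fr <- coh$manifest$realized_nuclear_fraction[coh$manifest$label == "normal"]
  target <- 0.04239
  se <- target * 0.15 / sqrt(21)
  expect_lt(abs(mean(fr) - target), 2 * se)
})
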