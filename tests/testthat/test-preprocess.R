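test_that("unsharp mask is identity on constants and at zero amount", {
  const <- matrix(128, 40, 40)
  expect_identical(unsharp_mask(const, radius = 2, amount = 1.5), const)
  img <- fixture_image(40, 40)
  storage.mode(img) <- "double"
  expect_identical(unsharp_mask(img, radius = 3, amount = 0), img)
})

test_that("unsharp mask matches a brute-force dense convolution oracle", {
  x <- matrix(0, 7, 7)
  x[4, 4] <- 200
  expect_equal(unsharp_mask(x, radius = 1, amount = 1), bf_unsharp(x, 1, 1))
  # and on a random image with different settings
  img <- fixture_image(12, 9, seed = 3)
  expect_equal(unsharp_mask(img, radius = 1.5, amount = 2),
               bf_unsharp(img, 1.5, 2))
})

test_that("unsharp mask validates its inputs", {
  img <- fixture_image(40, 40)
  expect_error(unsharp_mask(img, radius = 0), "radius")
  expect_error(unsharp_mask(img, radius = -1), "radius")
  expect_error(unsharp_mask(img, radius = 1, amount = -0.5), "amount")
  expect_error(unsharp_mask(array(0, c(4, 4, 2)), radius = 1), "2-D")
})

test_that("single-tile CLAHE with unbounded clip equals global histogram equalization", {
  img <- fixture_image(64, 64)
  out <- clahe(img, clip_limit = 1e9, tile_grid = c(1, 1))
  expect_equal(out, global_histeq(img))
})

test_that("CLAHE preserves range, monotonicity, and handles non-divisible grids", {
  img <- fixture_image(64, 64, seed = 5)
  out <- clahe(img, clip_limit = 2, tile_grid = c(8, 8))
  expect_gte(min(out), 0)
  expect_lte(max(out), 255)
  # monotone in input intensity within one tile (tile 1 covers rows/cols 1:8)
  tile_in <- img[1:4, 1:4]  # well inside tile (1,1)'s influence region
  tile_out <- out[1:4, 1:4]
  ord <- order(tile_in)
  expect_true(all(diff(tile_out[ord]) >= -1e-9))
  # non-divisible image sides are mirror-padded then cropped
  img2 <- fixture_image(60, 70, seed = 6)
  out2 <- clahe(img2, 2, c(8, 8))
  expect_equal(dim(out2), c(60, 70))
  # tile grid larger than the image errors
  expect_error(clahe(img, 2, c(128, 8)), "tile_grid")
  expect_error(clahe(img, clip_limit = 0, tile_grid = c(2, 2)), "clip_limit")
})

test_that("preprocess pipeline has the 3-channel contract and is deterministic", {
  img <- fixture_image(64, 48, seed = 9)
  pp <- preprocess_pipeline(img)
  expect_equal(dim(pp), c(64, 48, 3))
  expect_equal(attr(pp, "channel_roles"), c("usm", "clahe_a", "clahe_b"))
  expect_gte(min(pp), 0)
  expect_lte(max(pp), 255)
  pp2 <- preprocess_pipeline(img)
  expect_identical(unclass(pp), unclass(pp2))
  # constant input: channel 1 is the unchanged input (USM identity)
  const <- matrix(77, 64, 64)
  ppc <- preprocess_pipeline(const)
  expect_equal(ppc[, , 1], const)
})

test_that("the two CLAHE settings must differ", {
  expect_error(preprocess_params(
    clahe_a = list(clip_limit = 2, tile_grid = c(8, 8)),
    clahe_b = list(clip_limit = 2, tile_grid = c(8, 8))), "differ")
})

test_that("enhancement does not reduce vessel/background contrast on synthetic vessels", {
  s <- generate_tree(synthetic_spec(), seed = 21)
  raw_contrast <- vessel_background_contrast(s$image$pixels, s$mask)
  pp <- preprocess_pipeline(s$image)
  enh <- (pp[, , 1] + pp[, , 2] + pp[, , 3]) / 3
  enh_contrast <- vessel_background_contrast(enh, s$mask)
  expect_gte(enh_contrast, raw_contrast)
})

test_that("normalized float inputs come back on their own scale", {
  img <- fixture_image(48, 48, seed = 2) / 255
  pp <- preprocess_pipeline(img)
  expect_lte(max(pp), 1)
  expect_equal(unclass(pp) * 255,
               unclass(preprocess_pipeline(round(img * 255))),
               tolerance = 1e-12)
})
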