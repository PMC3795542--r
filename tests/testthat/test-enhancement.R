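test_that("histogram equalization follows the CDF remap convention", {
  # constant image: the single occupied level has CDF 1
  cst <- grey_image(matrix(40, 6, 6))
  expect_equal(as.matrix(histogram_equalize(cst)), matrix(255, 6, 6))

  # two equally occupied levels at 50 and 200: CDF 0.5 and 1.0
  two <- grey_image(matrix(c(50, 200), 10, 10))
  out <- as.matrix(histogram_equalize(two))
  expect_equal(sort(unique(as.vector(out))), c(127.5, 255))
  expect_equal(out[two == 50][1], 127.5)

  # a ramp occupying all 256 levels equally maps to itself within a quantum
  ramp <- grey_image(matrix(0:255, 16, 16))
  r <- as.matrix(histogram_equalize(ramp))
  expect_lt(max(abs(r - as.matrix(ramp))), 1 + 1e-9)

  # monotone non-decreasing in the input level
  set.seed(51)
  f <- grey_image(random_image(12, 12))
  h <- as.matrix(histogram_equalize(f))
  o <- order(as.vector(as.matrix(f)))
  expect_true(all(diff(as.vector(h)[o]) >= -1e-12))
})

test_that("linear stretching spans the display range", {
  f <- grey_image(matrix(c(10, 60, 110), 3, 3))
  out <- as.matrix(linear_stretch(f))
  expect_equal(out[f == 10][1], 0)
  expect_equal(out[f == 60][1], 127.5)
  expect_equal(out[f == 110][1], 255)

  cst <- grey_image(matrix(99, 4, 4))
  expect_equal(as.matrix(linear_stretch(cst)), matrix(0, 4, 4))

  full <- grey_image(matrix(c(0, 100, 255), 3, 3))
  expect_equal(as.matrix(linear_stretch(full)), as.matrix(full))
})

test_that("greyscale modification handles featureless and two-level top-hats", {
  zero <- grey_image(matrix(0, 8, 8))
  expect_equal(as.matrix(greyscale_modify(zero)), matrix(0, 8, 8))

  cstth <- grey_image(matrix(3, 8, 8))
  expect_equal(as.matrix(greyscale_modify(cstth)), matrix(0, 8, 8))

  # 90% zeros / 10% at level 10: nonzero pixels end at 255, zeros at 0
  px <- matrix(0, 10, 10); px[1, ] <- 10
  out <- as.matrix(greyscale_modify(grey_image(px)))
  expect_equal(out[px == 10][1], 255)
  expect_equal(out[px == 0][1], 0)

  # any non-constant input spans exactly the display range
  set.seed(52)
  g <- grey_image(matrix(abs(rnorm(100, 5, 3)), 10, 10))
  out2 <- as.matrix(greyscale_modify(g))
  expect_equal(range(out2), c(0, 255))

  expect_error(greyscale_modify(grey_image(matrix(-1, 4, 4))), "nonnegative")
})

test_that("the enhancement operator respects its contracts", {
  cfg <- enhance_config(se_size = 7, n_rot = 4)
  cst <- grey_image(matrix(120, 50, 50))
  expect_equal(as.matrix(enhance_lambda(cst, cfg)), matrix(120, 50, 50))

  ph <- generate_phantom(phantom_spec(height = 70, width = 70, seed = 3))
  e1 <- enhance_lambda(ph$image, cfg)
  expect_true(all(as.matrix(e1) >= 0 & as.matrix(e1) <= 255))
  # deterministic: no hidden randomness
  e2 <- enhance_lambda(ph$image, cfg)
  expect_identical(as.matrix(e1), as.matrix(e2))
  expect_equal(display_range(e1), c(0, 255))
})

test_that("a target-free noise-free phantom passes through almost unchanged", {
  spec <- phantom_spec(height = 80, width = 80,
                       blobs = data.frame(row = numeric(), col = numeric(),
                                          radius = numeric(),
                                          amplitude = numeric()),
                       noise_sigma = 0)
  ph <- generate_phantom(spec)
  cfg <- enhance_config(se_size = 9, n_rot = 4)
  enh <- enhance_lambda(ph$image, cfg)
  # away from the border band (where monotone-ramp residues of the clamped
  # composition live) the top-hats are zero and lambda is the identity
  interior <- 13:68
  expect_equal(as.matrix(enh)[interior, interior],
               as.matrix(ph$image)[interior, interior], tolerance = 1e-8)
  # local contrast is unchanged wherever the windows cannot reach the band
  cfgc <- cir_config(rc = 5, rn = 11)
  dC <- abs(as.matrix(local_contrast_map(enh, cfgc)) -
              as.matrix(local_contrast_map(ph$image, cfgc)))
  expect_lt(max(dC[interior, interior]), 1e-12)
})

test_that("pre-smoothing runs and stays within range", {
  ph <- generate_phantom(phantom_spec(height = 60, width = 60, seed = 5))
  cfg <- enhance_config(se_size = 9, n_rot = 2, presmooth = TRUE)
  enh <- enhance_lambda(ph$image, cfg)
  expect_true(all(as.matrix(enh) >= 0 & as.matrix(enh) <= 255))
})

test_that("rescale range mode spans the display range", {
  ph <- generate_phantom(phantom_spec(height = 60, width = 60, seed = 6))
  cfg <- enhance_config(se_size = 9, n_rot = 2, range_mode = "rescale")
  enh <- enhance_lambda(ph$image, cfg)
  expect_equal(range(as.matrix(enh)), c(0, 255))
})
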