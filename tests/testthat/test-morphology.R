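test_that("dilation and erosion match the brute-force oracle exactly", {
  set.seed(11)
  ses <- list(make_structuring_element("disc", 3),
              make_structuring_element("disc", 5),
              make_structuring_element("square", 3),
              make_structuring_element("line", 5, angle = pi / 5))
  for (i in 1:25) {
    px <- random_image(15, 17)
    for (B in ses) {
      expect_equal(as.matrix(dilate(px, B)), naive_dilate(px, B))
      expect_equal(as.matrix(erode(px, B)), naive_erode(px, B))
    }
  }
})

test_that("single-pixel features behave as documented", {
  B <- make_structuring_element("square", 3)
  f <- matrix(0, 5, 5); f[3, 3] <- 9
  d <- as.matrix(dilate(f, B))
  expect_equal(d[2:4, 2:4], matrix(9, 3, 3))
  expect_equal(sum(d), 9 * 9)
  # peak smaller than the SE is removed by opening
  expect_equal(as.matrix(opening(f, B)), matrix(0, 5, 5))
  # dark pit is filled by closing
  g <- matrix(9, 5, 5); g[3, 3] <- 0
  expect_equal(as.matrix(closing(g, B)), matrix(9, 5, 5))
  e <- as.matrix(erode(g, B))
  expect_equal(e[2:4, 2:4], matrix(0, 3, 3))
})

test_that("constant images are fixed points of all four operators", {
  f <- matrix(7, 6, 9)
  for (B in list(make_structuring_element("disc", 5),
                 make_structuring_element("line", 5, angle = 1))) {
    expect_equal(as.matrix(dilate(f, B)), f)
    expect_equal(as.matrix(erode(f, B)), f)
    expect_equal(as.matrix(opening(f, B)), f)
    expect_equal(as.matrix(closing(f, B)), f)
  }
})

test_that("ordering chain erode <= opening <= f <= closing <= dilate holds", {
  set.seed(12)
  ses <- list(make_structuring_element("disc", 5),
              make_structuring_element("square", 3),
              make_structuring_element("line", 5, angle = 0))
  for (i in 1:10) {
    f <- random_image(12, 14)
    for (B in ses) {
      e <- as.matrix(erode(f, B)); o <- as.matrix(opening(f, B))
      cl <- as.matrix(closing(f, B)); d <- as.matrix(dilate(f, B))
      expect_true(all(e <= o))
      expect_true(all(o <= f))
      expect_true(all(f <= cl))
      expect_true(all(cl <= d))
    }
  }
  # oblique line elements: the chain holds away from the border band
  B <- make_structuring_element("line", 7, angle = 0.7)
  idx <- 8:17
  for (i in 1:10) {
    f <- random_image(24, 24)
    o <- as.matrix(opening(f, B))[idx, idx]
    cl <- as.matrix(closing(f, B))[idx, idx]
    expect_true(all(as.matrix(erode(f, B))[idx, idx] <= o))
    expect_true(all(o <= f[idx, idx]))
    expect_true(all(f[idx, idx] <= cl))
    expect_true(all(cl <= as.matrix(dilate(f, B))[idx, idx]))
  }
})

test_that("opening and closing are idempotent on integer images", {
  set.seed(13)
  for (B in list(make_structuring_element("disc", 5),
                 make_structuring_element("square", 3))) {
    for (i in 1:10) {
      f <- random_image(10, 10)
      o <- opening(f, B); cl <- closing(f, B)
      expect_equal(as.matrix(opening(o, B)), as.matrix(o))
      expect_equal(as.matrix(closing(cl, B)), as.matrix(cl))
    }
  }
  # oblique line elements: idempotent away from the border band, where the
  # replicate rule interacts with the diagonal offsets
  B <- make_structuring_element("line", 5, angle = 1.2)
  for (i in 1:10) {
    f <- random_image(24, 24)
    o <- opening(f, B); cl <- closing(f, B)
    expect_equal(as.matrix(opening(o, B))[9:16, 9:16],
                 as.matrix(o)[9:16, 9:16])
    expect_equal(as.matrix(closing(cl, B))[9:16, 9:16],
                 as.matrix(cl)[9:16, 9:16])
  }
})

test_that("duality identities hold exactly", {
  set.seed(14)
  B <- make_structuring_element("disc", 5)
  for (i in 1:10) {
    f <- random_image(12, 12)
    # erosion is the dual of dilation under negation (symmetric SE)
    expect_equal(as.matrix(erode(f, B)), -as.matrix(dilate(-f, B)))
    expect_equal(as.matrix(closing(f, B)), -as.matrix(opening(-f, B)))
  }
})

test_that("all four operators are increasing", {
  set.seed(15)
  B <- make_structuring_element("disc", 3)
  for (i in 1:10) {
    f <- random_image(10, 10)
    g <- f + random_image(10, 10, 20)  # g >= f pointwise
    for (op in list(dilate, erode, opening, closing)) {
      expect_true(all(as.matrix(op(f, B)) <= as.matrix(op(g, B))))
    }
  }
})
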