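# Geometric transforms, online augmentation and six-view TTA.

test_that("every transform is exactly inverted by its inverse", {
  set.seed(1)
  m <- matrix(rnorm(81), 9)
  for (tr in tta_transforms()) {
    back <- apply_transform(apply_transform(m, tr), transform_inverse(tr))
    expect_identical(back, m)
  }
  # rot180 is an involution
  expect_identical(apply_transform(apply_transform(m, "rot180"), "rot180"), m)
  # rot90 really rotates: top-left corner moves to top-right
  m2 <- matrix(0, 3, 3); m2[1, 1] <- 1
  expect_equal(apply_transform(m2, "rot90")[1, 3], 1)
})

test_that("quarter rotations reject non-square grids", {
  expect_error(apply_transform(matrix(0, 2, 3), "rot90"), "square")
  expect_silent(apply_transform(matrix(0, 2, 3), "hflip"))
})

test_that("augment_pair applies one joint transform and is seed-reproducible", {
  set.seed(2)
  img <- matrix(runif(64), 8)
  msk <- random_mask(8)
  a1 <- augment_pair(img, msk, rng_seed = 123)
  a2 <- augment_pair(img, msk, rng_seed = 123)
  expect_identical(a1, a2)
  expect_true(a1$transform %in% tta_transforms())
  # mask stays binary with the same foreground count; image/mask aligned
  expect_true(all(a1$mask %in% c(0, 1)))
  expect_equal(sum(a1$mask), sum(msk))
  expect_identical(a1$image, apply_transform(img, a1$transform))
  expect_identical(a1$mask, apply_transform(msk, a1$transform))
})

test_that("TTA performs exactly six forward passes and averages aligned maps", {
  calls <- 0L
  const_model <- function(im) { calls <<- calls + 1L; im * 0 + 0.37 }
  img <- matrix(runif(64), 8)
  out <- tta_predict(const_model, img)
  expect_equal(calls, 6L)
  expect_equal(out, img * 0 + 0.37)
})

test_that("TTA of an identity pixel map returns the input exactly", {
  img <- matrix(runif(144), 12)
  expect_equal(tta_predict(function(im) im, img), img, tolerance = 1e-15)
})

test_that("TTA equals a hand-rolled loop over the six transforms", {
  # a deterministic, orientation-sensitive "model"
  f <- function(im) stats::plogis(im + 0.25 * row(im) / nrow(im) - 0.4 * col(im) / ncol(im))
  img <- matrix(runif(100), 10)
  acc <- matrix(0, 10, 10)
  for (tr in c("identity", "rot90", "rot180", "rot270", "hflip", "vflip"))
    acc <- acc + apply_transform(f(apply_transform(img, tr)),
                                 transform_inverse(tr))
  expect_equal(tta_predict(f, img), acc / 6, tolerance = 1e-14)
})

test_that("TTA on a real model is the mean of its six inverse-aligned views", {
  m <- build_model(tiny_config(), seed = 2)
  img <- matrix(0.5, 32, 32)
  acc <- matrix(0, 32, 32)
  for (tr in tta_transforms())
    acc <- acc + apply_transform(predict(m, apply_transform(img, tr)),
                                 transform_inverse(tr))
  expect_equal(tta_predict(m, img), acc / 6, tolerance = 1e-12)
})
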