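# Speckle phantom generator: determinism, geometry, intensity statistics,
# dataset round trips.

test_that("the same seed reproduces a phantom bit-identically", {
  a <- generate_phantom(phantom_config(size = 64, seed = 7))
  b <- generate_phantom(phantom_config(size = 64, seed = 7))
  expect_identical(a, b)
  c <- generate_phantom(phantom_config(size = 64, seed = 8))
  expect_false(identical(a$image, c$image))
})

test_that("phantom image lies in [0,1] with a binary, connected mask", {
  for (seed in 1:8) {
    ph <- generate_phantom(phantom_config(size = 64, seed = seed))
    expect_true(all(ph$image >= 0 & ph$image <= 1))
    expect_true(all(ph$mask %in% c(0, 1)))
    expect_gt(sum(ph$mask), 0)
    lab <- EBImage::bwlabel(ph$mask)
    expect_equal(max(lab), 1)  # one nodule -> one connected component
  }
})

test_that("nodules are hypoechoic: interior darker than surroundings", {
  n_fail <- 0L
  n <- 300L
  for (seed in seq_len(n)) {
    ph <- generate_phantom(phantom_config(size = 64, seed = 10000 + seed))
    if (mean(ph$image[ph$mask == 1]) >= mean(ph$image[ph$mask == 0]))
      n_fail <- n_fail + 1L
  }
  expect_lt(n_fail / n, 0.01)
})

test_that("zero irregularity yields an ellipse with the configured axis ratio", {
  ph <- generate_phantom(phantom_config(size = 128, irregularity = 0,
                                        aspect = 0.6, seed = 3))
  fg <- which(ph$mask == 1, arr.ind = TRUE)
  ev <- eigen(stats::cov(fg))$values
  measured_aspect <- sqrt(ev[2] / ev[1])
  expect_equal(measured_aspect, 0.6, tolerance = 0.05)
})

test_that("speckle is multiplicative: darker regions have smaller variance", {
  ph <- generate_phantom(phantom_config(size = 128, blur_sigma = 0.5,
                                        calcification_rate = 0, seed = 11))
  inside <- ph$image[ph$mask == 1]
  outside <- ph$image[ph$mask == 0]
  expect_lt(stats::var(inside), stats::var(outside))
})

test_that("configuration validation catches out-of-range parameters", {
  expect_error(phantom_config(contrast = 1.2), "contrast")
  expect_error(phantom_config(size = 4), "size")
  expect_error(phantom_config(aspect = 0), "aspect")
})

test_that("generate_dataset writes n consistent pairs and a faithful manifest", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(10, phantom_config(size = 32, seed = 77), dir)
  expect_equal(nrow(man), 10)
  expect_true(all(file.exists(file.path(dir, man$image))))
  expect_true(all(file.exists(file.path(dir, man$mask))))
  # manifest areas equal recomputed foreground counts from the files
  for (i in c(1, 5, 10)) {
    m <- png::readPNG(file.path(dir, man$mask[i]))
    expect_equal(sum(m > 0.5), man$area[i])
  }
})

test_that("re-running generate_dataset with the same master seed is byte-identical", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(4, phantom_config(size = 32, seed = 5), d1)
  m2 <- generate_dataset(4, phantom_config(size = 32, seed = 5), d2)
  expect_identical(m1, m2)
  for (f in c(m1$image, m1$mask))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
})
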