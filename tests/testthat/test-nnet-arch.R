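# Architecture components: pyramid, attention gate, SDC block, receptive
# fields, model assembly and parameter accounting.

test_that("multi-scale pyramid halves sizes and preserves means", {
  img <- matrix(runif(512 * 512), 512)
  p <- multi_scale_pyramid(img, levels = 4)
  expect_equal(vapply(p, nrow, numeric(1)), c(512, 256, 128, 64))
  expect_identical(p[[1]], img)
  # exact mean conservation at every level
  for (l in p) expect_equal(mean(l), mean(img), tolerance = 1e-14)
})

test_that("pyramid of a constant image is constant; checkerboard averages to 0.5", {
  cst <- multi_scale_pyramid(matrix(0.37, 16, 16), levels = 3)
  for (l in cst) expect_true(all(l == 0.37))
  cb <- matrix(c(0, 1), 4, 4)  # columns alternate 0,1 within each 2x2 block
  lv <- multi_scale_pyramid(cb, levels = 2)
  expect_equal(lv[[2]], matrix(0.5, 2, 2))
})

test_that("pyramid rejects non-divisible dimensions, naming the axis", {
  expect_error(multi_scale_pyramid(matrix(0, 6, 8), 3), "height")
  expect_error(multi_scale_pyramid(matrix(0, 8, 6), 3), "width")
})

test_that("attention gate keeps shape and its coefficients lie in (0,1)", {
  set.seed(11)
  for (C in c(1L, 3L, 8L)) {
    fm <- array(rnorm(16 * 16 * C), c(16, 16, C))
    img <- matrix(runif(16 * 16), 16)
    a <- attention_guidance(img, fm, seed = C)
    expect_equal(dim(a), dim(fm))
    g <- attr(a, "gate")
    expect_true(all(g > 0 & g < 1))
  }
})

test_that("zero gating weights give g = 0.5 everywhere, A = f_m / 2", {
  fm <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  w <- attention_weights(4, seed = 1)
  w <- lapply(w, function(x) x * 0)
  a <- attention_guidance(matrix(runif(64), 8), fm, weights = w)
  expect_equal(attr(a, "gate"), matrix(0.5, 8, 8))
  expect_equal(unclass(a), fm * 0.5, ignore_attr = TRUE)
})

test_that("attention gate rejects spatially mismatched inputs", {
  expect_error(
    attention_guidance(matrix(0, 8, 8), array(0, c(16, 16, 2))),
    "spatial mismatch")
})

test_that("SDC block preserves shape for random shapes and channel counts", {
  set.seed(21)
  for (i in 1:12) {
    h <- sample(c(6, 8, 9, 12, 16), 1)
    w <- sample(c(6, 8, 9, 12, 16), 1)
    C <- sample(1:6, 1)
    f <- array(rnorm(h * w * C), c(h, w, C))
    out <- sdc_block(f, seed = i)
    expect_equal(dim(out), dim(f))
    expect_true(all(is.finite(out)))
  }
})

test_that("SDC of a zero input with zero biases is zero; identity branch returns input", {
  C <- 3L
  f0 <- array(0, c(8, 8, C))
  expect_true(all(sdc_block(f0, seed = 5) == 0))
  # single branch [1]: zero 3x3 conv, identity 1x1 -> branch contributes 0
  # after ReLU of 0 stays 0 through the 1x1; output = input via the skip
  w <- sdc_weights(C, branches = list(1L), seed = 1)
  w[["b1.c1.w"]][] <- 0
  id <- array(0, c(1, 1, C, C))
  for (c in seq_len(C)) id[1, 1, c, c] <- 1
  w[["b1.p.w"]] <- id
  f <- array(abs(rnorm(8 * 8 * C)), c(8, 8, C))
  out <- sdc_block(f, branches = list(1L), weights = w)
  expect_equal(out, f)
})

test_that("receptive fields of the four SDC branches are 3, 7, 9, 31", {
  rfs <- vapply(sdc_default_branches(),
                function(b) receptive_field(sdc_branch_specs(b)), numeric(1))
  expect_equal(rfs, c(3, 7, 9, 31))
  expect_equal(receptive_field(list(layer_spec(1, 1))), 1)
})

test_that("analytic receptive field matches the impulse-response footprint", {
  for (b in sdc_default_branches()) {
    stack <- sdc_branch_specs(b)
    expect_equal(receptive_field_empirical(stack, size = 71),
                 receptive_field(stack))
  }
  # a non-default cascade as well
  stack <- list(layer_spec(3, 2), layer_spec(5, 1))
  expect_equal(receptive_field_empirical(stack, size = 41),
               receptive_field(stack))
})

test_that("layer and stack validation rejects bad specs", {
  expect_error(layer_spec(4, 1), "odd")
  expect_error(layer_spec(3, 0), "dilation")
  expect_error(receptive_field(list()), "nonempty")
  expect_error(receptive_field(list(layer_spec(3, 1, s = 2))), "stride")
})

test_that("conv parameter count follows the closed form and ignores dilation", {
  expect_equal(conv_param_count(3, 8, 8), 584)
  expect_equal(conv_param_count(1, 16, 16, bias = FALSE), 256)
  # the stored kernel of a dilated conv has the same size for any rate
  for (d in c(1L, 3L, 11L)) {
    w <- sdc_weights(4, branches = list(d), seed = 2)
    expect_equal(count_parameters(w),
                 conv_param_count(3, 4, 4) + conv_param_count(1, 4, 4))
  }
})

test_that("model builds for all ablation configs with nested parameter counts", {
  cfgs <- ablation_configs(32, 3, 4)
  counts <- vapply(cfgs, function(cf) count_parameters(build_model(cf, 1)),
                   numeric(1))
  expect_true(all(diff(counts) > 0))  # strictly increasing row 1 -> 4
})

test_that("forward pass maps an image to same-size probabilities in (0,1)", {
  m <- build_model(tiny_config(), seed = 7)
  img <- matrix(runif(32 * 32), 32)
  p <- predict(m, img)
  expect_equal(dim(p), c(32, 32))
  expect_true(all(p > 0 & p < 1))
  # spatial-size preservation on another valid input size (fully conv)
  img2 <- matrix(runif(64 * 64), 64)
  p2 <- predict(m, img2)
  expect_equal(dim(p2), c(64, 64))
})

test_that("invalid configurations are rejected before weight allocation", {
  expect_error(arch_config(depth = 1), "depth")
  expect_error(arch_config(input_size = 100, depth = 3), "divisible")
  expect_error(arch_config(sdc_branches = list(c(1, 0))), "rates")
  expect_error(build_model(list()), "arch_config")
})

test_that("same seed gives identical weights; different seed does not", {
  m1 <- build_model(tiny_config(), seed = 3)
  m2 <- build_model(tiny_config(), seed = 3)
  m3 <- build_model(tiny_config(), seed = 4)
  expect_identical(sdcnet:::model_state(m1), sdcnet:::model_state(m2))
  expect_false(identical(sdcnet:::model_state(m1)$params$enc1.c1.w,
                         sdcnet:::model_state(m3)$params$enc1.c1.w))
})
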