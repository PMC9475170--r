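# Differentiation engine: kernels against naive oracles, gradients against
# finite differences.

naive_conv <- function(x, w, b, dil, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; N <- dim(x)[4]
  k <- dim(w)[1]; Cout <- dim(w)[4]
  Ho <- H + 2 * pad - dil * (k - 1)
  Wo <- W + 2 * pad - dil * (k - 1)
  out <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (oh in 1:Ho) for (ow in 1:Wo) {
    s <- b[co]
    for (ci in 1:Cin) for (kh in 1:k) for (kw in 1:k) {
      ih <- oh - pad + (kh - 1) * dil
      iw <- ow - pad + (kw - 1) * dil
      if (ih >= 1 && ih <= H && iw >= 1 && iw <= W)
        s <- s + x[ih, iw, ci, n] * w[kh, kw, ci, co]
    }
    out[oh, ow, co, n] <- s
  }
  out
}

test_that("dilated convolution matches a naive quadruple-loop oracle", {
  set.seed(42)
  cases <- list(list(k = 3, d = 1, p = 1, H = 8), list(k = 3, d = 3, p = 3, H = 8),
                list(k = 3, d = 11, p = 11, H = 8), list(k = 1, d = 1, p = 0, H = 6),
                list(k = 3, d = 2, p = 0, H = 10))
  for (cs in cases) {
    x <- array(rnorm(cs$H * cs$H * 3 * 2), c(cs$H, cs$H, 3, 2))
    w <- array(rnorm(cs$k^2 * 3 * 4), c(cs$k, cs$k, 3, 4))
    b <- rnorm(4)
    expect_equal(sdcnet:::cpp_conv2d_fw(x, w, b, cs$d, cs$p),
                 naive_conv(x, w, b, cs$d, cs$p), tolerance = 1e-12)
  }
})

test_that("bilinear upsampling doubles size and reproduces constants exactly", {
  x <- array(0.42, c(5, 7, 2, 1))
  u <- sdcnet:::cpp_upsample2_fw(x)
  expect_equal(dim(u), c(10, 14, 2, 1))
  expect_true(all(abs(u - 0.42) < 1e-14))
})

test_that("model gradients agree with central finite differences", {
  cfg <- arch_config(16, depth = 2, base_channels = 2)
  m <- build_model(cfg, seed = 3)
  set.seed(9)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  y <- array((runif(16 * 16 * 2) > 0.5) * 1, c(16, 16, 1, 2))
  fwd_loss <- function() {
    out <- sdcnet:::forward_nnet(m, x, training = TRUE)
    sdcnet:::ad_bce_logits(out$logit, y)
  }
  loss <- fwd_loss()
  sdcnet:::ad_backward(loss)
  # one sampled coordinate from a spread of layers across the network
  picks <- names(m$params)[seq(1, length(m$params), by = 6)]
  for (nm in picks) {
    p <- m$params[[nm]]
    i <- sample(length(p$value), 1)
    g <- if (is.null(p$grad)) 0 else p$grad[i]
    st <- sdcnet:::model_state(m)
    eps <- 1e-5
    p$value[i] <- p$value[i] + eps
    l1 <- fwd_loss()$value
    sdcnet:::restore_state(m, st)
    p$value[i] <- p$value[i] - eps
    l0 <- fwd_loss()$value
    sdcnet:::restore_state(m, st)
    fd <- (l1 - l0) / (2 * eps)
    expect_equal(g, fd, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})

test_that("an Adam step with zero learning rate leaves weights unchanged", {
  m <- build_model(arch_config(16, depth = 2, base_channels = 2), seed = 1)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  y <- array(1, c(16, 16, 1, 1))
  out <- sdcnet:::forward_nnet(m, x, training = TRUE)
  sdcnet:::ad_backward(sdcnet:::ad_bce_logits(out$logit, y))
  before <- sdcnet:::model_state(m)$params
  opt <- sdcnet:::adam_init(m$params)
  sdcnet:::adam_step(m$params, opt, lr = 0)
  expect_identical(sdcnet:::model_state(m)$params, before)
})
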