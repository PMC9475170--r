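# Minimal reverse-mode differentiation tape.
#
# Nodes are environments carrying a value (a 4-d array, layout H x W x C x N,
# except the loss which is scalar), an accumulated gradient, parent links and
# a backward closure. The graph is rebuilt on every forward pass; parameter
# nodes persist across passes so the optimizer can update them in place.

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L

.new_node <- function(value, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  .ad$id <- .ad$id + 1L
  e$id <- .ad$id
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$is_param <- FALSE
  class(e) <- "ad_node"
  e
}

ad_param <- function(value) {
  n <- .new_node(value)
  n$is_param <- TRUE
  n
}

ad_const <- function(value) .new_node(value)

.acc <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Reverse sweep from a scalar loss node. Gradients of every node reachable
# from `loss` are reset before accumulation, so one call per step suffices.
ad_backward <- function(loss) {
  topo <- vector("list", 256L)
  n_topo <- 0L
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  stack <- list(list(node = loss, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents)
        if (is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      n_topo <- n_topo + 1L
      if (n_topo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[n_topo]] <- node
    }
  }
  topo <- topo[seq_len(n_topo)]
  for (n in topo) n$grad <- NULL
  loss$grad <- 1
  for (n in rev(topo))
    if (!is.null(n$backward) && !is.null(n$grad)) n$backward(n$grad)
  invisible(loss)
}

## ---- differentiable operations ------------------------------------------

ad_conv2d <- function(x, w, b, dilation = 1L, pad = 0L) {
  v <- cpp_conv2d_fw(x$value, w$value, b$value, dilation, pad)
  .new_node(v, list(x, w, b), function(g) {
    r <- cpp_conv2d_bw(g, x$value, w$value, dilation, pad)
    .acc(x, r$dx); .acc(w, r$dw); .acc(b, r$db)
  })
}

ad_relu <- function(x) {
  v <- x$value
  mask <- v > 0
  v[!mask] <- 0
  .new_node(v, list(x), function(g) .acc(x, g * mask))
}

ad_sigmoid <- function(x) {
  s <- stats::plogis(x$value)
  dim(s) <- dim(x$value)
  .new_node(s, list(x), function(g) .acc(x, g * s * (1 - s)))
}

ad_add <- function(a, b) {
  .new_node(a$value + b$value, list(a, b), function(g) {
    .acc(a, g); .acc(b, g)
  })
}

ad_maxpool2 <- function(x) {
  r <- cpp_maxpool2_fw(x$value)
  xd <- dim(x$value)
  .new_node(r$out, list(x), function(g) .acc(x, cpp_maxpool2_bw(g, r$idx, xd)))
}

ad_avgpool2 <- function(x) {
  xd <- dim(x$value)
  .new_node(cpp_avgpool2_fw(x$value), list(x),
            function(g) .acc(x, cpp_avgpool2_bw(g, xd)))
}

ad_upsample2 <- function(x) {
  xd <- dim(x$value)
  .new_node(cpp_upsample2_fw(x$value), list(x),
            function(g) .acc(x, cpp_upsample2_bw(g, xd)))
}

# Concatenate along the channel axis (dim 3).
ad_concat <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  v <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  v[, , seq_len(da[3]), ] <- a$value
  v[, , da[3] + seq_len(db[3]), ] <- b$value
  .new_node(v, list(a, b), function(g) {
    .acc(a, g[, , seq_len(da[3]), , drop = FALSE])
    .acc(b, g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# Multiply a one-channel gate (H,W,1,N) onto every channel of x (H,W,C,N).
ad_gate_mul <- function(gate, x) {
  .new_node(cpp_gate_mul_fw(gate$value, x$value), list(gate, x), function(g) {
    r <- cpp_gate_mul_bw(g, gate$value, x$value)
    .acc(x, r$dx)
    .acc(gate, r$dgate)
  })
}

# Channel sums over (H, W, N); a: array (H,W,C,N) -> length-C vector.
.ch_sum <- function(a) cpp_ch_sum(a)

# Batch normalisation over (H, W, N) per channel. `state` is an environment
# with running `mean` and `var`, updated in training mode.
ad_batchnorm <- function(x, gamma, beta, state, training = FALSE,
                         momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  m <- prod(d[c(1, 2, 4)])
  bc <- function(v) rep(v, each = d[1] * d[2])  # recycles over batch dim
  if (training) {
    mu <- .ch_sum(x$value) / m
    xc <- x$value - bc(mu)
    va <- .ch_sum(xc * xc) / m
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va * m / max(m - 1, 1)
  } else {
    mu <- state$mean
    va <- state$var
    xc <- x$value - bc(mu)
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * bc(istd)
  v <- xhat * bc(gamma$value) + bc(beta$value)
  dim(v) <- d
  .new_node(v, list(x, gamma, beta), function(g) {
    .acc(gamma, .ch_sum(g * xhat))
    .acc(beta, .ch_sum(g))
    dxhat <- g * bc(gamma$value)
    if (training) {
      t1 <- bc(.ch_sum(dxhat) / m)
      t2 <- xhat * bc(.ch_sum(dxhat * xhat) / m)
      dx <- bc(istd) * (dxhat - t1 - t2)
    } else {
      dx <- dxhat * bc(istd)
    }
    dim(dx) <- d
    .acc(x, dx)
  })
}

# Numerically stable binary cross-entropy on logits; returns a scalar node.
ad_bce_logits <- function(logits, target) {
  z <- logits$value
  y <- target
  v <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  .new_node(v, list(logits), function(g) {
    dz <- (stats::plogis(z) - y) * (g / length(z))
    dim(dz) <- dim(z)
    .acc(logits, dz)
  })
}

## ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  zeros <- function(p) {
    if (is.null(dim(p$value))) numeric(length(p$value))
    else array(0, dim(p$value))
  }
  list(m = lapply(params, zeros), v = lapply(params, zeros), t = 0L)
}

adam_step <- function(params, state, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    p$value <- p$value -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a
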