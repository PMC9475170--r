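# N-shape encoder-decoder architecture: U-Net backbone, multi-scale
# image-pyramid input, attention-gated skips, stackable dilated convolution
# (SDC) bottleneck.

#' Default SDC branch dilation stacks
#'
#' The SDC bottleneck has four parallel branches of cascaded 3x3 dilated
#' convolutions. The dilation stacks `[1]`, `[3]`, `[1,3]` and `[1,3,11]`
#' give theoretical receptive fields of 3, 7, 9 and 31 pixels respectively
#' (see [receptive_field()]).
#'
#' @return A list of integer vectors, one per branch.
#' @export
sdc_default_branches <- function() {
  list(1L, 3L, c(1L, 3L), c(1L, 3L, 11L))
}

#' Architecture configuration
#'
#' Structural hyperparameters of the segmentation network. With all three
#' component flags off the model reduces to a plain U-Net; switching on
#' `use_attention`, `use_multiscale` and `use_sdc` adds, respectively,
#' attention-gated skip connections, the image-pyramid input layer, and the
#' SDC bottleneck, mirroring the ablation ladder.
#'
#' @param input_size Working resolution in pixels (square). Must be
#'   divisible by `2^depth`.
#' @param depth Number of encoder levels (>= 2). Channels double per level.
#' @param base_channels Channels at the first encoder level; level `i` has
#'   `base_channels * 2^(i-1)` channels and the bottleneck
#'   `base_channels * 2^depth`.
#' @param sdc_branches List of integer vectors, the dilation stack of each
#'   SDC branch. All rates must be >= 1.
#' @param use_multiscale,use_attention,use_sdc Component switches.
#' @param use_batchnorm Insert batch normalisation after each 3x3
#'   convolution (pre-ReLU) in the encoder/decoder blocks.
#' @return An object of class `arch_config`.
#' @examples
#' cfg <- arch_config(input_size = 64, depth = 3, base_channels = 8)
#' @export
arch_config <- function(input_size = 512L, depth = 4L, base_channels = 64L,
                        sdc_branches = sdc_default_branches(),
                        use_multiscale = TRUE, use_attention = TRUE,
                        use_sdc = TRUE, use_batchnorm = TRUE) {
  depth <- as.integer(depth)
  input_size <- as.integer(input_size)
  base_channels <- as.integer(base_channels)
  if (depth < 2L) stop("`depth` must be at least 2, got ", depth)
  if (base_channels < 1L) stop("`base_channels` must be positive")
  if (input_size %% 2L^depth != 0L)
    stop("`input_size` (", input_size, ") must be divisible by 2^depth = ",
         2L^depth)
  if (!is.list(sdc_branches) || !length(sdc_branches))
    stop("`sdc_branches` must be a nonempty list of dilation stacks")
  for (br in sdc_branches) {
    if (!length(br) || any(br < 1) || any(br != round(br)))
      stop("every SDC dilation stack must be a nonempty vector of rates >= 1")
  }
  structure(
    list(input_size = input_size, depth = depth,
         base_channels = base_channels,
         sdc_branches = lapply(sdc_branches, as.integer),
         use_multiscale = isTRUE(use_multiscale),
         use_attention = isTRUE(use_attention),
         use_sdc = isTRUE(use_sdc),
         use_batchnorm = isTRUE(use_batchnorm),
         out_activation = "sigmoid"),
    class = "arch_config")
}

#' The four ablation configurations
#'
#' Plain U-Net, attention-gated U-Net, multi-scale + attention, and the full
#' network with the SDC bottleneck.
#'
#' @inheritParams arch_config
#' @return Named list of [arch_config()] objects, ordered by increasing
#'   component count.
#' @export
ablation_configs <- function(input_size = 512L, depth = 4L,
                             base_channels = 64L) {
  list(
    unet = arch_config(input_size, depth, base_channels,
                       use_multiscale = FALSE, use_attention = FALSE,
                       use_sdc = FALSE),
    ag_unet = arch_config(input_size, depth, base_channels,
                          use_multiscale = FALSE, use_attention = TRUE,
                          use_sdc = FALSE),
    ms_ag_unet = arch_config(input_size, depth, base_channels,
                             use_multiscale = TRUE, use_attention = TRUE,
                             use_sdc = FALSE),
    nnet = arch_config(input_size, depth, base_channels,
                       use_multiscale = TRUE, use_attention = TRUE,
                       use_sdc = TRUE))
}

## ---- tensor plumbing -----------------------------------------------------

# Promote a matrix / (H,W,C) array to the internal (H,W,C,N) layout,
# remembering the original rank so results can be demoted again.
as_tensor <- function(x) {
  if (is.matrix(x)) {
    rank <- 2L
    dim(x) <- c(dim(x), 1L, 1L)
  } else if (length(dim(x)) == 3L) {
    rank <- 3L
    dim(x) <- c(dim(x), 1L)
  } else if (length(dim(x)) == 4L) {
    rank <- 4L
  } else {
    stop("expected a matrix or an (H, W, C[, N]) array")
  }
  attr(x, "rank") <- rank
  x
}

from_tensor <- function(x, rank) {
  d <- dim(x)
  attr(x, "rank") <- NULL
  if (rank == 2L) {
    dim(x) <- d[1:2]
  } else if (rank == 3L) {
    dim(x) <- d[1:3]
  }
  x
}

## ---- multi-scale input pyramid ------------------------------------------

#' Multi-scale image pyramid by 2x2 average pooling
#'
#' Builds the pyramid input: level 1 is the image unchanged and each
#' further level halves both spatial dimensions by non-overlapping 2x2 mean
#' pooling, so global mean intensity is preserved exactly at every level.
#'
#' @param image Matrix or (H, W, C) / (H, W, C, N) array.
#' @param levels Number of pyramid levels (level 1 = input).
#' @return List of `levels` grids with the same rank as the input; level
#'   `i` has spatial size `dim(image) / 2^(i-1)`.
#' @examples
#' p <- multi_scale_pyramid(matrix(1, 16, 16), levels = 3)
#' sapply(p, nrow)  # 16 8 4
#' @export
multi_scale_pyramid <- function(image, levels) {
  levels <- as.integer(levels)
  if (levels < 1L) stop("`levels` must be >= 1")
  x <- as_tensor(image)
  rank <- attr(x, "rank")
  d <- dim(x)
  f <- 2L^(levels - 1L)
  if (d[1] %% f != 0L)
    stop("image height (", d[1], ") is not divisible by 2^(levels-1) = ", f)
  if (d[2] %% f != 0L)
    stop("image width (", d[2], ") is not divisible by 2^(levels-1) = ", f)
  out <- vector("list", levels)
  out[[1]] <- from_tensor(x, rank)
  cur <- x
  for (i in seq_len(levels - 1L)) {
    cur <- cpp_avgpool2_fw(cur)
    out[[i + 1L]] <- from_tensor(cur, rank)
  }
  out
}

## ---- receptive-field arithmetic -----------------------------------------

#' Specify one convolutional layer for receptive-field arithmetic
#'
#' @param k Odd kernel side length in pixels.
#' @param d Dilation rate (>= 1).
#' @param s Stride (always 1 inside the SDC block).
#' @return A `layer_spec` object.
#' @export
layer_spec <- function(k = 3L, d = 1L, s = 1L) {
  k <- as.integer(k); d <- as.integer(d); s <- as.integer(s)
  if (k < 1L || k %% 2L == 0L) stop("kernel size `k` must be odd and >= 1")
  if (d < 1L) stop("dilation `d` must be >= 1")
  if (s < 1L) stop("stride `s` must be >= 1")
  structure(list(k = k, d = d, s = s), class = "layer_spec")
}

#' Dilation stack as a list of layer specs
#'
#' @param dilations Integer vector of dilation rates; each becomes a 3x3,
#'   stride-1 [layer_spec()].
#' @return List of `layer_spec` objects.
#' @export
sdc_branch_specs <- function(dilations) {
  lapply(as.integer(dilations), function(d) layer_spec(3L, d, 1L))
}

#' Theoretical receptive field of a cascaded convolution stack
#'
#' For stride-1 layers the side length of the receptive field grows by
#' `(k - 1) * d` per layer: `rf = 1 + sum((k_i - 1) * d_i)`. The default
#' SDC branches (dilation stacks 1; 3; 1,3; 1,3,11 with 3x3 kernels) give
#' 3, 7, 9 and 31.
#'
#' @param stack Nonempty list of [layer_spec()] objects, all with stride 1.
#' @return Receptive-field side length in pixels.
#' @examples
#' receptive_field(sdc_branch_specs(c(1, 3, 11)))  # 31
#' @export
receptive_field <- function(stack) {
  if (!is.list(stack) || !length(stack)) stop("`stack` must be a nonempty list")
  if (inherits(stack, "layer_spec")) stack <- list(stack)
  rf <- 1L
  for (l in stack) {
    if (!inherits(l, "layer_spec")) stop("every element must be a `layer_spec`")
    if (l$s != 1L) stop("receptive_field() assumes stride 1 throughout")
    rf <- rf + (l$k - 1L) * l$d
  }
  rf
}

#' Measured receptive field by impulse propagation
#'
#' Independent check of [receptive_field()]: instantiates the stack as
#' single-channel convolutions with all-ones kernels, propagates a central
#' unit impulse through it and measures the side length of the nonzero
#' output footprint.
#'
#' @inheritParams receptive_field
#' @param size Odd grid side length; must exceed the footprint.
#' @return Measured footprint side length in pixels.
#' @export
receptive_field_empirical <- function(stack, size = 129L) {
  if (!is.list(stack) || !length(stack)) stop("`stack` must be a nonempty list")
  if (inherits(stack, "layer_spec")) stack <- list(stack)
  size <- as.integer(size)
  if (size %% 2L == 0L) size <- size + 1L
  x <- array(0, c(size, size, 1L, 1L))
  mid <- (size + 1L) %/% 2L
  x[mid, mid, 1L, 1L] <- 1
  for (l in stack) {
    w <- array(1, c(l$k, l$k, 1L, 1L))
    pad <- as.integer(l$d * (l$k - 1L) / 2L)
    x <- cpp_conv2d_fw(x, w, numeric(1L), l$d, pad)
  }
  m <- x[, , 1L, 1L]
  rows <- which(apply(m != 0, 1L, any))
  cols <- which(apply(m != 0, 2L, any))
  if (min(rows, cols) == 1L || max(rows, cols) == size)
    stop("footprint reached the grid border; increase `size`")
  side_r <- max(rows) - min(rows) + 1L
  side_c <- max(cols) - min(cols) + 1L
  if (side_r != side_c) stop("non-square impulse footprint (internal error)")
  side_r
}

## ---- parameter initialisation and layer units ---------------------------

he_uniform <- function(k, cin, cout) {
  lim <- sqrt(6 / (k * k * cin))
  array(stats::runif(k * k * cin * cout, -lim, lim), c(k, k, cin, cout))
}

#' Learnable parameter count of one convolution
#'
#' Closed form `k^2 * c_in * c_out + c_out * bias`; independent of the
#' dilation rate, which only spaces the kernel taps.
#'
#' @param k Kernel side length.
#' @param c_in,c_out Input / output channels.
#' @param bias Include a bias vector?
#' @return Number of learnable scalars.
#' @export
conv_param_count <- function(k, c_in, c_out, bias = TRUE) {
  k^2 * c_in * c_out + if (isTRUE(bias)) c_out else 0
}

## ---- model builder -------------------------------------------------------

#' Assemble the segmentation network from a configuration
#'
#' Builds the encoder (two 3x3 conv + BN + ReLU units then 2x2 max-pool per
#' level), the optional pyramid-input fusion, the bottleneck conv block with
#' the optional SDC block, the decoder (bilinear x2 upsampling, a 3x3 conv
#' unit, concatenation with the — optionally attention-gated — encoder skip,
#' then a two-unit conv block) and a 1x1 convolution + sigmoid head. With
#' all component flags off this is a plain U-Net.
#'
#' Weights are He-uniform, biases zero, drawn under `seed` so two builds
#' with the same seed are identical.
#'
#' @param config An [arch_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `nnet_model`.
#' @examples
#' m <- build_model(arch_config(64, depth = 2, base_channels = 4))
#' count_parameters(m)
#' @export
build_model <- function(config, seed = 1L) {
  if (!inherits(config, "arch_config"))
    stop("`config` must be an `arch_config` object")
  P <- list()
  BN <- list()
  bn_on <- config$use_batchnorm
  add_param <- function(name, value) P[[name]] <<- ad_param(value)
  conv_unit <- function(name, k, cin, cout, bn = bn_on, act = "relu",
                        dilation = 1L) {
    add_param(paste0(name, ".w"), he_uniform(k, cin, cout))
    add_param(paste0(name, ".b"), numeric(cout))
    if (bn) {
      add_param(paste0(name, ".gamma"), rep(1, cout))
      add_param(paste0(name, ".beta"), numeric(cout))
      st <- new.env(parent = emptyenv())
      st$mean <- numeric(cout)
      st$var <- rep(1, cout)
      BN[[name]] <<- st
    }
    list(name = name, k = k, cin = cin, cout = cout, bn = bn, act = act,
         dilation = as.integer(dilation),
         pad = as.integer(dilation * (k - 1) / 2))
  }

  depth <- config$depth
  ch <- config$base_channels * 2L^(0:depth)  # ch[i]: level i; ch[depth+1]: bottleneck

  arch <- withr::with_seed(seed, {
    enc <- vector("list", depth)
    ms <- vector("list", depth)
    for (i in seq_len(depth)) {
      cin <- if (i == 1L) 1L else if (config$use_multiscale) 2L * ch[i - 1L] else ch[i - 1L]
      if (i > 1L && config$use_multiscale)
        ms[[i]] <- conv_unit(sprintf("ms%d", i), 3L, 1L, ch[i - 1L])
      enc[[i]] <- list(conv_unit(sprintf("enc%d.c1", i), 3L, cin, ch[i]),
                       conv_unit(sprintf("enc%d.c2", i), 3L, ch[i], ch[i]))
    }
    bott <- list(conv_unit("bott.c1", 3L, ch[depth], ch[depth + 1L]),
                 conv_unit("bott.c2", 3L, ch[depth + 1L], ch[depth + 1L]))
    sdc <- NULL
    if (config$use_sdc) {
      cb <- ch[depth + 1L]
      sdc <- lapply(seq_along(config$sdc_branches), function(j) {
        dils <- config$sdc_branches[[j]]
        units <- lapply(seq_along(dils), function(t)
          conv_unit(sprintf("sdc.b%d.c%d", j, t), 3L, cb, cb, bn = FALSE,
                    dilation = dils[t]))
        c(units, list(conv_unit(sprintf("sdc.b%d.p", j), 1L, cb, cb,
                                bn = FALSE)))
      })
    }
    att <- NULL
    if (config$use_attention) {
      att <- lapply(seq_len(depth), function(i) {
        inter <- max(ch[i] %/% 2L, 1L)
        list(img = conv_unit(sprintf("att%d.img", i), 1L, 1L, inter,
                             bn = FALSE, act = "none"),
             feat = conv_unit(sprintf("att%d.feat", i), 1L, ch[i], inter,
                              bn = FALSE, act = "none"),
             psi = conv_unit(sprintf("att%d.psi", i), 1L, inter, 1L,
                             bn = FALSE, act = "none"))
      })
    }
    dec <- vector("list", depth)
    for (i in rev(seq_len(depth))) {
      dec[[i]] <- list(
        up = conv_unit(sprintf("dec%d.up", i), 3L, ch[i + 1L], ch[i]),
        c1 = conv_unit(sprintf("dec%d.c1", i), 3L, 2L * ch[i], ch[i]),
        c2 = conv_unit(sprintf("dec%d.c2", i), 3L, ch[i], ch[i]))
    }
    head <- conv_unit("head", 1L, ch[1L], 1L, bn = FALSE, act = "none")
    list(enc = enc, ms = ms, bott = bott, sdc = sdc, att = att, dec = dec,
         head = head)
  })

  structure(list(config = config, params = P, bn = BN, arch = arch,
                 seed = as.integer(seed)),
            class = "nnet_model")
}

# Apply one conv unit (conv [+ BN] [+ ReLU]) to an ad node.
apply_unit <- function(model, unit, h, training = FALSE) {
  w <- model$params[[paste0(unit$name, ".w")]]
  b <- model$params[[paste0(unit$name, ".b")]]
  y <- ad_conv2d(h, w, b, unit$dilation, unit$pad)
  if (unit$bn)
    y <- ad_batchnorm(y, model$params[[paste0(unit$name, ".gamma")]],
                      model$params[[paste0(unit$name, ".beta")]],
                      model$bn[[unit$name]], training)
  if (unit$act == "relu") y <- ad_relu(y)
  y
}

# SDC graph: identity skip plus the element-wise sum of all branch outputs.
sdc_graph <- function(model, branches, h, training = FALSE) {
  acc <- NULL
  for (br in branches) {
    y <- h
    for (u in br) y <- apply_unit(model, u, y, training)
    acc <- if (is.null(acc)) y else ad_add(acc, y)
  }
  ad_add(h, acc)
}

# Attention gate graph: one-channel sigmoid gate from the scaled image and
# the encoder feature map, multiplied onto every feature channel.
attention_graph <- function(model, gate_units, img, feat, training = FALSE) {
  a <- ad_add(apply_unit(model, gate_units$img, img, training),
              apply_unit(model, gate_units$feat, feat, training))
  g <- ad_sigmoid(apply_unit(model, gate_units$psi, ad_relu(a), training))
  list(attended = ad_gate_mul(g, feat), gate = g)
}

# Full forward graph. `x` is an (H, W, 1, N) array; returns ad nodes for the
# sigmoid probabilities and the pre-sigmoid logits.
forward_nnet <- function(model, x, training = FALSE) {
  cfg <- model$config
  d <- dim(x)
  if (d[3] != 1L) stop("the network expects a single input channel")
  if (d[1] %% 2L^cfg$depth != 0L || d[2] %% 2L^cfg$depth != 0L)
    stop("input spatial dims (", d[1], "x", d[2],
         ") must be divisible by 2^depth = ", 2L^cfg$depth)
  depth <- cfg$depth
  pyr <- vector("list", depth)
  pyr[[1]] <- x
  for (i in seq_len(depth - 1L)) pyr[[i + 1L]] <- cpp_avgpool2_fw(pyr[[i]])

  e <- vector("list", depth)
  h <- ad_const(x)
  for (i in seq_len(depth)) {
    if (i > 1L) {
      h <- ad_maxpool2(e[[i - 1L]])
      if (cfg$use_multiscale) {
        m <- apply_unit(model, model$arch$ms[[i]], ad_const(pyr[[i]]), training)
        h <- ad_concat(m, h)
      }
    }
    for (u in model$arch$enc[[i]]) h <- apply_unit(model, u, h, training)
    e[[i]] <- h
  }
  h <- ad_maxpool2(e[[depth]])
  for (u in model$arch$bott) h <- apply_unit(model, u, h, training)
  if (cfg$use_sdc) h <- sdc_graph(model, model$arch$sdc, h, training)
  for (i in rev(seq_len(depth))) {
    u <- apply_unit(model, model$arch$dec[[i]]$up, ad_upsample2(h), training)
    skip <- e[[i]]
    if (cfg$use_attention)
      skip <- attention_graph(model, model$arch$att[[i]], ad_const(pyr[[i]]),
                              skip, training)$attended
    h <- ad_concat(skip, u)
    h <- apply_unit(model, model$arch$dec[[i]]$c1, h, training)
    h <- apply_unit(model, model$arch$dec[[i]]$c2, h, training)
  }
  logit <- apply_unit(model, model$arch$head, h, training)
  list(prob = ad_sigmoid(logit), logit = logit)
}

#' Predict a segmentation probability map
#'
#' Runs the network in evaluation mode (batch-norm running statistics) on
#' one grayscale image, optionally with six-view test-time augmentation.
#'
#' @param object An `nnet_model`.
#' @param image Numeric matrix in `[0, 1]`, spatial dims divisible by
#'   `2^depth`.
#' @param tta Average predictions over the six geometric test-time views
#'   (see [tta_predict()]).
#' @param ... Unused.
#' @return Probability matrix in `(0, 1)` with the input's dimensions.
#' @export
predict.nnet_model <- function(object, image, tta = FALSE, ...) {
  if (isTRUE(tta)) return(tta_predict(object, image))
  x <- array(image, c(dim(image)[1], dim(image)[2], 1L, 1L))
  out <- forward_nnet(object, x, training = FALSE)
  out$prob$value[, , 1L, 1L]
}

#' Count learnable parameters
#'
#' @param x An `nnet_model`, a named list of parameter arrays (as returned
#'   by the weight helpers), or a single array.
#' @return Total number of learnable scalars. Batch-norm running statistics
#'   are not learnable and are excluded.
#' @export
count_parameters <- function(x) UseMethod("count_parameters")

#' @export
count_parameters.nnet_model <- function(x) {
  sum(vapply(x$params, function(p) length(p$value), numeric(1)))
}

#' @export
count_parameters.list <- function(x) {
  sum(vapply(x, length, numeric(1)))
}

#' @export
count_parameters.default <- function(x) length(x)

#' @export
print.nnet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<nnet_model> depth %d, base %d ch, input %dpx | multiscale=%s attention=%s sdc=%s bn=%s | %s parameters\n",
    cfg$depth, cfg$base_channels, cfg$input_size,
    cfg$use_multiscale, cfg$use_attention, cfg$use_sdc, cfg$use_batchnorm,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

## ---- standalone module surfaces -----------------------------------------

#' He-uniform weights for a standalone attention gate
#'
#' @param channels Channels of the feature map to be gated.
#' @param inter Intermediate gating channels (default `max(channels/2, 1)`).
#' @param seed Integer seed.
#' @return Named list of arrays: `img.w`, `img.b`, `feat.w`, `feat.b`,
#'   `psi.w`, `psi.b`.
#' @export
attention_weights <- function(channels, inter = max(channels %/% 2L, 1L),
                              seed = 1L) {
  withr::with_seed(seed, list(
    img.w = he_uniform(1L, 1L, inter), img.b = numeric(inter),
    feat.w = he_uniform(1L, channels, inter), feat.b = numeric(inter),
    psi.w = he_uniform(1L, inter, 1L), psi.b = numeric(1L)))
}

#' Attention guidance: gate an encoder feature map by the scaled input image
#'
#' Computes a one-channel gate
#' `g = sigmoid(conv1x1(relu(conv1x1(image) + conv1x1(f_m))))`
#' and returns `A = g * f_m`, broadcasting the gate over channels. Gating
#' values are strictly inside `(0, 1)`, so the gate attenuates but never
#' zeroes a feature.
#'
#' @param scaled_image One-channel grid (matrix) at the feature map's
#'   spatial resolution — the matching level of the input pyramid.
#' @param f_m Feature map, an (H, W, C) array (or matrix for C = 1).
#' @param weights Gate weights as from [attention_weights()]; freshly drawn
#'   when `NULL`.
#' @param seed Seed for fresh weights.
#' @return The attended feature map, same shape as `f_m`, with the gate
#'   matrix attached as attribute `"gate"`.
#' @export
attention_guidance <- function(scaled_image, f_m, weights = NULL, seed = 1L) {
  img <- as_tensor(scaled_image)
  ft <- as_tensor(f_m)
  rank <- attr(ft, "rank")
  di <- dim(img); df <- dim(ft)
  if (di[1] != df[1] || di[2] != df[2])
    stop("spatial mismatch: image is ", di[1], "x", di[2],
         " but feature map is ", df[1], "x", df[2])
  if (di[3] != 1L) stop("`scaled_image` must have one channel")
  C <- df[3]
  if (is.null(weights)) weights <- attention_weights(C, seed = seed)
  need <- c("img.w", "img.b", "feat.w", "feat.b", "psi.w", "psi.b")
  if (!all(need %in% names(weights)))
    stop("`weights` must contain: ", paste(need, collapse = ", "))
  if (dim(weights$feat.w)[3] != C)
    stop("gate weights expect ", dim(weights$feat.w)[3],
         " feature channels but f_m has ", C)
  a <- ad_add(
    ad_conv2d(ad_const(img), ad_const(weights$img.w), ad_const(weights$img.b), 1L, 0L),
    ad_conv2d(ad_const(ft), ad_const(weights$feat.w), ad_const(weights$feat.b), 1L, 0L))
  g <- ad_sigmoid(ad_conv2d(ad_relu(a), ad_const(weights$psi.w),
                            ad_const(weights$psi.b), 1L, 0L))
  out <- ad_gate_mul(g, ad_const(ft))
  res <- from_tensor(out$value, rank)
  attr(res, "gate") <- g$value[, , 1L, 1L]
  res
}

#' He-uniform weights for a standalone SDC block
#'
#' @param channels Feature-map channels (preserved by the block).
#' @param branches Dilation stacks, as in [sdc_default_branches()].
#' @param seed Integer seed.
#' @return Named list of arrays keyed `b<j>.c<t>.{w,b}` for the cascaded
#'   3x3 convolutions of branch `j` and `b<j>.p.{w,b}` for its final 1x1.
#' @export
sdc_weights <- function(channels, branches = sdc_default_branches(),
                        seed = 1L) {
  withr::with_seed(seed, {
    w <- list()
    for (j in seq_along(branches)) {
      for (t in seq_along(branches[[j]])) {
        w[[sprintf("b%d.c%d.w", j, t)]] <- he_uniform(3L, channels, channels)
        w[[sprintf("b%d.c%d.b", j, t)]] <- numeric(channels)
      }
      w[[sprintf("b%d.p.w", j)]] <- he_uniform(1L, channels, channels)
      w[[sprintf("b%d.p.b", j)]] <- numeric(channels)
    }
    w
  })
}

#' Stackable dilated convolution block
#'
#' Each branch applies its 3x3 dilated convolutions in cascade (channels
#' preserved, padding equal to the dilation rate, ReLU after each), then a
#' 1x1 convolution with ReLU. The block output is the input plus the
#' element-wise sum of all branch outputs (identity skip), so input and
#' output shapes are identical.
#'
#' @param f Feature map, an (H, W, C) array (or matrix for C = 1).
#' @param branches Dilation stacks; defaults to the four stacks with
#'   receptive fields 3, 7, 9, 31.
#' @param weights Weights as from [sdc_weights()]; freshly drawn when `NULL`.
#' @param seed Seed for fresh weights.
#' @return Array with the same shape as `f`.
#' @export
sdc_block <- function(f, branches = sdc_default_branches(), weights = NULL,
                      seed = 1L) {
  x <- as_tensor(f)
  rank <- attr(x, "rank")
  C <- dim(x)[3]
  for (br in branches)
    if (!length(br) || any(br < 1))
      stop("every branch stack must be nonempty with rates >= 1")
  if (is.null(weights)) weights <- sdc_weights(C, branches, seed)
  h <- ad_const(x)
  acc <- NULL
  for (j in seq_along(branches)) {
    y <- h
    for (t in seq_along(branches[[j]])) {
      w <- weights[[sprintf("b%d.c%d.w", j, t)]]
      if (dim(w)[3] != C)
        stop("branch ", j, " weights expect ", dim(w)[3],
             " channels but input has ", C)
      d <- as.integer(branches[[j]][t])
      y <- ad_relu(ad_conv2d(y, ad_const(w),
                             ad_const(weights[[sprintf("b%d.c%d.b", j, t)]]),
                             d, d))
    }
    y <- ad_relu(ad_conv2d(y, ad_const(weights[[sprintf("b%d.p.w", j)]]),
                           ad_const(weights[[sprintf("b%d.p.b", j)]]), 1L, 0L))
    if (!identical(dim(y$value), dim(x)))
      stop("SDC branch ", j, " changed the feature-map shape (internal error)")
    acc <- if (is.null(acc)) y else ad_add(acc, y)
  }
  from_tensor(ad_add(h, acc)$value, rank)
}
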