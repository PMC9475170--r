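# Geometric training augmentation and six-view test-time augmentation.
#
# The transform set is closed under inversion and every member is lossless
# on integer grids, so a transform followed by its inverse is bit-exact.

#' The six geometric test-time transforms
#'
#' Identity, rotations by 90/180/270 degrees and horizontal/vertical flips.
#'
#' @return Character vector of transform names.
#' @export
tta_transforms <- function() {
  c("identity", "rot90", "rot180", "rot270", "hflip", "vflip")
}

#' Apply a named geometric transform to a grid
#'
#' Rotations are clockwise; `hflip` mirrors left-right, `vflip` top-bottom.
#' Quarter rotations require a square grid.
#'
#' @param x Numeric matrix.
#' @param transform One of [tta_transforms()].
#' @return Transformed matrix.
#' @export
apply_transform <- function(x, transform) {
  if (!is.matrix(x)) stop("`x` must be a matrix")
  if (transform %in% c("rot90", "rot270") && nrow(x) != ncol(x))
    stop("quarter rotations need a square grid, got ",
         nrow(x), "x", ncol(x))
  switch(transform,
    identity = x,
    rot90 = t(x[nrow(x):1, , drop = FALSE]),
    rot180 = x[nrow(x):1, ncol(x):1, drop = FALSE],
    rot270 = t(x)[ncol(x):1, , drop = FALSE],
    hflip = x[, ncol(x):1, drop = FALSE],
    vflip = x[nrow(x):1, , drop = FALSE],
    stop("unknown transform: ", transform))
}

#' Inverse of a named transform (within the same set)
#'
#' @param transform One of [tta_transforms()].
#' @return Name of the inverse transform.
#' @export
transform_inverse <- function(transform) {
  switch(transform,
    identity = "identity",
    rot90 = "rot270",
    rot180 = "rot180",
    rot270 = "rot90",
    hflip = "hflip",
    vflip = "vflip",
    stop("unknown transform: ", transform))
}

#' Randomly augment an image/mask pair
#'
#' Draws one transform uniformly from the six-element set and applies it to
#' both grids identically, preserving mask binarity and foreground pixel
#' count. With `rng_seed` set the draw is reproducible; otherwise it
#' consumes the current RNG stream (online augmentation inside training).
#'
#' @param image,mask Square matrices of identical shape.
#' @param rng_seed Optional integer seed for a reproducible draw.
#' @return List with elements `image`, `mask` and `transform`.
#' @export
augment_pair <- function(image, mask, rng_seed = NULL) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask shapes differ")
  tr <- if (is.null(rng_seed)) {
    sample(tta_transforms(), 1L)
  } else {
    withr::with_seed(rng_seed, sample(tta_transforms(), 1L))
  }
  list(image = apply_transform(image, tr),
       mask = apply_transform(mask, tr),
       transform = tr)
}

#' Six-view test-time augmentation
#'
#' Predicts each of the six geometric views of the image (exactly six
#' forward passes), inverse-aligns the six probability maps and returns
#' their element-wise mean. Probabilities are averaged; thresholding, if
#' any, is the caller's job.
#'
#' @param model An `nnet_model`, or any function mapping an image matrix to
#'   a probability matrix of the same shape.
#' @param image Square numeric matrix.
#' @return Probability matrix, the mean of the six aligned predictions.
#' @export
tta_predict <- function(model, image) {
  if (nrow(image) != ncol(image))
    stop("test-time augmentation needs a square image, got ",
         nrow(image), "x", ncol(image))
  fwd <- if (is.function(model)) {
    model
  } else {
    function(im) predict(model, im, tta = FALSE)
  }
  acc <- NULL
  for (tr in tta_transforms()) {
    p <- fwd(apply_transform(image, tr))
    if (!identical(dim(p), dim(image)))
      stop("model output shape ", paste(dim(p), collapse = "x"),
           " does not match the input")
    p <- apply_transform(p, transform_inverse(tr))
    acc <- if (is.null(acc)) p else acc + p
  }
  acc / length(tta_transforms())
}
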