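# Synthetic ultrasound-like nodule phantoms.
#
# Image formation: a smooth tissue reflectivity field, darkened inside a
# star-convex nodule region (hypoechoic), blurred at the boundary, optionally
# dotted with bright calcification foci, then multiplied by Gamma-distributed
# speckle — the standard fully-developed-speckle approximation for B-mode
# images. The ground-truth mask is the *unblurred* nodule region, so margin
# ambiguity exists in the image but not in the label.

#' Image/mask pair container
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param mask Binary `{0,1}` matrix of the same shape; 1 = nodule
#'   foreground, origin top-left, row-major.
#' @param meta Optional list of generation metadata.
#' @return Object of class `image_pair`.
#' @export
image_pair <- function(image, mask, meta = NULL) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask shapes differ: ",
         paste(dim(image), collapse = "x"), " vs ",
         paste(dim(mask), collapse = "x"))
  if (any(!is.finite(image))) stop("image contains non-finite values")
  check_binary_mask(mask, "mask")
  structure(list(image = image, mask = mask, meta = meta),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair> %dx%d, %d foreground px (%.1f%%)\n",
              nrow(x$image), ncol(x$image), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Phantom generator configuration
#'
#' Generative parameters of the speckle/nodule model.
#'
#' @param size Image side length in pixels.
#' @param n_nodules Number of nodules per image.
#' @param contrast Nodule-to-background mean-intensity ratio in `(0, 1)`;
#'   below 1 makes the nodule hypoechoic (darker than background).
#' @param n_harmonics Number of radial harmonics perturbing the nodule
#'   boundary (harmonic orders `2 .. n_harmonics + 1`).
#' @param irregularity Peak relative amplitude of the boundary harmonics;
#'   0 gives a perfect ellipse.
#' @param aspect Ellipse axis ratio (minor/major) of the unperturbed
#'   nodule, in `(0, 1]`.
#' @param blur_sigma Gaussian blur of the reflectivity field in pixels;
#'   blurs the nodule margin in the image but not in the mask.
#' @param speckle_shape Shape parameter of the unit-mean Gamma multiplicative
#'   speckle; larger = less grainy (relative sd `1/sqrt(shape)`).
#' @param calcification_rate Expected number of bright calcification foci
#'   per nodule (Poisson).
#' @param seed Integer seed; the same seed reproduces the phantom
#'   bit-identically.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(size = 64L, n_nodules = 1L, contrast = 0.55,
                           n_harmonics = 3L, irregularity = 0.12,
                           aspect = 0.75, blur_sigma = 1.5,
                           speckle_shape = 16, calcification_rate = 0.3,
                           seed = 1L) {
  size <- as.integer(size)
  if (size < 16L) stop("`size` must be at least 16 pixels")
  if (contrast <= 0 || contrast >= 1)
    stop("`contrast` must lie in (0, 1): the nodule is hypoechoic")
  if (aspect <= 0 || aspect > 1) stop("`aspect` must lie in (0, 1]")
  if (irregularity < 0 || irregularity >= 0.5)
    stop("`irregularity` must lie in [0, 0.5)")
  if (speckle_shape <= 0) stop("`speckle_shape` must be positive")
  if (calcification_rate < 0) stop("`calcification_rate` must be >= 0")
  structure(list(size = size, n_nodules = as.integer(n_nodules),
                 contrast = contrast, n_harmonics = as.integer(n_harmonics),
                 irregularity = irregularity, aspect = aspect,
                 blur_sigma = blur_sigma, speckle_shape = speckle_shape,
                 calcification_rate = calcification_rate,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Gaussian blur via EBImage, keeping plain-matrix in/out.
.gblur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::imageData(EBImage::gblur(m, sigma = sigma))
}

# Rasterise one star-convex nodule: boundary radius (in circularised
# elliptical coordinates) r(theta) = r0 * (1 + sum_j a_j sin(j theta + phi_j)).
.nodule_mask <- function(size, center, r0, aspect, angle, amps, phases) {
  idx <- seq_len(size) - 0.5
  dx <- outer(idx - center[1], rep(1, size))
  dy <- outer(rep(1, size), idx - center[2])
  u <- cos(angle) * dx + sin(angle) * dy
  v <- (-sin(angle) * dx + cos(angle) * dy) / aspect
  r <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  rb <- rep(r0, length(theta))
  orders <- seq_along(amps) + 1L
  for (j in seq_along(amps))
    rb <- rb + r0 * amps[j] * sin(orders[j] * theta + phases[j])
  rb <- pmax(rb, 0.2 * r0)
  m <- matrix(0, size, size)
  m[r <= rb] <- 1
  m
}

#' Generate one speckle phantom with its ground-truth mask
#'
#' @param config A [phantom_config()].
#' @return An [image_pair()]; image in `[0, 1]`, mask `{0,1}`. `meta`
#'   records per-nodule centres and base radii. A nodule whose boundary
#'   would leave the frame is retried with a shrunken radius (and a message
#'   is emitted).
#' @examples
#' ph <- generate_phantom(phantom_config(size = 64, seed = 7))
#' mean(ph$image[ph$mask == 1]) < mean(ph$image[ph$mask == 0])  # hypoechoic
#' @export
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config"))
    stop("`config` must be a `phantom_config` object")
  s <- config$size
  withr::with_seed(config$seed, {
    # smooth background reflectivity with gentle large-scale variation
    bg <- matrix(stats::rnorm(s * s), s, s)
    bg <- .gblur(bg, s / 12)
    bg <- (bg - mean(bg)) / max(stats::sd(bg), 1e-12)
    field <- 0.72 + 0.06 * bg

    mask <- matrix(0, s, s)
    centers <- list()
    radii <- numeric(0)
    margin_amp <- 1 + config$irregularity
    for (k in seq_len(config$n_nodules)) {
      placed <- FALSE
      for (try in 1:50) {
        center <- stats::runif(2, 0.3 * s, 0.7 * s)
        r0 <- stats::runif(1, 0.14, 0.24) * s
        # shrink until the perturbed boundary fits inside the frame
        while (r0 * margin_amp >
               min(center - 1, s - center) && r0 > 2) {
          message("phantom seed ", config$seed,
                  ": nodule exceeds bounds, shrinking radius")
          r0 <- 0.8 * r0
        }
        ok <- TRUE
        for (j in seq_along(centers)) {
          if (sqrt(sum((center - centers[[j]])^2)) <
              margin_amp * (r0 + radii[j]) + 2) ok <- FALSE
        }
        if (ok) { placed <- TRUE; break }
      }
      if (!placed) next
      angle <- stats::runif(1, 0, pi)
      amps <- if (config$n_harmonics > 0 && config$irregularity > 0) {
        config$irregularity * stats::runif(config$n_harmonics, 0.3, 1) /
          seq_len(config$n_harmonics)
      } else {
        numeric(0)
      }
      phases <- if (length(amps)) stats::runif(length(amps), 0, 2 * pi) else numeric(0)
      m <- .nodule_mask(s, center, r0, config$aspect, angle, amps, phases)
      mask <- pmax(mask, m)
      centers[[length(centers) + 1L]] <- center
      radii <- c(radii, r0)
    }

    tissue <- field
    tissue[mask == 1] <- tissue[mask == 1] * config$contrast
    tissue <- .gblur(tissue, config$blur_sigma)

    # bright echogenic calcification foci inside nodules
    if (config$calcification_rate > 0 && sum(mask) > 0) {
      n_cal <- stats::rpois(1, config$calcification_rate * max(length(radii), 1))
      if (n_cal > 0) {
        fg <- which(mask == 1, arr.ind = TRUE)
        pick <- fg[sample.int(nrow(fg), min(n_cal, nrow(fg))), , drop = FALSE]
        idx <- seq_len(s)
        for (t in seq_len(nrow(pick))) {
          d2 <- outer((idx - pick[t, 1])^2, (idx - pick[t, 2])^2, `+`)
          tissue <- tissue + 0.5 * exp(-d2 / (2 * 1.2^2))
        }
      }
    }

    speckle <- matrix(stats::rgamma(s * s, shape = config$speckle_shape,
                                    rate = config$speckle_shape), s, s)
    img <- tissue * speckle
    img <- img / stats::quantile(img, 0.999)
    img <- pmin(pmax(img, 0), 1)

    image_pair(img, mask,
               meta = list(centers = centers, radii = radii,
                           seed = config$seed))
  })
}

#' Write a phantom dataset to disk
#'
#' Generates `n` phantoms with per-item seeds `seed, seed+1, ...`, writes
#' 8-bit grayscale image PNGs and `{0,255}` mask PNGs plus a CSV manifest.
#' Re-running with the same master seed reproduces every file byte-for-byte.
#'
#' @param n Number of image/mask pairs.
#' @param config A [phantom_config()]; its `seed` is the master seed.
#' @param out_dir Output directory (created if missing).
#' @return The manifest data.frame (invisibly written to
#'   `manifest.csv`): `image`, `mask`, `seed`, `area` (foreground pixels),
#'   `centroid_row`, `centroid_col`.
#' @export
generate_dataset <- function(n, config, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    ph <- generate_phantom(cfg)
    img8 <- round(ph$image * 255) / 255
    img_file <- sprintf("img_%04d.png", i)
    mask_file <- sprintf("mask_%04d.png", i)
    png::writePNG(img8, file.path(out_dir, img_file))
    png::writePNG(ph$mask, file.path(out_dir, mask_file))
    fg <- which(ph$mask == 1, arr.ind = TRUE)
    rows[[i]] <- data.frame(
      image = img_file, mask = mask_file, seed = cfg$seed,
      area = nrow(fg),
      centroid_row = if (nrow(fg)) mean(fg[, 1]) else NA_real_,
      centroid_col = if (nrow(fg)) mean(fg[, 2]) else NA_real_)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
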