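# Readers/writers for image-mask datasets, manifests and metric reports.

# Luminance conversion for RGB(A) PNG input.
.to_gray <- function(x) {
  if (is.matrix(x)) return(x)
  if (length(dim(x)) == 3L)
    return(0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3])
  stop("unsupported PNG layout: ", paste(dim(x), collapse = "x"))
}

.resize <- function(m, size, nearest = FALSE) {
  if (nrow(m) == size && ncol(m) == size) return(m)
  EBImage::imageData(EBImage::resize(
    m, w = size, h = size, filter = if (nearest) "none" else "bilinear"))
}

#' Load an image/mask pair from PNG files
#'
#' The image is converted to grayscale luminance (if RGB), scaled to
#' `[0, 1]` and resized with bilinear interpolation; the mask must contain
#' only the 8-bit values 0 and 255, is resized with nearest-neighbour
#' interpolation (preserving binarity) and binarized at the 127 threshold.
#'
#' @param image_path,mask_path PNG file paths.
#' @param target_size Optional square working resolution in pixels; `NULL`
#'   keeps the native size (image and mask must then agree).
#' @return An [image_pair()].
#' @export
load_pair <- function(image_path, mask_path, target_size = NULL) {
  if (!file.exists(image_path)) stop("cannot read image file: ", image_path)
  if (!file.exists(mask_path)) stop("cannot read mask file: ", mask_path)
  img <- .to_gray(png::readPNG(image_path))
  msk <- .to_gray(png::readPNG(mask_path))
  v <- round(msk * 255)
  n_bad <- sum(v != 0 & v != 255)
  if (n_bad > 0)
    stop("mask ", mask_path, " is not binary: ", n_bad,
         " pixel(s) outside {0, 255}")
  msk <- (v > 127) * 1
  if (!is.null(target_size)) {
    target_size <- as.integer(target_size)
    img <- .resize(img, target_size)
    msk <- .resize(msk, target_size, nearest = TRUE)
  }
  img <- pmin(pmax(img, 0), 1)
  if (!identical(dim(img), dim(msk)))
    stop("image and mask sizes differ after loading: ",
         paste(dim(img), collapse = "x"), " vs ",
         paste(dim(msk), collapse = "x"))
  image_pair(img, msk)
}

#' Load a phantom (or any manifest-described) dataset
#'
#' Reads `manifest.csv` as written by [generate_dataset()] — columns
#' `image` and `mask` with paths relative to the manifest — and loads every
#' pair.
#'
#' @param dir Directory containing `manifest.csv`, or a path to a manifest
#'   CSV file.
#' @param target_size Optional square working resolution (see
#'   [load_pair()]).
#' @return List of [image_pair()] objects, one per manifest row.
#' @export
load_dataset <- function(dir, target_size = NULL) {
  manifest_path <- if (dir.exists(dir)) file.path(dir, "manifest.csv") else dir
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  root <- dirname(manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("image", "mask") %in% names(man)))
    stop("manifest must have `image` and `mask` columns")
  if (anyDuplicated(man$image) || anyDuplicated(man$mask))
    stop("manifest paths must be unique")
  lapply(seq_len(nrow(man)), function(i)
    load_pair(file.path(root, man$image[i]), file.path(root, man$mask[i]),
              target_size = target_size))
}

#' Write / read a metric report
#'
#' Writes the per-image rows as CSV and the aggregate summary as JSON next
#' to it; `read_report()` reconstructs an equal report from the files. An
#' empty report yields a header-only CSV and a summary flagged `n = 0`.
#'
#' @param report A `metric_report` (see [evaluate_model()]).
#' @param path Base path without extension; `<path>.csv` and `<path>.json`
#'   are written.
#' @return `write_report` returns the two file paths invisibly;
#'   `read_report` returns the reconstructed `metric_report`.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "metric_report"))
    stop("`report` must be a `metric_report`")
  dir <- dirname(path)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir)
  csv <- paste0(path, ".csv")
  js <- paste0(path, ".json")
  utils::write.csv(report$per_image, csv, row.names = FALSE)
  jsonlite::write_json(
    list(n = report$n, use_tta = report$use_tta, empty = report$n == 0,
         summary = report$summary),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  csv <- paste0(path, ".csv")
  js <- paste0(path, ".json")
  if (!file.exists(csv) || !file.exists(js))
    stop("report files not found at base path: ", path)
  per_image <- utils::read.csv(csv, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  metric_report(per_image, use_tta = isTRUE(meta$use_tta))
}
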