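# Shared fixtures: everything is generated in code at test time.

# Tiny architecture used throughout: 32 px, depth 3, base 4 channels.
tiny_config <- function(...) {
  arch_config(input_size = 32L, depth = 3L, base_channels = 4L, ...)
}

# Small phantom set, deterministic.
tiny_phantoms <- function(n, size = 32L, seed0 = 500L) {
  lapply(seq_len(n), function(i)
    generate_phantom(phantom_config(size = size, seed = seed0 + i)))
}

# Random binary mask matrix.
random_mask <- function(h, w = h, p = 0.4) {
  matrix((stats::runif(h * w) < p) * 1, h, w)
}

# Brute-force metrics from explicit pixel index sets (independent oracle).
brute_metrics <- function(pred, gt) {
  P <- which(pred == 1)
  G <- which(gt == 1)
  tp <- length(intersect(P, G))
  fp <- length(setdiff(P, G))
  fn <- length(setdiff(G, P))
  dice_bf <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  prec_bf <- if (length(P) == 0) (if (length(G) == 0) 1 else 0) else tp / length(P)
  rec_bf <- if (length(G) == 0) (if (length(P) == 0) 1 else 0) else tp / length(G)
  f1_bf <- if (prec_bf + rec_bf == 0) 0 else 2 * prec_bf * rec_bf / (prec_bf + rec_bf)
  iou_set <- function(A, B) {
    u <- length(union(A, B))
    if (u == 0) 1 else length(intersect(A, B)) / u
  }
  all_px <- seq_len(length(pred))
  miou_bf <- mean(c(iou_set(setdiff(all_px, P), setdiff(all_px, G)),
                    iou_set(P, G)))
  list(dice = dice_bf, precision = prec_bf, recall = rec_bf, f1 = f1_bf,
       miou = miou_bf)
}
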