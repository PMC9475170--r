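# Training, k-fold evaluation and the ablation harness.

#' Training configuration
#'
#' @param lr Adam learning rate (> 0). The default follows the reference
#'   protocol at full 512 px scale; smaller desk-scale runs typically use
#'   1e-3.
#' @param batch_size Mini-batch size (>= 1).
#' @param max_epochs Number of training epochs (>= 1).
#' @param augment Apply one random geometric transform per sample per epoch
#'   (online augmentation).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement; `Inf` (default) disables early stopping, matching a
#'   fixed-epoch run with validation monitoring.
#' @param seed Integer seed governing batch order and augmentation draws.
#' @return Object of class `train_config`. The loss is pixel-wise binary
#'   cross-entropy and the optimizer Adam; checkpointing keeps the weights
#'   with the best validation Dice.
#' @export
train_config <- function(lr = 1e-4, batch_size = 16L, max_epochs = 300L,
                         augment = TRUE, patience = Inf, seed = 1L) {
  if (lr <= 0) stop("`lr` must be positive")
  if (batch_size < 1L) stop("`batch_size` must be >= 1")
  if (max_epochs < 1L) stop("`max_epochs` must be >= 1")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 augment = isTRUE(augment), patience = patience,
                 seed = as.integer(seed),
                 optimizer = "adam", loss = "bce"),
            class = "train_config")
}

#' 5-fold cross-validation plan with 6:2:2 splits
#'
#' Shuffles the indices once under `seed` and cuts them into `k` disjoint
#' test sets; within each fold the remaining items are split 3:1 into
#' training and validation, so the overall train:val:test ratio is 6:2:2
#' (up to one-sample rounding) for the default `k = 5`. With `strata`
#' given, test membership is allocated within each stratum.
#'
#' @param n_items Number of items (>= `2 * k`).
#' @param k Number of folds.
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @param strata Optional vector of length `n_items` with class labels to
#'   balance across test sets.
#' @return Object of class `fold_plan`: `$folds[[f]]` has integer index
#'   vectors `train`, `val`, `test`. The `k` test sets partition
#'   `1:n_items`.
#' @export
kfold_split <- function(n_items, k = 5L, seed = 1L, strata = NULL) {
  n_items <- as.integer(n_items)
  k <- as.integer(k)
  if (n_items < 2L * k)
    stop("need at least ", 2L * k, " items for k = ", k, ", got ", n_items)
  if (!is.null(strata) && length(strata) != n_items)
    stop("`strata` must have length `n_items`")
  folds <- withr::with_seed(seed, {
    chunk <- integer(n_items)
    if (is.null(strata)) {
      perm <- sample.int(n_items)
      chunk[perm] <- rep_len(seq_len(k), n_items)
    } else {
      for (s in unique(strata)) {
        idx <- which(strata == s)
        idx <- idx[sample.int(length(idx))]
        chunk[idx] <- rep_len(seq_len(k), length(idx))
      }
    }
    lapply(seq_len(k), function(f) {
      test <- which(chunk == f)
      rest <- which(chunk != f)
      rest <- rest[sample.int(length(rest))]
      n_val <- round(length(rest) / 4)
      list(train = sort(rest[-seq_len(n_val)]),
           val = sort(rest[seq_len(n_val)]),
           test = sort(test))
    })
  })
  # partition invariant, asserted on every construction
  all_test <- sort(unlist(lapply(folds, `[[`, "test")))
  stopifnot(identical(all_test, seq_len(n_items)))
  for (f in folds)
    stopifnot(!anyDuplicated(c(f$train, f$val, f$test)),
              length(c(f$train, f$val, f$test)) == n_items)
  structure(list(k = k, n = n_items, seed = as.integer(seed), folds = folds),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f)
    c(length(f$train), length(f$val), length(f$test)), numeric(3))
  cat(sprintf("<fold_plan> %d items, %d folds (train/val/test per fold: %s)\n",
              x$n, x$k, paste(sizes[, 1], collapse = "/")))
  invisible(x)
}

# Coerce list elements to image pairs.
.as_pair <- function(x) {
  if (inherits(x, "image_pair")) return(x)
  if (is.list(x) && !is.null(x$image) && !is.null(x$mask))
    return(image_pair(x$image, x$mask))
  stop("dataset items must be `image_pair` objects")
}

# Stack a list of pairs into (H, W, 1, N) input and target arrays,
# optionally applying one random transform per pair (consumes the RNG).
.make_batch <- function(pairs, augment) {
  d <- dim(pairs[[1]]$image)
  n <- length(pairs)
  x <- array(0, c(d[1], d[2], 1L, n))
  y <- array(0, c(d[1], d[2], 1L, n))
  for (i in seq_len(n)) {
    p <- pairs[[i]]
    if (augment) p <- augment_pair(p$image, p$mask)
    x[, , 1L, i] <- p$image
    y[, , 1L, i] <- p$mask
  }
  list(x = x, y = y)
}

# Snapshot / restore all learnable values and batch-norm running stats.
model_state <- function(model) {
  list(params = lapply(model$params, function(p) p$value),
       bn = lapply(model$bn, function(e) list(mean = e$mean, var = e$var)))
}

restore_state <- function(model, state) {
  for (nm in names(state$params)) model$params[[nm]]$value <- state$params[[nm]]
  for (nm in names(state$bn)) {
    model$bn[[nm]]$mean <- state$bn[[nm]]$mean
    model$bn[[nm]]$var <- state$bn[[nm]]$var
  }
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the architecture configuration, the initialisation
#' seed, every learnable parameter and the batch-norm running statistics,
#' so `load_checkpoint(save_checkpoint(m, f))` reproduces predictions
#' bit-identically.
#'
#' @param model An `nnet_model`.
#' @param path File path (`.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `nnet_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, seed = model$seed,
               state = model_state(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config, seed = ck$seed)
  restore_state(model, ck$state)
}

#' Train a segmentation model
#'
#' Minimises pixel-wise binary cross-entropy with Adam, with online
#' geometric augmentation, and tracks the validation Dice (threshold 0.5)
#' after every epoch. The returned model carries the weights of the best
#' validation epoch. Fully reproducible given the seeds (single-threaded
#' deterministic kernels).
#'
#' @param model An `nnet_model` (modified in place and returned).
#' @param train_set,val_set Nonempty lists of [image_pair()] objects with
#'   identical image sizes.
#' @param config A [train_config()].
#' @param checkpoint_path Optional path; the best state is written there as
#'   a checkpoint after training.
#' @param verbose Print one line per epoch.
#' @return List of class `train_result`: `model`, `history` (data.frame
#'   with `epoch`, `train_loss`, `val_dice`), `best_epoch`,
#'   `best_val_dice`.
#' @export
train_model <- function(model, train_set, val_set, config = train_config(),
                        checkpoint_path = NULL, verbose = FALSE) {
  if (!length(train_set)) stop("training set is empty")
  if (!length(val_set)) stop("validation set is empty")
  train_set <- lapply(train_set, .as_pair)
  val_set <- lapply(val_set, .as_pair)

  opt <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_dice = numeric(0))
  best <- list(dice = -Inf, epoch = 0L, state = model_state(model))
  since_best <- 0L

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(length(train_set))
      losses <- numeric(0)
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        b <- .make_batch(train_set[idx], config$augment)
        out <- forward_nnet(model, b$x, training = TRUE)
        loss <- ad_bce_logits(out$logit, b$y)
        if (!is.finite(loss$value))
          stop("non-finite training loss at epoch ", epoch,
               " (loss = ", loss$value, "); try a smaller learning rate")
        ad_backward(loss)
        opt <- adam_step(model$params, opt, lr = config$lr)
        losses <- c(losses, loss$value)
      }
      vd <- mean(vapply(val_set, function(p) {
        pm <- predict(model, p$image)
        dice(confusion_counts((pm >= 0.5) * 1, p$mask))
      }, numeric(1)))
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = mean(losses),
                                  val_dice = vd))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val dice %.4f", epoch,
                        mean(losses), vd))
      if (vd > best$dice) {
        best <- list(dice = vd, epoch = epoch, state = model_state(model))
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) break
      }
    }
  })

  restore_state(model, best$state)
  if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
  structure(list(model = model, history = history,
                 best_epoch = best$epoch, best_val_dice = best$dice),
            class = "train_result")
}

#' Evaluate a model on a test set
#'
#' Predicts every image (optionally with six-view test-time augmentation),
#' thresholds at 0.5 and computes per-image Dice, mIoU, precision, recall
#' and F1, plus their mean and standard deviation.
#'
#' @param model An `nnet_model`, or any function mapping an image matrix to
#'   a probability matrix.
#' @param test_set Nonempty list of [image_pair()] objects.
#' @param use_tta Average the six geometric test-time views before
#'   thresholding.
#' @param threshold Binarisation threshold on the probability map.
#' @return Object of class `metric_report`: `per_image` (one row per
#'   image), `summary` (mean and sd per metric), `n`, `use_tta`.
#' @export
evaluate_model <- function(model, test_set, use_tta = FALSE,
                           threshold = 0.5) {
  if (!length(test_set)) stop("test set is empty")
  test_set <- lapply(test_set, .as_pair)
  fwd <- if (is.function(model)) {
    model
  } else {
    function(im) predict(model, im)
  }
  rows <- lapply(seq_along(test_set), function(i) {
    p <- test_set[[i]]
    prob <- if (use_tta) tta_predict(fwd, p$image) else fwd(p$image)
    m <- segmentation_metrics((prob >= threshold) * 1, p$mask)
    cbind(data.frame(image = i), m)
  })
  per_image <- do.call(rbind, rows)
  metric_report(per_image, use_tta = use_tta)
}

#' Assemble a metric report from per-image rows
#'
#' @param per_image data.frame with columns `dice`, `miou`, `precision`,
#'   `recall`, `f1` (one row per image; extra id columns allowed).
#' @param use_tta Whether predictions used test-time augmentation.
#' @return Object of class `metric_report`.
#' @export
metric_report <- function(per_image, use_tta = FALSE) {
  metrics <- c("dice", "miou", "precision", "recall", "f1")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m)
      if (nrow(per_image)) mean(per_image[[m]]) else NA_real_, numeric(1)),
    sd = vapply(metrics, function(m)
      if (nrow(per_image) > 1) stats::sd(per_image[[m]]) else NA_real_,
      numeric(1)),
    row.names = NULL)
  structure(list(per_image = per_image, summary = summary,
                 n = nrow(per_image), use_tta = isTRUE(use_tta)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> n = %d images%s\n", x$n,
              if (x$use_tta) " (TTA)" else ""))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %.4f +/- %s\n", s$metric[i], s$mean[i],
                ifelse(is.na(s$sd[i]), "NA", sprintf("%.4f", s$sd[i]))))
  invisible(x)
}

#' Ablation harness: train and evaluate several configurations
#'
#' Trains every architecture configuration on the same folds with the same
#' seeds and reports the five segmentation metrics per configuration as
#' mean +/- SD across folds — the classic component-ablation table (plain
#' U-Net up to the full network).
#'
#' @param dataset List of [image_pair()] objects.
#' @param configs Named list of [arch_config()] objects (>= 2 for an
#'   ablation; a single config degenerates to train + evaluate).
#' @param train_cfg A [train_config()].
#' @param fold_plan Optional [kfold_split()] plan; defaults to 5 folds
#'   under `train_cfg$seed`.
#' @param folds Which fold indices to run (default all).
#' @param use_tta Use test-time augmentation at evaluation.
#' @param verbose Progress messages.
#' @return data.frame with one row per configuration: `config`, `n_folds`,
#'   and `<metric>_mean` / `<metric>_sd` columns; per-fold results are
#'   attached as attribute `"per_fold"`. If a fold fails, its error is
#'   recorded in the `failed` column and the attribute
#'   `"any_failed"` is set (the command-line wrapper exits nonzero).
#' @export
run_ablation <- function(dataset, configs, train_cfg = train_config(),
                         fold_plan = NULL, folds = NULL, use_tta = FALSE,
                         verbose = FALSE) {
  dataset <- lapply(dataset, .as_pair)
  if (is.null(names(configs)) || any(names(configs) == ""))
    names(configs) <- paste0("config", seq_along(configs))
  if (is.null(fold_plan))
    fold_plan <- kfold_split(length(dataset), k = 5L, seed = train_cfg$seed)
  if (is.null(folds)) folds <- seq_len(fold_plan$k)
  metrics <- c("dice", "miou", "precision", "recall", "f1")

  per_fold <- list()
  rows <- list()
  any_failed <- FALSE
  for (nm in names(configs)) {
    fold_means <- list()
    failed <- NA_character_
    for (f in folds) {
      res <- tryCatch({
        plan <- fold_plan$folds[[f]]
        model <- build_model(configs[[nm]], seed = train_cfg$seed)
        fit <- train_model(model, dataset[plan$train], dataset[plan$val],
                           train_cfg)
        rep <- evaluate_model(fit$model, dataset[plan$test],
                              use_tta = use_tta)
        if (verbose)
          message(sprintf("%s fold %d: dice %.4f", nm, f,
                          rep$summary$mean[rep$summary$metric == "dice"]))
        stats::setNames(rep$summary$mean, rep$summary$metric)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        any_failed <- TRUE
        failed <- conditionMessage(res)
        warning("configuration `", nm, "` failed on fold ", f, ": ",
                failed, call. = FALSE)
        break
      }
      fold_means[[length(fold_means) + 1L]] <-
        cbind(data.frame(config = nm, fold = f), as.data.frame(t(res)))
    }
    fm <- if (length(fold_means)) do.call(rbind, fold_means) else NULL
    per_fold[[nm]] <- fm
    row <- data.frame(config = nm,
                      n_folds = if (is.null(fm)) 0L else nrow(fm))
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- if (is.null(fm)) NA_real_ else mean(fm[[m]])
      row[[paste0(m, "_sd")]] <-
        if (is.null(fm) || nrow(fm) < 2) NA_real_ else stats::sd(fm[[m]])
    }
    row$failed <- failed
    rows[[nm]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_fold") <- do.call(rbind, per_fold)
  attr(out, "any_failed") <- any_failed
  out
}
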