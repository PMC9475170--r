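# Segmentation metrics: toy enumerations, identities, symmetries.

test_that("confusion counts enumerate the four outcomes exactly", {
  cc <- confusion_counts(matrix(c(1, 0, 1, 0), 2), matrix(c(1, 1, 0, 0), 2))
  expect_equal(cc$tp, 1); expect_equal(cc$fp, 1)
  expect_equal(cc$fn, 1); expect_equal(cc$tn, 1)
  # identity prediction
  g <- random_mask(7)
  cc2 <- confusion_counts(g, g)
  expect_equal(cc2$tp, sum(g)); expect_equal(cc2$fp, 0); expect_equal(cc2$fn, 0)
  # empty prediction
  cc3 <- confusion_counts(g * 0, g)
  expect_equal(cc3$tp, 0); expect_equal(cc3$fp, 0); expect_equal(cc3$fn, sum(g))
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes")
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0, 2, 2)), "0/1")
})

test_that("metric formulas evaluate the printed definitions", {
  cc <- structure(list(tp = 3, fp = 1, fn = 1, tn = 10),
                  class = "confusion_counts")
  expect_equal(dice(cc), 0.75)
  expect_equal(precision(cc), 0.75)
  expect_equal(recall(cc), 0.75)
  expect_equal(f1_score(cc), 0.75)
  # perfect and disjoint masks
  g <- random_mask(6, p = 0.5)
  perf <- confusion_counts(g, g)
  expect_equal(c(dice(perf), precision(perf), recall(perf), f1_score(perf)),
               rep(1, 4))
  dis <- confusion_counts(g, 1 - g)
  expect_equal(c(dice(dis), precision(dis), recall(dis), f1_score(dis)),
               rep(0, 4))
})

test_that("empty-vs-empty masks score 1.0 by convention", {
  z <- matrix(0, 4, 4)
  cc <- confusion_counts(z, z)
  expect_equal(dice(cc), 1.0)
  expect_equal(precision(cc), 1.0)
  expect_equal(recall(cc), 1.0)
  expect_equal(miou(list(cc)), 1.0)
})

test_that("mIoU averages class IoUs and matches explicit set computation", {
  # foreground IoU 0.6 and background IoU 0.8 -> 0.7
  fake <- list(structure(list(tp = 4, fp = 0, fn = 1, tn = 0),
                         class = "confusion_counts"),
               structure(list(tp = 3, fp = 1, fn = 1, tn = 0),
                         class = "confusion_counts"))
  expect_equal(miou(fake), mean(c(0.8, 0.6)))
  set.seed(5)
  for (i in 1:20) {
    p <- random_mask(8); g <- random_mask(8)
    bf <- brute_metrics(p, g)
    expect_equal(miou(sdcnet:::binary_class_counts(p, g)), bf$miou)
    # symmetry under swapping prediction and reference
    expect_equal(miou(sdcnet:::binary_class_counts(p, g)),
                 miou(sdcnet:::binary_class_counts(g, p)))
  }
  expect_error(miou(list()), "nonempty")
})

test_that("dice equals f1 identically and bounds the foreground IoU", {
  set.seed(6)
  for (i in 1:50) {
    p <- random_mask(8, p = runif(1, 0.1, 0.9))
    g <- random_mask(8, p = runif(1, 0.1, 0.9))
    cc <- confusion_counts(p, g)
    expect_identical(dice(cc), f1_score(cc))
    iou_fg <- sdcnet:::.safe_ratio(cc$tp, cc$fp + cc$tp + cc$fn, cc)
    expect_gte(dice(cc), iou_fg)
  }
})

test_that("metrics are invariant to joint rotation/flip of both masks", {
  set.seed(7)
  p <- random_mask(10); g <- random_mask(10)
  base <- segmentation_metrics(p, g)
  for (tr in c("rot90", "rot180", "hflip", "vflip")) {
    m <- segmentation_metrics(apply_transform(p, tr), apply_transform(g, tr))
    expect_equal(m, base)
  }
})

test_that("precision-recall curve is threshold-ordered with monotone recall", {
  set.seed(8)
  probs <- lapply(1:3, function(i) matrix(runif(64), 8))
  gts <- lapply(1:3, function(i) random_mask(8))
  pr <- pr_curve(probs, gts)
  expect_equal(nrow(pr), 101)
  expect_equal(pr$recall[1], 1.0)         # threshold 0 predicts everything
  expect_true(all(diff(pr$recall) <= 1e-12))
  # above the maximum probability nothing is predicted: precision 1 by convention
  pr2 <- pr_curve(list(matrix(0.3, 2, 2)), list(random_mask(2)),
                  thresholds = c(0.5, 1))
  expect_equal(pr2$precision[2], 1.0)
  expect_equal(pr2$recall[2], 0.0)
  # hand-binarized single 2x2 example at threshold 0.5
  pm <- matrix(c(0.9, 0.4, 0.6, 0.1), 2)
  gt <- matrix(c(1, 0, 0, 0), 2)
  pt <- pr_curve(list(pm), list(gt), thresholds = 0.5)
  expect_equal(pt$recall, 1)        # the one positive pixel is recovered
  expect_equal(pt$precision, 0.5)   # of two predicted pixels one is correct
  expect_error(pr_curve(probs, gts[1:2]), "masks")
})
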