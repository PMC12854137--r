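# Loss formulas, evaluation metrics, entropy and stratification against
# hand-computed values.

test_that("cross-entropy matches hand-computed values", {
  cfg <- loss_config(num_classes = 2L)
  # perfect one-hot prediction
  expect_equal(cross_entropy_loss(matrix(c(0, 1), 1), 1L, cfg), 0,
               tolerance = 1e-6)
  # p = 0.5 for the true class, N = 1
  expect_equal(cross_entropy_loss(matrix(c(0.5, 0.5), 1), 1L, cfg), log(2))
  # N = 2, true-class probs 0.8 and 0.4
  probs <- rbind(c(0.2, 0.8), c(0.6, 0.4))
  expect_equal(cross_entropy_loss(probs, c(1L, 1L), cfg),
               -(log(0.8) + log(0.4)) / 2)
  # zero probability at the true label is clamped, never NaN
  expect_true(is.finite(cross_entropy_loss(matrix(c(1, 0), 1), 1L, cfg)))
  expect_error(cross_entropy_loss(matrix(c(0.7, 0.7), 1), 1L, cfg), "sum to 1")
})

test_that("dice loss on hard masks: identical, disjoint, half-overlap", {
  cfg <- loss_config(smooth_eps = 0)
  m <- matrix(0L, 3, 3)
  a <- m; a[1, 1:2] <- 1L
  b <- m; b[1, 2] <- 1L; b[2, 2] <- 1L
  expect_equal(dice_loss(a, a, cfg), 0)
  d <- m; d[3, 3] <- 1L
  expect_equal(dice_loss(a, d, cfg), 1)
  expect_equal(dice_loss(a, b, cfg), 0.5) # |X|=|Y|=2, overlap 1
  # both empty -> 0 by the smoothing convention
  expect_equal(dice_loss(m, m, loss_config(smooth_eps = 1)), 0)
})

test_that("hybrid loss is the sigma-weighted combination", {
  probs <- rbind(c(0.5, 0.5))
  lab <- 1L
  c1 <- loss_config(sigma = 1)
  expect_equal(hybrid_loss(probs, lab, c1), cross_entropy_loss(probs, lab, c1))
  c0 <- loss_config(sigma = 0)
  p3 <- array(0, c(1, 1, 2)); p3[1, 1, ] <- c(0.5, 0.5)
  expect_equal(hybrid_loss(p3, matrix(1L), c0), dice_loss(p3, matrix(1L), c0))
  # sigma = 0.6 with CE = ln 2 and Dice = 0.5 gives ~0.6159
  expect_equal(0.6 * log(2) + 0.4 * 0.5, 0.61588830833596715)
  expect_error(loss_config(sigma = 1.2), "sigma")
})

test_that("hybrid loss is monotone nonincreasing in the true-class probability", {
  cfg <- loss_config()
  for (p_true in seq(0.05, 0.9, by = 0.1)) {
    a <- array(0, c(1, 1, 2)); a[1, 1, ] <- c(1 - p_true, p_true)
    b <- array(0, c(1, 1, 2)); b[1, 1, ] <- c(1 - p_true - 0.05, p_true + 0.05)
    expect_gt(hybrid_loss(a, matrix(1L), cfg), hybrid_loss(b, matrix(1L), cfg))
  }
})

test_that("confusion counts by exhaustive pixel comparison", {
  truth <- matrix(c(1, 1, 0,
                    0, 1, 0,
                    0, 0, 0), 3, 3, byrow = TRUE)
  pred <- matrix(c(1, 0, 0,
                   1, 1, 1,
                   0, 0, 0), 3, 3, byrow = TRUE)
  cnt <- confusion(pred, truth, 1L)
  # hand enumeration: TP {(1,1),(2,2)}, FP {(2,1),(2,3)}, FN {(1,2)}
  expect_equal(cnt, list(TP = 2L, FP = 2L, FN = 1L, TN = 4L))
  expect_equal(cnt$TP + cnt$FP + cnt$FN + cnt$TN, 9L)
  m <- precision_recall_miou(cnt)
  expect_equal(unname(m), 100 * c(2 / 4, 2 / 3, 2 / 5))
  # pred == truth and pred == !truth
  expect_equal(confusion(truth, truth, 1L)[c("FP", "FN")], list(FP = 0L, FN = 0L))
  expect_equal(confusion(1 - truth, truth, 1L)[c("TP", "TN")], list(TP = 0L, TN = 0L))
})

test_that("precision/recall/IoU formulas and conventions", {
  m <- precision_recall_miou(list(TP = 3, FP = 1, FN = 2))
  expect_equal(unname(m), c(75, 60, 50))
  expect_equal(unname(precision_recall_miou(list(TP = 0, FP = 0, FN = 0))),
               c(100, 100, 100))
  # IoU <= min(precision, recall) whenever TP > 0
  withr::with_seed(4, for (i in 1:20) {
    cnt <- list(TP = sample(1:50, 1), FP = sample(0:50, 1), FN = sample(0:50, 1))
    v <- precision_recall_miou(cnt)
    expect_true(all(v >= 0 & v <= 100))
    expect_lte(v[["iou"]], min(v[["precision"]], v[["recall"]]) + 1e-12)
  })
})

test_that("dice coefficient: bounds, symmetry, half overlap", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  b <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(dice_coefficient(a, a), 100)
  expect_equal(dice_coefficient(a, 1 - a), 0)
  expect_equal(dice_coefficient(a, b), 50)
  expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
  expect_equal(dice_coefficient(matrix(0, 2, 2), matrix(0, 2, 2)), 100)
})

test_that("mean IoU reduces to the pest-class IoU in the binary case", {
  truth <- matrix(c(1, 1, 0, 0), 2, 2)
  pred <- matrix(c(1, 0, 1, 0), 2, 2)
  cnt <- confusion(pred, truth, 1L)
  expect_equal(mean_iou(pred, truth, 2L),
               unname(precision_recall_miou(cnt)[["iou"]]))
})

test_that("image entropy: constant, uniform, two-level, permutation invariance", {
  expect_equal(image_entropy(matrix(7L, 16, 16)), 0)
  expect_equal(image_entropy(matrix(0:255, 16, 16)), 8)
  expect_equal(image_entropy(matrix(c(0L, 255L), 16, 16)), 1)
  g <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  perm <- sample(0:255) # relabel gray levels bijectively
  expect_equal(image_entropy(g), image_entropy(matrix(perm[g + 1], 8, 8)))
  expect_error(image_entropy(matrix(300L, 2, 2)), "0..255")
})

test_that("stratification boundary semantics match the printed bins", {
  rec <- data.frame(area_fraction = c(0.009, 0.01, 0.049, 0.05, 0.2, 0),
                    entropy = c(1, 2, 3, 4, 5, 6))
  s <- stratify(rec)
  expect_equal(as.character(s$size_bin),
               c("small", "medium", "medium", "large", "large", "small"))
  # entropy <= median is low; exact ties all low
  st <- stratify(data.frame(area_fraction = rep(0.02, 4), entropy = rep(3, 4)))
  expect_true(all(st$complexity_bin == "low"))
  # odd n with distinct entropies puts ceiling(n/2) in low
  so <- stratify(data.frame(area_fraction = rep(0.02, 7), entropy = 1:7))
  expect_equal(sum(so$complexity_bin == "low"), 4)
})
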