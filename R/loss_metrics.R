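# Hybrid training loss, evaluation statistics, image entropy and the
# stratified analysis rules.

#' Loss configuration
#'
#' @param sigma Weight on the cross-entropy term of the hybrid loss, in
#'   `[0, 1]` (default 0.6); `1 - sigma` weights the Dice term.
#' @param num_classes Number of classes including background.
#' @param smooth_eps Smoothing constant added to Dice numerator and
#'   denominator (default 1), which defines the empty-vs-empty case as a
#'   perfect overlap.
#' @param prob_clamp Lower clamp on probabilities inside the logarithm.
#' @return A `loss_config` list.
#' @export
loss_config <- function(sigma = 0.6, num_classes = 2L, smooth_eps = 1,
                        prob_clamp = 1e-7) {
  if (sigma < 0 || sigma > 1) stopf("sigma must lie in [0, 1]")
  if (smooth_eps < 0) stopf("smooth_eps must be >= 0")
  structure(list(sigma = sigma, num_classes = as.integer(num_classes),
                 smooth_eps = smooth_eps, prob_clamp = prob_clamp),
            class = "loss_config")
}

as_prob_mat <- function(probs) {
  if (is_fm(probs)) fm_mat(probs) else as.matrix(probs)
}

check_probs <- function(pm) {
  if (any(abs(rowSums(pm) - 1) > 1e-6))
    stopf("probability rows must sum to 1 (max deviation %.3g)",
          max(abs(rowSums(pm) - 1)))
}

#' Mean multiclass cross-entropy
#'
#' Mean negative log-probability of the true class over all pixels,
#' `-(1/N) sum_i sum_c y_ic log p_ic`. Probabilities are clamped at
#' `cfg$prob_clamp` so a zero at a true label never produces `NaN`.
#'
#' @param probs Per-pixel class probabilities: `N x C` matrix or
#'   `H x W x C` array, rows summing to 1.
#' @param labels Integer class labels in `0 .. C-1` (vector or `H x W`).
#' @param cfg A [loss_config()].
#' @return Nonnegative scalar.
#' @export
cross_entropy_loss <- function(probs, labels, cfg = loss_config()) {
  pm <- as_prob_mat(probs)
  check_probs(pm)
  lab <- as.integer(labels)
  if (any(lab < 0L | lab >= ncol(pm))) stopf("labels out of range")
  p_true <- pmax(pm[cbind(seq_len(nrow(pm)), lab + 1L)], cfg$prob_clamp)
  -mean(log(p_true))
}

#' Dice loss
#'
#' `1 - 2|X∩Y| / (|X| + |Y|)`, in `[0, 1]`. Hard masks use the foreground
#' pixel sets; an `H x W x C` probability array uses the soft
#' (differentiable) form averaged over foreground classes. When both sets
#' are empty the smoothed form returns 0.
#'
#' @param pred Predicted mask (integer, foreground = label > 0) or an
#'   `H x W x C` probability array.
#' @param truth Ground-truth integer mask.
#' @inheritParams cross_entropy_loss
#' @export
dice_loss <- function(pred, truth, cfg = loss_config()) {
  eps <- cfg$smooth_eps
  if (is_fm(pred)) {
    pm <- fm_mat(pred)
    lab <- as.integer(truth)
    terms <- vapply(seq_len(ncol(pm) - 1L), function(c) {
      p <- pm[, c + 1L]; y <- as.numeric(lab == c)
      1 - (2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)
    }, 0)
    mean(terms)
  } else {
    if (!identical(dim(pred) %||% length(pred), dim(truth) %||% length(truth)))
      stopf("dice_loss: mask shapes differ")
    x <- pred > 0; y <- truth > 0
    1 - (2 * sum(x & y) + eps) / (sum(x) + sum(y) + eps)
  }
}

#' Hybrid segmentation loss
#'
#' Convex combination `sigma * CE + (1 - sigma) * Dice`; `sigma = 1`
#' recovers pure cross-entropy, `sigma = 0` pure Dice.
#'
#' @inheritParams cross_entropy_loss
#' @export
hybrid_loss <- function(probs, labels, cfg = loss_config()) {
  soft <- probs
  if (!is_fm(soft)) { # N x C probability matrix -> N x 1 x C array
    soft <- as.matrix(soft)
    dim(soft) <- c(nrow(soft), 1L, ncol(soft))
  }
  cfg$sigma * cross_entropy_loss(probs, labels, cfg) +
    (1 - cfg$sigma) * dice_loss(soft, labels, cfg)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Training objective on logits: value and gradient d loss / d logits.
hybrid_loss_grad <- function(logits, labels, cfg) {
  d <- dim(logits)
  zm <- fm_mat(logits)
  pm <- softmax_rows(zm)
  n <- nrow(pm); K <- ncol(pm)
  lab <- as.integer(labels)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), lab + 1L)] <- 1
  ce <- -mean(log(pmax(pm[cbind(seq_len(n), lab + 1L)], cfg$prob_clamp)))
  dce <- (pm - Y) / n # d mean-CE / d logits
  eps <- cfg$smooth_eps
  dl_dp <- matrix(0, n, K)
  dice_terms <- numeric(K - 1L)
  for (c in seq_len(K - 1L)) {
    p <- pm[, c + 1L]; y <- Y[, c + 1L]
    den <- sum(p) + sum(y) + eps
    num <- 2 * sum(p * y) + eps
    dice_terms[c] <- 1 - num / den
    dl_dp[, c + 1L] <- dl_dp[, c + 1L] + (-2 * y / den + num / den^2) / (K - 1L)
  }
  dice <- mean(dice_terms)
  # softmax jacobian: dz = p * (dl_dp - rowSums(dl_dp * p))
  ddice <- pm * (dl_dp - rowSums(dl_dp * pm))
  loss <- cfg$sigma * ce + (1 - cfg$sigma) * dice
  dz <- cfg$sigma * dce + (1 - cfg$sigma) * ddice
  list(loss = loss, ce = ce, dice = dice, dlogits = mat_fm(dz, d[1], d[2]))
}

#' Per-class confusion counts
#'
#' Exhaustive pixel comparison of predicted and ground-truth masks for one
#' class id.
#'
#' @param pred_mask,truth_mask Integer label masks of identical shape.
#' @param class_id The class treated as positive.
#' @return List with `TP`, `FP`, `FN`, `TN` (their sum is the pixel count).
#' @export
confusion <- function(pred_mask, truth_mask, class_id = 1L) {
  if (length(pred_mask) != length(truth_mask))
    stopf("confusion: mask sizes differ")
  p <- pred_mask == class_id; y <- truth_mask == class_id
  list(TP = sum(p & y), FP = sum(p & !y), FN = sum(!p & y), TN = sum(!p & !y))
}

#' Precision, recall and IoU from confusion counts (percent)
#'
#' `Precision = TP/(TP+FP)`, `Recall = TP/(TP+FN)`,
#' `IoU = TP/(TP+FP+FN)`, each times 100. An undefined ratio (0/0, the
#' empty-class case) is reported as 100 by convention.
#'
#' @param counts A list with `TP`, `FP`, `FN` (as from [confusion()]).
#' @return Named numeric vector `precision`, `recall`, `iou` in `[0, 100]`.
#' @export
precision_recall_miou <- function(counts) {
  r <- function(num, den) if (den == 0) 100 else 100 * num / den
  c(precision = r(counts$TP, counts$TP + counts$FP),
    recall = r(counts$TP, counts$TP + counts$FN),
    iou = r(counts$TP, counts$TP + counts$FP + counts$FN))
}

#' Mean IoU over foreground classes
#'
#' Per-class IoU averaged over the foreground classes present in the union
#' of prediction and truth; with a single foreground class this is exactly
#' the pest-class IoU.
#'
#' @inheritParams confusion
#' @param num_classes Total class count including background.
#' @export
mean_iou <- function(pred_mask, truth_mask, num_classes = 2L) {
  ious <- c()
  for (c in seq_len(num_classes - 1L)) {
    cnt <- confusion(pred_mask, truth_mask, c)
    if (cnt$TP + cnt$FP + cnt$FN > 0)
      ious <- c(ious, 100 * cnt$TP / (cnt$TP + cnt$FP + cnt$FN))
  }
  if (length(ious) == 0) 100 else mean(ious)
}

#' Dice similarity coefficient (percent)
#'
#' `100 * 2|X∩Y| / (|X| + |Y|)` on the foreground pixel sets; 100 when
#' both masks are empty.
#'
#' @inheritParams confusion
#' @export
dice_coefficient <- function(pred_mask, truth_mask) {
  x <- pred_mask > 0; y <- truth_mask > 0
  if (sum(x) + sum(y) == 0) return(100)
  100 * 2 * sum(x & y) / (sum(x) + sum(y))
}

#' Shannon entropy of an 8-bit image (bits)
#'
#' Entropy of the 256-bin gray-level histogram,
#' `-sum_i p(i) log2 p(i)` over nonempty bins; in `[0, 8]`. RGB input is
#' converted to luminance (ITU-R BT.601, rounded to integers).
#'
#' @param image `H x W` integer gray levels in `0..255`, or an
#'   `H x W x 3` RGB array (values in `[0, 1]` or `0..255`).
#' @export
image_entropy <- function(image) {
  if (is_fm(image)) {
    if (max(image) <= 1) image <- image * 255
    g <- round(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  } else {
    g <- round(image)
  }
  if (any(g < 0 | g > 255)) stopf("gray levels must lie in 0..255")
  p <- tabulate(as.integer(g) + 1L, nbins = 256L)
  p <- p[p > 0] / length(g)
  -sum(p * log2(p))
}

#' Stratify sample records by pest size and background complexity
#'
#' Size bins follow the printed boundaries: small `< 1%`, medium
#' `1% <= area < 5%`, large `>= 5%` of the image area. Complexity is a
#' median split of the image entropies within the evaluated set, with
#' `entropy <= median` labelled low.
#'
#' @param records Data frame with columns `area_fraction` and `entropy`
#'   (bits), one row per sample.
#' @return The data frame with added factors `size_bin`
#'   (small/medium/large) and `complexity_bin` (low/high).
#' @export
stratify <- function(records) {
  records <- as.data.frame(records)
  af <- records$area_fraction
  records$size_bin <- factor(
    ifelse(af < 0.01, "small", ifelse(af < 0.05, "medium", "large")),
    levels = c("small", "medium", "large"))
  med <- median(records$entropy)
  records$complexity_bin <- factor(ifelse(records$entropy <= med, "low", "high"),
                                   levels = c("low", "high"))
  records
}
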