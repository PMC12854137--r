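# SGD training on the hybrid loss, k-fold protocol, and evaluation.

#' Training configuration
#'
#' Defaults follow the published protocol: SGD with constant learning
#' rate 1e-4, batch size 15, momentum 0.5, weight decay 1e-5, 5-fold
#' cross-validation. `iterations` defaults to 300 (a desk-scale run; the
#' full protocol uses 3000 per fold).
#'
#' @param model A [model_config()].
#' @param loss A [loss_config()]; defaults to sigma 0.6 with the model's
#'   class count.
#' @param learning_rate,batch_size,momentum,weight_decay,iterations SGD
#'   hyperparameters.
#' @param k_folds Folds for [train_kfold()].
#' @param seed Seed for batch sampling (weights use `model$seed`).
#' @export
train_config <- function(model = desk_config(), loss = NULL,
                         learning_rate = 1e-4, batch_size = 15L,
                         momentum = 0.5, weight_decay = 1e-5,
                         iterations = 300L, k_folds = 5L, seed = 0L) {
  if (learning_rate <= 0 || batch_size < 1L || iterations < 1L)
    stopf("rates must be positive and iterations >= 1")
  if (is.null(loss))
    loss <- loss_config(sigma = model$loss_sigma, num_classes = model$num_classes)
  structure(list(model = model, loss = loss, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), momentum = momentum,
                 weight_decay = weight_decay, iterations = as.integer(iterations),
                 k_folds = as.integer(k_folds), seed = as.integer(seed)),
            class = "train_config")
}

loss_grad_one <- function(model, image, mask, lcfg) {
  fw <- model_fwd(model, image)
  lg <- hybrid_loss_grad(fw$logits, mask, lcfg)
  if (!is.finite(lg$loss))
    stopf("training diverged: loss is %s", lg$loss)
  g <- model_bwd(model, fw$cache, lg$dlogits)
  list(loss = lg$loss, g = g)
}

#' Train a model by SGD on the hybrid loss
#'
#' Mini-batch SGD with momentum and weight decay; each iteration samples
#' `batch_size` records (without replacement) and averages their
#' gradients. Aborts with a diagnostic if the loss diverges to `NaN`.
#' Deterministic given the seeds (single-threaded).
#'
#' @param model A `vss_model` (or `NULL` to build from `tc$model`).
#' @param records Training records (lists with `image` and `mask`).
#' @param tc A [train_config()].
#' @param log_every Record the running loss every this many iterations.
#' @return List with the trained `model` and a `log` data frame
#'   (`iteration`, `loss`).
#' @export
train_model <- function(model, records, tc, log_every = 10L) {
  if (is.null(model)) model <- build_model(tc$model)
  p <- model$params
  vel <- tree_map(p, function(x) x * 0)
  n <- length(records)
  bs <- min(tc$batch_size, n)
  log_it <- integer(0); log_loss <- numeric(0)
  for (it in seq_len(tc$iterations)) {
    idx <- local_seed((as.numeric(tc$seed) * 100003 + it) %% 2147483647,
                      sample.int(n, bs))
    gsum <- NULL; lsum <- 0
    for (i in idx) {
      model$params <- p
      r <- loss_grad_one(model, records[[i]]$image, records[[i]]$mask, tc$loss)
      lsum <- lsum + r$loss
      gsum <- if (is.null(gsum)) r$g else tree_map2(gsum, r$g, `+`)
    }
    loss <- lsum / bs
    if (!is.finite(loss))
      stopf("training diverged: loss is %s at iteration %d", loss, it)
    g <- tree_map(gsum, function(x) x / bs)
    g <- tree_map2(g, p, function(gg, pp) gg + tc$weight_decay * pp)
    vel <- tree_map2(vel, g, function(v, gg) tc$momentum * v - tc$learning_rate * gg)
    p <- tree_map2(p, vel, `+`)
    if (it %% log_every == 0L || it == 1L || it == tc$iterations) {
      log_it <- c(log_it, it); log_loss <- c(log_loss, loss)
    }
  }
  model$params <- p
  list(model = model, log = data.frame(iteration = log_it, loss = log_loss))
}

#' Per-image segmentation metrics
#'
#' @param model A `vss_model`.
#' @param records Records with `image`, `mask` (and optionally
#'   `area_fraction`, `entropy`, `fold`).
#' @return Data frame of per-image precision, recall, mIoU, DSC plus the
#'   record metadata.
#' @export
evaluate_model <- function(model, records) {
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    sg <- segment(model, r$image)
    cnt <- confusion(sg$predicted_mask, r$mask, 1L)
    m <- precision_recall_miou(cnt)
    data.frame(id = i,
               precision = m[["precision"]], recall = m[["recall"]],
               miou = mean_iou(sg$predicted_mask, r$mask, model$cfg$num_classes),
               dsc = dice_coefficient(sg$predicted_mask, r$mask),
               area_fraction = r$area_fraction %||% mean(r$mask > 0),
               entropy = r$entropy %||% image_entropy(r$image),
               fold = r$fold %||% NA_integer_)
  })
  do.call(rbind, rows)
}

summarize_group <- function(df) {
  data.frame(n = nrow(df), precision = mean(df$precision),
             recall = mean(df$recall), miou = mean(df$miou), dsc = mean(df$dsc))
}

#' Stratified evaluation report
#'
#' Per-image metrics averaged overall and within each pest-size and
#' background-complexity stratum; with fold ids present, fold-level mean
#' and standard deviation of DSC are included.
#'
#' @inheritParams evaluate_model
#' @return List with `overall`, `per_stratum` (data frame), `per_image`,
#'   and optional `fold_summary`.
#' @export
eval_report <- function(model, records) {
  per <- evaluate_model(model, records)
  per <- stratify(per)
  strata <- rbind(
    do.call(rbind, lapply(split(per, per$size_bin), summarize_group)),
    do.call(rbind, lapply(split(per, per$complexity_bin), summarize_group)))
  strata <- cbind(stratum = rownames(strata), strata)
  rownames(strata) <- NULL
  rep <- list(overall = summarize_group(per), per_stratum = strata,
              per_image = per)
  if (!all(is.na(per$fold))) {
    fm <- vapply(split(per$dsc, per$fold), mean, 0)
    rep$fold_summary <- data.frame(fold = names(fm), dsc_mean = unname(fm))
    rep$dsc_fold_mean <- mean(fm)
    rep$dsc_fold_sd <- stats::sd(fm)
  }
  rep
}

#' Write an evaluation report as JSON and CSV
#'
#' @param report An [eval_report()] result.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    out <- list(overall = as.list(report$overall),
                per_stratum = report$per_stratum)
    if (!is.null(report$fold_summary)) {
      out$dsc_fold_mean <- report$dsc_fold_mean
      out$dsc_fold_sd <- report$dsc_fold_sd
    }
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(csv_path)) utils::write.csv(report$per_image, csv_path, row.names = FALSE)
  invisible(report)
}

#' Five-fold cross-validated training
#'
#' Runs the k-fold protocol: for each fold, trains on the remaining
#' folds and evaluates on the held-out fold; returns per-fold models and
#' validation reports.
#'
#' @inheritParams train_model
#' @export
train_kfold <- function(records, tc) {
  folds <- vapply(records, function(r) r$fold %||% NA_integer_, 0L)
  if (all(is.na(folds)))
    folds <- kfold_split(records, k = tc$k_folds, seed = tc$seed)
  out <- lapply(sort(unique(folds)), function(f) {
    tr <- records[folds != f]
    va <- records[folds == f]
    fit <- train_model(NULL, tr, tc)
    list(fold = f, model = fit$model, log = fit$log,
         validation = evaluate_model(fit$model, va))
  })
  out
}
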