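# End-to-end network: patch embedding, encoder stages of MSVSS blocks with
# IPM downsampling between stages, AVSS bottleneck, mirrored decoder with
# IPE and IAF-gated skips, and a 4x patch-expanding segmentation head.

#' Model hyperparameters
#'
#' @param embed_dim Embedding width `C` of the first stage (default 96).
#' @param patch_size Side of the non-overlapping embedding patches
#'   (default 4).
#' @param stage_depth Blocks per stage (default 2, the "dual" block pair).
#' @param num_stages Encoder/decoder stages (default 4); channel widths
#'   follow `C, 2C, 4C, ...`.
#' @param num_classes Segmentation classes including background (>= 2).
#' @param state_dim Selective-scan state size (default 16).
#' @param use_msvss,use_iaf,use_avss,use_ipm_ipe Ablation switches: plain
#'   VSS blocks instead of MSVSS, concatenation skips instead of IAF,
#'   plain VSS bottleneck instead of AVSS, max-pool/upsample instead of
#'   IPM/IPE.
#' @param loss_sigma Hybrid-loss weight on cross-entropy (default 0.6;
#'   1 recovers pure cross-entropy).
#' @param msvss_outer_residual Add the MSVSS input to its output (the
#'   literal block composition has the residual only inside VSS).
#' @param seed Weight-initialization seed.
#' @param ... Further arguments passed to [block_config()].
#' @return A `model_config` list.
#' @export
model_config <- function(embed_dim = 96L, patch_size = 4L, stage_depth = 2L,
                         num_stages = 4L, num_classes = 2L, state_dim = 16L,
                         use_msvss = TRUE, use_iaf = TRUE, use_avss = TRUE,
                         use_ipm_ipe = TRUE, loss_sigma = 0.6,
                         msvss_outer_residual = FALSE, seed = 0L, ...) {
  if (embed_dim < 1L) stopf("embed_dim must be >= 1")
  if (num_classes < 2L) stopf("num_classes must be >= 2")
  if (loss_sigma < 0 || loss_sigma > 1) stopf("loss_sigma must lie in [0, 1]")
  structure(list(
    embed_dim = as.integer(embed_dim), patch_size = as.integer(patch_size),
    stage_depth = as.integer(stage_depth), num_stages = as.integer(num_stages),
    num_classes = as.integer(num_classes), state_dim = as.integer(state_dim),
    use_msvss = isTRUE(use_msvss), use_iaf = isTRUE(use_iaf),
    use_avss = isTRUE(use_avss), use_ipm_ipe = isTRUE(use_ipm_ipe),
    loss_sigma = loss_sigma, msvss_outer_residual = isTRUE(msvss_outer_residual),
    seed = as.integer(seed), block_extra = list(...)), class = "model_config")
}

#' Desk-scale configuration for CPU experiments
#'
#' A small instantiation (embedding width 16, two stages, state size 8)
#' that trains in minutes on one CPU core with 64x64 inputs, used by the
#' worked examples and the capacity checks. The outer MSVSS residual is
#' enabled here so the encoder keeps an identity path at depth.
#'
#' @param ... Overrides passed to [model_config()].
#' @export
desk_config <- function(...) {
  args <- modifyList(list(embed_dim = 16L, num_stages = 2L, stage_depth = 2L,
                          state_dim = 8L, msvss_outer_residual = TRUE), list(...))
  do.call(model_config, args)
}

stage_channels <- function(cfg) cfg$embed_dim * 2L^(seq_len(cfg$num_stages) - 1L)

stage_block_cfg <- function(cfg, channels) {
  do.call(block_config, c(list(channels = channels, state_dim = cfg$state_dim,
                               outer_residual = cfg$msvss_outer_residual),
                          cfg$block_extra))
}

min_divisor <- function(cfg) cfg$patch_size * 2L^(cfg$num_stages - 1L)

#' Build the segmentation model
#'
#' Assembles and initializes the full parameter tree from a
#' [model_config()]: embedding, `num_stages` encoder stages of
#' `stage_depth` blocks with downsampling between stages, bottleneck,
#' mirrored decoder with gated skips, and the patch-expanding head.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [model_config()].
#' @return A `vss_model` list with `cfg`, `params` and a config `hash`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  ch <- stage_channels(cfg)
  S <- cfg$num_stages
  params <- local_seed(cfg$seed, {
    mk_stage <- function(C) {
      bc <- stage_block_cfg(cfg, C)
      lapply(seq_len(cfg$stage_depth), function(i)
        if (cfg$use_msvss) msvss_init(bc) else vss_init(bc))
    }
    p <- list()
    p$embed <- lin_init(cfg$patch_size^2 * 3L, cfg$embed_dim)
    p$enc <- lapply(ch, mk_stage)
    p$down <- lapply(ch[-S], function(C)
      if (cfg$use_ipm_ipe) ipm_init(C) else list(lin = lin_init(C, 2L * C)))
    bc_last <- stage_block_cfg(cfg, ch[S])
    p$bottleneck <- if (cfg$use_avss) avss_init(bc_last) else vss_init(bc_last)
    p$skip <- lapply(ch, function(C) {
      bc <- stage_block_cfg(cfg, C)
      if (cfg$use_iaf) iaf_init(bc) else list(lin = lin_init(2L * C, C))
    })
    p$dec <- lapply(ch, mk_stage)
    p$up <- lapply(ch[-1], function(C)
      if (cfg$use_ipm_ipe) ipe_init(C) else list(lin = lin_init(C, C %/% 2L)))
    p$final <- list(expand = lin_init(cfg$embed_dim, cfg$patch_size^2 * cfg$embed_dim),
                    ln = ln_init(cfg$embed_dim),
                    head = lin_init(cfg$embed_dim, cfg$num_classes))
    p
  })
  structure(list(cfg = cfg, params = params,
                 hash = config_hash(unclass(cfg))), class = "vss_model")
}

#' Patch embedding
#'
#' Splits the image into non-overlapping `patch_size` squares and linearly
#' projects each to `C` channels, giving an `(H/p) x (W/p) x C` map.
#'
#' @param image `H x W x 3` array; `H`, `W` divisible by `patch_size`.
#' @param params Embedding parameters (`model$params$embed`), a linear
#'   layer `(p^2*3) -> C`.
#' @param patch_size Patch side.
#' @export
patch_embed <- function(image, params, patch_size = 4L) {
  d <- dim(image)
  p <- patch_size
  if (d[1] %% p || d[2] %% p)
    stopf("image %dx%d not divisible by patch size %d", d[1], d[2], p)
  X <- array(image, c(p, d[1] %/% p, p, d[2] %/% p, d[3]))
  X <- aperm(X, c(2, 4, 1, 3, 5))
  dim(X) <- c(d[1] %/% p, d[2] %/% p, p * p * d[3])
  lin_fwd(X, params)$y
}

patch_embed_fwd <- function(image, params, p) {
  d <- dim(image)
  X <- array(image, c(p, d[1] %/% p, p, d[2] %/% p, d[3]))
  X <- aperm(X, c(2, 4, 1, 3, 5))
  dim(X) <- c(d[1] %/% p, d[2] %/% p, p * p * d[3])
  o <- lin_fwd(X, params)
  list(y = o$y, cache = o$cache)
}

# pixel shuffle: (h, w, p^2*C) -> (h*p, w*p, C); feature index order (a,b,c)
pixel_shuffle <- function(x, p) {
  d <- dim(x)
  C <- d[3] %/% (p * p)
  X <- array(x, c(d[1], d[2], p, p, C))
  X <- aperm(X, c(3, 1, 4, 2, 5))
  dim(X) <- c(d[1] * p, d[2] * p, C)
  X
}

pixel_shuffle_bwd <- function(dy, p) {
  d <- dim(dy)
  h <- d[1] %/% p; w <- d[2] %/% p
  X <- array(dy, c(p, h, p, w, d[3]))
  X <- aperm(X, c(2, 4, 1, 3, 5))
  dim(X) <- c(h, w, p * p * d[3])
  X
}

maxpool2_fwd <- function(x) {
  d <- dim(x)
  X <- aperm(array(x, c(2L, d[1] %/% 2L, 2L, d[2] %/% 2L, d[3])), c(2, 4, 5, 1, 3))
  n <- (d[1] %/% 2L) * (d[2] %/% 2L) * d[3]
  dim(X) <- c(n, 4L)
  j <- max.col(X, ties.method = "first")
  y <- X[cbind(seq_len(n), j)]
  list(y = array(y, c(d[1] %/% 2L, d[2] %/% 2L, d[3])),
       cache = list(j = j, d = d))
}

maxpool2_bwd <- function(dy, cache) {
  d <- cache$d
  n <- length(dy)
  dX <- matrix(0, n, 4L)
  dX[cbind(seq_len(n), cache$j)] <- as.vector(dy)
  dim(dX) <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], 2L, 2L)
  dX <- aperm(dX, c(4, 1, 5, 2, 3))
  dim(dX) <- d
  dX
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  ri <- rep(seq_len(d[1]), each = 2L); ci <- rep(seq_len(d[2]), each = 2L)
  list(y = x[ri, ci, , drop = FALSE], cache = d)
}

upsample2_bwd <- function(dy, d) {
  X <- array(dy, c(2L, d[1], 2L, d[2], d[3]))
  colSums(aperm(X, c(1, 3, 2, 4, 5)), dims = 2L)
}

stage_fwd <- function(x, blocks, bc, use_msvss) {
  caches <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    o <- if (use_msvss) msvss_fwd(x, blocks[[i]], bc) else vss_fwd(x, blocks[[i]])
    x <- o$y; caches[[i]] <- o$cache
  }
  list(y = x, caches = caches)
}

stage_bwd <- function(dy, caches, blocks, bc, use_msvss) {
  g <- vector("list", length(blocks))
  for (i in rev(seq_along(blocks))) {
    b <- if (use_msvss) msvss_bwd(dy, caches[[i]], blocks[[i]], bc)
         else vss_bwd(dy, caches[[i]], blocks[[i]])
    dy <- b$dx; g[[i]] <- b$g
  }
  list(dx = dy, g = g)
}

model_fwd <- function(model, image) {
  cfg <- model$cfg; p <- model$params
  d <- dim(image)
  if (d[1] %% min_divisor(cfg) || d[2] %% min_divisor(cfg))
    stopf("input %dx%d must be divisible by %d", d[1], d[2], min_divisor(cfg))
  ch <- stage_channels(cfg); S <- cfg$num_stages
  bcs <- lapply(ch, function(C) stage_block_cfg(cfg, C))
  cc <- list()
  cc$embed <- patch_embed_fwd(image, p$embed, cfg$patch_size)
  x <- cc$embed$y
  enc_out <- vector("list", S)
  cc$enc <- vector("list", S); cc$down <- vector("list", S - 1L)
  for (s in seq_len(S)) {
    st <- stage_fwd(x, p$enc[[s]], bcs[[s]], cfg$use_msvss)
    cc$enc[[s]] <- st$caches
    enc_out[[s]] <- st$y
    x <- st$y
    if (s < S) {
      if (cfg$use_ipm_ipe) {
        dn <- ipm_fwd(x, p$down[[s]])
      } else {
        mp <- maxpool2_fwd(x)
        ln <- lin_fwd(mp$y, p$down[[s]]$lin)
        dn <- list(y = ln$y, cache = list(mp = mp, ln = ln))
      }
      cc$down[[s]] <- dn$cache
      x <- dn$y
    }
  }
  bt <- if (cfg$use_avss) avss_fwd(x, p$bottleneck, bcs[[S]])
        else vss_fwd(x, p$bottleneck)
  cc$bott <- bt$cache
  x <- bt$y
  cc$skip <- vector("list", S); cc$dec <- vector("list", S)
  cc$up <- vector("list", S - 1L)
  for (s in rev(seq_len(S))) {
    if (cfg$use_iaf) {
      sk <- iaf_fwd(enc_out[[s]], x, p$skip[[s]], bcs[[s]])
      cc$skip[[s]] <- sk$cache
      x <- x + sk$y
    } else {
      dcat <- dim(x)
      cat_ <- mat_fm(cbind(fm_mat(enc_out[[s]]), fm_mat(x)), dcat[1], dcat[2])
      sk <- lin_fwd(cat_, p$skip[[s]]$lin)
      cc$skip[[s]] <- sk$cache
      x <- sk$y
    }
    st <- stage_fwd(x, p$dec[[s]], bcs[[s]], cfg$use_msvss)
    cc$dec[[s]] <- st$caches
    x <- st$y
    if (s > 1L) {
      if (cfg$use_ipm_ipe) {
        up <- ipe_fwd(x, p$up[[s - 1L]])
      } else {
        us <- upsample2_fwd(x)
        ln <- lin_fwd(us$y, p$up[[s - 1L]]$lin)
        up <- list(y = ln$y, cache = list(us = us, ln = ln))
      }
      cc$up[[s - 1L]] <- up$cache
      x <- up$y
    }
  }
  ex <- lin_fwd(x, p$final$expand)
  shuf <- pixel_shuffle(ex$y, cfg$patch_size)
  fl <- ln_fwd(shuf, p$final$ln)
  hd <- lin_fwd(fl$y, p$final$head)
  cc$final <- list(ex = ex, fl = fl, hd = hd)
  list(logits = hd$y, cache = cc)
}

model_bwd <- function(model, cache, dlogits) {
  cfg <- model$cfg; p <- model$params
  ch <- stage_channels(cfg); S <- cfg$num_stages
  bcs <- lapply(ch, function(C) stage_block_cfg(cfg, C))
  g <- list()
  bh <- lin_bwd(dlogits, cache$final$hd$cache, p$final$head)
  bl <- ln_bwd(bh$dx, cache$final$fl$cache, p$final$ln)
  dex <- pixel_shuffle_bwd(bl$dx, cfg$patch_size)
  be <- lin_bwd(dex, cache$final$ex$cache, p$final$expand)
  g$final <- list(expand = be$g, ln = bl$g, head = bh$g)
  dx <- be$dx
  g$skip <- vector("list", S); g$dec <- vector("list", S)
  g$up <- vector("list", S - 1L)
  denc <- vector("list", S) # gradient flowing into each encoder output
  for (s in seq_len(S)) {
    if (s > 1L) {
      if (cfg$use_ipm_ipe) {
        b <- ipe_bwd(dx, cache$up[[s - 1L]], p$up[[s - 1L]])
        g$up[[s - 1L]] <- b$g
        dx <- b$dx
      } else {
        b <- lin_bwd(dx, cache$up[[s - 1L]]$ln$cache, p$up[[s - 1L]]$lin)
        g$up[[s - 1L]] <- list(lin = b$g)
        dx <- upsample2_bwd(b$dx, cache$up[[s - 1L]]$us$cache)
      }
    }
    sb <- stage_bwd(dx, cache$dec[[s]], p$dec[[s]], bcs[[s]], cfg$use_msvss)
    g$dec[[s]] <- sb$g
    dx <- sb$dx
    if (cfg$use_iaf) {
      b <- iaf_bwd(dx, cache$skip[[s]], p$skip[[s]])
      g$skip[[s]] <- b$g
      denc[[s]] <- b$d_en
      dx <- dx + b$d_de # decoder stream passes through the addition
    } else {
      b <- lin_bwd(dx, cache$skip[[s]], p$skip[[s]]$lin)
      g$skip[[s]] <- list(lin = b$g)
      dcat <- fm_mat(b$dx)
      C <- ch[s]
      dd <- dim(dx)
      denc[[s]] <- mat_fm(dcat[, seq_len(C), drop = FALSE], dd[1], dd[2])
      dx <- mat_fm(dcat[, C + seq_len(C), drop = FALSE], dd[1], dd[2])
    }
  }
  if (cfg$use_avss) {
    b <- avss_bwd(dx, cache$bott, p$bottleneck)
  } else {
    b <- vss_bwd(dx, cache$bott, p$bottleneck)
  }
  g$bottleneck <- b$g
  dx <- b$dx
  g$enc <- vector("list", S); g$down <- vector("list", S - 1L)
  for (s in rev(seq_len(S))) {
    if (s < S) {
      if (cfg$use_ipm_ipe) {
        b <- ipm_bwd(dx, cache$down[[s]], p$down[[s]])
        g$down[[s]] <- b$g
        dx <- b$dx
      } else {
        b <- lin_bwd(dx, cache$down[[s]]$ln$cache, p$down[[s]]$lin)
        g$down[[s]] <- list(lin = b$g)
        dx <- maxpool2_bwd(b$dx, cache$down[[s]]$mp$cache)
      }
    }
    dx <- dx + denc[[s]]
    sb <- stage_bwd(dx, cache$enc[[s]], p$enc[[s]], bcs[[s]], cfg$use_msvss)
    g$enc[[s]] <- sb$g
    dx <- sb$dx
  }
  be <- lin_bwd(dx, cache$embed$cache, p$embed)
  g$embed <- be$g
  g
}

#' Run the model on an image
#'
#' @param model A [build_model()] result.
#' @param image `H x W x 3` array with values in `[0, 1]`; spatial dims
#'   divisible by `patch_size * 2^(num_stages - 1)`.
#' @return List with `logits` (`H x W x num_classes`) and
#'   `predicted_mask` (`H x W` integer labels in `0 .. num_classes-1`).
#' @export
segment <- function(model, image) {
  check_fm(image, "image")
  out <- model_fwd(model, image)
  lm <- fm_mat(out$logits)
  pred <- max.col(lm, ties.method = "first") - 1L
  d <- dim(image)
  list(logits = out$logits,
       predicted_mask = matrix(pred, d[1], d[2]))
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the JSON-serializable configuration, its hash,
#' and the named parameter tensors. Loading verifies the stored hash;
#' a caller-supplied expected config must match unless `force = TRUE`.
#'
#' @param model A `vss_model`.
#' @param path File path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(cfg = unclass(model$cfg), hash = model$hash,
               params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expect_cfg Optional [model_config()] the checkpoint must match.
#' @param force Skip the config-hash check.
#' @export
load_checkpoint <- function(path, expect_cfg = NULL, force = FALSE) {
  if (!file.exists(path)) stopf("checkpoint not found: %s", path)
  ck <- readRDS(path)
  if (!force) {
    if (!identical(ck$hash, config_hash(ck$cfg)))
      stopf("checkpoint hash mismatch (corrupt or edited): %s", path)
    if (!is.null(expect_cfg) && !identical(config_hash(unclass(expect_cfg)), ck$hash))
      stopf("checkpoint config does not match the expected config")
  }
  structure(list(cfg = structure(ck$cfg, class = "model_config"),
                 params = ck$params, hash = ck$hash), class = "vss_model")
}
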