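# Composite building blocks of the network.
#
# Internal *_fwd/*_bwd pairs carry caches for backprop; the exported
# *_forward()/*_fuse() wrappers apply a block to a feature map and return
# only the output, which is the user-facing surface.

#' Block hyperparameters
#'
#' @param channels Channel width the block operates on.
#' @param msdc_kernels Kernel sizes of the four parallel multiscale
#'   convolution branches (odd, default 1/3/5/7).
#' @param msdc_combine How MSDC branches are combined: elementwise `"sum"`
#'   (default) or `"concat_project"` (concatenate, then 1x1 projection).
#' @param msdc_dilated If `TRUE`, branches use kernel 3 with dilations
#'   1/2/3 (plus the 1x1 branch), the dilated-convolution reading of the
#'   multiscale stage; default is the literal kernel-size set.
#' @param csa_spatial_kernel Kernel of the spatial-attention convolution
#'   (odd, default 7).
#' @param csa_mlp_reduction Hidden-layer reduction ratio of the shared
#'   channel-attention MLP (default 8, clipped so the hidden size is >= 1).
#' @param csa_spatial_padding `"zero"` (default) or `"replicate"` border
#'   handling for the spatial-attention convolution.
#' @param expansion_ratio Inner width multiplier of the VSS block
#'   (default 2).
#' @param outer_residual If `TRUE`, MSVSS adds its input to its output;
#'   the default `FALSE` is the literal composition (only the inner VSS
#'   carries a residual).
#' @param state_dim Hidden state size of the selective scan (default 16).
#' @return A `block_config` list.
#' @export
block_config <- function(channels, msdc_kernels = c(1L, 3L, 5L, 7L),
                         msdc_combine = c("sum", "concat_project"),
                         msdc_dilated = FALSE,
                         csa_spatial_kernel = 7L, csa_mlp_reduction = 8L,
                         csa_spatial_padding = c("zero", "replicate"),
                         expansion_ratio = 2, outer_residual = FALSE,
                         state_dim = 16L) {
  if (any(msdc_kernels %% 2L == 0L) || any(msdc_kernels < 1L))
    stopf("msdc_kernels must be odd and >= 1")
  if (csa_spatial_kernel %% 2L == 0L) stopf("csa_spatial_kernel must be odd")
  structure(list(
    channels = as.integer(channels),
    msdc_kernels = as.integer(msdc_kernels),
    msdc_combine = match.arg(msdc_combine),
    msdc_dilated = isTRUE(msdc_dilated),
    csa_spatial_kernel = as.integer(csa_spatial_kernel),
    csa_mlp_reduction = max(1L, as.integer(csa_mlp_reduction)),
    csa_spatial_padding = match.arg(csa_spatial_padding),
    expansion_ratio = expansion_ratio,
    outer_residual = isTRUE(outer_residual),
    state_dim = as.integer(state_dim)), class = "block_config")
}

check_channels <- function(x, cfg, what) {
  if (dim(x)[3] != cfg$channels)
    stopf("%s: input has %d channels, block expects %d", what, dim(x)[3], cfg$channels)
}

# ---- VSS -------------------------------------------------------------

vss_init <- function(cfg) {
  C <- cfg$channels
  D <- as.integer(round(cfg$expansion_ratio * C))
  list(ln1 = ln_init(C), lin1 = lin_init(C, D), dw = dwconv_init(D, 3L),
       ss = ss2d_layer_init(D, cfg$state_dim),
       ln2 = ln_init(D), lin3 = lin_init(C, D), lin2 = lin_init(D, C))
}

vss_fwd <- function(x, p) {
  l1 <- ln_fwd(x, p$ln1)
  a <- lin_fwd(l1$y, p$lin1)
  dwc <- dwconv_fwd(a$y, p$dw)
  s <- silu_fwd(dwc$y)
  sc <- ss2d_layer_fwd(s$y, p$ss)
  l2 <- ln_fwd(sc$y, p$ln2)
  vp <- lin_fwd(l1$y, p$lin3)
  vls <- silu_fwd(vp$y)
  gm <- l2$y * vls$y
  o <- lin_fwd(gm, p$lin2)
  list(y = o$y + x,
       cache = list(l1 = l1, a = a, dwc = dwc, s = s, sc = sc, l2 = l2,
                    vp = vp, vls = vls, l2y = l2$y, vlsy = vls$y, o = o))
}

vss_bwd <- function(dy, cache, p) {
  bo <- lin_bwd(dy, cache$o$cache, p$lin2)
  dgm <- bo$dx
  dl2 <- dgm * cache$vlsy
  dvls <- dgm * cache$l2y
  dvp <- silu_bwd(dvls, cache$vls$cache)
  b3 <- lin_bwd(dvp, cache$vp$cache, p$lin3)
  bl2 <- ln_bwd(dl2, cache$l2$cache, p$ln2)
  bss <- ss2d_layer_bwd(bl2$dx, cache$sc$cache, p$ss)
  ds <- silu_bwd(bss$dx, cache$s$cache)
  bdw <- dwconv_bwd(ds, cache$dwc$cache, p$dw)
  b1 <- lin_bwd(bdw$dx, cache$a$cache, p$lin1)
  bl1 <- ln_bwd(b1$dx + b3$dx, cache$l1$cache, p$ln1)
  list(dx = bl1$dx + dy,
       g = list(ln1 = bl1$g, lin1 = b1$g, dw = bdw$g, ss = bss$g,
                ln2 = bl2$g, lin3 = b3$g, lin2 = bo$g))
}

# ---- MSDC ------------------------------------------------------------

msdc_geometry <- function(cfg) {
  if (cfg$msdc_dilated)
    list(k = c(1L, 3L, 3L, 3L), dil = c(1L, 1L, 2L, 3L))
  else
    list(k = cfg$msdc_kernels, dil = rep(1L, length(cfg$msdc_kernels)))
}

msdc_init <- function(cfg) {
  C <- cfg$channels
  geo <- msdc_geometry(cfg)
  br <- lapply(geo$k, function(k) conv2d_init(C, C, k))
  p <- list(branches = br)
  if (cfg$msdc_combine == "concat_project")
    p$proj <- lin_init(length(geo$k) * C, C)
  p
}

msdc_fwd <- function(x, p, cfg) {
  geo <- msdc_geometry(cfg)
  outs <- vector("list", length(geo$k))
  for (i in seq_along(geo$k))
    outs[[i]] <- conv2d_fwd(x, p$branches[[i]], dilation = geo$dil[i])
  if (cfg$msdc_combine == "sum") {
    y <- Reduce(`+`, lapply(outs, `[[`, "y"))
    list(y = y, cache = list(outs = outs))
  } else {
    d <- dim(x)
    cat_ <- do.call(cbind, lapply(outs, function(o) fm_mat(o$y)))
    pr <- lin_fwd(mat_fm(cat_, d[1], d[2]), p$proj)
    list(y = pr$y, cache = list(outs = outs, pr = pr, d = d))
  }
}

msdc_bwd <- function(dy, cache, p, cfg) {
  geo <- msdc_geometry(cfg)
  nb <- length(geo$k)
  g <- list(branches = vector("list", nb))
  if (cfg$msdc_combine == "sum") {
    dys <- rep(list(dy), nb)
  } else {
    bp <- lin_bwd(dy, cache$pr$cache, p$proj)
    g$proj <- bp$g
    C <- dim(dy)[3] # proj restores cfg$channels
    dcat <- fm_mat(bp$dx)
    Cb <- ncol(dcat) / nb
    d <- cache$d
    dys <- lapply(seq_len(nb), function(i)
      mat_fm(dcat[, (i - 1) * Cb + seq_len(Cb), drop = FALSE], d[1], d[2]))
  }
  dx <- 0
  for (i in seq_len(nb)) {
    bb <- conv2d_bwd(dys[[i]], cache$outs[[i]]$cache, p$branches[[i]])
    dx <- dx + bb$dx
    g$branches[[i]] <- bb$g
  }
  list(dx = dx, g = g)
}

# ---- MSVSS -----------------------------------------------------------

msvss_init <- function(cfg) {
  C <- cfg$channels
  list(vss = vss_init(cfg), ln3 = ln_init(C), msdc = msdc_init(cfg),
       lin4 = lin_init(C, C))
}

msvss_fwd <- function(x, p, cfg) {
  v <- vss_fwd(x, p$vss)
  l3 <- ln_fwd(v$y, p$ln3)
  m <- msdc_fwd(l3$y, p$msdc, cfg)
  o <- lin_fwd(m$y, p$lin4)
  y <- if (cfg$outer_residual) o$y + x else o$y
  list(y = y, cache = list(v = v, l3 = l3, m = m, o = o))
}

msvss_bwd <- function(dy, cache, p, cfg) {
  bo <- lin_bwd(dy, cache$o$cache, p$lin4)
  bm <- msdc_bwd(bo$dx, cache$m$cache, p$msdc, cfg)
  bl3 <- ln_bwd(bm$dx, cache$l3$cache, p$ln3)
  bv <- vss_bwd(bl3$dx, cache$v$cache, p$vss)
  dx <- if (cfg$outer_residual) bv$dx + dy else bv$dx
  list(dx = dx, g = list(vss = bv$g, ln3 = bl3$g, msdc = bm$g, lin4 = bo$g))
}

# ---- CSA: channel attention then spatial attention -------------------

chan_attn_init <- function(cfg) {
  C <- cfg$channels
  Cr <- max(1L, C %/% cfg$csa_mlp_reduction)
  list(W1 = init_mat(C, Cr), b1 = numeric(Cr), W2 = init_mat(Cr, C), b2 = numeric(C))
}

mlp2 <- function(v, p) {
  h_pre <- as.vector(v %*% p$W1) + p$b1
  h <- pmax(h_pre, 0)
  list(o = as.vector(h %*% p$W2) + p$b2, h = h, h_pre = h_pre)
}

mlp2_bwd <- function(do, v, fw, p) {
  dW2 <- outer(fw$h, do); db2 <- do
  dh <- as.vector(p$W2 %*% do) * (fw$h_pre > 0)
  list(dv = as.vector(p$W1 %*% dh),
       g = list(W1 = outer(as.vector(v), dh), b1 = dh, W2 = dW2, b2 = db2))
}

chan_attn_fwd <- function(x, p) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- fm_mat(x)
  avg <- colMeans(xm)
  amax <- apply(xm, 2, which.max)
  mx <- xm[cbind(amax, seq_len(d[3]))]
  fa <- mlp2(avg, p); fm <- mlp2(mx, p)
  pre <- fa$o + fm$o
  gate <- sigmoid_(pre)
  y <- sweep(x, 3, gate, "*")
  list(y = y, cache = list(xm = xm, d = d, avg = avg, mx = mx, amax = amax,
                           fa = fa, fmx = fm, gate = gate))
}

chan_attn_bwd <- function(dy, cache, p) {
  d <- cache$d; n <- d[1] * d[2]
  dym <- fm_mat(dy)
  dgate <- colSums(dym * cache$xm)
  dpre <- dgate * cache$gate * (1 - cache$gate)
  ba <- mlp2_bwd(dpre, cache$avg, cache$fa, p)
  bm <- mlp2_bwd(dpre, cache$mx, cache$fmx, p)
  dxm <- sweep(dym, 2, cache$gate, "*")
  dxm <- dxm + matrix(ba$dv / n, n, d[3], byrow = TRUE)
  dxm[cbind(cache$amax, seq_len(d[3]))] <-
    dxm[cbind(cache$amax, seq_len(d[3]))] + bm$dv
  list(dx = mat_fm(dxm, d[1], d[2]), g = tree_map2(ba$g, bm$g, `+`))
}

spat_attn_init <- function(cfg) {
  list(conv = conv2d_init(2L, 1L, cfg$csa_spatial_kernel))
}

spat_attn_fwd <- function(x, p, cfg) {
  d <- dim(x)
  xm <- fm_mat(x)
  pm <- rowMeans(xm)
  amax <- max.col(xm, ties.method = "first")
  px <- xm[cbind(seq_len(nrow(xm)), amax)]
  maps <- mat_fm(cbind(pm, px), d[1], d[2])
  cv <- conv2d_fwd(maps, p$conv, padding = cfg$csa_spatial_padding)
  gate <- sigmoid_(as.vector(cv$y))
  y <- x * gate # recycles the H*W gate over channels
  list(y = y, cache = list(xm = xm, d = d, amax = amax, cv = cv, gate = gate))
}

spat_attn_bwd <- function(dy, cache, p) {
  d <- cache$d
  dym <- fm_mat(dy)
  dgate <- rowSums(dym * cache$xm)
  dpre <- dgate * cache$gate * (1 - cache$gate)
  bc <- conv2d_bwd(mat_fm(matrix(dpre), d[1], d[2]), cache$cv$cache, p$conv)
  dmaps <- fm_mat(bc$dx)
  dxm <- dym * cache$gate
  dxm <- dxm + dmaps[, 1] / d[3]
  dxm[cbind(seq_len(nrow(dxm)), cache$amax)] <-
    dxm[cbind(seq_len(nrow(dxm)), cache$amax)] + dmaps[, 2]
  list(dx = mat_fm(dxm, d[1], d[2]), g = list(conv = bc$g))
}

csa_init <- function(cfg) list(ch = chan_attn_init(cfg), sp = spat_attn_init(cfg))

csa_fwd <- function(x, p, cfg) {
  a <- chan_attn_fwd(x, p$ch)
  b <- spat_attn_fwd(a$y, p$sp, cfg)
  list(y = b$y, cache = list(a = a, b = b))
}

csa_bwd <- function(dy, cache, p) {
  bb <- spat_attn_bwd(dy, cache$b$cache, p$sp)
  ba <- chan_attn_bwd(bb$dx, cache$a$cache, p$ch)
  list(dx = ba$dx, g = list(ch = ba$g, sp = bb$g))
}

# ---- IAF: attention-gated skip fusion --------------------------------

iaf_init <- function(cfg) {
  C <- cfg$channels
  list(csa_en = csa_init(cfg), csa_de = csa_init(cfg),
       proj_en = conv2d_init(C, C, 1L), proj_de = conv2d_init(C, C, 1L),
       gate = conv2d_init(C, 1L, 1L))
}

iaf_fwd <- function(f_en, f_de, p, cfg) {
  if (!identical(dim(f_en), dim(f_de)))
    stopf("iaf: encoder %s and decoder %s shapes differ",
          paste(dim(f_en), collapse = "x"), paste(dim(f_de), collapse = "x"))
  ce <- csa_fwd(f_en, p$csa_en, cfg)
  cd <- csa_fwd(f_de, p$csa_de, cfg)
  pe <- conv2d_fwd(ce$y, p$proj_en)
  pd <- conv2d_fwd(cd$y, p$proj_de)
  s <- relu_fwd(pe$y + pd$y)
  gp <- conv2d_fwd(s$y, p$gate)
  gate <- sigmoid_(as.vector(gp$y))
  y <- f_en * gate
  list(y = y, cache = list(ce = ce, cd = cd, pe = pe, pd = pd, s = s,
                           gp = gp, gate = gate, f_en = f_en))
}

iaf_bwd <- function(dy, cache, p) {
  d <- dim(dy)
  dym <- fm_mat(dy)
  dgate <- rowSums(dym * fm_mat(cache$f_en))
  dpre <- dgate * cache$gate * (1 - cache$gate)
  bg <- conv2d_bwd(mat_fm(matrix(dpre), d[1], d[2]), cache$gp$cache, p$gate)
  dsum <- relu_bwd(bg$dx, cache$s$cache)
  bpe <- conv2d_bwd(dsum, cache$pe$cache, p$proj_en)
  bpd <- conv2d_bwd(dsum, cache$pd$cache, p$proj_de)
  bce <- csa_bwd(bpe$dx, cache$ce$cache, p$csa_en)
  bcd <- csa_bwd(bpd$dx, cache$cd$cache, p$csa_de)
  den <- bce$dx + dy * cache$gate
  list(d_en = den, d_de = bcd$dx,
       g = list(csa_en = bce$g, csa_de = bcd$g, proj_en = bpe$g,
                proj_de = bpd$g, gate = bg$g))
}

# ---- AVSS bottleneck -------------------------------------------------

avss_init <- function(cfg) {
  C <- cfg$channels
  list(vss = vss_init(cfg), ln = ln_init(C), conv = conv2d_init(C, C, 3L))
}

avss_fwd <- function(x, p, cfg) {
  v <- vss_fwd(x, p$vss)
  l <- ln_fwd(v$y, p$ln)
  f <- conv2d_fwd(l$y, p$conv)
  fmm <- fm_mat(f$y)
  pm <- rowMeans(fmm)
  amax <- max.col(fmm, ties.method = "first")
  px <- fmm[cbind(seq_len(nrow(fmm)), amax)]
  gate <- sigmoid_(pm + px)
  y <- f$y * gate + v$y
  list(y = y, cache = list(v = v, l = l, f = f, fmm = fmm, amax = amax,
                           gate = gate))
}

avss_bwd <- function(dy, cache, p) {
  d <- dim(dy)
  dym <- fm_mat(dy)
  dgate <- rowSums(dym * cache$fmm)
  dpre <- dgate * cache$gate * (1 - cache$gate)
  dfm <- dym * cache$gate
  dfm <- dfm + dpre / d[3]
  dfm[cbind(seq_len(nrow(dfm)), cache$amax)] <-
    dfm[cbind(seq_len(nrow(dfm)), cache$amax)] + dpre
  bf <- conv2d_bwd(mat_fm(dfm, d[1], d[2]), cache$f$cache, p$conv)
  bl <- ln_bwd(bf$dx, cache$l$cache, p$ln)
  bv <- vss_bwd(bl$dx + dy, cache$v$cache, p$vss)
  list(dx = bv$dx, g = list(vss = bv$g, ln = bl$g, conv = bf$g))
}

# ---- IPM / IPE -------------------------------------------------------

ipm_init <- function(cin) {
  cout <- 2L * cin
  list(conv_a = conv2d_init(cin, cout, 1L), dw = dwconv_init(cout, 3L),
       pw = conv2d_init(cout, cout, 1L), conv_b = conv2d_init(cout, cout, 1L))
}

ipm_fwd <- function(x, p) {
  d <- dim(x)
  if (d[1] %% 2L || d[2] %% 2L)
    stopf("ipm: spatial dims (%dx%d) must be even", d[1], d[2])
  a <- conv2d_fwd(x, p$conv_a)
  dw <- dwconv_fwd(a$y, p$dw, stride = 2L)
  pw <- conv2d_fwd(dw$y, p$pw)
  b <- conv2d_fwd(pw$y, p$conv_b)
  list(y = b$y, cache = list(a = a, dw = dw, pw = pw, b = b))
}

ipm_bwd <- function(dy, cache, p) {
  bb <- conv2d_bwd(dy, cache$b$cache, p$conv_b)
  bpw <- conv2d_bwd(bb$dx, cache$pw$cache, p$pw)
  bdw <- dwconv_bwd(bpw$dx, cache$dw$cache, p$dw)
  ba <- conv2d_bwd(bdw$dx, cache$a$cache, p$conv_a)
  list(dx = ba$dx,
       g = list(conv_a = ba$g, dw = bdw$g, pw = bpw$g, conv_b = bb$g))
}

ipe_init <- function(cin) {
  cout <- cin %/% 2L
  list(conv_a = conv2d_init(cin, cout, 1L), tconv = tconv_init(cout, cout),
       conv_b = conv2d_init(cout, cout, 1L), ln = ln_init(cout))
}

ipe_fwd <- function(x, p) {
  d <- dim(x)
  if (d[3] %% 2L) stopf("ipe: channel count (%d) must be even", d[3])
  a <- conv2d_fwd(x, p$conv_a)
  tc <- tconv_fwd(a$y, p$tconv)
  b <- conv2d_fwd(tc$y, p$conv_b)
  l <- ln_fwd(b$y, p$ln)
  list(y = l$y, cache = list(a = a, tc = tc, b = b, l = l))
}

ipe_bwd <- function(dy, cache, p) {
  bl <- ln_bwd(dy, cache$l$cache, p$ln)
  bb <- conv2d_bwd(bl$dx, cache$b$cache, p$conv_b)
  btc <- tconv_bwd(bb$dx, cache$tc$cache, p$tconv)
  ba <- conv2d_bwd(btc$dx, cache$a$cache, p$conv_a)
  list(dx = ba$dx,
       g = list(conv_a = ba$g, tconv = btc$g, conv_b = bb$g, ln = bl$g))
}

# ---- exported user-facing wrappers -----------------------------------

#' Initialize a block's parameters
#'
#' `init_vss()`, `init_msvss()`, `init_msdc()`, `init_csa()`, `init_iaf()`
#' and `init_avss()` draw a block's weights (truncated normal, sd 0.02)
#' under `seed`; `init_ipm()`/`init_ipe()` take the input channel count
#' directly since they change the channel width.
#'
#' @param cfg A [block_config()].
#' @param seed Integer seed.
#' @return A parameter tree consumed by the matching forward function.
#' @export
init_vss <- function(cfg, seed = 0L) local_seed(seed, vss_init(cfg))

#' @rdname init_vss
#' @export
init_msvss <- function(cfg, seed = 0L) local_seed(seed, msvss_init(cfg))

#' @rdname init_vss
#' @export
init_msdc <- function(cfg, seed = 0L) local_seed(seed, msdc_init(cfg))

#' @rdname init_vss
#' @export
init_csa <- function(cfg, seed = 0L) local_seed(seed, csa_init(cfg))

#' @rdname init_vss
#' @export
init_iaf <- function(cfg, seed = 0L) local_seed(seed, iaf_init(cfg))

#' @rdname init_vss
#' @export
init_avss <- function(cfg, seed = 0L) local_seed(seed, avss_init(cfg))

#' @rdname init_vss
#' @param cin Input channel count.
#' @export
init_ipm <- function(cin, seed = 0L) local_seed(seed, ipm_init(as.integer(cin)))

#' @rdname init_vss
#' @export
init_ipe <- function(cin, seed = 0L) local_seed(seed, ipe_init(as.integer(cin)))

#' Apply a block to a feature map
#'
#' Shape-preserving residual VSS block: layer norm, linear expansion,
#' depthwise 3x3 convolution, SiLU, four-direction selective scan (SS2D),
#' layer norm, multiplication with the SiLU-gated side path, linear
#' contraction, plus the input.
#'
#' @param x An `H x W x C` feature map (`C = cfg$channels`).
#' @param params Parameters from the matching `init_*` function.
#' @param cfg The [block_config()] used at initialization.
#' @return Feature map; shape-preserving except [ipm_forward()]
#'   (spatial / 2, channels x 2) and [ipe_forward()] (spatial x 2,
#'   channels / 2).
#' @export
vss_forward <- function(x, params, cfg) {
  check_fm(x); check_channels(x, cfg, "vss")
  vss_fwd(x, params)$y
}

#' @rdname vss_forward
#' @export
msvss_forward <- function(x, params, cfg) {
  check_fm(x); check_channels(x, cfg, "msvss")
  msvss_fwd(x, params, cfg)$y
}

#' @rdname vss_forward
#' @export
msdc_forward <- function(x, params, cfg) {
  check_fm(x)
  msdc_fwd(x, params, cfg)$y
}

#' @rdname vss_forward
#' @export
channel_attention <- function(x, params, cfg) {
  check_fm(x)
  chan_attn_fwd(x, params$ch %||% params)$y
}

#' @rdname vss_forward
#' @export
spatial_attention <- function(x, params, cfg) {
  check_fm(x)
  spat_attn_fwd(x, params$sp %||% params, cfg)$y
}

#' @rdname vss_forward
#' @export
csa_forward <- function(x, params, cfg) {
  check_fm(x)
  csa_fwd(x, params, cfg)$y
}

#' Attention-gated skip fusion
#'
#' Gates the encoder features by a sigmoid attention map computed from the
#' channel-spatial-attended, 1x1-projected encoder and decoder features;
#' returns the gated encoder features (fusion into the decoder stream is
#' elementwise addition, done by the network assembly).
#'
#' @param f_en,f_de Encoder / decoder feature maps of identical shape.
#' @inheritParams vss_forward
#' @return Gated encoder feature map, same shape as `f_en`.
#' @export
iaf_fuse <- function(f_en, f_de, params, cfg) {
  check_fm(f_en); check_fm(f_de)
  iaf_fwd(f_en, f_de, params, cfg)$y
}

#' @rdname vss_forward
#' @export
avss_forward <- function(x, params, cfg) {
  check_fm(x); check_channels(x, cfg, "avss")
  avss_fwd(x, params, cfg)$y
}

#' @rdname vss_forward
#' @export
ipm_forward <- function(x, params) {
  check_fm(x)
  ipm_fwd(x, params)$y
}

#' @rdname vss_forward
#' @export
ipe_forward <- function(x, params) {
  check_fm(x)
  ipe_fwd(x, params)$y
}
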