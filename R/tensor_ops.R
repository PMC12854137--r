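# Low-level differentiable ops on H x W x C arrays.
#
# Every layer comes as a forward returning list(y, cache) and a backward
# taking (dy, cache) and returning list(dx = ..., g = <grads matching params>).
# Convolutions are im2col gathers (index matrices cached per geometry)
# followed by one BLAS matmul, which keeps the training loop CPU-feasible.

.geom_cache <- new.env(parent = emptyenv())

# Gather-index matrix: rows = output positions (column-major over H x W),
# cols = kernel taps; entries index into the zero-padded (Hp x Wp) plane.
conv_index <- function(H, W, k, dilation = 1L) {
  key <- paste(H, W, k, dilation, sep = "_")
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  pad <- (k - 1L) %/% 2L * dilation
  Hp <- H + 2L * pad
  off <- (seq_len(k) - 1L - (k - 1L) %/% 2L) * dilation
  rows <- rep(seq_len(H), times = W)
  cols <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, k * k)
  t <- 1L
  for (dc in off) for (dr in off) {   # column-major tap order: dr fastest
    idx[, t] <- (cols + dc + pad - 1L) * Hp + (rows + dr + pad)
    t <- t + 1L
  }
  out <- list(idx = idx, pad = pad, Hp = Hp, Wp = W + 2L * pad)
  .geom_cache[[key]] <- out
  out
}

pad_zero <- function(x, pad) {
  d <- dim(x)
  if (pad == 0L) return(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

unpad <- function(xp, pad, H, W) {
  if (pad == 0L) return(xp)
  xp[pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
}

# Fold gradients that fell on replicate-padding cells back onto edge cells.
fold_replicate <- function(dxp, pad, H, W) {
  if (pad > 0L) {
    for (i in seq_len(pad)) { # rows
      dxp[pad + 1L, , ] <- dxp[pad + 1L, , ] + dxp[i, , ]
      dxp[pad + H, , ] <- dxp[pad + H, , ] + dxp[pad + H + i, , ]
    }
    for (j in seq_len(pad)) { # cols
      dxp[, pad + 1L, ] <- dxp[, pad + 1L, ] + dxp[, j, ]
      dxp[, pad + W, ] <- dxp[, pad + W, ] + dxp[, pad + W + j, ]
    }
  }
  dxp[pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
}

pad_replicate <- function(x, pad) {
  d <- dim(x)
  if (pad == 0L) return(x)
  ri <- c(rep(1L, pad), seq_len(d[1]), rep(d[1], pad))
  ci <- c(rep(1L, pad), seq_len(d[2]), rep(d[2], pad))
  x[ri, ci, , drop = FALSE]
}

im2col <- function(x, k, dilation = 1L, padding = c("zero", "replicate")) {
  padding <- match.arg(padding)
  d <- dim(x)
  if (k == 1L) # 1x1 convolution: gather is the identity
    return(list(P = fm_mat(x), g = NULL, H = d[1], W = d[2], C = d[3],
                padding = padding, one = TRUE))
  g <- conv_index(d[1], d[2], k, dilation)
  xp <- if (padding == "zero") pad_zero(x, g$pad) else pad_replicate(x, g$pad)
  # channel-expanded gather index, cached per geometry + channel count
  ckey <- paste("cx", d[1], d[2], k, dilation, d[3], sep = "_")
  full <- .geom_cache[[ckey]]
  if (is.null(full)) {
    plane <- g$Hp * g$Wp
    full <- rep(as.vector(g$idx), times = d[3]) +
      rep((seq_len(d[3]) - 1L) * plane, each = length(g$idx))
    .geom_cache[[ckey]] <- full
  }
  M <- xp[full]
  dim(M) <- c(d[1] * d[2], k * k * d[3])         # taps fastest, then channel
  list(P = M, g = g, H = d[1], W = d[2], C = d[3], padding = padding)
}

col2im <- function(dP, meta) {
  g <- meta$g; k2 <- ncol(g$idx)
  dXp <- matrix(0, g$Hp * g$Wp, meta$C)
  dim(dP) <- c(meta$H * meta$W, k2, meta$C)
  for (o in seq_len(k2)) {
    rows <- g$idx[, o]
    dXp[rows, ] <- dXp[rows, ] + dP[, o, ]
  }
  dXp <- array(dXp, c(g$Hp, g$Wp, meta$C))
  if (meta$padding == "zero") unpad(dXp, g$pad, meta$H, meta$W)
  else fold_replicate(dXp, g$pad, meta$H, meta$W)
}

#' @keywords internal
conv2d_init <- function(cin, cout, k, sd = 0.02) {
  list(W = init_mat(k * k * cin, cout, sd), b = numeric(cout), k = k)
}

add_bias <- function(y, b) y + rep(b, each = nrow(y))

conv2d_fwd <- function(x, p, dilation = 1L, padding = "zero") {
  ic <- im2col(x, p$k, dilation, padding)
  y <- add_bias(ic$P %*% p$W, p$b)
  list(y = mat_fm(y, ic$H, ic$W), cache = list(ic = ic, dilation = dilation))
}

# stride-1 'same' input gradient = convolution of dy with the tap-flipped,
# in/out-transposed kernel; only valid for zero padding (replicate borders
# fall back to the explicit scatter).
flip_kernel <- function(W, k, cin, cout) {
  dim(W) <- c(k * k, cin, cout)
  W <- W[rev(seq_len(k * k)), , , drop = FALSE]
  W <- aperm(W, c(1, 3, 2))
  dim(W) <- c(k * k * cout, cin)
  W
}

conv2d_bwd <- function(dy, cache, p) {
  ic <- cache$ic
  dym <- fm_mat(dy)
  g <- list(W = crossprod(ic$P, dym), b = colSums(dym), k = 0)
  if (ic$padding == "zero") {
    cout <- ncol(p$W); cin <- ic$C
    icb <- im2col(dy, p$k, cache$dilation)
    dx <- mat_fm(icb$P %*% flip_kernel(p$W, p$k, cin, cout), ic$H, ic$W)
  } else {
    dP <- dym %*% t(p$W)
    dx <- col2im(dP, ic)
  }
  list(dx = dx, g = g)
}

# Depthwise conv (one k x k filter per channel), stride 1 or 2, zero padding.
dwconv_init <- function(c, k, sd = 0.02) {
  list(W = matrix(trunc_normal(k * k * c, sd), k * k, c), b = numeric(c), k = k)
}

dwconv_fwd <- function(x, p, stride = 1L) {
  d <- dim(x)
  ic <- im2col(x, p$k)
  k2 <- p$k * p$k
  M <- ic$P; dim(M) <- c(d[1] * d[2], k2, d[3])
  y <- matrix(0, d[1] * d[2], d[3])
  for (o in seq_len(k2)) y <- y + M[, o, ] * rep(p$W[o, ], each = d[1] * d[2])
  y <- add_bias(y, p$b)
  y <- mat_fm(y, d[1], d[2])
  keep <- NULL
  if (stride == 2L) {
    ri <- seq(1L, d[1], by = 2L); ci <- seq(1L, d[2], by = 2L)
    y <- y[ri, ci, , drop = FALSE]
    keep <- list(ri = ri, ci = ci)
  }
  list(y = y, cache = list(ic = ic, M = M, d = d, keep = keep, stride = stride))
}

dwconv_bwd <- function(dy, cache, p) {
  d <- cache$d; k2 <- p$k * p$k
  if (cache$stride == 2L) {
    full <- array(0, c(d[1], d[2], d[3]))
    full[cache$keep$ri, cache$keep$ci, ] <- dy
    dy <- full
  }
  dym <- fm_mat(dy)
  dW <- matrix(0, k2, d[3])
  for (o in seq_len(k2)) dW[o, ] <- colSums(cache$M[, o, ] * dym)
  # input gradient: depthwise conv of dy with tap-flipped weights
  icb <- im2col(mat_fm(dym, d[1], d[2]), p$k)
  M2 <- icb$P; dim(M2) <- c(d[1] * d[2], k2, d[3])
  Wf <- p$W[rev(seq_len(k2)), , drop = FALSE]
  dx <- matrix(0, d[1] * d[2], d[3])
  for (o in seq_len(k2)) dx <- dx + M2[, o, ] * rep(Wf[o, ], each = d[1] * d[2])
  list(dx = mat_fm(dx, d[1], d[2]), g = list(W = dW, b = colSums(dym), k = 0))
}

# Transposed 3x3 conv, stride 2: zero-stuff to 2H x 2W then ordinary conv.
tconv_init <- function(cin, cout, sd = 0.02) conv2d_init(cin, cout, 3L, sd)

tconv_fwd <- function(x, p) {
  d <- dim(x)
  up <- array(0, c(2L * d[1], 2L * d[2], d[3]))
  ri <- seq(1L, 2L * d[1], by = 2L); ci <- seq(1L, 2L * d[2], by = 2L)
  up[ri, ci, ] <- x
  out <- conv2d_fwd(up, p)
  list(y = out$y, cache = list(conv = out$cache, ri = ri, ci = ci))
}

tconv_bwd <- function(dy, cache, p) {
  b <- conv2d_bwd(dy, cache$conv, p)
  list(dx = b$dx[cache$ri, cache$ci, , drop = FALSE], g = b$g)
}

# Per-position layer norm over channels.
ln_init <- function(c) list(gamma = rep(1, c), beta = numeric(c))

ln_fwd <- function(x, p, eps = 1e-5) {
  d <- dim(x); xm <- fm_mat(x)
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- add_bias(xhat * rep(p$gamma, each = nrow(xm)), p$beta)
  list(y = mat_fm(y, d[1], d[2]),
       cache = list(xhat = xhat, inv = inv, d = d))
}

ln_bwd <- function(dy, cache, p) {
  d <- cache$d; C <- d[3]
  dym <- fm_mat(dy)
  dxhat <- dym * rep(p$gamma, each = nrow(dym))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dx = mat_fm(dx, d[1], d[2]),
       g = list(gamma = colSums(dym * cache$xhat), beta = colSums(dym)))
}

lin_init <- function(nin, nout, sd = 0.02) list(W = init_mat(nin, nout, sd), b = numeric(nout))

lin_fwd <- function(x, p) {
  d <- dim(x); xm <- fm_mat(x)
  y <- add_bias(xm %*% p$W, p$b)
  list(y = mat_fm(y, d[1], d[2]), cache = list(xm = xm, d = d))
}

lin_bwd <- function(dy, cache, p) {
  dym <- fm_mat(dy)
  list(dx = mat_fm(dym %*% t(p$W), cache$d[1], cache$d[2]),
       g = list(W = crossprod(cache$xm, dym), b = colSums(dym)))
}

silu_fwd <- function(x) list(y = silu_(x), cache = x)
silu_bwd <- function(dy, cache) dy * silu_grad_(cache)
relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dy, cache) dy * cache
sigmoid_fwd <- function(x) { s <- sigmoid_(x); list(y = s, cache = s) }
sigmoid_bwd <- function(dy, cache) dy * cache * (1 - cache)

# Recursive parameter-tree arithmetic (params and grads share structure).
# Lists may be named or positional; fields named "k" or "shared" are
# structural (kernel sizes, layout flags), never trained or flattened.
tree_idx <- function(a) {
  nms <- names(a)
  if (is.null(nms)) seq_along(a) else which(!nms %in% c("k", "shared"))
}

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    named <- !is.null(names(a))
    for (i in tree_idx(a)) {
      j <- if (named) names(a)[i] else i
      a[[i]] <- tree_map2(a[[i]], b[[j]], f)
    }
    a
  } else f(a, b)
}

tree_map <- function(a, f) {
  if (is.list(a)) {
    for (i in tree_idx(a)) a[[i]] <- tree_map(a[[i]], f)
    a
  } else f(a)
}

tree_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a[tree_idx(a)], tree_flatten), use.names = FALSE)
  else as.numeric(a)
}
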