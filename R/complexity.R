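# Analytic multiply-accumulate accounting for the forward pass, used to
# verify the linear O(n)-in-pixels cost claim, with a quadratic
# self-attention reference for contrast.

macs_vss <- function(n, C, N, ratio = 2) {
  D <- round(ratio * C)
  ln <- function(nn, cc) 4 * nn * cc
  ss2d <- 4 * (n * D * D + 2 * n * D * N + 4 * n * D * N) # dt/B/C proj + scan
  ln(n, C) + n * C * D + 9 * n * D + 2 * n * D + ss2d + ln(n, D) +
    n * C * D + 2 * n * D + n * D + n * D * C
}

macs_msdc <- function(n, C, kernels = c(1, 3, 5, 7)) sum(n * C * C * kernels^2)

macs_msvss <- function(n, C, N) {
  macs_vss(n, C, N) + 4 * n * C + macs_msdc(n, C) + n * C * C
}

macs_csa <- function(n, C, red = 8, ksp = 7) {
  Cr <- max(1, C %/% red)
  2 * 2 * (C * Cr) + n * 2 * ksp^2 + 2 * n * C
}

macs_iaf <- function(n, C) 2 * macs_csa(n, C) + 2 * n * C * C + n * C + n * C

macs_avss <- function(n, C, N) macs_vss(n, C, N) + 4 * n * C + 9 * n * C * C + 2 * n * C

macs_ipm <- function(n, C) n * C * 2 * C + (n / 4) * (9 * 2 * C + 2 * C * 2 * C + 2 * C * 2 * C)

macs_ipe <- function(n, C) {
  Co <- C / 2
  n * C * Co + 4 * n * 9 * Co * Co + 4 * n * Co * Co + 4 * n * 4 * Co
}

#' Analytic operation count of one forward pass
#'
#' Multiply-accumulate count of every layer as a function of the input
#' size, evaluated without running the network.
#'
#' @param cfg A [model_config()].
#' @param H,W Input image size.
#' @return Total MAC count (double).
#' @export
count_macs <- function(cfg, H, W) {
  p <- cfg$patch_size; S <- cfg$num_stages
  ch <- stage_channels(cfg); N <- cfg$state_dim
  n1 <- (H / p) * (W / p)
  total <- n1 * p^2 * 3 * cfg$embed_dim
  blk <- function(n, C) if (cfg$use_msvss) macs_msvss(n, C, N) else macs_vss(n, C, N)
  for (s in seq_len(S)) {
    n_s <- n1 / 4^(s - 1)
    total <- total + 2 * cfg$stage_depth * blk(n_s, ch[s]) # enc + dec stages
    total <- total + if (cfg$use_iaf) macs_iaf(n_s, ch[s]) else n_s * 2 * ch[s] * ch[s]
    if (s < S) {
      total <- total + if (cfg$use_ipm_ipe) macs_ipm(n_s, ch[s]) else n_s * ch[s] * 2 * ch[s]
      total <- total + if (cfg$use_ipm_ipe) macs_ipe(n_s / 4, ch[s + 1]) else
        n_s * ch[s + 1] * ch[s + 1] / 2
    }
  }
  nS <- n1 / 4^(S - 1)
  total <- total + if (cfg$use_avss) macs_avss(nS, ch[S], N) else macs_vss(nS, ch[S], N)
  total + n1 * cfg$embed_dim * p^2 * cfg$embed_dim +
    H * W * 4 * cfg$embed_dim + H * W * cfg$embed_dim * cfg$num_classes
}

#' Complexity probe: cost scaling with pixel count
#'
#' Evaluates the analytic per-forward MAC count over a ladder of input
#' sizes and fits the slope of log(cost) against log(pixels). A global
#' self-attention reference layer (`L^2 * C` over the embedded tokens) is
#' included for contrast; its fitted slope is ~2.
#'
#' @param cfg A [model_config()].
#' @param sizes List of `c(H, W)` input sizes (at least 2; a doubling
#'   ladder of 3+ is recommended).
#' @return List with per-size counts (`data.frame`), `slope` and
#'   `attention_slope`.
#' @export
complexity_probe <- function(cfg, sizes) {
  if (length(sizes) < 2L) stopf("complexity_probe needs at least 2 sizes")
  px <- vapply(sizes, function(s) s[1] * s[2], 0)
  macs <- vapply(sizes, function(s) count_macs(cfg, s[1], s[2]), 0)
  attn <- vapply(sizes, function(s) {
    L <- (s[1] / cfg$patch_size) * (s[2] / cfg$patch_size)
    L^2 * cfg$embed_dim
  }, 0)
  fit <- function(y) unname(coef(lm(log(y) ~ log(px)))[2])
  list(counts = data.frame(H = vapply(sizes, `[`, 0, 1),
                           W = vapply(sizes, `[`, 0, 2),
                           pixels = px, macs = macs, attention_macs = attn),
       slope = fit(macs), attention_slope = fit(attn))
}
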