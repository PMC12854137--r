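# Shape contracts, gate bounds, zero-weight identities, and
# recomposition oracles for the composite blocks.

cfg4 <- block_config(4L, csa_mlp_reduction = 2L, state_dim = 3L)

test_that("block_config validates kernels", {
  expect_error(block_config(4L, msdc_kernels = c(1, 2, 5, 7)), "odd")
  expect_error(block_config(4L, csa_spatial_kernel = 4L), "odd")
})

test_that("all shape-preserving blocks keep shape; ipm/ipe trade space for channels", {
  x <- rand_fm(4, 6, 4, seed = 2)
  expect_equal(dim(vss_forward(x, init_vss(cfg4, 1L), cfg4)), dim(x))
  expect_equal(dim(msvss_forward(x, init_msvss(cfg4, 1L), cfg4)), dim(x))
  expect_equal(dim(msdc_forward(x, init_msdc(cfg4, 1L), cfg4)), dim(x))
  expect_equal(dim(csa_forward(x, init_csa(cfg4, 1L), cfg4)), dim(x))
  expect_equal(dim(avss_forward(x, init_avss(cfg4, 1L), cfg4)), dim(x))
  expect_equal(dim(ipm_forward(x, init_ipm(4L, 1L))), c(2L, 3L, 8L))
  y <- rand_fm(2, 3, 8, seed = 3)
  expect_equal(dim(ipe_forward(y, init_ipe(8L, 1L))), c(4L, 6L, 4L))
})

test_that("ipm and ipe are shape-inverse; forced examples hold", {
  x8 <- rand_fm(8, 8, 16, seed = 4)
  y <- ipm_forward(x8, init_ipm(16L, 1L))
  expect_equal(dim(y), c(4L, 4L, 32L))
  expect_equal(dim(ipe_forward(y, init_ipe(32L, 1L))), dim(x8))
  x2 <- rand_fm(2, 2, 4, seed = 4)
  expect_equal(dim(ipm_forward(x2, init_ipm(4L, 1L))), c(1L, 1L, 8L))
  expect_equal(dim(ipe_forward(rand_fm(1, 1, 8, seed = 1), init_ipe(8L, 1L))),
               c(2L, 2L, 4L))
  expect_true(all(is.finite(ipe_forward(rand_fm(3, 3, 8, seed = 5), init_ipe(8L, 1L)))))
})

test_that("ipm rejects odd spatial dims; ipe rejects odd channels", {
  expect_error(ipm_forward(rand_fm(3, 4, 4), init_ipm(4L, 1L)), "even")
  expect_error(ipe_forward(rand_fm(4, 4, 3), init_ipe(3L, 1L)), "even")
})

test_that("vss with all weights zero is the identity (residual path)", {
  x <- rand_fm(3, 3, 4, seed = 6)
  p <- zero_params(init_vss(cfg4, 1L))
  expect_equal(vss_forward(x, p, cfg4), x)
})

test_that("msvss as printed has no outer residual: zero weights give zero", {
  x <- rand_fm(3, 3, 4, seed = 6)
  p <- zero_params(init_msvss(cfg4, 1L))
  expect_equal(msvss_forward(x, p, cfg4), array(0, dim(x)))
  # the optional outer residual restores the identity
  cfg_r <- block_config(4L, csa_mlp_reduction = 2L, state_dim = 3L,
                        outer_residual = TRUE)
  expect_equal(msvss_forward(x, p, cfg_r), x)
})

test_that("msdc has four branches; identity-like weights reproduce the input", {
  p <- init_msdc(cfg4, 1L)
  expect_length(p$branches, 4L)
  p0 <- zero_params(p)
  # 1x1 branch = identity, other branches zero, sum combine
  p0$branches[[1]]$W <- diag(4)
  x <- rand_fm(5, 5, 4, seed = 8)
  expect_equal(msdc_forward(x, p0, cfg4), x)
})

test_that("msdc with constant input and same padding is constant per channel", {
  # padding with zeros would break this off the borders; verify the interior
  # contract on a constant patch for every kernel size
  p <- init_msdc(cfg4, 2L)
  x <- array(1.5, c(9, 9, 4))
  y <- msdc_forward(x, p, cfg4)
  inner <- y[4:6, 4:6, , drop = FALSE]
  for (c in 1:4) expect_lt(max(abs(inner[, , c] - inner[1, 1, c])), 1e-12)
})

test_that("dilated msdc variant builds and keeps shape", {
  cfgd <- block_config(4L, msdc_dilated = TRUE, csa_mlp_reduction = 2L,
                       state_dim = 3L)
  x <- rand_fm(6, 6, 4, seed = 9)
  expect_equal(dim(msdc_forward(x, init_msdc(cfgd, 1L), cfgd)), dim(x))
  cfgc <- block_config(4L, msdc_combine = "concat_project",
                       csa_mlp_reduction = 2L, state_dim = 3L)
  expect_equal(dim(msdc_forward(x, init_msdc(cfgc, 1L), cfgc)), dim(x))
})

test_that("channel attention: constants, zero weights, and the gate bound", {
  p <- init_csa(cfg4, 3L)$ch
  # zero MLP: gate = sigmoid(0) = 0.5 everywhere
  x <- rand_fm(4, 4, 4, seed = 10)
  expect_equal(channel_attention(x, zero_params(p), cfg4), x / 2)
  # output never exceeds input in magnitude (gate < 1)
  y <- channel_attention(x, p, cfg4)
  expect_true(all(abs(y) <= abs(x) + 1e-12))
  # constant-per-channel input: avg and max descriptors coincide
  xc <- array(rep(c(1, -2, 3, 0.5), each = 16), c(4, 4, 4))
  yc <- channel_attention(xc, p, cfg4)
  ns <- asNamespace("vssunet")
  mlp_out <- ns$mlp2(c(1, -2, 3, 0.5), p)$o
  gate <- 1 / (1 + exp(-2 * mlp_out))
  expect_equal(yc[1, 1, ], c(1, -2, 3, 0.5) * gate)
})

test_that("spatial attention: zero conv gives x/2; gate lies in (0,1)", {
  p <- init_csa(cfg4, 3L)$sp
  x <- rand_fm(5, 5, 4, seed = 11)
  expect_equal(spatial_attention(x, zero_params(p), cfg4), x / 2)
  g <- vssunet:::spat_attn_fwd(x, p, cfg4)$cache$gate
  expect_true(all(g > 0 & g < 1))
})

test_that("spatially constant input gives a spatially constant gate under replicate padding", {
  cfg_rep <- block_config(4L, csa_spatial_padding = "replicate",
                          csa_mlp_reduction = 2L, state_dim = 3L)
  p <- init_csa(cfg_rep, 4L)$sp
  xc <- array(rep(c(0.3, -1, 2, 0.7), each = 49), c(7, 7, 4))
  g <- vssunet:::spat_attn_fwd(xc, p, cfg_rep)$cache$gate
  expect_lt(diff(range(g)), 1e-12)
})

test_that("csa equals channel attention followed by spatial attention", {
  p <- init_csa(cfg4, 5L)
  x <- rand_fm(4, 5, 4, seed = 12)
  step <- spatial_attention(channel_attention(x, p$ch, cfg4), p$sp, cfg4)
  expect_equal(csa_forward(x, p, cfg4), step)
})

test_that("iaf: zero gate conv halves the encoder features; zero encoder kills output", {
  p <- init_iaf(cfg4, 6L)
  en <- rand_fm(4, 4, 4, seed = 13)
  de <- rand_fm(4, 4, 4, seed = 14)
  p0 <- p
  p0$gate <- zero_params(p0$gate)
  expect_equal(iaf_fuse(en, de, p0, cfg4), en / 2)
  expect_equal(iaf_fuse(array(0, dim(en)), de, p, cfg4), array(0, dim(en)))
  g <- vssunet:::iaf_fwd(en, de, p, cfg4)$cache$gate
  expect_true(all(g > 0 & g < 1))
  expect_error(iaf_fuse(en, rand_fm(2, 2, 4), p, cfg4), "shapes differ")
})

test_that("avss: zero conv leaves only the vss path; gate lies in (0,1)", {
  p <- init_avss(cfg4, 7L)
  x <- rand_fm(4, 4, 4, seed = 15)
  p0 <- p
  p0$conv <- zero_params(p0$conv)
  expect_equal(avss_forward(x, p0, cfg4), vss_forward(x, p$vss, cfg4))
  g <- vssunet:::avss_fwd(x, p, cfg4)$cache$gate
  expect_true(all(g > 0 & g < 1))
})

test_that("vss recomposes from its six named stages (fixed-seed oracle)", {
  p <- init_vss(cfg4, 20L)
  x <- rand_fm(4, 4, 4, seed = 16)
  ns <- asNamespace("vssunet")
  l1 <- ns$ln_fwd(x, p$ln1)$y
  a <- ns$lin_fwd(l1, p$lin1)$y
  dw <- ns$dwconv_fwd(a, p$dw)$y
  s <- dw * (1 / (1 + exp(-dw)))
  sc <- ns$ss2d_layer_fwd(s, p$ss)$y
  l2 <- ns$ln_fwd(sc, p$ln2)$y
  vp <- ns$lin_fwd(l1, p$lin3)$y
  vls <- vp * (1 / (1 + exp(-vp)))
  want <- ns$lin_fwd(l2 * vls, p$lin2)$y + x
  expect_lt(rel_err(vss_forward(x, p, cfg4), want), 1e-10)
})

test_that("msvss recomposes as Lin4(MSDC(LN3(VSS(x))))", {
  p <- init_msvss(cfg4, 21L)
  x <- rand_fm(4, 4, 4, seed = 17)
  ns <- asNamespace("vssunet")
  v <- vss_forward(x, p$vss, cfg4)
  want <- ns$lin_fwd(msdc_forward(ns$ln_fwd(v, p$ln3)$y, p$msdc, cfg4), p$lin4)$y
  expect_lt(rel_err(msvss_forward(x, p, cfg4), want), 1e-10)
})

test_that("avss recomposes as sig(avg+max) * conv(ln(vss)) + vss", {
  p <- init_avss(cfg4, 22L)
  x <- rand_fm(4, 4, 4, seed = 18)
  ns <- asNamespace("vssunet")
  v <- vss_forward(x, p$vss, cfg4)
  fp <- ns$conv2d_fwd(ns$ln_fwd(v, p$ln)$y, p$conv)$y
  fmm <- fp; dim(fmm) <- c(16, 4)
  gate <- 1 / (1 + exp(-(rowMeans(fmm) + apply(fmm, 1, max))))
  want <- fp * gate + v
  expect_lt(rel_err(avss_forward(x, p, cfg4), want), 1e-10)
})

test_that("iaf recomposes step by step from exported primitives", {
  p <- init_iaf(cfg4, 23L)
  en <- rand_fm(3, 4, 4, seed = 19)
  de <- rand_fm(3, 4, 4, seed = 20)
  ns <- asNamespace("vssunet")
  pe <- ns$conv2d_fwd(csa_forward(en, p$csa_en, cfg4), p$proj_en)$y
  pd <- ns$conv2d_fwd(csa_forward(de, p$csa_de, cfg4), p$proj_de)$y
  gp <- ns$conv2d_fwd(pmax(pe + pd, 0), p$gate)$y
  want <- en * as.vector(1 / (1 + exp(-gp)))
  expect_lt(rel_err(iaf_fuse(en, de, p, cfg4), want), 1e-10)
})

test_that("channel mismatch is a contract error", {
  x <- rand_fm(3, 3, 5)
  expect_error(vss_forward(x, init_vss(cfg4, 1L), cfg4), "channels")
})

test_that("residual paths keep the input-output jacobian alive at zero weights", {
  # with branch weights zeroed, a perturbation of the input still moves the
  # output through the residual connections of VSS and AVSS
  x <- rand_fm(3, 3, 4, seed = 24)
  dx <- rand_fm(3, 3, 4, seed = 25) * 1e-3
  for (fwd in list(
    function(z) vss_forward(z, zero_params(init_vss(cfg4, 1L)), cfg4),
    function(z) avss_forward(z, zero_params(init_avss(cfg4, 1L)), cfg4))) {
    jvp <- fwd(x + dx) - fwd(x)
    expect_gt(max(abs(jvp)), 1e-6)
  }
})
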