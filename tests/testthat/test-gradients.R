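# Analytic backward passes agree with central finite differences, per
# block and end to end.

cfgg <- block_config(4L, csa_mlp_reduction = 2L, state_dim = 3L)

grad_case <- function(init, fwd, bwd, x, n_check = 8, tol = 1e-3) {
  params <- init()
  dy <- withr::with_seed(31, array(rnorm(length(fwd(params, x)$y)), dim(fwd(params, x)$y)))
  loss_of <- function(p) sum(fwd(p, x)$y * dy)
  o <- fwd(params, x)
  b <- bwd(dy, o$cache, params)
  # input gradient at a few entries
  withr::with_seed(32, {
    for (i in 1:4) {
      j <- sample(length(x), 1)
      xp <- x; xp[j] <- xp[j] + 1e-5
      xm <- x; xm[j] <- xm[j] - 1e-5
      fp <- params
      num <- (sum(fwd(fp, xp)$y * dy) - sum(fwd(fp, xm)$y * dy)) / 2e-5
      expect_lt(abs(num - b$dx[j]) / max(1e-6, abs(num) + abs(b$dx[j])), tol)
    }
  })
  expect_lt(check_param_grads(loss_of, params, b$g, n_check = n_check, tol = tol),
            tol)
}

test_that("convolution layers backpropagate exactly (incl. dilation and stride)", {
  ns <- asNamespace("vssunet")
  x <- rand_fm(4, 6, 4, seed = 41)
  grad_case(function() withr::with_seed(1, ns$conv2d_init(4L, 3L, 5L)),
            function(p, xx) ns$conv2d_fwd(xx, p),
            function(dy, cc, p) ns$conv2d_bwd(dy, cc, p), x)
  grad_case(function() withr::with_seed(1, ns$conv2d_init(4L, 4L, 3L)),
            function(p, xx) ns$conv2d_fwd(xx, p, dilation = 2L),
            function(dy, cc, p) ns$conv2d_bwd(dy, cc, p), x)
  grad_case(function() withr::with_seed(1, ns$conv2d_init(4L, 1L, 7L)),
            function(p, xx) ns$conv2d_fwd(xx, p, padding = "replicate"),
            function(dy, cc, p) ns$conv2d_bwd(dy, cc, p), x)
  grad_case(function() withr::with_seed(1, ns$dwconv_init(4L, 3L)),
            function(p, xx) ns$dwconv_fwd(xx, p, stride = 2L),
            function(dy, cc, p) ns$dwconv_bwd(dy, cc, p), x)
  grad_case(function() withr::with_seed(1, ns$tconv_init(4L, 2L)),
            function(p, xx) ns$tconv_fwd(xx, p),
            function(dy, cc, p) ns$tconv_bwd(dy, cc, p), x)
})

test_that("selective-scan layer gradients match finite differences", {
  ns <- asNamespace("vssunet")
  x <- rand_fm(3, 4, 4, seed = 42)
  grad_case(function() withr::with_seed(2, ns$ss2d_layer_init(4L, 3L)),
            function(p, xx) ns$ss2d_layer_fwd(xx, p),
            function(dy, cc, p) ns$ss2d_layer_bwd(dy, cc, p), x, n_check = 16)
})

test_that("composite block gradients match finite differences", {
  ns <- asNamespace("vssunet")
  x <- rand_fm(4, 4, 4, seed = 43)
  grad_case(function() withr::with_seed(3, ns$msvss_init(cfgg)),
            function(p, xx) ns$msvss_fwd(xx, p, cfgg),
            function(dy, cc, p) ns$msvss_bwd(dy, cc, p, cfgg), x, n_check = 16)
  grad_case(function() withr::with_seed(3, ns$csa_init(cfgg)),
            function(p, xx) ns$csa_fwd(xx, p, cfgg),
            function(dy, cc, p) ns$csa_bwd(dy, cc, p), x, n_check = 10)
  grad_case(function() withr::with_seed(3, ns$avss_init(cfgg)),
            function(p, xx) ns$avss_fwd(xx, p, cfgg),
            function(dy, cc, p) ns$avss_bwd(dy, cc, p), x, n_check = 12)
  grad_case(function() withr::with_seed(3, ns$ipm_init(4L)),
            function(p, xx) ns$ipm_fwd(xx, p),
            function(dy, cc, p) ns$ipm_bwd(dy, cc, p), x)
  grad_case(function() withr::with_seed(3, ns$ipe_init(4L)),
            function(p, xx) ns$ipe_fwd(xx, p),
            function(dy, cc, p) ns$ipe_bwd(dy, cc, p), x)
})

test_that("the full model's training gradient matches finite differences", {
  ns <- asNamespace("vssunet")
  cfg <- desk_config(embed_dim = 8L, state_dim = 2L, seed = 5L)
  m <- build_model(cfg)
  img <- withr::with_seed(44, array(runif(32 * 32 * 3), c(32, 32, 3)))
  mask <- withr::with_seed(45, matrix(as.integer(runif(32 * 32) > 0.8), 32, 32))
  lcfg <- loss_config(num_classes = 2L)
  fw <- ns$model_fwd(m, img)
  lg <- ns$hybrid_loss_grad(fw$logits, mask, lcfg)
  g <- ns$model_bwd(m, fw$cache, lg$dlogits)
  loss_of <- function(p) {
    m2 <- m; m2$params <- p
    ns$hybrid_loss_grad(ns$model_fwd(m2, img)$logits, mask, lcfg)$loss
  }
  expect_lt(check_param_grads(loss_of, m$params, g, n_check = 12, tol = 2e-3),
            2e-3)
  # no dead parameter tensors: every leaf gets a nonzero gradient somewhere
  leaves <- tree_leaves(g)
  frac_dead <- mean(vapply(leaves, function(lf)
    all(abs(tree_get(g, lf$path)) == 0), TRUE))
  expect_lt(frac_dead, 0.02)
})

test_that("hybrid loss gradient on logits matches finite differences", {
  ns <- asNamespace("vssunet")
  withr::with_seed(46, {
    z <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
    lab <- matrix(sample(0:2, 16, replace = TRUE), 4, 4)
    cfg <- loss_config(sigma = 0.6, num_classes = 3L)
    lg <- ns$hybrid_loss_grad(z, lab, cfg)
    for (i in 1:8) {
      j <- sample(length(z), 1)
      zp <- z; zp[j] <- zp[j] + 1e-6
      zm <- z; zm[j] <- zm[j] - 1e-6
      num <- (ns$hybrid_loss_grad(zp, lab, cfg)$loss -
              ns$hybrid_loss_grad(zm, lab, cfg)$loss) / 2e-6
      expect_lt(abs(num - lg$dlogits[j]) / max(1e-8, abs(num) + abs(lg$dlogits[j])),
                1e-3)
    }
    # and the value equals the exported hybrid_loss on the softmax probs
    zm2 <- z; dim(zm2) <- c(16, 3)
    pm <- exp(zm2 - apply(zm2, 1, max)); pm <- pm / rowSums(pm)
    p3 <- pm; dim(p3) <- c(4, 4, 3)
    expect_equal(lg$loss, hybrid_loss(p3, lab, cfg), tolerance = 1e-10)
  })
})
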