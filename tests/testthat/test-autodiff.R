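## The engine is exercised end-to-end by the network tests; here the ops are
## checked directly against finite differences through composite functions.

fd_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("composite op gradients match finite differences", {
  ad <- asNamespace("graphmqa")
  with_test_seed(50, {
    x0 <- matrix(rnorm(12), 4, 3)
    cases <- list(
      softmax = function(x) ad$ad_sum(ad$ad_mul(ad$ad_softmax_rows(x),
                                                matrix(1:12 / 6, 4, 3))),
      layernorm = function(x) ad$ad_sum(ad$ad_square(
        ad$ad_layernorm(x, matrix(c(1, 2, 0.5), 1), matrix(0.1, 1, 3)))),
      gelu_sig = function(x) ad$ad_sum(ad$ad_sigmoid(ad$ad_gelu(x))),
      sqrt_abs = function(x) ad$ad_sum(ad$ad_sqrt(ad$ad_add(
        ad$ad_abs(x), 0.3))),
      gather = function(x) ad$ad_sum(ad$ad_square(
        ad$ad_gather_rows(x, c(2L, 2L, 0L, 4L, 1L)))),
      logsoftmax = local({
        w <- matrix(runif(12), 4, 3)
        function(x) ad$ad_sum(ad$ad_mul(ad$ad_logsoftmax_rows(x), w))
      }))
    for (nm in names(cases)) {
      f <- cases[[nm]]
      node <- ad$ad_param(x0)
      out <- f(node)
      ad$ad_backward(out)
      gfd <- fd_grad(function(x) ad$ad_val(f(x)), x0)
      expect_equal(node$grad, gfd, tolerance = 1e-5, label = nm)
    }
  })
})

test_that("the fused conv2d matches its own finite differences and zero-pads edges", {
  ad <- asNamespace("graphmqa")
  with_test_seed(51, {
    n <- 5
    idx <- ad$conv_im2col_idx(n, 1L)
    x0 <- matrix(rnorm(n * n * 2), n * n, 2)
    W0 <- matrix(rnorm(18 * 3), 18, 3)
    b0 <- matrix(rnorm(3), 1, 3)
    f <- function(x, W, b) ad$ad_sum(ad$ad_square(ad$ad_conv2d(x, W, b, idx)))
    nx <- ad$ad_param(x0); nW <- ad$ad_param(W0); nb <- ad$ad_param(b0)
    ad$ad_backward(f(nx, nW, nb))
    expect_equal(nx$grad, fd_grad(function(x) ad$ad_val(f(x, W0, b0)), x0),
                 tolerance = 1e-5)
    expect_equal(nW$grad, fd_grad(function(W) ad$ad_val(f(x0, W, b0)), W0),
                 tolerance = 1e-5)
    expect_equal(as.numeric(nb$grad),
                 as.numeric(fd_grad(function(b) ad$ad_val(f(x0, W0, b)), b0)),
                 tolerance = 1e-5)
    ## a corner pixel only sees in-bounds neighbours
    expect_equal(sum(idx[1, ] > 0), 4)
  })
})

test_that("every model parameter's gradient agrees with finite differences", {
  st <- tiny_setup(n = 10, seed = 2,
                   cfg = toy_network_config(K = 5L, n_trunk = 2L))
  ens <- perturb_dihedrals(st$s, 12, 1, seed = 5)
  lab <- compute_lddt(ens$decoys[[1]], st$s)
  out <- mqa_forward(st$model, st$fwd, train = TRUE)
  lo <- compute_loss(out, lab, st$s, st$fwd)
  ad_backward(lo$total)
  eval_loss <- function(m) compute_loss(mqa_forward(m, st$fwd, train = FALSE),
                                        lab, st$s, st$fwd)$total_value
  with_test_seed(52, {
    picks <- sample(names(st$model$params), 18)
    for (nm in picks) {
      p <- st$model$params[[nm]]
      i <- sample(length(p), 1)
      g_ad <- out$params_ad[[nm]]$grad[i]
      if (is.null(g_ad)) g_ad <- 0
      eps <- 1e-5
      m2 <- st$model
      m2$params[[nm]][i] <- p[i] + eps
      lp <- eval_loss(m2)
      m2$params[[nm]][i] <- p[i] - eps
      lm <- eval_loss(m2)
      fd <- (lp - lm) / (2 * eps)
      expect_lt(abs(g_ad - fd) / max(abs(fd), 1e-4), 1e-3,
                label = paste("grad", nm))
    }
  })
})

test_that("plain inputs short-circuit to plain outputs (no tape at inference)", {
  ad <- asNamespace("graphmqa")
  x <- matrix(1:6 / 6, 2, 3)
  expect_false(ad$is_ad(ad$ad_gelu(x)))
  expect_false(ad$is_ad(ad$ad_linear(x, matrix(1, 3, 2))))
  expect_true(ad$is_ad(ad$ad_linear(x, ad$ad_param(matrix(1, 3, 2)))))
})
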