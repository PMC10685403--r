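## Layer-level behaviour: attention normalisation against an unfused
## reference, IPA invariance, EGNN equivariance, decoder head contracts, and
## the scoring identity.

## straightforward reference implementation of one edge-biased attention head
reference_gt_head <- function(qv, kv, vv, mv, fwd, a_d) {
  n <- fwd$n
  L <- (qv %*% t(kv)) / sqrt(a_d)
  for (r in seq_along(fwd$ipair)) {
    i <- fwd$ipair[r]; j <- fwd$jpair[r]
    L[i, j] <- L[i, j] + sum(qv[i, ] * mv[r, ]) / sqrt(a_d)
  }
  C <- t(apply(L, 1, function(z) exp(z - max(z)) / sum(exp(z - max(z)))))
  out <- C %*% vv
  for (r in seq_along(fwd$ipair)) {
    i <- fwd$ipair[r]; j <- fwd$jpair[r]
    out[i, ] <- out[i, ] + C[i, j] * mv[r, ]
  }
  list(out = out, attn = C)
}

test_that("the graph-transformer head equals an unfused reference and its attention rows sum to 1", {
  with_test_seed(60, {
    s <- random_structure(9)
    fwd <- make_min_fwd(s, 4)
    a_d <- 4
    qv <- matrix(rnorm(9 * a_d), 9)
    kv <- matrix(rnorm(9 * a_d), 9)
    vv <- matrix(rnorm(9 * a_d), 9)
    mv <- matrix(rnorm(length(fwd$ipair) * a_d), length(fwd$ipair))
    got <- graphmqa:::ad_gt_head(qv, kv, vv, mv, fwd$ipair, fwd$flat_knn,
                                 9, a_d)
    ref <- reference_gt_head(qv, kv, vv, mv, fwd, a_d)
    expect_equal(got, ref$out, tolerance = 1e-12)
    expect_equal(rowSums(ref$attn), rep(1, 9), tolerance = 1e-9)
  })
})

test_that("the gated residual mixes with complementary weights (C1 + C2 = 1)", {
  st <- tiny_setup(n = 8, seed = 3)
  P <- st$model$params
  h <- matrix(rnorm(8 * st$cfg$d_n), 8)
  hbar <- matrix(rnorm(8 * st$cfg$d_n), 8)
  c1 <- as.numeric(1 / (1 + exp(-(cbind(h - hbar, h, hbar) %*% P$gt1_wg +
                                    as.numeric(P$gt1_bg)))))
  mix <- h * c1 + hbar * (1 - c1)
  ## the two gate coefficients are c1 and 1 - c1 by construction; the layer
  ## must reproduce exactly this mixture before its layer norm
  gin <- cbind(h - hbar, h, hbar)
  c1b <- 1 / (1 + exp(-(gin %*% P$gt1_wg + as.numeric(P$gt1_bg))))
  expect_equal(c1, as.numeric(c1b))
  expect_equal(mix, h * as.numeric(c1b) + hbar * (1 - as.numeric(c1b)))
})

test_that("graph-transformer layer commutes with residue permutations", {
  with_test_seed(61, {
    st <- tiny_setup(n = 10, seed = 4)
    n <- 10
    h <- matrix(rnorm(n * st$cfg$d_n), n)
    e <- matrix(rnorm(length(st$fwd$ipair) * st$cfg$d_e),
                length(st$fwd$ipair))
    out0 <- graph_transformer_layer(h, e, st$fwd, st$model$params, "gt1_",
                                    st$cfg)
    perm <- sample(n)
    ## permuted forward constants: remap pair indices, reorder edge rows
    inv <- integer(n); inv[perm] <- seq_len(n)
    fwd2 <- st$fwd
    new_i <- inv[st$fwd$ipair]
    new_j <- inv[st$fwd$jpair]
    ord <- order(new_i, seq_along(new_i))
    fwd2$ipair <- new_i[ord]
    fwd2$jpair <- new_j[ord]
    fwd2$flat_knn <- fwd2$ipair + (fwd2$jpair - 1L) * n
    out1 <- graph_transformer_layer(h[perm, ], e[ord, ], fwd2,
                                    st$model$params, "gt1_", st$cfg)
    expect_equal(out1, out0[perm, ], tolerance = 1e-9)
  })
})

test_that("IPA scalar outputs are invariant and zero point queries reduce to plain attention", {
  with_test_seed(62, {
    s <- random_structure(12)
    st <- tiny_setup(n = 12, seed = 5)
    fwd <- make_min_fwd(s, 6)
    h <- matrix(rnorm(12 * st$cfg$d_n), 12)
    e <- matrix(rnorm(length(fwd$ipair) * st$cfg$d_e), length(fwd$ipair))
    out0 <- ipa_block(h, e, fwd, st$model$params, "ipa1_", st$cfg)
    for (r in 1:50) {
      tr <- random_rigid()
      s2 <- apply_transform(s, tr)
      fwd2 <- make_min_fwd(s2, 6)
      out1 <- ipa_block(h, e, fwd2, st$model$params, "ipa1_", st$cfg)
      expect_equal(out1, out0, tolerance = 1e-6)
    }
    ## zero point projections and zero gamma: the head's scalar slice
    ## equals plain attention (no geometric term)
    a_d <- st$cfg$a_d
    qv <- matrix(rnorm(12 * a_d), 12); kv <- matrix(rnorm(12 * a_d), 12)
    vv <- matrix(rnorm(12 * a_d), 12)
    zp <- matrix(0, 12, 6)
    bias <- matrix(0, length(fwd$ipair), 1)
    cr <- cbind(fwd$coords, fwd$coords)
    head <- graphmqa:::ad_ipa_head(qv, kv, vv, zp, zp, zp, bias, 0,
                                   fwd$R9, cr, fwd$flat_knn, 12, a_d, 2,
                                   sqrt(2 / 18))
    L <- qv %*% t(kv) / sqrt(a_d)   # point distances all zero -> no term
    C <- t(apply(L, 1, function(z) exp(z - max(z)) / sum(exp(z - max(z)))))
    expect_equal(head[, 1:a_d], C %*% vv, tolerance = 1e-9)
  })
})

test_that("the EGNN layer is E(3)-equivariant in coordinates and invariant in features", {
  with_test_seed(63, {
    s <- random_structure(12)
    st <- tiny_setup(n = 12, seed = 6)
    fwd <- make_min_fwd(s, 6)
    h <- matrix(rnorm(12 * st$cfg$d_n), 12)
    e <- matrix(rnorm(length(fwd$ipair) * st$cfg$d_e), length(fwd$ipair))
    x <- fwd$coords
    out0 <- egnn_layer(h, e, x, fwd, st$model$params, "egnn1_", st$cfg)
    for (r in 1:50) {
      tr <- random_rigid()
      xt <- transform_points(x, tr)
      fwd2 <- fwd; fwd2$coords <- xt
      out1 <- egnn_layer(h, e, xt, fwd2, st$model$params, "egnn1_", st$cfg)
      expect_equal(out1$x, transform_points(out0$x, tr), tolerance = 1e-6)
      expect_equal(out1$h, out0$h, tolerance = 1e-6)
    }
    ## zero coordinate-gate weights: coordinates pass through unchanged
    P0 <- st$model$params
    P0$egnn1_ww <- P0$egnn1_ww * 0
    P0$egnn1_bw <- P0$egnn1_bw * 0
    keep <- egnn_layer(h, e, x, fwd, P0, "egnn1_", st$cfg)
    expect_equal(keep$x, x, tolerance = 1e-12)
  })
})

test_that("decoder heads are normalised, bounded and symmetric; pair map tiles row-wise", {
  st <- tiny_setup(n = 10, seed = 7)
  out <- mqa_forward(st$model, st$fwd, train = FALSE)
  expect_equal(rowSums(out$error_probs), rep(1, 100), tolerance = 1e-6)
  expect_true(all(out$threshold_probs > 0 & out$threshold_probs < 1))
  ep <- array(out$error_probs, c(10, 10, 5))
  tp <- matrix(out$threshold_probs, 10, 10)
  expect_equal(ep, aperm(ep, c(2, 1, 3)), tolerance = 1e-12)
  expect_equal(tp, t(tp), tolerance = 1e-12)

  ## tiling: entry (i, j) of the pair map carries node i's vector
  h <- matrix(seq_len(10 * st$cfg$d_n), 10)
  e <- matrix(0, length(st$fwd$ipair), st$cfg$d_e)
  pm <- assemble_pair_map(h, e, st$fwd, st$model$params)
  n <- 10
  p12 <- 1 + (2 - 1) * n          # flat index of pair (i=1, j=2)
  expect_equal(pm[p12, seq_len(st$cfg$d_n)], h[1, ])
  expect_equal(ncol(pm), st$cfg$d_n + st$cfg$d_star + st$cfg$d_e +
                 st$cfg$d_star)
})

test_that("scoring head: one-hot truth reproduces lDDT; degenerate masses hit the bounds", {
  with_test_seed(64, {
    ref <- random_structure(20)
    for (r in 1:5) {
      ens <- perturb_dihedrals(ref, c(5, 30)[1 + r %% 2], 1, seed = r)
      lab <- ens$labels[[1]]
      n <- 20
      onehot <- array(0, c(n, n, 5))
      for (b in 0:4) onehot[, , b + 1] <- (lab$error_bins == b) * 1
      sc <- score_lddt(onehot, lab$threshold_mask)
      expect_equal(sc$pred_local_lddt, lab$local_lddt, tolerance = 1e-12)
    }
    n <- 6
    all0 <- array(0, c(n, n, 5)); all0[, , 1] <- 1
    full <- matrix(1, n, n)
    expect_equal(score_lddt(all0, full)$pred_local_lddt, rep(1, n))
    all4 <- array(0, c(n, n, 5)); all4[, , 5] <- 1
    expect_equal(score_lddt(all4, full)$pred_local_lddt, rep(0, n))
    ## zero contact mass: flagged, scored 0
    z <- score_lddt(all0, matrix(0, n, n))
    expect_true(all(z$no_support))
    expect_equal(z$pred_local_lddt, rep(0, n))
  })
})

test_that("the differentiable scoring path agrees with the plain implementation", {
  with_test_seed(65, {
    st <- tiny_setup(n = 9, seed = 8)
    ep <- matrix(runif(81 * 5), 81)
    ep <- ep / rowSums(ep)
    tp <- matrix(runif(81), ncol = 1)
    v1 <- graphmqa:::ad_score_lddt(ep, tp, st$fwd)
    v2 <- score_lddt(array(ep, c(9, 9, 5)), matrix(tp, 9, 9))
    expect_equal(as.numeric(v1), v2$pred_local_lddt, tolerance = 1e-7)
  })
})

test_that("the end-to-end forward pass is deterministic, fast, and pose-invariant off the Euler channels", {
  st <- tiny_setup(n = 15, seed = 9)
  t0 <- Sys.time()
  o1 <- mqa_forward(st$model, st$fwd, train = FALSE)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
  o2 <- mqa_forward(st$model, st$fwd, train = FALSE)
  expect_identical(o1$pred_local, o2$pred_local)
  expect_true(all(o1$pred_local >= 0 & o1$pred_local <= 1))
  expect_equal(as.numeric(o1$pred_global), mean(o1$pred_local))

  ## transform the structure, reuse the (invariant) embeddings, zero the
  ## pose-sensitive Euler channels on both sides
  with_test_seed(66, {
    s2 <- apply_transform(st$s, random_rigid())
    fwd2 <- prepare_inputs(s2, st$emb, st$cfg)
    nl <- assemble_features(st$s,
                            utils::modifyList(feature_config_default(),
                                              list(K = st$cfg$K)))$layout$node
    off <- cumsum(unlist(nl))
    euler <- (off[["triangular_location"]] - 5):off[["triangular_location"]]
    f1 <- st$fwd; f1$node_in[, euler] <- 0
    f2 <- fwd2; f2$node_in[, euler] <- 0
    p1 <- mqa_forward(st$model, f1, train = FALSE)$pred_local
    p2 <- mqa_forward(st$model, f2, train = FALSE)$pred_local
    expect_equal(p2, p1, tolerance = 1e-6)
  })
})

test_that("checkpoints round-trip and refuse a mismatched feature layout", {
  st <- tiny_setup(n = 8, seed = 10)
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(st$model, p)
  m2 <- load_checkpoint(p, expect_layout_hash = st$model$layout_hash)
  o1 <- mqa_forward(st$model, st$fwd, train = FALSE)$pred_local
  o2 <- mqa_forward(m2, st$fwd, train = FALSE)$pred_local
  expect_identical(o1, o2)
  expect_error(load_checkpoint(p, expect_layout_hash = 123), "hash mismatch")
})
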