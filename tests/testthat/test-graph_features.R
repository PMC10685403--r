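test_that("KNN graph caps K, sorts by distance, and matches a brute-force sort", {
  s <- toy_structure(3)
  g <- build_graph(s, 30)
  expect_equal(g$K, 2)
  expect_equal(ncol(g$knn_indices), 2)

  ## collinear equispaced chain: nearest neighbour of i is i +/- 1
  ca <- cbind(seq(0, 3.8 * 7, by = 3.8), 0, 0)
  sc <- structure_from_ca(ca)
  g2 <- build_graph(sc, 3)
  for (i in 2:7) expect_true(g2$knn_indices[i, 1] %in% c(i - 1, i + 1))

  with_test_seed(30, {
    s3 <- random_structure(40)
    g3 <- build_graph(s3, 10)
    d <- as.matrix(dist(ca_coords(s3)))
    for (i in c(1, 13, 40)) {
      ord <- order(round(d[i, -i], 6), seq_len(40)[-i])
      expect_equal(g3$knn_indices[i, ], (seq_len(40)[-i])[ord][1:10])
      expect_false(i %in% g3$knn_indices[i, ])
    }
  })
})

test_that("relative position encoding has the zero pattern, sine antisymmetry and clipping", {
  pe0 <- relative_position_encoding(0, 16)
  expect_equal(as.numeric(pe0), rep(c(0, 1), 8))
  pe_p <- relative_position_encoding(7, 16)
  pe_m <- relative_position_encoding(-7, 16)
  sin_ch <- seq(1, 16, 2); cos_ch <- seq(2, 16, 2)
  expect_equal(pe_p[, sin_ch], -pe_m[, sin_ch])
  expect_equal(pe_p[, cos_ch], pe_m[, cos_ch])
  expect_equal(relative_position_encoding(100, 16),
               relative_position_encoding(32, 16))
  expect_error(relative_position_encoding(1, 15))
})

test_that("backbone dihedrals recover builder inputs, are isometry-invariant and mirror-odd", {
  n <- 14
  phi <- rep(-57, n); psi <- rep(-47, n)
  s <- build_backbone(strrep("A", n), phi, psi)
  ang <- backbone_dihedrals(s)$angles * 180 / pi
  expect_equal(ang[2:n, "phi"], rep(-57, n - 1), tolerance = 1e-6)
  expect_equal(ang[1:(n - 1), "psi"], rep(-47, n - 1), tolerance = 1e-6)
  expect_true(all(is.na(ang[1, c("phi", "omega")])))
  expect_true(is.na(ang[n, "psi"]))

  with_test_seed(31, {
    tr <- random_rigid()
    sc2 <- backbone_dihedrals(apply_transform(s, tr))$sincos
    expect_equal(sc2, backbone_dihedrals(s)$sincos, tolerance = 1e-9)
  })
  ## mirror: negate z of every atom -> dihedrals negate
  sm <- s
  sm$coords[, , 3] <- -sm$coords[, , 3]
  angm <- backbone_dihedrals(sm)$angles
  expect_equal(angm[2:n, "phi"], -backbone_dihedrals(s)$angles[2:n, "phi"],
               tolerance = 1e-9)
})

test_that("pair geometry is frame-relative: invariant, norm-preserving, identity on i==j", {
  with_test_seed(32, {
    s <- random_structure(12)
    fr <- local_frames(s)
    pg <- pair_geometry(fr, 3, 9)
    d <- sqrt(sum((ca_coords(s)[9, ] - ca_coords(s)[3, ])^2))
    expect_equal(sqrt(sum(pg$s_ij^2)), d, tolerance = 1e-9)
    self <- pair_geometry(fr, 5, 5)
    expect_equal(self$s_ij, rep(0, 3))
    expect_equal(self$q_ij, c(1, 0, 0, 0), tolerance = 1e-12)
    for (r in 1:5) {
      st <- apply_transform(s, random_rigid())
      pg2 <- pair_geometry(local_frames(st), 3, 9)
      expect_equal(pg2$s_ij, pg$s_ij, tolerance = 1e-9)
      expect_equal(pg2$q_ij, pg$q_ij, tolerance = 1e-9)
    }
    expect_gte(pg$q_ij[1], 0)
  })
})

test_that("RBF expansion peaks at centres, is symmetric between them, and stays in (0,1]", {
  centers <- seq(0, 20, length.out = 16)
  v <- rbf_expand(centers[5], centers)
  expect_equal(v[1, 5], 1)
  mid <- (centers[7] + centers[8]) / 2
  vm <- rbf_expand(mid, centers)
  expect_equal(vm[1, 7], vm[1, 8])
  r <- rbf_expand(seq(0, 25, by = 0.5), centers)
  expect_true(all(r > 0 & r <= 1))
  expect_error(rbf_expand(1, centers, sigma = 0))
})

test_that("phi/psi secondary structure assigns helix, strand, and coil termini", {
  h <- build_backbone(strrep("A", 10), rep(-57, 10), rep(-47, 10))
  ssh <- secondary_structure(h)
  expect_true(all(ssh[2:9] == "H"))
  expect_equal(ssh[c(1, 10)], c("C", "C"))
  e <- build_backbone(strrep("A", 10), rep(-120, 10), rep(120, 10))
  expect_true(all(secondary_structure(e)[2:9] == "E"))
})

test_that("the assembled feature bundle is finite, reproducible, and pose-stable off the Euler channels", {
  s <- toy_structure(12)
  cfg <- feature_config_default()
  cfg$K <- 6
  fb1 <- assemble_features(s, cfg)
  fb2 <- assemble_features(s, cfg)
  expect_identical(fb1$node, fb2$node)
  expect_identical(fb1$edge, fb2$edge)
  expect_identical(fb1$layout_hash, fb2$layout_hash)
  expect_false(any(!is.finite(fb1$node)))
  expect_false(any(!is.finite(fb1$edge)))

  ## all node channels except the 6 Euler sin/cos are rigid-invariant
  nl <- fb1$layout$node
  off <- cumsum(unlist(nl))
  euler_cols <- (off[["triangular_location"]] - 5):off[["triangular_location"]]
  with_test_seed(33, {
    fbt <- assemble_features(apply_transform(s, random_rigid()), cfg)
    keep <- setdiff(seq_len(ncol(fb1$node)), euler_cols)
    expect_equal(fbt$node[, keep], fb1$node[, keep], tolerance = 1e-6)
    expect_equal(fbt$edge, fb1$edge, tolerance = 1e-6)
  })
})
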