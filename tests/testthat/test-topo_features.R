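test_that("triangular location reproduces the hand-computed collinear and equilateral cases", {
  s <- collinear3()
  tl <- triangular_location(s, 1)
  expect_equal(tl$p2, 3)
  expect_equal(tl$p3, 2)
  expect_equal(tl$side_lengths, c(7.6, 3.8, 3.8))
  expect_true(tl$degenerate)

  ## equilateral triangle, side 10
  ca <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, 5 * sqrt(3), 0))
  s2 <- structure_from_ca(ca)
  tl2 <- triangular_location(s2, 1)
  expect_equal(tl2$side_lengths, rep(10, 3), tolerance = 1e-9)
  expect_false(tl2$degenerate)

  expect_error(triangular_location(structure_from_ca(ca[1:2, ]), 1),
               "3 residues")
})

test_that("triangular distances are invariant under rigid transforms; Euler angles are not", {
  with_test_seed(20, {
    s <- random_structure(15)
    tl0 <- lapply(1:15, function(i) triangular_location(s, i))
    moved <- FALSE
    for (r in 1:10) {
      st <- apply_transform(s, random_rigid())
      for (i in c(1, 7, 15)) {
        tl <- triangular_location(st, i)
        expect_equal(tl$side_lengths, tl0[[i]]$side_lengths,
                     tolerance = 1e-9)
        expect_equal(tl$avg_distances, tl0[[i]]$avg_distances,
                     tolerance = 1e-9)
        if (max(abs(tl$euler_angles - tl0[[i]]$euler_angles)) > 1e-3)
          moved <- TRUE
      }
    }
    expect_true(moved)   # the frame rotates with the pose
  })
})

test_that("contact order reproduces hand values and the naive oracle", {
  s <- collinear3()
  co <- contact_order(s)
  expect_equal(co$node_order[1], 0.5)            # (1+2)/(2*3)
  ## O_ij = |i-j| / d_ij: residues 1 and 3 are 7.6 A apart
  expect_equal(co$pair_order[1, 3], 2 / 7.6)

  ## direct formula case |i-j| = 5, d = 10
  ca <- cbind(seq(0, 3.8 * 9, by = 3.8), 0, 0)
  s2 <- structure_from_ca(ca)
  d16 <- sqrt(sum((ca[6, ] - ca[1, ])^2))
  expect_equal(contact_order(s2)$pair_order[1, 6], 5 / d16)

  with_test_seed(21, {
    for (r in 1:5) {
      sr <- random_structure(sample(20:50, 1))
      co1 <- contact_order(sr)
      co2 <- oracle_contact_order(sr)
      expect_equal(co1$node_order, co2$node_order, tolerance = 1e-12)
      expect_equal(co1$pair_order, co2$pair_order, tolerance = 1e-12)
    }
  })
})

test_that("an isolated residue gets contact order 0 without division errors", {
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(100, 0, 0))
  s <- structure_from_ca(ca)
  co <- contact_order(s)
  expect_equal(co$node_order[3], 0)
  expect_true(all(is.finite(co$pair_order)))
})

test_that("voxelization is pose-invariant and counts atoms like the brute-force oracle", {
  ## single residue: only its own 5 atoms, binned near the centre
  one <- structure_from_ca(matrix(c(0, 0, 0), 1))  # CB imputed, not counted
  g1 <- voxelize(one, 1)
  expect_equal(sum(g1), 4)
  mid <- which(g1 > 0, arr.ind = TRUE)
  expect_true(all(mid >= 3 & mid <= 6))

  with_test_seed(22, {
    s <- random_structure(20)
    g0 <- lapply(1:20, function(i) voxelize(s, i))
    for (r in 1:5) {
      st <- apply_transform(s, random_rigid())
      for (i in c(2, 11, 20))
        expect_equal(voxelize(st, i), g0[[i]], tolerance = 1e-9)
    }
    for (i in c(1, 9, 16))
      expect_equal(sum(g0[[i]]), oracle_voxel_total(s, i))
  })
})
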