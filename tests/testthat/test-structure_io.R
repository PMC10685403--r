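test_that("read_pdb parses minimal fixtures, imputes CB for glycine, and keeps chains", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(p, lapply(1:3, fixture_res))
  s <- read_pdb(p)
  expect_s3_class(s, "backbone_structure")
  expect_length(s, 3)
  expect_true(all(s$cb_present))
  expect_equal(s$sequence, rep("A", 3))

  ## glycine: no CB in the file, flag false, CB imputed ~1.52 A from CA
  resg <- lapply(1:3, fixture_res)
  resg[[2]] <- fixture_res(2, resid = "GLY", with_cb = FALSE)
  write_fixture_pdb(p, resg)
  s <- read_pdb(p)
  expect_equal(s$cb_present, c(TRUE, FALSE, TRUE))
  expect_equal(s$sequence[2], "G")
  d <- sqrt(sum((s$coords[2, "CB", ] - s$coords[2, "CA", ])^2))
  expect_lt(abs(d - 1.52), 0.05)

  ## two chains concatenate in order with chain ids preserved
  res2 <- c(lapply(1:3, fixture_res),
            lapply(1:2, function(k) fixture_res(k, chain = "B")))
  write_fixture_pdb(p, res2)
  s <- read_pdb(p)
  expect_length(s, 5)
  expect_equal(s$chain_ids, c("A", "A", "A", "B", "B"))
})

test_that("read_pdb resolves altlocs by occupancy and drops incomplete residues", {
  p <- withr::local_tempfile(fileext = ".pdb")
  res <- lapply(1:3, fixture_res)
  ## residue 2: two CA altlocs; B has the higher occupancy and a shifted x
  r2 <- res[[2]]
  ca <- r2$atoms$CA
  r2$atoms$CA <- NULL
  r2$atoms <- c(r2$atoms, list(CA.A = ca, CA.B = ca + c(0.5, 0, 0)))
  r2$occ <- list(CA.A = 0.3, CA.B = 0.7)
  res[[2]] <- r2
  write_fixture_pdb(p, res)
  s <- read_pdb(p)
  expect_equal(unname(s$coords[2, "CA", 1]), ca[1] + 0.5, tolerance = 1e-3)

  ## residue missing CA entirely is dropped with a warning
  res <- lapply(1:3, fixture_res)
  res[[2]]$atoms$CA <- NULL
  write_fixture_pdb(p, res)
  w <- capture_warnings(s <- read_pdb(p))
  expect_true(any(grepl("dropped", w)))
  expect_length(s, 2)

  expect_error(read_pdb(withr::local_tempfile(fileext = ".pdb")), "read")
})

test_that("write -> read round-trip preserves sequence, chains and coordinates", {
  s <- toy_structure(15)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, p)
  s2 <- read_pdb(p)
  expect_equal(s2$sequence, s$sequence)
  expect_equal(s2$chain_ids, s$chain_ids)
  expect_equal(s2$coords[, c("N", "CA", "C"), ],
               s$coords[, c("N", "CA", "C"), ], tolerance = 1e-3)
  ## PDB stores 3 decimals
  expect_lt(max(abs(s2$coords - s$coords)), 5.1e-4 * sqrt(3) + 1e-3)
})

test_that("impute_cbeta has the ideal bond length, is equivariant, and rejects collinear input", {
  res <- build_backbone("AA", c(-57, -57), c(-47, -47))
  n <- res$coords[2, "N", ]; ca <- res$coords[2, "CA", ]
  c <- res$coords[2, "C", ]
  cb <- impute_cbeta(n, ca, c)
  expect_lt(abs(sqrt(sum((cb - ca)^2)) - 1.52), 0.05)
  with_test_seed(4, {
    for (r in 1:10) {
      tr <- random_rigid()
      cb2 <- impute_cbeta(transform_points(n, tr), transform_points(ca, tr),
                          transform_points(c, tr))
      expect_equal(cb2, transform_points(cb, tr), tolerance = 1e-9)
    }
  })
  expect_error(impute_cbeta(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
})

test_that("apply_transform is an isometry and composes as a group action", {
  s <- toy_structure(10)
  id <- rigid_transform()
  expect_identical(apply_transform(s, id)$coords, s$coords)
  with_test_seed(5, {
    t1 <- random_rigid(); t2 <- random_rigid()
    a <- apply_transform(apply_transform(s, t1), t2)
    b <- apply_transform(s, compose_rigid(t2, t1))
    expect_equal(a$coords, b$coords, tolerance = 1e-9)
    d0 <- dist(ca_coords(s))
    d1 <- dist(ca_coords(a))
    expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  })
})

test_that("missing O is imputed in the peptide plane and logged", {
  s <- toy_structure(6)
  co <- s$coords
  co[3, "O", ] <- NA
  expect_message(s2 <- backbone_structure(s$sequence, co), "imputed O")
  d <- sqrt(sum((s2$coords[3, "O", ] - s2$coords[3, "C", ])^2))
  expect_equal(d, 1.231, tolerance = 1e-6)
})

test_that("unusual CA spacing warns but does not fail", {
  ca <- cbind(c(0, 10, 20), 0, 0)   # 10 A consecutive CA
  expect_warning(structure_from_ca(ca) -> s, NA)  # helper suppresses
  expect_warning(backbone_structure(s$sequence, s$coords), "outside")
})
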