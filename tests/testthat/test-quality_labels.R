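test_that("identical structures score exactly 1 and agree with the hand-computed case", {
  s <- toy_structure()
  lab <- compute_lddt(s, s)
  expect_identical(lab$local_lddt, rep(1, 30))
  expect_identical(lab$global_lddt, 1)
  expect_true(all(lab$error_bins == 0L))

  ## collinear reference, residue 3 displaced by 0.8 A along the axis
  ref <- collinear3()
  mdl <- ref
  mdl$coords[3, , 1] <- mdl$coords[3, , 1] + 0.8
  lab <- compute_lddt(mdl, ref)
  expect_equal(lab$local_lddt, c(0.875, 0.875, 0.75))
})

test_that("lDDT matches the brute-force double-loop oracle on random pairs", {
  with_test_seed(10, {
    for (r in 1:12) {
      n <- sample(30:50, 1)
      ref <- random_structure(n)
      ens <- perturb_dihedrals(ref, sigma = sample(c(5, 15, 30), 1),
                               n_decoys = 1, seed = r)
      lab <- compute_lddt(ens$decoys[[1]], ref)
      expect_identical(lab$local_lddt, oracle_lddt(ens$decoys[[1]], ref))
    }
  })
})

test_that("error bins use half-open edges and a symmetric mask with zero diagonal", {
  ref <- structure_from_ca(cbind(c(0, 3.8, 7.6, 11.4), 0, 0))
  mdl <- ref
  ## slide residue 4 along the axis: every distance to it changes by 2.5 A
  mdl$coords[4, , 1] <- mdl$coords[4, , 1] + 2.5
  lab <- compute_lddt(mdl, ref)
  expect_equal(lab$error_bins[1, 4], 3L)        # [2,4)
  expect_equal(lab$error_bins[3, 4], 3L)
  expect_true(all(lab$error_bins[1, 2:3] == 0L))
  mdl2 <- ref
  mdl2$coords[4, , 1] <- mdl2$coords[4, , 1] + 0.5
  lab2 <- compute_lddt(mdl2, ref)
  expect_equal(lab2$error_bins[3, 4], 1L)       # boundary 0.5 -> class 1
  expect_identical(lab$error_bins, t(lab$error_bins))
  expect_identical(lab$threshold_mask, t(lab$threshold_mask))
  expect_true(all(diag(lab$threshold_mask) == 0))
})

test_that("lDDT is invariant under rigid transforms and chain relabelling", {
  with_test_seed(11, {
    ref <- random_structure(20)
    ens <- perturb_dihedrals(ref, 15, 1, seed = 3)
    mdl <- ens$decoys[[1]]
    lab0 <- compute_lddt(mdl, ref)
    for (r in 1:5) {
      lab1 <- compute_lddt(apply_transform(mdl, random_rigid()),
                           apply_transform(ref, random_rigid()))
      expect_equal(lab1$local_lddt, lab0$local_lddt, tolerance = 1e-9)
    }
    mdl$chain_ids <- rep("Z", 20); ref$chain_ids <- rep("Z", 20)
    expect_equal(compute_lddt(mdl, ref)$local_lddt, lab0$local_lddt)
  })
})

test_that("labels fail cleanly on mismatched inputs and tiny structures", {
  a <- toy_structure(10)
  b <- toy_structure(12)
  expect_error(compute_lddt(a, b), "length")
  a2 <- a; a2$sequence[1] <- "W"
  expect_error(compute_lddt(a2, a), "sequence")
  one <- structure_from_ca(matrix(c(0, 0, 0), 1))
  expect_error(compute_lddt(one, one), "2 residues")
})

test_that("label containers round-trip through disk with a JSON sidecar", {
  s <- toy_structure(8)
  ens <- perturb_dihedrals(s, 10, 1, seed = 1)
  lab <- ens$labels[[1]]
  p <- withr::local_tempfile(fileext = ".rds")
  write_labels(lab, p)
  expect_true(file.exists(paste0(p, ".json")))
  lab2 <- read_labels(p)
  expect_identical(lab2$local_lddt, lab$local_lddt)
  expect_identical(lab2$error_bins, lab$error_bins)
  meta <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(meta$n_residues, 8)
})
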