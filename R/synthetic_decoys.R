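## Synthetic reference structures and decoy ensembles via graded dihedral
## perturbation. This is the fixture engine for tests and training demos.

IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2 * pi / 180, a_ca_c_n = 116.2 * pi / 180,
  a_c_n_ca = 121.7 * pi / 180, a_ca_c_o = 120.8 * pi / 180)

#' Build an idealized backbone from dihedral angles
#'
#' Sequential (NeRF-style) placement with ideal bond lengths and angles
#' (N-CA 1.458 A, CA-C 1.525 A, C-N 1.329 A). `phi[1]` and `omega[1]` are
#' unused; `psi[n]` only orients the final carbonyl O. The construction is
#' deterministic and is the exact inverse of [backbone_dihedrals()] for the
#' defined angles.
#'
#' @param sequence one-letter sequence (string or vector).
#' @param phi,psi,omega per-residue dihedrals in degrees.
#' @return A [backbone_structure()] (single chain "A").
#' @export
build_backbone <- function(sequence, phi, psi, omega = NULL) {
  if (length(sequence) == 1L && nchar(sequence[1]) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  n <- length(sequence)
  if (is.null(omega)) omega <- rep(180, n)
  if (length(phi) != n || length(psi) != n || length(omega) != n)
    stop("angle arrays must match sequence length", call. = FALSE)
  g <- IDEAL_GEOM
  phi <- phi * pi / 180; psi <- psi * pi / 180; omega <- omega * pi / 180
  coords <- array(NA_real_, c(n, 5, 3),
                  dimnames = list(NULL, BACKBONE_ATOMS, c("x", "y", "z")))
  ## residue 1 in a canonical pose
  N1 <- c(0, 0, 0)
  CA1 <- c(g$b_n_ca, 0, 0)
  C1 <- CA1 + g$b_ca_c * c(-cos(g$a_n_ca_c), sin(g$a_n_ca_c), 0)
  coords[1, "N", ] <- N1; coords[1, "CA", ] <- CA1; coords[1, "C", ] <- C1
  for (i in seq_len(n)[-1]) {
    Ni <- place_atom(coords[i - 1, "N", ], coords[i - 1, "CA", ],
                     coords[i - 1, "C", ], g$b_c_n, g$a_ca_c_n, psi[i - 1])
    CAi <- place_atom(coords[i - 1, "CA", ], coords[i - 1, "C", ], Ni,
                      g$b_n_ca, g$a_c_n_ca, omega[i])
    Ci <- place_atom(coords[i - 1, "C", ], Ni, CAi,
                     g$b_ca_c, g$a_n_ca_c, phi[i])
    coords[i, "N", ] <- Ni; coords[i, "CA", ] <- CAi; coords[i, "C", ] <- Ci
  }
  for (i in seq_len(n))
    coords[i, "O", ] <- place_atom(coords[i, "N", ], coords[i, "CA", ],
                                   coords[i, "C", ], g$b_c_o, g$a_ca_c_o,
                                   psi[i] + pi)
  suppressMessages(backbone_structure(sequence, coords))
}

#' A deterministic 30-residue toy protein
#'
#' Mixed topology (an alpha-helix, a turn, and a beta-like extended segment)
#' so that local environments, secondary structure and lDDT neighbourhoods
#' vary along the chain.
#'
#' @param n residue count (default 30).
#' @return A [backbone_structure()].
#' @export
toy_structure <- function(n = 30L) {
  seqs <- strsplit(paste(rep("ACDEFGHIKLMNPQRSTVWY", ceiling(n / 20)),
                         collapse = ""), "")[[1]][seq_len(n)]
  phi <- rep(-57, n); psi <- rep(-47, n)
  h_end <- floor(n * 0.45)
  loop <- seq(h_end + 1, min(h_end + 4, n))
  phi[loop] <- c(-80, 60, -100, -70)[seq_along(loop)]
  psi[loop] <- c(70, 40, 120, 150)[seq_along(loop)]
  if (max(loop) < n) {
    ext <- seq(max(loop) + 1, n)
    phi[ext] <- -120
    psi[ext] <- 120
  }
  build_backbone(seqs, phi, psi)
}

## Measure full internal coordinates of a (single-chain) structure so it can
## be rebuilt exactly, with torsions selectively overridden.
measure_internal <- function(s) {
  n <- length(s)
  if (length(unique(s$chain_ids)) != 1L)
    stop("decoy generation supports single-chain references", call. = FALSE)
  co <- s$coords
  geom <- matrix(NA_real_, n, 9)
  colnames(geom) <- c("b_cn", "a_cacn", "psi_prev", "b_nca", "a_cnca",
                      "omega", "b_cac", "a_ncac", "phi")
  for (i in seq_len(n)[-1]) {
    geom[i, "b_cn"] <- vnorm(co[i, "N", ] - co[i - 1, "C", ])
    geom[i, "a_cacn"] <- bond_angle(co[i - 1, "CA", ], co[i - 1, "C", ],
                                    co[i, "N", ])
    geom[i, "psi_prev"] <- torsion_angle(co[i - 1, "N", ], co[i - 1, "CA", ],
                                         co[i - 1, "C", ], co[i, "N", ])
    geom[i, "b_nca"] <- vnorm(co[i, "CA", ] - co[i, "N", ])
    geom[i, "a_cnca"] <- bond_angle(co[i - 1, "C", ], co[i, "N", ],
                                    co[i, "CA", ])
    geom[i, "omega"] <- torsion_angle(co[i - 1, "CA", ], co[i - 1, "C", ],
                                      co[i, "N", ], co[i, "CA", ])
    geom[i, "b_cac"] <- vnorm(co[i, "C", ] - co[i, "CA", ])
    geom[i, "a_ncac"] <- bond_angle(co[i, "N", ], co[i, "CA", ], co[i, "C", ])
    geom[i, "phi"] <- torsion_angle(co[i - 1, "C", ], co[i, "N", ],
                                    co[i, "CA", ], co[i, "C", ])
  }
  oxy <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("b", "a", "t")))
  cb <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("b", "a", "t")))
  for (i in seq_len(n)) {
    oxy[i, ] <- c(vnorm(co[i, "O", ] - co[i, "C", ]),
                  bond_angle(co[i, "CA", ], co[i, "C", ], co[i, "O", ]),
                  torsion_angle(co[i, "N", ], co[i, "CA", ], co[i, "C", ],
                                co[i, "O", ]))
    if (s$cb_present[i])
      cb[i, ] <- c(vnorm(co[i, "CB", ] - co[i, "CA", ]),
                   bond_angle(co[i, "N", ], co[i, "CA", ], co[i, "CB", ]),
                   torsion_angle(co[i, "C", ], co[i, "N", ], co[i, "CA", ],
                                 co[i, "CB", ]))
  }
  list(first = co[1, c("N", "CA", "C"), ], geom = geom, oxy = oxy, cb = cb,
       sequence = s$sequence, cb_present = s$cb_present)
}

## Rebuild from measured internals; delta_phi/delta_psi are radian offsets.
rebuild_internal <- function(int, delta_phi = NULL, delta_psi = NULL) {
  n <- length(int$sequence)
  if (is.null(delta_phi)) delta_phi <- numeric(n)
  if (is.null(delta_psi)) delta_psi <- numeric(n)
  co <- array(NA_real_, c(n, 5, 3),
              dimnames = list(NULL, BACKBONE_ATOMS, c("x", "y", "z")))
  co[1, c("N", "CA", "C"), ] <- int$first
  g <- int$geom
  for (i in seq_len(n)[-1]) {
    Ni <- place_atom(co[i - 1, "N", ], co[i - 1, "CA", ], co[i - 1, "C", ],
                     g[i, "b_cn"], g[i, "a_cacn"],
                     g[i, "psi_prev"] + delta_psi[i - 1])
    CAi <- place_atom(co[i - 1, "CA", ], co[i - 1, "C", ], Ni,
                      g[i, "b_nca"], g[i, "a_cnca"], g[i, "omega"])
    Ci <- place_atom(co[i - 1, "C", ], Ni, CAi,
                     g[i, "b_cac"], g[i, "a_ncac"], g[i, "phi"] + delta_phi[i])
    co[i, "N", ] <- Ni; co[i, "CA", ] <- CAi; co[i, "C", ] <- Ci
  }
  for (i in seq_len(n)) {
    co[i, "O", ] <- place_atom(co[i, "N", ], co[i, "CA", ], co[i, "C", ],
                               int$oxy[i, "b"], int$oxy[i, "a"],
                               int$oxy[i, "t"])
    if (int$cb_present[i])
      co[i, "CB", ] <- place_atom(co[i, "C", ], co[i, "N", ], co[i, "CA", ],
                                  int$cb[i, "b"], int$cb[i, "a"],
                                  int$cb[i, "t"])
  }
  suppressMessages(backbone_structure(int$sequence, co,
                                      cb_present = int$cb_present))
}

#' Generate a decoy ensemble by graded dihedral perturbation
#'
#' Adds zero-mean Gaussian noise (sd `sigma` degrees) to the phi/psi torsions
#' of a random subset of residues (default 30%), rebuilds the backbone from
#' the reference's own internal coordinates (bond lengths/angles preserved,
#' so `sigma = 0` reproduces the reference and labels are exactly 1), and
#' labels every decoy against the reference with [compute_lddt()].
#'
#' @param reference a single-chain `backbone_structure`.
#' @param sigma perturbation scale in degrees (may be a vector recycled over
#'   decoys, giving a graded ensemble).
#' @param n_decoys number of decoys.
#' @param seed integer RNG seed; the ensemble is a pure function of
#'   (reference, sigma, n_decoys, seed).
#' @param perturb_fraction fraction of residues perturbed per decoy.
#' @return An object of class `decoy_ensemble`: `reference`, `decoys` (list),
#'   `labels` (list of `lddt_labels`), `perturbation_sigma` (per decoy),
#'   `seed`.
#' @export
perturb_dihedrals <- function(reference, sigma, n_decoys, seed = 0L,
                              perturb_fraction = 0.3) {
  stopifnot(all(sigma >= 0), n_decoys >= 1)
  int <- measure_internal(reference)
  n <- length(reference)
  sig <- rep_len(sigma, n_decoys)
  decoys <- vector("list", n_decoys)
  labels <- vector("list", n_decoys)
  with_seed(seed, {
    for (d in seq_len(n_decoys)) {
      n_pick <- max(1L, round(perturb_fraction * n))
      pick <- sample.int(n, n_pick)
      dphi <- numeric(n); dpsi <- numeric(n)
      dphi[pick] <- stats::rnorm(n_pick, sd = sig[d]) * pi / 180
      dpsi[pick] <- stats::rnorm(n_pick, sd = sig[d]) * pi / 180
      dec <- suppressWarnings(rebuild_internal(int, dphi, dpsi))
      decoys[[d]] <- dec
      labels[[d]] <- compute_lddt(dec, reference)
    }
  })
  structure(list(reference = reference, decoys = decoys, labels = labels,
                 perturbation_sigma = sig, seed = as.integer(seed)),
            class = "decoy_ensemble")
}

#' @export
print.decoy_ensemble <- function(x, ...) {
  gl <- vapply(x$labels, function(l) l$global_lddt, numeric(1))
  cat(sprintf(
    "<decoy_ensemble> %d decoys of a %d-residue reference; global lDDT %.3f-%.3f\n",
    length(x$decoys), length(x$reference), min(gl), max(gl)))
  invisible(x)
}

#' Filter near-duplicate decoys
#'
#' Greedy pass in ensemble order: a decoy is kept only if its global lDDT
#' against every already-kept decoy is at most `1 - min_mutual_lddt_gap`.
#' `min_mutual_lddt_gap = 0` keeps everything.
#'
#' @param ensemble a `decoy_ensemble`.
#' @param min_mutual_lddt_gap required mutual dissimilarity in lDDT units.
#' @return The filtered `decoy_ensemble`.
#' @export
filter_similar <- function(ensemble, min_mutual_lddt_gap) {
  stopifnot(length(ensemble$decoys) >= 1)
  keep <- integer(0)
  for (d in seq_along(ensemble$decoys)) {
    ok <- TRUE
    for (j in keep) {
      g <- compute_lddt(ensemble$decoys[[d]], ensemble$decoys[[j]])$global_lddt
      if (g > 1 - min_mutual_lddt_gap) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, d)
  }
  ensemble$decoys <- ensemble$decoys[keep]
  ensemble$labels <- ensemble$labels[keep]
  ensemble$perturbation_sigma <- ensemble$perturbation_sigma[keep]
  ensemble
}
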