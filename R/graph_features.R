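## Residue graph and node/edge feature channels.

## Meiler 7-descriptor amino-acid parameterisation (steric bulk,
## polarizability, volume, hydrophobicity, isoelectric point, helix and
## sheet propensity).
MEILER7 <- matrix(c(
  1.28, 0.05, 1.00, 0.31, 6.11, 0.42, 0.23,   # A
  2.34, 0.29, 6.13, -1.01, 10.74, 0.36, 0.25, # R
  1.60, 0.13, 2.95, -0.60, 6.52, 0.21, 0.22,  # N
  1.60, 0.11, 2.78, -0.77, 2.95, 0.25, 0.20,  # D
  1.77, 0.13, 2.43, 1.54, 6.35, 0.17, 0.41,   # C
  1.56, 0.18, 3.95, -0.22, 5.65, 0.36, 0.25,  # Q
  1.56, 0.15, 3.78, -0.64, 3.09, 0.42, 0.21,  # E
  0.00, 0.00, 0.00, 0.00, 6.07, 0.13, 0.15,   # G
  2.99, 0.23, 4.66, 0.13, 7.69, 0.27, 0.30,   # H
  4.19, 0.19, 4.00, 1.80, 6.04, 0.30, 0.45,   # I
  2.59, 0.19, 4.00, 1.70, 6.04, 0.39, 0.31,   # L
  1.89, 0.22, 4.77, -0.99, 9.99, 0.32, 0.27,  # K
  2.35, 0.22, 4.43, 1.23, 5.71, 0.38, 0.32,   # M
  2.94, 0.29, 5.89, 1.79, 5.67, 0.30, 0.38,   # F
  2.67, 0.00, 2.72, 0.72, 6.80, 0.13, 0.34,   # P
  1.31, 0.06, 1.60, -0.04, 5.70, 0.20, 0.28,  # S
  3.03, 0.11, 2.60, 0.26, 5.60, 0.21, 0.36,   # T
  3.21, 0.41, 6.46, 2.25, 5.94, 0.32, 0.42,   # W
  2.94, 0.30, 6.47, 0.96, 5.66, 0.25, 0.41,   # Y
  3.67, 0.14, 3.00, 1.22, 6.02, 0.27, 0.49),  # V
  nrow = 20, byrow = TRUE,
  dimnames = list(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], NULL))

## BLOSUM62 substitution scores over the 20 standard amino acids.
BLOSUM62_20 <- local({
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  v <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-2,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-2, 4)
  matrix(v, 20, 20, byrow = TRUE, dimnames = list(aas, aas))
})

aa_index <- function(seq1) {
  i <- match(seq1, rownames(MEILER7))
  i[is.na(i)] <- match("A", rownames(MEILER7))  # unknown residues as ALA
  i
}

#' K-nearest-neighbour residue graph topology
#'
#' Each residue's neighbours are its `min(K, N-1)` nearest residues by CA
#' distance, sorted ascending, ties broken by residue index; self excluded.
#'
#' @param s a `backbone_structure` with at least 2 residues.
#' @param K neighbour count (default 30).
#' @return list with `knn_indices` (N x K' integer matrix), `knn_dist`
#'   (N x K' CA distances) and `K` (the effective K').
#' @export
build_graph <- function(s, K = 30L) {
  n <- length(s)
  if (n < 2) stop("need at least 2 residues", call. = FALSE)
  d <- ca_dist_matrix(s)
  k_eff <- min(K, n - 1L)
  idx <- matrix(0L, n, k_eff)
  dst <- matrix(0, n, k_eff)
  for (i in seq_len(n)) {
    ## distances rounded to 1e-6 A before ordering so that exact geometric
    ## ties (e.g. ideal helices) break by residue index, stably under
    ## floating-point jitter from rigid transforms
    ord <- order(round(d[i, -i], 6), seq_len(n)[-i])
    nb <- (seq_len(n)[-i])[ord][seq_len(k_eff)]
    idx[i, ] <- nb
    dst[i, ] <- d[i, nb]
  }
  list(knn_indices = idx, knn_dist = dst, K = k_eff)
}

#' Sinusoidal relative-position encoding
#'
#' Transformer-style encoding of the clipped relative sequence index
#' `i - j`. Channels alternate sin/cos at geometric wavelengths; the encoding
#' of 0 is (0, 1, 0, 1, ...), and negating the offset flips only the sine
#' channels. Offsets are clipped to +-`clip`.
#'
#' @param delta integer offset(s) `i - j` (vectorised).
#' @param d_model even embedding width (default 16).
#' @param clip clip window (default 32).
#' @return `length(delta) x d_model` matrix.
#' @export
relative_position_encoding <- function(delta, d_model = 16L, clip = 32L) {
  stopifnot(d_model %% 2 == 0)
  delta <- pmax(pmin(delta, clip), -clip)
  k <- seq_len(d_model / 2)
  freq <- 1 / (10000^((2 * (k - 1)) / d_model))
  ang <- outer(delta, freq)
  out <- matrix(0, length(delta), d_model)
  out[, seq(1, d_model, 2)] <- sin(ang)
  out[, seq(2, d_model, 2)] <- cos(ang)
  out
}

#' Backbone dihedral angles
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1);
#' omega(i) = CA(i-1)-C(i-1)-N(i)-CA(i). Undefined angles at chain termini
#' are `NA` in `angles` and encode to (0, 0) in `sincos`.
#'
#' @param s a `backbone_structure`.
#' @return list with `angles` (N x 3 radians, columns phi/psi/omega, NA where
#'   undefined) and `sincos` (N x 6: sin/cos of each).
#' @export
backbone_dihedrals <- function(s) {
  n <- length(s)
  ang <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("phi", "psi", "omega")))
  for (i in seq_len(n)) {
    prev_ok <- i > 1 && s$chain_ids[i - 1] == s$chain_ids[i]
    next_ok <- i < n && s$chain_ids[i + 1] == s$chain_ids[i]
    if (prev_ok)
      ang[i, "phi"] <- torsion_angle(s$coords[i - 1, "C", ], s$coords[i, "N", ],
                                     s$coords[i, "CA", ], s$coords[i, "C", ])
    if (next_ok)
      ang[i, "psi"] <- torsion_angle(s$coords[i, "N", ], s$coords[i, "CA", ],
                                     s$coords[i, "C", ], s$coords[i + 1, "N", ])
    if (prev_ok)
      ang[i, "omega"] <- torsion_angle(s$coords[i - 1, "CA", ],
                                       s$coords[i - 1, "C", ],
                                       s$coords[i, "N", ], s$coords[i, "CA", ])
  }
  sc <- matrix(0, n, 6)
  for (j in 1:3) {
    ok <- !is.na(ang[, j])
    sc[ok, 2 * j - 1] <- sin(ang[ok, j])
    sc[ok, 2 * j] <- cos(ang[ok, j])
  }
  list(angles = ang, sincos = sc)
}

#' Local backbone frames for every residue
#'
#' @param s a `backbone_structure`.
#' @return list of per-residue lists with `origin` (CA) and `rotation`
#'   (3x3 orthonormal, det +1, Gram-Schmidt on N/CA/C).
#' @export
local_frames <- function(s) {
  lapply(seq_len(length(s)), function(i)
    list(origin = s$coords[i, "CA", ],
         rotation = backbone_frame(s$coords[i, "N", ], s$coords[i, "CA", ],
                                   s$coords[i, "C", ])))
}

#' Frame-relative pair geometry
#'
#' `s_ij = R_i^T (CA_j - CA_i)` (the displacement seen from residue i's
#' frame) and `Q_ij`, the quaternion of `R_i^T R_j` with non-negative scalar
#' part. Both are invariant under a global rigid transform.
#'
#' @param frames output of [local_frames()].
#' @param i,j residue indices.
#' @return list with `s_ij` (length 3) and `q_ij` (length 4, w >= 0).
#' @export
pair_geometry <- function(frames, i, j) {
  fi <- frames[[i]]; fj <- frames[[j]]
  s_ij <- as.numeric(t(fi$rotation) %*% (fj$origin - fi$origin))
  q_ij <- rot_to_quat(t(fi$rotation) %*% fj$rotation)
  list(s_ij = s_ij, q_ij = q_ij)
}

#' Gaussian radial basis expansion of a distance
#'
#' Component k is `exp(-(d - c_k)^2 / (2 sigma^2))`. Defaults: 16 centres
#' uniform on \[0, 20\] A, sigma equal to the centre spacing.
#'
#' @param d distance(s) in angstroms (vectorised).
#' @param centers RBF centres.
#' @param sigma kernel width (> 0).
#' @return `length(d) x length(centers)` matrix.
#' @export
rbf_expand <- function(d, centers = seq(0, 20, length.out = 16),
                       sigma = diff(range(centers)) / (length(centers) - 1)) {
  stopifnot(sigma > 0)
  exp(-(outer(d, centers, "-"))^2 / (2 * sigma^2))
}

#' Three-state secondary structure from backbone dihedrals
#'
#' Self-contained phi/psi-region assignment (no external DSSP binary):
#' helix when phi in \[-100, -30\] and psi in \[-80, -5\]; strand when phi in
#' \[-180, -80\] and psi in \[80, 180\] or \[-180, -170\]; otherwise coil.
#' Terminal residues with undefined phi or psi are coil.
#'
#' @param s a `backbone_structure` with at least 3 residues.
#' @return character vector of "H", "E", "C".
#' @export
secondary_structure <- function(s) {
  if (length(s) < 3) stop("need at least 3 residues", call. = FALSE)
  ang <- backbone_dihedrals(s)$angles * 180 / pi
  out <- rep("C", length(s))
  phi <- ang[, "phi"]; psi <- ang[, "psi"]
  ok <- !is.na(phi) & !is.na(psi)
  helix <- ok & phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5
  strand <- ok & phi >= -180 & phi <= -80 &
    ((psi >= 80 & psi <= 180) | (psi >= -180 & psi <= -170))
  out[strand] <- "E"
  out[helix] <- "H"
  out
}

feature_config_default <- function() {
  list(K = 30L, pe_dim = 16L, pe_clip = 32L,
       rbf_centers = seq(0, 20, length.out = 16), rbf_sigma = 20 / 15,
       voxel_grid = 8L, voxel_extent = 16,
       rosetta_energy_dim = 1L)   # pluggable channel, zero-filled by default
}

#' Assemble the full feature bundle for a structure
#'
#' Builds the KNN residue graph and concatenates every node and edge channel.
#' Node channels: absolute-index positional encoding, Meiler 7, BLOSUM62 row,
#' secondary-structure one-hot, dihedral sin/cos, triangular location
#' (3 sides + 3 average distances + Euler sin/cos), contact order `O_i`, and
#' the flattened local voxel grid. Edge channels (per (i, neighbour) pair):
#' RBF-dispersed N-N/CA-CA/C-C/O-O/CB-CB distances, frame-relative `s_ij`,
#' quaternion `Q_ij`, pair contact order `O_ij`, relative-index positional
#' encoding, and a zero-filled inter-residue energy slot (provider hook).
#' A JSON-able layout (channel names, offsets, parameters) and a stable
#' layout hash are attached.
#'
#' @param s a `backbone_structure`.
#' @param config feature configuration (see `feature_config_default()`).
#' @return list of class `feature_bundle`: `node` (N x Dn), `edge`
#'   (N x K x De), `graph`, `frames`, `layout`, `layout_hash`.
#' @export
assemble_features <- function(s, config = feature_config_default()) {
  cfg <- utils::modifyList(feature_config_default(), config)
  n <- length(s)
  g <- build_graph(s, cfg$K)
  frames <- local_frames(s)
  ai <- aa_index(s$sequence)

  pe <- relative_position_encoding(seq_len(n), cfg$pe_dim, cfg$pe_clip)
  meiler <- MEILER7[ai, , drop = FALSE]
  blosum <- BLOSUM62_20[ai, , drop = FALSE] / 10
  ss <- secondary_structure(s)
  ss1h <- t(vapply(ss, function(x) as.numeric(c("H", "E", "C") == x),
                   numeric(3)))
  dih <- backbone_dihedrals(s)$sincos
  tri <- matrix(0, n, 12)
  co <- contact_order(s)
  vox_len <- cfg$voxel_grid^3
  vox <- matrix(0, n, vox_len)
  for (i in seq_len(n)) {
    tl <- triangular_location(s, i)
    tri[i, ] <- c(tl$side_lengths / 10, tl$avg_distances / 10,
                  sin(tl$euler_angles), cos(tl$euler_angles))
    vox[i, ] <- as.numeric(voxelize(s, i, cfg$voxel_grid, cfg$voxel_extent))
  }
  node <- cbind(pe, meiler, blosum, ss1h, dih, tri, co$node_order, vox)

  node_layout <- list(
    position_encoding = ncol(pe), meiler = 7L, blosum62 = 20L,
    secondary_structure = 3L, dihedral_sincos = 6L, triangular_location = 12L,
    contact_order_node = 1L, voxel = vox_len)

  k <- g$K
  nc <- length(cfg$rbf_centers)
  e_rbf <- matrix(0, n * k, 5 * nc)
  e_geo <- matrix(0, n * k, 7)
  e_ord <- numeric(n * k)
  e_rel <- matrix(0L, n * k, 1)
  row <- 0L
  atom_pairs <- BACKBONE_ATOMS
  for (i in seq_len(n)) {
    for (kk in seq_len(k)) {
      row <- row + 1L
      j <- g$knn_indices[i, kk]
      dists <- vapply(atom_pairs, function(a)
        vnorm(s$coords[i, a, ] - s$coords[j, a, ]), numeric(1))
      e_rbf[row, ] <- as.numeric(t(rbf_expand(dists, cfg$rbf_centers,
                                              cfg$rbf_sigma)))
      pg <- pair_geometry(frames, i, j)
      e_geo[row, ] <- c(pg$s_ij / 10, pg$q_ij)
      e_ord[row] <- co$pair_order[i, j]
      e_rel[row, 1] <- i - j
    }
  }
  e_pe <- relative_position_encoding(e_rel[, 1], cfg$pe_dim, cfg$pe_clip)
  e_energy <- matrix(0, n * k, cfg$rosetta_energy_dim)
  edge_flat <- cbind(e_rbf, e_geo, e_ord, e_pe, e_energy)
  ## edge_flat rows are ordered i-major (i fixed, neighbours consecutive)
  edge <- array(0, c(n, k, ncol(edge_flat)))
  for (c_i in seq_len(ncol(edge_flat)))
    edge[, , c_i] <- matrix(edge_flat[, c_i], n, k, byrow = TRUE)

  edge_layout <- list(
    rbf_distances = 5L * nc, local_vector = 3L, frame_quaternion = 4L,
    contact_order_pair = 1L, relative_position_encoding = ncol(e_pe),
    energy_terms = cfg$rosetta_energy_dim)

  layout <- list(node = node_layout, edge = edge_layout,
                 K = k, rbf_centers = cfg$rbf_centers,
                 rbf_sigma = cfg$rbf_sigma,
                 voxel = c(grid = cfg$voxel_grid, extent = cfg$voxel_extent))
  hash <- string_hash31(jsonlite::toJSON(layout, auto_unbox = TRUE,
                                         digits = 10))
  structure(list(node = node, edge = edge, graph = g, frames = frames,
                 layout = layout, layout_hash = hash),
            class = "feature_bundle")
}
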