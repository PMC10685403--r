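## Shared fixtures and independent oracles. Everything is generated in code;
## no binary fixtures.

## A structure with CA atoms at given positions; N and C are placed in a
## fixed offset pattern so residue frames are well-defined.
structure_from_ca <- function(ca, sequence = NULL) {
  n <- nrow(ca)
  if (is.null(sequence)) sequence <- rep("A", n)
  coords <- array(NA_real_, c(n, 5, 3))
  for (i in seq_len(n)) {
    coords[i, 2, ] <- ca[i, ]
    coords[i, 1, ] <- ca[i, ] + c(-1.0, 0.6, 0.2)    # N
    coords[i, 3, ] <- ca[i, ] + c(1.0, 0.6, -0.2)    # C
  }
  suppressWarnings(suppressMessages(
    backbone_structure(sequence, coords)))
}

## collinear 3-residue chain used by several hand-computed checks
collinear3 <- function() {
  structure_from_ca(cbind(c(0, 3.8, 7.6), 0, 0))
}

## random compact structure from random dihedrals (fixed RNG state assumed
## set by the caller)
random_structure <- function(n) {
  phi <- stats::runif(n, -160, -40)
  psi <- stats::runif(n, -70, 150)
  build_backbone(strrep("A", n), phi, psi)
}

## independently coded O(N^2) double-loop lDDT oracle (CA atoms, reference
## 15 A inclusion radius, thresholds 0.5/1/2/4)
oracle_lddt <- function(model, reference) {
  dm <- as.matrix(dist(ca_coords(model)))
  dr <- as.matrix(dist(ca_coords(reference)))
  n <- nrow(dr)
  out <- numeric(n)
  for (i in seq_len(n)) {
    hits <- 0L
    pairs <- 0L
    for (j in seq_len(n)) {
      if (j == i) next
      if (dr[i, j] >= 15) next
      pairs <- pairs + 1L
      delta <- abs(dm[i, j] - dr[i, j])
      for (s in c(0.5, 1, 2, 4)) if (delta < s) hits <- hits + 1L
    }
    out[i] <- if (pairs == 0) 1 else hits / (4 * pairs)
  }
  out
}

## naive double-loop contact order oracle
oracle_contact_order <- function(s) {
  d <- as.matrix(dist(ca_coords(s)))
  n <- nrow(d)
  node <- numeric(n)
  pair <- matrix(0, n, n)
  for (i in seq_len(n)) {
    r_i <- 0L
    acc <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      if (d[i, j] <= 15) {
        r_i <- r_i + 1L
        acc <- acc + abs(i - j)
      }
      if (d[i, j] > 0) pair[i, j] <- abs(i - j) / d[i, j]
    }
    node[i] <- if (r_i == 0) 0 else acc / (r_i * n)
  }
  list(node_order = node, pair_order = pair)
}

## brute-force count of backbone atoms inside residue i's local cube
oracle_voxel_total <- function(s, i, grid = 8L, extent = 16) {
  R <- graphmqa:::backbone_frame(s$coords[i, "N", ], s$coords[i, "CA", ],
                                 s$coords[i, "C", ])
  origin <- s$coords[i, "CA", ]
  total <- 0L
  h <- extent / grid
  for (r in seq_len(length(s))) {
    atoms <- c("N", "CA", "C", "O", if (s$cb_present[r]) "CB")
    for (a in atoms) {
      y <- as.numeric(t(R) %*% (s$coords[r, a, ] - origin))
      idx <- floor((y + extent / 2) / h)
      if (all(idx >= 0 & idx < grid)) total <- total + 1L
    }
  }
  total
}

## write a minimal fixed-column PDB text fixture
write_fixture_pdb <- function(path, residues) {
  ## residues: list of list(resno, chain, resid, atoms = named list of xyz,
  ## optionally alt + occ per atom entry name like "CA.A"
  lines <- character(0)
  serial <- 0L
  for (r in residues) {
    for (nm in names(r$atoms)) {
      serial <- serial + 1L
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      aname <- parts[1]
      alt <- if (length(parts) > 1) parts[2] else " "
      occ <- if (!is.null(r$occ[[nm]])) r$occ[[nm]] else 1.0
      xyz <- r$atoms[[nm]]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
        serial, aname, alt, r$resid, r$chain, r$resno,
        xyz[1], xyz[2], xyz[3], occ, 0, substr(aname, 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

## ideal-ish backbone atom positions for fixture residue k along x
fixture_res <- function(k, chain = "A", resid = "ALA", with_cb = TRUE) {
  base <- c(3.8 * (k - 1), 0, 0)
  atoms <- list(
    N = base + c(-0.8, 1.1, 0.0),
    CA = base,
    C = base + c(1.2, 0.8, 0.0),
    O = base + c(1.3, 2.0, 0.1))
  if (with_cb) atoms$CB <- base + c(-0.5, -1.0, 1.1)
  list(resno = k, chain = chain, resid = resid, atoms = atoms)
}

## minimal forward-constant bundle for layer-level tests (no features)
make_min_fwd <- function(s, K) {
  g <- build_graph(s, K)
  n <- length(s)
  k <- g$K
  frames <- local_frames(s)
  ipair <- rep(seq_len(n), each = k)
  jpair <- as.integer(t(g$knn_indices))
  i_flat <- rep(seq_len(n), times = n)
  j_flat <- rep(seq_len(n), each = n)
  list(n = n, k = k, ipair = ipair, jpair = jpair,
       flat_knn = ipair + (jpair - 1L) * n,
       i_flat = i_flat, j_flat = j_flat,
       perm_t = j_flat + (i_flat - 1L) * n,
       offdiag = matrix(as.numeric(i_flat != j_flat), ncol = 1),
       R9 = t(vapply(frames, function(f) as.numeric(f$rotation), numeric(9))),
       coords = ca_coords(s))
}

## tiny trained-forward setup shared across network tests
tiny_setup <- function(n = 12, seed = 1, cfg = NULL) {
  if (is.null(cfg))
    cfg <- toy_network_config(K = 6L, n_trunk = 2L)
  s <- with_test_seed(seed, random_structure(n))
  emb <- mock_embed(s, "single", seed = seed)
  fwd <- prepare_inputs(s, emb, cfg)
  model <- mqa_model(ncol(fwd$node_in), ncol(fwd$edge_in), cfg,
                     fwd$layout_hash)
  list(s = s, cfg = cfg, emb = emb, fwd = fwd, model = model)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
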