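## Designed topological descriptors: triangular location, residue-level
## contact order, and a pose-invariant local voxelization.

#' Triangular location descriptor of a residue
#'
#' Places residue i relative to a triangle of global extreme points: P1 is
#' residue i's CA, P2 the farthest CA from P1, P3 the farthest CA from P2
#' (excluding P1). Reports the triangle side lengths, the mean distance of
#' all residues to each vertex, and the Euler angles (intrinsic Z-Y-X) of the
#' local frame built from the triangle edges. Distances are invariant under
#' rigid transforms; the Euler angles rotate with the global pose.
#'
#' @param s a `backbone_structure` with at least 3 residues.
#' @param i residue index (1-based).
#' @return list with `side_lengths` (D12, D13, D23), `avg_distances` (mean
#'   distance of all residues to P1, P2, P3), `euler_angles` (radians),
#'   `p2`, `p3` (indices) and `degenerate` flag (collinear triangle).
#' @export
triangular_location <- function(s, i) {
  ca <- ca_coords(s)
  n <- nrow(ca)
  if (n < 3) stop("need at least 3 residues", call. = FALSE)
  stopifnot(i >= 1, i <= n)
  p1 <- ca[i, ]
  d1 <- sqrt(colSums((t(ca) - p1)^2))
  p2_idx <- which.max(d1)                      # ties: lowest index
  p2 <- ca[p2_idx, ]
  d2 <- sqrt(colSums((t(ca) - p2)^2))
  d2_mask <- d2
  d2_mask[c(i, p2_idx)] <- -Inf
  p3_idx <- which.max(d2_mask)
  p3 <- ca[p3_idx, ]
  d3 <- sqrt(colSums((t(ca) - p3)^2))
  side <- c(vnorm(p2 - p1), vnorm(p3 - p1), vnorm(p3 - p2))
  avg <- c(mean(d1), mean(d2), mean(d3))
  ex <- unit(p3 - p1)
  v <- p2 - p1
  vex <- sum(v * ex) * ex
  degenerate <- vnorm(v - vex) < 1e-8
  if (degenerate) {
    ## arbitrary unit vector orthogonal to ex
    ref <- if (abs(ex[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ey <- unit(cross3(ex, ref))
  } else {
    ey <- unit(v - vex)
  }
  R <- cbind(ex, ey, cross3(ex, ey), deparse.level = 0)
  list(side_lengths = side, avg_distances = avg,
       euler_angles = rot_to_euler_zyx(R),
       p2 = p2_idx, p3 = p3_idx, degenerate = degenerate)
}

#' Residue-level contact order
#'
#' Extends classical contact order to per-residue and per-pair descriptors of
#' topological complexity. `node_order[i]` averages the sequence separation
#' of residue i's spatial neighbours within 15 A, normalised by protein
#' length: `O_i = sum_{j != i, d_ij <= 15} |i - j| / (R_i * N)` with `R_i`
#' the neighbour count (0 neighbours gives `O_i = 0`). `pair_order[i, j] =
#' |i - j| / d_ij` on CA distances (diagonal 0; coincident pairs skipped with
#' a warning).
#'
#' @param s a `backbone_structure` with at least 2 residues.
#' @return list with `node_order` (length N) and `pair_order` (N x N).
#' @export
contact_order <- function(s) {
  n <- length(s)
  if (n < 2) stop("need at least 2 residues", call. = FALSE)
  d <- ca_dist_matrix(s)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  within <- d <= LDDT_RADIUS
  diag(within) <- FALSE
  r_i <- rowSums(within)
  node <- ifelse(r_i > 0, rowSums(sep * within) / (pmax(r_i, 1) * n), 0)
  dz <- d
  diag(dz) <- 1
  zero_off <- dz == 0
  if (any(zero_off)) {
    warning("coincident CA pair(s): pair_order entry skipped (set to 0)",
            call. = FALSE)
    dz[zero_off] <- Inf
  }
  pair <- sep / dz
  diag(pair) <- 0
  list(node_order = unname(node), pair_order = unname(pair))
}

#' Pose-invariant voxelization of a residue's environment
#'
#' Bins backbone atoms (N, CA, C, O, and CB where present) of all residues
#' into a `grid^3` occupancy histogram over an `extent`-angstrom cube centred
#' on residue i's CA and expressed in the residue's backbone frame
#' (Gram-Schmidt on N, CA, C), which makes the counts independent of the
#' global pose.
#'
#' @param s a `backbone_structure`.
#' @param i residue index.
#' @param grid voxels per axis (default 8).
#' @param extent cube side length in angstroms (default 16).
#' @return `grid x grid x grid` integer occupancy array.
#' @export
voxelize <- function(s, i, grid = 8L, extent = 16) {
  n <- length(s)
  stopifnot(i >= 1, i <= n)
  R <- backbone_frame(s$coords[i, "N", ], s$coords[i, "CA", ],
                      s$coords[i, "C", ])
  origin <- s$coords[i, "CA", ]
  pts <- NULL
  for (a in BACKBONE_ATOMS) {
    m <- s$coords[, a, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    if (a == "CB") m <- m[s$cb_present, , drop = FALSE]
    pts <- rbind(pts, m)
  }
  local <- sweep(pts, 2, origin) %*% R     # rows: atoms in the local frame
  h <- extent / grid
  idx <- floor((local + extent / 2) / h) + 1
  ok <- rowSums(idx >= 1 & idx <= grid) == 3
  g <- array(0L, c(grid, grid, grid))
  if (any(ok)) {
    idx <- idx[ok, , drop = FALSE]
    flat <- (idx[, 3] - 1) * grid * grid + (idx[, 2] - 1) * grid + idx[, 1]
    tab <- table(flat)
    g[as.integer(names(tab))] <- as.integer(tab)
  }
  g
}
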