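## Backbone structure container and PDB input/output.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "CB")

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "C", PYL = "K")

AA1_TO_3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL", X = "UNK")

#' Construct a backbone structure
#'
#' The universal structural container: per-residue backbone coordinates for
#' the five atoms N, CA, C, O, CB (CB imputed by ideal tetrahedral geometry
#' when absent, e.g. glycine), the one-letter sequence, chain labels and
#' author residue numbers.
#'
#' @param sequence character vector of one-letter residue codes (or a single
#'   string, which is split).
#' @param coords numeric array `c(N, 5, 3)`; atom order N, CA, C, O, CB.
#'   Missing O/CB entries may be `NA` and are imputed.
#' @param chain_ids per-residue chain label (recycled if length 1).
#' @param residue_numbers per-residue author numbering (default `1:N`).
#' @param cb_present logical per-residue flag; defaults to `sequence != "G"`.
#' @return An object of class `backbone_structure` with fields `sequence`,
#'   `chain_ids`, `residue_numbers`, `coords`, `cb_present`.
#' @export
backbone_structure <- function(sequence, coords, chain_ids = "A",
                               residue_numbers = NULL, cb_present = NULL) {
  if (length(sequence) == 1L && nchar(sequence[1]) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  n <- length(sequence)
  stopifnot(length(dim(coords)) == 3L, dim(coords)[1] == n,
            dim(coords)[2] == 5L, dim(coords)[3] == 3L)
  dimnames(coords) <- list(NULL, BACKBONE_ATOMS, c("x", "y", "z"))
  if (length(chain_ids) == 1L) chain_ids <- rep(chain_ids, n)
  if (is.null(residue_numbers)) residue_numbers <- seq_len(n)
  if (is.null(cb_present)) cb_present <- sequence != "G"
  stopifnot(length(chain_ids) == n, length(residue_numbers) == n,
            length(cb_present) == n)
  core <- coords[, c("N", "CA", "C"), , drop = FALSE]
  if (any(!is.finite(core)))
    stop("N, CA, C coordinates must all be finite", call. = FALSE)
  ## impute missing O from peptide-plane geometry
  for (i in seq_len(n)) {
    if (any(!is.finite(coords[i, "O", ]))) {
      coords[i, "O", ] <- impute_oxygen(
        n = coords[i, "N", ], ca = coords[i, "CA", ], c = coords[i, "C", ],
        n_next = if (i < n && chain_ids[i + 1] == chain_ids[i])
          coords[i + 1, "N", ] else NULL)
      message("imputed O for residue ", i)
    }
    if (any(!is.finite(coords[i, "CB", ]))) {
      coords[i, "CB", ] <- impute_cbeta(coords[i, "N", ], coords[i, "CA", ],
                                        coords[i, "C", ])
      cb_present[i] <- FALSE
    }
  }
  s <- structure(list(sequence = sequence, chain_ids = chain_ids,
                      residue_numbers = as.integer(residue_numbers),
                      coords = coords, cb_present = as.logical(cb_present)),
                 class = "backbone_structure")
  check_ca_spacing(s)
  s
}

#' @export
length.backbone_structure <- function(x) length(x$sequence)

#' @export
print.backbone_structure <- function(x, ...) {
  cat(sprintf("<backbone_structure> %d residues, %d chain(s): %s\n",
              length(x), length(unique(x$chain_ids)),
              paste(unique(x$chain_ids), collapse = ",")))
  invisible(x)
}

#' Calpha coordinate matrix of a structure
#'
#' @param s a `backbone_structure`.
#' @return `N x 3` matrix of CA coordinates (angstroms).
#' @export
ca_coords <- function(s) {
  m <- s$coords[, "CA", , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  m
}

check_ca_spacing <- function(s) {
  ca <- ca_coords(s)
  n <- nrow(ca)
  if (n < 2) return(invisible(TRUE))
  same_chain <- s$chain_ids[-1] == s$chain_ids[-n]
  d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  bad <- same_chain & (d <= 2.0 | d >= 4.5)
  if (any(bad))
    warning(sprintf("%d consecutive CA-CA distance(s) outside (2.0, 4.5) A",
                    sum(bad)), call. = FALSE)
  invisible(TRUE)
}

#' Impute a Cbeta position from backbone atoms
#'
#' Places CB by ideal tetrahedral geometry around CA, about 1.52 A from CA.
#' The construction is equivariant under rigid transforms.
#'
#' @param n,ca,c length-3 coordinates of backbone N, CA, C.
#' @return length-3 CB coordinate.
#' @export
impute_cbeta <- function(n, ca, c) {
  b <- ca - n
  g <- c - ca
  a <- cross3(b, g)
  if (vnorm(a) < 1e-8)
    stop("degenerate geometry: N, CA, C are collinear", call. = FALSE)
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * g + ca
}

## Carbonyl O in the peptide plane, 1.231 A from C. With the next residue's N
## the O direction is the external bisector; for chain-terminal residues fall
## back to the local N-CA-C plane.
impute_oxygen <- function(n, ca, c, n_next = NULL) {
  if (!is.null(n_next)) {
    d <- unit(unit(c - ca) + unit(c - n_next))
  } else {
    d <- unit(unit(c - ca) + unit(cross3(cross3(c - ca, ca - n), c - ca)))
  }
  c + 1.231 * d
}

#' Read a backbone structure from a PDB file
#'
#' Reads ATOM records (HETATM ignored), resolves alternate locations to the
#' highest occupancy, orders residues by (chain, residue number, insertion
#' code) and concatenates multimer chains into one structure. Residues missing
#' any of N, CA, C are dropped with a warning; missing O and CB are imputed.
#'
#' @param path PDB file path.
#' @param model_index 1-based MODEL index for multi-model files (default 1).
#' @return A [backbone_structure()].
#' @export
read_pdb <- function(path, model_index = 1L) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                   verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file: ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  nmod <- if (!is.null(pdb$xyz) && is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model_index > nmod)
    stop("model_index ", model_index, " out of range (file has ", nmod,
         " model(s))", call. = FALSE)
  if (model_index > 1L) {
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    keep <- pdb$atom$type == "ATOM"
    at$x <- xyz[keep, 1]; at$y <- xyz[keep, 2]; at$z <- xyz[keep, 3]
  }
  if (nrow(at) == 0) stop("no ATOM records in ", path, call. = FALSE)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  ## resolve altlocs: within (chain, resno, insert, elety) keep max occupancy
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  at <- at[order(key, -at$o), , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "|")), , drop = FALSE]
  rkey <- paste(at$chain, at$resno, at$insert, sep = "|")
  ord <- order(at$chain, at$resno, at$insert)
  at <- at[ord, , drop = FALSE]
  rkey <- rkey[ord]
  residues <- unique(rkey)
  n_all <- length(residues)
  seq1 <- character(n_all); chain <- character(n_all)
  resno <- integer(n_all); keep <- logical(n_all)
  coords <- array(NA_real_, c(n_all, 5, 3))
  for (k in seq_len(n_all)) {
    rows <- at[rkey == residues[k], , drop = FALSE]
    chain[k] <- rows$chain[1]
    resno[k] <- rows$resno[1]
    aa3 <- rows$resid[1]
    seq1[k] <- if (aa3 %in% names(AA3_TO_1)) AA3_TO_1[[aa3]] else "X"
    for (a in BACKBONE_ATOMS) {
      hit <- which(rows$elety == a)
      if (length(hit))
        coords[k, match(a, BACKBONE_ATOMS), ] <-
          as.numeric(rows[hit[1], c("x", "y", "z")])
    }
    keep[k] <- all(is.finite(coords[k, 1:3, ]))
  }
  if (any(!keep))
    warning(sprintf("dropped %d residue(s) missing N/CA/C", sum(!keep)),
            call. = FALSE)
  if (!any(keep)) stop("no complete residues in ", path, call. = FALSE)
  backbone_structure(seq1[keep], coords[keep, , , drop = FALSE],
                     chain_ids = chain[keep], residue_numbers = resno[keep])
}

#' Write a backbone structure to a PDB file
#'
#' Emits standard fixed-column ATOM records for the five stored backbone
#' atoms. An imputed CB (e.g. glycine) is not written. The B-factor column
#' can carry per-residue scores (pLDDT convention, 0-100 scale).
#'
#' @param s a `backbone_structure`.
#' @param path output file path.
#' @param bfactor optional per-residue value written to the B-factor column.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path, bfactor = NULL) {
  n <- length(s)
  if (is.null(bfactor)) bfactor <- rep(0, n)
  stopifnot(length(bfactor) == n)
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (i in seq_len(n)) {
    atoms <- BACKBONE_ATOMS
    if (!s$cb_present[i]) atoms <- setdiff(atoms, "CB")
    res3 <- if (s$sequence[i] %in% names(AA1_TO_3))
      AA1_TO_3[[s$sequence[i]]] else "UNK"
    for (a in atoms) {
      serial <- serial + 1L
      xyz <- s$coords[i, a, ]
      name_fmt <- if (nchar(a) < 4) sprintf(" %-3s", a) else a
      writeLines(sprintf(
        "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
        serial, name_fmt, res3, s$chain_ids[i], s$residue_numbers[i],
        xyz[1], xyz[2], xyz[3], 1.0, bfactor[i], substr(a, 1, 1)), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Apply a rigid transform to a structure
#'
#' Maps every stored coordinate `x -> R x + t`; sequence, chains and flags are
#' untouched. All pairwise distances are preserved.
#'
#' @param s a `backbone_structure`.
#' @param tr a [rigid_transform()].
#' @return The transformed `backbone_structure`.
#' @export
apply_transform <- function(s, tr) {
  stopifnot(inherits(tr, "rigid_transform"))
  for (a in BACKBONE_ATOMS) {
    m <- s$coords[, a, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    s$coords[, a, ] <- transform_points(m, tr)
  }
  s
}
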