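## Ground-truth labels: per-residue lDDT, per-pair distance-error bins and
## the 15 A inclusion mask used by the decoder heads.

LDDT_THRESHOLDS <- c(0.5, 1, 2, 4)
LDDT_RADIUS <- 15
ERROR_BIN_EDGES <- c(0, 0.5, 1, 2, 4, Inf)

ca_dist_matrix <- function(s) {
  as.matrix(stats::dist(ca_coords(s)))
}

check_label_inputs <- function(model, reference) {
  if (length(model) != length(reference))
    stop("model and reference lengths differ", call. = FALSE)
  if (!all(model$sequence == reference$sequence))
    stop("model and reference sequences differ", call. = FALSE)
  if (length(model) < 2)
    stop("need at least 2 residues", call. = FALSE)
}

#' Compute lDDT labels for a model against a reference
#'
#' Superposition-free local Distance Difference Test on CA atoms. For residue
#' i the score is the mean, over thresholds 0.5/1/2/4 A, of the fraction of
#' partners j (with reference CA distance < 15 A, j != i) whose model
#' distance deviates by less than the threshold. Residues with no in-radius
#' partner are reported as 1 and flagged.
#'
#' @param model,reference `backbone_structure`s of identical sequence/length.
#' @return An object of class `lddt_labels` with fields `local_lddt` (length
#'   N, in \[0,1\]), `global_lddt` (mean of local), `error_bins` (N x N
#'   integer classes 0..4 over |d_model - d_ref|), `threshold_mask` (N x N
#'   0/1, 1 iff d_ref < 15 and i != j) and `no_partner` (logical length N).
#' @export
compute_lddt <- function(model, reference) {
  check_label_inputs(model, reference)
  dm <- ca_dist_matrix(model)
  dr <- ca_dist_matrix(reference)
  n <- nrow(dr)
  mask <- (dr < LDDT_RADIUS) * 1
  diag(mask) <- 0
  delta <- abs(dm - dr)
  npair <- rowSums(mask)
  local <- numeric(n)
  for (s in LDDT_THRESHOLDS) local <- local + rowSums(mask * (delta < s))
  no_partner <- npair == 0
  local <- ifelse(no_partner, 1,
                  local / (length(LDDT_THRESHOLDS) * pmax(npair, 1)))
  bins <- matrix(findInterval(delta, ERROR_BIN_EDGES,
                              rightmost.closed = FALSE) - 1L, n, n)
  diag(bins) <- 0L
  local <- unname(local)
  structure(list(local_lddt = local, global_lddt = mean(local),
                 error_bins = unname(bins),
                 threshold_mask = unname(mask),
                 no_partner = unname(no_partner)),
            class = "lddt_labels")
}

#' Per-pair distance-error classes and the 15 A inclusion mask
#'
#' The classes bin the absolute CA-CA distance error into
#' \[0,0.5), \[0.5,1), \[1,2), \[2,4), \[4,Inf) (codes 0..4, half-open edges,
#' so an error of exactly 0.5 falls in class 1).
#'
#' @inheritParams compute_lddt
#' @return list with `error_bins` (N x N integer) and `threshold_mask`
#'   (N x N 0/1).
#' @export
label_error_bins <- function(model, reference) {
  lab <- compute_lddt(model, reference)
  list(error_bins = lab$error_bins, threshold_mask = lab$threshold_mask)
}

#' Write labels to disk
#'
#' Container format: an `.rds` file holding the `lddt_labels` list plus a
#' JSON sidecar (`<path>.json`) recording the array names and shapes.
#'
#' @param labels an `lddt_labels` object.
#' @param path output path (conventionally `labels.rds`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  saveRDS(unclass(labels), path)
  meta <- list(keys = names(labels),
               n_residues = length(labels$local_lddt),
               thresholds = LDDT_THRESHOLDS, radius = LDDT_RADIUS)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  structure(readRDS(path), class = "lddt_labels")
}
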