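## Uniform interface for protein language-model embeddings, with the
## dimensionalities used downstream (1280 single / 768 + 144 MSA / 512
## structural) and the 1022-residue split rule for long sequences.
## A deterministic mock provider makes the whole pipeline testable without
## model weights; real providers plug in behind the same interface.

EMBED_DIMS <- list(single = list(seq = 1280L, struct = 512L),
                   msa = list(seq = 768L, pair = 144L, struct = 512L))

#' Split a sequence for length-limited embedding models
#'
#' Sequences up to `limit` residues pass through as one segment. Longer
#' sequences (but shorter than `2 * limit`) are cut into two halves at
#' `floor(L / 2)`; segment embeddings are later concatenated in order, so the
#' reassembly map covers every index exactly once. Sequences of length
#' `>= 2 * limit` are refused.
#'
#' @param sequence one-letter sequence string.
#' @param limit maximum model input length (default 1022).
#' @return list with `segments` (character vector) and `map` (list of index
#'   vectors into the original sequence, one per segment).
#' @export
split_for_embedding <- function(sequence, limit = 1022L) {
  L <- nchar(sequence)
  stopifnot(L > 0)
  if (L >= 2L * limit)
    stop("unsupported sequence length ", L, " (limit ", 2L * limit - 1L, ")",
         call. = FALSE)
  if (L <= limit)
    return(list(segments = sequence, map = list(seq_len(L))))
  cut <- floor(L / 2)
  list(segments = c(substr(sequence, 1L, cut), substr(sequence, cut + 1L, L)),
       map = list(seq_len(cut), seq(cut + 1L, L)))
}

## per-residue pose-invariant scalar summaries used to make the mock
## structural embedding structure-sensitive
invariant_residue_scalars <- function(s) {
  ca <- ca_coords(s)
  ctr <- colMeans(ca)
  d <- ca_dist_matrix(s)
  cbind(sqrt(colSums((t(ca) - ctr)^2)),          # radial position
        rowMeans(d),                             # mean distance to others
        rowSums(d < 10) - 1)                     # 10 A neighbour count
}

#' Deterministic mock embedding provider
#'
#' Produces pseudo-random embeddings of the exact shapes a language-model
#' provider would return, as a pure function of (sequence, seed). The
#' structural embedding is additionally modulated by smooth pose-invariant
#' functions of the CA geometry so it is structure-sensitive (two decoys of
#' one sequence get different structural embeddings but identical sequence
#' embeddings).
#'
#' @param structure a `backbone_structure`.
#' @param mode `"single"` (1280-dim sequence embedding) or `"msa"` (768-dim
#'   sequence embedding plus an N x N x 144 pair-attention tensor).
#' @param seed integer seed.
#' @return An object of class `embedding_bundle` with `seq_embedding`
#'   (N x 1280 or N x 768), `struct_embedding` (N x 512), and for MSA mode
#'   `pair_attention` (N x N x 144).
#' @export
mock_embed <- function(structure, mode = c("single", "msa"), seed = 0L) {
  mode <- match.arg(mode)
  n <- length(structure)
  dims <- EMBED_DIMS[[mode]]
  seq_str <- paste(structure$sequence, collapse = "")
  base_seed <- (string_hash31(c(mode, seq_str)) + as.numeric(seed) * 7919) %%
    2147483647
  out <- with_seed(as.integer(base_seed), {
    seq_emb <- matrix(stats::rnorm(n * dims$seq, sd = 0.2), n, dims$seq)
    pair <- NULL
    if (mode == "msa")
      pair <- array(stats::rnorm(n * n * dims$pair, sd = 0.1),
                    c(n, n, dims$pair))
    w <- matrix(stats::rnorm(3 * dims$struct, sd = 0.5), 3, dims$struct)
    b <- stats::runif(dims$struct, 0, 2 * pi)
    base <- matrix(stats::rnorm(n * dims$struct, sd = 0.1), n, dims$struct)
    sc <- invariant_residue_scalars(structure)
    sc <- sweep(sc, 2, c(10, 10, 5), "/")
    struct_emb <- base + sin(sweep(sc %*% w, 2, b, "+"))
    list(seq_embedding = seq_emb, struct_embedding = struct_emb,
         pair_attention = pair)
  })
  structure(c(out, list(mode = mode, seed = as.integer(seed))),
            class = "embedding_bundle")
}

#' On-disk embedding cache
#'
#' Stores an `embedding_bundle` in an `.rds` container keyed by the sequence
#' hash; `read_embeddings` round-trips bit-exactly.
#'
#' @param bundle an `embedding_bundle`.
#' @param dir cache directory.
#' @param sequence the one-letter sequence string the bundle belongs to.
#' @return The cache file path (invisibly for write).
#' @export
write_embeddings <- function(bundle, dir, sequence) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("emb_%s_%d.rds",
                                 bundle$mode, string_hash31(sequence)))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname write_embeddings
#' @param mode embedding mode of the cached bundle.
#' @export
read_embeddings <- function(dir, sequence, mode = "single") {
  path <- file.path(dir, sprintf("emb_%s_%d.rds", mode,
                                 string_hash31(sequence)))
  if (!file.exists(path)) stop("no cached embeddings at ", path, call. = FALSE)
  readRDS(path)
}
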