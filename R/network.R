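## The graph-coupled quality-assessment network: graph-transformer encoder
## with edge-biased multi-head attention and gated residual updates,
## invariant-point-attention refinement in residue-local rigid frames, an
## E(3)-equivariant GNN stage on the KNN graph, pairwise decoding through a
## dilated-convolution residual trunk with inverted bottlenecks, and the
## cumulative error-bin scoring head that turns per-pair predictions into
## per-residue lDDT.
##
## Every layer is written against the internal autodiff ops, so the same code
## path serves plain (inference) and differentiable (training) execution.

#' Network hyper-parameter configuration
#'
#' Defaults: 3 graph-transformer layers (width 128, 8 heads of dimension 16),
#' 2 IPA blocks (4 heads, 4 points), 2 EGNN layers, a decoder trunk of 8
#' residual blocks at 64 channels with 4x inverted bottlenecks. All sizes are
#' configurable; tests and the training demo use a reduced configuration.
#'
#' @param ... overrides of the default fields.
#' @return A named list of hyper-parameters.
#' @export
network_config <- function(...) {
  cfg <- list(
    d_n = 128L, d_e = 64L,
    n_gt = 3L, n_heads = 8L, a_d = 16L,
    n_ipa = 2L, ipa_heads = 4L, ipa_points = 4L,
    n_egnn = 2L, egnn_dm = 32L, egnn_fourier = 8L,
    n_trunk = 8L, c_trunk = 64L, expand = 4L, d_star = 32L,
    K = 30L, mode = "single", init_seed = 42L)
  utils::modifyList(cfg, list(...))
}

#' Reduced configuration for desk-scale demonstrations
#'
#' The small architecture used by the package's training demonstration and
#' examples: 1 graph-transformer layer (2 heads of width 4), 1 IPA block
#' (2 heads, 2 points), 1 EGNN layer, a 2-block decoder trunk at 8 channels
#' with 2x bottleneck expansion, K = 10 neighbours. Sized so a 30-residue
#' protein trains in minutes on one CPU.
#'
#' @param ... overrides, as in [network_config()].
#' @return A [network_config()] list.
#' @export
toy_network_config <- function(...) {
  network_config(d_n = 16L, d_e = 8L, n_gt = 1L, n_heads = 2L, a_d = 4L,
                 n_ipa = 1L, ipa_heads = 2L, ipa_points = 2L,
                 n_egnn = 1L, egnn_dm = 8L, egnn_fourier = 4L,
                 n_trunk = 2L, c_trunk = 8L, expand = 2L, d_star = 8L,
                 K = 10L, ...)
}

xavier <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

add_ln <- function(P, name, d) {
  P[[paste0(name, "_ln_g")]] <- matrix(1, 1, d)
  P[[paste0(name, "_ln_o")]] <- matrix(0, 1, d)
  P
}

#' Initialise a quality-assessment model
#'
#' @param node_in_dim,edge_in_dim input feature widths (structural channels
#'   plus embedding channels for nodes).
#' @param config a [network_config()].
#' @param layout_hash feature-layout hash the model is bound to; scoring
#'   refuses inputs with a different layout.
#' @return list of class `mqa_model` with `params`, `config`, `layout_hash`.
#' @export
mqa_model <- function(node_in_dim, edge_in_dim, config = network_config(),
                      layout_hash = 0) {
  cf <- config
  with_seed(cf$init_seed, {
    P <- list()
    dn <- cf$d_n; de <- cf$d_e; H <- cf$n_heads; a <- cf$a_d
    P$node_in_w <- xavier(node_in_dim, dn); P$node_in_b <- matrix(0, 1, dn)
    P <- add_ln(P, "node_in", dn)
    P$edge_in_w <- xavier(edge_in_dim, de); P$edge_in_b <- matrix(0, 1, de)
    P <- add_ln(P, "edge_in", de)
    for (l in seq_len(cf$n_gt)) {
      p <- sprintf("gt%d_", l)
      P[[paste0(p, "wq")]] <- xavier(dn, H * a)
      P[[paste0(p, "wk")]] <- xavier(dn, H * a)
      P[[paste0(p, "wv")]] <- xavier(dn, H * a)
      P[[paste0(p, "wm")]] <- xavier(de, H * a)
      P[[paste0(p, "wo")]] <- xavier(H * a, dn)
      P[[paste0(p, "bo")]] <- matrix(0, 1, dn)
      P[[paste0(p, "wg")]] <- xavier(3L * dn, 1L)
      P[[paste0(p, "bg")]] <- matrix(0, 1, 1)
      P <- add_ln(P, paste0(p, "out"), dn)
    }
    Hi <- cf$ipa_heads; Pp <- cf$ipa_points
    for (l in seq_len(cf$n_ipa)) {
      p <- sprintf("ipa%d_", l)
      P[[paste0(p, "wq")]] <- xavier(dn, Hi * a)
      P[[paste0(p, "wk")]] <- xavier(dn, Hi * a)
      P[[paste0(p, "wv")]] <- xavier(dn, Hi * a)
      P[[paste0(p, "wqp")]] <- xavier(dn, Hi * Pp * 3L) * 0.1
      P[[paste0(p, "wkp")]] <- xavier(dn, Hi * Pp * 3L) * 0.1
      P[[paste0(p, "wvp")]] <- xavier(dn, Hi * Pp * 3L) * 0.1
      P[[paste0(p, "wb")]] <- xavier(de, Hi)
      P[[paste0(p, "gamma")]] <- matrix(0.5, 1, Hi)
      d_out <- Hi * (a + 4L * Pp)          # scalars + local points + norms
      P[[paste0(p, "wo")]] <- xavier(d_out, dn)
      P[[paste0(p, "bo")]] <- matrix(0, 1, dn)
      P <- add_ln(P, paste0(p, "att"), dn)
      P[[paste0(p, "wt1")]] <- xavier(dn, dn); P[[paste0(p, "bt1")]] <- matrix(0, 1, dn)
      P[[paste0(p, "wt2")]] <- xavier(dn, dn); P[[paste0(p, "bt2")]] <- matrix(0, 1, dn)
      P <- add_ln(P, paste0(p, "tr"), dn)
    }
    P$coord_w <- xavier(dn, 3L) * 0.1; P$coord_b <- matrix(0, 1, 3)
    dm <- cf$egnn_dm; Ff <- cf$egnn_fourier
    for (l in seq_len(cf$n_egnn)) {
      p <- sprintf("egnn%d_", l)
      d_in <- 2L * dn + 2L * Ff + de
      P[[paste0(p, "wm1")]] <- xavier(d_in, dm); P[[paste0(p, "bm1")]] <- matrix(0, 1, dm)
      P[[paste0(p, "wm2")]] <- xavier(dm, dm); P[[paste0(p, "bm2")]] <- matrix(0, 1, dm)
      P[[paste0(p, "ww")]] <- xavier(dm, 1L) * 0.1; P[[paste0(p, "bw")]] <- matrix(0, 1, 1)
      P[[paste0(p, "wv1")]] <- xavier(dm + dn, dn); P[[paste0(p, "bv1")]] <- matrix(0, 1, dn)
      P[[paste0(p, "wv2")]] <- xavier(dn, dn); P[[paste0(p, "bv2")]] <- matrix(0, 1, dn)
      P <- add_ln(P, paste0(p, "out"), dn)
    }
    ds <- cf$d_star
    P$vstar_w <- xavier(node_in_dim, ds); P$vstar_b <- matrix(0, 1, ds)
    P$estar_w <- xavier(edge_in_dim, ds); P$estar_b <- matrix(0, 1, ds)
    c0 <- dn + ds + de + ds
    ct <- cf$c_trunk; ce <- ct * cf$expand
    P$dec_in_w <- xavier(c0, ct); P$dec_in_b <- matrix(0, 1, ct)
    mk_block <- function(P, p) {
      P <- add_ln(P, paste0(p, "n"), ct)
      P[[paste0(p, "w1")]] <- xavier(9L * ct, ce); P[[paste0(p, "b1")]] <- matrix(0, 1, ce)
      P[[paste0(p, "w2")]] <- xavier(9L * ce, ct); P[[paste0(p, "b2")]] <- matrix(0, 1, ct)
      P[[paste0(p, "w3")]] <- xavier(ct, ct); P[[paste0(p, "b3")]] <- matrix(0, 1, ct)
      P
    }
    for (b in seq_len(cf$n_trunk)) P <- mk_block(P, sprintf("dec%d_", b))
    P <- mk_block(P, "errb_")
    P <- mk_block(P, "cutb_")
    P$err_head_w <- xavier(ct, 5L); P$err_head_b <- matrix(0, 1, 5)
    P$cut_head_w <- xavier(ct, 1L); P$cut_head_b <- matrix(0, 1, 1)
    structure(list(params = P, config = cf, layout_hash = layout_hash),
              class = "mqa_model")
  })
}

#' @export
print.mqa_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<mqa_model> %d parameters, d_n=%d, %d GT / %d IPA / %d EGNN / %d trunk\n",
              np, x$config$d_n, x$config$n_gt, x$config$n_ipa,
              x$config$n_egnn, x$config$n_trunk))
  invisible(x)
}

## ---- forward-pass constants -----------------------------------------------

#' Precompute the per-structure constants of a forward pass
#'
#' Assembles features, flattens edges, gathers graph indexing, residue
#' frames and convolution index tables into the constant bundle consumed by
#' [mqa_forward()].
#'
#' @param structure a `backbone_structure`.
#' @param embeddings an `embedding_bundle` for the same structure.
#' @param config a [network_config()].
#' @param features optional precomputed [assemble_features()] bundle.
#' @return list of forward constants (documented fields include `node_in`,
#'   `edge_in`, `ipair`, `jpair`, `R9`, `coords`, `layout_hash`).
#' @export
prepare_inputs <- function(structure, embeddings, config = network_config(),
                           features = NULL) {
  n <- length(structure)
  fcfg <- feature_config_default()
  fcfg$K <- config$K
  fb <- if (is.null(features)) assemble_features(structure, fcfg) else features
  k <- fb$graph$K
  node_in <- cbind(fb$node, embeddings$seq_embedding,
                   embeddings$struct_embedding)
  de_raw <- dim(fb$edge)[3]
  ipair <- rep(seq_len(n), each = k)
  jpair <- as.integer(t(fb$graph$knn_indices))
  ef <- matrix(0, n * k, de_raw)
  for (cc in seq_len(de_raw)) ef[, cc] <- as.vector(t(fb$edge[, , cc]))
  if (config$mode == "msa" && !is.null(embeddings$pair_attention)) {
    pa <- embeddings$pair_attention
    pa_flat <- matrix(0, n * k, dim(pa)[3])
    for (r in seq_len(n * k)) pa_flat[r, ] <- pa[ipair[r], jpair[r], ]
    ef <- cbind(ef, pa_flat)
  }
  R9 <- t(vapply(fb$frames, function(f) as.numeric(f$rotation), numeric(9)))
  coords <- ca_coords(structure)
  i_flat <- rep(seq_len(n), times = n)
  j_flat <- rep(seq_len(n), each = n)
  dil <- unique(c(1L, c(1L, 4L, 9L, 16L)[((seq_len(config$n_trunk) - 1L) %% 4L) + 1L]))
  conv_idx <- stats::setNames(lapply(dil, function(d) conv_im2col_idx(n, d)),
                              as.character(dil))
  list(n = n, k = k, node_in = node_in, edge_in = ef,
       ipair = ipair, jpair = jpair,
       flat_knn = ipair + (jpair - 1L) * n,
       i_flat = i_flat, j_flat = j_flat,
       perm_t = j_flat + (i_flat - 1L) * n,
       offdiag = matrix(as.numeric(i_flat != j_flat), ncol = 1),
       R9 = R9, coords = coords, conv_idx = conv_idx,
       layout_hash = fb$layout_hash)
}

## ---- layers ---------------------------------------------------------------

head_cols <- function(hh, a) ((hh - 1L) * a + 1L):(hh * a)

#' Graph-transformer layer with edge-biased attention and gated residual
#'
#' Each residue attends over all residues with scaled dot-product attention;
#' edge projections of the KNN edge features bias both the logits and the
#' values. The updated embedding is mixed with the input through a learned
#' sigmoid gate, then layer-normalised.
#'
#' @param h node representation (N x d_n), plain matrix or `ad` node.
#' @param e edge representation (N*K x d_e).
#' @param fwd constants from `prepare_inputs`.
#' @param P parameter list (plain or `ad`-wrapped).
#' @param prefix parameter name prefix, e.g. `"gt1_"`.
#' @param config a [network_config()].
#' @return updated node representation (same type as input).
#' @export
graph_transformer_layer <- function(h, e, fwd, P, prefix, config) {
  n <- fwd$n; a <- config$a_d; H <- config$n_heads
  g <- function(s) P[[paste0(prefix, s)]]
  Q <- ad_linear(h, g("wq"))
  K_ <- ad_linear(h, g("wk"))
  V <- ad_linear(h, g("wv"))
  M <- ad_linear(e, g("wm"))
  heads <- vector("list", H)
  for (hh in seq_len(H)) {
    cols <- head_cols(hh, a)
    heads[[hh]] <- ad_gt_head(ad_slice_cols(Q, cols), ad_slice_cols(K_, cols),
                              ad_slice_cols(V, cols), ad_slice_cols(M, cols),
                              fwd$ipair, fwd$flat_knn, n, a)
  }
  hbar <- ad_linear(ad_concat_cols(heads), g("wo"), g("bo"))
  gate_in <- ad_concat_cols(list(ad_sub(h, hbar), h, hbar))
  c1 <- ad_sigmoid(ad_linear(gate_in, g("wg"), g("bg")))
  hup <- ad_add(ad_mul_colvec(h, c1), ad_mul_colvec(hbar, ad_sub(1, c1)))
  ad_layernorm(hup, g("out_ln_g"), g("out_ln_o"))
}

#' Invariant point attention block
#'
#' Attention in residue-local rigid frames: scalar queries/keys, learned 3D
#' point queries/keys/values lifted to the global frame, an edge-bias term,
#' and a squared point-distance penalty per head. Scalar outputs are
#' invariant under any global rigid transform of frames and coordinates;
#' attended value points are mapped back into each residue's local frame.
#' Followed by a residual + layer norm and a transition MLP.
#'
#' @inheritParams graph_transformer_layer
#' @return updated node representation.
#' @export
ipa_block <- function(h, e, fwd, P, prefix, config) {
  n <- fwd$n; a <- config$a_d
  H <- config$ipa_heads; Pp <- config$ipa_points
  g <- function(s) P[[paste0(prefix, s)]]
  cr <- do.call(cbind, rep(list(fwd$coords), Pp))   # N x 3P tiled origins
  Q <- ad_linear(h, g("wq")); K_ <- ad_linear(h, g("wk"))
  V <- ad_linear(h, g("wv"))
  QP <- ad_linear(h, g("wqp")); KP <- ad_linear(h, g("wkp"))
  VP <- ad_linear(h, g("wvp"))
  B <- ad_linear(e, g("wb"))
  wc <- sqrt(2 / (9 * Pp))
  outs <- vector("list", H)
  for (hh in seq_len(H)) {
    cols <- head_cols(hh, a)
    pcols <- ((hh - 1L) * Pp * 3L + 1L):(hh * Pp * 3L)
    gamma <- ad_softplus(ad_slice_cols(g("gamma"), hh))
    outs[[hh]] <- ad_ipa_head(
      ad_slice_cols(Q, cols), ad_slice_cols(K_, cols), ad_slice_cols(V, cols),
      ad_slice_cols(QP, pcols), ad_slice_cols(KP, pcols),
      ad_slice_cols(VP, pcols), ad_slice_cols(B, hh), gamma,
      fwd$R9, cr, fwd$flat_knn, n, a, Pp, wc)
  }
  upd <- ad_linear(ad_concat_cols(outs), g("wo"), g("bo"))
  h <- ad_layernorm(ad_add(h, upd), g("att_ln_g"), g("att_ln_o"))
  t1 <- ad_gelu(ad_linear(h, g("wt1"), g("bt1")))
  t2 <- ad_linear(t1, g("wt2"), g("bt2"))
  ad_layernorm(ad_add(h, t2), g("tr_ln_g"), g("tr_ln_o"))
}

#' E(3)-equivariant GNN layer on the KNN graph
#'
#' Messages are built from the two node states, Fourier features of the
#' inter-node distance and the edge state; the coordinate channel is updated
#' along difference vectors with a learned scalar weight and the 1/(N-1)
#' normalisation, so coordinates transform covariantly with any rigid motion
#' while node features stay invariant.
#'
#' @inheritParams graph_transformer_layer
#' @param x coordinate matrix (N x 3), plain or `ad`.
#' @return list with `h` (updated nodes) and `x` (updated coordinates).
#' @export
egnn_layer <- function(h, e, x, fwd, P, prefix, config) {
  n <- fwd$n
  if (n < 2) stop("EGNN coordinate normalisation undefined for N = 1",
                  call. = FALSE)
  g <- function(s) P[[paste0(prefix, s)]]
  freqs <- matrix(2^(seq_len(config$egnn_fourier) - 1) / 4, nrow = 1)
  W <- list(wm1 = g("wm1"), bm1 = g("bm1"), wm2 = g("wm2"), bm2 = g("bm2"),
            ww = g("ww"), bw = g("bw"), wv1 = g("wv1"), bv1 = g("bv1"),
            wv2 = g("wv2"), bv2 = g("bv2"),
            g = g("out_ln_g"), o = g("out_ln_o"))
  res <- ad_egnn_fused(h, e, x, W, fwd$ipair, fwd$jpair, n, freqs)
  if (is.list(res)) return(res)          # plain path
  d_n <- ncol(ad_val(res)) - 3L
  list(h = ad_slice_cols(res, seq_len(d_n)),
       x = ad_slice_cols(res, d_n + 1:3))
}

#' Assemble the pairwise decoder input map
#'
#' Concatenates, per ordered pair (i, j): the encoder node state of residue i
#' (row-tiled), a fresh projection of the raw node features of i, the dense
#' scattered encoder edge state, and a fresh projection of the raw edge
#' features (off-graph pairs are zero). New projections use their own
#' parameters, separate from the encoder input projections.
#'
#' @inheritParams graph_transformer_layer
#' @return an `(N^2) x C` map (flat, column-major over the (i, j) grid).
#' @export
assemble_pair_map <- function(h, e, fwd, P) {
  n <- fwd$n
  vstar <- ad_linear(fwd$node_in, P$vstar_w, P$vstar_b)
  estar <- ad_linear(fwd$edge_in, P$estar_w, P$estar_b)
  vcat <- ad_concat_cols(list(h, vstar))
  node_part <- ad_gather_rows(vcat, fwd$i_flat)
  ehat_d <- ad_scatter_rows(e, fwd$flat_knn, n * n)
  estar_d <- ad_scatter_rows(estar, fwd$flat_knn, n * n)
  ad_concat_cols(list(node_part, ehat_d, estar_d))
}

## fused residual stack (C++): each block is
## LN -> GELU -> conv3x3(dil) -> GELU -> conv3x3(dil) -> GELU -> 1x1 -> +x
dec_stack <- function(x, fwd, P, prefixes, dils) {
  pnames <- c("n_ln_g", "n_ln_o", "w1", "b1", "w2", "b2", "w3", "b3")
  plist <- lapply(seq_along(prefixes), function(b) {
    p <- prefixes[b]
    list(lng = ad_val(P[[paste0(p, "n_ln_g")]]),
         lno = ad_val(P[[paste0(p, "n_ln_o")]]),
         W1 = ad_val(P[[paste0(p, "w1")]]),
         b1 = ad_val(P[[paste0(p, "b1")]]),
         W2 = ad_val(P[[paste0(p, "w2")]]),
         b2 = ad_val(P[[paste0(p, "b2")]]),
         W3 = ad_val(P[[paste0(p, "w3")]]),
         b3 = ad_val(P[[paste0(p, "b3")]]))
  })
  idxs <- lapply(dils, function(d) fwd$conv_idx[[as.character(d)]])
  res <- decoder_fwd_cpp(ad_val(x), plist, idxs)
  track <- is_ad(x) || is_ad(P[[paste0(prefixes[1], "w1")]])
  if (!track) return(res$out)
  parents <- list(x)
  for (p in prefixes) for (nm in pnames)
    parents[[length(parents) + 1L]] <- P[[paste0(p, nm)]]
  new_ad(res$out, parents, function(g) {
    bw <- decoder_bwd_cpp(g, plist, idxs, res$stash)
    out <- list(if (is_ad(x)) bw$gx)
    for (b in seq_along(prefixes)) {
      gb <- bw$grads[[b]]
      out <- c(out, list(gb$lng, gb$lno, gb$W1, gb$b1, gb$W2, gb$b2,
                         gb$W3, gb$b3))
    }
    out
  })
}

symmetrize_pairs <- function(z, fwd) {
  ad_scale(ad_add(z, ad_gather_rows(z, fwd$perm_t)), 0.5)
}

#' Decode a pair map into error-bin and threshold heads
#'
#' Residual trunk of dilated 3x3 convolution blocks (dilations cycling
#' 1, 4, 9, 16) with inverted bottlenecks, then two branch residual blocks:
#' the error block emits 5-class distance-error probabilities (softmax) and
#' the cutoff block a 15 A contact probability (sigmoid). Both heads are
#' symmetrised by averaging logits over (i, j) and (j, i).
#'
#' @param mcat `(N^2) x C` pair map from [assemble_pair_map()].
#' @inheritParams graph_transformer_layer
#' @return list with `error_probs` (N^2 x 5), `threshold_probs` (N^2 x 1)
#'   and the pre-activation `error_logits`, `threshold_logits`.
#' @export
decode <- function(mcat, fwd, P, config) {
  dil_cycle <- c(1L, 4L, 9L, 16L)
  x <- ad_linear(mcat, P$dec_in_w, P$dec_in_b)
  trunk_dils <- dil_cycle[((seq_len(config$n_trunk) - 1L) %% 4L) + 1L]
  x <- dec_stack(x, fwd, P, sprintf("dec%d_", seq_len(config$n_trunk)),
                 trunk_dils)
  xe <- dec_stack(x, fwd, P, "errb_", 1L)
  ze <- symmetrize_pairs(ad_linear(xe, P$err_head_w, P$err_head_b), fwd)
  xc <- dec_stack(x, fwd, P, "cutb_", 1L)
  zc <- symmetrize_pairs(ad_linear(xc, P$cut_head_w, P$cut_head_b), fwd)
  list(error_probs = ad_softmax_rows(ze), threshold_probs = ad_sigmoid(zc),
       error_logits = ze, threshold_logits = zc)
}

## differentiable cumulative-bin lDDT scoring on flat (N^2) heads
ad_score_lddt <- function(error_probs, threshold_probs, fwd) {
  n <- fwd$n
  w <- ad_mul(threshold_probs, fwd$offdiag)
  msum <- NULL
  for (s in 1:4) {
    cum <- ad_rowsums(ad_slice_cols(error_probs, seq_len(s)))
    msum <- if (is.null(msum)) cum else ad_add(msum, cum)
  }
  numer <- ad_rowsums(ad_reshape(ad_mul(w, msum), n, n))
  denom <- ad_rowsums(ad_reshape(w, n, n))
  ad_clip(ad_div(numer, ad_add(ad_scale(denom, 4), 1e-9)), 0, 1)
}

#' Predicted lDDT from error-bin and threshold probabilities
#'
#' Cumulative scoring head: for thresholds s in \{0.5, 1, 2, 4\} A the mass
#' of error bins below s, weighted by the 15 A contact probability, summed
#' over partners and normalised by the number of thresholds times the summed
#' contact mass. Feeding exact one-hot labels reproduces the ground-truth
#' lDDT. Residues whose contact mass is zero score 0 and are flagged.
#'
#' @param error_probs `N x N x 5` array (rows of bin probabilities) or an
#'   `N^2 x 5` matrix.
#' @param threshold_probs `N x N` matrix (or `N^2` vector) in \[0, 1\].
#' @return list with `pred_local_lddt` (length N), `pred_global` and
#'   `no_support` flag vector.
#' @export
score_lddt <- function(error_probs, threshold_probs) {
  if (length(dim(error_probs)) == 3L) {
    n <- dim(error_probs)[1]
    ep <- matrix(error_probs, n * n, dim(error_probs)[3])
  } else {
    ep <- error_probs
    n <- as.integer(sqrt(nrow(ep)))
  }
  tp <- matrix(as.numeric(threshold_probs), n, n)
  diag(tp) <- 0
  cum <- ep[, 1] * 0
  msum <- rep(0, n * n)
  for (s in 1:4) msum <- msum + rowSums(ep[, seq_len(s), drop = FALSE])
  contrib <- matrix(as.numeric(tp) * msum, n, n)
  numer <- rowSums(contrib)
  denom <- rowSums(tp)
  no_support <- denom == 0
  pred <- ifelse(no_support, 0, numer / (4 * pmax(denom, 1e-300)))
  pred <- pmin(pmax(pred, 0), 1)
  list(pred_local_lddt = pred, pred_global = mean(pred),
       no_support = no_support)
}

#' Full forward pass of the quality-assessment network
#'
#' Runs encoder (graph transformer, IPA, EGNN), pair-map assembly, decoder
#' and the scoring head. With `train = TRUE` parameters are wrapped as
#' autodiff leaves and the returned fields are `ad` nodes ready for
#' [compute_loss()] / [ad_backward()].
#'
#' @param model an [mqa_model()].
#' @param fwd constants from `prepare_inputs`.
#' @param train build a gradient tape?
#' @return list with plain or `ad` fields: `error_probs`, `threshold_probs`,
#'   `error_logits`, `threshold_logits`, `pred_local` (N x 1),
#'   `pred_global`, `coords_pred`, `h`, and `params_ad` when training.
#' @export
mqa_forward <- function(model, fwd, train = FALSE) {
  cf <- model$config
  P <- if (train) lapply(model$params, ad_param) else model$params
  h <- ad_layernorm(ad_linear(fwd$node_in, P$node_in_w, P$node_in_b),
                    P$node_in_ln_g, P$node_in_ln_o)
  e <- ad_layernorm(ad_linear(fwd$edge_in, P$edge_in_w, P$edge_in_b),
                    P$edge_in_ln_g, P$edge_in_ln_o)
  for (l in seq_len(cf$n_gt))
    h <- graph_transformer_layer(h, e, fwd, P, sprintf("gt%d_", l), cf)
  for (l in seq_len(cf$n_ipa))
    h <- ipa_block(h, e, fwd, P, sprintf("ipa%d_", l), cf)
  x <- ad_add(fwd$coords, ad_rot3(ad_linear(h, P$coord_w, P$coord_b), fwd$R9))
  for (l in seq_len(cf$n_egnn)) {
    eg <- egnn_layer(h, e, x, fwd, P, sprintf("egnn%d_", l), cf)
    h <- eg$h; x <- eg$x
  }
  mcat <- assemble_pair_map(h, e, fwd, P)
  dec <- decode(mcat, fwd, P, cf)
  ## during training the loss differentiates the logits directly, so the
  ## scoring chain is evaluated on plain values
  pred <- if (train) {
    matrix(score_lddt(matrix(ad_val(dec$error_probs), ncol = 5),
                      ad_val(dec$threshold_probs))$pred_local_lddt, ncol = 1)
  } else {
    ad_score_lddt(dec$error_probs, dec$threshold_probs, fwd)
  }
  list(error_probs = dec$error_probs, threshold_probs = dec$threshold_probs,
       error_logits = dec$error_logits,
       threshold_logits = dec$threshold_logits,
       pred_local = pred, pred_global = ad_mean(pred),
       coords_pred = x, h = h,
       params_ad = if (train) P else NULL)
}

#' Save / load a model checkpoint
#'
#' Container: `.rds` with the parameter list plus an embedded JSON config
#' string and the feature-layout hash. Loading refuses a checkpoint whose
#' layout hash differs from `expect_layout_hash`.
#'
#' @param model an `mqa_model`.
#' @param path checkpoint path.
#' @param expect_layout_hash if non-NULL, required layout hash.
#' @return the model (invisibly for save).
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(params = model$params,
              config_json = jsonlite::toJSON(model$config, auto_unbox = TRUE),
              layout_hash = model$layout_hash)
  saveRDS(obj, path)
  invisible(model)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, expect_layout_hash = NULL) {
  obj <- readRDS(path)
  cfg <- jsonlite::fromJSON(obj$config_json)
  cfg[c("d_n", "d_e", "n_gt", "n_heads", "a_d", "n_ipa", "ipa_heads",
        "ipa_points", "n_egnn", "egnn_dm", "egnn_fourier", "n_trunk",
        "c_trunk", "expand", "d_star", "K", "init_seed")] <-
    lapply(cfg[c("d_n", "d_e", "n_gt", "n_heads", "a_d", "n_ipa", "ipa_heads",
                 "ipa_points", "n_egnn", "egnn_dm", "egnn_fourier", "n_trunk",
                 "c_trunk", "expand", "d_star", "K", "init_seed")], as.integer)
  if (!is.null(expect_layout_hash) &&
      !isTRUE(all.equal(obj$layout_hash, expect_layout_hash)))
    stop("checkpoint feature-layout hash mismatch: refuse to score",
         call. = FALSE)
  structure(list(params = obj$params, config = cfg,
                 layout_hash = obj$layout_hash), class = "mqa_model")
}
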