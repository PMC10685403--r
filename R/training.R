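## Composite loss and the desk-scale training loop.

#' Loss weights
#'
#' All components default to weight 1.
#'
#' @param geometric,error_ce,threshold_bce,lddt_mse non-negative weights.
#' @return named list.
#' @export
loss_weights <- function(geometric = 1, error_ce = 1, threshold_bce = 1,
                         lddt_mse = 1) {
  list(geometric = geometric, error_ce = error_ce,
       threshold_bce = threshold_bce, lddt_mse = lddt_mse)
}

#' Composite training loss
#'
#' `geometric`: mean squared error between the encoder's predicted CA
#' coordinates (after optimal rigid superposition onto the reference, Kabsch,
#' with the alignment treated as constant) and the reference CA coordinates,
#' plus the mean L1 error between predicted and reference pairwise CA
#' distances. `error_ce`: categorical cross-entropy of the 5 error bins,
#' masked to reference pairs within 15 A. `threshold_bce`: binary
#' cross-entropy of the 15 A contact head over off-diagonal pairs.
#' `lddt_mse`: mean squared error between predicted and true per-residue
#' lDDT. `total` is the weighted sum and (when the forward pass was built
#' with `train = TRUE`) a differentiable node.
#'
#' @param out result of [mqa_forward()].
#' @param labels `lddt_labels` for the same model/reference pair.
#' @param reference the reference `backbone_structure`.
#' @param fwd forward constants used for the pass.
#' @param weights a [loss_weights()] list.
#' @return list of class `loss_breakdown`: numeric `l_geometric`,
#'   `l_error_ce`, `l_threshold_bce`, `l_lddt_mse`, `total_value`, plus
#'   `total` (the `ad` node or plain numeric).
#' @export
compute_loss <- function(out, labels, reference, fwd,
                         weights = loss_weights(), cache = NULL) {
  if (is.null(cache)) cache <- loss_cache(labels, reference, fwd)
  al <- kabsch(ad_val(out$coords_pred), cache$ref_ca)
  total <- ad_loss_head(out$error_logits, out$threshold_logits,
                        out$coords_pred, cache, fwd, weights, al)
  comp <- attr(total, "components")
  structure(list(l_geometric = unname(comp["l_geometric"]),
                 l_error_ce = unname(comp["l_error_ce"]),
                 l_threshold_bce = unname(comp["l_threshold_bce"]),
                 l_lddt_mse = unname(comp["l_lddt_mse"]),
                 total_value = as.numeric(ad_val(total)),
                 total = total),
            class = "loss_breakdown")
}

## per-item constants of the loss that do not change across epochs
loss_cache <- function(labels, reference, fwd) {
  n <- fwd$n
  maskv <- matrix(as.numeric(labels$threshold_mask), ncol = 1)
  onehot <- matrix(0, n * n, 5)
  onehot[cbind(seq_len(n * n), as.integer(labels$error_bins) + 1L)] <- 1
  list(ref_ca = ca_coords(reference),
       dref = matrix(as.numeric(ca_dist_matrix(reference)), ncol = 1),
       maskv = maskv, mask_sum = sum(maskv),
       onehot_m = onehot * as.numeric(maskv),
       local_col = matrix(labels$local_lddt, ncol = 1))
}

## Flat AdamW: parameters are updated as one concatenated vector.
## Decoupled weight decay; layer norms, biases and gammas are not decayed.
adamw_init <- function(params) {
  sizes <- vapply(params, length, integer(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  ntot <- ends[length(ends)]
  decay_mask <- rep(1, ntot)
  for (k in seq_along(params))
    if (grepl("(_b[a-z0-9]*$|_ln_|_b$|gamma)", names(params)[k]))
      decay_mask[starts[k]:ends[k]] <- 0
  list(m = numeric(ntot), v = numeric(ntot), t = 0L,
       starts = starts, ends = ends, names = names(params),
       dims = lapply(params, dim), decay_mask = decay_mask)
}

flatten_params <- function(params, state) {
  out <- numeric(state$ends[length(state$ends)])
  for (k in seq_along(params))
    out[state$starts[k]:state$ends[k]] <- params[[k]]
  out
}

unflatten_params <- function(flat, state) {
  out <- vector("list", length(state$names))
  names(out) <- state$names
  for (k in seq_along(out)) {
    v <- flat[state$starts[k]:state$ends[k]]
    dim(v) <- state$dims[[k]]
    out[[k]] <- v
  }
  out
}

adamw_step_flat <- function(flat, gflat, state, lr, beta1 = 0.9,
                            beta2 = 0.999, eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * gflat
  state$v <- beta2 * state$v + (1 - beta2) * gflat^2
  ## flush vanishing moments to zero: decaying moments of dead directions
  ## otherwise drift into denormal range and stall vector arithmetic
  state$m[abs(state$m) < 1e-120] <- 0
  state$v[state$v < 1e-240] <- 0
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  flat <- flat - lr * (mhat / (sqrt(vhat) + eps) +
                       weight_decay * state$decay_mask * flat)
  list(flat = flat, state = state)
}

#' Training configuration
#'
#' @param epochs epoch count.
#' @param lr initial AdamW learning rate (decays by `lr_decay` per epoch).
#' @param lr_decay multiplicative per-epoch decay factor (1% decay = 0.99).
#' @param weight_decay AdamW decoupled weight decay.
#' @param val_fraction held-out fraction (4% of the models).
#' @param weights a [loss_weights()] list.
#' @param seed RNG seed for shuffling and the validation split.
#' @param keep_top checkpoints retained (best by validation Pearson).
#' @param verbose print one line per epoch?
#' @return named list.
#' @export
training_config <- function(epochs = 40L, lr = 1e-3, lr_decay = 0.99,
                            weight_decay = 0.01, val_fraction = 0.04,
                            weights = loss_weights(), seed = 0L,
                            keep_top = 5L, verbose = FALSE) {
  list(epochs = as.integer(epochs), lr = lr, lr_decay = lr_decay,
       weight_decay = weight_decay, val_fraction = val_fraction,
       weights = weights, seed = as.integer(seed),
       keep_top = as.integer(keep_top), verbose = isTRUE(verbose))
}

#' Flatten decoy ensembles into per-model training items
#'
#' Precomputes features, mock embeddings and forward constants once per
#' decoy so repeated epochs only pay for network passes.
#'
#' @param ensembles a `decoy_ensemble` or list of them.
#' @param model the [mqa_model()] whose config decides mode and K.
#' @param embed_seed seed offset for the mock embedding provider.
#' @return list of items (`fwd`, `labels`, `reference`).
#' @export
prepare_training_items <- function(ensembles, model, embed_seed = 0L) {
  if (inherits(ensembles, "decoy_ensemble")) ensembles <- list(ensembles)
  items <- list()
  for (ens in ensembles) {
    for (d in seq_along(ens$decoys)) {
      dec <- ens$decoys[[d]]
      emb <- mock_embed(dec, mode = model$config$mode,
                        seed = embed_seed + d)
      fwd <- prepare_inputs(dec, emb, model$config)
      items[[length(items) + 1L]] <- list(fwd = fwd, labels = ens$labels[[d]],
                                          reference = ens$reference)
    }
  }
  items
}

pooled_pearson <- function(model, items) {
  pred <- c(); truth <- c()
  for (it in items) {
    out <- mqa_forward(model, it$fwd, train = FALSE)
    pred <- c(pred, as.numeric(out$pred_local))
    truth <- c(truth, it$labels$local_lddt)
  }
  if (stats::sd(pred) < 1e-12 || stats::sd(truth) < 1e-12) return(0)
  stats::cor(pred, truth)
}

## Destroy the label-structure mapping (sanity control): permute label sets
## across models and permute residue assignment within each.
shuffle_item_labels <- function(items, seed) {
  with_seed(seed, {
    perm <- sample(length(items))
    for (k in seq_along(items)) {
      lab <- items[[perm[k]]]$labels
      n <- length(lab$local_lddt)
      rp <- sample(n)
      lab$local_lddt <- lab$local_lddt[rp]
      lab$global_lddt <- mean(lab$local_lddt)
      lab$error_bins <- lab$error_bins[rp, rp]
      lab$threshold_mask <- lab$threshold_mask[rp, rp]
      items[[k]]$labels_shuffled <- lab
    }
  })
  for (k in seq_along(items)) items[[k]]$labels <- items[[k]]$labels_shuffled
  items
}

#' Train the quality-assessment network on decoy ensembles
#'
#' Batch size is one model; 4% of models are held out for validation; the
#' learning rate decays 1% per epoch; per-residue validation Pearson is
#' tracked each epoch and the best `keep_top` parameter snapshots retained
#' (the best one is returned). Fully deterministic given the seeds.
#'
#' @param ensembles a `decoy_ensemble` or list of them.
#' @param model an [mqa_model()] (its config decides mode and sizes).
#' @param config a [training_config()].
#' @param shuffle_labels if TRUE, train against a label set whose
#'   model/residue assignment has been destroyed (negative control).
#' @param items optional precomputed training items (overrides `ensembles`).
#' @return list of class `mqa_fit`: `model` (best), `history` (data.frame
#'   with epoch, mean losses, val_pearson, lr), `val_idx`, `top_models`.
#' @export
train_mqa <- function(ensembles, model, config = training_config(),
                      shuffle_labels = FALSE, items = NULL) {
  if (is.null(items))
    items <- prepare_training_items(ensembles, model, embed_seed = config$seed)
  for (k in seq_along(items))
    if (is.null(items[[k]]$cache))
      items[[k]]$cache <- loss_cache(items[[k]]$labels, items[[k]]$reference,
                                     items[[k]]$fwd)
  n_items <- length(items)
  if (n_items < 2) stop("need at least 2 models to split train/validation",
                        call. = FALSE)
  if (shuffle_labels) {
    items <- shuffle_item_labels(items, config$seed + 7L)
    for (k in seq_along(items))
      items[[k]]$cache <- loss_cache(items[[k]]$labels, items[[k]]$reference,
                                     items[[k]]$fwd)
  }
  n_val <- max(1L, ceiling(config$val_fraction * n_items))
  val_idx <- with_seed(config$seed + 1L, sample(n_items, n_val))
  tr_idx <- setdiff(seq_len(n_items), val_idx)
  params <- model$params
  state <- adamw_init(params)
  flat <- flatten_params(params, state)
  hist <- data.frame()
  top <- list()
  for (ep in seq_len(config$epochs)) {
    lr <- config$lr * config$lr_decay^(ep - 1)
    ord <- with_seed(config$seed + 100L + ep, sample(tr_idx))
    comp <- c(l_geometric = 0, l_error_ce = 0, l_threshold_bce = 0,
              l_lddt_mse = 0, total = 0)
    mdl <- structure(list(params = params, config = model$config,
                          layout_hash = model$layout_hash),
                     class = "mqa_model")
    for (ii in ord) {
      it <- items[[ii]]
      out <- mqa_forward(mdl, it$fwd, train = TRUE)
      lo <- compute_loss(out, it$labels, it$reference, it$fwd, config$weights,
                         cache = it$cache)
      ad_backward(lo$total)
      gflat <- numeric(length(flat))
      pa <- out$params_ad
      for (k in seq_along(pa)) {
        gr <- pa[[k]]$grad
        if (!is.null(gr)) gflat[state$starts[k]:state$ends[k]] <- gr
      }
      upd <- adamw_step_flat(flat, gflat, state, lr,
                             weight_decay = config$weight_decay)
      flat <- upd$flat
      state <- upd$state
      params <- unflatten_params(flat, state)
      mdl$params <- params
      comp <- comp + c(lo$l_geometric, lo$l_error_ce, lo$l_threshold_bce,
                       lo$l_lddt_mse, lo$total_value)
    }
    comp <- comp / length(ord)
    vp <- pooled_pearson(mdl, items[val_idx])
    hist <- rbind(hist, data.frame(epoch = ep, t(comp), val_pearson = vp,
                                   lr = lr))
    top[[length(top) + 1L]] <- list(pearson = vp, params = params, epoch = ep)
    top <- top[order(vapply(top, function(x) -x$pearson, numeric(1)))]
    if (length(top) > config$keep_top) top <- top[seq_len(config$keep_top)]
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.4f  val r %.3f", ep,
                      comp[["total"]], vp))
  }
  best <- top[[1]]
  best_model <- structure(list(params = best$params, config = model$config,
                               layout_hash = model$layout_hash),
                          class = "mqa_model")
  structure(list(model = best_model, history = hist, val_idx = val_idx,
                 top_models = lapply(top, function(x)
                   list(epoch = x$epoch, pearson = x$pearson))),
            class = "mqa_fit")
}

#' @export
print.mqa_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<mqa_fit> %d epochs; final loss %.4f; best val Pearson %.3f (epoch %d)\n",
              nrow(h), h$total[nrow(h)], x$top_models[[1]]$pearson,
              x$top_models[[1]]$epoch))
  invisible(x)
}
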