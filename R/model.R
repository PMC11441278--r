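#' Model configuration
#'
#' Collects every tunable of the pipeline with defaults matching the study
#' protocol where one is stated: 3-mers, two graph-attention layers, hidden
#' width 512, learning rate 1e-4, unit Gaussian bandwidth, 8:2 split,
#' decision threshold 0.5. The embedding dimension, context window, epoch
#' counts and scoring-head width are not pinned by the protocol; their
#' defaults are documented package choices.
#'
#' @param k k-mer length.
#' @param dim Sequence embedding dimension.
#' @param window Embedding context window (preceding tokens).
#' @param epochs_embed Embedding training epochs.
#' @param embed_lr Initial embedding learning rate.
#' @param gal Number of graph-attention layers per encoder.
#' @param hln Hidden width of each attention layer.
#' @param mix_dim Fused (post-projection) feature width.
#' @param head_hidden Scoring-head hidden width (default `hln / 2`).
#' @param lr Learning rate of the end-to-end Adam optimizer.
#' @param epochs End-to-end training epochs (full-batch).
#' @param sigma Gaussian kernel bandwidth.
#' @param ratio Train fraction of the positive edges.
#' @param threshold Decision threshold for point metrics.
#' @param negative_slope Leaky rectifier slope in the attention logits.
#' @param ablation `"full"`, `"OG"` (Gaussian branches only) or `"OM"`
#'   (meta-path branches only).
#' @return A list of class `lmi_config`.
#' @export
lmi_config <- function(k = 3L, dim = 128L, window = 5L, epochs_embed = 50L,
                       embed_lr = 0.025, gal = 2L, hln = 512L, mix_dim = 512L,
                       head_hidden = NULL, lr = 1e-4, epochs = 200L,
                       sigma = 1, ratio = 0.8, threshold = 0.5,
                       negative_slope = 0.2,
                       ablation = c("full", "OG", "OM")) {
  ablation <- match.arg(ablation)
  if (is.null(head_hidden)) head_hidden <- max(2L, as.integer(hln / 2))
  structure(list(k = as.integer(k), dim = as.integer(dim),
                 window = as.integer(window),
                 epochs_embed = as.integer(epochs_embed), embed_lr = embed_lr,
                 gal = as.integer(gal), hln = as.integer(hln),
                 mix_dim = as.integer(mix_dim),
                 head_hidden = as.integer(head_hidden),
                 lr = lr, epochs = as.integer(epochs), sigma = sigma,
                 ratio = ratio, threshold = threshold,
                 negative_slope = negative_slope, ablation = ablation),
            class = "lmi_config")
}

#' Switch a configuration to an ablation variant
#'
#' `"OG"` drops the meta-path branches (Gaussian-kernel similarity only);
#' `"OM"` drops the Gaussian branches (meta-path similarity only). All other
#' settings are untouched.
#'
#' @param config An [lmi_config()].
#' @param which `"full"`, `"OG"` or `"OM"`.
#' @export
ablation_variant <- function(config, which = c("full", "OG", "OM")) {
  config$ablation <- match.arg(which)
  config
}

# Which similarity views feed encoders under an ablation setting.
active_branches <- function(config) {
  switch(config$ablation,
         full = c("gs", "ms"), OG = "gs", OM = "ms")
}

#' Concatenated pair feature vector
#'
#' The scoring head sees, for a candidate pair, the fused lncRNA row
#' concatenated with the fused miRNA row.
#'
#' @param mixf_l,mixf_m Fused feature matrices.
#' @param lncrna_index,mirna_index 1-based row indices (vectorized).
#' @return A matrix with one row per pair, width `ncol(mixf_l) + ncol(mixf_m)`.
#' @export
pair_vector <- function(mixf_l, mixf_m, lncrna_index, mirna_index) {
  if (any(lncrna_index < 1 | lncrna_index > nrow(mixf_l)) ||
      any(mirna_index < 1 | mirna_index > nrow(mixf_m))) {
    stop("pair index out of range")
  }
  cbind(mixf_l[lncrna_index, , drop = FALSE],
        mixf_m[mirna_index, , drop = FALSE])
}

sigmoid <- function(z) 1 / (1 + exp(-z))

head_logits <- function(V, head) {
  U1 <- sweep(V %*% head$W1, 2L, head$b1, "+")
  A1 <- pmax(U1, 0)
  drop(A1 %*% head$w2) + head$b2
}

#' Score pair vectors with a trained head
#'
#' Two-layer feed-forward head: rectified hidden layer, then a sigmoid
#' output mapping each pair vector to an interaction probability in (0, 1).
#'
#' @param v Pair-vector matrix (rows = pairs) or a single vector.
#' @param params Head parameters: list with `W1`, `b1`, `w2`, `b2`.
#' @return Numeric vector of probabilities, strictly inside (0, 1).
#' @export
score_pairs <- function(v, params) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  p <- sigmoid(head_logits(v, params))
  pmin(pmax(p, 1e-7), 1 - 1e-7)
}

#' Binary cross-entropy loss
#'
#' `-[y log p + (1 - y) log(1 - p)]`, averaged over samples. Probabilities
#' are clamped to `[1e-7, 1 - 1e-7]` so the loss stays finite at the
#' boundaries.
#'
#' @param y 0/1 labels.
#' @param p Predicted probabilities.
#' @return Mean loss, a nonnegative scalar.
#' @export
bce_loss <- function(y, p) {
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  if (length(y) != length(p)) stop("label/probability length mismatch")
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## ---- end-to-end forward / gradient ---------------------------------------

# Forward pass to the fused matrices only (no caches); used for prediction.
model_mix <- function(params, inp) {
  mix_side <- function(fm, side) {
    branches <- lapply(inp$active, function(br) {
      encoder_fwd(fm, params$enc[[paste0(br, "_", side)]], inp$slope,
                  inp$masks[[paste0(br, "_", side)]])$out
    })
    C <- do.call(cbind, c(list(fm), branches))
    fp <- params[[paste0("fuse_", side)]]
    sweep(C %*% fp$W, 2L, fp$b, "+")
  }
  list(mix_l = mix_side(inp$fm_l, "l"), mix_m = mix_side(inp$fm_m, "m"))
}

# Full-batch loss and flat gradient; the single function both the Adam loop
# and the finite-difference gradient check call.
model_loss_grad <- function(theta, skeleton, inp) {
  params <- unflatten_params(theta, skeleton)
  d0 <- ncol(inp$fm_l)
  dh <- ncol(params$enc[[1]][[length(params$enc[[1]])]]$W)

  fwd_side <- function(fm, side) {
    branches <- list()
    for (br in inp$active) {
      branches[[br]] <- encoder_fwd(fm, params$enc[[paste0(br, "_", side)]],
                                    inp$slope, inp$masks[[paste0(br, "_", side)]])
    }
    C <- do.call(cbind, c(list(fm), lapply(branches, `[[`, "out")))
    fp <- params[[paste0("fuse_", side)]]
    list(C = C, mix = sweep(C %*% fp$W, 2L, fp$b, "+"), branches = branches)
  }
  L <- fwd_side(inp$fm_l, "l")
  M <- fwd_side(inp$fm_m, "m")

  V <- cbind(L$mix[inp$li, , drop = FALSE], M$mix[inp$mi, , drop = FALSE])
  U1 <- sweep(V %*% params$head$W1, 2L, params$head$b1, "+")
  A1 <- pmax(U1, 0)
  z <- drop(A1 %*% params$head$w2) + params$head$b2
  y <- inp$y
  n <- length(y)
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))

  ## backward
  dz <- (sigmoid(z) - y) / n
  dU1 <- outer(dz, params$head$w2) * (U1 > 0)
  g_head <- list(W1 = crossprod(V, dU1), b1 = colSums(dU1),
                 w2 = drop(crossprod(A1, dz)), b2 = sum(dz))
  dV <- tcrossprod(dU1, params$head$W1)

  d_mix <- ncol(L$mix)
  bwd_side <- function(S, fm, side, dV_side, idx) {
    dMix <- matrix(0, nrow(fm), d_mix)
    agg <- rowsum(dV_side, idx)
    dMix[as.integer(rownames(agg)), ] <- agg
    fp <- params[[paste0("fuse_", side)]]
    g_fuse <- list(W = crossprod(S$C, dMix), b = colSums(dMix))
    dC <- tcrossprod(dMix, fp$W)
    g_enc <- list()
    off <- d0
    for (br in inp$active) {
      dBr <- dC[, off + seq_len(dh), drop = FALSE]
      g_enc[[paste0(br, "_", side)]] <- encoder_bwd(dBr, S$branches[[br]]$caches)
      off <- off + dh
    }
    list(fuse = g_fuse, enc = g_enc)
  }
  gl <- bwd_side(L, inp$fm_l, "l", dV[, seq_len(d_mix), drop = FALSE], inp$li)
  gm <- bwd_side(M, inp$fm_m, "m", dV[, d_mix + seq_len(d_mix), drop = FALSE], inp$mi)

  ## assemble gradients in the exact skeleton order
  g_enc_all <- list()
  for (br in inp$active) {
    g_enc_all[[paste0(br, "_l")]] <- gl$enc[[paste0(br, "_l")]]
    g_enc_all[[paste0(br, "_m")]] <- gm$enc[[paste0(br, "_m")]]
  }
  grads <- list(enc = g_enc_all, fuse_l = gl$fuse, fuse_m = gm$fuse,
                head = g_head)
  list(loss = loss, grad = flatten_params(grads))
}

adam_train <- function(theta, skeleton, inp, lr, epochs, verbose = FALSE) {
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  losses <- numeric(epochs)
  for (t in seq_len(epochs)) {
    lg <- model_loss_grad(theta, skeleton, inp)
    if (!is.finite(lg$loss)) {
      stop("training diverged: non-finite loss at epoch ", t)
    }
    losses[t] <- lg$loss
    m <- b1 * m + (1 - b1) * lg$grad
    v <- b2 * v + (1 - b2) * lg$grad^2
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
    if (verbose && (t %% 25L == 0L || t == 1L)) {
      message(sprintf("epoch %4d  loss %.5f", t, lg$loss))
    }
  }
  list(theta = theta, losses = losses)
}

#' Train the interaction prediction model
#'
#' Runs the full pipeline on a dataset with sequences: balanced 8:2 split of
#' the positive edges; shared k-mer embedding of all sequences; meta-path
#' similarity matrices built from the *training* positives only (so no
#' validation edge leaks into the attention graph) and Gaussian-kernel
#' matrices from the embeddings; one two-layer graph-attention encoder per
#' similarity view and entity side; skip concatenation + linear fusion; and
#' a feed-forward scoring head. Fusion and head parameters train jointly by
#' full-batch Adam on the binary cross-entropy of the balanced training
#' pairs; the sequence embeddings stay frozen after pretraining.
#'
#' @param dataset An [interaction_dataset()] with sequences.
#' @param config An [lmi_config()].
#' @param seed Master seed; per-stage seeds (split, embedding, parameter
#'   initialization) are derived from it, making the run reproducible.
#' @param features Optional precomputed `list(fm_l, fm_m)` (e.g. from
#'   [featurize_dataset()]) to reuse across runs; skips embedding training.
#' @param splits Optional precomputed split tibble from
#'   [split_interactions()].
#' @param verbose Log the training loss every 25 epochs.
#' @return An object of class `lmi_model`.
#' @export
lmi_train <- function(dataset, config = lmi_config(), seed = 1L,
                      features = NULL, splits = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "interaction_dataset"))
  seeds <- derive_seeds(seed)
  if (is.null(splits)) {
    splits <- split_interactions(dataset, config$ratio, seeds[["split"]])
  }
  if (is.null(features)) {
    features <- featurize_dataset(dataset, k = config$k, dim = config$dim,
                                  window = config$window,
                                  epochs = config$epochs_embed,
                                  lr = config$embed_lr,
                                  seed = seeds[["embed"]])
  }
  fm_l <- features$fm_l; fm_m <- features$fm_m

  A_train <- build_adjacency(subset_edges(dataset, splits, "train"))
  active <- active_branches(config)
  sims <- list()
  if ("ms" %in% active) {
    sims$ms_l <- metapath_similarity(A_train, "lncrna")
    sims$ms_m <- metapath_similarity(A_train, "mirna")
  }
  if ("gs" %in% active) {
    sims$gs_l <- gaussian_similarity(fm_l, config$sigma)
    sims$gs_m <- gaussian_similarity(fm_m, config$sigma)
  }
  masks <- lapply(sims, function(S) mask_info(S > 0))

  tr <- splits[splits$partition == "train", ]
  inp <- list(fm_l = fm_l, fm_m = fm_m, masks = masks, active = active,
              slope = config$negative_slope,
              li = match(tr$lncrna_id, dataset$lncrna_ids),
              mi = match(tr$mirna_id, dataset$mirna_ids),
              y = tr$label)

  params <- init_params(d0 = config$dim, d_hidden = config$hln,
                        n_layers = config$gal, d_mix = config$mix_dim,
                        d_head = config$head_hidden, active = active,
                        seed = seeds[["init"]])
  theta <- flatten_params(params)
  fit <- adam_train(theta, params, inp, config$lr, config$epochs, verbose)
  params <- unflatten_params(fit$theta, params)
  mix <- model_mix(params, inp)

  structure(list(config = config, seed = seed, stage_seeds = seeds,
                 lncrna_ids = dataset$lncrna_ids,
                 mirna_ids = dataset$mirna_ids,
                 edges = dataset$edges,
                 fm_l = fm_l, fm_m = fm_m,
                 params = params,
                 mixf_l = mix$mix_l, mixf_m = mix$mix_m,
                 splits = splits, losses = fit$losses),
            class = "lmi_model")
}

#' @export
print.lmi_model <- function(x, ...) {
  cat(sprintf("<lmi_model> %s variant; %d lncRNAs x %d miRNAs\n",
              x$config$ablation, length(x$lncrna_ids), length(x$mirna_ids)))
  cat(sprintf("  %d training epochs, final loss %.4f\n",
              length(x$losses), x$losses[length(x$losses)]))
  invisible(x)
}

#' Score candidate lncRNA-miRNA pairs
#'
#' @param object A trained [lmi_train()] model.
#' @param pairs Data frame with columns `lncrna_id` and `mirna_id`; defaults
#'   to the model's validation partition.
#' @param ... Unused.
#' @return `pairs` as a tibble with a `score` column of interaction
#'   probabilities, order preserved.
#' @export
predict.lmi_model <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) {
    pairs <- object$splits[object$splits$partition == "validation", ]
  }
  li <- match(pairs$lncrna_id, object$lncrna_ids)
  mi <- match(pairs$mirna_id, object$mirna_ids)
  unknown <- c(unique(pairs$lncrna_id[is.na(li)]), unique(pairs$mirna_id[is.na(mi)]))
  if (length(unknown)) {
    stop("identifiers unknown to the model: ",
         paste(head(unknown, 10L), collapse = ", "))
  }
  V <- pair_vector(object$mixf_l, object$mixf_m, li, mi)
  dplyr::mutate(tibble::as_tibble(pairs),
                score = score_pairs(V, object$params$head))
}

#' Rank candidate miRNA partners for one lncRNA
#'
#' Scores every miRNA in the vocabulary against the given lncRNA and returns
#' the top `k` by descending score; ties break by vocabulary order. With
#' `exclude_known = TRUE` the miRNAs already recorded as interacting with
#' this lncRNA are removed before ranking (the case-study protocol).
#'
#' @param model A trained [lmi_train()] model.
#' @param lncrna_id Identifier known to the model.
#' @param k Number of partners to return.
#' @param exclude_known Drop already-known partners first (default `TRUE`).
#' @return Tibble with columns `rank`, `mirna_id`, `score`.
#' @export
rank_partners <- function(model, lncrna_id, k = 10L, exclude_known = TRUE) {
  i <- match(lncrna_id, model$lncrna_ids)
  if (is.na(i)) stop("unknown lncRNA identifier: ", lncrna_id)
  cand <- seq_along(model$mirna_ids)
  if (exclude_known) {
    known <- model$edges[model$edges[, 1] == i, 2]
    cand <- setdiff(cand, known)
  }
  V <- pair_vector(model$mixf_l, model$mixf_m, rep(i, length(cand)), cand)
  s <- score_pairs(V, model$params$head)
  if (k > length(cand)) {
    warning("requested top ", k, " but only ", length(cand),
            " candidate miRNAs; truncating")
    k <- length(cand)
  }
  ord <- order(-s)[seq_len(k)]           # stable: ties keep vocabulary order
  tibble::tibble(rank = seq_len(k),
                 mirna_id = model$mirna_ids[cand[ord]],
                 score = s[ord])
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint holding all parameters, the configuration echo,
#' seeds and vocabulary snapshot.
#'
#' @param model An `lmi_model`.
#' @param path Checkpoint path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "lmi_model"))
  m
}
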