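#' Graph-attention building blocks
#'
#' These functions expose the attention arithmetic used inside the fusion
#' encoders so each step can be inspected and tested in isolation. A layer's
#' parameters are a list with elements `W` (`d_in` x `d_out` weight matrix),
#' `a` (attention vector of length `2 * d_out`) and `negative_slope` (leaky
#' rectifier slope, default 0.2).
#'
#' For nodes `i`, `j` with features `x_i`, `x_j` the attention logit is
#' `e_ij = LeakyReLU(a' [W x_i || W x_j])`, computed only over adjacent pairs
#' (strictly positive adjacency entries; self-loops count). Logits are
#' softmax-normalized per neighbourhood and the layer output is
#' `h_i = act(sum_j alpha_ij W x_j)`.
#'
#' @param x Numeric feature matrix, one row per node.
#' @param params Layer parameter list (`W`, `a`, `negative_slope`).
#' @param adjacency Square matrix; entries `> 0` mark neighbours.
#' @return `attention_logits`: an `n` x `n` matrix of logits with `NA` at
#'   non-adjacent pairs. `attention_coefficients`: the row-normalized
#'   coefficients (zeros at non-adjacent pairs; each row sums to 1 over its
#'   neighbourhood). `gat_layer`: the `n` x `d_out` output feature matrix.
#' @name gat_ops
NULL

leaky_relu <- function(x, slope) ifelse(x >= 0, x, slope * x)
elu <- function(x) ifelse(x > 0, x, exp(x) - 1)

split_attention <- function(params) {
  d_out <- ncol(params$W)
  a <- params$a
  if (length(a) != 2L * d_out) {
    stop("attention vector length must be 2 * ncol(W)")
  }
  list(a_src = a[seq_len(d_out)], a_dst = a[d_out + seq_len(d_out)],
       slope = if (is.null(params$negative_slope)) 0.2 else params$negative_slope)
}

#' @rdname gat_ops
#' @export
attention_logits <- function(x, params, adjacency) {
  x <- as.matrix(x)
  if (nrow(x) != nrow(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency must be square with side length nrow(x)")
  }
  if (ncol(x) != nrow(params$W)) stop("feature width does not match nrow(W)")
  at <- split_attention(params)
  H <- x %*% params$W
  f <- drop(H %*% at$a_src)
  g <- drop(H %*% at$a_dst)
  E <- leaky_relu(outer(f, g, "+"), at$slope)
  E[!(adjacency > 0)] <- NA_real_
  E
}

#' @rdname gat_ops
#' @param logits Matrix from [attention_logits()] (`NA` = masked pair).
#' @export
attention_coefficients <- function(logits) {
  mask <- !is.na(logits)
  if (any(rowSums(mask) == 0L)) {
    stop("node with empty neighbourhood; add self-loops to the adjacency")
  }
  E <- logits
  E[!mask] <- -Inf
  m <- apply(E, 1L, max)
  P <- exp(E - m)
  P[!mask] <- 0
  P / rowSums(P)
}

#' @rdname gat_ops
#' @param activation `"identity"` or `"elu"`, the elementwise nonlinearity
#'   applied to the aggregated features.
#' @export
gat_layer <- function(x, params, adjacency, activation = c("identity", "elu")) {
  activation <- match.arg(activation)
  P <- attention_coefficients(attention_logits(x, params, adjacency))
  H <- as.matrix(x) %*% params$W
  Z <- P %*% H
  if (activation == "elu") elu(Z) else Z
}

#' Two-layer graph-attention encoder
#'
#' Stacks [gat_layer()] applications: the smooth exponential-linear
#' nonlinearity between layers, identity after the final one. This is the
#' per-branch encoder that turns a feature matrix plus one similarity view
#' (meta-path or Gaussian adjacency) into the branch output matrix.
#'
#' @param x Feature matrix.
#' @param layers List of layer parameter lists (see [gat_ops]).
#' @param adjacency Square adjacency; entries `> 0` are neighbours.
#' @return Feature matrix with `nrow(x)` rows.
#' @export
gat_encode <- function(x, layers, adjacency) {
  n <- length(layers)
  for (l in seq_len(n)) {
    x <- gat_layer(x, layers[[l]], adjacency,
                   activation = if (l < n) "elu" else "identity")
  }
  x
}

#' Skip-concatenation and linear fusion
#'
#' Concatenates the initial features with the branch encoder outputs
#' (order: initial, Gaussian branch, meta-path branch) and projects rows
#' through a linear layer to the fused dimension.
#'
#' @param initial Initial feature matrix.
#' @param gs_branch,ms_branch Branch matrices (either may be `NULL` for the
#'   ablation variants).
#' @param weights Projection matrix, `sum of input widths` x `fused dim`.
#' @param bias Bias vector of length `fused dim`.
#' @return The fused feature matrix.
#' @export
fuse_features <- function(initial, gs_branch, ms_branch, weights, bias) {
  parts <- Filter(Negate(is.null), list(initial, gs_branch, ms_branch))
  ns <- vapply(parts, nrow, integer(1))
  if (length(unique(ns)) != 1L) stop("row counts of fused matrices disagree")
  C <- do.call(cbind, parts)
  if (ncol(C) != nrow(weights)) {
    stop("projection expects ", nrow(weights), " input columns, got ", ncol(C))
  }
  sweep(C %*% weights, 2L, bias, "+")
}

## ---- internal cached forward/backward used by training --------------------
## The exported functions above are the readable reference path; training
## uses these equivalents that keep intermediates for reverse-mode gradients.
## A test asserts both paths agree.

# `mask` is a precomputed adjacency descriptor from mask_info(): logical
# matrix plus the linear indices of masked (non-adjacent) pairs, so the
# per-epoch path never re-scans the adjacency.
mask_info <- function(adj_positive) {
  list(mask = adj_positive, masked_idx = which(!adj_positive))
}

gat_layer_fwd <- function(X, W, a_src, a_dst, slope, mask, act) {
  n <- nrow(X)
  H <- X %*% W
  f <- drop(H %*% a_src)
  g <- drop(H %*% a_dst)
  El <- rep(g, each = n) + f            # El[i, j] = f_i + g_j, column-major
  dim(El) <- c(n, n)
  neg <- El < 0
  El[neg] <- slope * El[neg]
  if (length(mask$masked_idx)) El[mask$masked_idx] <- -Inf
  m <- El[cbind(seq_len(n), max.col(El, "first"))]
  P <- exp(El - m)                      # exp(-Inf) = 0 zeroes masked pairs
  P <- P / rowSums(P)
  Z <- P %*% H
  out <- if (act == "elu") {
    pos <- Z > 0
    o <- expm1(Z)
    o[pos] <- Z[pos]
    o
  } else Z
  list(out = out,
       cache = list(X = X, W = W, a_src = a_src, a_dst = a_dst, slope = slope,
                    neg = neg, H = H, P = P, Z = Z, act = act))
}

gat_layer_bwd <- function(dOut, cache) {
  with(cache, {
    dZ <- if (act == "elu") {
      dact <- exp(Z)
      dact[Z > 0] <- 1
      dOut * dact
    } else dOut
    dP <- dZ %*% t(H)
    dH <- crossprod(P, dZ)
    dEl <- P * (dP - rowSums(P * dP))
    dEl[neg] <- dEl[neg] * slope
    df <- rowSums(dEl)
    dg <- colSums(dEl)
    dH <- dH + outer(df, a_src) + outer(dg, a_dst)
    list(dX = dH %*% t(W),
         dW = crossprod(X, dH),
         da_src = drop(crossprod(H, df)),
         da_dst = drop(crossprod(H, dg)))
  })
}

encoder_fwd <- function(X, layers, slope, mask) {
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    act <- if (l < length(layers)) "elu" else "identity"
    r <- gat_layer_fwd(X, layers[[l]]$W, layers[[l]]$a_src, layers[[l]]$a_dst,
                       slope, mask, act)
    caches[[l]] <- r$cache
    X <- r$out
  }
  list(out = X, caches = caches)
}

encoder_bwd <- function(dOut, caches) {
  grads <- vector("list", length(caches))
  for (l in rev(seq_along(caches))) {
    g <- gat_layer_bwd(dOut, caches[[l]])
    grads[[l]] <- list(W = g$dW, a_src = g$da_src, a_dst = g$da_dst)
    dOut <- g$dX
  }
  grads
}

## Glorot-style uniform initialization
glorot <- function(fan_in, fan_out, n_row = fan_in, n_col = fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(n_row * n_col, -lim, lim), n_row, n_col)
}

init_layer <- function(d_in, d_out) {
  list(W = glorot(d_in, d_out),
       a_src = drop(glorot(2 * d_out, 1, n_row = d_out, n_col = 1)),
       a_dst = drop(glorot(2 * d_out, 1, n_row = d_out, n_col = 1)))
}

init_encoder <- function(d_in, d_hidden, n_layers) {
  lapply(seq_len(n_layers), function(l) {
    init_layer(if (l == 1L) d_in else d_hidden, d_hidden)
  })
}

# Full trainable parameter set. `active` is a character subset of
# c("gs", "ms"); each active branch gets one encoder per entity side.
init_params <- function(d0, d_hidden, n_layers, d_mix, d_head, active, seed) {
  with_local_seed(seed, {
    enc <- list()
    for (br in active) {
      enc[[paste0(br, "_l")]] <- init_encoder(d0, d_hidden, n_layers)
      enc[[paste0(br, "_m")]] <- init_encoder(d0, d_hidden, n_layers)
    }
    d_cat <- d0 + length(active) * d_hidden
    list(enc = enc,
         fuse_l = list(W = glorot(d_cat, d_mix), b = numeric(d_mix)),
         fuse_m = list(W = glorot(d_cat, d_mix), b = numeric(d_mix)),
         head = list(W1 = glorot(2 * d_mix, d_head), b1 = numeric(d_head),
                     w2 = drop(glorot(d_head, 1)), b2 = 0))
  })
}

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(vec, skeleton) {
  idx <- 0L
  walk <- function(node) {
    if (is.list(node)) return(lapply(node, walk))
    n <- length(node)
    out <- vec[idx + seq_len(n)]
    idx <<- idx + n
    if (!is.null(dim(node))) dim(out) <- dim(node)
    out
  }
  out <- walk(skeleton)
  stopifnot(idx == length(vec))
  out
}
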