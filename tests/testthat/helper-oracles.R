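# Brute-force reference implementations used as independent oracles.

# Shared-partner similarity by explicit double loop over entity pairs.
bf_metapath <- function(A, side, self_loops = TRUE) {
  if (side == "mirna") A <- t(A)
  n <- nrow(A)
  S <- matrix(0, n, n)
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      S[p, q] <- as.numeric(any(A[p, ] > 0 & A[q, ] > 0))
    }
  }
  if (self_loops) diag(S) <- 1
  S
}

# AUC by enumeration of all positive-negative pairs, ties worth one half.
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# AUPR by an explicit sweep over every distinct score as threshold,
# descending, accumulating (R_i - R_{i-1}) * P_i.
bf_aupr <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  r_prev <- 0
  area <- 0
  n_pos <- sum(labels == 1)
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    r <- tp / n_pos
    p <- tp / (tp + fp)
    area <- area + (r - r_prev) * p
    r_prev <- r
  }
  area
}

# One graph-attention layer as nested loops over nodes and neighbours.
bf_gat_layer <- function(x, params, adjacency, activation = "identity") {
  n <- nrow(x)
  d_out <- ncol(params$W)
  slope <- if (is.null(params$negative_slope)) 0.2 else params$negative_slope
  lrelu <- function(v) if (v >= 0) v else slope * v
  H <- x %*% params$W
  out <- matrix(0, n, d_out)
  for (i in seq_len(n)) {
    nb <- which(adjacency[i, ] > 0)
    e <- vapply(nb, function(j) {
      lrelu(sum(params$a * c(H[i, ], H[j, ])))
    }, numeric(1))
    a <- exp(e - max(e))
    a <- a / sum(a)
    h <- numeric(d_out)
    for (idx in seq_along(nb)) h <- h + a[idx] * H[nb[idx], ]
    out[i, ] <- if (activation == "elu") ifelse(h > 0, h, exp(h) - 1) else h
  }
  out
}

# Small deterministic dataset with sequences, for pipeline tests.
make_toy_dataset <- function(seed = 5L) {
  simulate_interactions(n_l = 12L, n_m = 16L, n_blocks = 2L,
                        p_in = 0.7, p_out = 0.05, seed = seed,
                        seq_len_l = c(60L, 100L))
}

# A small but trainable configuration.
toy_config <- function(...) {
  lmi_config(dim = 12L, window = 3L, epochs_embed = 3L, hln = 8L,
             mix_dim = 8L, head_hidden = 6L, lr = 5e-3, epochs = 30L, ...)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
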