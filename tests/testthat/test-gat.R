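make_layer <- function(d_in, d_out, seed = 1) {
  set.seed(seed)
  list(W = matrix(rnorm(d_in * d_out, sd = 0.5), d_in, d_out),
       a = rnorm(2 * d_out, sd = 0.5), negative_slope = 0.2)
}

test_that("attention logits follow the concatenated leaky-rectifier form", {
  # zero attention vector kills all logits
  p <- make_layer(2, 2)
  p$a <- rep(0, 4)
  x <- matrix(rnorm(6), 3, 2)
  e <- attention_logits(x, p, matrix(1, 3, 3))
  expect_true(all(e == 0))

  # single node with self-loop
  p1 <- make_layer(2, 2, seed = 2)
  x1 <- matrix(c(0.3, -0.7), 1, 2)
  h <- x1 %*% p1$W
  expected <- sum(p1$a * c(h, h))
  expected <- if (expected >= 0) expected else 0.2 * expected
  expect_equal(attention_logits(x1, p1, matrix(1, 1, 1))[1, 1], expected)

  # hand-set 2-node case
  p2 <- list(W = diag(2), a = c(1, 0, 0, 0), negative_slope = 0.2)
  x2 <- rbind(c(1, 0), c(-1, 0))
  e2 <- attention_logits(x2, p2, matrix(1, 2, 2))
  expect_equal(e2[1, 2], 1)
  expect_equal(e2[2, 1], -0.2)

  # non-adjacent pairs are masked out
  adj <- rbind(c(1, 0), c(0, 1))
  e3 <- attention_logits(x2, p2, adj)
  expect_true(is.na(e3[1, 2]) && is.na(e3[2, 1]))
})

test_that("attention coefficients are neighbourhood softmaxes", {
  e <- matrix(c(1, 1, 1), 1, 3)
  expect_equal(attention_coefficients(e)[1, ], rep(1 / 3, 3))
  e2 <- matrix(c(0, log(3)), 1, 2)
  expect_equal(attention_coefficients(e2)[1, ], c(0.25, 0.75))

  set.seed(11)
  n <- 12
  adj <- matrix(rbinom(n * n, 1, 0.4), n, n)
  diag(adj) <- 1
  lg <- attention_logits(matrix(rnorm(n * 3), n), make_layer(3, 4), adj)
  P <- attention_coefficients(lg)
  expect_equal(unname(rowSums(P)), rep(1, n), tolerance = 1e-12)
  expect_true(all(P[adj == 0] == 0))

  expect_error(attention_coefficients(matrix(NA_real_, 1, 1)), "neighbourhood")
})

test_that("a gat layer reduces to its fixed points on degenerate graphs", {
  # single node, identity weights, linear activation: h = x
  p <- list(W = diag(2), a = rnorm(4), negative_slope = 0.2)
  x <- matrix(c(0.4, -1.2), 1)
  expect_equal(gat_layer(x, p, matrix(1, 1, 1)), x %*% diag(2))

  # two identical neighbours: output equals W x regardless of coefficients
  x2 <- rbind(c(1, 2), c(1, 2))
  p2 <- make_layer(2, 3, seed = 3)
  out <- gat_layer(x2, p2, matrix(1, 2, 2))
  expect_equal(out[1, ], drop(x2[1, ] %*% p2$W), tolerance = 1e-12)
})

test_that("gat layer matches the brute-force loop oracle on small graphs", {
  set.seed(12)
  for (n in c(3, 5, 8, 10)) {
    adj <- matrix(rbinom(n * n, 1, 0.5), n, n)
    diag(adj) <- 1
    x <- matrix(rnorm(n * 4), n)
    p <- make_layer(4, 3, seed = n)
    for (act in c("identity", "elu")) {
      expect_equal(gat_layer(x, p, adj, activation = act),
                   bf_gat_layer(x, p, adj, activation = act),
                   tolerance = 1e-10)
    }
  }
})

test_that("with zero attention and identity weights a layer is a neighbourhood mean", {
  set.seed(13)
  n <- 9
  adj <- matrix(rbinom(n * n, 1, 0.5), n, n)
  diag(adj) <- 1
  x <- matrix(rnorm(n * n), n)          # square so W = I conforms
  p <- list(W = diag(n), a = rep(0, 2 * n), negative_slope = 0.2)
  out <- gat_layer(x, p, adj)
  means <- t(vapply(seq_len(n), function(i) colMeans(x[adj[i, ] > 0, , drop = FALSE]),
                    numeric(n)))
  expect_equal(out, means, tolerance = 1e-12)
})

test_that("two-layer encoding is the composition of its layers", {
  set.seed(14)
  n <- 7
  adj <- matrix(rbinom(n * n, 1, 0.6), n, n)
  diag(adj) <- 1
  x <- matrix(rnorm(n * 3), n)
  layers <- list(make_layer(3, 4, seed = 21), make_layer(4, 4, seed = 22))
  enc <- gat_encode(x, layers, adj)
  manual <- gat_layer(gat_layer(x, layers[[1]], adj, activation = "elu"),
                      layers[[2]], adj, activation = "identity")
  expect_equal(enc, manual, tolerance = 1e-14)
  expect_equal(nrow(enc), n)
  expect_identical(enc, gat_encode(x, layers, adj))  # pure function
})

test_that("the cached training path reproduces the reference ops", {
  set.seed(15)
  n <- 8
  adj <- matrix(rbinom(n * n, 1, 0.5), n, n)
  diag(adj) <- 1
  x <- matrix(rnorm(n * 3), n)
  layers <- list(make_layer(3, 5, seed = 31), make_layer(5, 5, seed = 32))
  internal <- lapply(layers, function(p) {
    at <- lncmir:::split_attention(p)
    list(W = p$W, a_src = at$a_src, a_dst = at$a_dst)
  })
  fwd <- lncmir:::encoder_fwd(x, internal, 0.2, lncmir:::mask_info(adj > 0))
  expect_equal(fwd$out, gat_encode(x, layers, adj), tolerance = 1e-12)
})

test_that("node permutation equivariance holds", {
  set.seed(16)
  n <- 10
  adj <- matrix(rbinom(n * n, 1, 0.5), n, n)
  diag(adj) <- 1
  x <- matrix(rnorm(n * 4), n)
  layers <- list(make_layer(4, 3, seed = 41), make_layer(3, 3, seed = 42))
  perm <- sample(n)
  out <- gat_encode(x, layers, adj)
  out_perm <- gat_encode(x[perm, ], layers, adj[perm, perm])
  expect_equal(out_perm, out[perm, ], tolerance = 1e-12)
})

test_that("fusion concatenates and projects with shape checks", {
  ini <- matrix(1:6, 3, 2)
  gs <- matrix(rnorm(9), 3, 3)
  ms <- matrix(rnorm(6), 3, 2)
  W0 <- matrix(0, 7, 4)
  expect_true(all(fuse_features(ini, gs, ms, W0, rep(0, 4)) == 0))

  # identity block selecting the initial slice
  W <- rbind(diag(2), matrix(0, 5, 2))
  expect_equal(fuse_features(ini, gs, ms, W, c(0, 0)), ini, ignore_attr = TRUE)

  for (w_gs in c(1, 3)) {
    gs2 <- matrix(rnorm(3 * w_gs), 3)
    for (d_mix in c(2, 5)) {
      Wx <- matrix(rnorm((2 + w_gs + 2) * d_mix), 2 + w_gs + 2, d_mix)
      expect_equal(dim(fuse_features(ini, gs2, ms, Wx, rnorm(d_mix))),
                   c(3L, d_mix))
    }
  }
  expect_error(fuse_features(ini, gs[1:2, ], ms, W, c(0, 0)), "row counts")
})

test_that("analytic gradients match finite differences on a small problem", {
  set.seed(42)
  n_l <- 5; n_m <- 4; d0 <- 3
  ms_l <- diag(n_l); ms_l[1, 2] <- ms_l[2, 1] <- 1; ms_l[3, 4] <- ms_l[4, 3] <- 1
  ms_m <- diag(n_m); ms_m[1, 3] <- ms_m[3, 1] <- 1
  inp <- list(fm_l = matrix(rnorm(n_l * d0), n_l),
              fm_m = matrix(rnorm(n_m * d0), n_m),
              masks = list(gs_l = lncmir:::mask_info(matrix(TRUE, n_l, n_l)),
                           gs_m = lncmir:::mask_info(matrix(TRUE, n_m, n_m)),
                           ms_l = lncmir:::mask_info(ms_l > 0),
                           ms_m = lncmir:::mask_info(ms_m > 0)),
              active = c("gs", "ms"), slope = 0.2,
              li = c(1, 2, 3, 5, 4), mi = c(1, 2, 3, 4, 2), y = c(1, 0, 1, 0, 1))
  skel <- lncmir:::init_params(d0, 4, 2, 3, 4, c("gs", "ms"), seed = 9)
  theta <- lncmir:::flatten_params(skel)
  lg <- lncmir:::model_loss_grad(theta, skel, inp)
  eps <- 1e-5
  num <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (lncmir:::model_loss_grad(tp, skel, inp)$loss -
       lncmir:::model_loss_grad(tm, skel, inp)$loss) / (2 * eps)
  }, numeric(1))
  rel <- abs(num - lg$grad) / pmax(1e-6, abs(num) + abs(lg$grad))
  expect_lt(max(rel), 1e-4)
})

test_that("parameter flatten/unflatten is a faithful round trip", {
  p <- lncmir:::init_params(3, 4, 2, 3, 4, c("gs", "ms"), seed = 77)
  v <- lncmir:::flatten_params(p)
  expect_identical(lncmir:::unflatten_params(v, p), p)
})
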