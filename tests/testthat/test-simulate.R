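test_that("the deterministic limit plants exact blocks", {
  ds <- simulate_interactions(4, 4, 2, p_in = 1, p_out = 0, seed = 1,
                              sequences = FALSE)
  expect_equal(nrow(ds$edges), 8L)        # 2 blocks of 2 x 2, all present
  ms_l <- metapath_similarity(build_adjacency(ds), "lncrna")
  blocks <- (seq_len(4) - 1) %% 2 + 1
  expect_equal(unname(ms_l), (outer(blocks, blocks, "==")) * 1)
})

test_that("generation is reproducible and block density tracks p_in", {
  d1 <- simulate_interactions(20, 30, 2, 0.4, 0.02, seed = 7)
  d2 <- simulate_interactions(20, 30, 2, 0.4, 0.02, seed = 7)
  expect_identical(d1$edges, d2$edges)
  expect_identical(d1$lncrna_seqs, d2$lncrna_seqs)

  # empirical within-block density within 3 standard errors of p_in
  n_within <- 0; n_edges_within <- 0
  for (seed in 1:20) {
    ds <- simulate_interactions(20, 30, 2, 0.3, 0.02, seed = seed,
                                sequences = FALSE)
    A <- build_adjacency(ds)
    same <- outer(attr(ds, "lncrna_blocks"), attr(ds, "mirna_blocks"), "==")
    n_within <- n_within + sum(same)
    n_edges_within <- n_edges_within + sum(A[same])
  }
  p_hat <- n_edges_within / n_within
  se <- sqrt(0.3 * 0.7 / n_within)
  expect_lt(abs(p_hat - 0.3), 3 * se + 0.01)  # +0.01 slack for rewiring
})

test_that("equal probabilities erase the block signal", {
  w <- 0; b <- 0; nw <- 0; nb <- 0
  for (seed in 1:20) {
    ds <- simulate_interactions(16, 24, 2, 0.15, 0.15, seed = seed,
                                sequences = FALSE)
    A <- build_adjacency(ds)
    same <- outer(attr(ds, "lncrna_blocks"), attr(ds, "mirna_blocks"), "==")
    w <- w + sum(A[same]); nw <- nw + sum(same)
    b <- b + sum(A[!same]); nb <- nb + sum(!same)
  }
  # two-proportion z statistic, should be unremarkable
  p_pool <- (w + b) / (nw + nb)
  z <- (w / nw - b / nb) / sqrt(p_pool * (1 - p_pool) * (1 / nw + 1 / nb))
  expect_lt(abs(z), 4)
})

test_that("sequences carry the planted motif within the length bounds", {
  ds <- simulate_interactions(8, 10, 2, 0.5, 0.05, seed = 3,
                              seq_len_l = c(60, 90), seq_len_m = c(18, 25),
                              motif_len = 6)
  motifs <- attr(ds, "motifs")
  lens_l <- nchar(ds$lncrna_seqs)
  expect_true(all(lens_l >= 60 & lens_l <= 90))
  lens_m <- nchar(ds$mirna_seqs)
  expect_true(all(lens_m >= 18 & lens_m <= 25))
  bl <- attr(ds, "lncrna_blocks")
  for (i in seq_along(ds$lncrna_seqs)) {
    expect_true(grepl(motifs[bl[i]], ds$lncrna_seqs[i], fixed = TRUE))
  }
  bm <- attr(ds, "mirna_blocks")
  for (j in seq_along(ds$mirna_seqs)) {
    expect_true(grepl(motifs[bm[j]], ds$mirna_seqs[j], fixed = TRUE))
  }
  expect_error(simulate_interactions(4, 4, 2, 0.5, 0.1, seed = 1,
                                     seq_len_m = c(4, 6), motif_len = 8),
               "motif longer")
})

test_that("blocks differ in motif dose", {
  ds <- simulate_interactions(20, 20, 2, 0.5, 0.05, seed = 5,
                              seq_len_l = c(120, 200))
  motifs <- attr(ds, "motifs")
  bl <- attr(ds, "lncrna_blocks")
  count1 <- vapply(ds$lncrna_seqs, function(s) {
    lengths(regmatches(s, gregexpr(motifs[1], s, fixed = TRUE)))
  }, integer(1))
  expect_gt(mean(count1[bl == 1]), mean(count1[bl == 2]))
})

test_that("fixture bundles are written, sized and round-trip losslessly", {
  dir <- tempfile("fx_")
  paths <- fixture_suite("tiny", dir, seed = 2)
  ds <- attr(paths, "dataset")
  expect_equal(length(ds$lncrna_ids), 6L)
  expect_equal(length(ds$mirna_ids), 8L)

  back <- suppressMessages(read_interactions(paths$edges))
  expect_equal(nrow(back$edges), nrow(ds$edges))
  seqs_l <- read_fasta(paths$lncrna_fasta)
  expect_identical(seqs_l[ds$lncrna_ids], ds$lncrna_seqs)
  manifest <- jsonlite::read_json(paths$manifest)
  expect_equal(manifest$n_edges, nrow(ds$edges))
})

test_that("the benchmark-scale fixture matches the benchmark geometry", {
  paths <- fixture_suite("benchmark_scale", tempfile("fxp_"), seed = 4)
  ds <- attr(paths, "dataset")
  expect_equal(length(ds$lncrna_ids), 284L)
  expect_equal(length(ds$mirna_ids), 520L)
  expect_lt(abs(nrow(ds$edges) - 1057) / 1057, 0.10)
  A <- build_adjacency(ds)
  expect_equal(dim(A), c(284L, 520L))
  expect_equal(dim(metapath_similarity(A, "lncrna")), c(284L, 284L))
  expect_equal(dim(metapath_similarity(A, "mirna")), c(520L, 520L))
})

test_that("permuting edges preserves size but destroys block structure", {
  ds <- simulate_interactions(20, 30, 2, 0.5, 0.02, seed = 6, sequences = FALSE)
  pe <- permute_edges(ds, seed = 1)
  expect_equal(nrow(pe$edges), nrow(ds$edges))
  expect_false(any(duplicated(paste(pe$edges[, 1], pe$edges[, 2]))))
  same <- outer(attr(ds, "lncrna_blocks"), attr(ds, "mirna_blocks"), "==")
  A <- build_adjacency(pe)
  frac_within <- sum(A[same]) / sum(A)
  expect_lt(abs(frac_within - mean(same)), 0.2)
})
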