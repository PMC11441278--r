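#' Simulate a planted-block bipartite interaction network
#'
#' Entities on both sides are assigned round-robin to `n_blocks` blocks; a
#' lncRNA-miRNA pair is an interaction with probability `p_in` when the two
#' entities share a block and `p_out` otherwise. Entities that end up
#' isolated are rewired with one random within-block edge so the meta-path
#' matrices are non-degenerate. With `sequences = TRUE`, every entity also
#' receives a uniform random RNA string in the given length range with its
#' block's motif embedded at random offsets, coupling sequence features to
#' the graph blocks.
#'
#' @param n_l,n_m Numbers of lncRNAs and miRNAs.
#' @param n_blocks Number of planted blocks (`<= min(n_l, n_m)`).
#' @param p_in,p_out Within-/between-block edge probabilities
#'   (`0 <= p_out < p_in <= 1`, unless equal by intent).
#' @param seed Integer seed; output is fully reproducible.
#' @param sequences Also generate sequences (default `TRUE`).
#' @param seq_len_l,seq_len_m Length ranges `c(min, max)` for lncRNA and
#'   miRNA sequences.
#' @param motif_len Length of the block motif planted in every sequence; one
#'   motif is drawn per block. Must not exceed the minimum sequence length.
#' @return An [interaction_dataset()]; attributes `lncrna_blocks`,
#'   `mirna_blocks` and `motifs` record the planted structure.
#' @export
simulate_interactions <- function(n_l, n_m, n_blocks = 4L, p_in = 0.3,
                                  p_out = 0.01, seed = 1L, sequences = TRUE,
                                  seq_len_l = c(200L, 500L),
                                  seq_len_m = c(18L, 25L),
                                  motif_len = 6L) {
  if (!(p_out <= p_in && p_in <= 1 && p_out >= 0)) {
    stop("need 0 <= p_out <= p_in <= 1")
  }
  if (n_blocks > min(n_l, n_m)) stop("more blocks than entities on one side")
  blk_l <- (seq_len(n_l) - 1L) %% n_blocks + 1L
  blk_m <- (seq_len(n_m) - 1L) %% n_blocks + 1L
  same <- outer(blk_l, blk_m, "==")
  p_mat <- ifelse(same, p_in, p_out)
  if (sum(p_mat) < 1) stop("expected edge count is below one; raise p_in/p_out")

  with_local_seed(seed, {
    A <- matrix(rbinom(n_l * n_m, 1L, as.vector(p_mat)), n_l, n_m)
    # rewire isolated entities with one within-block edge
    for (i in which(rowSums(A) == 0L)) {
      cand <- which(blk_m == blk_l[i])
      A[i, cand[sample.int(length(cand), 1L)]] <- 1L
    }
    for (j in which(colSums(A) == 0L)) {
      cand <- which(blk_l == blk_m[j])
      A[cand[sample.int(length(cand), 1L)], j] <- 1L
    }
    lnc_ids <- sprintf("LNC%04d", seq_len(n_l))
    mir_ids <- sprintf("MIR%04d", seq_len(n_m))
    idx <- which(A == 1L, arr.ind = TRUE)
    ds <- interaction_dataset(data.frame(lncrna_id = lnc_ids[idx[, 1]],
                                         mirna_id = mir_ids[idx[, 2]]))
    # interaction_dataset orders vocabularies by first appearance in the edge
    # list; re-anchor to the generation order for block bookkeeping
    ds$lncrna_ids <- lnc_ids
    ds$mirna_ids <- mir_ids
    ds$edges <- cbind(lncrna = idx[, 1], mirna = idx[, 2])

    motifs <- NULL
    if (sequences) {
      motifs <- vapply(seq_len(n_blocks), function(b) random_rna(motif_len),
                       character(1))
      ds$lncrna_seqs <- setNames(vapply(seq_len(n_l), function(i) {
        planted_sequence(seq_len_l, motifs[blk_l[i]])
      }, character(1)), lnc_ids)
      ds$mirna_seqs <- setNames(vapply(seq_len(n_m), function(j) {
        planted_sequence(seq_len_m, motifs[blk_m[j]])
      }, character(1)), mir_ids)
    }
    attr(ds, "lncrna_blocks") <- blk_l
    attr(ds, "mirna_blocks") <- blk_m
    attr(ds, "motifs") <- motifs
    ds
  })
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Uniform random RNA string with the motif overwritten at random offsets,
# one copy per ~150 nt (at least one), so longer sequences carry a
# proportional motif dose.
planted_sequence <- function(len_range, motif) {
  len <- sample(seq(len_range[1], len_range[2]), 1L)
  mlen <- nchar(motif)
  if (mlen > len) stop("motif longer than the minimum sequence length")
  s <- strsplit(random_rna(len), "")[[1]]
  n_copies <- max(1L, len %/% 150L)
  for (rep in seq_len(n_copies)) {
    off <- sample.int(len - mlen + 1L, 1L)
    s[off:(off + mlen - 1L)] <- strsplit(motif, "")[[1]]
  }
  paste(s, collapse = "")
}

#' Replace the edge set with uniformly random pairs (negative control)
#'
#' Keeps vocabularies and sequences but substitutes the interactions with an
#' equally sized uniform random edge set, destroying the planted
#' graph-sequence coupling. Used as the label-permuted control: a model
#' trained on the permuted dataset should sit at chance level.
#'
#' @param dataset An [interaction_dataset()].
#' @param seed Integer seed.
#' @return The dataset with randomized edges.
#' @export
permute_edges <- function(dataset, seed = 1L) {
  n_l <- length(dataset$lncrna_ids)
  n_m <- length(dataset$mirna_ids)
  n_e <- nrow(dataset$edges)
  with_local_seed(seed, {
    lin <- sample.int(n_l * n_m, n_e)
    dataset$edges <- cbind(lncrna = ((lin - 1L) %% n_l) + 1L,
                           mirna = ((lin - 1L) %/% n_l) + 1L)
  })
  dataset
}

#' Write a ready-to-use fixture bundle to disk
#'
#' Generates a planted-block dataset at a named scale and writes the
#' edge-list TSV, the two FASTA files and a JSON manifest of counts and
#' generator settings. `"benchmark_scale"` mirrors the benchmark layout
#' (284 lncRNAs x 520 miRNAs at a density giving ~1057 expected edges);
#' `"tiny"` and `"small"` are for fast tests.
#'
#' @param name `"tiny"` (6 x 8), `"small"` (30 x 50) or `"benchmark_scale"`
#'   (284 x 520).
#' @param dir Output directory (created if missing).
#' @param seed Integer seed.
#' @return Named list of file paths, invisibly; the dataset as attribute
#'   `"dataset"`.
#' @export
fixture_suite <- function(name = c("tiny", "small", "benchmark_scale"),
                          dir = tempfile("lmi_fixture_"), seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = list(n_l = 6L, n_m = 8L, n_blocks = 2L, p_in = 0.7, p_out = 0.05,
                seq_len_l = c(60L, 120L)),
    small = list(n_l = 30L, n_m = 50L, n_blocks = 3L, p_in = 0.3, p_out = 0.02,
                 seq_len_l = c(100L, 250L)),
    # expected edges: 36920 * 0.02 + 110760 * 0.003 ~ 1071, within 10% of 1057
    benchmark_scale = list(n_l = 284L, n_m = 520L, n_blocks = 4L, p_in = 0.02,
                       p_out = 0.003, seq_len_l = c(200L, 500L)))
  ds <- simulate_interactions(cfg$n_l, cfg$n_m, cfg$n_blocks, cfg$p_in,
                              cfg$p_out, seed = seed,
                              seq_len_l = cfg$seq_len_l)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(edges = file.path(dir, "edges.tsv"),
                lncrna_fasta = file.path(dir, "lncrna.fasta"),
                mirna_fasta = file.path(dir, "mirna.fasta"),
                manifest = file.path(dir, "manifest.json"))
  readr::write_tsv(as_tibble(ds), paths$edges, col_names = FALSE)
  write_fasta(ds$lncrna_seqs, paths$lncrna_fasta)
  write_fasta(ds$mirna_seqs, paths$mirna_fasta)
  jsonlite::write_json(list(name = name, seed = seed,
                            n_lncrna = length(ds$lncrna_ids),
                            n_mirna = length(ds$mirna_ids),
                            n_edges = nrow(ds$edges),
                            generator = cfg),
                       paths$manifest, auto_unbox = TRUE)
  attr(paths, "dataset") <- ds
  invisible(paths)
}

write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}
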