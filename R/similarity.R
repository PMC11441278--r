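#' Meta-path (shared-partner) similarity matrix
#'
#' Two entities on the same side of the bipartite interaction graph are
#' called similar when a path of type lncRNA-miRNA-lncRNA (or
#' miRNA-lncRNA-miRNA) connects them, i.e. when they share at least one
#' interacting partner on the opposite side. The result is the binary matrix
#' `sign(D %*% t(D))` (lncRNA side) or `sign(t(D) %*% D)` (miRNA side).
#'
#' The diagonal is forced to 1 for every entity — including isolated ones —
#' so that the matrix can serve directly as a graph-attention adjacency in
#' which each node has at least itself as a neighbour (the attention softmax
#' is undefined over an empty neighbourhood). Set `self_loops = FALSE` to
#' keep the raw `sign` diagonal instead.
#'
#' @param adjacency Binary lncRNA x miRNA matrix from [build_adjacency()].
#' @param side `"lncrna"` or `"mirna"`: which same-side matrix to build.
#' @param self_loops Force unit diagonal (default `TRUE`).
#' @return A symmetric binary `n` x `n` matrix.
#' @export
metapath_similarity <- function(adjacency, side = c("lncrna", "mirna"),
                                self_loops = TRUE) {
  side <- match.arg(side)
  D <- adjacency
  S <- if (side == "lncrna") tcrossprod(D) else crossprod(D)
  S <- (S > 0) * 1
  if (self_loops) diag(S) <- 1
  S
}

#' Gaussian kernel similarity matrix
#'
#' Radial-basis similarity on feature vectors:
#' `exp(-||x_p - x_q||^2 / (2 * sigma^2))` with the Euclidean norm. Entries
#' lie in `(0, 1]` with an exactly unit diagonal; identical rows score 1 and
#' similarity decays with distance at rate set by the bandwidth.
#'
#' @param features Numeric matrix, one row per entity (e.g. `fm_l` from
#'   [featurize_dataset()]).
#' @param sigma Kernel bandwidth, a positive real (default 1).
#' @return A symmetric `n` x `n` matrix of similarities in `(0, 1]`.
#' @examples
#' gaussian_similarity(rbind(c(1, 0), c(0, 1)))[1, 2]  # exp(-1)
#' @export
gaussian_similarity <- function(features, sigma = 1) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a positive real")
  }
  X <- as.matrix(features)
  if (!all(is.finite(X))) stop("non-finite feature values")
  sq <- rowSums(X^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0                       # clip tiny negative round-off
  S <- exp(-d2 / (2 * sigma^2))
  S <- (S + t(S)) / 2                   # enforce exact symmetry
  diag(S) <- 1
  S
}

#' Write a similarity matrix as TSV with identifier headers
#'
#' @param sim Square matrix with dimnames.
#' @param path Output path.
#' @export
write_similarity <- function(sim, path) {
  df <- data.frame(id = rownames(sim), sim, check.names = FALSE, row.names = NULL)
  readr::write_tsv(df, path)
  invisible(path)
}
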