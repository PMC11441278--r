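#' Train distributed-memory document embeddings over a k-mer corpus
#'
#' Each document (RNA sequence, tokenized into overlapping k-mers) receives a
#' fixed-length vector trained jointly with per-token vectors: at every
#' position the mean of the document vector and the preceding `window` token
#' vectors feeds a softmax (with bias) that predicts the next k-mer. The
#' document vectors are returned as the feature matrix. Training is
#' single-threaded stochastic gradient descent and bit-reproducible from
#' `seed`.
#'
#' @param corpus Named list of k-mer token vectors, one per document (see
#'   [kmerize()]). Every document must contain at least one token.
#' @param dim Embedding dimension (default 128).
#' @param window Number of preceding context tokens (default 5).
#' @param epochs Training passes over the corpus (default 50).
#' @param lr Initial learning rate of the decaying SGD schedule.
#' @param seed Integer seed.
#' @return A numeric matrix with one row per document (rownames = document
#'   identifiers) and `dim` columns; attribute `"token_vectors"` carries the
#'   trained per-k-mer vectors.
#' @export
train_embeddings <- function(corpus, dim = 128L, window = 5L, epochs = 50L,
                             lr = 0.025, seed = 1L) {
  if (length(corpus) == 0L) stop("empty corpus")
  if (dim < 2) stop("embedding dimension must be >= 2")
  empty <- lengths(corpus) == 0L
  if (any(empty)) {
    stop("document(s) with zero k-mer tokens: ",
         paste(head(names(corpus)[empty], 10L), collapse = ", "))
  }
  vocab <- sort(unique(unlist(corpus, use.names = FALSE)))
  docs <- lapply(corpus, function(tok) match(tok, vocab) - 1L)
  fit <- .dm_train_cpp(docs, length(vocab), as.integer(dim), as.integer(window),
                       as.integer(epochs), lr, as.integer(seed))
  mat <- fit$doc
  rownames(mat) <- names(corpus)
  tok <- fit$token
  rownames(tok) <- vocab
  attr(mat, "token_vectors") <- tok
  mat
}

#' Sequence feature matrices for an interaction dataset
#'
#' Tokenizes every lncRNA and miRNA sequence into k-mers and trains one
#' shared embedding model on the joint corpus, so both entity types live in a
#' common feature space. Returns the per-entity feature matrices, row-aligned
#' with the dataset vocabularies.
#'
#' @param dataset An [interaction_dataset()] with sequences attached.
#' @inheritParams train_embeddings
#' @param k k-mer length (default 3).
#' @return A list with elements `fm_l` (`n_lncrna` x `dim`) and `fm_m`
#'   (`n_mirna` x `dim`), rownames set to the identifiers.
#' @export
featurize_dataset <- function(dataset, k = 3L, dim = 128L, window = 5L,
                              epochs = 50L, lr = 0.025, seed = 1L) {
  stopifnot(inherits(dataset, "interaction_dataset"))
  if (!has_sequences(dataset)) {
    stop("dataset has no sequences; attach them with attach_sequences()")
  }
  seqs <- c(dataset$lncrna_seqs, dataset$mirna_seqs)
  corpus <- lapply(seqs, kmerize, k = k)
  names(corpus) <- names(seqs)
  emb <- train_embeddings(corpus, dim = dim, window = window, epochs = epochs,
                          lr = lr, seed = seed)
  n_l <- length(dataset$lncrna_ids)
  fm_l <- emb[seq_len(n_l), , drop = FALSE]
  fm_m <- emb[n_l + seq_len(length(dataset$mirna_ids)), , drop = FALSE]
  attr(fm_l, "token_vectors") <- NULL
  attr(fm_m, "token_vectors") <- NULL
  list(fm_l = fm_l, fm_m = fm_m)
}

#' Write / read a feature matrix as TSV
#'
#' Plain-text round trip for feature matrices: identifiers in the first
#' column, one embedding dimension per remaining column.
#'
#' @param features Matrix with rownames (from [featurize_dataset()]).
#' @param path File path.
#' @return `write_features` returns `path` invisibly; `read_features` the
#'   matrix.
#' @export
write_features <- function(features, path) {
  df <- data.frame(id = rownames(features), features,
                   check.names = FALSE, row.names = NULL)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  dimnames(mat) <- list(df[[1]], NULL)
  mat
}
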