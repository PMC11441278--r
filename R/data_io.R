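#' Build an interaction dataset from an edge table
#'
#' The central data container: two identifier vocabularies (lncRNAs and
#' miRNAs, each ordered by first appearance), the set of known interaction
#' edges between them, and optionally the RNA sequences of every entity.
#'
#' @param edges A data frame whose first two columns are lncRNA and miRNA
#'   identifiers (character). Duplicate rows are collapsed.
#' @param lncrna_seqs,mirna_seqs Optional named character vectors mapping
#'   identifiers to RNA sequences (as returned by [read_fasta()]).
#' @return An object of class `interaction_dataset`: a list with elements
#'   `lncrna_ids`, `mirna_ids`, `edges` (two-column integer matrix of
#'   1-based `(lncrna, mirna)` index pairs), `lncrna_seqs`, `mirna_seqs`.
#' @examples
#' d <- interaction_dataset(data.frame(lncrna_id = c("L1", "L2"),
#'                                     mirna_id  = c("M1", "M1")))
#' d$lncrna_ids
#' @export
interaction_dataset <- function(edges, lncrna_seqs = NULL, mirna_seqs = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) stop("`edges` needs at least two columns (lncRNA id, miRNA id)")
  lnc <- as.character(edges[[1]])
  mir <- as.character(edges[[2]])
  if (anyNA(lnc) || anyNA(mir)) stop("missing identifiers in edge table")
  keep <- !duplicated(paste0(lnc, "\r", mir))
  lnc <- lnc[keep]; mir <- mir[keep]
  lncrna_ids <- unique(lnc)
  mirna_ids  <- unique(mir)
  edge_mat <- cbind(lncrna = match(lnc, lncrna_ids),
                    mirna  = match(mir, mirna_ids))
  obj <- structure(list(lncrna_ids = lncrna_ids,
                        mirna_ids  = mirna_ids,
                        edges      = edge_mat,
                        lncrna_seqs = NULL, mirna_seqs = NULL),
                   class = "interaction_dataset")
  if (!is.null(lncrna_seqs) || !is.null(mirna_seqs)) {
    obj <- attach_sequences(obj, lncrna_seqs, mirna_seqs)
  }
  obj
}

#' @export
print.interaction_dataset <- function(x, ...) {
  cat(sprintf("<interaction_dataset> %d lncRNAs x %d miRNAs, %d interactions\n",
              length(x$lncrna_ids), length(x$mirna_ids), nrow(x$edges)))
  cat(sprintf("  sequences: %s\n",
              if (has_sequences(x)) "present" else "absent"))
  invisible(x)
}

#' @export
as_tibble.interaction_dataset <- function(x, ...) {
  tibble::tibble(lncrna_id = x$lncrna_ids[x$edges[, 1]],
                 mirna_id  = x$mirna_ids[x$edges[, 2]])
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

has_sequences <- function(dataset) {
  !is.null(dataset$lncrna_seqs) && !is.null(dataset$mirna_seqs)
}

#' Attach RNA sequences to a dataset
#'
#' @param dataset An [interaction_dataset()].
#' @param lncrna_seqs,mirna_seqs Named character vectors of RNA sequences.
#'   Every vocabulary identifier must be present; extra sequences are dropped.
#' @return The dataset with sequences attached.
#' @export
attach_sequences <- function(dataset, lncrna_seqs, mirna_seqs) {
  stopifnot(inherits(dataset, "interaction_dataset"))
  miss_l <- setdiff(dataset$lncrna_ids, names(lncrna_seqs))
  miss_m <- setdiff(dataset$mirna_ids, names(mirna_seqs))
  if (length(miss_l) || length(miss_m)) {
    stop("missing sequences for: ",
         paste(head(c(miss_l, miss_m), 10L), collapse = ", "))
  }
  dataset$lncrna_seqs <- unname(lncrna_seqs[dataset$lncrna_ids])
  names(dataset$lncrna_seqs) <- dataset$lncrna_ids
  dataset$mirna_seqs <- unname(mirna_seqs[dataset$mirna_ids])
  names(dataset$mirna_seqs) <- dataset$mirna_ids
  dataset
}

#' Read an interaction edge list
#'
#' Reads a tab-delimited edge list (lncRNA id, miRNA id; optional
#' `#`-prefixed header lines) into an [interaction_dataset()]. Duplicate rows
#' are collapsed; vocabularies keep first-appearance order.
#'
#' @param path Path to a UTF-8 TSV file with at least two columns.
#' @return An `interaction_dataset`.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no interactions in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, function(f) length(f) < 2L || !nzchar(f[[1]]) || !nzchar(f[[2]]), logical(1)))
  if (length(bad)) {
    stop(sprintf("malformed row at line %d of %s (need two tab-separated identifiers)",
                 line_no[bad[1]], path))
  }
  edges <- data.frame(lncrna_id = vapply(fields, `[[`, character(1), 1L),
                      mirna_id  = vapply(fields, `[[`, character(1), 2L))
  ds <- interaction_dataset(edges)
  message(sprintf("read %d interactions: %d lncRNAs, %d miRNAs",
                  nrow(ds$edges), length(ds$lncrna_ids), length(ds$mirna_ids)))
  ds
}

#' Read RNA sequences from a FASTA file
#'
#' Identifiers are the first whitespace-delimited token of each header line;
#' multi-line records are concatenated; DNA input is normalized to the RNA
#' alphabet (`T` becomes `U`, lower case raised).
#'
#' @param path Path to a FASTA file over the `A,C,G,U,T,N` alphabet.
#' @return A named character vector, identifier -> RNA sequence.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier: ", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("T", "U", seqs)
  if (any(!nzchar(seqs))) stop("empty sequence for: ", ids[!nzchar(seqs)][1])
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad)) {
    stop("sequence for ", ids[bad][1],
         " contains characters outside the A,C,G,U,T,N alphabet")
  }
  setNames(seqs, ids)
}

#' Bipartite adjacency matrix of known interactions
#'
#' @param dataset An [interaction_dataset()].
#' @return A binary `n_lncrna` x `n_mirna` matrix with identifier dimnames;
#'   entry `[i, j]` is 1 iff lncRNA `i` is known to interact with miRNA `j`.
#' @export
build_adjacency <- function(dataset) {
  stopifnot(inherits(dataset, "interaction_dataset"))
  A <- matrix(0, length(dataset$lncrna_ids), length(dataset$mirna_ids),
              dimnames = list(dataset$lncrna_ids, dataset$mirna_ids))
  A[dataset$edges] <- 1
  A
}

# Run code under a temporary RNG state so seeded helpers do not disturb the
# caller's random stream.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Stage seeds derived from one master seed, kept below .Machine$integer.max.
derive_seeds <- function(seed) {
  with_local_seed(seed, {
    s <- sample.int(2147483646L, 4L)
    names(s) <- c("split", "embed", "init", "negatives")
    s
  })
}

#' Balanced train/validation split of interaction pairs
#'
#' Positive edges are partitioned at random in proportion `ratio` (the
#' training side receives `ceiling(ratio * n_edges)`). Each partition is then
#' balanced with an equal number of non-interacting pairs drawn uniformly
#' from the bipartite non-edges; negatives are disjoint between partitions
#' and from all positives.
#'
#' @param dataset An [interaction_dataset()].
#' @param ratio Fraction of positive edges assigned to training (default 0.8,
#'   the 8:2 protocol).
#' @param seed Integer seed; the split is fully reproducible from it.
#' @return A tibble with columns `lncrna_id`, `mirna_id`, `label` (0/1) and
#'   `partition` (`"train"`/`"validation"`).
#' @export
split_interactions <- function(dataset, ratio = 0.8, seed = 1L) {
  stopifnot(inherits(dataset, "interaction_dataset"))
  if (!(ratio > 0 && ratio < 1)) stop("`ratio` must be strictly between 0 and 1")
  n_l <- length(dataset$lncrna_ids)
  n_m <- length(dataset$mirna_ids)
  n_edges <- nrow(dataset$edges)
  pos_lin <- (dataset$edges[, 2] - 1L) * n_l + dataset$edges[, 1]
  pool <- setdiff(seq_len(n_l * n_m), pos_lin)
  if (length(pool) < n_edges) {
    stop(sprintf("non-edge pool (%d) smaller than the %d negatives required",
                 length(pool), n_edges))
  }
  with_local_seed(seed, {
    n_train <- as.integer(ceiling(ratio * n_edges))
    train_idx <- sample.int(n_edges, n_train)
    neg_lin <- sample(pool, n_edges)
  })
  part <- rep("validation", n_edges)
  part[train_idx] <- "train"
  neg_i <- ((neg_lin - 1L) %% n_l) + 1L
  neg_j <- ((neg_lin - 1L) %/% n_l) + 1L
  neg_part <- c(rep("train", n_train), rep("validation", n_edges - n_train))
  tibble::tibble(
    lncrna_id = c(dataset$lncrna_ids[dataset$edges[, 1]], dataset$lncrna_ids[neg_i]),
    mirna_id  = c(dataset$mirna_ids[dataset$edges[, 2]], dataset$mirna_ids[neg_j]),
    label     = rep(c(1L, 0L), each = n_edges),
    partition = c(part, neg_part)
  )
}

#' Write a split table to TSV
#'
#' @param splits Tibble from [split_interactions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_splits <- function(splits, path) {
  readr::write_tsv(splits, path)
  invisible(path)
}

# Restrict a dataset's edge set to the rows of a split table with the given
# partition/label, preserving vocabularies. Used to build leakage-free
# meta-path graphs from training positives only.
subset_edges <- function(dataset, splits, partition = "train") {
  sel <- splits$partition == partition & splits$label == 1L
  dataset$edges <- cbind(lncrna = match(splits$lncrna_id[sel], dataset$lncrna_ids),
                         mirna  = match(splits$mirna_id[sel], dataset$mirna_ids))
  dataset
}
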