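#' Overlapping k-mer tokens of an RNA sequence
#'
#' Slides a window of length `k` over the sequence with stride 1. Sequences
#' shorter than `k` yield an empty token vector. Tokens containing `N` are
#' kept as literal tokens rather than dropped.
#'
#' @param sequence A single RNA string (normalized alphabet, see
#'   [read_fasta()]).
#' @param k Window length, a positive integer (default 3).
#' @return Character vector of `max(0, nchar(sequence) - k + 1)` tokens.
#' @examples
#' kmerize("AUGCAU", 3)
#' @export
kmerize <- function(sequence, k = 3L) {
  if (length(k) != 1L || is.na(k) || k < 1) stop("`k` must be a positive integer")
  k <- as.integer(k)
  n <- nchar(sequence)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(sequence, starts, starts + k - 1L)
}

#' Per-document k-mer frequency table
#'
#' @param corpus A named list of token vectors (one per document), e.g.
#'   `lapply(seqs, kmerize, k = 3)`.
#' @return A named list of named integer count vectors; counts in each
#'   element sum to that document's token count.
#' @export
kmer_frequencies <- function(corpus) {
  if (length(corpus) == 0L) stop("empty corpus")
  lapply(corpus, function(tokens) {
    if (length(tokens) == 0L) return(integer(0))
    tab <- table(tokens)
    setNames(as.integer(tab), names(tab))
  })
}
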