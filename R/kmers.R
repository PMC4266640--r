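# Shared k-mer (word) machinery. Words containing any non-ACGT character are
# never indexed -- Biostrings counts only pure-ACGT words -- which is exactly
# the property the N-gap stitched construction relies on.

#' Usable words of a sequence
#'
#' Returns the distinct `word_size`-mers of `seq` as 1-based integer codes in
#' lexicographic (A<C<G<T) order, excluding every window that contains a
#' non-ACGT character. For a stitched read R1+"N"+R2 the result is exactly
#' the union of the words of R1 and of R2: no word spans the junction.
#'
#' @param seq sequence string (IUPAC; ambiguous positions void the windows
#'   covering them).
#' @param word_size word length (default 8).
#' @return sorted integer vector of word codes in `1..4^word_size`.
#' @export
usable_words <- function(seq, word_size = 8L) {
  if (nchar(seq) < word_size) return(integer())
  f <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                            width = word_size)
  unname(which(f > 0L))
}

#' Decode integer word codes back to sequences
#'
#' @param codes integer codes as returned by [usable_words()].
#' @param word_size word length.
#' @return character vector of words.
#' @export
decode_words <- function(codes, word_size = 8L) {
  mkAllStrings <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), word_size)
  mkAllStrings[codes]
}

# distinct-word integer codes for many sequences; list of integer vectors
word_sets <- function(seqs, word_size = 8L, chunk = 200L) {
  out <- vector("list", length(seqs))
  idx <- seq_along(seqs)
  for (grp in split(idx, ceiling(idx / chunk))) {
    m <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(seqs[grp]), width = word_size)
    for (j in seq_along(grp)) out[[grp[j]]] <- unname(which(m[j, ] > 0L))
  }
  out
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

revcomp_many <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

# shared-word counts between one query word set and a list of word sets
shared_word_counts <- function(query_words, sets, word_size = 8L) {
  if (!length(query_words)) return(rep(0L, length(sets)))
  lw <- logical(4L^word_size)
  lw[query_words] <- TRUE
  vapply(sets, function(w) sum(lw[w]), 0L)
}

# sparse word-presence matrix (4^word_size x n sequences)
word_matrix <- function(seqs, word_size = 8L) {
  sets <- word_sets(seqs, word_size)
  Matrix::sparseMatrix(i = unlist(sets),
                       j = rep(seq_along(sets), lengths(sets)),
                       x = 1,
                       dims = c(4L^word_size, length(sets)))
}

# shared-word counts of one query word set against the columns of a
# word_matrix; fast path for large row sets (template alignments)
shared_counts_matrix <- function(query_words, mat) {
  if (!length(query_words)) return(numeric(ncol(mat)))
  as.vector(Matrix::crossprod(
    mat, Matrix::sparseVector(1, i = query_words, length = nrow(mat))))
}
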