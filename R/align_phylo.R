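# Template-threaded multiple alignment into a fixed column space (the
# pipeline role a covariance-model aligner fills: per-mate split/align/
# rejoin with a negative-score filter), plus neighbor-joining phylogeny on
# Jukes-Cantor distances and cophenetic matrices.

#' Load a template (seed) alignment
#'
#' @param rows named character vector of equal-length gapped sequences
#'   (gap characters `-` or `.`), or a path to an aligned FASTA file.
#' @return a `template_alignment`: rows, column count, per-row ungapped
#'   sequences, ungapped-position -> column maps, and word indexes of the
#'   ungapped rows (both strands) for template-row selection.
#' @export
template_alignment <- function(rows) {
  if (length(rows) == 1L && file.exists(rows[1]) && is.null(names(rows))) {
    lib <- read_fasta(rows)
    rows <- setNames(lib$seq, lib$id)
  }
  rows <- toupper(chartr(".", "-", rows))
  if (!length(rows)) stop("template alignment is empty")
  width <- unique(nchar(rows))
  if (length(width) != 1L) stop("template rows must have equal length")
  chars <- strsplit(rows, "")
  colmap <- lapply(chars, function(ch) which(ch != "-"))
  ungapped <- vapply(chars, function(ch) paste(ch[ch != "-"], collapse = ""), "")
  structure(list(rows = rows, column_count = width, ungapped = ungapped,
                 colmap = colmap, words_mat = word_matrix(ungapped)),
            class = "template_alignment")
}

#' @export
print.template_alignment <- function(x, ...) {
  cat(sprintf("<template_alignment> rows=%d columns=%d\n",
              length(x$rows), x$column_count))
  invisible(x)
}

#' Thread one query onto the template column space
#'
#' The best-matching template row is chosen by shared 8-mer count (both
#' query orientations are considered, and the better-scoring orientation is
#' kept, so reads delivered in reverse-complement orientation -- R2 mates --
#' thread correctly without the pipeline ever flipping them). The query is
#' aligned to the chosen row's ungapped sequence (match +1, mismatch -2, gap
#' open -10, extend -1; the query aligns end-to-end, the template locally),
#' matched bases are placed into template columns through the row's column
#' map, and query insertions relative to the template are dropped and
#' counted. A query sharing no 8-mer with any row in either orientation gets
#' score -1, guaranteeing removal by the negative-score filter.
#'
#' @param seq query sequence string.
#' @param template a [template_alignment()].
#' @return list with `columns` (gapped string of template width), `score`,
#'   `insertion_count`, `template_row`, and `strand` (`"+"`/`"-"`).
#' @export
align_to_template <- function(seq, template) {
  align_batch(seq, template)[[1]]
}

# thread one query (already in plus orientation) onto one template row
thread_query <- function(q, row, template) {
  out <- rep("-", template$column_count)
  cm <- template$colmap[[row]]
  # fast path: the query is an exact substring of the chosen row (the
  # alignment optimum under the scoring scheme), as every error-free
  # amplicon read of a template taxon is
  hit <- regexpr(q, template$ungapped[row], fixed = TRUE)
  if (hit > 0L) {
    out[cm[hit:(hit + nchar(q) - 1L)]] <- strsplit(q, "")[[1]]
    return(list(columns = paste(out, collapse = ""), score = nchar(q),
                insertion_count = 0L))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(template$ungapped[row]),
    type = "global-local", substitutionMatrix = nuc_submat(),
    gapOpening = 10, gapExtension = 1)
  p <- strsplit(as.character(pa), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  refpos <- BiocGenerics::start(Biostrings::subject(pa)) - 1L
  ins <- 0L
  for (k in seq_along(p)) {
    if (s[k] != "-") {
      refpos <- refpos + 1L
      if (p[k] != "-") out[cm[refpos]] <- p[k]
    } else if (p[k] != "-") ins <- ins + 1L
  }
  list(columns = paste(out, collapse = ""), score = Biostrings::score(pa),
       insertion_count = ins)
}

# vectorized row/strand selection (one sparse product per strand), then
# per-query threading
align_batch <- function(seqs, template) {
  if (!length(seqs)) return(list())
  sh_f <- as.matrix(Matrix::crossprod(template$words_mat, word_matrix(seqs)))
  sh_r <- as.matrix(Matrix::crossprod(template$words_mat,
                                      word_matrix(revcomp_many(seqs))))
  all_gap <- paste(rep("-", template$column_count), collapse = "")
  lapply(seq_along(seqs), function(i) {
    if (max(sh_f[, i], sh_r[, i]) == 0)
      return(list(columns = all_gap, score = -1, insertion_count = 0L,
                  template_row = NA_character_, strand = "+"))
    strand <- if (max(sh_f[, i]) >= max(sh_r[, i])) "+" else "-"
    row <- which.max(if (strand == "+") sh_f[, i] else sh_r[, i])
    q <- if (strand == "+") seqs[i] else revcomp(seqs[i])
    c(thread_query(q, row, template),
      list(template_row = names(template$rows)[row], strand = strand))
  })
}

#' Align a single-read or full-length library to the template
#'
#' Each read is threaded with [align_to_template()]; reads with negative
#' alignment score are removed.
#'
#' @param lib a [seq_library()] of unjoined reads.
#' @param template a [template_alignment()].
#' @return list with `ids`, `rows` (named gapped strings), `scores`,
#'   `insertions`, and `removed` (ids filtered by the score rule).
#' @export
align_library <- function(lib, template) {
  al <- align_batch(lib$seq, template)
  scores <- vapply(al, `[[`, 0, "score")
  keep <- scores >= 0
  rows <- setNames(vapply(al[keep], `[[`, "", "columns"), lib$id[keep])
  list(ids = lib$id[keep], rows = rows, scores = scores[keep],
       insertions = vapply(al[keep], `[[`, 0L, "insertion_count"),
       removed = lib$id[!keep])
}

#' Align a paired (concatenated) library mate-by-mate
#'
#' Each joined read is split at its recorded `pair_split` into R1 and R2
#' components, each component is threaded independently (a structural
#' aligner cannot bridge the unsequenced gap between the mates), pairs in
#' which either component scores negative are removed entirely, and
#' surviving pairs are rejoined column-wise: all R1-region columns followed
#' by all R2-region columns (width = twice the template width).
#'
#' @param concat_lib a `paired_concat` [seq_library()] with `pair_split`.
#' @param template a [template_alignment()].
#' @return as [align_library()].
#' @export
align_paired <- function(concat_lib, template) {
  if (concat_lib$type != "paired_concat")
    stop("align_paired requires a paired_concat library")
  if (is.null(concat_lib$pair_split)) stop("missing pair_split")
  ids <- concat_lib$id
  sp <- unname(concat_lib$pair_split[ids])
  r1s <- substr(concat_lib$seq, 1L, sp)
  r2s <- substr(concat_lib$seq, sp + 1L, nchar(concat_lib$seq))
  al1 <- align_batch(r1s, template)
  al2 <- align_batch(r2s, template)
  keep <- logical(length(ids))
  rows <- character(length(ids))
  scores <- numeric(length(ids))
  ins <- integer(length(ids))
  for (i in seq_along(ids)) {
    a1 <- al1[[i]]
    a2 <- al2[[i]]
    if (a1$score < 0 || a2$score < 0) next
    keep[i] <- TRUE
    rows[i] <- paste0(a1$columns, a2$columns)
    scores[i] <- a1$score + a2$score
    ins[i] <- a1$insertion_count + a2$insertion_count
  }
  list(ids = ids[keep], rows = setNames(rows[keep], ids[keep]),
       scores = scores[keep], insertions = ins[keep],
       removed = ids[!keep])
}

#' Remove empty (all-gap) columns from an alignment
#'
#' @param rows named character vector of equal-length gapped strings.
#' @return the rows with every all-gap column removed; row order preserved.
#' @export
strip_empty_columns <- function(rows) {
  if (!length(rows)) return(rows)
  m <- do.call(rbind, strsplit(rows, ""))
  keep <- colSums(m != "-") > 0L
  setNames(apply(m[, keep, drop = FALSE], 1L, paste, collapse = ""),
           names(rows))
}

#' Jukes-Cantor (JC69) distance matrix from an alignment
#'
#' Pairwise-deletion p-distances (columns where either row is a gap are
#' ignored for that pair) transformed by `d = -3/4 log(1 - 4/3 p)`. Pairs at
#' or beyond the JC69 saturation point (`p >= 0.74`), and pairs sharing no
#' ungapped column, are set to the saturation distance 5.0.
#'
#' @param rows named character vector of equal-length gapped strings.
#' @param saturation distance assigned to saturated pairs.
#' @return symmetric distance matrix with zero diagonal.
#' @export
jc69_distance_matrix <- function(rows, saturation = 5.0) {
  n <- length(rows)
  if (n < 2L) stop("need at least two sequences")
  m <- do.call(rbind, strsplit(chartr(".", "-", rows), ""))
  nongap <- m %in% c("A", "C", "G", "T")
  dim(nongap) <- dim(m)
  shared <- nongap %*% t(nongap)
  matches <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    ib <- (m == b) & nongap
    matches <- matches + ib %*% t(ib)
  }
  p <- ifelse(shared > 0, 1 - matches / pmax(shared, 1), 1)
  d <- matrix(saturation, n, n)
  ok <- shared > 0 & p < 0.74
  d[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  diag(d) <- 0
  dimnames(d) <- list(names(rows), names(rows))
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via ape) with negative branch lengths
#' clamped to zero. The 2-taxon case is returned as two pendant edges of
#' half the distance each, preserving the leaf-to-leaf path length.
#'
#' @param D symmetric distance matrix with labels and zero diagonal.
#' @return an `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (is.null(rownames(D))) stop("distance matrix must be labeled")
  if (nrow(D) < 2L) stop("need at least two taxa")
  if (max(abs(D - t(D))) > 1e-8 || any(D < 0))
    stop("distance matrix must be symmetric and nonnegative")
  if (nrow(D) == 2L) {
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2L),
               edge.length = rep(D[1, 2] / 2, 2L),
               tip.label = rownames(D), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Cophenetic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths on the tree path between
#' leaves i and j.
#'
#' @param tree an `ape::phylo` tree with at least 2 leaves.
#' @return symmetric matrix over the tip labels.
#' @export
cophenetic_matrix <- function(tree) {
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 leaves")
  ape::cophenetic.phylo(tree)
}
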