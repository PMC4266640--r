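# Pair tracking, length uniformization and the two join constructions:
# direct concatenation (for OTU clustering, which needs globally alignable
# reads of uniform length) and N-gap stitching (for word-based taxonomy,
# which skips words containing ambiguous bases).
#
# R2 is deliberately NOT reverse-complemented before joining: reads are kept
# exactly as sequenced, and every downstream step is orientation-insensitive
# (the classifier is trained on both strands; the structural aligner threads
# each mate in its better-scoring orientation).

#' Pair-joining parameters
#'
#' @param r2_trim_len length R2 mates are truncated to before joining. The
#'   default is 4/5 of the R2 original length (200 bp for 250 bp reads),
#'   chosen because read-2 quality degrades toward the 3' end.
#' @param gap_char single IUPAC ambiguity character inserted between mates by
#'   the stitched construction.
#' @param r2_original_length as-sequenced R2 length used for the default trim.
#' @return a list of class `pair_join_params`.
#' @export
pair_join_params <- function(r2_trim_len = NULL, gap_char = "N",
                             r2_original_length = 250L) {
  if (is.null(r2_trim_len))
    r2_trim_len <- as.integer(round(0.8 * r2_original_length))
  if (r2_trim_len <= 0) stop("r2_trim_len must be positive")
  iupac_ambig <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  if (!gap_char %in% iupac_ambig)
    stop("gap_char must be an IUPAC ambiguity code")
  structure(list(r2_trim_len = as.integer(r2_trim_len), gap_char = gap_char),
            class = "pair_join_params")
}

#' Keep matched pairs and uniformize R2 length
#'
#' Keeps only reads whose id (after stripping a trailing `/1` or `/2`)
#' occurs in both libraries. R1 reads are kept whole; R2 reads are truncated
#' to `min(length, r2_trim_len)` -- reads already shorter than the cutoff are
#' retained as they are. Sample-of-origin annotations are carried through.
#'
#' @param r1,r2 quality-filtered [seq_library()] objects.
#' @param params a [pair_join_params()].
#' @return list of `r1` and `r2` libraries restricted to matched pairs, in
#'   R1's id order.
#' @export
pair_and_trim <- function(r1, r2, params = pair_join_params()) {
  k1 <- strip_mate_suffix(r1$id)
  k2 <- strip_mate_suffix(r2$id)
  common <- intersect(k1, k2)
  if (!length(common))
    warning("no read pairs survive in both libraries")
  i1 <- match(common, k1)
  i2 <- match(common, k2)
  out1 <- seq_library("R1", common, r1$seq[i1], r1$sample_id[i1],
                      qual = if (!is.null(r1$qual)) r1$qual[i1])
  trimmed <- substr(r2$seq[i2], 1L, params$r2_trim_len)
  out2 <- seq_library("R2", common, trimmed, r2$sample_id[i2],
                      qual = if (!is.null(r2$qual))
                        lapply(r2$qual[i2], function(q)
                          q[seq_len(min(length(q), params$r2_trim_len))]))
  list(r1 = out1, r2 = out2)
}

#' Build the concatenated and N-gap-stitched joined libraries
#'
#' From matched, trimmed mates builds (i) the `paired_concat` library, the
#' plain concatenation R1+R2 used for dereplication, OTU picking and
#' mapping, and (ii) the `paired_stitched` library, R1+gap+R2, used for
#' taxonomy so that no classifier word spans the unsequenced junction. Both
#' record `pair_split` (the R1 component length) for later splitting.
#'
#' @param r1,r2 output of [pair_and_trim()] (identical id sets and order).
#' @param params a [pair_join_params()].
#' @return list with `concat` and `stitched` [seq_library()] objects.
#' @export
make_joined_reads <- function(r1, r2, params = pair_join_params()) {
  if (!identical(r1$id, r2$id))
    stop("internal error: mate libraries must have identical id sets")
  if (!length(r1$id)) {
    return(list(concat = seq_library("paired_concat",
                                     pair_split = integer()),
                stitched = seq_library("paired_stitched",
                                       pair_split = integer())))
  }
  split <- setNames(nchar(r1$seq), r1$id)
  concat <- seq_library("paired_concat", r1$id, paste0(r1$seq, r2$seq),
                        r1$sample_id, pair_split = split)
  stitched <- seq_library("paired_stitched", r1$id,
                          paste0(r1$seq, params$gap_char, r2$seq),
                          r1$sample_id, pair_split = split)
  list(concat = concat, stitched = stitched)
}

#' Split a joined read back into its mates
#'
#' @param lib a `paired_concat` or `paired_stitched` [seq_library()].
#' @param id read id to split.
#' @return list with `r1` and `r2` sequence strings.
#' @export
split_joined_read <- function(lib, id) {
  if (!lib$type %in% c("paired_concat", "paired_stitched"))
    stop("split_joined_read requires a joined library")
  i <- match(id, lib$id)
  if (is.na(i)) stop("unknown read id '", id, "'")
  s <- lib$pair_split[[id]]
  gap <- if (lib$type == "paired_stitched") 1L else 0L
  list(r1 = substr(lib$seq[i], 1L, s),
       r2 = substr(lib$seq[i], s + gap + 1L, nchar(lib$seq[i])))
}
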