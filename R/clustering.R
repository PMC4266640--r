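# Dereplication, abundance-sorted greedy de novo OTU picking at 97% identity
# with a two-parent chimera screen, and mapping of all reads back to the OTU
# representatives.

nuc_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                           baseOnly = TRUE)
}

align_pair <- function(pattern, subject, type = "overlap") {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(pattern), Biostrings::DNAString(subject),
    type = type, substitutionMatrix = nuc_submat(),
    gapOpening = 10, gapExtension = 1)
}

# identity from aligned pairs: matches / alignment columns; the overlap
# alignment type has already clipped terminal-gap columns, and internal gap
# columns are counted via the indel widths
identity_from_alignment <- function(pa) {
  ni <- Biostrings::nindel(pa)
  cols <- Biostrings::nmatch(pa) + Biostrings::nmismatch(pa) +
    Biostrings::insertion(ni)[, "WidthSum"] +
    Biostrings::deletion(ni)[, "WidthSum"]
  unname(ifelse(cols == 0L, 0, Biostrings::nmatch(pa) / cols))
}

# candidates that could possibly reach `threshold` identity with a query of
# `n_words` distinct words: each edit destroys at most `word_size` words
word_count_gate <- function(shared, n_words, query_len, threshold,
                            word_size = 8L) {
  m_max <- ceiling((1 - threshold) * (query_len + 20)) + 2L
  shared >= n_words - word_size * m_max
}

#' Pairwise sequence identity
#'
#' Global alignment with match +1, mismatch -2, gap open -10, gap extend -1
#' and free terminal gaps; identity is the number of matching columns divided
#' by the number of alignment columns, excluding terminal-gap columns
#' (internal gap columns count against identity).
#'
#' @param a,b sequence strings (or `b` a character vector of subjects, in
#'   which case a vector of identities of `a` against each is returned).
#' @return identity fraction(s) in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nchar(a) || any(!nchar(b))) stop("sequences must be non-empty")
  identity_from_alignment(align_pair(b, a))
}

# per-position match profile of `candidate` against `parent`: logical vector
# over candidate positions, TRUE where the base aligns to an equal base.
# Equal-length pairs (the uniform-length libraries the picker is designed
# for) are compared position-wise without alignment; unequal lengths go
# through the full alignment.
match_profile <- function(candidate, parent) {
  if (nchar(candidate) == nchar(parent)) {
    return(strsplit(candidate, "")[[1]] == strsplit(parent, "")[[1]])
  }
  pa <- align_pair(candidate, parent)
  prof <- logical(nchar(candidate))
  p <- strsplit(as.character(pa), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  qpos <- BiocGenerics::start(Biostrings::pattern(pa)) - 1L
  for (k in seq_along(p)) {
    if (p[k] != "-") {
      qpos <- qpos + 1L
      prof[qpos] <- p[k] == s[k]
    }
  }
  prof
}

#' Dereplicate a library into 100%-identity clusters
#'
#' Groups exactly identical sequences. Clusters are sorted by decreasing
#' size, with ties broken lexicographically by sequence and then by
#' representative id, so the result is invariant under input permutation.
#' The representative of a cluster is its lexicographically smallest member
#' id.
#'
#' @param lib a [seq_library()].
#' @return list of clusters, each a list with `rep_id`, `seq`, `size`,
#'   `member_ids`, and `sample_ids` (samples of the members, parallel to
#'   `member_ids`).
#' @export
dereplicate <- function(lib) {
  if (!length(lib)) return(list())
  groups <- split(seq_along(lib$id), lib$seq)
  clusters <- lapply(groups, function(ix) {
    ord <- order(lib$id[ix])
    ix <- ix[ord]
    list(rep_id = lib$id[ix[1]], seq = lib$seq[ix[1]],
         size = length(ix), member_ids = lib$id[ix],
         sample_ids = lib$sample_id[ix])
  })
  sizes <- vapply(clusters, `[[`, 0L, "size")
  seqs <- vapply(clusters, `[[`, "", "seq")
  reps <- vapply(clusters, `[[`, "", "rep_id")
  unname(clusters[order(-sizes, seqs, reps)])
}

# chimera screen: is `cand` explainable as parent A prefix + parent B suffix
# at >= model_identity? Parents below `profile_floor` single-parent identity
# are not considered: a bimera whose minor parent falls below that floor is,
# by the same arithmetic, near-identical to its major parent and is handled
# by the absorption rule instead.
is_chimeric <- function(cand_seq, cand_size, parent_seqs, parent_abund,
                        best_identity, threshold,
                        model_identity = 0.99, profile_floor = 0.85) {
  if (best_identity >= threshold) return(FALSE)
  ok <- parent_abund >= 2 * cand_size
  if (sum(ok) < 2L) return(FALSE)
  idx <- which(ok)
  profs <- lapply(parent_seqs[idx], function(p) match_profile(cand_seq, p))
  keep <- vapply(profs, mean, 0) >= profile_floor
  if (sum(keep) < 2L) return(FALSE)
  profs <- profs[keep]
  L <- nchar(cand_seq)
  pref <- lapply(profs, function(pr) c(0, cumsum(pr)))
  for (a in seq_along(pref)) {
    for (b in seq_along(pref)) {
      if (a == b) next
      # crossover after column k: A covers 1..k, B covers (k+1)..L
      chim <- max(pref[[a]][1:(L + 1)] + pref[[b]][L + 1] - pref[[b]][1:(L + 1)])
      if (chim / L >= model_identity) return(TRUE)
    }
  }
  FALSE
}

#' Greedy de novo OTU picking at fixed identity
#'
#' Abundance-sorted greedy centroid clustering: dereplicated clusters are
#' filtered (singletons and representatives shorter than `min_len` are
#' discarded), then processed in decreasing-abundance order. Each candidate
#' is compared to the existing centroids (candidate selection by shared
#' 8-mer count, alignment of the top `max_accepts` candidates); if the best
#' identity reaches `threshold` the candidate is absorbed, otherwise it is
#' screened as a putative two-parent chimera (parents must each have at
#' least twice the candidate's abundance and a crossover model at >= 99%
#' identity to the candidate), and failing that it founds a new centroid
#' `OTU_k` in creation order.
#'
#' @param clusters output of [dereplicate()] (already sorted).
#' @param threshold identity threshold (default 0.97).
#' @param min_len minimum representative length (0 disables; uniform-length
#'   joined libraries use the full joined length, synthetic full-length reads
#'   need no length screen).
#' @param drop_singletons discard size-1 clusters before picking.
#' @param chimera_check enable the chimera screen.
#' @param max_accepts number of top word-sharing centroids aligned per
#'   candidate.
#' @return list with `centroids` (list of `otu_id`, `seq`, `abundance`,
#'   `rep_id`) and `assignment` (named character: cluster rep id ->
#'   `otu_id`, `"chimera"`, or `"dropped"`).
#' @export
pick_otus <- function(clusters, threshold = 0.97, min_len = 0L,
                      drop_singletons = TRUE, chimera_check = TRUE,
                      max_accepts = 16L) {
  assignment <- character()
  centroids <- list()
  if (!length(clusters))
    return(list(centroids = centroids, assignment = assignment))
  keep <- vapply(clusters, function(cl)
    (!drop_singletons || cl$size >= 2L) && nchar(cl$seq) >= min_len, TRUE)
  for (cl in clusters[!keep]) assignment[cl$rep_id] <- "dropped"
  clusters <- clusters[keep]
  cent_seqs <- character()
  cent_words <- list()
  cent_abund <- integer()
  cluster_words <- word_sets(vapply(clusters, `[[`, "", "seq"))
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    w <- cluster_words[[ci]]
    shared <- if (length(cent_seqs)) shared_word_counts(w, cent_words)
              else integer()
    # absorption: only centroids passing the shared-word bound can possibly
    # reach the identity threshold, so only those are aligned
    gate <- which(word_count_gate(shared, length(w), nchar(cl$seq),
                                  threshold))
    gate <- gate[order(-shared[gate], gate)]
    gate <- gate[seq_len(min(max_accepts, length(gate)))]
    if (length(gate)) {
      ids <- identity_from_alignment(align_pair(cent_seqs[gate], cl$seq))
      best <- which.max(ids)
      best_id <- ids[best]
    } else best_id <- 0
    if (best_id >= threshold) {
      j <- gate[best]
      cent_abund[j] <- cent_abund[j] + cl$size
      assignment[cl$rep_id] <- paste0("OTU_", j)
      next
    }
    chimeric <- FALSE
    if (chimera_check && length(cent_seqs) >= 2L) {
      # a 99%-identity two-parent model requires the parents to jointly
      # carry nearly all of the candidate's words: every edit destroys at
      # most 8 words and the crossover itself at most 8 more, so pairs
      # falling short of this bound cannot explain the candidate and are
      # never aligned
      m_chim <- ceiling(0.01 * (nchar(cl$seq) + 20)) + 2L
      pair_bound <- length(w) - 8L * m_chim - 8L
      par <- which(cent_abund >= 2L * cl$size)
      if (length(par) >= 2L) {
        s <- shared[par]
        best_other <- vapply(seq_along(par), function(a)
          max(s[-a]), 0L)
        par <- par[s + best_other >= pair_bound]
      }
      if (length(par) >= 2L) {
        par <- par[order(-shared[par], par)]
        par <- par[seq_len(min(8L, length(par)))]
        chimeric <- is_chimeric(cl$seq, cl$size, cent_seqs[par],
                                cent_abund[par], best_id, threshold)
      }
    }
    if (chimeric) {
      assignment[cl$rep_id] <- "chimera"
    } else {
      cent_seqs <- c(cent_seqs, cl$seq)
      cent_words <- c(cent_words, list(w))
      cent_abund <- c(cent_abund, cl$size)
      assignment[cl$rep_id] <- paste0("OTU_", length(cent_seqs))
    }
  }
  centroids <- lapply(seq_along(cent_seqs), function(j) {
    rep_id <- names(assignment)[match(paste0("OTU_", j), assignment)]
    list(otu_id = paste0("OTU_", j), seq = cent_seqs[j],
         abundance = cent_abund[j], rep_id = rep_id)
  })
  list(centroids = centroids, assignment = assignment)
}

#' Check that no two centroids reach the identity threshold
#'
#' Post hoc sanity screen on a picked centroid set: for each centroid, its
#' top word-sharing neighbours are aligned and the maximum inter-centroid
#' identity is returned.
#'
#' @param centroids centroid list from [pick_otus()].
#' @param threshold identity threshold the centroids were picked at; only
#'   pairs whose shared-word count makes that identity possible are aligned
#'   (pairs failing the word bound cannot reach it).
#' @return maximum pairwise identity found among plausible pairs (0 if no
#'   pair can reach the threshold).
#' @export
max_centroid_identity <- function(centroids, threshold = 0.97) {
  n <- length(centroids)
  if (n < 2L) return(0)
  seqs <- vapply(centroids, `[[`, "", "seq")
  ws <- word_sets(seqs)
  worst <- 0
  for (i in seq_len(n)) {
    shared <- shared_word_counts(ws[[i]], ws)
    shared[i] <- -1L
    cand <- which(word_count_gate(shared, length(ws[[i]]), nchar(seqs[i]),
                                  threshold))
    if (!length(cand)) next
    worst <- max(worst,
                 identity_from_alignment(align_pair(seqs[cand], seqs[i])))
  }
  worst
}

#' Map reads to OTU representatives
#'
#' Every read (including singletons and reads below the picking length
#' cutoff) is assigned to the centroid of highest identity, provided that
#' identity reaches `threshold`; identity ties go to the centroid of larger
#' abundance, then to the lower OTU index. Unassigned reads are counted and
#' excluded from the table. Counts are accumulated per sample of origin.
#'
#' @param lib a `paired_concat` or `full_length` (or single-read)
#'   [seq_library()].
#' @param centroids centroid list from [pick_otus()] (after taxonomy
#'   cleaning).
#' @param threshold identity threshold (default 0.97).
#' @param max_accepts top word-sharing centroids aligned per distinct read
#'   sequence.
#' @return list with `counts` (OTU x sample integer matrix), `unmapped`
#'   (integer), and `assignment` (named character read id -> otu id or NA).
#' @export
map_reads_to_otus <- function(lib, centroids, threshold = 0.97,
                              max_accepts = 16L) {
  if (!length(centroids)) stop("empty centroid list (pipeline ordering bug)")
  cent_seqs <- vapply(centroids, `[[`, "", "seq")
  cent_ids <- vapply(centroids, `[[`, "", "otu_id")
  cent_abund <- vapply(centroids, function(x) as.integer(x$abundance), 0L)
  cent_words <- word_sets(cent_seqs)
  samples <- unique(lib$sample_id)
  counts <- matrix(0L, length(centroids), length(samples),
                   dimnames = list(cent_ids, samples))
  uniq <- unique(lib$seq)
  exact_all <- match(uniq, cent_seqs)
  uniq_words <- word_sets(uniq[is.na(exact_all)])
  names(uniq_words) <- uniq[is.na(exact_all)]
  hit <- integer(length(uniq))
  for (k in seq_along(uniq)) {
    s <- uniq[k]
    exact <- exact_all[k]
    if (!is.na(exact)) { hit[k] <- exact; next }
    w <- uniq_words[[s]]
    shared <- shared_word_counts(w, cent_words)
    cand <- which(word_count_gate(shared, length(w), nchar(s), threshold))
    cand <- cand[order(-shared[cand], cand)]
    cand <- cand[seq_len(min(max_accepts, length(cand)))]
    if (!length(cand)) { hit[k] <- 0L; next }
    ids <- identity_from_alignment(align_pair(cent_seqs[cand], s))
    ok <- ids >= threshold
    if (!any(ok)) { hit[k] <- 0L; next }
    top <- max(ids[ok])
    tied <- cand[ok][ids[ok] >= top - 1e-9]
    tied <- tied[order(-cent_abund[tied], tied)]
    hit[k] <- tied[1]
  }
  read_hit <- hit[match(lib$seq, uniq)]
  mapped <- read_hit > 0L
  if (any(mapped)) {
    tab <- table(factor(cent_ids[read_hit[mapped]], levels = cent_ids),
                 factor(lib$sample_id[mapped], levels = samples))
    counts[] <- as.integer(tab)
  }
  assignment <- setNames(ifelse(mapped, cent_ids[pmax(read_hit, 1L)],
                                NA_character_), lib$id)
  list(counts = counts, unmapped = sum(!mapped), assignment = assignment)
}
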