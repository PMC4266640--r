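# Validation harnesses: taxonomy accuracy per library type, comparable-trees
# phylogeny comparison (Mantel on cophenetic matrices), and beta-diversity
# comparison (Mantel on unweighted UniFrac matrices), with Wilcoxon
# signed-rank significance across communities.

#' Per-rank taxonomy accuracy
#'
#' Percentage of ids whose assigned name equals the ground-truth name at
#' each rank; a rank left unclassified counts as incorrect.
#'
#' @param assignments named list of `tax_assignment`s.
#' @param truth named character vector of 7-rank lineage strings covering the
#'   same ids.
#' @return named numeric vector (domain..species) of percentages.
#' @export
taxonomy_accuracy <- function(assignments, truth) {
  ids <- names(assignments)
  if (!length(truth) || !length(ids)) stop("empty truth or assignment set")
  if (!all(ids %in% names(truth)))
    stop("truth lineages missing for some ids")
  truth_mat <- do.call(rbind, lapply(ids, function(id)
    parse_lineage(truth[[id]], id)))
  assigned <- do.call(rbind, lapply(assignments, function(a) a$names))
  acc <- vapply(seq_len(7L), function(r)
    100 * mean(assigned[, r] == truth_mat[, r]), 0)
  setNames(acc, TAX_RANKS)
}

# one community x one library type through the validation pipeline:
# dereplicate -> pick OTUs -> (optional taxonomy cleaning) -> align ->
# strip empty columns -> map reads -> tree
run_community_pipeline <- function(lib, template, model = NULL,
                                   stitched = NULL, threshold = 0.97,
                                   min_len = 0L, n_bootstrap = 100L) {
  clusters <- dereplicate(lib)
  picked <- pick_otus(clusters, threshold = threshold, min_len = min_len)
  centroids <- picked$centroids
  if (!length(centroids)) stop("no OTU centroids picked")
  if (!is.null(model)) {
    query <- if (!is.null(stitched) && lib$type == "paired_concat") {
      idx <- match(vapply(centroids, `[[`, "", "rep_id"), stitched$id)
      setNames(stitched$seq[idx], vapply(centroids, `[[`, "", "rep_id"))
    } else {
      setNames(vapply(centroids, `[[`, "", "seq"),
               vapply(centroids, `[[`, "", "rep_id"))
    }
    assignments <- lapply(query, classify_seq, model = model,
                          n_bootstrap = n_bootstrap)
    centroids <- filter_unclassified(centroids, assignments)$centroids
    if (!length(centroids)) stop("all centroids removed as unclassified")
  }
  cent_lib <- if (lib$type == "paired_concat") {
    ids <- vapply(centroids, `[[`, "", "rep_id")
    seq_library("paired_concat", ids,
                vapply(centroids, `[[`, "", "seq"),
                "centroids", pair_split = lib$pair_split[ids])
  } else {
    seq_library(lib$type, vapply(centroids, `[[`, "", "rep_id"),
                vapply(centroids, `[[`, "", "seq"), "centroids")
  }
  al <- if (lib$type == "paired_concat") align_paired(cent_lib, template)
        else align_library(cent_lib, template)
  keep <- vapply(centroids, `[[`, "", "rep_id") %in% al$ids
  centroids <- centroids[keep]
  if (length(centroids) < 2L)
    stop("fewer than 2 aligned centroids; cannot build a tree")
  rows <- strip_empty_columns(al$rows)
  names(rows) <- vapply(centroids, `[[`, "", "otu_id")
  mapping <- map_reads_to_otus(lib, centroids, threshold = threshold)
  tree <- neighbor_joining(jc69_distance_matrix(rows))
  list(centroids = centroids, counts = mapping$counts,
       unmapped = mapping$unmapped, tree = tree, aligned = rows)
}

LIB_TYPES_SHORT <- c("paired", "R1", "R2")

#' Compare beta-diversity across library types
#'
#' For every community, runs the validation pipeline (dereplication, OTU
#' picking, template alignment, read mapping, neighbor-joining tree) on the
#' full-length, paired (concatenated), R1-only and R2-only libraries,
#' computes each library's unweighted UniFrac distance matrix between the
#' community's samples, and reports the Mantel correlation of each
#' short-read matrix against the full-length matrix. With at least five
#' communities, Wilcoxon signed-rank p-values across communities are
#' attached for paired-vs-R1 and paired-vs-R2.
#'
#' The default (`classify = FALSE`) mirrors the validation procedure for
#' contaminant-free synthetic reads, where OTU representatives are not
#' taxonomy-screened; set `classify = TRUE` (and pass `model`) to run the
#' full pipeline including removal of fully unclassified representatives.
#'
#' @param communities output of [build_communities()].
#' @param template a [template_alignment()] (e.g. the true reference
#'   alignment).
#' @param model optional `nb_model` for taxonomy cleaning.
#' @param classify run the taxonomy-cleaning stage.
#' @param threshold OTU identity threshold.
#' @param n_perm Mantel permutations.
#' @param seed seed for the Mantel permutation draws.
#' @return list with `per_community` (data.frame: community, library_type,
#'   mantel_r, mantel_p) and `wilcoxon` (named p-values, NA when fewer than
#'   5 communities).
#' @export
compare_beta_diversity <- function(communities, template, model = NULL,
                                   classify = FALSE, threshold = 0.97,
                                   n_perm = 999, seed = 1L) {
  if (classify && is.null(model))
    stop("classify = TRUE requires a trained model")
  res <- data.frame()
  skipped <- character()
  for (ci in seq_along(communities)) {
    comm <- communities[[ci]]
    runs <- tryCatch({
      list(
        full = run_community_pipeline(comm$full_length, template,
                                      model = if (classify) model,
                                      threshold = threshold),
        paired = run_community_pipeline(comm$paired_concat, template,
                                        model = if (classify) model,
                                        stitched = comm$paired_stitched,
                                        threshold = threshold),
        R1 = run_community_pipeline(comm$r1, template,
                                    model = if (classify) model,
                                    threshold = threshold),
        R2 = run_community_pipeline(comm$r2, template,
                                    model = if (classify) model,
                                    threshold = threshold))
    }, error = function(e) e)
    if (inherits(runs, "error")) {
      warning("community ", ci, " excluded: ", conditionMessage(runs))
      skipped <- c(skipped, as.character(ci))
      next
    }
    mats <- lapply(runs, function(r)
      unifrac_matrix(r$tree, otu_table(r$counts)))
    ok <- vapply(mats, function(m) nrow(m) >= 3L, TRUE)
    if (!all(ok)) {
      warning("community ", ci, " excluded: fewer than 3 samples with OTUs")
      skipped <- c(skipped, as.character(ci))
      next
    }
    for (ty in LIB_TYPES_SHORT) {
      mt <- mantel_test(mats[[ty]], mats$full, n_perm = n_perm,
                        seed = seed + ci)
      res <- rbind(res, data.frame(community = ci, library_type = ty,
                                   mantel_r = mt$r, mantel_p = mt$p))
    }
  }
  list(per_community = res,
       wilcoxon = wilcoxon_across_communities(res),
       excluded = skipped)
}

wilcoxon_across_communities <- function(res) {
  out <- c(paired_vs_R1 = NA_real_, paired_vs_R2 = NA_real_)
  if (!nrow(res)) return(out)
  wide <- split(res$mantel_r, res$library_type)
  if (length(unique(res$community)) < 5L) {
    message("fewer than 5 communities: Wilcoxon step skipped")
    return(out)
  }
  for (ty in c("R1", "R2")) {
    p <- tryCatch(wilcoxon_signed_rank(wide$paired, wide[[ty]])$p,
                  error = function(e) NA_real_)
    out[paste0("paired_vs_", ty)] <- p
  }
  out
}

#' Compare phylogenies across library types via comparable trees
#'
#' For every community, OTUs are picked de novo from the full-length
#' library; the representatives' source reference ids then define equivalent
#' read sets in all four library types, which are aligned and treed
#' independently. The four trees therefore share leaf ids (any id failing
#' alignment in one type is dropped from all four), and each short-read
#' tree's cophenetic matrix is compared to the full-length tree's by Mantel
#' correlation.
#'
#' @param communities output of [build_communities()].
#' @param libs master libraries from [in_silico_pcr()].
#' @param template a [template_alignment()].
#' @param threshold OTU identity threshold.
#' @param n_perm Mantel permutations.
#' @param seed seed for the Mantel permutation draws.
#' @return as [compare_beta_diversity()], plus `leaf_counts` per community.
#' @export
compare_phylogenies <- function(communities, libs, template,
                                threshold = 0.97, n_perm = 999, seed = 1L) {
  res <- data.frame()
  leaf_counts <- integer()
  for (ci in seq_along(communities)) {
    comm <- communities[[ci]]
    clusters <- dereplicate(comm$full_length)
    picked <- pick_otus(clusters, threshold = threshold)
    if (length(picked$centroids) < 4L) {
      warning("community ", ci, " excluded: too few full-length OTUs")
      next
    }
    otu_ids <- vapply(picked$centroids, `[[`, "", "otu_id")
    src <- source_ref_id(vapply(picked$centroids, `[[`, "", "rep_id"))
    bad <- !(src %in% libs$full$id)
    if (any(bad))
      stop("centroid source ids unresolvable: ", paste(src[bad], collapse = ", "))
    r1 <- setNames(libs$r1$seq[match(src, libs$r1$id)], otu_ids)
    r2 <- setNames(libs$r2$seq[match(src, libs$r2$id)], otu_ids)
    fl <- setNames(libs$full$seq[match(src, libs$full$id)], otu_ids)
    libset <- list(
      full = align_library(seq_library("full_length", otu_ids, fl), template),
      paired = align_paired(
        seq_library("paired_concat", otu_ids, paste0(r1, r2),
                    pair_split = setNames(nchar(r1), otu_ids)), template),
      R1 = align_library(seq_library("R1", otu_ids, r1), template),
      R2 = align_library(seq_library("R2", otu_ids, r2), template))
    common <- Reduce(intersect, lapply(libset, `[[`, "ids"))
    if (length(common) < 4L) {
      warning("community ", ci, " excluded: too few aligned leaves")
      next
    }
    leaf_counts <- c(leaf_counts, length(common))
    trees <- lapply(libset, function(al) {
      rows <- strip_empty_columns(al$rows[common])
      neighbor_joining(jc69_distance_matrix(rows))
    })
    cmat <- lapply(trees, function(tr) {
      m <- cophenetic_matrix(tr)
      m[common, common]
    })
    for (ty in LIB_TYPES_SHORT) {
      mt <- mantel_test(cmat[[ty]], cmat$full, n_perm = n_perm,
                        seed = seed + ci)
      res <- rbind(res, data.frame(community = ci, library_type = ty,
                                   mantel_r = mt$r, mantel_p = mt$p))
    }
  }
  list(per_community = res, wilcoxon = wilcoxon_across_communities(res),
       leaf_counts = leaf_counts)
}

#' Taxonomy-accuracy benchmark across library types
#'
#' Splits the reference taxa into a training and a held-out query set
#' (every genus with at least two members contributes held-out taxa, so each
#' query's genus remains trainable), trains the word classifier on the
#' training taxa's full-length sequences, and classifies the held-out
#' queries in four forms: full-length, R1 (250 bp), R2 uniformized to its
#' pipeline length (4/5 of the read), and the N-gap stitched pair. Returns
#' the per-rank accuracy table (rows = library type, columns =
#' domain..species).
#'
#' @param refs a `reference_set`.
#' @param pcr master libraries from [in_silico_pcr()].
#' @param holdout_frac fraction of each genus held out (at least one taxon
#'   per eligible genus).
#' @param seed seed for the hold-out draw and bootstrap.
#' @param n_bootstrap classifier bootstrap count.
#' @param conf_cutoff classifier confidence cutoff.
#' @return list with `accuracy` (data.frame), `n_queries`, `held_out` ids.
#' @export
taxonomy_benchmark <- function(refs, pcr, holdout_frac = 0.3, seed = 1L,
                               n_bootstrap = 100L, conf_cutoff = 0.80) {
  set.seed(seed)
  ids <- pcr$full$id
  genus <- vapply(refs$lineages[ids], function(l) parse_lineage(l)[6], "")
  held <- character()
  for (g in unique(genus)) {
    members <- ids[genus == g]
    if (length(members) < 2L) next
    n_hold <- max(1L, floor(length(members) * holdout_frac))
    n_hold <- min(n_hold, length(members) - 1L)
    held <- c(held, sample(members, n_hold))
  }
  if (!length(held)) stop("no genus has 2 or more members; nothing to hold out")
  train_ids <- setdiff(ids, held)
  model <- train_classifier(refs$sequences[train_ids],
                            refs$lineages[train_ids])
  jp <- pair_join_params(r2_original_length = nchar(pcr$r2$seq[1]))
  i1 <- match(held, pcr$r1$id)
  i2 <- match(held, pcr$r2$id)
  ifl <- match(held, pcr$full$id)
  r2_trim <- substr(pcr$r2$seq[i2], 1L, jp$r2_trim_len)
  queries <- list(
    full_length = setNames(pcr$full$seq[ifl], held),
    paired = setNames(paste0(pcr$r1$seq[i1], jp$gap_char, r2_trim), held),
    R1 = setNames(pcr$r1$seq[i1], held),
    R2 = setNames(r2_trim, held))
  acc <- lapply(queries, function(qs) {
    assignments <- lapply(qs, classify_seq, model = model,
                          n_bootstrap = n_bootstrap,
                          conf_cutoff = conf_cutoff)
    taxonomy_accuracy(assignments, refs$lineages)
  })
  tab <- data.frame(library_type = names(acc),
                    do.call(rbind, acc), row.names = NULL,
                    check.names = FALSE)
  list(accuracy = tab, n_queries = length(held), held_out = held)
}

#' Closed-reference mapping of a read library to a reference set
#'
#' Maps reads at fixed identity against an external reference set used as
#' centroids (reference sequences trimmed to `trim_len`), the procedure used
#' to model realistic communities from real short-read libraries.
#'
#' @param lib a [seq_library()].
#' @param refs a `reference_set` or named character vector of reference
#'   sequences.
#' @param trim_len references are trimmed to this length before mapping
#'   (default 1300).
#' @param threshold identity threshold (default 0.97).
#' @return as [map_reads_to_otus()]; OTU ids are the reference ids.
#' @export
map_library_to_refs <- function(lib, refs, trim_len = 1300L,
                                threshold = 0.97) {
  seqs <- if (inherits(refs, "reference_set")) refs$sequences else refs
  centroids <- lapply(names(seqs), function(id)
    list(otu_id = id, seq = substr(seqs[[id]], 1L, trim_len),
         abundance = 1L, rep_id = id))
  map_reads_to_otus(lib, centroids, threshold = threshold)
}
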