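# Synthetic mock-community generator: 16S-like reference sets with a
# ground-truth tree and taxonomy, conserved primer sites, in-silico PCR
# amplicon ends, and log-series community abundances. This module stands in
# for a curated full-length reference database so the whole paired-vs-single
# read comparison is reproducible from scratch.

ROOT_LENGTH <- 1550L

#' Canonical 16S primer set
#'
#' The five standard primers used throughout: 27F and 1492R bracketing the
#' near-full-length gene, 357F/926R for the V3-V5 amplicon, and 968F/1492R
#' for V6-V9. Reverse primers are given in primer (sequencing) orientation;
#' their plus-strand site is the reverse complement.
#'
#' @return named character vector of IUPAC primer sequences.
#' @export
primers_16s <- function() {
  c(`27F` = "AGAGTTTGATCMTGGCTCAG",
    `357F` = "CCTACGGGAGGCAGCAG",
    `926R` = "CCGTCAATTCMTTTRAGT",
    `968F` = "AACGCGAAGAACCTTAC",
    `1492R` = "CGGTTACCTTGTTACGACTT")
}

# plus-strand layout of the primer sites on the ~1.5 kb reference gene;
# spacing keeps both the V3-V5 and V6-V9 250+250 bp read pairs
# non-overlapping, as they are on the real gene
primer_layout <- function() {
  p <- primers_16s()
  data.frame(name = names(p),
             start = c(8L, 340L, 920L, 975L, 1510L),
             len = nchar(p),
             reverse = names(p) %in% c("926R", "1492R"),
             row.names = names(p))
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# one concrete realization of a degenerate primer
realize_primer <- function(primer) {
  paste(vapply(strsplit(primer, "")[[1]],
               function(b) sample(IUPAC_SETS[[b]], 1L), ""), collapse = "")
}

# per-site relative substitution-rate profile: conserved backbone with
# elevated hypervariable windows (V1-V9-like), primer sites frozen at rate
# 0. The V3/V4 windows are broad and moderately hot while V5 is narrower
# and cooler, reflecting the documented variability ranking of the gene
# (V3 > V4 > V5): the read downstream of the 357F primer carries more
# informative sites than the read upstream of 926R. Window/backbone
# contrast is kept moderate so that within-read rate heterogeneity does
# not dominate distance estimation on any single read.
rate_profile <- function(layout) {
  prof <- rep(0.4, ROOT_LENGTH)
  windows <- list(c(60, 110, 2.2), c(120, 250, 1.9), c(400, 530, 2.4),
                  c(555, 690, 2.0), c(780, 890, 1.6), c(990, 1070, 2.0),
                  c(1110, 1200, 1.6), c(1240, 1330, 1.5), c(1390, 1500, 1.9))
  for (w in windows) prof[w[1]:w[2]] <- w[3]
  for (i in seq_len(nrow(layout)))
    prof[layout$start[i]:(layout$start[i] + layout$len[i] - 1L)] <- 0
  prof / mean(prof)
}

mutate_along_branch <- function(seq_chars, p_mut) {
  hits <- which(runif(length(seq_chars)) < p_mut)
  if (length(hits)) {
    bases <- c("A", "C", "G", "T")
    for (i in hits) {
      seq_chars[i] <- sample(setdiff(bases, seq_chars[i]), 1L)
    }
  }
  seq_chars
}

# rank labels from cutting the tree at fixed depth fractions of root height
taxonomy_from_tree <- function(tree, cut_fracs = c(0.15, 0.3, 0.45, 0.6,
                                                   0.75, 0.9)) {
  nt <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(nt)])
  parent <- integer(nt + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  prefixes <- c("P", "C", "O", "F", "G", "S")
  rank_groups <- matrix("", nt, 6L)
  for (r in seq_along(cut_fracs)) {
    cut_depth <- cut_fracs[r] * height
    grp <- integer(nt)
    for (tip in seq_len(nt)) {
      node <- tip
      while (parent[node] != 0L && depth[parent[node]] >= cut_depth)
        node <- parent[node]
      grp[tip] <- node
    }
    rank_groups[, r] <- paste0(prefixes[r], match(grp, sort(unique(grp))))
  }
  lineages <- apply(rank_groups, 1L, function(g)
    paste0(c("k__Bacteria_sim", paste0(RANK_PREFIXES[-1], g)),
           collapse = "; "))
  setNames(lineages, tree$tip.label)
}

#' Simulate a 16S-like reference set
#'
#' Draws a pure-birth (Yule) tree, scaled to unit height, and evolves a
#' random ~1.5 kb root sequence along it under per-site substitution with a
#' hypervariable-region rate profile. The five canonical primer sites are
#' embedded in the root (reverse primers as reverse complements) and
#' mutation-protected, so in-silico PCR recovers an amplicon from every
#' taxon. Taxonomy labels come from cutting the tree at six fixed depth
#' fractions (0.15/0.3/0.45/0.6/0.75/0.9 of root height); the domain is the
#' constant `Bacteria_sim`.
#'
#' @param n_taxa number of reference taxa (>= 4).
#' @param seed integer seed.
#' @param sub_rate expected substitutions per site (at profile mean rate 1)
#'   from root to tip.
#' @param indel_rate must be 0: the reference keeps a fixed coordinate
#'   system so that primer sites are identical across taxa and the true
#'   gapless alignment can serve as the seed template.
#' @return a `reference_set`: `sequences` (named), `tree` (`ape::phylo`,
#'   ground truth), `lineages` (named 7-rank strings), `primer_sites`
#'   (name -> start/end), and `primers` (realized concrete sequences).
#' @export
simulate_reference <- function(n_taxa, seed = 1L, sub_rate = 0.15,
                               indel_rate = 0) {
  if (n_taxa < 4L) stop("n_taxa must be >= 4")
  if (indel_rate != 0)
    stop("indel_rate > 0 is not supported: primer coordinates are fixed ",
         "across taxa")
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$tip.label <- sprintf("ref_%04d", seq_len(n_taxa))
  depth <- ape::node.depth.edgelength(tree)
  tree$edge.length <- tree$edge.length / max(depth[seq_len(n_taxa)])
  layout <- primer_layout()
  primers <- primers_16s()
  realized <- vapply(primers, realize_primer, "")
  root <- sample(c("A", "C", "G", "T"), ROOT_LENGTH, replace = TRUE)
  for (i in seq_len(nrow(layout))) {
    site <- realized[[layout$name[i]]]
    if (layout$reverse[i]) site <- revcomp(site)
    root[layout$start[i]:(layout$start[i] + layout$len[i] - 1L)] <-
      strsplit(site, "")[[1]]
  }
  prof <- rate_profile(layout)
  nt <- n_taxa
  seqs <- vector("list", nt + tree$Nnode)
  seqs[[nt + 1L]] <- root # root node id
  # preorder: parents before children
  ord <- order(depth[tree$edge[, 2]])
  for (k in ord) {
    par <- tree$edge[k, 1]
    child <- tree$edge[k, 2]
    p_mut <- 1 - exp(-sub_rate * prof * tree$edge.length[k])
    seqs[[child]] <- mutate_along_branch(seqs[[par]], p_mut)
  }
  sequences <- setNames(vapply(seqs[seq_len(nt)], paste, "", collapse = ""),
                        tree$tip.label)
  sites <- lapply(seq_len(nrow(layout)), function(i)
    c(start = layout$start[i], end = layout$start[i] + layout$len[i] - 1L))
  names(sites) <- layout$name
  structure(list(sequences = sequences, tree = tree,
                 lineages = taxonomy_from_tree(tree),
                 primer_sites = sites, primers = realized,
                 sub_rate = sub_rate, seed = seed),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> taxa=%d length=%d genera=%d\n",
              length(x$sequences), nchar(x$sequences[1]),
              length(unique(sub(".*g__([^;]+);.*", "\\1", x$lineages)))))
  invisible(x)
}

iupac_match_first <- function(subject, pattern, max_mismatch = 0L) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                   Biostrings::DNAString(subject),
                                   max.mismatch = max_mismatch,
                                   fixed = FALSE)
  if (!length(hits)) return(NULL)
  c(start = BiocGenerics::start(hits)[1], end = BiocGenerics::end(hits)[1])
}

#' In-silico PCR amplicon extraction
#'
#' IUPAC-aware search (e.g. M matches A or C) for the forward primer and for
#' the reverse complement of the reverse primer in each reference. R1 is the
#' first `end_len` bases downstream of the forward primer's 3' end; R2 is
#' the reverse complement of the `end_len` bases upstream of the
#' reverse-primer site (i.e. the read as the sequencer delivers it); the
#' full-length read is the region between the 27F 3' end and the 1492R
#' site. References in which a primer is not found, whose amplicon would run
#' past the sequence boundary, or whose reads contain an ambiguous character
#' are skipped and counted. No quality scores are attached: the reads are
#' perfect by construction.
#'
#' @param refs a `reference_set` (or named character vector of sequences).
#' @param fwd,rev forward/reverse primer sequences (IUPAC); default V3-V5
#'   pair 357F/926R.
#' @param end_len read length extracted from each amplicon end.
#' @param max_mismatch mismatches tolerated in primer matching.
#' @return list with `r1`, `r2`, `full` ([seq_library()] objects sharing the
#'   reference ids) and `skipped` (count).
#' @export
in_silico_pcr <- function(refs, fwd = primers_16s()[["357F"]],
                          rev = primers_16s()[["926R"]],
                          end_len = 250L, max_mismatch = 0L) {
  seqs <- if (inherits(refs, "reference_set")) refs$sequences else refs
  p <- primers_16s()
  rev_rc <- revcomp(rev)
  full_fwd <- p[["27F"]]
  full_rev_rc <- revcomp(p[["1492R"]])
  ids <- character(); r1 <- character(); r2 <- character(); fl <- character()
  skipped <- 0L
  for (id in names(seqs)) {
    s <- seqs[[id]]
    hf <- iupac_match_first(s, fwd, max_mismatch)
    hr <- iupac_match_first(s, rev_rc, max_mismatch)
    h27 <- iupac_match_first(s, full_fwd, max_mismatch)
    h1492 <- iupac_match_first(s, full_rev_rc, max_mismatch)
    if (is.null(hf) || is.null(hr) || is.null(h27) || is.null(h1492) ||
        hf[["end"]] + end_len > nchar(s) || hr[["start"]] - end_len < 1L) {
      skipped <- skipped + 1L
      next
    }
    read1 <- substr(s, hf[["end"]] + 1L, hf[["end"]] + end_len)
    read2 <- revcomp(substr(s, hr[["start"]] - end_len, hr[["start"]] - 1L))
    flread <- substr(s, h27[["end"]] + 1L, h1492[["start"]] - 1L)
    if (grepl("[^ACGT]", read1) || grepl("[^ACGT]", read2) ||
        grepl("[^ACGT]", flread)) {
      skipped <- skipped + 1L
      next
    }
    ids <- c(ids, id); r1 <- c(r1, read1); r2 <- c(r2, read2)
    fl <- c(fl, flread)
  }
  list(r1 = seq_library("R1", ids, r1, "master"),
       r2 = seq_library("R2", ids, r2, "master"),
       full = seq_library("full_length", ids, fl, "master"),
       skipped = skipped)
}

#' Log-series clone-count sampler
#'
#' Draws from the log-series pmf `p(n) = -x^n / (n log(1 - x))`,
#' `n = 1, 2, ...`, by inverse CDF with the cumulative truncated at
#' `1 - 1e-12`. Uses the current RNG state (seed upstream).
#'
#' @param n number of draws.
#' @param x log-series parameter in (0, 1).
#' @return integer vector of clone counts (>= 1).
#' @export
rlogseries <- function(n, x = 0.9) {
  if (x <= 0 || x >= 1) stop("x must be in (0, 1)")
  pmf <- numeric(0)
  k <- 0L
  total <- 0
  while (total < 1 - 1e-12) {
    k <- k + 1L
    pmf[k] <- -x^k / (k * log(1 - x))
    total <- total + pmf[k]
    if (k > 100000L) break
  }
  cum <- cumsum(pmf)
  findInterval(runif(n) * cum[length(cum)], cum) + 1L
}

#' Log-series pmf
#'
#' @param k integer support points.
#' @param x log-series parameter in (0, 1).
#' @return `p(k) = -x^k / (k log(1 - x))`.
#' @export
dlogseries <- function(k, x = 0.9) {
  if (x <= 0 || x >= 1) stop("x must be in (0, 1)")
  -x^k / (k * log(1 - x))
}

#' Community design parameters
#'
#' Defaults are the desk-scale fixture: 3 communities of 8 samples with 150
#' ids per sample; the original experiment's scale (100 communities, 20
#' samples, 2,500 ids) is reached by raising these.
#'
#' @param n_communities,samples_per_community,ids_per_sample design sizes.
#' @param logseries_x clone-count distribution parameter.
#' @param seed integer seed.
#' @return a list of class `community_design`.
#' @export
community_design <- function(n_communities = 3L, samples_per_community = 8L,
                             ids_per_sample = 150L, logseries_x = 0.9,
                             seed = 1L) {
  stopifnot(n_communities > 0, samples_per_community > 0, ids_per_sample > 0,
            logseries_x > 0, logseries_x < 1)
  structure(list(n_communities = as.integer(n_communities),
                 samples_per_community = as.integer(samples_per_community),
                 ids_per_sample = as.integer(ids_per_sample),
                 logseries_x = logseries_x, seed = as.integer(seed)),
            class = "community_design")
}

clone_ids <- function(ids, mult, sample_index) {
  paste0(rep(ids, mult), "_s", sample_index, "c", sequence(mult))
}

#' Strip the clone suffix from community read ids
#'
#' @param ids read ids produced by [build_communities()].
#' @return the source reference ids.
#' @export
source_ref_id <- function(ids) sub("_s[0-9]+c[0-9]+$", "", ids)

#' Build synthetic mock communities
#'
#' Per sample, `ids_per_sample` distinct reference ids are drawn uniformly
#' without replacement and each receives a log-series clone multiplicity.
#' The identical id+multiplicity sets are instantiated in four library
#' types: R1, R2, paired (concatenated and N-gap stitched, built from the
#' unmodified mates) and full-length, so any downstream difference between
#' the types reflects the reads, not the sampling. A ground-truth abundance
#' table per community is emitted.
#'
#' @param libs master libraries as returned by [in_silico_pcr()].
#' @param design a [community_design()].
#' @return list of communities; each has `r1`, `r2`, `paired_concat`,
#'   `paired_stitched`, `full_length` ([seq_library()]s over all samples)
#'   and `truth` (reference x sample multiplicity matrix).
#' @export
build_communities <- function(libs, design = community_design()) {
  ids_all <- Reduce(intersect, list(libs$r1$id, libs$r2$id, libs$full$id))
  if (design$ids_per_sample > length(ids_all))
    stop("ids_per_sample exceeds the ", length(ids_all), " available ids")
  set.seed(design$seed)
  i1 <- match(ids_all, libs$r1$id)
  i2 <- match(ids_all, libs$r2$id)
  ifl <- match(ids_all, libs$full$id)
  seqs <- list(r1 = setNames(libs$r1$seq[i1], ids_all),
               r2 = setNames(libs$r2$seq[i2], ids_all),
               full = setNames(libs$full$seq[ifl], ids_all))
  communities <- vector("list", design$n_communities)
  for (ci in seq_len(design$n_communities)) {
    cid <- character(); csam <- character()
    pick_list <- vector("list", design$samples_per_community)
    truth <- matrix(0L, length(ids_all), design$samples_per_community,
                    dimnames = list(ids_all,
                                    sprintf("C%dS%d", ci,
                                            seq_len(design$samples_per_community))))
    for (si in seq_len(design$samples_per_community)) {
      picked <- sample(ids_all, design$ids_per_sample)
      mult <- rlogseries(design$ids_per_sample, design$logseries_x)
      truth[picked, si] <- mult
      rid <- clone_ids(picked, mult, si)
      cid <- c(cid, rid)
      csam <- c(csam, rep(colnames(truth)[si], length(rid)))
      pick_list[[si]] <- list(ids = picked, mult = mult)
    }
    src <- source_ref_id(cid)
    r1 <- seq_library("R1", cid, unname(seqs$r1[src]), csam)
    r2 <- seq_library("R2", cid, unname(seqs$r2[src]), csam)
    joined <- make_joined_reads(r1, r2)
    fl <- seq_library("full_length", cid, unname(seqs$full[src]), csam)
    communities[[ci]] <- list(r1 = r1, r2 = r2,
                              paired_concat = joined$concat,
                              paired_stitched = joined$stitched,
                              full_length = fl, truth = truth)
  }
  communities
}
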