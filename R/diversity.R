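# Beta-diversity and comparison statistics: unweighted UniFrac, Mantel
# correlation (vegan's implementation, seeded), and a Wilcoxon signed-rank
# test exact under ties.

# edge x tip incidence: which tips descend from each edge's child
edge_tip_incidence <- function(tree) {
  nt <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  tipsets <- vector("list", nt + tr$Nnode)
  for (i in seq_len(nt)) tipsets[[i]] <- i
  ne <- nrow(tr$edge)
  desc <- matrix(FALSE, ne, nt)
  for (k in seq_len(ne)) {
    parent <- tr$edge[k, 1]
    child <- tr$edge[k, 2]
    desc[k, tipsets[[child]]] <- TRUE
    tipsets[[parent]] <- c(tipsets[[parent]], tipsets[[child]])
  }
  list(desc = desc, lengths = tr$edge.length)
}

#' Unweighted UniFrac distance matrix
#'
#' Classic (non-normalized-by-depth) unweighted UniFrac: for samples A and
#' B, the fraction of branch length leading exclusively to leaves present
#' only in A or only in B, over the branch length leading to any leaf
#' present in A or B. Branches leading only to leaves absent from both
#' samples are excluded from the denominator. Unrooted (trifurcating-root)
#' trees are handled as stored: there is no edge above the root, so the root
#' acts as a degree-3 junction. A sample with no present OTUs is at distance
#' 1 from any non-empty sample and 0 from another empty sample.
#'
#' @param tree `ape::phylo` tree whose tips cover every OTU with nonzero
#'   count.
#' @param table an [otu_table()]; presence is count > 0.
#' @return symmetric distance matrix over the samples.
#' @export
unifrac_matrix <- function(tree, table) {
  cnt <- table$counts
  present_otus <- rownames(cnt)[rowSums(cnt) > 0L]
  missing <- setdiff(present_otus, tree$tip.label)
  if (length(missing))
    stop("OTUs missing from tree: ", paste(missing, collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  inc <- edge_tip_incidence(tree)
  pres <- matrix(FALSE, length(tree$tip.label), ncol(cnt),
                 dimnames = list(tree$tip.label, colnames(cnt)))
  hit <- intersect(rownames(cnt), tree$tip.label)
  pres[hit, ] <- cnt[hit, , drop = FALSE] > 0L
  E <- inc$desc %*% pres > 0L # edge x sample: edge leads to a present leaf
  ns <- ncol(cnt)
  d <- matrix(0, ns, ns, dimnames = list(colnames(cnt), colnames(cnt)))
  empty <- colSums(pres) == 0L
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      if (empty[i] || empty[j]) {
        d[i, j] <- d[j, i] <- if (empty[i] && empty[j]) 0 else 1
        next
      }
      both <- E[, i] | E[, j]
      uniq <- xor(E[, i], E[, j])
      d[i, j] <- d[j, i] <- sum(inc$lengths[uniq]) / sum(inc$lengths[both])
    }
  }
  d
}

#' Mantel correlation test between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle vectors, with
#' one-sided (greater) permutation significance from vegan's Mantel
#' implementation: `p = (1 + #{r* >= r}) / (1 + n_perm)`, permuting rows and
#' columns of the second matrix jointly. vegan switches to complete
#' enumeration when the permutation set is small.
#'
#' @param d1,d2 labeled symmetric matrices with identical labels in
#'   identical order.
#' @param n_perm requested permutation count (default 999).
#' @param seed optional integer seed for the permutation draw; the caller's
#'   RNG state is restored afterwards.
#' @return list with `r`, `p`, and `n_perm` (permutations actually used).
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!identical(dimnames(d1), dimnames(d2)))
    stop("distance matrices must share labels in the same order")
  if (nrow(d1) < 3L) stop("need at least 3 labels")
  v1 <- d1[lower.tri(d1)]; v2 <- d2[lower.tri(d2)]
  if (sd(v1) == 0 || sd(v2) == 0)
    stop("constant lower triangle: Mantel correlation undefined")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  mt <- suppressWarnings(suppressMessages(
    vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                  method = "pearson", permutations = n_perm)))
  list(r = unname(mt$statistic), p = unname(mt$signif),
       n_perm = length(mt$perm))
}

#' Wilcoxon signed-rank test (two-sided)
#'
#' Zero differences are dropped. For up to 25 non-zero differences the
#' two-sided p-value comes from the exact null distribution of the
#' positive-rank sum, computed by convolution over the (tie-averaged,
#' doubled-to-integer) ranks, so ties are handled exactly. For larger n a
#' normal approximation with continuity and tie corrections is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list with `p`, `statistic` (positive-rank sum `V`), and `n`
#'   (non-zero differences used).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero: no information")
  if (n < 5L) stop("need at least 5 non-zero differences")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25L) {
    r2 <- as.integer(round(2 * r))
    # coefficient vector over doubled rank sums 0..sum(r2)
    f <- c(1, rep(0, sum(r2)))
    for (ri in r2) {
      g <- f
      g[(ri + 1):length(f)] <- g[(ri + 1):length(f)] + f[1:(length(f) - ri)]
      f <- g
    }
    f <- f / 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(f[1:(v2 + 1)])
    p_ge <- sum(f[(v2 + 1):length(f)])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - 0.5 * sign(V - mu)) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  list(p = p, statistic = V, n = n)
}

#' Write / read a labeled square distance matrix as TSV
#'
#' @param d labeled square matrix.
#' @param path file path.
#' @return `write_distance_matrix`: `path` invisibly;
#'   `read_distance_matrix`: the matrix.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
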