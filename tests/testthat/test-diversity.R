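# independent brute-force unweighted UniFrac: enumerate every branch, find
# its descendant tips by walking root-to-tip paths
unifrac_oracle <- function(tree, presence) {
  nt <- length(tree$tip.label)
  parent <- integer(nt + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  tips_below <- function(node) {
    hits <- logical(nt)
    for (tip in seq_len(nt)) {
      n <- tip
      repeat {
        if (n == node) { hits[tip] <- TRUE; break }
        if (parent[n] == 0L) break
        n <- parent[n]
      }
    }
    tree$tip.label[hits]
  }
  pair <- function(A, B) {
    if (!length(A) && !length(B)) return(0)
    if (!length(A) || !length(B)) return(1)
    uniq <- 0; tot <- 0
    for (e in seq_len(nrow(tree$edge))) {
      below <- tips_below(tree$edge[e, 2])
      inA <- any(below %in% A)
      inB <- any(below %in% B)
      if (inA || inB) tot <- tot + tree$edge.length[e]
      if (xor(inA, inB)) uniq <- uniq + tree$edge.length[e]
    }
    uniq / tot
  }
  ns <- ncol(presence)
  d <- matrix(0, ns, ns, dimnames = list(colnames(presence),
                                         colnames(presence)))
  sets <- lapply(seq_len(ns), function(j)
    rownames(presence)[presence[, j]])
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) d[i, j] <- d[j, i] <- pair(sets[[i]], sets[[j]])
  }
  d
}

tab_from_presence <- function(presence) {
  otu_table(matrix(as.integer(presence), nrow(presence),
                   dimnames = dimnames(presence)))
}

test_that("UniFrac handles the canonical small cases", {
  f <- withr::local_tempfile()
  writeLines("((a:1,b:1):1,(c:1,d:1):1);", f)
  tr <- read_newick(f)
  pres <- cbind(A = c(a = TRUE, b = TRUE, c = FALSE, d = FALSE),
                B = c(a = TRUE, b = FALSE, c = TRUE, d = FALSE))
  d <- unifrac_matrix(tr, tab_from_presence(pres))
  expect_equal(d["A", "B"], 3 / 5)

  # identical presence sets are at distance 0
  pres2 <- cbind(A = c(a = TRUE, b = TRUE, c = FALSE, d = FALSE),
                 B = c(a = TRUE, b = TRUE, c = FALSE, d = FALSE))
  expect_equal(unifrac_matrix(tr, tab_from_presence(pres2))["A", "B"], 0)

  # star tree with unit branches and disjoint singletons: distance 1
  writeLines("(a:1,b:1,c:1);", f)
  star <- read_newick(f)
  pres3 <- cbind(A = c(a = TRUE, b = FALSE, c = FALSE),
                 B = c(a = FALSE, b = TRUE, c = FALSE))
  expect_equal(unifrac_matrix(star, tab_from_presence(pres3))["A", "B"], 1)

  # empty-sample conventions
  pres4 <- cbind(A = c(a = TRUE, b = FALSE, c = FALSE),
                 B = c(a = FALSE, b = FALSE, c = FALSE),
                 C = c(a = FALSE, b = FALSE, c = FALSE))
  d4 <- unifrac_matrix(star, tab_from_presence(pres4))
  expect_equal(d4["A", "B"], 1)
  expect_equal(d4["B", "C"], 0)

  expect_error(unifrac_matrix(star, otu_table(
    matrix(1L, 1, 1, dimnames = list("zz", "A")))), "missing from tree")
})

test_that("UniFrac agrees with the brute-force oracle on random trees", {
  set.seed(40)
  for (rep in 1:20) {
    tr <- ape::rtree(10)
    pres <- matrix(runif(40) < 0.5, 10, 4,
                   dimnames = list(tr$tip.label, paste0("s", 1:4)))
    got <- unifrac_matrix(tr, tab_from_presence(pres))
    want <- unifrac_oracle(tr, pres)
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1))
    # invariance under uniform branch scaling
    tr2 <- tr
    tr2$edge.length <- tr$edge.length * 7.3
    expect_equal(unifrac_matrix(tr2, tab_from_presence(pres)), got,
                 tolerance = 1e-12)
  }
})

test_that("UniFrac agrees with picante on rooted binary trees", {
  skip_if_not_installed("picante")
  set.seed(41)
  tr <- ape::rtree(12)
  comm <- matrix(as.integer(runif(60) < 0.5), 5, 12,
                 dimnames = list(paste0("s", 1:5), tr$tip.label))
  while (any(rowSums(comm) == 0)) comm[rowSums(comm) == 0, 1] <- 1L
  ours <- unifrac_matrix(tr, otu_table(t(comm)))
  theirs <- as.matrix(picante::unifrac(comm, tr))
  expect_equal(ours[rownames(theirs), colnames(theirs)], theirs,
               tolerance = 1e-10)
})

test_that("Mantel statistics behave as Pearson on lower triangles", {
  set.seed(42)
  m <- matrix(runif(36), 6, 6); m <- m + t(m); diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:6), paste0("s", 1:6))
  self <- mantel_test(m, m, n_perm = 99, seed = 1)
  expect_equal(self$r, 1)
  affine <- 2 * m + 3
  diag(affine) <- 0
  expect_equal(mantel_test(m, affine, n_perm = 99, seed = 1)$r, 1)
  expect_error(mantel_test(m, matrix(0, 6, 6,
                                     dimnames = dimnames(m)),
                           n_perm = 99), "constant")
})

test_that("Mantel permutation p matches exhaustive enumeration at n = 4", {
  set.seed(43)
  m1 <- matrix(runif(16), 4, 4); m1 <- m1 + t(m1); diag(m1) <- 0
  m2 <- matrix(runif(16), 4, 4); m2 <- m2 + t(m2); diag(m2) <- 0
  labs <- paste0("s", 1:4)
  dimnames(m1) <- dimnames(m2) <- list(labs, labs)
  # exhaustive enumeration over all 24 relabelings of m2
  lower <- function(m) m[lower.tri(m)]
  r_obs <- cor(lower(m1), lower(m2))
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  r_all <- apply(perms, 1, function(p) cor(lower(m1), lower(m2[p, p])))
  p_exact <- mean(r_all >= r_obs - 1e-12)
  got <- mantel_test(m1, m2, n_perm = 999, seed = 7)
  expect_equal(got$r, r_obs)
  # vegan enumerates the full permutation set at this size; its p has the
  # +1/(n+1) convention over the 23 non-identity permutations
  expect_equal(got$p, p_exact, tolerance = 1.5 / 24)
})

test_that("Wilcoxon signed-rank matches exact enumeration and wilcox.test", {
  # n = 6, all differences positive: two-sided exact p = 2/64
  expect_equal(wilcoxon_signed_rank(1:6, rep(0, 6))$p, 0.03125)
  expect_error(wilcoxon_signed_rank(1:6, 1:6), "zero")
  expect_error(wilcoxon_signed_rank(1:4, rep(0, 4)), "at least 5")

  set.seed(44)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12, 0.4)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    # antisymmetry
    expect_equal(wilcoxon_signed_rank(y, x)$p, ours$p)
  }

  # ties: exact convolution over tie-averaged ranks still sums to 1 and
  # stays in (0, 1]
  xt <- c(1, 2, 2, 3, 3, 3, 5, 6)
  yt <- rep(0, 8)
  pt <- wilcoxon_signed_rank(xt, yt)
  expect_equal(pt$p, 2 / 2^8)

  # large-n path: normal approximation close to wilcox.test
  set.seed(45)
  xl <- rnorm(40); yl <- rnorm(40, 0.3)
  ours_l <- wilcoxon_signed_rank(xl, yl)
  ref_l <- wilcox.test(xl, yl, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(ours_l$p, ref_l$p.value, tolerance = 1e-9)
})

test_that("distance matrices round-trip through TSV", {
  m <- matrix(runif(9), 3, 3); m <- m + t(m); diag(m) <- 0
  dimnames(m) <- list(c("a", "b", "c"), c("a", "b", "c"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(m, f)
  back <- read_distance_matrix(f)
  expect_equal(back, m, tolerance = 1e-12)
})
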