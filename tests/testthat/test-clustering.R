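test_that("pairwise identity matches hand-derived values", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1.0)
  # 9 matches over 10 columns
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGTACGTAT"), 0.9)
  # terminal gaps are excluded from the column count
  expect_equal(pairwise_identity("ACGT", "ACGTAA"), 1.0)
  # an internal gap column counts against identity: 60 matches / 61 columns
  set.seed(77)
  a60 <- random_dna(1, 60)
  b61 <- paste0(substr(a60, 1, 30), "T", substr(a60, 31, 60))
  expect_equal(pairwise_identity(a60, b61), 60 / 61)
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
})

test_that("dereplication groups exact duplicates and sorts deterministically", {
  s1 <- strrep("ACGT", 10)
  s2 <- strrep("TTGA", 10)
  lib <- seq_library("full_length", c("r3", "r1", "r2", "r4"),
                     c(s1, s1, s2, s1), c("a", "a", "b", "b"))
  cl <- dereplicate(lib)
  expect_equal(vapply(cl, `[[`, 0L, "size"), c(3L, 1L))
  expect_equal(cl[[1]]$rep_id, "r1") # smallest member id
  expect_equal(cl[[1]]$seq, s1)
  expect_equal(sort(cl[[1]]$member_ids), c("r1", "r3", "r4"))

  # determinism under permutation
  set.seed(3)
  n <- 40
  lib2 <- seq_library("R1", sprintf("x%02d", 1:n),
                      sample(random_dna(8, 50), n, replace = TRUE), "s")
  ref <- dereplicate(lib2)
  for (i in 1:5) {
    perm <- sample(n)
    shuffled <- seq_library("R1", lib2$id[perm], lib2$seq[perm], "s")
    expect_identical(dereplicate(shuffled), ref)
  }
})

test_that("OTU picking separates families, absorbs near-identical clusters
           and drops singletons", {
  fam <- make_family_library(k = 5)
  clusters <- dereplicate(fam$lib)
  picked <- pick_otus(clusters)
  expect_length(picked$centroids, 5L)
  expect_setequal(vapply(picked$centroids, `[[`, "", "seq"), fam$base)
  # base (3 copies) + absorbed variant (2 copies)
  expect_equal(vapply(picked$centroids, function(x) x$abundance, 0L),
               rep(5L, 5))
  expect_true(max_centroid_identity(picked$centroids) < 0.97)

  # singleton clusters never reach the output
  single <- seq_library("R1", "lonely", random_dna(1, 200), "s")
  both <- seq_library("R1", c(fam$lib$id, "lonely"),
                      c(fam$lib$seq, single$seq), "s")
  picked2 <- pick_otus(dereplicate(both))
  expect_length(picked2$centroids, 5L)
  expect_equal(unname(picked2$assignment["lonely"]), "dropped")

  # two clusters at 96% identity found two OTUs
  a <- random_dna(1, 100)
  b <- a
  for (p in c(10, 35, 60, 85))
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"), substr(b, p, p))[1]
  expect_equal(pairwise_identity(a, b), 0.96)
  lib96 <- seq_library("R1", paste0("r", 1:5),
                       c(rep(a, 3), rep(b, 2)), "s")
  expect_length(pick_otus(dereplicate(lib96))$centroids, 2L)

  expect_length(pick_otus(list())$centroids, 0L)
})

test_that("a constructed bimera is flagged chimeric", {
  set.seed(21)
  a <- random_dna(1, 250)
  b <- a
  # parents at 90% identity
  pos <- seq(5, 245, length.out = 25)
  for (p in pos)
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"), substr(b, p, p))[1]
  chimera <- paste0(substr(a, 1, 125), substr(b, 126, 250))
  lib <- seq_library("R1",
                     c(paste0("a", 1:10), paste0("b", 1:10), "chi1", "chi2"),
                     c(rep(a, 10), rep(b, 10), chimera, chimera), "s")
  picked <- pick_otus(dereplicate(lib))
  expect_length(picked$centroids, 2L)
  rep_of_chimera <- "chi1" # lexicographically smallest member id
  expect_equal(unname(picked$assignment[rep_of_chimera]), "chimera")
})

test_that("read mapping respects threshold, ties and conservation", {
  fam <- make_family_library(k = 4)
  picked <- pick_otus(dereplicate(fam$lib))
  centroids <- picked$centroids

  # a read identical to a centroid maps to it
  m <- map_reads_to_otus(seq_library("R1", "q1", centroids[[2]]$seq, "sA"),
                         centroids)
  expect_equal(unname(m$assignment["q1"]), centroids[[2]]$otu_id)

  # a read far from every centroid stays unmapped but is counted
  m2 <- map_reads_to_otus(seq_library("R1", "far", random_dna(1, 200), "sA"),
                          centroids)
  expect_equal(m2$unmapped, 1L)
  expect_true(all(m2$counts == 0L))

  # identity tie between two centroids goes to the larger abundance
  base <- random_dna(1, 100)
  substr(base, 10, 11) <- "CC"
  v1 <- base
  substr(v1, 10, 11) <- "AA"
  c1 <- list(otu_id = "OTU_1", seq = base, abundance = 10L, rep_id = "p")
  c2 <- list(otu_id = "OTU_2", seq = v1, abundance = 3L, rep_id = "q")
  q <- base
  substr(q, 10, 10) <- "A" # one mismatch to either centroid
  expect_equal(pairwise_identity(q, base), pairwise_identity(q, v1))
  m3 <- map_reads_to_otus(seq_library("R1", "tie", q, "sA"), list(c1, c2))
  expect_equal(unname(m3$assignment["tie"]), "OTU_1")

  # conservation: mapped + unmapped = reads in
  lib <- fam$lib
  m4 <- map_reads_to_otus(lib, centroids)
  expect_equal(sum(m4$counts) + m4$unmapped, length(lib))
  expect_error(map_reads_to_otus(lib, list()), "empty centroid")
})

test_that("OTU picking is deterministic under input permutation", {
  fam <- make_family_library(k = 6, seed = 17)
  ref <- pick_otus(dereplicate(fam$lib))
  set.seed(2)
  for (i in 1:3) {
    perm <- sample(length(fam$lib))
    shuffled <- seq_library("full_length", fam$lib$id[perm],
                            fam$lib$seq[perm], "s1")
    got <- pick_otus(dereplicate(shuffled))
    expect_identical(vapply(got$centroids, `[[`, "", "seq"),
                     vapply(ref$centroids, `[[`, "", "seq"))
    expect_identical(got$assignment[order(names(got$assignment))],
                     ref$assignment[order(names(ref$assignment))])
  }
})
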