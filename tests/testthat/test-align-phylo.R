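make_template <- function(n = 5, len = 400, seed = 30) {
  set.seed(seed)
  rows <- setNames(random_dna(n, len), paste0("t", 1:n))
  template_alignment(rows)
}

test_that("template threading reproduces a row exactly and scores it fully", {
  tpl <- make_template()
  q <- tpl$ungapped[[2]]
  al <- align_to_template(q, tpl)
  expect_equal(al$columns, unname(tpl$rows[2]))
  expect_equal(al$insertion_count, 0L)
  expect_gt(al$score, 0)
  expect_equal(al$template_row, "t2")
})

test_that("query insertions are dropped and counted", {
  tpl <- make_template()
  base <- tpl$ungapped[[1]]
  q <- paste0(substr(base, 1, 200), "GG", substr(base, 201, nchar(base)))
  al <- align_to_template(q, tpl)
  expect_equal(al$insertion_count, 2L)
  expect_gt(al$score, 0)
  # matched bases fill the same column space: degapping recovers a
  # base-length sequence (the 2 inserted bases were dropped)
  expect_equal(nchar(gsub("-", "", al$columns)), nchar(base))
})

test_that("unrelated queries get negative scores and are filtered", {
  tpl <- make_template()
  set.seed(31)
  junk <- random_dna(1, 250)
  al <- align_to_template(junk, tpl)
  expect_lt(al$score, 0)

  lib <- seq_library("R1", c("good", "bad"),
                     c(substr(tpl$ungapped[[3]], 10, 200), junk), "s")
  out <- align_library(lib, tpl)
  expect_equal(out$ids, "good")
  expect_equal(out$removed, "bad")
})

test_that("reverse-complement queries thread onto the plus strand", {
  tpl <- make_template()
  q <- revcomp(substr(tpl$ungapped[[4]], 50, 300))
  al <- align_to_template(q, tpl)
  expect_equal(al$strand, "-")
  expect_gt(al$score, 0)
  expect_equal(gsub("-", "", al$columns), substr(tpl$ungapped[[4]], 50, 300))
})

test_that("paired alignment splits, aligns and rejoins; negative mates drop
           the whole pair", {
  tpl <- make_template()
  r1a <- substr(tpl$ungapped[[1]], 1, 120)
  r2a <- revcomp(substr(tpl$ungapped[[1]], 250, 369))
  set.seed(32)
  junk <- random_dna(1, 120)
  lib <- seq_library(
    "paired_concat", c("ok", "badmate"),
    c(paste0(r1a, r2a), paste0(r1a, junk)), "s",
    pair_split = c(ok = 120L, badmate = 120L))
  out <- align_paired(lib, tpl)
  expect_equal(out$ids, "ok")
  expect_equal(out$removed, "badmate")
  expect_equal(nchar(out$rows[["ok"]]), 2L * tpl$column_count)
  # R1 region columns then R2 region columns
  expect_equal(gsub("-", "", substr(out$rows[["ok"]], 1, tpl$column_count)),
               r1a)
  expect_equal(gsub("-", "", substr(out$rows[["ok"]], tpl$column_count + 1,
                                    2L * tpl$column_count)),
               substr(tpl$ungapped[[1]], 250, 369))

  empty <- align_paired(seq_library("paired_concat", pair_split = integer()),
                        tpl)
  expect_length(empty$ids, 0L)
})

test_that("gapped template rows place queries into the right columns", {
  rows <- c(a = "AC-GTAC--GT", b = "ACTGTACGGGT")
  tpl <- template_alignment(rows)
  expect_equal(tpl$column_count, 11L)
  al <- align_to_template("ACGTACGT", tpl)
  expect_equal(al$template_row, "a")
  expect_equal(al$columns, "AC-GTAC--GT")
})

test_that("strip_empty_columns removes exactly the all-gap columns", {
  rows <- c(x = "A-C-", y = "A-G-")
  expect_equal(unname(strip_empty_columns(rows)), c("AC", "AG"))
  rows2 <- c(x = "ACGT", y = "TGCA")
  expect_identical(strip_empty_columns(rows2), rows2)
  expect_equal(unname(strip_empty_columns(c(solo = "-A-C-"))), "AC")
})

test_that("JC69 distances match the closed form and saturate", {
  rows <- c(a = strrep("A", 100), b = strrep("A", 100))
  expect_equal(jc69_distance_matrix(rows)["a", "b"], 0)

  # p = 0.25
  rows2 <- c(a = strrep("ACGT", 25),
             b = paste0(strrep("ACGT", 18), strrep("AGGT", 7)))
  p <- 1 - mean(strsplit(rows2[1], "")[[1]] == strsplit(rows2[2], "")[[1]])
  expect_equal(p, 0.07)
  d <- jc69_distance_matrix(rows2)["a", "b"]
  expect_equal(d, -0.75 * log(1 - 4 * 0.07 / 3))

  p25 <- c(a = strrep("AAAA", 25), b = strrep("AAAC", 25))
  expect_equal(jc69_distance_matrix(p25)["a", "b"],
               -0.75 * log(1 - (4 / 3) * 0.25), tolerance = 1e-9)
  expect_equal(jc69_distance_matrix(p25)["a", "b"], 0.30409,
               tolerance = 1e-4)

  sat <- c(a = strrep("A", 100), b = paste0(strrep("C", 75), strrep("A", 25)))
  # p = 0.75 saturates
  expect_equal(jc69_distance_matrix(sat)["a", "b"], 5.0)

  nogap <- c(a = paste0(strrep("A", 50), strrep("-", 50)),
             b = paste0(strrep("-", 50), strrep("A", 50)))
  expect_equal(jc69_distance_matrix(nogap)["a", "b"], 5.0)

  # pairwise deletion: gap columns ignored per pair
  pd <- c(a = "AC-GT", b = "ACCGT")
  expect_equal(jc69_distance_matrix(pd)["a", "b"], 0)
})

test_that("neighbor joining solves the three-point case and additive inputs", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  cm <- cophenetic_matrix(tr)
  expect_equal(cm[rownames(D), colnames(D)], D)
  # pendant branch lengths 1, 1, 3
  pendant <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(pendant[c("A", "B", "C")]), c(1, 1, 3))

  # 2-taxon case: leaf-to-leaf distance preserved
  D2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  tr2 <- neighbor_joining(D2)
  expect_equal(sum(tr2$edge.length), 0.5)

  # exact recovery from an additive (tree-generated) matrix
  set.seed(33)
  for (i in 1:5) {
    true <- ape::rtree(5 + i)
    D3 <- cophenetic_matrix(true)
    rec <- neighbor_joining(D3)
    expect_equal(cophenetic_matrix(rec)[rownames(D3), colnames(D3)], D3,
                 tolerance = 1e-8)
  }
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "symmetric")
})

test_that("cophenetic distances are path sums of branch lengths", {
  f <- withr::local_tempfile()
  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- read_newick(f)
  cm <- cophenetic_matrix(tr)
  expect_equal(cm["A", "B"], 2)
  expect_equal(cm["A", "C"], 4)
  expect_equal(cm["B", "C"], 4)
})
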