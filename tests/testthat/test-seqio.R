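test_that("parse_fastq decodes Phred+33 and keeps header up to whitespace", {
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@read1 extra words", "ACGTA", "+", "IIII#"), f)
  lib <- parse_fastq(f, "sampleA")
  expect_equal(length(lib), 1L)
  expect_equal(lib$id, "read1")
  expect_equal(lib$sample_id, "sampleA")
  expect_equal(lib$qual[[1]], c(40L, 40L, 40L, 40L, 2L))
})

test_that("parse_fastq rejects malformed records", {
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTA", "+", "IIII"), f) # 5 bases, 4 quality chars
  expect_error(parse_fastq(f, "s"), "mismatch.*r1")
  writeLines(c("@r1", "ACGTA", "+", "IIIII", "@r2", "ACGT"), f)
  expect_error(parse_fastq(f, "s"), "truncated")
})

test_that("parse_fastq rejects Phred+64-looking files", {
  f <- withr::local_tempfile(fileext = ".fastq")
  # all quality codes in the Phred+64 band (ASCII >= 59, some > 74)
  writeLines(c("@r1", "ACGTACGT", "+", "ffffhhhh"), f)
  expect_error(parse_fastq(f, "s"), "Phred\\+64")
})

test_that("fastq round-trip is the identity on well-formed libraries", {
  set.seed(1)
  n <- 20
  lib <- seq_library("R1", sprintf("r%02d", 1:n), random_dna(n, 60), "sX",
                     qual = lapply(1:n, function(i)
                       sample(2:40, 60, replace = TRUE)))
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(lib, f)
  back <- parse_fastq(f, "sX")
  expect_identical(back$id, lib$id)
  expect_identical(back$seq, lib$seq)
  expect_identical(back$qual, lib$qual)
})

test_that("seq_library enforces its invariants", {
  expect_error(seq_library("R1", c("a", "a"), c("ACGT", "ACGT")), "unique")
  expect_error(seq_library("R1", "a", "ACGT", qual = list(1:3)), "mismatch")
  expect_error(seq_library("paired_concat", "a", "ACGT"), "pair_split")
  expect_error(seq_library("paired_concat", "a", "ACGT",
                           pair_split = c(a = 4L)), "split")
})

test_that("R1/R2 pairing keys strip trailing /1 and /2", {
  r1 <- seq_library("R1", "readA/1", "ACGTACGT", "s",
                    qual = list(rep(40L, 8)))
  r2 <- seq_library("R2", "readA/2", "TTGCACGT", "s",
                    qual = list(rep(40L, 8)))
  pt <- pair_and_trim(r1, r2)
  expect_equal(pt$r1$id, "readA")
  expect_equal(pt$r2$id, "readA")
})

test_that("BIOM writing produces valid sparse BIOM 1.0 that round-trips", {
  cnt <- matrix(c(1L, 0L, 0L, 3L), 2, 2,
                dimnames = list(c("OTU_1", "OTU_2"), c("s1", "s2")))
  tax <- c(OTU_1 = "k__Bacteria; p__X; c__Y; o__Z; f__F; g__G; s__S",
           OTU_2 = "k__Bacteria; p__Q; c__; o__; f__; g__; s__")
  sm <- data.frame(group = c("a", "b"), row.names = c("s1", "s2"))
  tab <- otu_table(cnt, taxonomy = tax, sample_metadata = sm)
  f <- withr::local_tempfile(fileext = ".biom")
  write_biom(tab, f)
  doc <- jsonlite::read_json(f)
  expect_equal(doc$type, "OTU table")
  expect_equal(doc$matrix_type, "sparse")
  expect_equal(unlist(doc$shape), c(2, 2))
  expect_true(all(c("id", "format", "type", "shape", "rows", "columns",
                    "data") %in% names(doc)))
  expect_length(doc$rows[[1]]$metadata$taxonomy, 7L)
  back <- read_biom_table(f)
  expect_identical(back$counts, cnt)
  expect_identical(back$taxonomy[names(tax)], tax)
  expect_equal(back$sample_metadata["s1", "group"], "a")
})

test_that("BIOM output is readable by the independent biomformat reader", {
  skip_if_not_installed("biomformat")
  cnt <- matrix(c(5L, 0L, 2L, 0L, 0L, 7L), 3, 2,
                dimnames = list(paste0("OTU_", 1:3), c("sampleA", "sampleB")))
  f <- withr::local_tempfile(fileext = ".biom")
  write_biom(otu_table(cnt), f)
  b <- biomformat::read_biom(f)
  expect_equal(as.matrix(biomformat::biom_data(b)),
               matrix(as.numeric(cnt), 3, 2,
                      dimnames = dimnames(cnt)))
})

test_that("empty OTU table serializes with the right shape", {
  cnt <- matrix(integer(), 0, 2, dimnames = list(NULL, c("s1", "s2")))
  f <- withr::local_tempfile(fileext = ".biom")
  write_biom(otu_table(cnt), f)
  doc <- jsonlite::read_json(f)
  expect_equal(unlist(doc$shape), c(0, 2))
})

test_that("newick round-trip preserves topology, labels and lengths", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- read_newick(f)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  write_newick(tr, f)
  tr2 <- read_newick(f)
  expect_equal(cophenetic_matrix(tr2)[tr$tip.label, tr$tip.label],
               cophenetic_matrix(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-9)

  set.seed(5)
  big <- ape::rtree(50)
  write_newick(big, f)
  back <- read_newick(f)
  expect_equal(cophenetic_matrix(back)[big$tip.label, big$tip.label],
               cophenetic_matrix(big)[big$tip.label, big$tip.label],
               tolerance = 1e-9)
  writeLines("((A:1,B:1:1,C:2);", f)
  expect_error(read_newick(f), "parse")

  writeLines("A:0.5;", f) # single leaf is still a valid tree
  single <- read_newick(f)
  expect_equal(single$tip.label, "A")
  expect_equal(single$edge.length, 0.5)
})

test_that("mapping files require the #SampleID convention", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#SampleID\tgroup", "s1\tcase", "s2\tcontrol"), f)
  m <- read_mapping_file(f)
  expect_equal(rownames(m), c("s1", "s2"))
  expect_equal(m["s2", "group"], "control")
  writeLines(c("sample\tgroup", "s1\tcase"), f)
  expect_error(read_mapping_file(f), "#SampleID")
})
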