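# Shared fixtures, built once per test run.

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

make_fastq <- function(path, ids, seqs, quals) {
  qstr <- vapply(quals, function(q) rawToChar(as.raw(q + 33L)), "")
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qstr)), path)
  path
}

# small simulated reference shared across test files (lazy, cached)
fixture_env <- new.env()

get_fixture_refs <- function() {
  if (is.null(fixture_env$refs)) {
    fixture_env$refs <- simulate_reference(80, seed = 11)
    fixture_env$pcr <- in_silico_pcr(fixture_env$refs)
    fixture_env$template <- template_alignment(fixture_env$refs$sequences)
  }
  fixture_env
}

# well-separated sequence families (random bases are < 90% mutually
# identical): per family, 3 exact copies of the base plus 2 copies of a
# 1-mismatch variant (> 97% identical, absorbed at picking)
make_family_library <- function(k = 4, len = 200, seed = 99) {
  set.seed(seed)
  base <- random_dna(k, len)
  ids <- character(); seqs <- character()
  for (f in seq_len(k)) {
    variant <- base[f]
    substr(variant, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                       substr(variant, 10, 10))[1]
    fam_seqs <- c(rep(base[f], 3), rep(variant, 2))
    ids <- c(ids, sprintf("fam%d_read%d", f, seq_along(fam_seqs)))
    seqs <- c(seqs, fam_seqs)
  }
  list(lib = seq_library("full_length", ids, seqs, "s1"), base = base)
}
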