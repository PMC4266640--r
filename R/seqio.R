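# Sequence data model and on-disk formats: FASTQ (Phred+33), FASTA,
# aligned FASTA, BIOM 1.0 JSON, newick, QIIME-style mapping files.

LIBRARY_TYPES <- c("R1", "R2", "paired_concat", "paired_stitched", "full_length")

#' Construct a sequence library
#'
#' A `seq_library` is the shared in-memory model for a collection of reads:
#' parallel vectors of read ids, samples of origin, sequences, optional
#' per-read Phred qualities, and -- for the two paired ("joined") types --
#' the split point recording how many leading characters belong to the R1
#' mate.
#'
#' @param type one of `"R1"`, `"R2"`, `"paired_concat"`, `"paired_stitched"`,
#'   `"full_length"`.
#' @param id character vector of unique, non-empty read ids.
#' @param seq character vector of IUPAC DNA sequences (non-empty).
#' @param sample_id character vector of samples of origin (recycled if
#'   length 1).
#' @param qual optional list of integer Phred score vectors, one per read,
#'   each the same length as its sequence.
#' @param pair_split named integer vector (names = read ids) giving the R1
#'   component length of each joined read; required for the paired types.
#' @return an object of class `seq_library`.
#' @export
seq_library <- function(type, id = character(), seq = character(),
                        sample_id = rep("sample1", length(id)),
                        qual = NULL, pair_split = NULL) {
  type <- match.arg(type, LIBRARY_TYPES)
  id <- as.character(id)
  seq <- as.character(seq)
  if (length(sample_id) == 1L) sample_id <- rep(sample_id, length(id))
  sample_id <- as.character(sample_id)
  stopifnot(length(id) == length(seq), length(id) == length(sample_id))
  if (anyDuplicated(id)) stop("read ids must be unique within a library")
  if (length(id) && (any(!nzchar(id)) || any(!nzchar(seq))))
    stop("read ids and sequences must be non-empty")
  if (!is.null(qual)) {
    stopifnot(is.list(qual), length(qual) == length(id))
    bad <- which(nchar(seq) != lengths(qual))
    if (length(bad))
      stop("sequence/quality length mismatch for read '", id[bad[1]], "'")
  }
  if (type %in% c("paired_concat", "paired_stitched")) {
    if (is.null(pair_split)) stop("paired library types require pair_split")
    pair_split <- pair_split[id]
    if (anyNA(pair_split)) stop("pair_split missing for some read ids")
    if (length(id) && any(pair_split <= 0 | pair_split >= nchar(seq)))
      stop("pair_split must satisfy 0 < split < read length")
  }
  structure(list(type = type, id = id, sample_id = sample_id, seq = seq,
                 qual = qual, pair_split = pair_split),
            class = "seq_library")
}

#' @export
length.seq_library <- function(x) length(x$id)

#' @export
print.seq_library <- function(x, ...) {
  cat(sprintf("<seq_library> type=%s reads=%d samples=%d qualities=%s\n",
              x$type, length(x$id), length(unique(x$sample_id)),
              if (is.null(x$qual)) "absent" else "present"))
  invisible(x)
}

#' Subset a sequence library
#'
#' @param x a [seq_library()].
#' @param i index vector (logical, integer or read-id character).
#' @param ... unused.
#' @return a `seq_library` of the selected reads.
#' @export
`[.seq_library` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$id)
  seq_library(x$type, x$id[i], x$seq[i], x$sample_id[i],
              qual = if (!is.null(x$qual)) x$qual[i],
              pair_split = x$pair_split)
}

strip_mate_suffix <- function(ids) sub("/[12]$", "", ids)

#' Parse a FASTQ file (Phred+33)
#'
#' Reads a 4-line-per-record FASTQ file. Read ids keep the header up to the
#' first whitespace; qualities are decoded as ASCII code minus 33. Files in
#' Phred+64 encoding (no quality character below ASCII 59 anywhere in the
#' file) are rejected rather than silently mis-decoded.
#'
#' @param path FASTQ file path.
#' @param sample_id sample of origin recorded on every read.
#' @param type library type of the result (default `"R1"`).
#' @return a [seq_library()] with qualities.
#' @export
parse_fastq <- function(path, sample_id, type = "R1") {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record at end of ", path)
  if (length(lines) == 0L)
    return(seq_library(type, qual = list()))
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  if (any(substr(hdr, 1L, 1L) != "@"))
    stop("malformed FASTQ header (missing '@') in ", path)
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("sequence/quality length mismatch for record '", ids[bad[1]],
         "' in ", path)
  qraw <- lapply(quals, function(s) as.integer(charToRaw(s)))
  if (length(qraw) && min(unlist(qraw, use.names = FALSE)) >= 59L &&
      max(unlist(qraw, use.names = FALSE)) > 74L)
    stop("quality strings look Phred+64 encoded; only Phred+33 is supported")
  seq_library(type, ids, toupper(seqs), sample_id,
              qual = lapply(qraw, function(q) q - 33L))
}

#' Write a FASTQ file (Phred+33)
#'
#' @param lib a quality-bearing [seq_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(lib, path) {
  if (is.null(lib$qual)) stop("library has no qualities to write")
  qstr <- vapply(lib$qual, function(q) rawToChar(as.raw(q + 33L)), "")
  writeLines(as.vector(rbind(paste0("@", lib$id), lib$seq, "+", qstr)), path)
  invisible(path)
}

#' Read a FASTA file into a sequence library
#'
#' @param path FASTA file (wrapped or single-line).
#' @param sample_id sample of origin recorded on every read.
#' @param type library type of the result.
#' @return a quality-free [seq_library()].
#' @export
read_fasta <- function(path, sample_id = "sample1", type = "full_length") {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seq_library(type, ids, toupper(as.character(ss)), sample_id)
}

#' Write sequences to FASTA
#'
#' @param lib a [seq_library()], or a named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (0 = single line).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(lib, path, width = 0L) {
  seqs <- if (inherits(lib, "seq_library")) setNames(lib$seq, lib$id) else lib
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path,
                              width = if (width > 0L) width else 20001L)
  invisible(path)
}

# ---- OTU tables and BIOM 1.0 JSON ------------------------------------------

#' Construct an OTU table
#'
#' OTU-by-sample count matrix with optional taxonomy strings per OTU and
#' key/value sample metadata, serializable as BIOM 1.0 JSON.
#'
#' @param counts nonnegative integer matrix, rows = OTUs, columns = samples,
#'   with dimnames.
#' @param taxonomy optional named character vector of 7-rank lineage strings
#'   (`"k__...; p__...; ...; s__..."`); names must be OTU ids.
#' @param sample_metadata optional data.frame keyed by sample id (rownames).
#' @return an object of class `otu_table`.
#' @export
otu_table <- function(counts, taxonomy = NULL, sample_metadata = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      is.null(colnames(counts)))
    stop("counts must have OTU rownames and sample colnames")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (any(counts < 0)) stop("counts must be nonnegative")
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    unknown <- setdiff(names(taxonomy), rownames(counts))
    if (length(unknown))
      stop("taxonomy given for unknown OTUs: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(sample_metadata) &&
      !all(rownames(sample_metadata) %in% colnames(counts)))
    stop("sample_metadata rows must match sample ids")
  structure(list(counts = counts, taxonomy = taxonomy,
                 sample_metadata = sample_metadata), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d OTUs x %d samples, total count %d\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

split_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";[ ]?")[[1]]
  length(parts) <- 7L
  parts[is.na(parts)] <- ""
  parts
}

#' Write an OTU table as BIOM 1.0 JSON
#'
#' Produces a sparse-representation BIOM 1.0 document of type "OTU table".
#' Taxonomy lineage strings are split on `"; "` and stored as a rank list
#' under the observation metadata key `"taxonomy"`; sample metadata columns
#' are stored per sample. The output round-trips losslessly through
#' [read_biom_table()] (and is readable by the biomformat package).
#'
#' @param table an [otu_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_biom <- function(table, path) {
  cnt <- table$counts
  rows <- lapply(rownames(cnt), function(oid) {
    md <- if (!is.null(table$taxonomy) && oid %in% names(table$taxonomy))
      list(taxonomy = as.list(split_lineage(table$taxonomy[[oid]])))
    else NULL
    list(id = oid, metadata = md)
  })
  cols <- lapply(colnames(cnt), function(sid) {
    md <- NULL
    sm <- table$sample_metadata
    if (!is.null(sm) && sid %in% rownames(sm))
      md <- lapply(as.list(sm[sid, , drop = FALSE]), as.character)
    list(id = sid, metadata = md)
  })
  nz <- which(cnt != 0L, arr.ind = TRUE)
  data <- lapply(seq_len(nrow(nz)), function(k)
    list(nz[k, 1L] - 1L, nz[k, 2L] - 1L, cnt[nz[k, 1L], nz[k, 2L]]))
  doc <- list(
    id = NULL,
    format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table",
    generated_by = paste0("paired16S ", utils::packageVersion("paired16S")),
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    matrix_type = "sparse",
    matrix_element_type = "int",
    shape = dim(cnt),
    rows = rows,
    columns = cols,
    data = data)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Read a BIOM 1.0 JSON OTU table
#'
#' @param path BIOM file written by [write_biom()] (or any sparse/dense
#'   BIOM 1.0 JSON of type "OTU table").
#' @return an [otu_table()].
#' @export
read_biom_table <- function(path) {
  doc <- jsonlite::read_json(path)
  shape <- as.integer(unlist(doc$shape))
  oids <- vapply(doc$rows, function(r) r$id, "")
  sids <- vapply(doc$columns, function(cc) cc$id, "")
  cnt <- matrix(0L, shape[1], shape[2], dimnames = list(oids, sids))
  if (identical(doc$matrix_type, "dense")) {
    for (i in seq_along(doc$data))
      cnt[i, ] <- as.integer(unlist(doc$data[[i]]))
  } else {
    for (tr in doc$data)
      cnt[tr[[1]] + 1L, tr[[2]] + 1L] <- as.integer(tr[[3]])
  }
  tax <- NULL
  taxl <- lapply(doc$rows, function(r) r$metadata$taxonomy)
  if (any(!vapply(taxl, is.null, TRUE))) {
    tax <- vapply(taxl, function(tl)
      if (is.null(tl)) NA_character_ else paste(unlist(tl), collapse = "; "),
      "")
    names(tax) <- oids
    tax <- tax[!is.na(tax)]
  }
  sm <- NULL
  mdl <- lapply(doc$columns, function(cc) cc$metadata)
  if (any(!vapply(mdl, is.null, TRUE))) {
    keys <- unique(unlist(lapply(mdl, names)))
    sm <- as.data.frame(lapply(keys, function(k)
      vapply(mdl, function(m)
        if (is.null(m[[k]])) NA_character_ else as.character(m[[k]]), "")),
      col.names = keys)
    rownames(sm) <- sids
  }
  otu_table(cnt, taxonomy = tax, sample_metadata = sm)
}

# ---- newick and mapping files ----------------------------------------------

#' Read / write newick trees
#'
#' Thin wrappers around ape's newick parser/serializer, pinned to 10
#' significant digits so that branch lengths round-trip.
#'
#' @param path newick file path.
#' @return `read_newick`: an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  if (lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE))) !=
      lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE))))
    stop("newick parse error: unbalanced parentheses")
  # single-leaf newick ("A:0.5;"): below ape's representable minimum, stored
  # as a root with one pendant edge
  m <- regmatches(txt, regexec("^\\s*([^():,;]+?)(:([0-9.eE+-]+))?;\\s*$",
                               txt))[[1]]
  if (length(m)) {
    tr <- structure(list(edge = matrix(c(2L, 1L), 1L),
                         tip.label = m[2],
                         edge.length = if (nzchar(m[4])) as.numeric(m[4]),
                         Nnode = 1L), class = "phylo")
    return(tr)
  }
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error in ", path)
  tr
}

#' @rdname read_newick
#' @param tree an `ape::phylo` tree.
#' @return `write_newick`: `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read a QIIME-style sample mapping file
#'
#' Tab-delimited, first column `#SampleID`.
#'
#' @param path mapping file path.
#' @return data.frame with sample ids as rownames.
#' @export
read_mapping_file <- function(path) {
  df <- read.delim(path, check.names = FALSE, comment.char = "",
                   stringsAsFactors = FALSE)
  if (colnames(df)[1] != "#SampleID")
    stop("mapping file must start with a '#SampleID' column")
  rownames(df) <- df[[1]]
  df[-1]
}
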