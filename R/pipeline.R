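# End-to-end orchestration: QC -> pair/join -> dereplicate -> OTU picking ->
# taxonomy on stitched representatives -> unclassified-representative
# removal -> per-mate structural alignment -> read mapping -> BIOM ->
# neighbor-joining tree, with a per-stage read ledger and a run manifest.

#' Pipeline configuration
#'
#' @param samples data.frame with columns `sample_id`, `r1`, and (paired
#'   mode) `r2`: one FASTQ file per mate per sample.
#' @param ref_seqs path to the taxonomy reference FASTA.
#' @param ref_tax path to the matching `id<TAB>lineage` taxonomy table.
#' @param template path to the seed alignment (aligned FASTA).
#' @param out_dir output directory (created if missing).
#' @param mode `"paired"`, `"R1"`, or `"R2"`.
#' @param read_length_r1,read_length_r2 as-sequenced read lengths.
#' @param r2_trim_len R2 uniformization length (default 4/5 of R2 length).
#' @param threshold OTU identity threshold.
#' @param n_bootstrap,conf_cutoff classifier parameters.
#' @param mapping_file optional QIIME-style sample metadata file.
#' @param seed seed for classifier bootstrap randomness.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(samples, ref_seqs, ref_tax, template, out_dir,
                            mode = c("paired", "R1", "R2"),
                            read_length_r1 = 250L,
                            read_length_r2 = read_length_r1,
                            r2_trim_len = NULL, threshold = 0.97,
                            n_bootstrap = 100L, conf_cutoff = 0.80,
                            mapping_file = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(samples), "sample_id" %in% names(samples),
            "r1" %in% names(samples))
  if (mode == "paired" && !"r2" %in% names(samples))
    stop("paired mode requires an r2 column in samples")
  paths <- c(samples$r1, if (mode == "paired") samples$r2,
             ref_seqs, ref_tax, template, mapping_file)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input files not found: ", paste(missing, collapse = ", "))
  structure(list(samples = samples, ref_seqs = ref_seqs, ref_tax = ref_tax,
                 template = template, out_dir = out_dir, mode = mode,
                 read_length_r1 = as.integer(read_length_r1),
                 read_length_r2 = as.integer(read_length_r2),
                 r2_trim_len = r2_trim_len, threshold = threshold,
                 n_bootstrap = as.integer(n_bootstrap),
                 conf_cutoff = conf_cutoff, mapping_file = mapping_file,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a flat key=value pipeline configuration file
#'
#' Keys mirror [pipeline_config()] arguments; `sample_ids`, `r1_files` and
#' `r2_files` are comma-separated and zipped into the samples table.
#'
#' @param path configuration file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), value = TRUE, invert = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  splitcsv <- function(x) trimws(strsplit(x, ",")[[1]])
  samples <- data.frame(sample_id = splitcsv(vals[["sample_ids"]]),
                        r1 = splitcsv(vals[["r1_files"]]))
  if ("r2_files" %in% names(vals)) samples$r2 <- splitcsv(vals[["r2_files"]])
  opt <- function(key, default, f = identity)
    if (key %in% names(vals)) f(vals[[key]]) else default
  pipeline_config(samples,
                  ref_seqs = vals[["ref_seqs"]], ref_tax = vals[["ref_tax"]],
                  template = vals[["template"]], out_dir = vals[["out_dir"]],
                  mode = opt("mode", "paired"),
                  read_length_r1 = opt("read_length_r1", 250L, as.integer),
                  read_length_r2 = opt("read_length_r2",
                                       opt("read_length_r1", 250L, as.integer),
                                       as.integer),
                  r2_trim_len = opt("r2_trim_len", NULL, as.integer),
                  threshold = opt("threshold", 0.97, as.numeric),
                  n_bootstrap = opt("n_bootstrap", 100L, as.integer),
                  conf_cutoff = opt("conf_cutoff", 0.80, as.numeric),
                  mapping_file = opt("mapping_file", NULL),
                  seed = opt("seed", 1L, as.integer))
}

#' Run the full pipeline
#'
#' Executes, in order: quality filtering, pair matching and R2
#' uniformization, joined-read construction, dereplication, greedy OTU
#' picking with chimera screening, taxonomy assignment of the stitched
#' representatives, removal of fully unclassified representatives, per-mate
#' template alignment with the negative-score filter, empty-column removal,
#' mapping of all reads to the clean representatives, BIOM output, and
#' neighbor-joining tree construction. Single-read modes run the same stage
#' list with joining disabled. A per-stage read ledger and a manifest
#' (parameters, seeds, input checksums) are written to the output directory.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the `otu_table`, `tree`, `assignments`,
#'   `ledger`, and output paths.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  paired <- config$mode == "paired"
  ledger <- list()
  note <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, paste0(...))
    message(line)
    ledger[[length(ledger) + 1L]] <<- line
  }

  r1 <- do.call(rbind_libs, lapply(seq_len(nrow(config$samples)), function(i)
    parse_fastq(config$samples$r1[i], config$samples$sample_id[i], "R1")))
  note("input", "R1 reads: ", length(r1))
  if (paired) {
    r2 <- do.call(rbind_libs, lapply(seq_len(nrow(config$samples)),
                                     function(i)
      parse_fastq(config$samples$r2[i], config$samples$sample_id[i], "R2")))
    note("input", "R2 reads: ", length(r2))
  } else {
    r2 <- NULL
  }

  qp1 <- qc_params(original_length = config$read_length_r1)
  if (paired) {
    qp2 <- qc_params(original_length = config$read_length_r2)
    qf <- quality_filter(r1, r2, qp1, qp2)
    note("qc", "surviving R1: ", length(qf$r1), ", R2: ", length(qf$r2))
    jp <- pair_join_params(r2_trim_len = config$r2_trim_len,
                           r2_original_length = config$read_length_r2)
    pt <- pair_and_trim(qf$r1, qf$r2, jp)
    note("pair_and_trim", "matched pairs: ", length(pt$r1))
    joined <- make_joined_reads(pt$r1, pt$r2, jp)
    work_lib <- joined$concat
    stitched <- joined$stitched
    min_len <- config$read_length_r1 + jp$r2_trim_len
  } else {
    qf <- qc_filter_one(r1, qp1)
    note("qc", "surviving reads: ", length(qf))
    work_lib <- qf
    stitched <- NULL
    min_len <- min_length_cutoff(config$read_length_r1)
  }
  if (!length(work_lib))
    stop("pipeline stage 'qc' failed: no reads survive quality filtering",
         call. = FALSE)

  clusters <- dereplicate(work_lib)
  note("dereplicate", length(clusters), " distinct sequences")
  picked <- pick_otus(clusters, threshold = config$threshold,
                      min_len = min_len)
  note("pick_otus", length(picked$centroids), " OTU representatives; ",
       sum(picked$assignment == "chimera"), " chimeric, ",
       sum(picked$assignment == "dropped"), " dropped")
  if (!length(picked$centroids))
    stop("pipeline stage 'pick_otus' failed: no OTU representatives",
         call. = FALSE)

  ref_lib <- read_fasta(config$ref_seqs)
  lineages <- read_taxonomy_file(config$ref_tax)
  model <- train_classifier(setNames(ref_lib$seq, ref_lib$id), lineages)
  rep_ids <- vapply(picked$centroids, `[[`, "", "rep_id")
  query <- if (paired) setNames(stitched$seq[match(rep_ids, stitched$id)],
                                rep_ids)
           else setNames(vapply(picked$centroids, `[[`, "", "seq"), rep_ids)
  assignments <- lapply(query, classify_seq, model = model,
                        n_bootstrap = config$n_bootstrap,
                        conf_cutoff = config$conf_cutoff)
  cleaned <- filter_unclassified(picked$centroids, assignments)
  note("taxonomy", length(cleaned$centroids), " classified representatives; ",
       length(cleaned$removed), " fully unclassified removed")
  if (!length(cleaned$centroids))
    stop("pipeline stage 'taxonomy' failed: all representatives removed",
         call. = FALSE)

  template <- template_alignment(config$template)
  cent_ids <- vapply(cleaned$centroids, `[[`, "", "rep_id")
  cent_seqs <- vapply(cleaned$centroids, `[[`, "", "seq")
  cent_lib <- if (paired)
    seq_library("paired_concat", cent_ids, cent_seqs, "centroids",
                pair_split = work_lib$pair_split[cent_ids])
  else seq_library(work_lib$type, cent_ids, cent_seqs, "centroids")
  al <- if (paired) align_paired(cent_lib, template)
        else align_library(cent_lib, template)
  note("align", length(al$ids), " representatives aligned; ",
       length(al$removed), " removed by the negative-score filter")
  keep <- cent_ids %in% al$ids
  centroids <- cleaned$centroids[keep]
  if (length(centroids) < 2L)
    stop("pipeline stage 'align' failed: fewer than 2 aligned representatives",
         call. = FALSE)
  otu_ids <- vapply(centroids, `[[`, "", "otu_id")
  rows <- strip_empty_columns(al$rows)
  names(rows) <- otu_ids

  mapping <- map_reads_to_otus(work_lib, centroids,
                               threshold = config$threshold)
  note("map_reads", sum(mapping$counts), " reads mapped, ",
       mapping$unmapped, " unmapped")
  assign_by_otu <- setNames(
    cleaned$assignments[match(otu_ids, names(cleaned$assignments))], otu_ids)
  taxonomy <- vapply(assign_by_otu, assignment_lineage, "")
  sm <- if (!is.null(config$mapping_file))
    read_mapping_file(config$mapping_file)
  table <- otu_table(mapping$counts, taxonomy = taxonomy,
                     sample_metadata = sm)

  tree <- neighbor_joining(jc69_distance_matrix(rows))

  paths <- list(biom = file.path(config$out_dir, "otu_table.biom"),
                tree = file.path(config$out_dir, "otus.nwk"),
                taxonomy = file.path(config$out_dir, "taxonomy.tsv"),
                alignment = file.path(config$out_dir, "otus.afa"),
                manifest = file.path(config$out_dir, "manifest.json"),
                log = file.path(config$out_dir, "pipeline.log"))
  write_biom(table, paths$biom)
  write_newick(tree, paths$tree)
  write_taxonomy_file(assign_by_otu, paths$taxonomy)
  write_fasta(rows, paths$alignment, width = 80L)
  manifest <- list(package = "paired16S",
                   version = as.character(utils::packageVersion("paired16S")),
                   mode = config$mode, seed = config$seed,
                   threshold = config$threshold,
                   read_length_r1 = config$read_length_r1,
                   read_length_r2 = config$read_length_r2,
                   n_bootstrap = config$n_bootstrap,
                   conf_cutoff = config$conf_cutoff,
                   inputs = lapply(setNames(nm = c(config$samples$r1,
                                                   if (paired) config$samples$r2)),
                                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  writeLines(unlist(ledger), paths$log)
  invisible(list(otu_table = table, tree = tree,
                 assignments = assign_by_otu, ledger = unlist(ledger),
                 paths = paths))
}

# concatenate libraries of the same type
rbind_libs <- function(...) {
  libs <- list(...)
  seq_library(libs[[1]]$type,
              unlist(lapply(libs, `[[`, "id")),
              unlist(lapply(libs, `[[`, "seq")),
              unlist(lapply(libs, `[[`, "sample_id")),
              qual = if (!is.null(libs[[1]]$qual))
                do.call(c, lapply(libs, `[[`, "qual")))
}
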