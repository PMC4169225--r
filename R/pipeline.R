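#' Build a pipeline configuration
#'
#' Collects every input path and threshold of the pipeline into a single
#' declarative list, mirroring the per-stage function arguments so a run
#' is fully reproducible from its configuration alone.  All thresholds
#' default to the values used throughout the package documentation.
#'
#' @param reads Path to the input FASTA/FASTQ (or a read tibble).
#' @param reads2 Optional mate-2 FASTQ for paired-end input; pairs are
#'   collapsed with [collapse_pairs()] before demultiplexing.
#' @param barcodes Barcode TSV path or tibble.
#' @param ltr,lc LTR and (optional) linker-cassette sequences or FASTA
#'   paths.
#' @param reference Reference FASTA path (or named sequences) including
#'   the vector dummy chromosome.
#' @param vector_name Dummy-chromosome name (default `"VECTOR"`).
#' @param bed Optional BED feature file (or feature tibble) for
#'   annotation.
#' @param metadata Optional sample metadata (TSV path or tibble with
#'   columns `label`, `source`, `cell_type`, `time_point`).
#' @param min_length Minimum trimmed fragment length (default 20).
#' @param homology,lc_homology LTR / LC homology thresholds in percent.
#' @param min_identity Minimum hit identity for the prefilter and quality
#'   filter (default 95).
#' @param max_start Maximum query start position kept by the prefilter
#'   (default 3).
#' @param as_t,hs_t Ambiguity-classification gap thresholds (defaults 15
#'   and 20).
#' @param min_hs Minimum homology score in the quality filter (default 80).
#' @param window Locus-merge window (default 3).
#' @param chunks Alignment chunk count (default 1; results are identical
#'   for any value).
#' @param keep_tag,ignore_strand,hs_inclusive,lv_any Behavioural switches
#'   documented in [demultiplex()], [merge_loci()], [homology_score()] and
#'   [classify_reads()].
#' @param tag_length Barcode tag length (default 6).
#' @return A config list of class `lampis_config`.
#' @export
pipeline_config <- function(reads, barcodes, ltr, reference, reads2 = NULL,
                            lc = NULL, vector_name = "VECTOR", bed = NULL,
                            metadata = NULL, min_length = 20, homology = 89,
                            lc_homology = 89, min_identity = 95, max_start = 3,
                            as_t = 15, hs_t = 20, min_hs = 80, window = 3,
                            chunks = 1, keep_tag = FALSE, ignore_strand = FALSE,
                            hs_inclusive = FALSE, lv_any = TRUE,
                            tag_length = 6) {
  cfg <- as.list(environment())
  structure(cfg, class = "lampis_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat key-value YAML with keys matching the arguments of
#' [pipeline_config()]; relative paths are resolved against the file's
#' directory.
#'
#' @param path Path to the YAML file.
#' @return A `lampis_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  base <- dirname(normalizePath(path))
  for (k in intersect(names(raw), c("reads", "reads2", "barcodes", "ltr", "lc",
                                    "reference", "bed", "metadata"))) {
    if (is.character(raw[[k]]) && !file.exists(raw[[k]]) &&
        file.exists(file.path(base, raw[[k]]))) {
      raw[[k]] <- file.path(base, raw[[k]])
    }
  }
  do.call(pipeline_config, raw)
}

#' Run the full integration-site pipeline
#'
#' Executes every stage end-to-end: input conversion (FASTQ to FASTA,
#' optional paired-end collapse), exact-barcode demultiplexing, LTR/LC
#' trimming, alignment against the reference plus vector dummy
#' chromosome, ambiguity classification, the final quality filter,
#' sliding-window locus merging, and (when a BED file is configured)
#' nearest-feature annotation -- per barcode, with a per-stage accounting
#' report.  The run is deterministic: no stage draws random numbers, so a
#' rerun with the same configuration is bit-identical.
#'
#' @param config A `lampis_config` list from [pipeline_config()], a plain
#'   named list with the same keys, or a YAML path.
#' @param outdir Optional output directory; when given, per-stage files
#'   are written (demultiplexed FASTA, trim audit TSV, classification
#'   TSV, redundant-IS TSV, loci TSV + BED, annotation TSV, `stats.json`,
#'   `report.txt`).
#' @return A `lampis_run` object: a list with `stats` (per-sample stage
#'   counts plus a `total` row), `classifications` (per-read `class` of
#'   `N`/`LV`/`A`/`U`), `r_set`, `loci`, `annotated` (all tibbles carrying
#'   the sample in a `label` column), and the `config`.  [tidy()],
#'   [glance()] and [autoplot()] methods are provided.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  if (!inherits(config, "lampis_config")) {
    config <- do.call(pipeline_config, config)
  }
  cfg <- config

  # --- input conversion -----------------------------------------------------
  reads <- load_input_reads(cfg)
  n_raw <- nrow(reads)

  # --- demultiplex ----------------------------------------------------------
  barcodes <- if (is.data.frame(cfg$barcodes)) {
    validate_barcodes(cfg$barcodes, tag_length = cfg$tag_length)
  } else {
    read_barcodes(cfg$barcodes, tag_length = cfg$tag_length)
  }
  demux <- demultiplex(reads, barcodes, trim_tag = !cfg$keep_tag,
                       tag_length = cfg$tag_length)

  ref <- as_reference_checked(cfg$reference, cfg$vector_name)
  features <- if (is.null(cfg$bed)) NULL else if (is.data.frame(cfg$bed)) {
    as_tibble(cfg$bed)
  } else {
    load_bed(cfg$bed)
  }

  # --- per-barcode stages ---------------------------------------------------
  stats <- list()
  cls_all <- list()
  r_all <- list()
  loci_all <- list()
  ann_all <- list()
  trim_all <- list()
  for (lab in barcodes$label) {
    sample_reads <- demux |>
      filter(!is.na(label), label == lab) |>
      select(id, seq)
    res <- run_sample(sample_reads, cfg, ref, features)
    stats[[lab]] <- res$stats |> mutate(label = lab, .before = 1)
    trim_all[[lab]] <- res$trim |> mutate(label = lab, .before = 1)
    # within the run object `label` is the sample; the read's N/LV/A/U
    # class moves to `class`
    cls_all[[lab]] <- res$classifications |>
      rename(class = label) |>
      mutate(label = lab, .before = 1)
    r_all[[lab]] <- res$r_set |> mutate(label = lab, .before = 1)
    loci_all[[lab]] <- res$loci |> mutate(label = lab, .before = 1)
    ann_all[[lab]] <- res$annotated |> mutate(label = lab, .before = 1)
  }

  stats <- purrr::list_rbind(stats)
  total <- stats |>
    summarise(across(-label, sum)) |>
    mutate(label = "total", .before = 1)
  n_unmatched <- sum(is.na(demux$label))
  stats <- bind_rows(stats, total) |>
    mutate(
      raw = if_else(label == "total", n_raw, NA_integer_),
      unmatched = if_else(label == "total", n_unmatched, NA_integer_),
      .before = 2
    )

  annotated <- purrr::list_rbind(ann_all)
  metadata <- load_metadata(cfg$metadata)
  if (!is.null(metadata) && nrow(annotated) > 0) {
    annotated <- join_metadata(annotated, metadata)
  }

  run <- structure(
    list(
      stats = stats,
      trim = purrr::list_rbind(trim_all),
      classifications = purrr::list_rbind(cls_all),
      r_set = purrr::list_rbind(r_all),
      loci = purrr::list_rbind(loci_all),
      annotated = annotated,
      metadata = metadata,
      config = cfg
    ),
    class = "lampis_run"
  )
  if (!is.null(outdir)) write_run(run, demux, outdir)
  run
}

# One sample through trim -> align -> classify -> quality -> merge -> annotate.
run_sample <- function(sample_reads, cfg, ref, features) {
  trim <- trim_reads(sample_reads, ltr = cfg$ltr, lc = cfg$lc,
                     min_length = cfg$min_length, homology = cfg$homology,
                     lc_homology = cfg$lc_homology)
  t_set <- trimmed_set(trim)
  hits <- align_reads(t_set, ref, chunks = cfg$chunks)
  kept <- prefilter_hits(hits, min_identity = cfg$min_identity,
                         max_start = cfg$max_start)
  cls <- classify_reads(kept, t_set, as_t = cfg$as_t, hs_t = cfg$hs_t,
                        vector_name = cfg$vector_name, lv_any = cfg$lv_any,
                        hs_inclusive = cfg$hs_inclusive)
  r_set <- quality_filter(cls, min_identity = cfg$min_identity,
                          min_hs = cfg$min_hs)
  loci <- merge_loci(r_set, window = cfg$window,
                     ignore_strand = cfg$ignore_strand)
  annotated <- if (is.null(features)) {
    tibble(
      chromosome = character(), position = integer(), strand = character(),
      read_count = integer(), feature_name = character(),
      feature_strand = character(), feature_start = integer(),
      feature_end = integer(), distance = integer(),
      tss_distance = integer(), relative_position = character(),
      integration_percentage = double()
    )
  } else {
    annotate_loci(loci |> select(-members), features)
  }
  n_u <- sum(cls$label == "U")
  stats <- tibble(
    barcode_matched = nrow(sample_reads),
    no_ltr = sum(trim$status == "no_ltr"),
    too_short = sum(trim$status == "too_short"),
    t = nrow(t_set),
    n = sum(cls$label == "N"),
    lv = sum(cls$label == "LV"),
    a = sum(cls$label == "A"),
    u = n_u,
    quality_discarded = n_u - nrow(r_set),
    r = nrow(r_set),
    l = nrow(loci)
  )
  list(stats = stats, trim = trim, classifications = cls, r_set = r_set,
       loci = loci, annotated = annotated)
}

load_input_reads <- function(cfg) {
  if (is.data.frame(cfg$reads)) {
    reads <- validate_reads(cfg$reads)
    if (!is.null(cfg$reads2)) {
      abort("Paired-end input requires file paths, not in-memory tables.")
    }
    return(reads)
  }
  is_fastq <- grepl("\\.(fastq|fq)$", cfg$reads, ignore.case = TRUE)
  if (!is.null(cfg$reads2)) {
    r1 <- if (is_fastq) fastq_to_fasta(cfg$reads) else read_fasta(cfg$reads)
    r2 <- if (is_fastq) fastq_to_fasta(cfg$reads2) else read_fasta(cfg$reads2)
    if (nrow(r1) != nrow(r2)) abort("Mate files differ in record count.")
    pairs <- tibble(id = r1$id, seq = r1$seq, mate = r2$seq)
    return(collapse_pairs(pairs, ltr = cfg$ltr, homology = cfg$homology) |>
             select(id, seq))
  }
  if (is_fastq) fastq_to_fasta(cfg$reads) else read_fasta(cfg$reads)
}

as_reference_checked <- function(reference, vector_name) {
  ref <- as_reference(reference)
  if (!vector_name %in% names(ref)) {
    abort(sprintf(
      "Reference lacks the vector dummy chromosome '%s'; append the vector genome to the reference.",
      vector_name
    ))
  }
  ref
}

load_metadata <- function(metadata) {
  if (is.null(metadata)) return(NULL)
  if (is.character(metadata) && length(metadata) == 1) {
    metadata <- readr::read_tsv(metadata, col_types = readr::cols(.default = "c"),
                                progress = FALSE)
  }
  metadata <- as_tibble(metadata)
  need <- c("label", "source", "cell_type", "time_point")
  if (!all(need %in% names(metadata))) {
    abort(sprintf("Metadata must have columns: %s", paste(need, collapse = ", ")))
  }
  metadata
}

#' Join annotated integration sites to sample metadata
#'
#' Adds the tissue source, cell type and time point of each sample to its
#' annotated IS rows, producing the long-format IS-by-sample table used
#' for clonal tracking.  Every label present in the IS table must appear
#' in the metadata; missing labels are an error naming them.
#'
#' @param annotated An annotated IS tibble carrying a `label` column.
#' @param metadata A tibble (or TSV path) with columns `label`, `source`,
#'   `cell_type`, `time_point`.
#' @return The annotated tibble with the metadata columns appended.
#' @export
join_metadata <- function(annotated, metadata) {
  metadata <- load_metadata(metadata)
  missing <- setdiff(unique(annotated$label), metadata$label)
  if (length(missing)) {
    abort(sprintf("Metadata missing for label(s): %s", paste(missing, collapse = ", ")))
  }
  annotated |>
    left_join(metadata, by = "label")
}

# Write all per-stage artefacts of a run.
write_run <- function(run, demux, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_demultiplexed(demux, file.path(outdir, "demux"))
  readr::write_tsv(run$trim, file.path(outdir, "trim_audit.tsv"))
  readr::write_tsv(run$classifications, file.path(outdir, "classifications.tsv"))
  readr::write_tsv(run$r_set, file.path(outdir, "redundant_is.tsv"))
  loci_flat <- run$loci |>
    mutate(offsets = purrr::map_chr(members, function(m) {
      paste(sprintf("%d:%d", m$position, m$count), collapse = ",")
    })) |>
    select(-members)
  readr::write_tsv(loci_flat, file.path(outdir, "loci.tsv"))
  if (nrow(run$loci) > 0) {
    loci_to_bed(run$loci, file.path(outdir, "loci.bed"))
  } else {
    writeLines(character(), file.path(outdir, "loci.bed"))
  }
  readr::write_tsv(run$annotated, file.path(outdir, "annotated_is.tsv"))
  jsonlite::write_json(
    list(stats = run$stats, thresholds = config_thresholds(run$config)),
    file.path(outdir, "stats.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  writeLines(format_report(run), file.path(outdir, "report.txt"))
  invisible(outdir)
}

# Result-affecting parameters only: execution details such as the chunk
# count never change the output and are kept out of the stats echo.
config_thresholds <- function(cfg) {
  cfg[c("min_length", "homology", "lc_homology", "min_identity", "max_start",
        "as_t", "hs_t", "min_hs", "window", "tag_length",
        "vector_name", "keep_tag", "ignore_strand", "hs_inclusive", "lv_any")]
}

format_report <- function(run) {
  s <- run$stats
  c(
    "Integration-site pipeline report",
    sprintf("Samples: %d", nrow(s) - 1),
    "",
    "Per-stage read accounting (columns: sample, matched, no_ltr, too_short, T, N, LV, A, U, qc_drop, R, loci):",
    sprintf(
      "  %-10s %8d %7d %9d %8d %7d %7d %7d %7d %8d %7d %6d",
      s$label, s$barcode_matched, s$no_ltr, s$too_short, s$t, s$n, s$lv,
      s$a, s$u, s$quality_discarded, s$r, s$l
    )
  )
}
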