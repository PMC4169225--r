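#' Generate a synthetic reference genome with a vector dummy chromosome
#'
#' Builds a random reference for desk-scale validation: `n_chrom`
#' chromosomes of i.i.d. bases, optional exact repeat blocks copied to
#' several locations (to create ambiguously mappable regions), and the
#' vector genome appended as an extra sequence under `vector_name` so that
#' vector-internal reads are caught at alignment time.  Deterministic
#' given `seed`.
#'
#' @param seed Integer seed for the generator.
#' @param n_chrom Number of host chromosomes (default 2), named `chr1`,
#'   `chr2`, ...
#' @param chrom_length Length of each chromosome in bases (default 10000;
#'   at least 1000).
#' @param repeat_spec Optional list describing exact repeats: each element
#'   a list with `length` (block size in bases) and `sites`, a list of
#'   `c(chrom_index, position)` destinations that all receive the same
#'   block.
#' @param vector_name Name of the vector dummy chromosome (default
#'   `"VECTOR"`).
#' @param vector_length Length of the vector sequence (default 1500).
#' @return A named character vector of sequences (host chromosomes then
#'   the vector), usable directly as a reference by [align_reads()].
#' @export
#' @examples
#' ref <- make_reference(seed = 1, n_chrom = 2, chrom_length = 1000)
#' names(ref)
make_reference <- function(seed, n_chrom = 2, chrom_length = 10000,
                           repeat_spec = NULL, vector_name = "VECTOR",
                           vector_length = 1500) {
  stopifnot(chrom_length >= 1000, n_chrom >= 1)
  withr::with_seed(seed, {
    chroms <- purrr::map_chr(seq_len(n_chrom), function(i) random_dna(chrom_length))
    names(chroms) <- paste0("chr", seq_len(n_chrom))
    for (rs in repeat_spec %||% list()) {
      block <- random_dna(rs$length)
      for (site in rs$sites) {
        ci <- site[1]
        pos <- site[2]
        stopifnot(ci <= n_chrom, pos + rs$length - 1 <= chrom_length)
        substring(chroms[ci], pos, pos + rs$length - 1) <- block
      }
    }
    vec <- random_dna(vector_length)
    c(chroms, setNames(vec, vector_name))
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate LAM-PCR reads from planted integration sites
#'
#' Emulates the structure of LAM-PCR sequencing products: each read is
#' `barcode + LTR + genomic fragment (+ linker cassette)`, where the
#' fragment starts at a planted IS position and runs in the planted
#' orientation (plus-strand fragments extend toward higher coordinates;
#' minus-strand fragments are the reverse complement of the sequence
#' ending at the planted position).  Fragment lengths are drawn uniformly
#' from `frag_range` (default 100-1000 bp, the size range of LAM-PCR
#' products) and truncated to the chromosome bounds; substitution errors
#' are applied to the whole read at `error_rate`.  Planting an IS on the
#' vector dummy chromosome yields vector-internal reads.  Deterministic
#' given `seed`.
#'
#' @param reference A named character vector or `DNAStringSet` from
#'   [make_reference()] (or any reference).
#' @param planted A data frame with columns `chromosome`, `position`,
#'   `strand`, `n_reads` -- the ground-truth IS table.
#' @param barcode Barcode tag prepended to every read (default none).
#' @param ltr LTR sequence included verbatim after the barcode.
#' @param lc Optional linker-cassette sequence; when given, `lc_prob` of
#'   reads carry it after the fragment.
#' @param lc_prob Fraction of reads carrying the LC (default 0.5).
#' @param error_rate Per-base substitution probability (default 0).
#' @param indel_rate Per-base indel probability (default 0).
#' @param frag_range Fragment length range (default `c(100, 1000)`).
#' @param seed Integer seed.
#' @param id_prefix Prefix for read identifiers.
#' @return A list with `reads` (tibble `id`, `seq`) and `truth` (tibble
#'   `id`, `chromosome`, `position`, `strand`, `frag_len`, `n_errors`,
#'   `has_lc`).
#' @export
make_reads <- function(reference, planted, barcode = "", ltr, lc = NULL,
                       lc_prob = 0.5, error_rate = 0, indel_rate = 0,
                       frag_range = c(100, 1000), seed = 1,
                       id_prefix = "read") {
  ref <- if (methods::is(reference, "DNAStringSet")) {
    setNames(as.character(reference), names(reference))
  } else {
    reference
  }
  planted <- as_tibble(planted)
  need <- c("chromosome", "position", "strand", "n_reads")
  if (!all(need %in% names(planted))) {
    abort("`planted` must have columns chromosome, position, strand, n_reads.")
  }
  if (!all(planted$chromosome %in% names(ref))) {
    abort("Planted chromosomes missing from the reference.")
  }
  stopifnot(all(planted$n_reads >= 1), length(frag_range) == 2,
            frag_range[1] >= 1, frag_range[2] >= frag_range[1])
  ltr <- toupper(ltr)
  withr::with_seed(seed, {
    rows <- list()
    counter <- 0L
    for (i in seq_len(nrow(planted))) {
      chrom <- ref[[planted$chromosome[i]]]
      clen <- nchar(chrom)
      pos <- planted$position[i]
      strand <- planted$strand[i]
      stopifnot(pos >= 1, pos <= clen, strand %in% c("+", "-"))
      for (j in seq_len(planted$n_reads[i])) {
        counter <- counter + 1L
        avail <- if (strand == "+") clen - pos + 1L else pos
        flen <- min(avail, sample(frag_range[1]:frag_range[2], 1))
        frag <- if (strand == "+") {
          substring(chrom, pos, pos + flen - 1L)
        } else {
          revcomp(substring(chrom, pos - flen + 1L, pos))
        }
        has_lc <- !is.null(lc) && stats::runif(1) < lc_prob
        read <- paste0(barcode, ltr, frag, if (has_lc) toupper(lc) else "")
        mutated <- mutate_seq(read, error_rate, indel_rate)
        rows[[counter]] <- tibble(
          id = sprintf("%s_%05d", id_prefix, counter),
          seq = mutated$seq,
          chromosome = planted$chromosome[i],
          position = as.integer(pos),
          strand = strand,
          frag_len = as.integer(flen),
          n_errors = mutated$n_errors,
          has_lc = has_lc
        )
      }
    }
    all <- purrr::list_rbind(rows)
    list(
      reads = all |> select(id, seq),
      truth = all |> select(-seq)
    )
  })
}

# Substitution (and optional indel) mutation of one sequence.
mutate_seq <- function(seq, error_rate, indel_rate) {
  if (error_rate <= 0 && indel_rate <= 0) {
    return(list(seq = seq, n_errors = 0L))
  }
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_err <- 0L
  if (error_rate > 0) {
    hit <- which(stats::runif(length(bases)) < error_rate)
    for (k in hit) {
      bases[k] <- sample(setdiff(c("A", "C", "G", "T"), bases[k]), 1)
    }
    n_err <- n_err + length(hit)
  }
  if (indel_rate > 0) {
    out <- character(0)
    for (b in bases) {
      r <- stats::runif(1)
      if (r < indel_rate / 2) {
        n_err <- n_err + 1L            # deletion: drop the base
      } else if (r < indel_rate) {
        out <- c(out, b, sample(c("A", "C", "G", "T"), 1))  # insertion
        n_err <- n_err + 1L
      } else {
        out <- c(out, b)
      }
    }
    bases <- out
  }
  list(seq = paste(bases, collapse = ""), n_errors = n_err)
}

#' Generate a complete synthetic dataset on disk
#'
#' Convenience wrapper producing everything a pipeline run needs:
#' reference FASTA (host chromosomes + vector), multiplexed reads FASTA,
#' barcode TSV, LTR/LC FASTA files, a gene-like BED annotation, a sample
#' metadata TSV, and the ground-truth IS table.  Reads for each sample are
#' generated from independently planted ISs; `n_vector_reads` additional
#' vector-internal reads are planted per sample.  Deterministic given
#' `seed`.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_samples Number of barcoded samples (default 2).
#' @param n_is Number of planted ISs per sample (default 5).
#' @param reads_per_is Reads supporting each IS (default 3).
#' @param n_vector_reads Vector-internal reads per sample (default 1).
#' @param n_chrom,chrom_length,repeat_spec,vector_name Passed to
#'   [make_reference()].
#' @param error_rate,frag_range Passed to [make_reads()].
#' @param n_features Number of BED features per chromosome (default 5).
#' @return A list with `files` (named list of the paths written), the
#'   ground-truth `truth` tibble (with a `label` column), and the
#'   in-memory `reference`, `barcodes`, `ltr`, `lc`, `features`,
#'   `metadata` and `vector_name` objects.
#' @export
simulate_dataset <- function(outdir, seed = 1, n_samples = 2, n_is = 5,
                             reads_per_is = 3, n_vector_reads = 1,
                             n_chrom = 2, chrom_length = 10000,
                             repeat_spec = NULL, vector_name = "VECTOR",
                             error_rate = 0, frag_range = c(100, 1000),
                             n_features = 5) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ref <- make_reference(seed, n_chrom = n_chrom, chrom_length = chrom_length,
                        repeat_spec = repeat_spec, vector_name = vector_name)
  host <- setdiff(names(ref), vector_name)

  withr::with_seed(seed + 1L, {
    ltr <- random_dna(63)
    lc <- random_dna(30)
    barcodes <- tibble(
      label = sprintf("sample%02d", seq_len(n_samples)),
      tag = replicate(n_samples, random_dna(6))
    )
    while (anyDuplicated(barcodes$tag)) {
      barcodes$tag[duplicated(barcodes$tag)] <- replicate(
        sum(duplicated(barcodes$tag)), random_dna(6)
      )
    }
    margin <- max(frag_range)
    planted <- purrr::map(seq_len(n_samples), function(s) {
      # Grid-spaced candidate positions keep planted sites well beyond the
      # merge window apart, so ground truth stays one-locus-per-IS.
      pos <- sample(seq(margin + 1L, chrom_length - margin, by = 10L), n_is)
      tibble(
        label = barcodes$label[s],
        chromosome = sample(host, n_is, replace = TRUE),
        position = as.integer(pos),
        strand = sample(c("+", "-"), n_is, replace = TRUE),
        n_reads = as.integer(reads_per_is)
      )
    }) |> purrr::list_rbind()
    features <- purrr::map(host, function(ch) {
      starts <- sort(sample(seq(0L, chrom_length - 600L, by = 200L), n_features))
      tibble(
        chromosome = ch, start = starts, end = starts + 500L,
        name = sprintf("GENE_%s_%d", ch, seq_len(n_features)),
        score = 0, strand = sample(c("+", "-"), n_features, replace = TRUE)
      )
    }) |> purrr::list_rbind()
  })

  truth_all <- list()
  reads_all <- list()
  for (s in seq_len(n_samples)) {
    lab <- barcodes$label[s]
    pl <- planted |> filter(label == lab) |> select(-label)
    if (n_vector_reads > 0) {
      vec_len <- nchar(ref[[vector_name]])
      pl <- bind_rows(pl, tibble(
        chromosome = vector_name,
        position = as.integer(vec_len %/% 2),
        strand = "+",
        n_reads = as.integer(n_vector_reads)
      ))
    }
    sim <- make_reads(ref, pl, barcode = barcodes$tag[s], ltr = ltr, lc = lc,
                      lc_prob = 0.5, error_rate = error_rate,
                      frag_range = frag_range, seed = seed + 100L + s,
                      id_prefix = lab)
    reads_all[[s]] <- sim$reads
    truth_all[[s]] <- sim$truth |> mutate(label = lab)
  }
  reads <- purrr::list_rbind(reads_all)
  truth <- purrr::list_rbind(truth_all)

  metadata <- tibble(
    label = barcodes$label,
    source = rep_len(c("peripheral_blood", "bone_marrow"), n_samples),
    cell_type = rep_len(c("CD34", "CD4", "CD19"), n_samples),
    time_point = rep_len(c("m01", "m06", "m12"), n_samples)
  )

  paths <- list(
    reference = file.path(outdir, "reference.fa"),
    reads = file.path(outdir, "reads.fa"),
    barcodes = file.path(outdir, "barcodes.tsv"),
    ltr = file.path(outdir, "ltr.fa"),
    lc = file.path(outdir, "lc.fa"),
    bed = file.path(outdir, "features.bed"),
    metadata = file.path(outdir, "metadata.tsv"),
    truth = file.path(outdir, "truth.tsv")
  )
  write_fasta(tibble(id = names(ref), seq = unname(ref)), paths$reference)
  write_fasta(reads, paths$reads)
  readr::write_tsv(barcodes, paths$barcodes, col_names = FALSE)
  write_fasta(tibble(id = "LTR", seq = ltr), paths$ltr)
  write_fasta(tibble(id = "LC", seq = lc), paths$lc)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s", features$chromosome,
                     features$start, features$end, features$name,
                     features$score, features$strand), paths$bed)
  readr::write_tsv(metadata, paths$metadata)
  readr::write_tsv(truth, paths$truth)

  list(files = paths, truth = truth, reference = ref, barcodes = barcodes,
       ltr = ltr, lc = lc, features = features, metadata = metadata,
       vector_name = vector_name)
}
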