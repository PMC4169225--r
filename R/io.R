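#' Read a FASTA file into a read table
#'
#' Wraps [Biostrings::readDNAStringSet()] and returns the tidy read
#' representation used throughout the package: one row per record with the
#' identifier (first whitespace-separated token of the header) and the
#' uppercase sequence.
#'
#' @param path Path to a (multi-record) FASTA file; wrapped or unwrapped
#'   lines are both accepted.
#' @return A tibble with columns `id` and `seq`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ACGT"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  tibble(
    id = sub("\\s.*$", "", names(set)),
    seq = toupper(as.character(set, use.names = FALSE))
  )
}

#' Write a read table to FASTA
#'
#' @param reads A data frame with columns `id` and `seq`.
#' @param path Output path.  Sequences are written unwrapped (one line per
#'   record).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  reads <- validate_reads(reads)
  width <- max(1L, suppressWarnings(max(nchar(reads$seq), na.rm = TRUE)))
  set <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(set, path, width = if (is.finite(width)) width else 80L)
  invisible(path)
}

#' Read a FASTQ file with per-record validation
#'
#' Parses four-line FASTQ records into a tibble.  Unlike generic readers,
#' malformed records are rejected with the 1-based index of the offending
#' record, which downstream tooling relies on for triage.
#'
#' @param path Path to a FASTQ file (uncompressed).
#' @return A tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) == 0) {
    return(tibble(id = character(), seq = character(), qual = character()))
  }
  if (length(lines) %% 4 != 0) {
    abort(sprintf(
      "Truncated FASTQ: %d lines is not a multiple of 4 (record %d incomplete).",
      length(lines), length(lines) %/% 4 + 1
    ))
  }
  n <- length(lines) %/% 4
  hdr <- lines[seq(1, length(lines), by = 4)]
  seq <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    abort(sprintf("Malformed FASTQ record %d: header does not start with '@'.", bad[1]))
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    abort(sprintf("Malformed FASTQ record %d: separator line does not start with '+'.", bad[1]))
  }
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    abort(sprintf(
      "Malformed FASTQ record %d: sequence length %d != quality length %d.",
      bad[1], nchar(seq[bad[1]]), nchar(qual[bad[1]])
    ))
  }
  tibble(
    id = sub("\\s.*$", "", sub("^@", "", hdr)),
    seq = toupper(seq),
    qual = qual
  )
}

#' Convert FASTQ records to the FASTA read representation
#'
#' Drops base qualities while preserving identifiers and bases, the first
#' step of the pipeline for Illumina input.  Accepts either a path to a
#' FASTQ file or an already-parsed record table; records are re-validated
#' so that a malformed record is reported with its index.
#'
#' @param records A FASTQ path or a data frame with columns `id`, `seq`,
#'   `qual`.
#' @param path Optional output path; when given, the converted reads are
#'   also written as unwrapped FASTA.
#' @return A tibble with columns `id` and `seq` (one row per input record).
#' @export
fastq_to_fasta <- function(records, path = NULL) {
  if (is.character(records) && length(records) == 1) {
    records <- read_fastq(records)
  }
  if (!is.data.frame(records) || !all(c("id", "seq") %in% names(records))) {
    abort("`records` must be a FASTQ path or a data frame with `id`, `seq`, `qual`.")
  }
  records <- as_tibble(records)
  if ("qual" %in% names(records) && nrow(records) > 0) {
    bad <- which(nchar(records$seq) != nchar(records$qual))
    if (length(bad)) {
      abort(sprintf(
        "Malformed FASTQ record %d: sequence length %d != quality length %d.",
        bad[1], nchar(records$seq[bad[1]]), nchar(records$qual[bad[1]])
      ))
    }
  }
  out <- validate_reads(records[c("id", "seq")])
  if (!is.null(path)) write_fasta(out, path)
  out
}

#' Read a barcode list
#'
#' Barcode files are two-column TSVs (sample label, tag sequence) without a
#' header.  The returned table is validated with [validate_barcodes()].
#'
#' @param path Path to the TSV file.
#' @param tag_length Expected tag length (default 6 nucleotides).
#' @return A tibble with columns `label` and `tag`.
#' @export
read_barcodes <- function(path, tag_length = 6) {
  tab <- readr::read_tsv(
    path, col_names = c("label", "tag"),
    col_types = readr::cols(label = "c", tag = "c"),
    progress = FALSE
  )
  tab$tag <- toupper(tab$tag)
  validate_barcodes(tab, tag_length = tag_length)
}
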