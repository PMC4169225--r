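#' Validate a barcode table
#'
#' Barcodes are short sample tags ligated during library re-amplification;
#' demultiplexing relies on exact prefix matching, so the tag set must be
#' unambiguous: all tags the expected length, pairwise distinct, and no tag
#' a prefix of another (with nested tags, exact prefix matching cannot
#' decide which sample a read belongs to).
#'
#' @param barcodes A data frame with columns `label` and `tag`.
#' @param tag_length Required tag length; `NA` disables the length check.
#'   Defaults to the conventional 6 nucleotides.
#' @return The validated tibble, invisibly usable downstream.
#' @export
validate_barcodes <- function(barcodes, tag_length = 6) {
  if (!is.data.frame(barcodes) || !all(c("label", "tag") %in% names(barcodes))) {
    abort("`barcodes` must be a data frame with columns `label` and `tag`.")
  }
  barcodes <- as_tibble(barcodes)
  barcodes$tag <- toupper(barcodes$tag)
  if (nrow(barcodes) == 0) return(barcodes)
  if (anyDuplicated(barcodes$label)) {
    abort("Barcode labels must be unique.")
  }
  if (!is.na(tag_length) && any(nchar(barcodes$tag) != tag_length)) {
    bad <- barcodes$label[nchar(barcodes$tag) != tag_length]
    abort(sprintf(
      "Barcode tag(s) not of length %d: %s", tag_length,
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  if (any(grepl("[^ACGT]", barcodes$tag))) {
    abort("Barcode tags may contain only A, C, G, T.")
  }
  if (anyDuplicated(barcodes$tag)) {
    abort(sprintf(
      "Duplicate barcode tag(s): %s",
      paste(unique(barcodes$tag[duplicated(barcodes$tag)]), collapse = ", ")
    ))
  }
  for (i in seq_len(nrow(barcodes))) {
    nested <- startsWith(barcodes$tag, barcodes$tag[i]) & seq_len(nrow(barcodes)) != i
    if (any(nested)) {
      abort(sprintf(
        "Barcode tag %s is a prefix of tag %s; nested tags are ambiguous under exact matching.",
        barcodes$tag[i], barcodes$tag[which(nested)[1]]
      ))
    }
  }
  barcodes
}

#' Demultiplex reads by exact barcode prefix
#'
#' Assigns each read to the sample whose barcode tag is an exact prefix of
#' the read sequence.  No mismatches are tolerated, so similar tags are
#' never confused; reads starting with no known tag are routed to the
#' discarded stream.  Every input read appears in exactly one output
#' stream (the partition property `sum of per-barcode counts + discarded
#' = input count` always holds).
#'
#' @param reads A data frame with columns `id` and `seq`.
#' @param barcodes A data frame with columns `label` and `tag`, or a path
#'   to a two-column TSV; validated with [validate_barcodes()] before any
#'   read is touched.
#' @param trim_tag Remove the matched tag from the front of assigned reads
#'   (default `TRUE`, so the LTR search starts at the read start); set to
#'   `FALSE` to keep reads verbatim.
#' @param tag_length Expected tag length for validation (default 6).
#' @return A tibble with columns `label` (the sample, or `NA` for
#'   discarded reads), `id`, and `seq`.
#' @export
#' @examples
#' reads <- tibble::tibble(id = c("r1", "r2"), seq = c("AACGTTGGGG", "TACGTTGGGG"))
#' barcodes <- tibble::tibble(label = "s1", tag = "AACGTT")
#' demultiplex(reads, barcodes)
demultiplex <- function(reads, barcodes, trim_tag = TRUE, tag_length = 6) {
  reads <- validate_reads(reads)
  if (is.character(barcodes) && length(barcodes) == 1) {
    barcodes <- read_barcodes(barcodes, tag_length = tag_length)
  } else {
    barcodes <- validate_barcodes(barcodes, tag_length = tag_length)
  }
  if (nrow(reads) == 0) {
    return(tibble(label = character(), id = character(), seq = character()))
  }
  label <- rep(NA_character_, nrow(reads))
  taglen <- rep(NA_integer_, nrow(reads))
  for (i in seq_len(nrow(barcodes))) {
    hit <- is.na(label) & startsWith(reads$seq, barcodes$tag[i])
    label[hit] <- barcodes$label[i]
    taglen[hit] <- nchar(barcodes$tag[i])
  }
  seq_out <- reads$seq
  if (trim_tag) {
    assigned <- !is.na(label)
    seq_out[assigned] <- substring(reads$seq[assigned], taglen[assigned] + 1)
  }
  tibble(label = label, id = reads$id, seq = seq_out)
}

#' Write demultiplexed reads to per-sample FASTA files
#'
#' @param demux Output of [demultiplex()].
#' @param outdir Output directory; one `<label>.fa` per sample plus
#'   `unmatched.fa` for discarded reads.
#' @return A named character vector of the files written, invisibly.
#' @export
write_demultiplexed <- function(demux, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  labels <- unique(demux$label[!is.na(demux$label)])
  paths <- character()
  for (lab in labels) {
    p <- file.path(outdir, paste0(lab, ".fa"))
    write_fasta(demux[!is.na(demux$label) & demux$label == lab, c("id", "seq")], p)
    paths[lab] <- p
  }
  un <- demux[is.na(demux$label), c("id", "seq")]
  p <- file.path(outdir, "unmatched.fa")
  if (nrow(un) > 0) write_fasta(un, p) else writeLines(character(), p)
  paths["unmatched"] <- p
  invisible(paths)
}
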