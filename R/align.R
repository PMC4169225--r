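#' Coerce a reference to a DNAStringSet
#'
#' @param reference A `Biostrings::DNAStringSet`, a named character vector
#'   of sequences, or a path to a FASTA file.
#' @return A `DNAStringSet` with unique, whitespace-trimmed names.
#' @export
as_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    set <- reference
  } else if (is.character(reference) && length(reference) == 1 &&
             file.exists(reference)) {
    set <- Biostrings::readDNAStringSet(reference)
  } else if (is.character(reference) && !is.null(names(reference))) {
    set <- Biostrings::DNAStringSet(reference)
  } else {
    abort("`reference` must be a DNAStringSet, a named character vector, or a FASTA path.")
  }
  if (length(set) == 0) abort("Reference contains no sequences.")
  names(set) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(set))) abort("Reference sequence names must be unique.")
  set
}

#' Align trimmed reads against a reference with the internal local aligner
#'
#' Maps each trimmed genomic fragment against every reference sequence
#' (including the vector "dummy chromosome", which must be part of the
#' reference so vector-internal reads are caught at alignment time) and
#' reports all candidate hits in an engine-agnostic tabular form.  The
#' engine is seed-and-extend: exact k-mer seeds from the start, middle and
#' end of the read nominate candidate diagonals on both strands, and each
#' candidate window is realigned with a Smith-Waterman local alignment.
#' It is intended for desk-scale references (tens of kilobases); hits from
#' an external aligner's 12-column tabular output can be substituted via
#' [read_hits_tsv()].
#'
#' Reads are processed in `chunks` independent batches and the results
#' concatenated in input order, so the output is identical for any chunk
#' count -- the contract that makes the stage trivially parallelisable.
#'
#' @param reads A data frame with columns `id` and `seq` (the trimmed set).
#' @param reference Reference accepted by [as_reference()]; append the
#'   vector genome as an extra sequence to enable vector-read detection.
#' @param chunks Number of independent batches (default 1).
#' @param seed_length Exact seed length for candidate discovery (default 12).
#' @param pad Window padding around each candidate locus in bases.
#' @param match,mismatch,gap_opening,gap_extension Alignment scoring.
#' @return A tibble of hits with columns `read_id`, `subject`, `identity`
#'   (percent, gap-inclusive), `length` (alignment columns), `score`
#'   (alignment score), `qs`, `qe` (1-based query coordinates on the
#'   original read), `ss`, `se` (1-based subject coordinates, `ss <= se`),
#'   and `strand` (`"+"` or `"-"`).
#' @export
align_reads <- function(reads, reference, chunks = 1, seed_length = 12,
                        pad = 12, match = 1, mismatch = -1, gap_opening = 2,
                        gap_extension = 1) {
  reads <- validate_reads(reads)
  ref <- as_reference(reference)
  empty <- tibble(
    read_id = character(), subject = character(), identity = double(),
    length = integer(), score = double(), qs = integer(), qe = integer(),
    ss = integer(), se = integer(), strand = character()
  )
  if (nrow(reads) == 0) return(empty)
  chunks <- max(1L, as.integer(chunks))
  idx <- split(seq_len(nrow(reads)), ceiling(seq_len(nrow(reads)) / ceiling(nrow(reads) / chunks)))
  parts <- purrr::map(idx, function(ii) {
    purrr::map(ii, function(i) {
      align_one(reads$id[i], reads$seq[i], ref, seed_length, pad,
                match, mismatch, gap_opening, gap_extension)
    }) |> purrr::list_rbind()
  })
  out <- purrr::list_rbind(parts)
  if (nrow(out) == 0) empty else out
}

align_one <- function(id, seq, ref, seed_length, pad, match, mismatch,
                      gap_opening, gap_extension) {
  L <- nchar(seq)
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") seq else revcomp(seq)
    k <- min(seed_length, L)
    seed_starts <- unique(pmax(1L, c(1L, (L - k) %/% 2L + 1L, L - k + 1L)))
    for (ci in seq_along(ref)) {
      chrom <- ref[[ci]]
      clen <- length(chrom)
      cand <- integer()
      for (sp in seed_starts) {
        seed <- substring(q, sp, sp + k - 1)
        if (grepl("N", seed, fixed = TRUE)) next
        m <- Biostrings::matchPattern(seed, chrom)
        if (length(m) > 0) cand <- c(cand, Biostrings::start(m) - sp + 1L)
      }
      if (length(cand) == 0) next
      cand <- sort(unique(cand))
      # Collapse candidates on nearby diagonals (indel jitter) into one window.
      keep <- c(TRUE, diff(cand) > pad %/% 2)
      cand <- cand[keep]
      for (cc in cand) {
        ws <- max(1L, cc - pad)
        we <- min(clen, cc + L - 1L + pad)
        window <- as.character(Biostrings::subseq(chrom, ws, we))
        aln <- local_align(q, window, match, mismatch, gap_opening, gap_extension)
        ss <- ws + aln$subject_start - 1L
        se <- ws + aln$subject_end - 1L
        if (strand == "+") {
          qs <- aln$pattern_start
          qe <- aln$pattern_end
        } else {
          qs <- L - aln$pattern_end + 1L
          qe <- L - aln$pattern_start + 1L
        }
        hits[[length(hits) + 1]] <- tibble(
          read_id = id, subject = names(ref)[ci],
          identity = 100 * aln$n_match / aln$aln_length,
          length = as.integer(aln$aln_length),
          score = aln$score,
          qs = as.integer(qs), qe = as.integer(qe),
          ss = as.integer(ss), se = as.integer(se),
          strand = strand
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble(
      read_id = character(), subject = character(), identity = double(),
      length = integer(), score = double(), qs = integer(), qe = integer(),
      ss = integer(), se = integer(), strand = character()
    ))
  }
  purrr::list_rbind(hits) |>
    group_by(subject, strand, ss, se) |>
    slice_max(score, n = 1, with_ties = FALSE) |>
    ungroup() |>
    arrange(subject, ss, strand)
}

#' Import alignment hits from 12-column tabular output
#'
#' Reads the conventional tab-separated hit format produced by BLAST-style
#' engines (`qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore`) and normalises it to the hit table used by
#' the classifier: subject coordinates are reordered so `ss <= se`, with
#' the original orientation recorded in `strand`, and the bitscore column
#' is used as the alignment score.
#'
#' @param path Path to the tabular file (no header).
#' @return A hit tibble as documented in [align_reads()].
#' @export
read_hits_tsv <- function(path) {
  cols <- c("read_id", "subject", "identity", "length", "mismatch", "gapopen",
            "qs", "qe", "sstart", "send", "evalue", "score")
  tab <- readr::read_tsv(path, col_names = cols,
                         col_types = "ccdiiiiiiidd", progress = FALSE)
  tab |>
    mutate(
      strand = if_else(.data$sstart <= .data$send, "+", "-"),
      ss = pmin(.data$sstart, .data$send),
      se = pmax(.data$sstart, .data$send)
    ) |>
    select(read_id, subject, identity, length, score, qs, qe, ss, se, strand)
}
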