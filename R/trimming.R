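#' Locate the LTR tail in a read
#'
#' Searches a read for the terminal portion of the vector's long terminal
#' repeat (LTR).  The query is the last `tail_length` nucleotides of the
#' configured LTR (63 by default); a candidate local alignment is accepted
#' only when
#'
#' * the alignment homology -- identities divided by the tail length, as a
#'   percentage -- is at least `homology` (89% by default, i.e. at least
#'   `ceiling(0.89 * 63) = 57` of 63 bases identical), and
#' * the final 3 bases of the tail are aligned without gaps and match the
#'   read exactly.  This perfect-end rule pins down the LTR/genome junction,
#'   which is the integration site itself.
#'
#' @param seq A single read sequence (character scalar).
#' @param ltr The vector LTR sequence; only its last `tail_length` bases are
#'   searched for.  LTRs shorter than `tail_length` are used whole, with a
#'   warning, and the homology denominator scales accordingly.
#' @param homology Minimum percent homology (identities / tail length).
#' @param tail_length Length of the LTR tail used as the query (default 63).
#' @param perfect_end Number of terminal tail bases required to match
#'   exactly with no gaps (default 3).
#' @param match,mismatch,gap_opening,gap_extension Local-alignment scoring
#'   parameters.
#' @return A list with elements `ltr_end` (1-based position in the read
#'   where the LTR ends), `score`, `n_match`, and `homology`, or `NULL`
#'   when no acceptable match exists.
#' @export
find_ltr <- function(seq, ltr, homology = 89, tail_length = 63,
                     perfect_end = 3, match = 1, mismatch = -1,
                     gap_opening = 2, gap_extension = 1) {
  stopifnot(is.character(seq), length(seq) == 1, is.character(ltr), length(ltr) == 1)
  seq <- toupper(seq)
  ltr <- toupper(ltr)
  if (nchar(ltr) < tail_length) {
    warn(sprintf(
      "LTR is %d nt, shorter than the %d-nt tail; using the whole LTR (homology threshold scales).",
      nchar(ltr), tail_length
    ))
    tail_seq <- ltr
  } else {
    tail_seq <- substring(ltr, nchar(ltr) - tail_length + 1, nchar(ltr))
  }
  tlen <- nchar(tail_seq)
  if (nchar(seq) < perfect_end) return(NULL)

  aln <- local_align(tail_seq, seq, match, mismatch, gap_opening, gap_extension)
  hom <- 100 * aln$n_match / tlen
  if (hom < homology) return(NULL)
  # Perfect-end rule: the alignment must reach the last tail base, and the
  # trailing `perfect_end` columns must be gap-free identities.
  if (aln$pattern_end != tlen) return(NULL)
  if (aln$aln_length < perfect_end) return(NULL)
  p_tail <- substring(aln$aligned_pattern, aln$aln_length - perfect_end + 1, aln$aln_length)
  s_tail <- substring(aln$aligned_subject, aln$aln_length - perfect_end + 1, aln$aln_length)
  if (grepl("-", p_tail, fixed = TRUE) || grepl("-", s_tail, fixed = TRUE)) return(NULL)
  if (p_tail != s_tail) return(NULL)

  list(
    ltr_end = aln$subject_end,
    score = aln$score,
    n_match = aln$n_match,
    homology = hom
  )
}

# Locate the linker cassette inside a genomic fragment: same local-alignment
# machinery, homology over the full LC length, no perfect-end requirement.
# Returns the 1-based start of the LC within the fragment, or NA.
find_lc <- function(fragment, lc, lc_homology = 89, match = 1, mismatch = -1,
                    gap_opening = 2, gap_extension = 1) {
  if (is.na(fragment) || !nzchar(fragment) || is.null(lc) || !nzchar(lc)) {
    return(NA_integer_)
  }
  aln <- local_align(toupper(lc), toupper(fragment), match, mismatch,
                     gap_opening, gap_extension)
  if (100 * aln$n_match / nchar(lc) < lc_homology) return(NA_integer_)
  aln$subject_start
}

#' Trim LTR and linker-cassette sequences from reads
#'
#' The central trimming stage: each read is searched for the LTR tail with
#' [find_ltr()]; reads without a valid LTR are discarded (`status =
#' "no_ltr"`).  The LTR and everything before it are removed, the remainder
#' is searched for the linker cassette (LC) -- which, when present, is cut
#' away together with everything after it, though its absence never
#' discards a read -- and fragments shorter than `min_length` are dropped
#' (`status = "too_short"`).  Surviving reads form the trimmed set used for
#' alignment.
#'
#' @param reads A data frame with columns `id` and `seq`.
#' @param ltr Vector LTR sequence (character scalar or single-record FASTA
#'   path).
#' @param lc Optional linker-cassette sequence (character scalar, FASTA
#'   path, or `NULL` to skip LC trimming).
#' @param min_length Minimum genomic-fragment length kept (default 20 bp).
#' @param homology Minimum LTR homology percentage (default 89).
#' @param lc_homology Minimum LC homology percentage (default 89).
#' @param tail_length,perfect_end,match,mismatch,gap_opening,gap_extension
#'   Passed to [find_ltr()].
#' @return A tibble with one row per input read: `read_id`, `status`
#'   (`"trimmed"`, `"no_ltr"` or `"too_short"`), `genomic_seq` (`NA` unless
#'   trimmed), `ltr_end` (`NA` when the LTR was not found), `lc_found`, and
#'   `trimmed_length`.
#' @export
#' @examples
#' ltr <- strrep("ACGT", 16)  # 64 nt toy LTR
#' reads <- tibble::tibble(
#'   id = "r1",
#'   seq = paste0(ltr, strrep("TTGCA", 8))
#' )
#' trim_reads(reads, ltr = ltr)
trim_reads <- function(reads, ltr, lc = NULL, min_length = 20, homology = 89,
                       lc_homology = 89, tail_length = 63, perfect_end = 3,
                       match = 1, mismatch = -1, gap_opening = 2,
                       gap_extension = 1) {
  reads <- validate_reads(reads)
  ltr <- resolve_sequence(ltr, "ltr")
  lc <- if (is.null(lc)) NULL else resolve_sequence(lc, "lc")

  if (nrow(reads) == 0) {
    return(tibble(
      read_id = character(), status = character(), genomic_seq = character(),
      ltr_end = integer(), lc_found = logical(), trimmed_length = integer()
    ))
  }

  rows <- purrr::map(seq_len(nrow(reads)), function(i) {
    s <- reads$seq[i]
    m <- find_ltr(s, ltr, homology = homology, tail_length = tail_length,
                  perfect_end = perfect_end, match = match, mismatch = mismatch,
                  gap_opening = gap_opening, gap_extension = gap_extension)
    if (is.null(m)) {
      return(list(status = "no_ltr", genomic_seq = NA_character_,
                  ltr_end = NA_integer_, lc_found = FALSE))
    }
    frag <- substring(s, m$ltr_end + 1)
    lc_found <- FALSE
    if (!is.null(lc) && nzchar(frag)) {
      lc_start <- find_lc(frag, lc, lc_homology = lc_homology, match = match,
                          mismatch = mismatch, gap_opening = gap_opening,
                          gap_extension = gap_extension)
      if (!is.na(lc_start)) {
        frag <- substring(frag, 1, lc_start - 1)
        lc_found <- TRUE
      }
    }
    status <- if (nchar(frag) < min_length) "too_short" else "trimmed"
    list(
      status = status,
      genomic_seq = if (status == "trimmed") frag else NA_character_,
      ltr_end = as.integer(m$ltr_end),
      lc_found = lc_found
    )
  })

  tibble(
    read_id = reads$id,
    status = purrr::map_chr(rows, "status"),
    genomic_seq = purrr::map_chr(rows, "genomic_seq"),
    ltr_end = purrr::map_int(rows, "ltr_end"),
    lc_found = purrr::map_lgl(rows, "lc_found"),
    trimmed_length = ifelse(is.na(purrr::map_chr(rows, "genomic_seq")), NA_integer_,
                            nchar(purrr::map_chr(rows, "genomic_seq")))
  )
}

#' Extract the trimmed read set
#'
#' Convenience accessor returning the trimmed genomic fragments (the reads
#' that survive LTR recognition and the length filter) as a read table
#' ready for alignment.
#'
#' @param trim A trim table from [trim_reads()].
#' @return A tibble with columns `id` and `seq`.
#' @export
trimmed_set <- function(trim) {
  trim |>
    filter(status == "trimmed") |>
    transmute(id = read_id, seq = genomic_seq)
}

# Accept a literal sequence or a path to a single-record FASTA.
resolve_sequence <- function(x, arg) {
  if (!is.character(x) || length(x) != 1 || !nzchar(x)) {
    abort(sprintf("`%s` must be a single nucleotide sequence or FASTA path.", arg))
  }
  if (file.exists(x) && !grepl("^[ACGTUNRYSWKMBDHVacgtunryswkmbdhv]+$", x)) {
    set <- read_fasta(x)
    if (nrow(set) < 1) abort(sprintf("FASTA file for `%s` is empty.", arg))
    return(set$seq[1])
  }
  toupper(x)
}
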