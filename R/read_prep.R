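#' Collapse paired-end reads to single-strand reads
#'
#' LAM-PCR libraries sequenced paired-end yield two mates per fragment; the
#' pipeline operates on single-strand reads anchored at the LTR.  For each
#' pair the LTR-containing mate is identified (using the same LTR detection
#' as the trimming stage, so there is one definition of "contains the LTR"
#' in the package); when the mates overlap, the pair is merged into one
#' read oriented LTR-first, otherwise only the LTR-containing mate is kept.
#' Pairs where neither mate contains the LTR are dropped.
#'
#' Overlap detection takes the longest suffix/prefix overlap of at least
#' `min_overlap` bases with at least `min_overlap_identity` percent
#' identity between the LTR mate and the reverse complement of the other
#' mate; within the overlap, disagreeing bases are taken from the LTR mate,
#' which anchors the integration site.
#'
#' @param pairs A data frame with columns `id`, `seq` (mate 1) and `mate`
#'   (mate 2).
#' @param ltr Vector LTR sequence (character scalar or FASTA path).
#' @param min_overlap Minimum overlap length in bases (default 15).
#' @param min_overlap_identity Minimum percent identity within the overlap
#'   (default 95).
#' @param homology,tail_length LTR-detection parameters, as in [find_ltr()].
#' @return A tibble with columns `id`, `seq` and `merged` (logical); at
#'   most one row per input pair.
#' @export
collapse_pairs <- function(pairs, ltr, min_overlap = 15,
                           min_overlap_identity = 95, homology = 89,
                           tail_length = 63) {
  if (!is.data.frame(pairs) || !all(c("id", "seq", "mate") %in% names(pairs))) {
    abort("`pairs` must be a data frame with columns `id`, `seq`, `mate`.")
  }
  ltr <- resolve_sequence(ltr, "ltr")
  pairs <- as_tibble(pairs)
  out <- purrr::map(seq_len(nrow(pairs)), function(i) {
    collapse_one(toupper(pairs$seq[i]), toupper(pairs$mate[i]), ltr,
                 min_overlap, min_overlap_identity, homology, tail_length)
  })
  keep <- !purrr::map_lgl(out, is.null)
  tibble(
    id = pairs$id[keep],
    seq = purrr::map_chr(out[keep], "seq"),
    merged = purrr::map_lgl(out[keep], "merged")
  )
}

collapse_one <- function(m1, m2, ltr, min_overlap, min_overlap_identity,
                         homology, tail_length) {
  if (!nzchar(m1) || !nzchar(m2)) abort("Both mates must be non-empty.")
  has1 <- !is.null(find_ltr(m1, ltr, homology = homology, tail_length = tail_length))
  has2 <- !is.null(find_ltr(m2, ltr, homology = homology, tail_length = tail_length))
  if (!has1 && !has2) return(NULL)
  # Orient so `a` is the LTR-containing (forward) mate and `b` the opposite
  # end of the fragment, read inward from the other side.
  if (has1) {
    a <- m1
    b <- m2
  } else {
    a <- m2
    b <- m1
  }
  rb <- revcomp(b)
  o <- best_overlap(a, rb, min_overlap, min_overlap_identity)
  if (is.na(o)) {
    return(list(seq = a, merged = FALSE))
  }
  # Merge: `a` wins inside the overlap; append the non-overlapping tail of rb.
  list(seq = paste0(a, substring(rb, o + 1)), merged = TRUE)
}

# Longest suffix(a)/prefix(b) overlap of length >= min_len with percent
# identity >= min_identity; returns the overlap length or NA.
best_overlap <- function(a, b, min_len, min_identity) {
  la <- nchar(a)
  lb <- nchar(b)
  if (min(la, lb) < min_len) return(NA_integer_)
  for (o in seq(min(la, lb), min_len, by = -1)) {
    sa <- charToRaw(substring(a, la - o + 1, la))
    sb <- charToRaw(substring(b, 1, o))
    if (100 * sum(sa == sb) / o >= min_identity) return(o)
  }
  NA_integer_
}
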