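#' Prefilter alignment hits
#'
#' Removes mapping-error-prone hits before ambiguity classification: hits
#' with percent identity below `min_identity` (95 by default) and hits
#' whose alignment starts beyond base `max_start` of the query (3 by
#' default; the site of the LTR junction can oscillate by about +/- 3
#' bases, so informative alignments begin at the very start of the
#' fragment).
#'
#' @param hits A hit tibble (see [align_reads()]).
#' @param min_identity Minimum percent identity kept (inclusive).
#' @param max_start Maximum allowed query start position (inclusive).
#' @return The filtered hit tibble.
#' @export
prefilter_hits <- function(hits, min_identity = 95, max_start = 3) {
  hits |> filter(identity >= min_identity, qs <= max_start)
}

#' Homology score of a hit
#'
#' The homology score `hs` is the percentage of the read covered by the
#' alignment, `100 * |qs - qe| / read_length`.  The numerator is the
#' literal coordinate difference, one less than the aligned span;
#' `inclusive = TRUE` switches to the span-length variant
#' `100 * (|qs - qe| + 1) / read_length`.
#'
#' @param qs,qe 1-based query start/end coordinates (vectorised).
#' @param read_length Length of the read each hit belongs to (vectorised).
#' @param inclusive Use the span-length (+1) variant (default `FALSE`).
#' @return Numeric vector of homology scores (percent).
#' @export
#' @examples
#' homology_score(1, 81, 100)  # 80
homology_score <- function(qs, qe, read_length, inclusive = FALSE) {
  stopifnot(all(read_length >= 1))
  100 * (abs(qs - qe) + as.integer(inclusive)) / read_length
}

#' Classify reads by alignment ambiguity
#'
#' Assigns each trimmed read one of four disjoint labels from its
#' (prefiltered) hits:
#'
#' * `N` -- no hit survives the prefilter (unmapped);
#' * `LV` -- the read hits the vector dummy chromosome (vector-internal
#'   sequence, removed from IS calling);
#' * `U` -- unambiguously mapped: a single hit, or a best hit whose
#'   alignment score exceeds the second best by more than `as_t` *and*
#'   whose homology score exceeds it by more than `hs_t`;
#' * `A` -- ambiguously mapped (typically repeats): everything else.
#'
#' Hits are sorted by decreasing alignment score with deterministic
#' tie-breaking on (subject, ss); an exact score tie therefore always
#' yields `A`, the correct outcome for perfect repeats.  The result is
#' invariant under permutation of the hit table.
#'
#' @param hits A hit tibble, already passed through [prefilter_hits()].
#' @param reads The trimmed read set (`id`, `seq`): every read appears in
#'   the output even when it has no hits.
#' @param as_t Alignment-score gap threshold (default 15).
#' @param hs_t Homology-score gap threshold in percent (default 20).
#' @param vector_name Name of the vector dummy chromosome (default
#'   `"VECTOR"`).
#' @param lv_any When `TRUE` (default) any vector hit labels the read
#'   `LV`; when `FALSE` only reads whose *best* hit is on the vector are
#'   labelled `LV`.
#' @param hs_inclusive Passed to [homology_score()].
#' @return A tibble with one row per read: `read_id`, `label` (`N`, `LV`,
#'   `A` or `U`), best-hit columns (`subject`, `identity`, `score`, `qs`,
#'   `qe`, `ss`, `se`, `strand`; `NA` for `N`), `hs` (homology score of
#'   the best hit) and `n_hits`.
#' @export
classify_reads <- function(hits, reads, as_t = 15, hs_t = 20,
                           vector_name = "VECTOR", lv_any = TRUE,
                           hs_inclusive = FALSE) {
  reads <- validate_reads(reads)
  read_len <- setNames(nchar(reads$seq), reads$id)
  if (nrow(hits) > 0 && !all(hits$read_id %in% reads$id)) {
    abort("`hits` contains read_ids absent from `reads`.")
  }

  base <- tibble(
    read_id = reads$id, label = "N",
    subject = NA_character_, identity = NA_real_, score = NA_real_,
    qs = NA_integer_, qe = NA_integer_, ss = NA_integer_, se = NA_integer_,
    strand = NA_character_, hs = NA_real_, n_hits = 0L
  )
  if (nrow(hits) == 0) return(base)

  scored <- hits |>
    mutate(hs = homology_score(qs, qe, read_len[read_id], inclusive = hs_inclusive)) |>
    arrange(read_id, desc(score), subject, ss)

  cls <- scored |>
    group_by(read_id) |>
    summarise(
      label = classify_label(score, hs, subject, vector_name, as_t, hs_t, lv_any),
      subject = subject[1], identity = identity[1], score = score[1],
      qs = qs[1], qe = qe[1], ss = ss[1], se = se[1], strand = strand[1],
      hs = hs[1], n_hits = n(), .groups = "drop"
    )

  base |>
    rows_update(cls, by = "read_id") |>
    arrange(match(read_id, reads$id))
}

# Decision rule for one read's sorted hits (decreasing score).
classify_label <- function(score, hs, subject, vector_name, as_t, hs_t, lv_any) {
  n <- length(score)
  if (lv_any && any(subject == vector_name)) return("LV")
  if (!lv_any && subject[1] == vector_name) return("LV")
  if (n == 1) return("U")
  if (abs(score[2] - score[1]) > as_t && abs(hs[2] - hs[1]) > hs_t) "U" else "A"
}

#' Apply the final alignment quality filter and derive IS coordinates
#'
#' Unambiguously mapped reads (`U`) are kept as redundant integration
#' sites only when the best hit's identity is at least `min_identity` and
#' its homology score at least `min_hs`; either failure discards the read.
#' For survivors the IS coordinate is the genome position abutting the LTR
#' junction, via [is_position()].
#'
#' @param classified Output of [classify_reads()].
#' @param min_identity Minimum best-hit percent identity (default 95).
#' @param min_hs Minimum homology score in percent (default 80).
#' @return The redundant-IS tibble (the quality-passed read set):
#'   `read_id`, `chromosome`, `position`, `strand`, `identity`, `hs`.
#' @export
quality_filter <- function(classified, min_identity = 95, min_hs = 80) {
  classified |>
    filter(label == "U", identity >= min_identity, hs >= min_hs) |>
    is_position() |>
    select(read_id, chromosome, position, strand, identity, hs)
}

#' Integration-site coordinate of a best hit
#'
#' The IS is the first host base flanking the LTR: the subject start for
#' plus-strand alignments and the subject end for minus-strand alignments
#' (reads on the minus strand run away from the junction toward lower
#' coordinates, so the junction base is the alignment's right edge).
#'
#' @param hits A tibble with columns `subject`, `ss`, `se`, `strand` (for
#'   example classified reads or a hit table).
#' @return The input with `chromosome` and `position` columns added.
#' @export
is_position <- function(hits) {
  hits |>
    mutate(
      chromosome = subject,
      position = if_else(strand == "+", ss, se)
    )
}
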