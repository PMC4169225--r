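#' Load genomic features from a BED file
#'
#' Parses BED lines into a feature table, using the first six columns
#' (chrom, start, end, name, score, strand) and preserving the BED
#' convention of 0-based half-open intervals.  `track`, `browser` and `#`
#' comment lines are skipped; any malformed line -- too few columns,
#' non-integer coordinates, `start >= end`, or a strand other than `+`/`-`
#' -- is rejected with its line number.
#'
#' @param path Path to the BED file.
#' @return A tibble with columns `chromosome`, `start`, `end`, `name`,
#'   `score`, `strand` (start/end 0-based half-open).
#' @export
load_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(track|browser|#)", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  empty <- tibble(
    chromosome = character(), start = integer(), end = integer(),
    name = character(), score = double(), strand = character()
  )
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 6)) {
    abort(sprintf(
      "BED line %d: expected at least 6 tab-separated fields, found %d.",
      lineno[which(nfield < 6)[1]], nfield[which(nfield < 6)[1]]
    ))
  }
  get <- function(k) purrr::map_chr(fields, k)
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    abort(sprintf("BED line %d: non-integer start/end coordinates.", lineno[bad[1]]))
  }
  bad <- which(start >= end)
  if (length(bad)) {
    abort(sprintf(
      "BED line %d: start (%d) must be less than end (%d).",
      lineno[bad[1]], start[bad[1]], end[bad[1]]
    ))
  }
  strand <- get(6)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    abort(sprintf("BED line %d: strand must be '+' or '-', found '%s'.",
                  lineno[bad[1]], strand[bad[1]]))
  }
  tibble(
    chromosome = get(1), start = start, end = end, name = get(4),
    score = suppressWarnings(as.numeric(get(5))), strand = strand
  )
}

#' Closest feature(s) for each locus
#'
#' Finds, for every locus, all features on the same chromosome at minimal
#' distance.  Distance is measured to the feature body: 0 when the IS
#' coordinate lies inside the interval, otherwise the smaller of the
#' distances to the first and last covered base.  Ties are retained --
#' an IS exactly between two features reports both.  Loci on chromosomes
#' with no features yield no rows.
#'
#' @param loci A locus tibble (columns `chromosome`, `position`, `strand`;
#'   positions 1-based as produced by the pipeline).
#' @param features A feature tibble from [load_bed()] (0-based half-open).
#' @return The loci joined to their closest features, with a `distance`
#'   column (bases; 0 = inside).
#' @export
closest_features <- function(loci, features) {
  loci <- as_tibble(loci)
  features <- as_tibble(features) |>
    rename(feature_name = name, feature_strand = strand,
           feature_start = start, feature_end = end) |>
    select(chromosome, feature_name, feature_strand, feature_start, feature_end)
  joined <- loci |>
    mutate(.locus = dplyr::row_number()) |>
    inner_join(features, by = "chromosome", relationship = "many-to-many")
  if (nrow(joined) == 0) {
    return(joined |> mutate(distance = integer()) |> select(-".locus"))
  }
  joined |>
    mutate(
      pos0 = position - 1L,
      distance = if_else(
        pos0 >= feature_start & pos0 < feature_end,
        0L,
        pmin(abs(pos0 - feature_start), abs(pos0 - (feature_end - 1L)))
      )
    ) |>
    group_by(.data$.locus) |>
    filter(distance == min(distance)) |>
    ungroup() |>
    select(-".locus", -"pos0")
}

#' Annotate loci with their closest features
#'
#' Joins each locus to its closest feature(s) and derives the annotation
#' fields:
#'
#' * `tss_distance` -- signed distance in bases from the feature's
#'   transcription start site (TSS: the start of plus-strand features, the
#'   last covered base of minus-strand features), positive downstream in
#'   the feature's reading direction;
#' * `relative_position` -- `"in-gene"` when the IS coordinate lies inside
#'   the feature interval, otherwise `"upstream"`/`"downstream"` of the
#'   TSS in transcriptional orientation;
#' * `integration_percentage` -- for in-gene sites, how far along the
#'   feature the IS lies: 0% at the TSS, 100% at the opposite end
#'   (denominator `length - 1`, so both endpoints map exactly).
#'
#' @param loci A locus tibble from [merge_loci()] (or any table with
#'   `chromosome`, `position`, `strand`).
#' @param features A feature tibble from [load_bed()], or a BED path.
#' @return One row per (locus, closest feature) pair: the locus columns
#'   plus `feature_name`, `feature_strand`, `feature_start`,
#'   `feature_end`, `distance`, `tss_distance`, `relative_position`,
#'   `integration_percentage`.
#' @export
annotate_loci <- function(loci, features) {
  if (is.character(features) && length(features) == 1) {
    features <- load_bed(features)
  }
  closest_features(loci, features) |>
    mutate(
      pos0 = position - 1L,
      tss = if_else(feature_strand == "+", feature_start, feature_end - 1L),
      tss_distance = if_else(feature_strand == "+", pos0 - tss, tss - pos0),
      inside = pos0 >= feature_start & pos0 < feature_end,
      relative_position = case_when(
        inside ~ "in-gene",
        tss_distance < 0 ~ "upstream",
        TRUE ~ "downstream"
      ),
      integration_percentage = case_when(
        !inside ~ NA_real_,
        feature_end - feature_start == 1L ~ 0,
        TRUE ~ 100 * tss_distance / (feature_end - feature_start - 1L)
      )
    ) |>
    select(-"pos0", -"tss", -"inside")
}
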