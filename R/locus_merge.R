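#' Merge redundant integration sites into loci
#'
#' Quality-passed reads frequently pin the same integration event to
#' positions a base or two apart (PCR and alignment jitter), so reads
#' whose IS positions fall within a small tolerance window are collapsed
#' into one locus.  Per chromosome (and strand, unless `ignore_strand`),
#' positions are sorted ascending and windows are opened greedily: the
#' lowest unassigned position `p` anchors a window covering
#' `[p, p + window - 1]`, every read in that interval joins the locus
#' reported at `p`, and the scan continues from the next unassigned
#' position.  Windows are anchored, not chained, so any two loci on the
#' same chromosome and strand are at least `window` bases apart and a run
#' of adjacent positions can never smear into an arbitrarily wide locus.
#' The per-locus read count is the "signal power" of the integration.
#'
#' @param r_records The redundant-IS tibble from [quality_filter()]
#'   (columns `chromosome`, `position`, `strand`; one row per read).
#' @param window Window width in bases (default 3: positions `p`, `p+1`,
#'   `p+2`).  `window = 1` reproduces the distinct position tuples.
#' @param ignore_strand Merge reads regardless of strand (default `FALSE`:
#'   junctions on opposite strands face opposite directions and are kept
#'   apart).
#' @return A tibble of loci sorted by chromosome then position: columns
#'   `chromosome`, `position` (window anchor), `strand` (`"*"` when
#'   `ignore_strand`), `read_count`, and `members` (a list column of
#'   per-position tibbles `position`, `count` within the window).
#' @export
#' @examples
#' r <- tibble::tibble(
#'   chromosome = "chr1",
#'   position = c(100, 101, 102, 105),
#'   strand = "+"
#' )
#' merge_loci(r)
merge_loci <- function(r_records, window = 3, ignore_strand = FALSE) {
  stopifnot(window >= 1)
  need <- c("chromosome", "position", "strand")
  if (!is.data.frame(r_records) || !all(need %in% names(r_records))) {
    abort("`r_records` must have columns `chromosome`, `position`, `strand`.")
  }
  r <- as_tibble(r_records)
  if (ignore_strand) r$strand <- "*"
  if (nrow(r) == 0) {
    return(tibble(
      chromosome = character(), position = integer(), strand = character(),
      read_count = integer(), members = list()
    ))
  }
  r |>
    count(chromosome, strand, position, name = "count") |>
    group_by(chromosome, strand) |>
    group_modify(~ greedy_windows(.x, window)) |>
    ungroup() |>
    arrange(chromosome, position, strand)
}

# Greedy anchored sliding window over one chromosome/strand group of
# distinct positions with counts.
greedy_windows <- function(pos_counts, window) {
  pos_counts <- arrange(pos_counts, position)
  p <- pos_counts$position
  cnt <- pos_counts$count
  out <- list()
  i <- 1L
  while (i <= length(p)) {
    anchor <- p[i]
    in_win <- p >= anchor & p <= anchor + window - 1
    out[[length(out) + 1]] <- tibble(
      position = as.integer(anchor),
      read_count = as.integer(sum(cnt[in_win])),
      members = list(tibble(position = as.integer(p[in_win]), count = as.integer(cnt[in_win])))
    )
    i <- max(which(in_win)) + 1L
  }
  purrr::list_rbind(out)
}

#' Per-locus window-offset histogram
#'
#' For each window offset (0 = the anchor, up to `window - 1`), the number
#' and fraction of reads whose IS position sits at that offset inside its
#' locus window -- the precision profile of IS calling (with accurate
#' junctions most reads land on the anchor).
#'
#' @param loci Output of [merge_loci()].
#' @param window Window width the loci were built with.
#' @return A tibble with columns `offset`, `reads`, `fraction`.
#' @export
locus_offsets <- function(loci, window = 3) {
  offs <- tibble(offset = 0:(window - 1), reads = 0L)
  if (nrow(loci) > 0) {
    obs <- loci |>
      select(position, members) |>
      tidyr::unnest(members, names_sep = "_") |>
      mutate(offset = members_position - position) |>
      count(offset, wt = members_count, name = "reads")
    offs <- offs |>
      rows_update(obs, by = "offset")
  }
  offs |> mutate(fraction = if (sum(reads) > 0) reads / sum(reads) else 0)
}

#' Export loci as BED
#'
#' Writes one BED6 line per locus: 0-based half-open single-base interval
#' at the locus position, name `IS_<chrom>_<position>`, score = read
#' count, strand.
#'
#' @param loci Output of [merge_loci()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
loci_to_bed <- function(loci, path) {
  lines <- sprintf(
    "%s\t%d\t%d\tIS_%s_%d\t%d\t%s",
    loci$chromosome, loci$position - 1L, loci$position,
    loci$chromosome, loci$position, loci$read_count,
    ifelse(loci$strand == "*", ".", loci$strand)
  )
  writeLines(lines, path)
  invisible(path)
}
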