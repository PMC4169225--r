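#' @export
print.lampis_run <- function(x, ...) {
  s <- x$stats |> filter(label == "total")
  cat("<lampis_run>\n")
  cat(sprintf("  samples:        %d\n", nrow(x$stats) - 1))
  cat(sprintf("  raw reads:      %d (%d unmatched barcode)\n", s$raw, s$unmatched))
  cat(sprintf("  trimmed (T):    %d  [no_ltr %d, too_short %d]\n",
              s$t, s$no_ltr, s$too_short))
  cat(sprintf("  classified:     N %d | LV %d | A %d | U %d\n",
              s$n, s$lv, s$a, s$u))
  cat(sprintf("  quality (R):    %d  [%d discarded]\n", s$r, s$quality_discarded))
  cat(sprintf("  loci (L):       %d\n", s$l))
  invisible(x)
}

#' Tidy an integration-site run
#'
#' Returns the annotated integration sites of a pipeline run as one long
#' tibble (one row per locus/closest-feature pair, with the sample label
#' and any joined metadata), the broom-style observation-level view.
#'
#' @param x A `lampis_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lampis_run <- function(x, ...) {
  x$annotated
}

#' One-row summary of an integration-site run
#'
#' The run-level accounting in one row: raw and barcode-matched reads,
#' trimmed set size, the four classification counts, quality-passed reads
#' and distinct loci.
#'
#' @param x A `lampis_run`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.lampis_run <- function(x, ...) {
  x$stats |>
    filter(label == "total") |>
    select(-label)
}

#' Stage-accounting plot for a pipeline run
#'
#' Stacked per-sample bars of read fates across the pipeline: reads
#' without a valid LTR, too-short fragments, and the alignment classes
#' (unmapped N, vector LV, ambiguous A, quality-discarded, and the final
#' redundant-IS set R).
#'
#' @param object A `lampis_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lampis_run <- function(object, ...) {
  per_sample <- object$stats |>
    filter(label != "total") |>
    transmute(
      label,
      `no LTR` = no_ltr,
      `too short` = too_short,
      `unmapped (N)` = n,
      `vector (LV)` = lv,
      `ambiguous (A)` = a,
      `quality-discarded` = quality_discarded,
      `IS reads (R)` = r
    ) |>
    tidyr::pivot_longer(-label, names_to = "stage", values_to = "count") |>
    mutate(stage = factor(stage, levels = c(
      "no LTR", "too short", "unmapped (N)", "vector (LV)", "ambiguous (A)",
      "quality-discarded", "IS reads (R)"
    )))
  ggplot2::ggplot(per_sample, ggplot2::aes(x = label, y = count, fill = stage)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "reads", fill = NULL,
                  title = "Read fate per sample") +
    ggplot2::theme_minimal()
}

#' Window-offset precision plot
#'
#' Bar plot of the fraction of IS reads landing at each offset inside the
#' merge window (offset 0 = the locus anchor) -- the junction-precision
#' profile of a run.
#'
#' @param loci A locus tibble from [merge_loci()] (or `run$loci`).
#' @param window Merge window the loci were built with (default 3).
#' @return A ggplot object.
#' @export
plot_locus_offsets <- function(loci, window = 3) {
  offs <- locus_offsets(loci, window = window)
  ggplot2::ggplot(offs, ggplot2::aes(x = factor(offset), y = 100 * fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "offset within merge window (bp)",
                  y = "% of IS reads",
                  title = "IS position precision within the merge window") +
    ggplot2::theme_minimal()
}
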