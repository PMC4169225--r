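# Test helpers: deterministic sequence construction and independent
# brute-force oracles.  The oracles deliberately avoid the package's
# alignment code path (no Biostrings alignment calls): hits are found by
# exhaustive mismatch scans over every substring, clustering by a direct
# greedy loop, annotation by an all-pairs distance scan.

h_random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

h_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# A fixed 63-nt LTR tail used across trimming tests.
h_ltr <- function() {
  withr::with_seed(909, h_random_dna(63))
}

h_substitute <- function(seq, positions) {
  b <- strsplit(seq, "")[[1]]
  for (p in positions) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
  paste(b, collapse = "")
}

# ---- exhaustive alignment oracle -------------------------------------------
# All full-length, gap-free placements of `seq` on both strands of every
# reference sequence, with mismatch counts computed by raw-byte comparison.
oracle_hits <- function(seq, ref, max_mismatch_frac = 0.25) {
  L <- nchar(seq)
  out <- list()
  for (ci in seq_along(ref)) {
    refraw <- charToRaw(ref[[ci]])
    n <- length(refraw)
    if (n < L) next
    for (strand in c("+", "-")) {
      q <- if (strand == "+") seq else h_revcomp(seq)
      qraw <- charToRaw(q)
      mm <- integer(n - L + 1)
      for (i in seq_len(L)) {
        mm <- mm + (refraw[i:(n - L + i)] != qraw[i])
      }
      keep <- which(mm <= max_mismatch_frac * L)
      for (s in keep) {
        out[[length(out) + 1]] <- tibble::tibble(
          subject = names(ref)[ci],
          ss = s, se = s + L - 1L, strand = strand,
          identity = 100 * (L - mm[s]) / L,
          score = L - 2 * mm[s],
          qs = 1L, qe = L
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      subject = character(), ss = integer(), se = integer(),
      strand = character(), identity = double(), score = double(),
      qs = integer(), qe = integer()
    ))
  }
  do.call(rbind, out)
}

# Classification rule applied directly to oracle hits for one read.
oracle_classify <- function(hits, read_len, as_t = 15, hs_t = 20,
                            min_identity = 95, max_start = 3,
                            vector_name = "VECTOR") {
  hits <- hits[hits$identity >= min_identity & hits$qs <= max_start, , drop = FALSE]
  if (nrow(hits) == 0) return(list(label = "N"))
  if (any(hits$subject == vector_name)) return(list(label = "LV"))
  hits$hs <- 100 * abs(hits$qs - hits$qe) / read_len
  ord <- order(-hits$score, hits$subject, hits$ss)
  hits <- hits[ord, , drop = FALSE]
  label <- if (nrow(hits) == 1) {
    "U"
  } else if (abs(hits$score[2] - hits$score[1]) > as_t &&
             abs(hits$hs[2] - hits$hs[1]) > hs_t) {
    "U"
  } else {
    "A"
  }
  pos <- if (hits$strand[1] == "+") hits$ss[1] else hits$se[1]
  list(label = label, chromosome = hits$subject[1], position = pos,
       strand = hits$strand[1])
}

# ---- greedy clustering oracle ----------------------------------------------
# Direct loop: sort, anchor a window at the lowest unassigned position,
# absorb everything within window - 1 bases, repeat.
oracle_merge <- function(positions, window = 3) {
  positions <- sort(positions)
  anchors <- integer()
  counts <- integer()
  while (length(positions) > 0) {
    a <- positions[1]
    in_win <- positions <= a + window - 1
    anchors <- c(anchors, a)
    counts <- c(counts, sum(in_win))
    positions <- positions[!in_win]
  }
  data.frame(position = anchors, read_count = counts)
}

# ---- annotation oracle ------------------------------------------------------
# All-pairs scan for one IS (1-based position) over features of one
# chromosome (0-based half-open), returning indices of all closest
# features and their annotation fields.
oracle_annotate <- function(position, features) {
  pos0 <- position - 1
  d <- numeric(nrow(features))
  for (i in seq_len(nrow(features))) {
    if (pos0 >= features$start[i] && pos0 < features$end[i]) {
      d[i] <- 0
    } else {
      d[i] <- min(abs(pos0 - features$start[i]), abs(pos0 - (features$end[i] - 1)))
    }
  }
  idx <- which(d == min(d))
  rows <- lapply(idx, function(i) {
    st <- features$start[i]
    en <- features$end[i]
    tss <- if (features$strand[i] == "+") st else en - 1
    tssd <- if (features$strand[i] == "+") pos0 - tss else tss - pos0
    inside <- pos0 >= st && pos0 < en
    relpos <- if (inside) "in-gene" else if (tssd < 0) "upstream" else "downstream"
    pct <- if (!inside) NA_real_ else if (en - st == 1) 0 else 100 * tssd / (en - st - 1)
    data.frame(feature = features$name[i], distance = d[i], tss_distance = tssd,
               relative_position = relpos, integration_percentage = pct)
  })
  do.call(rbind, rows)
}

# Sample a read (fragment) from a reference at a known IS, matching the
# generator's orientation convention.
h_sample_fragment <- function(ref, chrom, pos, strand, len) {
  s <- ref[[chrom]]
  if (strand == "+") {
    substring(s, pos, pos + len - 1)
  } else {
    h_revcomp(substring(s, pos - len + 1, pos))
  }
}

# Small end-to-end fixture: simulated dataset plus assembled config.
h_fixture_config <- function(sim) {
  pipeline_config(
    reads = sim$files$reads, barcodes = sim$barcodes, ltr = sim$ltr,
    lc = sim$lc, reference = sim$reference, vector_name = sim$vector_name,
    bed = sim$features, metadata = sim$metadata
  )
}
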