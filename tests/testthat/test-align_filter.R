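# Toy reference shared by the alignment tests: two chromosomes plus the
# vector dummy chromosome.
toy_ref <- make_reference(seed = 41, n_chrom = 2, chrom_length = 2000,
                          vector_length = 600)

test_that("a unique substring maps to a single exact hit", {
  read <- substring(toy_ref[["chr1"]], 100, 129)
  hits <- align_reads(tibble::tibble(id = "r1", seq = read), toy_ref)
  best <- dplyr::slice_max(hits, score, n = 1, with_ties = FALSE)
  expect_equal(best$subject, "chr1")
  expect_equal(best$ss, 100L)
  expect_equal(best$se, 129L)
  expect_equal(best$identity, 100)
  expect_equal(best$strand, "+")
  expect_equal(c(best$qs, best$qe), c(1L, 30L))
})

test_that("a sequence planted twice yields two equal-score hits", {
  rep_ref <- make_reference(
    seed = 42, n_chrom = 2, chrom_length = 2000,
    repeat_spec = list(list(length = 300, sites = list(c(1, 500), c(2, 1200))))
  )
  read <- substring(rep_ref[["chr1"]], 520, 579)  # inside the repeat block
  hits <- align_reads(tibble::tibble(id = "r1", seq = read), rep_ref) |>
    dplyr::filter(identity == 100)
  expect_equal(nrow(hits), 2L)
  expect_equal(sort(hits$subject), c("chr1", "chr2"))
  expect_equal(hits$score[1], hits$score[2])
})

test_that("vector-internal reads hit the dummy chromosome", {
  read <- substring(toy_ref[["VECTOR"]], 200, 280)
  hits <- align_reads(tibble::tibble(id = "r1", seq = read), toy_ref)
  expect_true("VECTOR" %in% hits$subject)
})

test_that("minus-strand placements are reported in read coordinates", {
  frag <- h_revcomp(substring(toy_ref[["chr2"]], 301, 400))
  hits <- align_reads(tibble::tibble(id = "r1", seq = frag), toy_ref)
  best <- dplyr::slice_max(hits, score, n = 1, with_ties = FALSE)
  expect_equal(best$strand, "-")
  expect_equal(c(best$ss, best$se), c(301L, 400L))
  expect_equal(c(best$qs, best$qe), c(1L, 100L))
})

test_that("hit prefiltering applies the identity and start-position bounds", {
  hits <- tibble::tibble(
    read_id = "r", subject = "chr1",
    identity = c(94.9, 100, 95, 96),
    length = 100L, score = 100,
    qs = c(1L, 4L, 3L, 1L), qe = 100L, ss = 1L, se = 100L, strand = "+"
  )
  kept <- prefilter_hits(hits)
  expect_equal(kept$identity, c(95, 96))   # 94.9 dropped, qs 4 dropped
  expect_equal(kept$qs, c(3L, 1L))          # identity 95 / qs 3 are inclusive
})

test_that("homology score follows the printed coordinate-difference formula", {
  expect_equal(homology_score(1, 81, 100), 80)
  expect_equal(homology_score(50, 50, 120), 0)
  for (L in c(20L, 57L, 100L)) {
    expect_equal(homology_score(1, L, L), 100 * (L - 1) / L)
  }
  expect_equal(homology_score(1, 81, 100, inclusive = TRUE), 81)
  expect_equal(homology_score(81, 1, 100), 80)  # symmetric in qs, qe
})

make_cls_hits <- function(scores, qes, subjects = "chr1") {
  n <- length(scores)
  ss <- as.integer(seq(1000L, by = 5000L, length.out = n))
  tibble::tibble(
    read_id = "r", subject = rep_len(subjects, n), identity = 100,
    length = 100L, score = scores, qs = 1L, qe = as.integer(qes),
    ss = ss, se = ss + as.integer(qes) - 1L, strand = "+"
  )
}
one_read <- tibble::tibble(id = "r", seq = strrep("A", 100))

test_that("the two-threshold rule separates unambiguous from ambiguous reads", {
  # score gap 20 > 15 and hs gap 35 > 20 -> U
  cls <- classify_reads(make_cls_hits(c(100, 80), c(96, 61)), one_read)
  expect_equal(cls$label, "U")
  expect_equal(cls$hs, 95)
  # score gap 10 <= 15 -> A regardless of hs
  cls <- classify_reads(make_cls_hits(c(100, 90), c(96, 21)), one_read)
  expect_equal(cls$label, "A")
  # boundary: score gap exactly 15 is not enough
  cls <- classify_reads(make_cls_hits(c(100, 85), c(96, 61)), one_read)
  expect_equal(cls$label, "A")
  # score gap 16 with hs gap 21 -> U
  cls <- classify_reads(make_cls_hits(c(100, 84), c(96, 75)), one_read)
  expect_equal(cls$label, "U")
  # score gap 16 with hs gap exactly 20 -> A
  cls <- classify_reads(make_cls_hits(c(100, 84), c(96, 76)), one_read)
  expect_equal(cls$label, "A")
})

test_that("single hits are unambiguous and no hits are unmapped", {
  cls <- classify_reads(make_cls_hits(100, 96), one_read)
  expect_equal(cls$label, "U")
  cls <- classify_reads(make_cls_hits(c(100, 100), c(96, 96)), one_read)
  expect_equal(cls$label, "A")   # perfect score tie
  cls <- classify_reads(dplyr::slice(make_cls_hits(100, 96), 0), one_read)
  expect_equal(cls$label, "N")
  expect_equal(cls$n_hits, 0L)
})

test_that("any dummy-chromosome hit labels the read LV by default", {
  hits <- make_cls_hits(c(100, 40), c(96, 40), subjects = c("chr1", "VECTOR"))
  expect_equal(classify_reads(hits, one_read)$label, "LV")
  # restricted mode: LV only when the best hit is the vector; the weak
  # vector hit then competes like any other and loses clearly -> U
  expect_equal(classify_reads(hits, one_read, lv_any = FALSE)$label, "U")
  hits2 <- make_cls_hits(c(100, 40), c(96, 40), subjects = c("VECTOR", "chr1"))
  expect_equal(classify_reads(hits2, one_read, lv_any = FALSE)$label, "LV")
})

test_that("classification is invariant under hit-order permutation", {
  withr::local_seed(43)
  hits <- make_cls_hits(c(90, 100, 60), c(40, 96, 80))
  ref_cls <- classify_reads(hits, one_read)
  for (i in 1:5) {
    perm <- classify_reads(dplyr::slice_sample(hits, n = nrow(hits)), one_read)
    expect_equal(perm, ref_cls)
  }
})

test_that("the quality filter keeps U reads with identity >= 95 and hs >= 80", {
  cls <- tibble::tibble(
    read_id = c("a", "b", "c", "d"),
    label = c("U", "U", "U", "A"),
    subject = "chr1", identity = c(99, 99, 94, 100),
    score = 100, qs = 1L, qe = 90L,
    ss = 1000L, se = 1089L, strand = "+",
    hs = c(85, 79, 90, 100), n_hits = 1L
  )
  r <- quality_filter(cls)
  expect_equal(r$read_id, "a")                 # hs 79 and identity 94 dropped, A never enters
  expect_equal(r$position, 1000L)
  expect_equal(quality_filter(dplyr::mutate(cls, hs = 80, identity = 95))$read_id,
               c("a", "b", "c"))               # both bounds inclusive
})

test_that("IS positions sit on the junction side of the alignment", {
  hits <- tibble::tibble(
    subject = "chr5", ss = c(1000L, 1000L), se = c(1060L, 1060L),
    strand = c("+", "-")
  )
  pos <- is_position(hits)
  expect_equal(pos$position, c(1000L, 1060L))
  expect_equal(pos$chromosome, c("chr5", "chr5"))
})

test_that("reads of different lengths from one planted IS share a position", {
  for (strand in c("+", "-")) {
    p <- 900L
    reads <- tibble::tibble(
      id = c("short", "long"),
      seq = c(h_sample_fragment(toy_ref, "chr1", p, strand, 40),
              h_sample_fragment(toy_ref, "chr1", p, strand, 120))
    )
    hits <- align_reads(reads, toy_ref) |> prefilter_hits()
    cls <- classify_reads(hits, reads)
    r <- quality_filter(cls)
    expect_equal(nrow(r), 2L)
    expect_equal(unique(r$position), p)
    expect_equal(unique(r$strand), strand)
  }
})

test_that("alignment output is independent of the chunk count", {
  withr::local_seed(44)
  reads <- purrr::map(1:12, function(i) {
    p <- sample(100:1800, 1)
    tibble::tibble(id = paste0("r", i),
                   seq = h_sample_fragment(toy_ref, sample(c("chr1", "chr2"), 1),
                                           p, sample(c("+", "-"), 1), 60))
  }) |> purrr::list_rbind()
  h1 <- align_reads(reads, toy_ref, chunks = 1)
  h4 <- align_reads(reads, toy_ref, chunks = 4)
  h8 <- align_reads(reads, toy_ref, chunks = 8)
  expect_equal(h1, h4)
  expect_equal(h1, h8)
})

test_that("tabular hits import normalises subject orientation", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "r1\tchr1\t98.5\t100\t1\t0\t1\t100\t5000\t5099\t1e-50\t180",
    "r2\tchr2\t100\t80\t0\t0\t1\t80\t7000\t6921\t1e-40\t160"
  ), tsv)
  hits <- read_hits_tsv(tsv)
  expect_equal(hits$strand, c("+", "-"))
  expect_equal(hits$ss, c(5000L, 6921L))
  expect_equal(hits$se, c(5099L, 7000L))
  expect_equal(hits$score, c(180, 160))
})
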