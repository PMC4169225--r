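feat <- function(start, end, name = "G", strand = "+", chromosome = "chr1") {
  tibble::tibble(chromosome = chromosome, start = as.integer(start),
                 end = as.integer(end), name = name, score = 0, strand = strand)
}
locus <- function(position, chromosome = "chr1", strand = "+") {
  tibble::tibble(chromosome = chromosome, position = as.integer(position),
                 strand = strand, read_count = 1L)
}

test_that("BED lines parse to 0-based half-open features", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=genes",
               "chr1\t100\t200\tGENE1\t0\t+",
               "chr2\t50\t60\tGENE2\t3\t-"), bed)
  out <- load_bed(bed)
  expect_equal(nrow(out), 2L)
  expect_equal(out$start, c(100L, 50L))
  expect_equal(out$end, c(200L, 60L))
  expect_equal(out$strand, c("+", "-"))
})

test_that("empty and malformed BED inputs behave as specified", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(), bed)
  expect_equal(nrow(load_bed(bed)), 0L)

  writeLines(c("chr1\t100\t200\tA\t0\t+", "chr1\t300\t250\tB\t0\t+"), bed)
  expect_error(load_bed(bed), "line 2")
  writeLines("chr1\t100\t200", bed)
  expect_error(load_bed(bed), "line 1")
  writeLines("chr1\t1x0\t200\tA\t0\t+", bed)
  expect_error(load_bed(bed), "line 1")
  writeLines("chr1\t100\t200\tA\t0\t?", bed)
  expect_error(load_bed(bed), "line 1")
})

test_that("the closest feature is chosen by body distance with ties kept", {
  features <- dplyr::bind_rows(feat(100, 200, "A"), feat(300, 400, "B"))
  # inside the first feature -> only A, distance 0
  hit <- closest_features(locus(151), features)   # 0-based coordinate 150
  expect_equal(hit$feature_name, "A")
  expect_equal(hit$distance, 0L)
  # equidistant -> both (0-based 250: 50 from A's last base 200, 50 from B's start)
  features2 <- dplyr::bind_rows(feat(100, 201, "A"), feat(300, 400, "B"))
  hit <- closest_features(locus(251), features2)
  expect_equal(sort(hit$feature_name), c("A", "B"))
  expect_equal(hit$distance, c(50L, 50L))
  # no features on the chromosome -> no rows
  expect_equal(nrow(closest_features(locus(100, chromosome = "chrX"), features)), 0L)
})

test_that("TSS distance, relative position and percentage follow the feature strand", {
  f_plus <- feat(100, 201, "A", "+")   # length 101, TSS at 100
  # IS halfway: 0-based 150 -> tss_distance 50, 50%
  ann <- annotate_loci(locus(151), f_plus)
  expect_equal(ann$relative_position, "in-gene")
  expect_equal(ann$tss_distance, 50)
  expect_equal(ann$integration_percentage, 50)
  # IS at the TSS -> 0 / 0%
  ann <- annotate_loci(locus(101), f_plus)
  expect_equal(ann$tss_distance, 0)
  expect_equal(ann$integration_percentage, 0)
  # IS at the far end -> 100%
  ann <- annotate_loci(locus(201), f_plus)
  expect_equal(ann$integration_percentage, 100)

  # minus strand: TSS at the last covered base (0-based 200)
  f_minus <- feat(100, 201, "A", "-")
  ann <- annotate_loci(locus(201), f_minus)
  expect_equal(ann$tss_distance, 0)
  expect_equal(ann$integration_percentage, 0)
  ann <- annotate_loci(locus(101), f_minus)
  expect_equal(ann$integration_percentage, 100)

  # upstream/downstream are transcriptional, not left/right
  expect_equal(annotate_loci(locus(51), f_plus)$relative_position, "upstream")
  expect_equal(annotate_loci(locus(251), f_plus)$relative_position, "downstream")
  expect_equal(annotate_loci(locus(251), f_minus)$relative_position, "upstream")
  expect_equal(annotate_loci(locus(51), f_minus)$relative_position, "downstream")
})

test_that("integration percentage is strand-mirror invariant", {
  withr::local_seed(61)
  for (i in 1:50) {
    st <- sample(0:500, 1)
    len <- sample(2:300, 1)
    en <- st + len
    off <- sample(0:(len - 1), 1)
    pos0 <- st + off
    ann_p <- annotate_loci(locus(pos0 + 1), feat(st, en, strand = "+"))
    # mirror the IS about the feature midpoint and flip the strand
    pos0_m <- st + (len - 1 - off)
    ann_m <- annotate_loci(locus(pos0_m + 1), feat(st, en, strand = "-"))
    expect_equal(ann_p$integration_percentage, ann_m$integration_percentage)
    expect_equal(ann_p$tss_distance, ann_m$tss_distance)
  }
})

test_that("single-base features place the IS at their TSS", {
  ann <- annotate_loci(locus(101), feat(100, 101))
  expect_equal(ann$relative_position, "in-gene")
  expect_equal(ann$integration_percentage, 0)
})

test_that("annotation agrees with an all-pairs distance scan", {
  withr::local_seed(62)
  for (i in 1:60) {
    n_feat <- sample(1:12, 1)
    starts <- sample(0:2000, n_feat)
    features <- purrr::map(seq_len(n_feat), function(k) {
      feat(starts[k], starts[k] + sample(1:400, 1),
           name = paste0("G", k), strand = sample(c("+", "-"), 1))
    }) |> purrr::list_rbind()
    pos <- sample(1:2500, 1)
    ann <- annotate_loci(locus(pos), features) |> dplyr::arrange(feature_name)
    orc <- oracle_annotate(pos, features)
    orc <- orc[order(orc$feature), , drop = FALSE]
    expect_equal(ann$feature_name, orc$feature)
    expect_equal(ann$distance, orc$distance, ignore_attr = TRUE)
    expect_equal(ann$tss_distance, orc$tss_distance, ignore_attr = TRUE)
    expect_equal(ann$relative_position, orc$relative_position, ignore_attr = TRUE)
    expect_equal(ann$integration_percentage, orc$integration_percentage,
                 ignore_attr = TRUE)
  }
})

test_that("every locus on an annotated chromosome yields at least one row", {
  withr::local_seed(63)
  features <- dplyr::bind_rows(feat(100, 200, "A"), feat(500, 800, "B"),
                               feat(50, 120, "C", chromosome = "chr2"))
  loci <- dplyr::bind_rows(locus(10), locus(450), locus(1500),
                           locus(90, chromosome = "chr2"),
                           locus(5, chromosome = "chrZ"))
  ann <- annotate_loci(loci, features)
  annotated_chroms <- unique(features$chromosome)
  expect_equal(
    nrow(ann),
    nrow(closest_features(loci, features))
  )
  expect_true(all(loci$chromosome[loci$chromosome %in% annotated_chroms] %in%
                    ann$chromosome))
})
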