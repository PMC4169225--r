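ltr <- h_ltr()

test_that("an exact LTR tail is found with the junction at its end", {
  withr::local_seed(31)
  read <- paste0(ltr, h_random_dna(50))
  m <- find_ltr(read, ltr)
  expect_equal(m$ltr_end, 63L)
  expect_equal(m$homology, 100)
})

test_that("homology boundary sits at 57 of 63 identities", {
  withr::local_seed(32)
  genomic <- h_random_dna(50)
  # 6 substitutions -> 57 identities = 90.5% >= 89%: accepted
  read57 <- paste0(h_substitute(ltr, c(10, 15, 20, 25, 30, 35)), genomic)
  expect_false(is.null(find_ltr(read57, ltr)))
  # 7 substitutions -> 56 identities = 88.9% < 89%: rejected
  read56 <- paste0(h_substitute(ltr, c(10, 15, 20, 25, 30, 35, 40)), genomic)
  expect_null(find_ltr(read56, ltr))
  # 8 scattered substitutions in the first 60 bases (55/63 = 87.3%): rejected
  read55 <- paste0(h_substitute(ltr, c(5, 10, 15, 20, 25, 30, 35, 40)), genomic)
  expect_null(find_ltr(read55, ltr))
})

test_that("the last 3 LTR bases must match perfectly", {
  withr::local_seed(33)
  genomic <- h_random_dna(50)
  expect_null(find_ltr(paste0(h_substitute(ltr, 63), genomic), ltr))
  expect_null(find_ltr(paste0(h_substitute(ltr, 62), genomic), ltr))
  expect_null(find_ltr(paste0(h_substitute(ltr, 61), genomic), ltr))
  # a substitution just before the last 3 bases is tolerated
  expect_false(is.null(find_ltr(paste0(h_substitute(ltr, 60), genomic), ltr)))
})

test_that("trimming slices the genomic fragment after the junction", {
  withr::local_seed(34)
  frag <- h_random_dna(40)
  out <- trim_reads(tibble::tibble(id = "r1", seq = paste0(ltr, frag)), ltr)
  expect_equal(out$status, "trimmed")
  expect_equal(out$genomic_seq, frag)
  expect_equal(out$ltr_end, 63L)
  expect_equal(out$trimmed_length, 40L)
})

test_that("reads without an LTR are discarded, LTR at read end is too short", {
  withr::local_seed(35)
  out <- trim_reads(
    tibble::tibble(id = c("none", "end"),
                   seq = c(h_random_dna(100), ltr)),
    ltr
  )
  expect_equal(out$status, c("no_ltr", "too_short"))
  expect_true(all(is.na(out$genomic_seq)))
})

test_that("linker cassette is trimmed with everything after it, never discards", {
  withr::local_seed(36)
  lc <- h_random_dna(30)
  frag <- h_random_dna(60)
  reads <- tibble::tibble(
    id = c("with_lc", "without_lc", "lc_only"),
    seq = c(paste0(ltr, frag, lc, "TT"),
            paste0(ltr, frag),
            paste0(ltr, lc))
  )
  out <- trim_reads(reads, ltr, lc = lc)
  expect_equal(out$status, c("trimmed", "trimmed", "too_short"))
  expect_equal(out$genomic_seq[1], frag)
  expect_equal(out$lc_found, c(TRUE, FALSE, TRUE))
  expect_equal(out$genomic_seq[2], frag)
})

test_that("the 20-bp length filter is exclusive below 20", {
  withr::local_seed(37)
  reads <- tibble::tibble(
    id = c("len19", "len20"),
    seq = c(paste0(ltr, h_random_dna(19)), paste0(ltr, h_random_dna(20)))
  )
  out <- trim_reads(reads, ltr)
  expect_equal(out$status, c("too_short", "trimmed"))
})

test_that("trim statuses partition the input and fragments are substrings", {
  withr::local_seed(38)
  lc <- h_random_dna(25)
  reads <- purrr::map(1:30, function(i) {
    kind <- i %% 3
    s <- if (kind == 0) {
      h_random_dna(120)                                  # no LTR
    } else if (kind == 1) {
      paste0(ltr, h_random_dna(sample(5:18, 1)))         # too short
    } else {
      paste0(ltr, h_random_dna(sample(25:80, 1)),
             if (i %% 2 == 0) lc else "")                # keeps a fragment
    }
    tibble::tibble(id = paste0("r", i), seq = s)
  }) |> purrr::list_rbind()
  out <- trim_reads(reads, ltr, lc = lc)
  expect_equal(nrow(out), nrow(reads))
  expect_equal(sum(out$status %in% c("no_ltr", "too_short", "trimmed")), nrow(reads))
  trimmed <- dplyr::filter(out, status == "trimmed")
  expect_true(all(trimmed$trimmed_length >= 20))
  src <- reads$seq[match(trimmed$read_id, reads$id)]
  expect_true(all(substring(src, trimmed$ltr_end + 1,
                            trimmed$ltr_end + trimmed$trimmed_length) ==
                    trimmed$genomic_seq))
})

test_that("error-free synthetic reads round-trip their fragments exactly", {
  ref <- make_reference(seed = 5, n_chrom = 1, chrom_length = 2000,
                        vector_length = 1000)
  planted <- tibble::tibble(chromosome = "chr1", position = 500L,
                            strand = "+", n_reads = 4L)
  sim <- make_reads(ref, planted, ltr = ltr, frag_range = c(50, 200), seed = 6)
  out <- trim_reads(sim$reads, ltr)
  expect_true(all(out$status == "trimmed"))
  expect_equal(out$genomic_seq,
               substring(ref[["chr1"]], 500, 500 + sim$truth$frag_len - 1))
})

test_that("short LTRs warn and the homology threshold scales", {
  short_ltr <- substring(ltr, 34, 63)  # 30 nt
  read <- paste0(short_ltr, strrep("A", 30))
  expect_warning(m <- find_ltr(read, short_ltr), "shorter")
  expect_equal(m$ltr_end, 30L)
})
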