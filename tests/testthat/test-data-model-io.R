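test_that("profile matrix TSV round trip preserves bins and values", {
  bins <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                         start = c(0L, 100L, 0L), end = c(100L, 200L, 50L),
                         n_probes = c(10L, 12L, 5L), gc = c(0.4, 0.5, 0.6))
  vals <- matrix(c(0.1, -0.2, 0.3, 1.5, -1.5, 0), nrow = 3)
  pm <- profile_matrix(bins, vals, c("A", "B"))
  expect_equal(dim(pm), c(3L, 2L))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_matrix(pm, path)
  back <- read_profile_matrix(path)
  expect_equal(back$patients, pm$patients)
  expect_equal(back$values, pm$values)
  expect_equal(back$bins$gc, pm$bins$gc)
})

test_that("generated profile fixture survives a write/read round trip", {
  sim <- generate_matched_pair(synthetic_config(K1 = 12, K2 = 12, L = 4, M = 1,
                                                seed = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_matrix(sim$pair$tumor, path)
  back <- read_profile_matrix(path)
  expect_equal(back$values, sim$pair$tumor$values, tolerance = 1e-12)
  expect_equal(back$bins$start, sim$pair$tumor$bins$start)
})

test_that("profile matrix invariants are enforced with row identification", {
  bins <- tibble::tibble(chrom = "chr1", start = c(0L, 50L), end = c(100L, 40L))
  expect_error(profile_matrix(bins, matrix(0, 2, 1), "A"), "start >= end.*2")
  good <- tibble::tibble(chrom = "chr1", start = c(0L, 50L), end = c(50L, 90L))
  expect_error(profile_matrix(good, matrix(c(1, NA), 2, 1), "A"), "finite")
  expect_error(profile_matrix(good, matrix(0, 2, 2), c("A", "A")), "duplicate")
})

test_that("bins are sorted by (chrom, start) deterministically", {
  bins <- tibble::tibble(chrom = c("chr2", "chr1", "chr1"),
                         start = c(0L, 100L, 0L), end = c(10L, 110L, 10L))
  pm <- profile_matrix(bins, matrix(1:6, 3, 2), c("A", "B"))
  expect_equal(pm$bins$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(pm$bins$start, c(0L, 100L, 0L))
  expect_equal(pm$values[, 1], c(3, 2, 1))
})

test_that("match_patients intersects, sorts, aligns and is idempotent", {
  bins <- tibble::tibble(chrom = "chr1", start = 0:2, end = 1:3)
  tum <- profile_matrix(bins, matrix(1:9, 3), c("A", "B", "C"))
  nor <- profile_matrix(bins, matrix(10:18, 3), c("D", "C", "B"))
  pair <- match_patients(tum, nor)
  expect_equal(pair$tumor$patients, c("B", "C"))
  expect_equal(pair$normal$patients, c("B", "C"))
  # columns re-aligned per patient after shuffling
  expect_equal(pair$tumor$values[, "B"], c(4, 5, 6))
  expect_equal(pair$normal$values[, "B"], c(16, 17, 18))
  expect_equal(pair$normal$values[, "C"], c(13, 14, 15))

  twice <- match_patients(pair$tumor, pair$normal)
  expect_equal(twice$tumor$values, pair$tumor$values)
  expect_equal(twice$normal$values, pair$normal$values)

  only_a <- profile_matrix(bins, matrix(1:3, 3), "A")
  expect_error(match_patients(tum, only_a), "at least 2 shared")
})

test_that("identical patient lists pass through match_patients unchanged", {
  bins <- tibble::tibble(chrom = "chr1", start = 0:1, end = 1:2)
  tum <- profile_matrix(bins, matrix(1:4, 2), c("A", "B"))
  nor <- profile_matrix(bins, matrix(5:8, 2), c("A", "B"))
  pair <- match_patients(tum, nor)
  expect_equal(pair$tumor$values, tum$values)
  expect_equal(pair$normal$values, nor$values)
})

test_that("clinical TSV parses booleans, flags PFS > OS, rejects bad events", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tos_months\tos_event\tpfs_months\tstage\tplatinum",
               "P1\t10.5\t1\t5\tII\t1",
               "P2\t20\tfalse\t8\tIII\t0",
               "P3\t3\ttrue\tNA\tNA\tNA",
               "P4\t7\t0\t2.5\tIV\t1"), path)
  rec <- read_clinical(path)
  expect_equal(nrow(rec), 4)
  expect_equal(rec$os_event, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(rec$stage, c(2L, 3L, NA, 4L))
  expect_equal(rec$platinum, c(TRUE, FALSE, NA, TRUE))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tos_months\tos_event", "P1\t10\tmaybe"), bad)
  expect_error(read_clinical(bad), "os_event.*row\\(s\\): 1")

  nocol <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tos_months", "P1\t10"), nocol)
  expect_error(read_clinical(nocol), "os_event")

  flag <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tos_months\tos_event\tpfs_months",
               "P1\t10\t1\t15"), flag)
  expect_warning(fr <- read_clinical(flag), "pfs_months exceeds")
  expect_true(fr$pfs_exceeds_os[1])
})

test_that("synthetic survival records round trip through the clinical TSV", {
  cfg <- synthetic_config(K1 = 10, K2 = 10, L = 5, M = 1, seed = 9)
  rec <- generate_survival(rep(c(TRUE, FALSE), c(2, 3)), cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clinical(rec, path)
  back <- read_clinical(path)
  expect_equal(back$os_months, rec$os_months, tolerance = 1e-12)
  expect_equal(back$os_event, rec$os_event)
  expect_equal(back$platinum, rec$platinum)
})

test_that("segment BED + arm table reader validates structure", {
  bed <- withr::local_tempfile(fileext = ".bed")
  arms <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr6\t0\t100\tseg1", "chr6\t100\t250\tseg2",
               "chr12\t0\t80\tseg3"), bed)
  writeLines(c("name\tarm", "seg1\t6p", "seg2\t6p", "seg3\t12p"), arms)
  seg <- read_segments(bed, arms)
  expect_equal(seg$arm, c("6p", "6p", "12p"))

  writeLines(c("chr6\t0\t100\tseg1", "chr6\t50\t250\tseg2"), bed)
  writeLines(c("name\tarm", "seg1\t6p", "seg2\t6p"), arms)
  expect_error(read_segments(bed, arms), "overlapping")
})
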