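test_that("comparison enumeration reproduces the cohort combinatorics", {
  # study-sized cohort: 10 matched normals, 17 tumors
  m <- defaultCohort()
  cmp <- enumerateComparisons(m)
  expect_equal(sum(cmp$type == "matched"), 10)
  expect_equal(sum(cmp$type == "normal_normal"), 45)
  expect_equal(sum(cmp$type == "cross"), 160) # 10*17 - 10 matched
  cmp_all <- enumerateComparisons(m, include_matched_in_cross = TRUE)
  expect_equal(sum(cmp_all$type == "cross"), 170) # all normal x tumor

  one <- toyManifest(1)
  c1 <- enumerateComparisons(one)
  expect_equal(as.vector(table(factor(c1$type,
    c("matched", "normal_normal", "cross")))), c(1, 0, 0))

  # 3 matched normals + 5 tumors: 3 matched, C(3,2)=3 nn, 3*5-3=12 cross
  m3 <- toyManifest(3, n_tumor_only = 2)
  c3 <- enumerateComparisons(m3)
  expect_equal(sum(c3$type == "matched"), 3)
  expect_equal(sum(c3$type == "normal_normal"), 3)
  expect_equal(sum(c3$type == "cross"), 12)

  # normal_normal pairs are stored in canonical order
  nn <- c3[c3$type == "normal_normal", ]
  expect_true(all(nn$sample_ref < nn$sample_alt))
})

test_that("call loading snaps to the grid and rejects malformed widths", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tq_value",
               "chr1\t1000\t1500\t1e-5",
               "chr1\t1000\t1499\t1e-5",
               "chr1\t2000\t2500\t0.5"), f)
  expect_warning(calls <- loadDMRCalls(f, "c1"), "rejected")
  expect_equal(nrow(calls), 2) # the 499-bp row is gone
  expect_equal(calls$bin, c(2L, 4L))
  expect_equal(calls$q_value[2], 0.5) # retained; filtering is separate
  expect_equal(calls$direction, c("unset", "unset"))

  # signed statistic sets a provisional direction
  writeLines(c("chrom\tstart\tend\tq_value\tstat",
               "chr1\t0\t500\t1e-5\t-2.5",
               "chr1\t500\t1000\t1e-5\t3.1"), f)
  calls <- loadDMRCalls(f, "c1")
  expect_equal(calls$direction, c("hypo", "hyper"))
})

test_that("direction is assigned from bin mean methylation, tumor-relative", {
  calls <- data.frame(comparison_id = "c1", chrom = "chr1",
                      bin = c(0L, 1L, 2L), q_value = 1e-5,
                      direction = "unset")
  ref <- toyTrack(c(100, 600, 1100), c(0.8, 0.2, 0.5))
  alt <- toyTrack(c(100, 600, 1100), c(0.3, 0.6, 0.5))
  out <- assignDirection(calls, ref, alt)
  expect_equal(out$direction, c("hypo", "hyper", "ambiguous"))
  expect_equal(out$delta_mean, c(-0.5, 0.4, 0.0))

  # a call bin with no CpG coverage is an error
  bad <- data.frame(comparison_id = "c1", chrom = "chr1", bin = 9L,
                    q_value = 1e-5, direction = "unset")
  expect_error(assignDirection(bad, ref, alt), "without CpG")
})

test_that("Q threshold calibration implements the quoted ratios", {
  # one matched comparison with 200 DMRs; its normal appears in three
  # normal-normal comparisons with 10, 20 and 30 DMRs -> fpr 20/200
  cmp <- data.frame(
    comparison_id = c("m1", "nn12", "nn13", "nn14"),
    sample_ref = c("N1", "N1", "N1", "N1"),
    sample_alt = c("T1", "N2", "N3", "N4"),
    type = c("matched", rep("normal_normal", 3)),
    patient_id = c("P1", NA, NA, NA))
  mkcalls <- function(cid, n, bin0) data.frame(
    comparison_id = cid, chrom = "chr1", bin = bin0 + seq_len(n),
    q_value = 1e-6, direction = "hyper")
  calls <- rbind(mkcalls("m1", 200, 0), mkcalls("nn12", 10, 1000),
                 mkcalls("nn13", 20, 2000), mkcalls("nn14", 30, 3000))
  calls$delta_mean <- 0.25
  cal <- calibrateQThreshold(calls, cmp)
  row <- cal$per_comparison[cal$per_comparison$q_threshold == 1e-3, ]
  expect_equal(row$fpr_ratio, 20 / 200)
  expect_equal(row$large_change_fraction, 1.0) # all deltas 0.25 > 0.10
  expect_equal(row$shared_fraction, 0) # single matched comparison

  # no normal-normal DMRs at the threshold -> fpr 0
  calls2 <- mkcalls("m1", 50, 0); calls2$delta_mean <- 0.05
  cal2 <- calibrateQThreshold(calls2, cmp)
  row2 <- cal2$per_comparison[cal2$per_comparison$q_threshold == 1e-3, ]
  expect_equal(row2$fpr_ratio, 0)
  expect_equal(row2$large_change_fraction, 0) # 5% change is not large

  # zero matched DMRs at a threshold -> missing, not zero
  calls3 <- mkcalls("m1", 10, 0); calls3$q_value <- 5e-3
  calls3$delta_mean <- 0.2
  cal3 <- calibrateQThreshold(calls3, cmp)
  expect_true(is.na(cal3$per_comparison$fpr_ratio[
    cal3$per_comparison$q_threshold == 1e-3]))
  expect_false(is.na(cal3$per_comparison$fpr_ratio[
    cal3$per_comparison$q_threshold == 1e-2]))
})

test_that("fpr ratio never increases as the threshold tightens", {
  ds <- simulateDataset(seed = 31, tracks = FALSE)
  cal <- calibrateQThreshold(ds$calls, ds$comparisons)
  s <- cal$summary[order(-cal$summary$q_threshold), ]
  expect_true(all(diff(s$fpr_ratio) <= 1e-12))
})

test_that("call filtering is strict on q, chrY and blacklisted bins", {
  si <- c(chr1 = 2000, chrY = 2000)
  cpg <- GRanges(c("chr1", "chr1", "chrY"),
                 IRanges(c(100, 600, 100), width = 1))
  bl <- GRanges("chr1", IRanges(501, 1000)) # blacklists bin 1
  grid <- buildBinGrid(si, cpg, bl)
  calls <- data.frame(
    comparison_id = "c1",
    chrom = c("chr1", "chr1", "chr1", "chrY"),
    bin = c(0L, 0L, 1L, 0L),
    q_value = c(1e-3, 1e-9, 1e-9, 1e-9),
    direction = "hypo")
  out <- filterCalls(calls, grid)
  # q = 0.001 exactly: dropped (strict); chrY: dropped; blacklisted bin
  # 1: dropped; only the clean chr1 bin 0 call survives
  expect_equal(nrow(out), 1)
  expect_equal(out$bin, 0L)
  expect_equal(out$q_value, 1e-9)
})

test_that("catalogue IDs follow block/position numbering and are
           invariant to comparison order", {
  calls <- data.frame(
    comparison_id = c("c1", "c1", "c2"),
    chrom = "chr1", bin = c(2L, 3L, 6L), # bins at 1000,1500,3000
    q_value = 1e-6, direction = "hypo")
  cat1 <- buildCatalog(calls)
  expect_equal(mcols(dmrRanges(cat1))$dmr_id, c("B1.1", "B1.2", "B2.1"))
  expect_equal(start(dmrRanges(cat1)), c(1001, 1501, 3001))

  # same bin called in two comparisons: one unique DMR, recurrence 2
  calls2 <- data.frame(comparison_id = c("c1", "c2"), chrom = "chr1",
                       bin = 5L, q_value = 1e-6, direction = "hyper")
  cat2 <- buildCatalog(calls2)
  expect_equal(length(cat2), 1L)
  rec <- recurrence(cat2)
  expect_equal(rec$n_patients, 2L)

  # permuting input order leaves IDs identical
  cat3 <- buildCatalog(calls[c(3, 1, 2), ])
  expect_identical(mcols(dmrRanges(cat1))$dmr_id,
                   mcols(dmrRanges(cat3))$dmr_id)

  # blocks restart across chromosomes in karyotype order
  calls4 <- data.frame(comparison_id = "c1",
                       chrom = c("chr2", "chr1", "chr10"),
                       bin = c(0L, 0L, 0L), q_value = 1e-6,
                       direction = "hypo")
  cat4 <- buildCatalog(calls4)
  expect_equal(as.character(seqnames(dmrRanges(cat4))),
               c("chr1", "chr2", "chr10"))
  expect_equal(mcols(dmrRanges(cat4))$dmr_id, c("B1.1", "B2.1", "B3.1"))
})

test_that("recurrence histogram accounts for every unique DMR", {
  ds <- simulateDataset(seed = 17, tracks = FALSE)
  filt <- filterCalls(ds$calls, ds$grid)
  cat_ <- buildCatalog(filt, ds$comparisons)
  rec <- recurrence(cat_)
  for (d in unique(rec$direction)) {
    h <- table(rec$n_patients[rec$direction == d])
    expect_equal(sum(h), sum(rec$direction == d))
  }
  # a DMR called in opposite directions keeps both observations
  carr <- list(a = list(direction = "hypo", patients = "P1"))
  cmp <- data.frame(comparison_id = c("P1_cmp", "P2_cmp"),
                    sample_ref = c("P1_N", "P2_N"),
                    sample_alt = c("P1_T", "P2_T"),
                    type = "matched", patient_id = c("P1", "P2"))
  calls <- data.frame(comparison_id = c("P1_cmp", "P2_cmp"),
                      chrom = "chr1", bin = 4L, q_value = 1e-6,
                      direction = c("hypo", "hyper"))
  cb <- buildCatalog(calls, cmp)
  rec2 <- recurrence(cb)
  expect_equal(nrow(rec2), 2)
  expect_equal(sort(rec2$direction), c("hyper", "hypo"))
  expect_equal(rec2$n_patients, c(1L, 1L))
})
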