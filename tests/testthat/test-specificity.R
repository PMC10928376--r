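test_that("category rules validate their membership sets", {
  expect_error(categoryRule("x", c("P1", "P2"), c("P2")), "overlap")
  expect_error(categoryRule("x", "P1", "P2", lenient = "P3"),
               "lenient")
  expect_error(categoryRule("x", c("P1", "P2"), "P3",
                            min_members_with_dmr = 3), "exceeds")
  r <- categoryRule("x", c("P1", "P2"), "P3", lenient = "P2")
  expect_equal(r$min_members_with_dmr, 1L) # lenient excluded from default
})

test_that("exclusive DMRs respect carriage, absence and leniency", {
  pts <- sprintf("P%d", 1:7) # P1,P2 never; P3-P6 smoker; P7 unconfirmed
  carriage <- list(
    both_nevers = list(direction = "hypo",
                       patients = c("P1", "P2", "P7")),
    leaky = list(direction = "hypo",
                 patients = c("P3", "P4", "P5", "P1")),
    smoker3 = list(direction = "hyper", patients = c("P3", "P4", "P5")),
    wrong_dir = list(direction = "hyper", patients = c("P1", "P2")))
  cat_ <- craftCatalog(carriage, pts)
  never_rule <- categoryRule("never", c("P1", "P2"),
                             sprintf("P%d", 3:6), ignore = "P7")
  ex <- findExclusiveDMRs(cat_, never_rule)
  # DMR in both never-smokers, no smoker, unconfirmed carrier ignored:
  # exclusive in both directions' tables independently
  expect_equal(nrow(ex[ex$direction == "hypo", ]), 1)
  # the hyper wrong_dir DMR is never-exclusive too (hyper direction)
  expect_equal(nrow(ex[ex$direction == "hyper", ]), 1)

  smoker_rule <- categoryRule("smoker", sprintf("P%d", 3:6),
                              c("P1", "P2"), min_members_with_dmr = 3,
                              ignore = "P7")
  exs <- findExclusiveDMRs(cat_, smoker_rule)
  # 'leaky' is in 3 smokers but also a never-smoker -> not specific;
  # 'smoker3' is in exactly 3 smokers and no never -> specific
  expect_equal(nrow(exs), 1)
  expect_equal(exs$direction, "hyper")
  expect_equal(exs$n_members_with_dmr, 3L)

  # leniency: subtype pair {P1, P4999-like P2}; DMR in P1 only counts
  sub_rule <- categoryRule("acinar", c("P1", "P2"),
                           sprintf("P%d", 3:7), lenient = "P2")
  carr2 <- list(only_p1 = list(direction = "hyper", patients = "P1"))
  ex2 <- findExclusiveDMRs(craftCatalog(carr2, pts), sub_rule)
  expect_equal(nrow(ex2), 1)
  # without leniency the same DMR fails the carriage floor
  sub_strict <- categoryRule("acinar", c("P1", "P2"),
                             sprintf("P%d", 3:7))
  expect_equal(nrow(findExclusiveDMRs(craftCatalog(carr2, pts),
                                      sub_strict)), 0)

  expect_error(findExclusiveDMRs(cat_,
    categoryRule("bad", "P99", "P1")), "unknown patient")
})

test_that("label assignment enumeration matches multinomial counts", {
  pts6 <- sprintf("P%d", 1:6)
  a <- enumerateLabelAssignments(pts6, rep(c("never", "smoker"),
                                           c(2, 4)))
  expect_equal(nrow(a), 15) # C(6,2)
  expect_equal(ncol(a), 6)
  expect_false(any(duplicated(a)))

  pts10 <- sprintf("P%d", 1:10)
  b <- enumerateLabelAssignments(pts10, rep(c("m", "o"), c(2, 8)))
  expect_equal(nrow(b), 45) # all patient pairs

  c2 <- enumerateLabelAssignments(c("A", "B"), c("x", "y"))
  expect_equal(nrow(c2), 2)

  # multinomial coefficient for a 3-label multiset
  d <- enumerateLabelAssignments(sprintf("P%d", 1:5),
                                 c("a", "a", "b", "b", "c"))
  expect_equal(nrow(d), factorial(5) / (2 * 2 * 1))

  expect_error(enumerateLabelAssignments(sprintf("P%d", 1:30),
                                         rep(c("a", "b"), 15), cap = 100),
               "cap")
})

test_that("the observed count sits inside the exhaustive null support", {
  pts <- sprintf("P%d", 1:6)
  set.seed(21)
  carriage <- lapply(seq_len(12), function(i)
    list(direction = sample(c("hypo", "hyper"), 1),
         patients = sample(pts, sample(1:4, 1))))
  names(carriage) <- paste0("d", seq_len(12))
  cat_ <- craftCatalog(carriage, pts)
  rule <- categoryRule("never", c("P1", "P2"), sprintf("P%d", 3:6))
  pn <- permutationNull(cat_, rule)
  expect_equal(pn$n_permutations, 15)
  idn <- apply(pn$assignments, 1, function(a)
    setequal(colnames(pn$assignments)[a == "never"], c("P1", "P2")))
  expect_equal(sum(idn), 1)
  # identity labeling reproduces the observed count inside the null
  expect_equal(unname(pn$null[idn, ]), unname(pn$observed))
})

test_that("normal-lung field-effect DMRs are categorized and tiered", {
  man <- toyManifest(4, smoking = c("never", "never", "smoker",
                                    "smoker"))
  cmp <- enumerateComparisons(man)
  nn <- cmp[cmp$type == "normal_normal", ]
  id_of <- function(a, b) nn$comparison_id[
    (nn$sample_ref == a & nn$sample_alt == b) |
    (nn$sample_ref == b & nn$sample_alt == a)]
  mk <- function(cid, bin) data.frame(comparison_id = cid,
                                      chrom = "chr1", bin = bin,
                                      q_value = 1e-6,
                                      direction = "hypo")
  # DMR 'a' (bin 1): in 3 never-vs-smoker comparisons spanning both
  # nevers, absent from the never-never comparison -> example tier
  calls <- rbind(
    mk(id_of("P1_N", "P3_N"), 1L), mk(id_of("P1_N", "P4_N"), 1L),
    mk(id_of("P2_N", "P3_N"), 1L),
    # DMR 'b' (bin 2): also in the never-never comparison -> excluded
    mk(id_of("P1_N", "P3_N"), 2L), mk(id_of("P1_N", "P4_N"), 2L),
    mk(id_of("P2_N", "P3_N"), 2L), mk(id_of("P1_N", "P2_N"), 2L),
    # DMR 'c' (bin 3): smoker-smoker only
    mk(id_of("P3_N", "P4_N"), 3L))
  res <- normalFieldEffectDMRs(calls, cmp, man)
  expect_equal(sort(unique(res$by_category$category)),
               c("never_never", "never_smoker", "smoker_smoker"))
  expect_equal(res$example_tier, "chr1:1")
  ps <- res$per_sample
  expect_equal(ps$vs_smoker[ps$sample == "P1_N"], 4) # bins 1,2 x {P3,P4}
})

test_that("window densities are DMR counts over CpG bins", {
  si <- c(chr1 = 400 * 500) # one chromosome = 400 bins
  cpg <- GRanges("chr1", IRanges(seq_len(400) * 500 - 250, width = 1))
  grid <- buildBinGrid(si, cpg, NULL)
  win <- makeWindows(si, 400 * 500)
  calls <- data.frame(comparison_id = "c1", chrom = "chr1",
                      bin = 0:3, q_value = 1e-6, direction = "hypo")
  d <- windowDensity(calls, win, grid)
  expect_equal(d$n_cpg_bins, 400)
  expect_equal(d$density, 0.01) # 4 / 400 = 1%
  # no DMRs -> no rows, and the dense matrix is all zero
  d0 <- windowDensity(calls[0, ], win, grid)
  expect_equal(nrow(d0), 0)
  expect_equal(sum(densityMatrix(d0, "hypo", "c1")), 0)
  # genome-wide density is count / background-bin total
  gw <- genomeWideDensity(calls, grid)
  expect_equal(gw$genome$density, 4 / length(backgroundBins(grid)))
})

test_that("hotspot detection combines recurrence and top-N clauses", {
  # 50 windows x 3 patients; window 1: 1.5% in two patients ->
  # recurrent clause; window 2: 2% in one patient but rank > 15 when
  # 15 other windows are denser -> we arrange ranks explicitly
  nwin <- 50
  windows <- GRanges("chr1", IRanges((seq_len(nwin) - 1) * 1000 + 1,
                                     width = 1000))
  base <- expand.grid(window_idx = seq_len(nwin),
                      comparison_id = c("c1", "c2", "c3"))
  base$chrom <- "chr1"
  base$start <- (base$window_idx - 1) * 1000 + 1
  base$end <- base$start + 999
  base$n_cpg_bins <- 100
  base$direction <- "hypo"
  base$density <- 0
  base$density[base$window_idx == 1] <- c(0.015, 0.015, 0)
  base$density[base$window_idx == 2] <- c(0.02, 0, 0)
  # windows 3..20 dense in one patient only (rank fodder above 2%)
  for (wi in 3:20)
    base$density[base$window_idx == wi & base$comparison_id == "c1"] <-
      0.05
  # window 21 at 0.5% everywhere: below threshold but rank among top
  base$density[base$window_idx == 21] <- 0.005
  base$n_dmrs <- round(base$density * base$n_cpg_bins)
  base <- base[base$density > 0, ]
  attr(base, "windows") <- windows
  attr(base, "n_cpg_bins") <- rep(100, nwin)

  hs <- detectHotspots(base, "hypo")
  w1 <- hs[hs$window == "chr1:1-1000", ]
  expect_equal(nrow(w1), 1)
  expect_true(w1$by_recurrence)
  # window 2: single patient above 1%, rank 19 of top-15 fodder -> out
  expect_false("chr1:1001-2000" %in% hs$window)
  # recurrence clause alone when topN disabled
  hs0 <- detectHotspots(base, "hypo", analysisConfig(hotspotTopN = 0))
  expect_equal(hs0$window, c("chr1:1-1000"))
  # top-N clause rescues a below-threshold window when slots remain
  # (20 windows carry higher max density than window 21)
  hs_all <- detectHotspots(base, "hypo",
                           analysisConfig(hotspotTopN = 21))
  expect_true("chr1:20001-21000" %in% hs_all$window)
  expect_true(hs_all$by_topn[hs_all$window == "chr1:20001-21000"])
})

test_that("exclusive DMRs are located within dense windows", {
  windows <- GRanges("chr1", IRanges(c(1, 1001), width = 1000))
  d <- data.frame(window_idx = c(1L, 2L), chrom = "chr1",
                  start = c(1, 1001), end = c(1000, 2000),
                  n_cpg_bins = 2, comparison_id = "c1",
                  direction = "hypo", n_dmrs = c(1, 0),
                  density = c(0.5, 0))
  attr(d, "windows") <- windows
  ex <- GRanges("chr1", IRanges(c(101, 1101, 1201, 1301), width = 10))
  expect_equal(exclusiveInHotspotsFraction(ex, d, "c1", "hypo"), 0.25)
  expect_equal(exclusiveInHotspotsFraction(ex[1], d, "c1", "hypo"), 1.0)
  expect_equal(exclusiveInHotspotsFraction(ex[2], d, "c1", "hypo"), 0.0)
  expect_true(is.na(exclusiveInHotspotsFraction(ex[0], d, "c1",
                                                "hypo")))
})

test_that("window feature profiles normalize by window length", {
  win <- GRanges("chr1", IRanges(1, 1e6))
  cpgs <- GRanges("chr1", IRanges(seq_len(1000) * 900, width = 1))
  reps <- GRanges("chr1", IRanges(1, 1e6)) # fully repeat-covered
  mcols(reps)$subfamily <- "X"
  tx <- GRanges("chr1", IRanges(c(1000, 5000), width = 2000),
                strand = "+")
  mcols(tx) <- DataFrame(transcript_id = c("T1", "T2"),
                         gene_id = c("G1", "G1"),
                         gene_name = "G", biotype = "protein_coding")
  seg <- GRanges("chr1", IRanges(c(1, 400001), c(400000, 1e6)))
  mcols(seg)$state <- c("18_Quies", "1_TssA")
  prof <- windowFeatureProfile(win, cpgs, tx, reps, seg)
  expect_equal(prof$repeat_density, 1.0)
  expect_equal(prof$cpg_density, 0.001)
  expect_equal(prof$gene_density, 1 / 1e6)
  expect_equal(prof$transcript_density, 2 / 1e6)
  state_cols <- grep("^state_", names(prof), value = TRUE)
  expect_equal(sum(prof[, state_cols]), 1)
})

test_that("feature/density correlations recover planted relations", {
  set.seed(13)
  n <- 60
  f1 <- runif(n)
  prof <- data.frame(window = paste0("w", 1:n), f_density = f1,
                     f_noise = runif(n))
  dm <- cbind(c1 = f1, c2 = runif(n)) # density c1 equals feature f1
  rownames(dm) <- prof$window
  res <- correlateDensityFeatures(prof, dm)
  expect_equal(unname(res$correlations["f_density", "c1"]), 1)
  expect_lt(abs(res$correlations["f_noise", "c1"]), 0.4)
  expect_equal(sum(res$pca$variance_share), 1)
  # r is symmetric in its arguments
  expect_equal(unname(cor(f1, dm[, "c2"])),
               unname(cor(dm[, "c2"], f1)))
})
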