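test_that("log odds ratio satisfies its identities", {
  expect_equal(logOddsRatio(0.5, 0.5), 0)
  set.seed(3)
  p <- runif(50, 0.01, 0.99); q <- runif(50, 0.01, 0.99)
  expect_equal(logOddsRatio(p, p), rep(0, 50))
  expect_equal(logOddsRatio(p, q), -logOddsRatio(q, p))
})

test_that("feature LOR matches the closed form and corrects zero cells", {
  w <- 500L
  mkbins <- function(n, offset = 0)
    GRanges("chr1", IRanges(offset + (seq_len(n) - 1) * w + 1, width = w))
  dmr <- mkbins(100)
  bg <- mkbins(1000, offset = 1e6)
  # feature covering the first 80 DMR bins and the first 500 bg bins:
  # 80/100 vs 500/1000 -> lor = ln 4
  feat <- GRanges("chr1", IRanges(c(1, 1e6 + 1), c(80 * w, 1e6 + 500 * w)))
  r <- featureLOR(dmr, feat, bg)
  expect_equal(r$lor, log(4), tolerance = 1e-12)

  # pD = pB -> 0
  feat2 <- GRanges("chr1", IRanges(1, 50 * w))
  bg2 <- mkbins(100)
  expect_equal(featureLOR(dmr, feat2, bg2)$lor, 0)

  # zero overlap on the DMR side: finite negative via +0.5 on all cells
  dmr0 <- mkbins(100, offset = 2e6)
  r0 <- featureLOR(dmr0,
                   GRanges("chr1", IRanges(1e6 + 1, 1e6 + 500 * w)), bg)
  want <- log((0.5 / 100.5) / (500.5 / 500.5))
  expect_equal(r0$lor, want)
  expect_true(is.finite(r0$lor) && r0$lor < 0)

  expect_error(featureLOR(GRanges(), feat, bg), "empty")
})

test_that("uniformly planted DMRs show no feature enrichment at scale", {
  # invariance check: sampling DMRs uniformly from the background makes
  # every feature LOR shrink toward 0
  set.seed(41)
  w <- 500L
  bg <- GRanges("chr1", IRanges((seq_len(20000) - 1) * w + 1, width = w))
  feat <- GRanges("chr1", IRanges(1, 6000 * w)) # 30% of background
  dmr <- bg[sample.int(length(bg), 10000)]
  r <- featureLOR(dmr, feat, bg)
  expect_lt(abs(r$lor), 0.1)
})

test_that("repeat class composition counts elements (or bases)", {
  mk <- function(cls, n, w = 100) {
    gr <- GRanges("chr1", IRanges(seq_len(n) * 1000, width = w))
    mcols(gr)$repeat_class <- cls
    gr
  }
  allr <- c(mk("SINE", 50), mk("LINE", 50, w = 300))
  dmrr <- c(mk("SINE", 8), mk("LINE", 2, w = 300))
  comp <- repeatClassComposition(dmrr, allr)
  expect_equal(comp$genome_prop, c(0.5, 0.5))
  expect_equal(comp$dmr_prop[comp$repeat_class == "SINE"], 0.8)
  expect_equal(sum(comp$dmr_prop), 1)
  # base-weighted option
  compb <- repeatClassComposition(dmrr, allr, by = "base")
  expect_equal(compb$genome_prop[compb$repeat_class == "LINE"],
               50 * 300 / (50 * 100 + 50 * 300))
  # degenerate: no DMR-overlapping repeats
  expect_warning(c0 <- repeatClassComposition(allr[0], allr), "no DMR")
  expect_equal(sum(c0$dmr_prop), 0)

  # all repeats one class -> both distributions concentrate
  s <- repeatClassComposition(mk("SINE", 3), mk("SINE", 10))
  expect_equal(s$genome_prop, 1)
  expect_equal(s$dmr_prop, 1)
})

test_that("subfamily LOR uses DMR proportion vs repeat-length share", {
  # subfamily occupies 1% of repeat bases; 5/50 DMRs overlap it:
  # lor = ln[(0.1/0.9) / (0.01/0.99)]
  allr <- GRanges("chr1", IRanges(c(1, 100001), c(100, 109900)))
  mcols(allr)$subfamily <- c("SUBF", "OTHER")
  dmr_on <- GRanges("chr1", IRanges(seq(1, 81, 20), width = 10))  # 5 hit
  dmr_off <- GRanges("chr1", IRanges(2e5 + seq_len(45) * 1000,
                                     width = 10))
  dmrs <- c(dmr_on, dmr_off)
  r <- repeatSubfamilyLOR(dmrs, "SUBF", allr)
  expect_equal(r$dmr_count, 5L)
  expect_equal(r$lor, log((0.1 / 0.9) / (0.01 / 0.99)),
               tolerance = 1e-12)
  expect_equal(r$lor, 2.3979, tolerance = 1e-4)

  # pD == pB -> 0: subfamily is 50% of repeat bp, 25 of 50 DMRs hit
  allr2 <- GRanges("chr1", IRanges(c(1, 50001), width = 5000))
  mcols(allr2)$subfamily <- c("HALF", "OTHER")
  dmrs2 <- GRanges("chr1", IRanges(c(seq_len(25) * 100,
                                     3e4 + seq_len(25) * 100),
                                   width = 10))
  expect_equal(repeatSubfamilyLOR(dmrs2, "HALF", allr2)$lor, 0)

  expect_error(repeatSubfamilyLOR(dmrs, "NOPE", allr), "no elements")

  # reporting filter: a subfamily overlapping exactly 5 DMRs is excluded
  # ("more than 5" is strict)
  tab <- repeatSubfamilyEnrichment(dmrs, allr)
  expect_false("SUBF" %in% tab$unit_name)
  dmr6 <- c(GRanges("chr1", IRanges(seq(1, 96, 19)[1:6], width = 3)),
            dmr_off)
  tab6 <- repeatSubfamilyEnrichment(dmr6, allr)
  expect_true("SUBF" %in% tab6$unit_name)
})

test_that("Jukes-Cantor distance matches the closed form", {
  expect_equal(jukesCantorDistance(0), 0)
  expect_equal(jukesCantorDistance(0.1), 0.10732, tolerance = 1e-4)
  expect_equal(jukesCantorDistance(0.1),
               -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  # small-p linearity: d ~ p
  p <- c(1e-4, 1e-3, 5e-3)
  expect_equal(jukesCantorDistance(p), p, tolerance = 1e-2)
  # domain edge
  expect_warning(d <- jukesCantorDistance(c(0.2, 0.75)), "excluded")
  expect_true(is.na(d[2]))
  # strictly increasing on [0, 0.75)
  grid <- seq(0, 0.74, by = 0.01)
  expect_true(all(diff(jukesCantorDistance(grid)) > 0))
})

test_that("subfamily divergence summarizes the median distance", {
  gr <- GRanges("chr1", IRanges(c(1, 100, 200), width = 50))
  mcols(gr)$subfamily <- c("A", "A", "B")
  mcols(gr)$div_p <- c(0.1, 0.3, NA)
  div <- subfamilyDivergence(gr)
  a <- div[div$subfamily == "A", ]
  expect_equal(a$median_jc,
               median(jukesCantorDistance(c(0.1, 0.3))))
  expect_true(is.na(div$median_jc[div$subfamily == "B"]))
})

test_that("composite state mapping follows the published groupings", {
  expect_equal(mapCompositeState("1_TssA", "18"), "active_regulatory")
  expect_equal(mapCompositeState("9_EnhA1", "18"), "active_regulatory")
  expect_equal(mapCompositeState("5", "18"), "transcribed")
  expect_equal(mapCompositeState("6_TxWk", "18"), "transcribed")
  expect_equal(mapCompositeState("14_TssBiv", "18"), "polycomb")
  expect_equal(mapCompositeState("17_ReprPCWk", "18"), "polycomb")
  expect_equal(mapCompositeState("18_Quies", "18"), "other")
  expect_equal(mapCompositeState("1_TssA", "15"), "active_regulatory")
  expect_equal(mapCompositeState("6_EnhG", "15"), "active_regulatory")
  expect_equal(mapCompositeState("4_Tx", "15"), "other")
  expect_error(mapCompositeState("42_Wat", "18"), "unknown")
})

test_that("methylation categories use strict 30/70 boundaries", {
  expect_equal(categorizeMethylationLevel(c(0.25, 0.30, 0.5, 0.70, 0.90)),
               c("hypomethylated", "intermediate", "intermediate",
                 "intermediate", "hypermethylated"))
})

test_that("ChromHMM composition partitions DMR bases", {
  seg <- GRanges("chr1", IRanges(c(1, 1001), c(1000, 2000)))
  mcols(seg)$state <- c("18_Quies", "1_TssA")
  bg <- GRanges("chr1", IRanges(c(1, 501, 1001), width = 500))
  # DMR fully inside one segment
  d1 <- GRanges("chr1", IRanges(101, 600))
  c1 <- chromhmmComposition(d1, seg, bg)
  expect_equal(c1$dmr_prop[c1$state == "18_Quies"], 1)
  # 500-bp DMR split 250/250 across the two states
  d2 <- GRanges("chr1", IRanges(751, 1250))
  c2 <- chromhmmComposition(d2, seg, bg)
  expect_equal(c2$dmr_prop[c2$state == "18_Quies"], 0.5)
  expect_equal(c2$dmr_prop[c2$state == "1_TssA"], 0.5)
  # proportions (with unannotated) always sum to 1
  d3 <- GRanges("chr1", IRanges(1901, 2400)) # 400 bp beyond segments
  c3 <- chromhmmComposition(d3, seg, bg)
  expect_equal(sum(c3$dmr_prop), 1)
  expect_equal(c3$dmr_prop[c3$state == "unannotated"], 0.8)
  expect_equal(c3$dmr_prop[c3$state == "1_TssA"], 0.2)
  expect_equal(sum(c3$bg_prop), 1)
})

test_that("exclusive feature categories follow promoter > genic", {
  prom <- GRanges("chr1", IRanges(1000, 2000))
  gene <- GRanges("chr1", IRanges(1500, 9000))
  dmrs <- GRanges("chr1", IRanges(c(1900, 5000, 50000), width = 500))
  expect_equal(classifyExclusiveFeature(dmrs, prom, gene),
               c("promoter", "genic", "intergenic"))
})

test_that("promoter switch detection needs opposite directions on
           multiple promoters in one comparison", {
  prom <- GRanges("chr1", IRanges(c(1000, 5000, 9000), width = 500))
  mcols(prom)$transcript_id <- c("T1", "T2", "T3")
  mcols(prom)$gene_id <- c("G1", "G1", "G2")
  mkcat <- function(calls) buildCatalog(calls, data.frame(
    comparison_id = unique(calls$comparison_id),
    sample_ref = "N", sample_alt = "T", type = "matched",
    patient_id = unique(calls$comparison_id)))
  # promoter T1 hyper + T2 hypo in c1 -> G1 reported once
  calls <- data.frame(comparison_id = "c1", chrom = "chr1",
                      bin = c(2L, 10L), q_value = 1e-6,
                      direction = c("hyper", "hypo"))
  sw <- detectPromoterSwitches(mkcat(calls), prom)
  expect_equal(sw$gene_id, "G1")
  expect_equal(sw$n_comparisons, 1L)
  expect_equal(sw$tier, "single")
  # only hyperDMRs in two promoters -> nothing
  calls2 <- transform(calls, direction = "hyper")
  expect_equal(nrow(detectPromoterSwitches(mkcat(calls2), prom)), 0)
  # both directions on a single promoter -> nothing
  calls3 <- data.frame(comparison_id = "c1", chrom = "chr1",
                       bin = c(2L, 2L), q_value = 1e-6,
                       direction = c("hyper", "hypo"))
  expect_equal(nrow(detectPromoterSwitches(mkcat(calls3), prom)), 0)
  # recurrent across two comparisons -> recurrent tier
  calls4 <- rbind(calls, transform(calls, comparison_id = "c2"))
  sw4 <- detectPromoterSwitches(mkcat(calls4), prom)
  expect_equal(sw4$tier, "recurrent")
})

test_that("subfamily methylation profiles use unique CpGs with a floor", {
  # subfamily A: two overlapping elements sharing CpGs; 10 unique CpGs
  # subfamily B: 9 CpGs -> excluded
  a1 <- GRanges("chr1", IRanges(1, 500))
  a2 <- GRanges("chr1", IRanges(301, 800))
  b <- GRanges("chr2", IRanges(1, 500))
  reps <- suppressWarnings(c(a1, a2, b))
  mcols(reps)$subfamily <- c("A", "A", "B")
  posA <- seq(50, 500, by = 50)      # 10 CpGs, some inside both elements
  posB <- seq(50, 450, by = 50)      # 9 CpGs
  manifest <- toyManifest(1)
  tracks <- list(
    P1_N = suppressWarnings(c(toyTrack(posA, rep(0.9, 10)),
             toyTrack(posB, rep(0.5, 9), chrom = "chr2"))),
    P1_T = suppressWarnings(c(toyTrack(posA, rep(0.4, 10)),
             toyTrack(posB, rep(0.5, 9), chrom = "chr2"))))
  prof <- subfamilyMethylationProfile(reps, tracks, manifest)
  expect_equal(rownames(prof$means), "A") # B fell under the CpG floor
  expect_equal(unname(prof$means["A", "P1_N"]), 0.9)
  ct <- prof$contrasts
  expect_equal(ct$n_cpgs, 10L) # shared CpGs counted once
  expect_equal(ct$median_normal, 0.9)
  expect_equal(ct$median_delta, -0.5)
})
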