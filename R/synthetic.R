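#' Default synthetic cohort manifest
#'
#' Mirrors the published study design: 10 patients with matched
#' normal/tumor pairs and 7 additional tumor-only patients (17 tumors, 10
#' normals); among the matched patients two are confirmed never-smokers,
#' four confirmed smokers and four unconfirmed; five are stage 1A, three
#' stage 3A, two unconfirmed; two tumor-subtype pairs (acinar cell
#' carcinoma and adenosquamous carcinoma) sit among the matched patients.
#'
#' @return manifest data.frame (see \code{\link{readManifest}}).
#' @export
defaultCohort <- function() {
  matched <- sprintf("P%02d", 1:10)
  extra <- sprintf("P%02d", 11:17)
  smoking <- c("never", "never", "smoker", "smoker", "smoker", "smoker",
               rep("unconfirmed", 4))
  stage <- c(rep("1A", 5), rep("3A", 3), rep("unconfirmed", 2))
  subtype <- rep("LUAD", 10)
  subtype[c(4, 7)] <- "acinar cell carcinoma"
  subtype[c(5, 10)] <- "adenosquamous carcinoma"
  rows <- rbind(
    data.frame(sample_id = paste0(matched, "_N"), patient_id = matched,
               malignancy = "normal", smoking = smoking, stage = stage,
               subtype = subtype),
    data.frame(sample_id = paste0(matched, "_T"), patient_id = matched,
               malignancy = "tumor", smoking = smoking, stage = stage,
               subtype = subtype),
    data.frame(sample_id = paste0(extra, "_T"), patient_id = extra,
               malignancy = "tumor", smoking = "unconfirmed",
               stage = "unconfirmed", subtype = "LUAD"))
  rows$purity <- NA_real_
  rownames(rows) <- NULL
  rows
}

#' Built-in repeat subfamily catalogue for the generator
#'
#' One row per subfamily: class, family, name, typical element length,
#' milliDiv location and sampling weight. Mixes young (AluY, L1HS) and
#' diverged (L1M5, MER52A) transposable elements with non-TE repeat
#' classes.
#' @return data.frame.
#' @export
defaultSubfamilies <- function() {
  data.frame(
    repeat_class = c("SINE", "SINE", "LINE", "LINE", "LTR", "LTR",
                     "DNA", "Simple_repeat", "Low_complexity"),
    family = c("Alu", "Alu", "L1", "L1", "ERV1", "ERV1", "hAT-Charlie",
               "Simple_repeat", "Low_complexity"),
    subfamily = c("AluY", "AluSx", "L1HS", "L1M5", "LTR12C", "MER52A",
                  "MER5A", "(CA)n", "AT_rich"),
    length = c(300, 300, 900, 600, 1200, 400, 200, 100, 150),
    milli_div = c(30, 120, 20, 300, 120, 250, 180, 10, 10),
    # abundances roughly follow the real repeat landscape: Alu dominant,
    # ERV1 subfamilies (LTR12C, MER52A) rare
    weight = c(0.25, 0.25, 0.08, 0.12, 0.01, 0.05, 0.08, 0.08, 0.08))
}

#' Default 18-state segment frequencies
#'
#' Quiescent-dominated state mix resembling somatic tissue ChromHMM
#' segmentations.
#' @return named numeric vector summing to 1 over the 18-state labels.
#' @export
defaultStateFreqs <- function() {
  c("1_TssA" = 0.03, "2_TssFlnk" = 0.01, "3_TssFlnkU" = 0.01,
    "4_TssFlnkD" = 0.01, "5_Tx" = 0.05, "6_TxWk" = 0.12,
    "7_EnhG1" = 0.01, "8_EnhG2" = 0.01, "9_EnhA1" = 0.04,
    "10_EnhA2" = 0.02, "11_EnhWk" = 0.06, "12_ZNF/Rpts" = 0.02,
    "13_Het" = 0.07, "14_TssBiv" = 0.02, "15_EnhBiv" = 0.02,
    "16_ReprPC" = 0.03, "17_ReprPCWk" = 0.04, "18_Quies" = 0.43)
}

#' Synthetic dataset generator configuration
#'
#' Defines the toy genome (chromosome lengths, CpG background and island
#' rates, transcript, repeat, chromatin-state and blacklist layers), the
#' cohort, and the planted ground truth: recurrent hypo/hyper DMRs,
#' smoking- and subtype-specific DMRs, per-patient private DMRs,
#' density-hotspot windows, a repeat subfamily targeted for
#' hypomethylation, the methylation effect size, measurement noise, the
#' caller false-positive rate per background bin, and the generative
#' q-value models (planted calls: q ~ U(0, 1e-5); false positives:
#' q ~ U(0, q threshold)).
#'
#' The defaults define the standing simulation conditions used throughout
#' the package's validation: a 8.4-Mb five-chromosome genome, a
#' 17-tumor/10-normal cohort mirroring the study design, planted effect
#' size 0.4, noise sd 0.05, and false-positive rate 1e-3.
#'
#' @slot chromLengths named numeric vector of chromosome lengths (bp).
#' @slot cpgBackgroundRate CpGs per bp outside islands.
#' @slot islandCount CpG island clusters per chromosome.
#' @slot islandLength island length (bp).
#' @slot islandCpgRate CpGs per bp inside islands.
#' @slot cgiFraction fraction of islands annotated as CGIs.
#' @slot promoterCgiFraction fraction of transcripts whose TSS is placed
#'   on a CGI.
#' @slot nTranscripts number of transcripts.
#' @slot nRepeats number of repeat elements.
#' @slot subfamilies subfamily catalogue data.frame.
#' @slot segMeanLength mean chromatin segment length (bp).
#' @slot stateFreqs named state frequencies (18-state model).
#' @slot blacklistPerChrom,blacklistLength blacklist regions per
#'   chromosome and their length.
#' @slot cohort manifest data.frame.
#' @slot nRecurrentHypo,nRecurrentHyper planted recurrent DMRs per
#'   direction.
#' @slot recurrenceRange integer range of patients carrying a recurrent
#'   DMR.
#' @slot nNeverSpecific,nSmokerSpecific,nSubtypeSpecific planted
#'   category-specific DMRs.
#' @slot nPrivatePerPatient planted single-patient DMRs.
#' @slot nHotspots,hotspotRate,hotspotPatients,hotspotWidth hotspot
#'   windows: count, within-window planting rate over CpG bins, carrying
#'   patients, window width.
#' @slot targetSubfamily,targetFraction repeat subfamily targeted for
#'   hypomethylation and the fraction of recurrent hypoDMRs placed on it.
#' @slot delta planted methylation change.
#' @slot noiseSd per-CpG measurement noise sd.
#' @slot fpr caller false-positive rate per background bin per
#'   comparison.
#' @slot qPlantedMax,qFpMax upper bounds of the generative q models.
#' @slot repeatDownshift global tumor methylation loss over repeats.
#' @export
setClass("GeneratorConfig",
  representation(
    chromLengths = "numeric", cpgBackgroundRate = "numeric",
    islandCount = "integer", islandLength = "integer",
    islandCpgRate = "numeric", cgiFraction = "numeric",
    promoterCgiFraction = "numeric", nTranscripts = "integer",
    nRepeats = "integer", subfamilies = "data.frame",
    segMeanLength = "integer", stateFreqs = "numeric",
    blacklistPerChrom = "integer", blacklistLength = "integer",
    cohort = "data.frame",
    nRecurrentHypo = "integer", nRecurrentHyper = "integer",
    recurrenceRange = "integer",
    nNeverSpecific = "integer", nSmokerSpecific = "integer",
    nSubtypeSpecific = "integer", nPrivatePerPatient = "integer",
    nHotspots = "integer", hotspotRate = "numeric",
    hotspotPatients = "integer", hotspotWidth = "numeric",
    targetSubfamily = "character", targetFraction = "numeric",
    delta = "numeric", noiseSd = "numeric", fpr = "numeric",
    qPlantedMax = "numeric", qFpMax = "numeric",
    repeatDownshift = "numeric"),
  prototype(
    chromLengths = c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6, chrX = 2e6,
                     chrY = 4e5),
    cpgBackgroundRate = 0.008, islandCount = 25L, islandLength = 1000L,
    islandCpgRate = 0.08, cgiFraction = 0.8,
    promoterCgiFraction = 0.6, nTranscripts = 240L,
    nRepeats = 2500L, subfamilies = defaultSubfamilies(),
    segMeanLength = 2000L, stateFreqs = defaultStateFreqs(),
    blacklistPerChrom = 4L, blacklistLength = 5000L,
    cohort = defaultCohort(),
    nRecurrentHypo = 30L, nRecurrentHyper = 30L,
    recurrenceRange = c(2L, 6L),
    nNeverSpecific = 8L, nSmokerSpecific = 8L, nSubtypeSpecific = 6L,
    nPrivatePerPatient = 15L,
    nHotspots = 2L, hotspotRate = 0.05, hotspotPatients = 2L,
    hotspotWidth = 1e6,
    targetSubfamily = "LTR12C", targetFraction = 0.3,
    delta = 0.4, noiseSd = 0.05, fpr = 1e-3,
    qPlantedMax = 1e-5, qFpMax = 1e-3,
    repeatDownshift = 0.05))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  rates <- c(object@cpgBackgroundRate, object@islandCpgRate,
             object@cgiFraction, object@promoterCgiFraction,
             object@hotspotRate, object@targetFraction, object@fpr)
  if (any(rates < 0 | rates > 1)) msg <- c(msg, "rates must be in [0,1]")
  if (any(object@chromLengths <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (object@nRepeats > 0 &&
      sum(object@chromLengths) < max(object@subfamilies$length))
    msg <- c(msg, "repeats exceed genome size")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneratorConfig
#' @param ... named slot overrides.
#' @return A \linkS4class{GeneratorConfig}.
#' @export
generatorConfig <- function(...) {
  args <- list(...)
  ints <- c("islandCount", "islandLength", "nTranscripts", "nRepeats",
            "segMeanLength", "blacklistPerChrom", "blacklistLength",
            "nRecurrentHypo", "nRecurrentHyper", "recurrenceRange",
            "nNeverSpecific", "nSmokerSpecific", "nSubtypeSpecific",
            "nPrivatePerPatient", "nHotspots", "hotspotPatients")
  for (nm in ints)
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c("GeneratorConfig", args))
}

#' Generate the synthetic reference layers
#'
#' Deterministically (given the seed) generates chromosome sizes, CpG
#' positions (uniform background plus dense island clusters), a CGI BED
#' (a subset of the islands), a transcript table (a configurable fraction
#' of TSSs placed on CGIs so that promoters overlap them), a RepeatMasker
#' style repeat table, an 18-state chromatin segmentation mosaic, and a
#' blacklist.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param seed integer master seed.
#' @return list: \code{seqinfo, cpgs, cgis, transcripts, repeats,
#'   segmentation, blacklist}.
#' @export
generateReference <- function(config = generatorConfig(), seed = 1) {
  set.seed(subSeeds(seed, 4)[1])
  si <- asSeqinfo(config@chromLengths)
  chroms <- seqlevels(si)
  lens <- seqlengths(si)
  cpg_list <- list(); island_list <- list()
  for (ch in chroms) {
    len <- lens[[ch]]
    n_bg <- rpois(1, config@cpgBackgroundRate * len)
    bg <- sort(sample.int(len, min(n_bg, len)))
    n_isl <- config@islandCount
    isl_start <- sort(sample.int(max(1, len - config@islandLength),
                                 n_isl))
    isl <- GRanges(ch, IRanges(isl_start,
                               width = config@islandLength))
    isl <- reduce(isl)
    ipos <- unlist(lapply(seq_along(isl), function(i) {
      w <- width(isl)[i]
      n <- rpois(1, config@islandCpgRate * w)
      start(isl)[i] - 1L + sort(sample.int(w, min(n, w)))
    }))
    pos <- sort(unique(c(bg, ipos)))
    cpg_list[[ch]] <- GRanges(ch, IRanges(pos, width = 1))
    island_list[[ch]] <- isl
  }
  cpgs <- suppressWarnings(do.call(c, unname(cpg_list)))
  islands <- suppressWarnings(do.call(c, unname(island_list)))
  n_cgi <- round(config@cgiFraction * length(islands))
  cgis <- sortGenomic(islands[sort(sample.int(length(islands),
                                              n_cgi))])
  # transcripts: fraction with TSS on a CGI
  nt <- config@nTranscripts
  on_cgi <- runif(nt) < config@promoterCgiFraction
  tx_chrom <- sample(chroms, nt, replace = TRUE,
                     prob = lens / sum(lens))
  strand <- sample(c("+", "-"), nt, replace = TRUE)
  tss <- integer(nt)
  for (i in seq_len(nt)) {
    len <- lens[[tx_chrom[i]]]
    if (on_cgi[i]) {
      cand <- cgis[as.character(seqnames(cgis)) == tx_chrom[i]]
      tss[i] <- if (length(cand))
        start(cand)[sample.int(length(cand), 1)] +
          sample.int(config@islandLength, 1) - 1L
      else sample.int(len, 1)
    } else tss[i] <- sample.int(len, 1)
    tss[i] <- min(max(tss[i], 5000L), len - 30000L)
  }
  tx_len <- pmax(1000L, round(rnorm(nt, 8000, 3000)))
  tx_start <- ifelse(strand == "+", tss, pmax(1L, tss - tx_len))
  tx_end <- ifelse(strand == "+",
                   pmin(tss + tx_len, lens[tx_chrom] - 1L), tss)
  # ~2/3 of genes have one transcript; the rest share a gene id with the
  # next transcript on the same chromosome (multi-promoter genes)
  gene_id <- sprintf("G%04d", cumsum(runif(nt) > 0.3))
  biotype <- sample(c("protein_coding", "lincRNA", "antisense", "miRNA"),
                    nt, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
  transcripts <- GRanges(tx_chrom, IRanges(pmin(tx_start, tx_end) + 1L,
                                           pmax(tx_start, tx_end)),
                         strand = strand)
  mcols(transcripts) <- DataFrame(
    transcript_id = sprintf("T%04d", seq_len(nt)),
    gene_id = gene_id,
    gene_name = paste0("GENE", gene_id), biotype = biotype)
  transcripts <- sortGenomic(transcripts)
  # repeats
  nr <- config@nRepeats
  repeats <- GRanges()
  if (nr > 0) {
    sf <- config@subfamilies
    pick <- sample.int(nrow(sf), nr, replace = TRUE, prob = sf$weight)
    r_chrom <- sample(chroms, nr, replace = TRUE,
                      prob = lens / sum(lens))
    r_len <- pmax(50L, round(rnorm(nr, sf$length[pick],
                                   sf$length[pick] * 0.2)))
    r_start <- vapply(seq_len(nr), function(i)
      sample.int(max(1L, lens[[r_chrom[i]]] - r_len[i]), 1), integer(1))
    milli <- clip01(rnorm(nr, sf$milli_div[pick], 25), 0, 740) # per kb
    repeats <- GRanges(r_chrom, IRanges(r_start, width = r_len),
                       strand = sample(c("+", "-"), nr, replace = TRUE))
    mcols(repeats) <- DataFrame(
      subfamily = sf$subfamily[pick], family = sf$family[pick],
      repeat_class = sf$repeat_class[pick], div_p = milli / 1000,
      is_TE = sf$repeat_class[pick] %in% teClasses())
    repeats <- sortGenomic(repeats)
  }
  # chromatin-state mosaic
  seg_list <- list()
  freqs <- config@stateFreqs / sum(config@stateFreqs)
  for (ch in chroms) {
    len <- lens[[ch]]
    n_seg <- ceiling(len / config@segMeanLength) + 10L
    w <- pmax(200L, rpois(n_seg, config@segMeanLength))
    ends <- cumsum(w); ends <- ends[ends < len]
    starts <- c(1L, ends + 1L); ends <- c(ends, len)
    st <- sample(names(freqs), length(starts), replace = TRUE,
                 prob = freqs)
    g <- GRanges(ch, IRanges(starts, ends))
    mcols(g)$state <- st
    seg_list[[ch]] <- g
  }
  segmentation <- suppressWarnings(do.call(c, unname(seg_list)))
  # blacklist
  bl_list <- list()
  for (ch in chroms) {
    len <- lens[[ch]]
    s <- sort(sample.int(max(1L, len - config@blacklistLength),
                         config@blacklistPerChrom))
    bl_list[[ch]] <- GRanges(ch, IRanges(s,
                                         width = config@blacklistLength))
  }
  blacklist <- reduce(suppressWarnings(do.call(c, unname(bl_list))))
  list(seqinfo = si, cpgs = cpgs, cgis = cgis, transcripts = transcripts,
       repeats = repeats, segmentation = segmentation,
       blacklist = blacklist)
}

#' Plant the synthetic ground truth
#'
#' Samples disjoint background bins for the planted DMR layers: recurrent
#' hypo/hyper DMRs carried by 2-6 patients (a configurable fraction of
#' the recurrent hypoDMRs placed over the targeted repeat subfamily),
#' never-smoker- and smoker-specific DMRs, subtype-specific DMRs
#' (adenosquamous members), per-patient private DMRs, and hotspot
#' windows in which a high fraction of CpG bins is planted in a fixed
#' pair of patients.
#'
#' @param reference from \code{\link{generateReference}}.
#' @param config a \linkS4class{GeneratorConfig}.
#' @param seed master seed (same stream family as the other generators).
#' @param analysis_config an \linkS4class{AnalysisConfig}.
#' @return list: \code{planted} (data.frame \code{chrom, bin, direction,
#'   type, patients} -- comma-separated patient ids), \code{hotspots}
#'   (data.frame of hotspot windows), \code{grid} (the
#'   \linkS4class{BinGrid}), \code{target_subfamily}.
#' @export
plantTruth <- function(reference, config = generatorConfig(), seed = 1,
                       analysis_config = analysisConfig()) {
  set.seed(subSeeds(seed, 4)[2])
  grid <- buildBinGrid(reference$seqinfo, reference$cpgs,
                       reference$blacklist, analysis_config)
  bg <- backgroundBins(grid)
  bg_key <- paste(as.character(seqnames(bg)), mcols(bg)$bin, sep = ":")
  manifest <- config@cohort
  matched <- intersect(
    manifest$patient_id[manifest$malignancy == "normal"],
    manifest$patient_id[manifest$malignancy == "tumor"])
  never <- unique(manifest$patient_id[manifest$smoking == "never" &
                                      manifest$patient_id %in% matched])
  smokers <- unique(manifest$patient_id[manifest$smoking == "smoker" &
                                        manifest$patient_id %in% matched])
  subtype_tab <- unique(manifest[manifest$patient_id %in% matched,
                                 c("patient_id", "subtype")])
  adsq <- subtype_tab$patient_id[subtype_tab$subtype ==
                                   "adenosquamous carcinoma"]
  used <- logical(length(bg))
  takeBins <- function(n, from = NULL) {
    pool <- which(!used)
    if (!is.null(from)) pool <- intersect(pool, from)
    n <- min(n, length(pool))
    ix <- if (n > 0) pool[sample.int(length(pool), n)] else integer(0)
    used[ix] <<- TRUE
    ix
  }
  rows <- list()
  addRows <- function(ix, direction, type, patients_list) {
    if (!length(ix)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = as.character(seqnames(bg))[ix],
      bin = mcols(bg)$bin[ix], direction = direction, type = type,
      patients = vapply(patients_list, paste, character(1),
                        collapse = ","))
  }
  # sharing decays steeply with patient count (most DMRs are found in
  # few patients): truncated geometric over the recurrence range
  rec_k <- seq(config@recurrenceRange[1], config@recurrenceRange[2])
  sampleRec <- function() sample(rec_k, 1,
                                 prob = 0.5^(seq_along(rec_k) - 1))
  # recurrent hypo, partly over the targeted subfamily
  n_target <- round(config@targetFraction * config@nRecurrentHypo)
  target_pool <- integer(0)
  if (length(reference$repeats)) {
    el <- reference$repeats[
      mcols(reference$repeats)$subfamily == config@targetSubfamily]
    target_pool <- which(overlapsAny(bg, el, ignore.strand = TRUE))
  }
  ix_t <- takeBins(n_target, target_pool)
  ix_u <- takeBins(config@nRecurrentHypo - length(ix_t))
  for (ix in c(ix_t, ix_u))
    addRows(ix, "hypo", "recurrent",
            list(sample(matched, sampleRec())))
  ix_h <- takeBins(config@nRecurrentHyper)
  for (ix in ix_h)
    addRows(ix, "hyper", "recurrent",
            list(sample(matched, sampleRec())))
  # category-specific
  if (length(never) >= 2 && config@nNeverSpecific > 0) {
    ix <- takeBins(config@nNeverSpecific)
    dirs <- sample(c("hypo", "hyper"), length(ix), replace = TRUE)
    for (i in seq_along(ix))
      addRows(ix[i], dirs[i], "never_specific", list(never))
  }
  if (length(smokers) >= 3 && config@nSmokerSpecific > 0) {
    ix <- takeBins(config@nSmokerSpecific)
    dirs <- sample(c("hypo", "hyper"), length(ix), replace = TRUE)
    for (i in seq_along(ix))
      addRows(ix[i], dirs[i], "smoker_specific", list(smokers))
  }
  if (length(adsq) >= 2 && config@nSubtypeSpecific > 0) {
    ix <- takeBins(config@nSubtypeSpecific)
    for (i in seq_along(ix))
      addRows(ix[i], "hyper", "subtype_specific", list(adsq))
  }
  # private
  for (p in matched) {
    ix <- takeBins(config@nPrivatePerPatient)
    dirs <- sample(c("hypo", "hyper"), length(ix), replace = TRUE)
    for (i in seq_along(ix)) addRows(ix[i], dirs[i], "private", list(p))
  }
  # hotspot windows
  hot_rows <- list()
  if (config@nHotspots > 0) {
    win <- makeWindows(reference$seqinfo, config@hotspotWidth)
    n_cpg <- GenomicRanges::countOverlaps(win, bg)
    cand <- which(n_cpg >= 50)
    chosen <- cand[sample.int(length(cand),
                              min(config@nHotspots, length(cand)))]
    for (wi in chosen) {
      in_win <- which(overlapsAny(bg, win[wi], ignore.strand = TRUE))
      n_plant <- ceiling(config@hotspotRate * length(in_win))
      ix <- takeBins(n_plant, in_win)
      dirn <- sample(c("hypo", "hyper"), 1)
      pts <- sample(matched, config@hotspotPatients)
      for (i in ix) addRows(i, dirn, "hotspot", list(pts))
      hot_rows[[length(hot_rows) + 1L]] <- data.frame(
        window = paste0(seqnames(win)[wi], ":", start(win)[wi], "-",
                        end(win)[wi]),
        chrom = as.character(seqnames(win)[wi]),
        start = start(win)[wi], end = end(win)[wi],
        direction = dirn, patients = paste(pts, collapse = ","),
        n_planted = length(ix))
    }
  }
  planted <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), bin = integer(),
               direction = character(), type = character(),
               patients = character())
  hotspots <- if (length(hot_rows)) do.call(rbind, hot_rows) else
    data.frame(window = character(), chrom = character(),
               start = integer(), end = integer(), direction = character(),
               patients = character(), n_planted = integer())
  list(planted = planted, hotspots = hotspots, grid = grid,
       target_subfamily = config@targetSubfamily)
}

#' Generate cohort methylomes with planted effects
#'
#' Normal samples draw per-CpG levels around context baselines (CGI
#' promoter CpGs lowly methylated, repeat CpGs highly methylated,
#' remaining CpGs intermediate-high) with Gaussian measurement noise.
#' Tumor samples additionally shift the CpGs of each bin planted for
#' their patient by the effect size (negative for hypo, positive for
#' hyper) and lose a small amount of methylation over repeats globally.
#' Levels are clipped to [0, 1].
#'
#' @param reference from \code{\link{generateReference}}.
#' @param truth from \code{\link{plantTruth}}.
#' @param config a \linkS4class{GeneratorConfig}.
#' @param seed master seed.
#' @param analysis_config bin width provider.
#' @return named list of methylation tracks by sample_id.
#' @export
generateCohortMethylomes <- function(reference, truth,
                                     config = generatorConfig(),
                                     seed = 1,
                                     analysis_config = analysisConfig()) {
  set.seed(subSeeds(seed, 4)[3])
  cpgs <- reference$cpgs
  w <- analysis_config@binWidth
  pos <- start(cpgs)
  chrom <- as.character(seqnames(cpgs))
  cpg_bin_key <- paste(chrom, (pos - 1L) %/% w, sep = ":")
  promoters <- derivePromoters(reference$transcripts, analysis_config,
                               reference$seqinfo)
  cgi_prom <- mergeIntervals(c(granges(promoters[overlapsAny(
    promoters, reference$cgis, ignore.strand = TRUE)])))
  in_cgi_prom <- overlapsAny(cpgs, cgi_prom, ignore.strand = TRUE)
  in_cgi <- overlapsAny(cpgs, reference$cgis, ignore.strand = TRUE)
  in_rep <- if (length(reference$repeats))
    overlapsAny(cpgs, reference$repeats, ignore.strand = TRUE) else
    logical(length(cpgs))
  baseline <- rep(0.75, length(cpgs))
  baseline[in_rep] <- 0.85
  baseline[in_cgi & !in_cgi_prom] <- 0.25
  baseline[in_cgi_prom] <- 0.12
  planted <- truth$planted
  # per patient: planted keys and signed shifts
  patient_shift <- list()
  if (nrow(planted)) {
    pl <- planted
    pl_pat <- strsplit(pl$patients, ",")
    long <- data.frame(
      key = rep(paste(pl$chrom, pl$bin, sep = ":"),
                lengths(pl_pat)),
      dirn = rep(pl$direction, lengths(pl_pat)),
      patient = unlist(pl_pat))
    patient_shift <- split(long, long$patient)
  }
  manifest <- config@cohort
  tracks <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    lv <- baseline + rnorm(length(cpgs), 0, config@noiseSd)
    if (manifest$malignancy[i] == "tumor") {
      lv[in_rep] <- lv[in_rep] - config@repeatDownshift
      ps <- patient_shift[[manifest$patient_id[i]]]
      if (!is.null(ps)) {
        sgn <- ifelse(ps$dirn == "hyper", 1, -1)
        shift <- setNames(sgn * config@delta, ps$key)
        hitix <- match(cpg_bin_key, names(shift))
        sel <- !is.na(hitix)
        lv[sel] <- lv[sel] + shift[hitix[sel]]
      }
    }
    tr <- granges(cpgs)
    mcols(tr)$level <- clip01(lv)
    metadata(tr)$sample_id <- sid
    tracks[[sid]] <- tr
  }
  tracks
}

#' Generate per-comparison DMR call tables
#'
#' For every matched comparison, each bin planted for that patient is
#' emitted with q ~ U(0, qPlantedMax) and the planted direction; every
#' other background bin is emitted as a false positive with probability
#' \code{fpr} and q ~ U(0, qFpMax) with a random direction.
#' Normal-vs-normal comparisons contain false positives only. Cross
#' comparisons are not simulated.
#'
#' @param truth from \code{\link{plantTruth}}.
#' @param comparisons comparison table
#'   (\code{\link{enumerateComparisons}} of the cohort).
#' @param config a \linkS4class{GeneratorConfig}.
#' @param seed master seed.
#' @return call data.frame (\code{comparison_id, chrom, bin, q_value,
#'   direction}) across all simulated comparisons.
#' @export
generateDMRCalls <- function(truth, comparisons,
                             config = generatorConfig(), seed = 1) {
  set.seed(subSeeds(seed, 4)[4])
  bg <- backgroundBins(truth$grid)
  bg_chrom <- as.character(seqnames(bg))
  bg_bin <- mcols(bg)$bin
  bg_key <- paste(bg_chrom, bg_bin, sep = ":")
  planted <- truth$planted
  pl_key <- paste(planted$chrom, planted$bin, sep = ":")
  pl_pat <- strsplit(planted$patients, ",")
  out <- list()
  emitFP <- function(cid, exclude_keys = character(0)) {
    hit <- which(runif(length(bg)) < config@fpr)
    hit <- hit[!(bg_key[hit] %in% exclude_keys)]
    if (!length(hit)) return(NULL)
    data.frame(comparison_id = cid, chrom = bg_chrom[hit],
               bin = bg_bin[hit],
               q_value = runif(length(hit), 0, config@qFpMax),
               direction = sample(c("hypo", "hyper"), length(hit),
                                  replace = TRUE))
  }
  for (i in seq_len(nrow(comparisons))) {
    cid <- comparisons$comparison_id[i]
    type <- comparisons$type[i]
    if (type == "matched") {
      p <- comparisons$patient_id[i]
      mine <- which(vapply(pl_pat, function(x) p %in% x, logical(1)))
      pl_df <- if (length(mine))
        data.frame(comparison_id = cid, chrom = planted$chrom[mine],
                   bin = planted$bin[mine],
                   q_value = runif(length(mine), 0, config@qPlantedMax),
                   direction = planted$direction[mine])
      else NULL
      out[[length(out) + 1L]] <- rbind(pl_df,
                                       emitFP(cid, pl_key[mine]))
    } else if (type == "normal_normal") {
      out[[length(out) + 1L]] <- emitFP(cid)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(comparison_id = character(), chrom = character(),
                      bin = integer(), q_value = numeric(),
                      direction = character())
  rownames(res) <- NULL
  res
}

#' Simulate a complete dataset in memory
#'
#' Convenience wrapper running \code{\link{generateReference}},
#' \code{\link{plantTruth}}, optionally
#' \code{\link{generateCohortMethylomes}}, and
#' \code{\link{generateDMRCalls}} under one master seed with one RNG
#' stream per component (so e.g. regenerating with a different cohort
#' leaves the reference unchanged).
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param seed master seed.
#' @param tracks logical; also generate per-sample methylomes (the
#'   expensive layer). Default TRUE.
#' @param analysis_config an \linkS4class{AnalysisConfig}.
#' @return list: \code{reference, manifest, comparisons, truth, grid,
#'   tracks (or NULL), calls, config, seed}.
#' @export
simulateDataset <- function(config = generatorConfig(), seed = 1,
                            tracks = TRUE,
                            analysis_config = analysisConfig()) {
  reference <- generateReference(config, seed)
  truth <- plantTruth(reference, config, seed, analysis_config)
  manifest <- config@cohort
  comparisons <- enumerateComparisons(manifest)
  trk <- if (tracks)
    generateCohortMethylomes(reference, truth, config, seed,
                             analysis_config) else NULL
  calls <- generateDMRCalls(truth, comparisons, config, seed)
  list(reference = reference, manifest = manifest,
       comparisons = comparisons, truth = truth, grid = truth$grid,
       tracks = trk, calls = calls, config = config, seed = seed)
}
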