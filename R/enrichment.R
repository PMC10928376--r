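# Log odds ratio of two proportions with optional Haldane-Anscombe
# correction applied to the underlying 2x2 counts when any cell is zero.
lorFromCounts <- function(k1, n1, k2, n2) {
  cells <- c(k1, n1 - k1, k2, n2 - k2)
  if (any(cells == 0)) cells <- cells + 0.5
  log((cells[1] / cells[2]) / (cells[3] / cells[4]))
}

#' Log-odds-ratio enrichment of proportions
#'
#' \code{lor(pD, pB) = ln[(pD/(1-pD)) / (pB/(1-pB))]}, the enrichment of
#' an observed overlap proportion over a background proportion on the
#' natural-log odds scale. Satisfies \code{lor(p, p) = 0} and
#' \code{lor(a, b) = -lor(b, a)}.
#'
#' @param pD,pB proportions in (0,1).
#' @return numeric log odds ratio.
#' @export
logOddsRatio <- function(pD, pB) {
  log((pD / (1 - pD)) / (pB / (1 - pB)))
}

#' Feature enrichment of DMR bins over the background bin universe
#'
#' Compares the fraction of DMR bins overlapping a feature with the
#' fraction of background bins overlapping it, as a natural-log odds
#' ratio. When any cell of the implied 2x2 table is zero, 0.5 is added to
#' all four cells (Haldane-Anscombe) so the LOR stays finite; otherwise
#' counts are used unperturbed.
#'
#' @param dmr_bins GRanges of DMR bins.
#' @param feature_intervals GRanges of the feature.
#' @param background_bins GRanges of background bins (see
#'   \code{\link{backgroundBins}}).
#' @param unit_name label stored in the record.
#' @return one-row data.frame: \code{unit_name, dmr_count, dmr_total,
#'   background_count, background_total, lor}.
#' @export
featureLOR <- function(dmr_bins, feature_intervals, background_bins,
                       unit_name = "feature") {
  if (length(dmr_bins) == 0) stop("empty DMR set")
  k1 <- sum(overlapsAny(dmr_bins, feature_intervals, ignore.strand = TRUE))
  n1 <- length(dmr_bins)
  k2 <- sum(overlapsAny(background_bins, feature_intervals,
                        ignore.strand = TRUE))
  n2 <- length(background_bins)
  data.frame(unit_name = unit_name, dmr_count = k1, dmr_total = n1,
             background_count = k2, background_total = n2,
             lor = lorFromCounts(k1, n1, k2, n2))
}

#' Exclusive feature category of DMRs
#'
#' Assigns each DMR exactly one of three categories with precedence
#' promoter > genic > intergenic: promoter DMRs overlap a promoter (by at
#' least 1 bp); genic DMRs overlap a gene but no promoter; intergenic
#' DMRs overlap neither.
#'
#' @param dmrs GRanges of DMRs.
#' @param promoters,genes GRanges annotations.
#' @return character vector, one of \code{"promoter"}, \code{"genic"},
#'   \code{"intergenic"} per DMR.
#' @export
classifyExclusiveFeature <- function(dmrs, promoters, genes) {
  inProm <- overlapsAny(dmrs, promoters, ignore.strand = TRUE)
  inGene <- overlapsAny(dmrs, genes, ignore.strand = TRUE)
  ifelse(inProm, "promoter", ifelse(inGene, "genic", "intergenic"))
}

#' Repeat-class composition, genome-wide and DMR-overlapping
#'
#' Two normalized distributions over RepeatMasker classes: the proportion
#' of all repeat elements in each class, and the proportion of
#' DMR-overlapping elements in each class. Counted by element; set
#' \code{by = "base"} to weight each element by its length instead.
#'
#' @param dmr_overlapping_repeats GRanges of repeats overlapping DMRs
#'   (with \code{repeat_class}).
#' @param all_repeats GRanges of all repeats (with \code{repeat_class}).
#' @param by \code{"element"} (default) or \code{"base"}.
#' @return data.frame \code{repeat_class, genome_prop, dmr_prop} (classes
#'   absent from a set get proportion 0). Empty DMR set returns zero
#'   proportions with a warning.
#' @export
repeatClassComposition <- function(dmr_overlapping_repeats, all_repeats,
                                   by = c("element", "base")) {
  by <- match.arg(by)
  wt <- function(gr) if (by == "element") rep(1, length(gr)) else width(gr)
  tab <- function(gr) {
    if (length(gr) == 0) return(numeric(0))
    tapply(wt(gr), mcols(gr)$repeat_class, sum)
  }
  g <- tab(all_repeats); d <- tab(dmr_overlapping_repeats)
  if (length(d) == 0) warning("no DMR-overlapping repeats")
  classes <- sort(unique(c(names(g), names(d))))
  gp <- setNames(rep(0, length(classes)), classes)
  dp <- gp
  gp[names(g)] <- g / sum(g)
  if (length(d)) dp[names(d)] <- d / sum(d)
  data.frame(repeat_class = classes, genome_prop = unname(gp),
             dmr_prop = unname(dp), row.names = NULL)
}

#' Subfamily enrichment of DMRs over repeat bases
#'
#' For one repeat subfamily, compares the proportion of DMRs (of a given
#' direction / sharing tier) overlapping at least one element of the
#' subfamily with the proportion of total repeat length contributed by
#' the subfamily, as a natural-log odds ratio (Haldane-Anscombe corrected
#' only when a cell is zero).
#'
#' @param dmrs GRanges of the DMR set under consideration.
#' @param subfamily subfamily name.
#' @param all_repeats GRanges of all repeats with \code{subfamily}.
#' @return one-row data.frame: \code{unit_name, dmr_count, dmr_total,
#'   background_bp, background_total_bp, lor}.
#' @export
repeatSubfamilyLOR <- function(dmrs, subfamily, all_repeats) {
  el <- all_repeats[mcols(all_repeats)$subfamily == subfamily]
  if (length(el) == 0) stop("subfamily has no elements: ", subfamily)
  sub_bp <- sum(width(el)); tot_bp <- sum(width(all_repeats))
  if (sub_bp == 0) stop("zero-length subfamily")
  k <- sum(overlapsAny(dmrs, el, ignore.strand = TRUE))
  n <- length(dmrs)
  data.frame(unit_name = subfamily, dmr_count = k, dmr_total = n,
             background_bp = sub_bp, background_total_bp = tot_bp,
             lor = lorFromCounts(k, n, sub_bp, tot_bp))
}

#' Subfamily enrichment table with reporting filter
#'
#' \code{\link{repeatSubfamilyLOR}} applied to every subfamily, keeping
#' only subfamilies overlapping strictly more than
#' \code{minSubfamilyDmrs} DMRs (default 5).
#'
#' @param dmrs GRanges DMR set.
#' @param all_repeats GRanges of all repeats.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return data.frame, one row per reported subfamily.
#' @export
repeatSubfamilyEnrichment <- function(dmrs, all_repeats,
                                      config = analysisConfig()) {
  subs <- unique(mcols(all_repeats)$subfamily)
  rows <- lapply(subs, function(s) repeatSubfamilyLOR(dmrs, s, all_repeats))
  out <- do.call(rbind, rows)
  out[out$dmr_count > config@minSubfamilyDmrs, , drop = FALSE]
}

#' Jukes-Cantor evolutionary distance
#'
#' \code{d = -(3/4) ln(1 - 4p/3)} for an observed substitution proportion
#' \code{p} (RepeatMasker milliDiv / 1000), correcting for multiple hits.
#' Undefined for \code{p >= 0.75}; such elements are returned as NA with
#' a warning. Strictly increasing on [0, 0.75) and approximately equal to
#' p for small p.
#'
#' @param p numeric vector of substitution proportions.
#' @return numeric vector of distances.
#' @examples
#' jukesCantorDistance(c(0, 0.1))
#' @export
jukesCantorDistance <- function(p) {
  bad <- !is.na(p) & (p >= 0.75 | p < 0)
  if (any(bad))
    warning(sum(bad), " element(s) with p >= 0.75 (or < 0) excluded")
  d <- ifelse(is.na(p) | bad, NA_real_, -0.75 * log(1 - 4 * p / 3))
  d
}

#' Per-subfamily divergence summary
#'
#' Median Jukes-Cantor distance over the elements of each subfamily,
#' with element and base counts. Elements without a divergence estimate
#' are excluded.
#'
#' @param repeats GRanges with \code{subfamily} and \code{div_p}.
#' @return data.frame \code{subfamily, n_elements, total_bp, median_jc}.
#' @export
subfamilyDivergence <- function(repeats) {
  d <- jukesCantorDistance(mcols(repeats)$div_p)
  df <- data.frame(subfamily = mcols(repeats)$subfamily,
                   bp = width(repeats), jc = d)
  out <- do.call(rbind, lapply(split(df, df$subfamily), function(x)
    data.frame(subfamily = x$subfamily[1], n_elements = nrow(x),
               total_bp = sum(x$bp),
               median_jc = median(x$jc, na.rm = TRUE))))
  rownames(out) <- NULL
  out
}

#' Per-sample mean methylation over repeat subfamilies
#'
#' For each subfamily, the unique CpGs overlapping any of its elements
#' are identified (a CpG shared by two overlapping elements counts once)
#' and the mean methylation over those CpGs is computed per sample.
#' Subfamilies with fewer than \code{minSubfamilyCpgs} CpGs (default 10)
#' are excluded, as are subfamilies overlapping no CpG.
#'
#' @param repeats GRanges with \code{subfamily}.
#' @param tracks named list of methylation tracks by sample_id.
#' @param manifest cohort manifest (for normal/tumor contrasts).
#' @param config an \linkS4class{AnalysisConfig}.
#' @return list with \code{means} (subfamily x sample matrix of mean
#'   levels, plus \code{n_cpgs} attribute) and \code{contrasts}
#'   (per subfamily: median normal level, median matched tumor-normal
#'   change, across-sample sd).
#' @export
subfamilyMethylationProfile <- function(repeats, tracks, manifest,
                                        config = analysisConfig()) {
  stopifnot(length(tracks) > 0)
  # CpG universe: union of positions across tracks
  allpos <- unique(do.call(rbind, lapply(tracks, function(t)
    data.frame(chrom = as.character(seqnames(t)), pos = start(t)))))
  cpgs <- GRanges(allpos$chrom, IRanges(allpos$pos, width = 1))
  hits <- findOverlaps(cpgs, repeats, ignore.strand = TRUE)
  sub_of_hit <- mcols(repeats)$subfamily[subjectHits(hits)]
  cpg_by_sub <- lapply(split(queryHits(hits), sub_of_hit), unique)
  n_cpg <- vapply(cpg_by_sub, length, integer(1))
  keep <- n_cpg >= config@minSubfamilyCpgs
  cpg_by_sub <- cpg_by_sub[keep]
  if (!length(cpg_by_sub))
    return(list(means = NULL, contrasts = NULL))
  # per-track level lookup aligned to the CpG universe
  key <- paste(allpos$chrom, allpos$pos)
  means <- sapply(tracks, function(t) {
    lv <- setNames(mcols(t)$level, paste(seqnames(t), start(t)))[key]
    vapply(cpg_by_sub, function(ix) mean(lv[ix], na.rm = TRUE), numeric(1))
  })
  means <- matrix(means, nrow = length(cpg_by_sub),
                  dimnames = list(names(cpg_by_sub), names(tracks)))
  attr(means, "n_cpgs") <- n_cpg[keep]
  normals <- manifest$sample_id[manifest$malignancy == "normal"]
  tumors <- manifest$sample_id[manifest$malignancy == "tumor"]
  normals <- intersect(normals, colnames(means))
  pairs <- manifest[manifest$malignancy == "tumor" &
                    manifest$patient_id %in%
                      manifest$patient_id[manifest$malignancy == "normal"], ]
  deltas <- sapply(seq_len(nrow(pairs)), function(i) {
    tn <- pairs$sample_id[i]
    nn <- manifest$sample_id[manifest$malignancy == "normal" &
                             manifest$patient_id == pairs$patient_id[i]]
    if (!(tn %in% colnames(means)) || !(nn %in% colnames(means)))
      return(rep(NA_real_, nrow(means)))
    means[, tn] - means[, nn]
  })
  if (is.null(dim(deltas)))
    deltas <- matrix(deltas, nrow = nrow(means))
  contrasts <- data.frame(
    subfamily = rownames(means),
    n_cpgs = attr(means, "n_cpgs"),
    median_normal = apply(means[, normals, drop = FALSE], 1, median),
    median_delta = apply(deltas, 1, median, na.rm = TRUE),
    spread = apply(means, 1, sd))
  rownames(contrasts) <- NULL
  list(means = means, contrasts = contrasts)
}

#' ChromHMM state composition of a DMR set
#'
#' The fraction of DMR bases annotated with each chromatin state, the
#' same fraction over the background bins, and the fold and natural-log
#' odds-ratio enrichment per state. Bases covered by no segment are
#' reported as \code{"unannotated"}; proportions including it sum to 1.
#' Overlap is counted at the base level, matching how segmentations
#' partition the genome.
#'
#' @param dmrs GRanges DMR set.
#' @param segmentation GRanges with a \code{state} column.
#' @param background_bins GRanges background universe.
#' @return data.frame \code{state, dmr_bp, dmr_prop, bg_bp, bg_prop,
#'   fold, lor}.
#' @export
chromhmmComposition <- function(dmrs, segmentation, background_bins) {
  baseComp <- function(gr) {
    tot <- sum(width(gr))
    ov <- overlapQuery(gr, segmentation)
    bp <- if (nrow(ov))
      tapply(ov$overlap_bp, mcols(segmentation)$state[ov$subject_idx], sum)
    else numeric(0)
    res <- as.numeric(bp); names(res) <- names(bp)
    un <- tot - sum(res)
    if (un > 0 || length(res) == 0) res <- c(res, unannotated = un)
    list(bp = res, total = tot)
  }
  d <- baseComp(dmrs); b <- baseComp(background_bins)
  states <- sort(unique(c(names(d$bp), names(b$bp))))
  dbp <- setNames(rep(0, length(states)), states); dbp[names(d$bp)] <- d$bp
  bbp <- setNames(rep(0, length(states)), states); bbp[names(b$bp)] <- b$bp
  dprop <- dbp / d$total; bprop <- bbp / b$total
  lor <- vapply(states, function(s)
    lorFromCounts(dbp[s], d$total, bbp[s], b$total), numeric(1))
  data.frame(state = states, dmr_bp = unname(dbp),
             dmr_prop = unname(dprop), bg_bp = unname(bbp),
             bg_prop = unname(bprop),
             fold = unname(ifelse(bprop > 0, dprop / bprop, NA)),
             lor = unname(lor), row.names = NULL)
}

# Composite-state lookup tables for the Roadmap ChromHMM models.
compositeMaps <- local({
  s15 <- c("1_TssA", "2_TssAFlnk", "3_TxFlnk", "4_Tx", "5_TxWk",
           "6_EnhG", "7_Enh", "8_ZNF/Rpts", "9_Het", "10_TssBiv",
           "11_BivFlnk", "12_EnhBiv", "13_ReprPC", "14_ReprPCWk",
           "15_Quies")
  m15 <- setNames(rep("other", 15), s15)
  m15[c(1:3, 6:7)] <- "active_regulatory"
  s18 <- c("1_TssA", "2_TssFlnk", "3_TssFlnkU", "4_TssFlnkD", "5_Tx",
           "6_TxWk", "7_EnhG1", "8_EnhG2", "9_EnhA1", "10_EnhA2",
           "11_EnhWk", "12_ZNF/Rpts", "13_Het", "14_TssBiv", "15_EnhBiv",
           "16_ReprPC", "17_ReprPCWk", "18_Quies")
  m18 <- setNames(rep("other", 18), s18)
  m18[c(1:4, 7:11)] <- "active_regulatory"
  m18[5:6] <- "transcribed"
  m18[14:17] <- "polycomb"
  list(`15` = m15, `18` = m18)
})

#' Composite chromatin-state class of a ChromHMM state
#'
#' Maps mnemonic state labels to composite classes. Active regulatory
#' states are 1-3 and 6-7 in the 15-state model and 1-4 and 7-11 in the
#' 18-state model; 18-state states 5-6 are transcribed and 14-17
#' polycomb; all remaining states are \code{"other"}.
#'
#' @param state character vector of state mnemonics (e.g. "1_TssA"). A
#'   bare state number is also accepted.
#' @param model \code{"15"} or \code{"18"}.
#' @return character vector of composite classes.
#' @export
mapCompositeState <- function(state, model = c("18", "15")) {
  model <- match.arg(as.character(model), c("18", "15"))
  map <- compositeMaps[[model]]
  idx <- match(state, names(map))
  numeric_in <- is.na(idx) & grepl("^[0-9]+$", state)
  idx[numeric_in] <- suppressWarnings(as.integer(state[numeric_in]))
  idx[!is.na(idx) & (idx < 1 | idx > length(map))] <- NA
  if (anyNA(idx))
    stop("unknown ChromHMM state for the ", model, "-state model: ",
         paste(unique(state[is.na(idx)]), collapse = ", "))
  unname(map[idx])
}

#' Methylation-level category
#'
#' Levels strictly below 30\% are \code{hypomethylated}, strictly above
#' 70\% \code{hypermethylated}, and the closed interval [30\%, 70\%]
#' \code{intermediate}.
#'
#' @param level numeric vector of methylation fractions in [0,1].
#' @param config an \linkS4class{AnalysisConfig}.
#' @return character vector of categories.
#' @export
categorizeMethylationLevel <- function(level, config = analysisConfig()) {
  stopifnot(all(level >= 0 & level <= 1, na.rm = TRUE))
  ifelse(level < config@methLow, "hypomethylated",
         ifelse(level > config@methHigh, "hypermethylated",
                "intermediate"))
}

#' Detect candidate promoter switches
#'
#' Genes with multiple promoters overlapping DMRs, where the same
#' patient-matched comparison contributes at least one hypoDMR and one
#' hyperDMR over those promoters (on different promoters). Genes where
#' this holds in more than one comparison form the \code{"recurrent"}
#' tier selected for further investigation.
#'
#' @param catalog a \linkS4class{DMRCatalog}.
#' @param promoters GRanges of promoters with \code{transcript_id} and
#'   \code{gene_id}.
#' @return data.frame \code{gene_id, n_comparisons, tier} (tier is
#'   \code{"single"} or \code{"recurrent"}).
#' @export
detectPromoterSwitches <- function(catalog, promoters) {
  obs <- catalog@observations
  cmp <- catalog@comparisons
  matched <- cmp$comparison_id[cmp$type == "matched"]
  obs <- obs[obs$comparison_id %in% matched &
             obs$direction %in% c("hypo", "hyper"), , drop = FALSE]
  dmrs <- catalog@dmrs
  ov <- overlapQuery(dmrs, promoters)
  if (!nrow(ov) || !nrow(obs))
    return(data.frame(gene_id = character(), n_comparisons = integer(),
                      tier = character()))
  link <- data.frame(dmr_id = mcols(dmrs)$dmr_id[ov$query_idx],
                     transcript_id =
                       mcols(promoters)$transcript_id[ov$subject_idx],
                     gene_id = mcols(promoters)$gene_id[ov$subject_idx])
  m <- merge(obs, link, by = "dmr_id")
  hit <- do.call(rbind, lapply(
    split(m, list(m$gene_id, m$comparison_id), drop = TRUE),
    function(x) {
      ok <- length(unique(x$transcript_id)) >= 2 &&
        all(c("hypo", "hyper") %in% x$direction)
      if (!ok) return(NULL)
      data.frame(gene_id = x$gene_id[1], comparison_id = x$comparison_id[1])
    }))
  if (is.null(hit))
    return(data.frame(gene_id = character(), n_comparisons = integer(),
                      tier = character()))
  agg <- stats::aggregate(comparison_id ~ gene_id, data = hit,
                          FUN = function(x) length(unique(x)))
  names(agg)[2] <- "n_comparisons"
  agg$tier <- ifelse(agg$n_comparisons > 1, "recurrent", "single")
  agg
}
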