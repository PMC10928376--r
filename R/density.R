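#' Tile density windows across the genome
#'
#' Non-overlapping fixed-width windows across all chromosomes except the
#' excluded ones (chrY and chrM by convention for DMR density work).
#'
#' @param chromSizes named lengths or Seqinfo.
#' @param width window width in bp.
#' @param exclude chromosomes to omit (default chrY, chrM).
#' @return GRanges of windows.
#' @export
makeWindows <- function(chromSizes, width, exclude = c("chrY", "chrM")) {
  si <- asSeqinfo(chromSizes)
  keep <- setdiff(seqlevels(si), exclude)
  si <- si[keep]
  tileGenome(si, tilewidth = width, cut.last.tile.in.chrom = TRUE)
}

#' Per-window DMR density
#'
#' Density of a window, for one comparison and direction, is the number
#' of called DMR bins divided by the number of CpG-containing,
#' non-blacklisted 500-bp bins in the window. Windows with no such bins
#' are excluded (density undefined).
#'
#' @param filtered_calls filtered call data.frame with \code{direction}.
#' @param windows GRanges from \code{\link{makeWindows}}.
#' @param grid a \linkS4class{BinGrid}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return data.frame \code{window_idx, chrom, start, end, n_cpg_bins,
#'   comparison_id, direction, n_dmrs, density}; only windows with
#'   \code{n_cpg_bins > 0} appear, with a row per (window, comparison,
#'   direction) with at least one DMR plus zero-density rows implied
#'   absent. Use \code{\link{densityMatrix}} for a dense layout.
#' @export
windowDensity <- function(filtered_calls, windows, grid,
                          config = analysisConfig()) {
  bg <- backgroundBins(grid)
  n_cpg <- GenomicRanges::countOverlaps(windows, bg)
  ok <- which(n_cpg > 0)
  calls <- filtered_calls[filtered_calls$direction %in%
                            c("hypo", "hyper"), , drop = FALSE]
  gr <- callsToGRanges(calls, config@binWidth)
  hits <- findOverlaps(gr, windows[ok], ignore.strand = TRUE)
  if (length(hits)) {
    df <- data.frame(win = ok[subjectHits(hits)],
                     comparison_id = calls$comparison_id[queryHits(hits)],
                     direction = calls$direction[queryHits(hits)],
                     n = 1L)
    agg <- stats::aggregate(n ~ win + comparison_id + direction,
                            data = df, FUN = sum)
    names(agg)[4] <- "n_dmrs"
  } else {
    agg <- data.frame(win = integer(), comparison_id = character(),
                      direction = character(), n_dmrs = integer())
  }
  out <- data.frame(window_idx = agg$win,
                    chrom = as.character(seqnames(windows))[agg$win],
                    start = start(windows)[agg$win],
                    end = end(windows)[agg$win],
                    n_cpg_bins = n_cpg[agg$win],
                    comparison_id = agg$comparison_id,
                    direction = agg$direction,
                    n_dmrs = agg$n_dmrs)
  out$density <- out$n_dmrs / out$n_cpg_bins
  attr(out, "windows") <- windows
  attr(out, "n_cpg_bins") <- n_cpg
  out
}

#' Dense window x comparison density matrix for one direction
#'
#' @param density data.frame from \code{\link{windowDensity}}.
#' @param direction \code{"hypo"} or \code{"hyper"}.
#' @param comparison_ids columns to report (default those present).
#' @return numeric matrix windows x comparisons (zero where no DMR);
#'   rows are all windows with CpG bins, named "chrom:start-end".
#' @export
densityMatrix <- function(density, direction,
                          comparison_ids = NULL) {
  windows <- attr(density, "windows")
  n_cpg <- attr(density, "n_cpg_bins")
  ok <- which(n_cpg > 0)
  if (is.null(comparison_ids))
    comparison_ids <- sort(unique(density$comparison_id))
  m <- matrix(0, nrow = length(ok), ncol = length(comparison_ids),
              dimnames = list(paste0(seqnames(windows)[ok], ":",
                                     start(windows)[ok], "-",
                                     end(windows)[ok]),
                              comparison_ids))
  d <- density[density$direction == direction &
               density$comparison_id %in% comparison_ids, , drop = FALSE]
  if (nrow(d))
    m[cbind(match(d$window_idx, ok),
            match(d$comparison_id, comparison_ids))] <- d$density
  m
}

#' Genome-wide and per-chromosome DMR density
#'
#' The proportion of background bins (CpG-containing, non-blacklisted)
#' called as DMRs, per comparison and direction; the same ratio per
#' chromosome.
#'
#' @param filtered_calls filtered call data.frame.
#' @param grid a \linkS4class{BinGrid}.
#' @return list: \code{genome} (comparison x direction densities),
#'   \code{per_chrom}.
#' @export
genomeWideDensity <- function(filtered_calls, grid) {
  bg <- backgroundBins(grid)
  n_bg <- length(bg)
  n_bg_chrom <- table(as.character(seqnames(bg)))
  calls <- filtered_calls[filtered_calls$direction %in%
                            c("hypo", "hyper"), , drop = FALSE]
  calls$n <- 1L
  g <- stats::aggregate(n ~ comparison_id + direction, data = calls,
                        FUN = sum)
  names(g)[3] <- "n_dmrs"
  g$density <- g$n_dmrs / n_bg
  pc <- stats::aggregate(n ~ comparison_id + direction + chrom,
                         data = calls, FUN = sum)
  names(pc)[4] <- "n_dmrs"
  pc$density <- pc$n_dmrs / as.numeric(n_bg_chrom[pc$chrom])
  list(genome = g, per_chrom = pc)
}

#' Detect DMR density hotspots
#'
#' Per direction, a window is a hotspot if its density exceeds the
#' threshold (default 1\%) in more than one matched comparison, or if it
#' ranks among the top \code{hotspotTopN} (default 15) windows by maximum
#' density across comparisons. Ties at the top-N boundary are broken by
#' genomic order. The top-N clause presumes a genome-scale window count;
#' set \code{hotspotTopN = 0} to use the recurrent-density clause alone.
#'
#' @param density data.frame from \code{\link{windowDensity}} (matched
#'   comparisons, typically at 1 Mb).
#' @param direction \code{"hypo"} or \code{"hyper"}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return data.frame of flagged windows: \code{window, n_above,
#'   max_density, by_recurrence, by_topn}.
#' @export
detectHotspots <- function(density, direction,
                           config = analysisConfig()) {
  m <- densityMatrix(density, direction)
  n_above <- rowSums(m > config@densityHotspot)
  max_d <- apply(m, 1, max)
  rec <- n_above >= 2
  topn <- rep(FALSE, nrow(m))
  k <- min(config@hotspotTopN, nrow(m))
  if (k > 0) {
    # rank by max density, ties broken by genomic (row) order
    ord <- order(-max_d, seq_len(nrow(m)))
    topn[ord[seq_len(k)]] <- TRUE
  }
  flag <- rec | topn
  data.frame(window = rownames(m)[flag], n_above = n_above[flag],
             max_density = max_d[flag], by_recurrence = rec[flag],
             by_topn = topn[flag], row.names = NULL)
}

#' Covariate features of density windows
#'
#' Per window: CpG density (CpGs per bp), repeat density (repeat bp per
#' bp, after collapsing overlapping elements), gene / protein-coding gene
#' / transcript / protein-coding transcript counts per bp, the proportion
#' of the window in each ChromHMM state (with \code{unannotated}; the
#' proportions sum to 1), and the mean methylation over the window's
#' CpGs in a designated (normal) track.
#'
#' @param windows GRanges of windows.
#' @param cpgs GRanges of CpG positions.
#' @param transcripts transcript GRanges (with \code{gene_id, biotype}).
#' @param repeats repeat GRanges.
#' @param segmentation GRanges with \code{state}, or NULL.
#' @param track methylation track for mean methylation, or NULL.
#' @return data.frame, one row per window.
#' @export
windowFeatureProfile <- function(windows, cpgs, transcripts, repeats,
                                 segmentation = NULL, track = NULL) {
  w <- width(windows)
  out <- data.frame(
    window = paste0(seqnames(windows), ":", start(windows), "-",
                    end(windows)),
    cpg_density = GenomicRanges::countOverlaps(windows, cpgs) / w)
  repM <- mergeIntervals(repeats)
  ovr <- overlapQuery(windows, repM)
  rep_bp <- rep(0, length(windows))
  if (nrow(ovr)) {
    agg <- tapply(ovr$overlap_bp, ovr$query_idx, sum)
    rep_bp[as.integer(names(agg))] <- agg
  }
  out$repeat_density <- rep_bp / w
  pc <- mcols(transcripts)$biotype == "protein_coding"
  countDensity <- function(gr, ids) {
    hits <- findOverlaps(windows, gr, ignore.strand = TRUE)
    n <- rep(0L, length(windows))
    if (length(hits)) {
      cnt <- tapply(ids[subjectHits(hits)], queryHits(hits),
                    function(x) length(unique(x)))
      n[as.integer(names(cnt))] <- cnt
    }
    n / w
  }
  out$gene_density <- countDensity(transcripts,
                                   mcols(transcripts)$gene_id)
  out$pc_gene_density <- countDensity(transcripts[pc],
                                      mcols(transcripts)$gene_id[pc])
  out$transcript_density <- countDensity(transcripts,
                                         mcols(transcripts)$transcript_id)
  out$pc_transcript_density <-
    countDensity(transcripts[pc],
                 mcols(transcripts)$transcript_id[pc])
  if (!is.null(segmentation)) {
    ovs <- overlapQuery(windows, segmentation)
    states <- sort(unique(mcols(segmentation)$state))
    sm <- matrix(0, nrow = length(windows), ncol = length(states),
                 dimnames = list(NULL, paste0("state_", states)))
    if (nrow(ovs)) {
      st <- mcols(segmentation)$state[ovs$subject_idx]
      for (s in states) {
        sel <- st == s
        if (any(sel)) {
          agg <- tapply(ovs$overlap_bp[sel], ovs$query_idx[sel], sum)
          sm[as.integer(names(agg)), paste0("state_", s)] <- agg
        }
      }
    }
    sm <- sm / w
    out <- cbind(out, sm)
    out$state_unannotated <- pmax(0, 1 - rowSums(sm))
  }
  if (!is.null(track)) out$mean_normal_meth <- binMeans(windows, track)
  out
}

#' Correlate window features with DMR density
#'
#' Pearson correlation of each window feature with (i) DMR density in
#' each comparison, (ii) the number of comparisons with density above
#' 1\%, and (iii) the mean density across comparisons. Also runs a
#' feature-space PCA (centered, scaled) over windows and reports variance
#' shares plus the correlation of each feature with the first three
#' components.
#'
#' @param profiles data.frame from \code{\link{windowFeatureProfile}}
#'   (rows aligned with the density matrix rows).
#' @param density_mat windows x comparisons density matrix
#'   (\code{\link{densityMatrix}}).
#' @param threshold recurrence threshold on density (default 0.01).
#' @return list: \code{correlations} (feature x summary), \code{pca}
#'   (variance shares, loadings as feature-PC correlations).
#' @export
correlateDensityFeatures <- function(profiles, density_mat,
                                     threshold = 0.01) {
  stopifnot(nrow(profiles) == nrow(density_mat), nrow(profiles) >= 3)
  feats <- profiles[vapply(profiles, is.numeric, logical(1))]
  summaries <- cbind(density_mat,
                     n_above = rowSums(density_mat > threshold),
                     mean_density = rowMeans(density_mat))
  corr <- suppressWarnings(cor(as.matrix(feats), summaries,
                               use = "pairwise.complete.obs"))
  keep <- vapply(feats, function(x) sd(x, na.rm = TRUE) > 0, logical(1))
  pcs <- prcomp(as.matrix(feats[, keep, drop = FALSE])[
    complete.cases(feats[, keep, drop = FALSE]), , drop = FALSE],
    center = TRUE, scale. = TRUE)
  vs <- pcs$sdev^2 / sum(pcs$sdev^2)
  k <- min(3, ncol(pcs$x))
  load <- suppressWarnings(
    cor(as.matrix(feats[, keep, drop = FALSE])[
      complete.cases(feats[, keep, drop = FALSE]), , drop = FALSE],
      pcs$x[, seq_len(k), drop = FALSE]))
  list(correlations = corr,
       pca = list(variance_share = vs, loadings = load))
}

#' Fraction of comparison-exclusive DMRs inside high-density windows
#'
#' For one comparison and direction: the fraction of DMRs exclusive to
#' that comparison that fall inside the comparison's windows with
#' density above the threshold (default 10\%, at 1 Mb).
#'
#' @param exclusive_dmrs GRanges of the comparison's exclusive DMRs.
#' @param density data.frame from \code{\link{windowDensity}}.
#' @param comparison_id the comparison.
#' @param direction DMR direction.
#' @param threshold density cutoff (default 0.10).
#' @return numeric fraction, or NA when there are no exclusive DMRs.
#' @export
exclusiveInHotspotsFraction <- function(exclusive_dmrs, density,
                                        comparison_id, direction,
                                        threshold = 0.10) {
  if (length(exclusive_dmrs) == 0) return(NA_real_)
  windows <- attr(density, "windows")
  d <- density[density$comparison_id == comparison_id &
               density$direction == direction &
               density$density > threshold, , drop = FALSE]
  if (!nrow(d)) return(0)
  dense <- windows[d$window_idx]
  mean(overlapsAny(exclusive_dmrs, dense, ignore.strand = TRUE))
}
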