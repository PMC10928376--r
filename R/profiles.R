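#' Mean methylation over a feature set
#'
#' Features are first internally collapsed (merging overlapping and
#' abutting intervals) so that each covered CpG contributes exactly once;
#' the unweighted mean over all covered CpGs is then returned.
#'
#' @param intervals GRanges feature set.
#' @param track methylation track (width-1 GRanges with \code{level}).
#' @return numeric mean level, or NA when no CpG is covered (flagged with
#'   attribute \code{no_cpg = TRUE}).
#' @export
meanMethylationOverIntervals <- function(intervals, track) {
  if (length(intervals) == 0) {
    out <- NA_real_; attr(out, "no_cpg") <- TRUE; return(out)
  }
  merged <- mergeIntervals(intervals)
  hit <- overlapsAny(track, merged, ignore.strand = TRUE)
  if (!any(hit)) {
    out <- NA_real_; attr(out, "no_cpg") <- TRUE; return(out)
  }
  mean(mcols(track)$level[hit])
}

#' Methylation-level category proportions of a sample
#'
#' The fraction of a track's CpGs that are lowly (< 30\%), intermediately
#' (30\%-70\%) or highly (> 70\%) methylated, plus the genome-wide mean.
#' The three fractions sum to 1.
#'
#' @param track methylation track.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return named list: \code{low, intermediate, high, mean}.
#' @export
methylationCategoryProportions <- function(track,
                                           config = analysisConfig()) {
  lv <- mcols(track)$level
  stopifnot(length(lv) > 0)
  cat <- categorizeMethylationLevel(lv, config)
  list(low = mean(cat == "hypomethylated"),
       intermediate = mean(cat == "intermediate"),
       high = mean(cat == "hypermethylated"),
       mean = mean(lv))
}

#' Windowed mean-methylation matrix across samples
#'
#' Non-overlapping fixed-width windows are tiled across the genome; for
#' each window the mean methylation over its CpGs is computed per sample.
#' Windows containing no CpG in the union track are excluded.
#'
#' @param tracks named list of methylation tracks by sample_id.
#' @param chromSizes named lengths or Seqinfo.
#' @param width window width in bp (default 1 kb).
#' @return numeric matrix, windows (rownames "chrom:start-end", 1-based)
#'   x samples. Cells are NA where a sample has no CpG in the window.
#' @export
buildWindowMatrix <- function(tracks, chromSizes, width = 1000) {
  stopifnot(length(tracks) >= 1)
  si <- asSeqinfo(chromSizes)
  win <- tileGenome(si, tilewidth = width, cut.last.tile.in.chrom = TRUE)
  cols <- lapply(tracks, function(t) binMeans(win, t))
  m <- do.call(cbind, cols)
  colnames(m) <- names(tracks)
  rownames(m) <- paste0(seqnames(win), ":", start(win), "-", end(win))
  keep <- rowSums(!is.na(m)) > 0
  m[keep, , drop = FALSE]
}

#' Per-sample distance to group centroid in principal-component space
#'
#' Windows without variation across samples are dropped, the matrix is
#' centered and scaled per window, and samples are projected onto
#' principal components. Group centroids are the per-group means along
#' each component, and each sample's Euclidean distance to its own group
#' centroid is computed over all components (no truncation), which by
#' rotation invariance equals the distance in the scaled original space.
#'
#' @param matrix windows x samples numeric matrix (no NAs in used rows).
#' @param group_labels character/factor, one label per sample (column).
#' @return list: \code{distances} (named per sample), \code{variance_share}
#'   (per component), \code{degenerate} (labels of singleton groups,
#'   whose distance is 0 by construction).
#' @export
centroidDistances <- function(matrix, group_labels) {
  stopifnot(ncol(matrix) == length(group_labels), ncol(matrix) >= 2)
  m <- matrix[complete.cases(matrix), , drop = FALSE]
  v <- apply(m, 1, stats::var)
  m <- m[v > 0, , drop = FALSE]
  if (nrow(m) == 0) stop("no windows with variation across samples")
  x <- t(m) # samples x windows
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  scores <- pc$x
  labs <- as.character(group_labels)
  cent <- do.call(rbind, lapply(split(seq_len(nrow(scores)), labs),
                                function(ix)
                                  colMeans(scores[ix, , drop = FALSE])))
  d <- sqrt(rowSums((scores - cent[labs, , drop = FALSE])^2))
  names(d) <- colnames(matrix)
  vs <- pc$sdev^2 / sum(pc$sdev^2)
  singleton <- names(which(table(labs) == 1))
  list(distances = d, variance_share = vs, degenerate = singleton)
}

#' Pairwise Pearson correlation distance between samples
#'
#' \code{1 - r} over the window means; symmetric with zero diagonal.
#' Samples without variance yield NA entries and are reported in the
#' \code{"zero_variance"} attribute.
#'
#' @param matrix windows x samples numeric matrix.
#' @return samples x samples distance matrix.
#' @export
sampleCorrelationMatrix <- function(matrix) {
  stopifnot(ncol(matrix) >= 2)
  m <- matrix[complete.cases(matrix), , drop = FALSE]
  sds <- apply(m, 2, sd)
  r <- suppressWarnings(cor(m))
  d <- 1 - r
  diag(d) <- 0
  d[, sds == 0] <- NA; d[sds == 0, ] <- NA
  attr(d, "zero_variance") <- colnames(m)[sds == 0]
  d
}
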