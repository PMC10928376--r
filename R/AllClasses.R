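#' @import methods
#' @importFrom stats cor median prcomp qnorm quantile rbeta rbinom rnorm
#'   rpois runif sd setNames complete.cases chisq.test
#' @importFrom utils read.delim write.table head
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- queryHits
#'   subjectHits
#' @importFrom IRanges IRanges width pintersect overlapsAny
#' @importFrom GenomicRanges GRanges findOverlaps reduce seqnames start end
#'   strand granges tileGenome
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels keepSeqlevels
NULL

#' Analysis configuration
#'
#' Holds the tunable constants of the downstream DMR analysis: the 500-bp
#' bin width of the caller grid, promoter extents around the TSS, the
#' Q-value significance threshold and its calibration grid, methylation
#' category boundaries, the large-change cutoff used in threshold
#' calibration, density-hotspot parameters, repeat subfamily reporting
#' filters, the multi-resolution window widths, and the chromosome sets
#' used for the background and for DMR exclusion.
#'
#' Defaults reproduce the published analysis: promoters span 2000 bp
#' upstream to 500 bp downstream of the TSS; DMRs require Q < 0.001
#' (strict) selected from the grid 1e-2..1e-5; methylation levels below
#' 30\% are "low" and above 70\% "high"; a calibration DMR counts as a
#' large change above 10\% absolute difference; 1-Mb windows are hotspot
#' candidates when density exceeds 1\% recurrently or ranks in the top 15;
#' repeat subfamilies need at least 10 CpGs for methylation profiling and
#' more than 5 DMR overlaps for enrichment reporting.
#'
#' @slot binWidth integer, caller bin width in bp.
#' @slot promoterUpstream,promoterDownstream integer, promoter extent in bp.
#' @slot qThreshold numeric, strict upper bound on the DMR Q value.
#' @slot qCalibrationGrid numeric vector of candidate thresholds.
#' @slot methLow,methHigh numeric, methylation category boundaries (fractions).
#' @slot largeChange numeric, absolute methylation change defining a
#'   "large" change during threshold calibration.
#' @slot densityHotspot numeric, per-window DMR density above which a
#'   window counts toward the recurrent-hotspot clause.
#' @slot hotspotTopN integer, number of top-density windows always flagged.
#' @slot minSubfamilyCpgs integer, minimum unique CpGs for a subfamily
#'   methylation profile.
#' @slot minSubfamilyDmrs integer, subfamilies must overlap strictly more
#'   DMRs than this to be reported in enrichment tables.
#' @slot windowWidths numeric vector of window widths (bp) for density.
#' @slot backgroundChroms character, chromosomes forming the background
#'   bin universe.
#' @slot excludedDmrChroms character, chromosomes whose calls are dropped.
#'
#' @export
setClass("AnalysisConfig",
  representation(
    binWidth = "integer",
    promoterUpstream = "integer",
    promoterDownstream = "integer",
    qThreshold = "numeric",
    qCalibrationGrid = "numeric",
    methLow = "numeric",
    methHigh = "numeric",
    largeChange = "numeric",
    densityHotspot = "numeric",
    hotspotTopN = "integer",
    minSubfamilyCpgs = "integer",
    minSubfamilyDmrs = "integer",
    windowWidths = "numeric",
    backgroundChroms = "character",
    excludedDmrChroms = "character"
  ),
  prototype(
    binWidth = 500L,
    promoterUpstream = 2000L,
    promoterDownstream = 500L,
    qThreshold = 1e-3,
    qCalibrationGrid = c(1e-2, 1e-3, 1e-4, 1e-5),
    methLow = 0.30,
    methHigh = 0.70,
    largeChange = 0.10,
    densityHotspot = 0.01,
    hotspotTopN = 15L,
    minSubfamilyCpgs = 10L,
    minSubfamilyDmrs = 5L,
    windowWidths = c(1e4, 1e5, 1e6, 1e7),
    backgroundChroms = c(paste0("chr", 1:22), "chrX"),
    excludedDmrChroms = "chrY"
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (object@binWidth <= 0L) msg <- c(msg, "binWidth must be positive")
  if (!(object@methLow > 0 && object@methLow < object@methHigh &&
        object@methHigh < 1))
    msg <- c(msg, "need 0 < methLow < methHigh < 1")
  if (!any(abs(object@qCalibrationGrid - object@qThreshold) < 1e-15))
    msg <- c(msg, "qThreshold must be one of qCalibrationGrid")
  if (length(msg)) msg else TRUE
})

#' Construct an AnalysisConfig
#'
#' @param ... named slot overrides, e.g. \code{qThreshold = 1e-4}.
#' @return An \linkS4class{AnalysisConfig}.
#' @examples
#' cfg <- analysisConfig()
#' qThreshold(cfg)
#' @export
analysisConfig <- function(...) {
  args <- list(...)
  for (nm in c("binWidth", "promoterUpstream", "promoterDownstream",
               "hotspotTopN", "minSubfamilyCpgs", "minSubfamilyDmrs"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c("AnalysisConfig", args))
}

#' @describeIn analysisConfig Q-value threshold accessor.
#' @param object an AnalysisConfig.
#' @export
qThreshold <- function(object) object@qThreshold

#' @describeIn analysisConfig bin width accessor.
#' @export
binWidth <- function(object) object@binWidth

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n")
  cat("  bin width:      ", object@binWidth, "bp\n")
  cat("  promoter:       -", object@promoterUpstream, "/ +",
      object@promoterDownstream, "bp around TSS\n")
  cat("  Q threshold:    <", format(object@qThreshold), "\n")
  cat("  meth categories: <", object@methLow, " / >", object@methHigh, "\n")
  cat("  window widths:  ", paste(format(object@windowWidths,
      scientific = FALSE, big.mark = ","), collapse = ", "), "bp\n")
})

#' Genome-wide bin grid
#'
#' Tiles every chromosome with fixed-width bins (last bin may be short)
#' and flags each bin for CpG content and blacklist overlap. The
#' "background" set -- all bins on the background chromosomes that contain
#' a CpG and do not overlap the blacklist -- is the universe of potential
#' DMRs against which enrichments and densities are computed.
#'
#' @slot bins a \link[GenomicRanges]{GRanges} tiling the genome, with
#'   logical metadata columns \code{contains_cpg} and \code{blacklisted}
#'   and integer column \code{bin} (0-based index within chromosome).
#' @slot width integer bin width in bp.
#' @slot backgroundChroms character vector of background chromosomes.
#'
#' @seealso \code{\link{buildBinGrid}}, \code{\link{backgroundBins}}
#' @export
setClass("BinGrid",
  representation(bins = "GRanges", width = "integer",
                 backgroundChroms = "character"))

setValidity("BinGrid", function(object) {
  need <- c("contains_cpg", "blacklisted", "bin")
  if (!all(need %in% names(mcols(object@bins))))
    return("bins must carry contains_cpg, blacklisted and bin columns")
  TRUE
})

setMethod("show", "BinGrid", function(object) {
  bg <- backgroundBins(object)
  cat("BinGrid of", length(object@bins), sprintf("%d-bp", object@width),
      "bins on", length(seqlevels(object@bins)), "chromosomes\n")
  cat("  background (CpG+, non-blacklisted,",
      paste(head(object@backgroundChroms, 3), collapse = ","),
      "...):", length(bg), "bins\n")
})

#' Unique-DMR catalogue
#'
#' The position-keyed catalogue built from filtered DMR calls across all
#' comparisons. Every 500-bp bin ever called is assigned a stable
#' identifier \code{B<block>.<pos>}: genomically adjacent called bins are
#' merged into blocks numbered in karyotype order, and bins are numbered
#' 5'-to-3' within their block. Identifiers depend only on the set of
#' called bins, never on the order in which comparisons were loaded.
#'
#' @slot dmrs \link[GenomicRanges]{GRanges} of unique DMR bins with
#'   metadata columns \code{dmr_id}, \code{block_id}, \code{pos_in_block}.
#' @slot observations data.frame with one row per (DMR, comparison)
#'   instance: \code{dmr_id}, \code{comparison_id}, \code{direction},
#'   \code{q_value}.
#' @slot comparisons data.frame of comparison specifications (see
#'   \code{\link{enumerateComparisons}}).
#'
#' @seealso \code{\link{buildCatalog}}, \code{\link{recurrence}}
#' @export
setClass("DMRCatalog",
  representation(dmrs = "GRanges", observations = "data.frame",
                 comparisons = "data.frame"))

setMethod("show", "DMRCatalog", function(object) {
  cat("DMRCatalog:", length(object@dmrs), "unique DMRs,",
      nrow(object@observations), "instances across",
      length(unique(object@observations$comparison_id)), "comparisons\n")
})

#' @describeIn buildCatalog Unique DMR ranges of a catalogue.
#' @export
dmrRanges <- function(catalog) catalog@dmrs

#' @describeIn buildCatalog Per-instance observation table of a catalogue.
#' @export
observations <- function(catalog) catalog@observations

#' Number of unique DMRs in a catalogue
#' @param x a \linkS4class{DMRCatalog}.
#' @export
setMethod("length", "DMRCatalog", function(x) length(x@dmrs))
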