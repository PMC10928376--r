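#' Read a chrom.sizes file
#'
#' Two-column tab-separated text: chromosome name, length in bp.
#' Chromosome names are normalized to carry the \code{"chr"} prefix.
#'
#' @param path file path.
#' @return A \link[GenomeInfoDb]{Seqinfo} in karyotype order.
#' @export
readChromSizes <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("chrom", "size"),
                   colClasses = c("character", "numeric"))
  if (any(df$size <= 0)) stop("chrom.sizes: non-positive length")
  sizes <- setNames(df$size, normChrom(df$chrom))
  if (anyDuplicated(names(sizes))) stop("chrom.sizes: duplicate chromosome")
  asSeqinfo(sizes)
}

#' Read a cohort sample manifest
#'
#' Tab-separated text with header columns \code{sample_id, patient_id,
#' malignancy, smoking, stage, subtype, purity}. Malignancy must be
#' \code{normal} or \code{tumor}. Smoking is normalized to the controlled
#' vocabulary \code{never / smoker / unconfirmed}; former smokers are
#' classed as smokers. Empty or unknown stage/subtype/smoking cells become
#' \code{"unconfirmed"}; missing purity becomes \code{NA}.
#'
#' @param path file path.
#' @return data.frame with one row per sample.
#' @export
readManifest <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = "character",
                   na.strings = c("", "NA"))
  need <- c("sample_id", "patient_id", "malignancy", "smoking", "stage",
            "subtype", "purity")
  if (!all(need %in% names(df)))
    stop("manifest: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[need]
  if (anyDuplicated(df$sample_id))
    stop("manifest: duplicate sample_id")
  mal <- tolower(df$malignancy)
  if (!all(mal %in% c("normal", "tumor")))
    stop("manifest: unknown malignancy token: ",
         paste(unique(df$malignancy[!mal %in% c("normal", "tumor")]),
               collapse = ", "))
  df$malignancy <- mal
  smk <- tolower(ifelse(is.na(df$smoking), "unconfirmed", df$smoking))
  smk[smk %in% c("former", "current", "ever", "smoker")] <- "smoker"
  smk[smk %in% c("never", "never-smoker", "nonsmoker")] <- "never"
  smk[!smk %in% c("never", "smoker")] <- "unconfirmed"
  df$smoking <- smk
  df$stage <- ifelse(is.na(df$stage), "unconfirmed", df$stage)
  df$subtype <- ifelse(is.na(df$subtype), "unconfirmed", df$subtype)
  df$purity <- suppressWarnings(as.numeric(df$purity))
  if (any(!is.na(df$purity) & (df$purity < 0 | df$purity > 1)))
    stop("manifest: purity outside [0,1]")
  dupN <- duplicated(df$patient_id[df$malignancy == "normal"])
  if (any(dupN))
    stop("manifest: patient with two normal samples: ",
         paste(unique(df$patient_id[df$malignancy == "normal"][dupN]),
               collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Read a BED file
#'
#' BED3 (or BED4 for segmentations, where column 4 is the state label)
#' in the usual 0-based half-open convention. Lines with
#' \code{start >= end} are skipped with a warning; non-numeric coordinates
#' are a hard error.
#'
#' @param path file path.
#' @param kind one of \code{"generic"}, \code{"cgi"}, \code{"blacklist"},
#'   \code{"segmentation"}. Segmentations require a 4th column and return
#'   a \code{state} metadata column.
#' @return A \link[GenomicRanges]{GRanges} sorted by (chrom, start).
#' @export
readBed <- function(path, kind = c("generic", "cgi", "blacklist",
                                   "segmentation")) {
  kind <- match.arg(kind)
  df <- read.delim(path, header = FALSE, colClasses = "character",
                   comment.char = "#")
  if (ncol(df) < 3) stop("BED: fewer than 3 columns")
  start <- suppressWarnings(as.numeric(df[[2]]))
  end <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(start) || anyNA(end)) stop("BED: malformed coordinates")
  bad <- start >= end
  if (any(bad)) {
    warning(sum(bad), " BED line(s) with start >= end skipped")
    df <- df[!bad, , drop = FALSE]; start <- start[!bad]; end <- end[!bad]
  }
  gr <- GRanges(normChrom(df[[1]]), IRanges(start + 1, end))
  if (kind == "segmentation") {
    if (ncol(df) < 4) stop("segmentation BED requires a state column")
    mcols(gr)$state <- df[[4]]
  }
  sortGenomic(gr)
}

#' Read a RepeatMasker rmsk table
#'
#' Tab-separated table with (at least) columns \code{genoName, genoStart,
#' genoEnd, strand, repName, repClass, repFamily, milliDiv}. Coordinates
#' are 0-based half-open. Each element is flagged \code{is_TE} when its
#' class belongs to the transposable-element class vocabulary
#' (DNA, DNA?, LINE, LINE?, LTR, LTR?, Other, RC, SINE, SINE?, Unknown,
#' Unknown?). \code{milliDiv} (substitutions per kb vs. the subfamily
#' consensus) is stored as a substitution proportion \code{div_p}; rows
#' with missing milliDiv are kept with \code{div_p = NA} and excluded
#' from divergence analyses.
#'
#' @param path file path.
#' @return GRanges with metadata columns \code{subfamily, family,
#'   repeat_class, div_p, is_TE}.
#' @export
readRmsk <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = "character",
                   na.strings = c("", "NA"))
  need <- c("genoName", "genoStart", "genoEnd", "strand", "repName",
            "repClass", "repFamily", "milliDiv")
  if (!all(need %in% names(df)))
    stop("rmsk: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  start <- as.numeric(df$genoStart); end <- as.numeric(df$genoEnd)
  if (anyNA(start) || anyNA(end)) stop("rmsk: malformed coordinates")
  gr <- GRanges(normChrom(df$genoName), IRanges(start + 1, end),
                strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"))
  milli <- suppressWarnings(as.numeric(df$milliDiv))
  if (any(!is.na(milli) & (milli < 0 | milli > 1000)))
    stop("rmsk: milliDiv outside [0, 1000]")
  mcols(gr)$subfamily <- df$repName
  mcols(gr)$family <- df$repFamily
  mcols(gr)$repeat_class <- df$repClass
  mcols(gr)$div_p <- milli / 1000
  mcols(gr)$is_TE <- df$repClass %in% teClasses()
  sortGenomic(gr)
}

#' Transposable-element RepeatMasker classes
#'
#' The repeat classes treated as transposable elements; everything else
#' (simple repeats, low complexity, satellites, structural RNAs) is not.
#' @return character vector of class names.
#' @export
teClasses <- function() {
  c("DNA", "DNA?", "LINE", "LINE?", "LTR", "LTR?", "Other", "RC",
    "SINE", "SINE?", "Unknown", "Unknown?")
}

#' Read a per-CpG methylation bedGraph
#'
#' One CpG per line: chrom, start, end, level. Levels may be fractions in
#' [0,1] or percentages in [0,100]; if any value exceeds 1 the whole file
#' is taken to be on the percent scale and divided by 100. Values outside
#' both ranges are a hard error. Unsorted input is sorted with a warning.
#' The CpG position is the 0-based offset of the C on the + strand
#' (= bedGraph start).
#'
#' @param path file path.
#' @param sample_id sample identifier stored in the track metadata.
#' @return width-1 GRanges with metadata column \code{level} (fraction)
#'   and \code{metadata(track)$sample_id}.
#' @export
readMethylationBedGraph <- function(path, sample_id) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   colClasses = c("character", "numeric", "numeric",
                                  "numeric"))
  level <- df[[4]]
  if (any(level < 0) || any(level > 100))
    stop("bedGraph: methylation value outside [0,1] and [0,100]")
  if (any(level > 1)) level <- level / 100
  gr <- GRanges(normChrom(df[[1]]), IRanges(df[[2]] + 1, width = 1))
  mcols(gr)$level <- level
  ord <- order(karyotypeOrder(as.character(seqnames(gr))), start(gr))
  if (is.unsorted(ord)) {
    warning("bedGraph not position-sorted; sorting")
    gr <- gr[ord]
  }
  if (anyDuplicated(paste(seqnames(gr), start(gr))))
    stop("bedGraph: duplicate CpG position")
  metadata(gr)$sample_id <- sample_id
  gr
}

#' Read a transcript model table
#'
#' Tab-separated with header \code{transcript_id, gene_id, gene_name,
#' biotype, chrom, strand, tx_start, tx_end} (0-based half-open
#' coordinates, as in a UCSC table dump).
#'
#' @param path file path.
#' @return GRanges with transcript metadata columns.
#' @export
readTranscripts <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = "character")
  need <- c("transcript_id", "gene_id", "gene_name", "biotype", "chrom",
            "strand", "tx_start", "tx_end")
  if (!all(need %in% names(df)))
    stop("transcripts: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  s <- as.numeric(df$tx_start); e <- as.numeric(df$tx_end)
  if (anyNA(s) || anyNA(e) || any(s >= e))
    stop("transcripts: invalid tx_start/tx_end")
  if (!all(df$strand %in% c("+", "-")))
    stop("transcripts: strand must be + or -")
  gr <- GRanges(normChrom(df$chrom), IRanges(s + 1, e), strand = df$strand)
  mcols(gr) <- DataFrame(transcript_id = df$transcript_id,
                         gene_id = df$gene_id, gene_name = df$gene_name,
                         biotype = df$biotype)
  sortGenomic(gr)
}

#' Derive promoter intervals from transcript models
#'
#' Promoters span \code{promoterUpstream} bp upstream to
#' \code{promoterDownstream} bp downstream of each transcription start
#' site (default 2000/500). The TSS of a minus-strand transcript is its
#' end coordinate. Promoters are clipped to chromosome bounds.
#'
#' @param transcripts GRanges from \code{\link{readTranscripts}}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param seqinfo optional \link[GenomeInfoDb]{Seqinfo} used for clipping.
#' @return GRanges with \code{transcript_id} (and \code{gene_id},
#'   \code{gene_name}, \code{biotype} when present) carried over.
#' @export
derivePromoters <- function(transcripts, config = analysisConfig(),
                            seqinfo = NULL) {
  pr <- GenomicRanges::promoters(transcripts,
                                 upstream = config@promoterUpstream,
                                 downstream = config@promoterDownstream)
  # clip to [1, chrom length]
  GenomicRanges::start(pr) <- pmax(GenomicRanges::start(pr), 1L)
  if (!is.null(seqinfo)) {
    len <- seqlengths(seqinfo)[as.character(seqnames(pr))]
    GenomicRanges::end(pr) <- pmin(end(pr), unname(len))
  }
  pr
}

#' Build the genome-wide bin grid
#'
#' Tiles every chromosome with fixed-width bins (the last bin of a
#' chromosome may be short), then flags each bin for CpG content (union of
#' CpG positions across samples) and blacklist overlap. The background set
#' -- potential DMR locations -- consists of bins on the background
#' chromosomes that contain a CpG and do not overlap the blacklist.
#'
#' @param chromSizes named vector of chromosome lengths or a Seqinfo.
#' @param cpgPositions GRanges of CpG positions (union over samples), or
#'   NULL for none.
#' @param blacklist GRanges of blacklisted regions, or NULL.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return A \linkS4class{BinGrid}.
#' @export
buildBinGrid <- function(chromSizes, cpgPositions = NULL, blacklist = NULL,
                         config = analysisConfig()) {
  si <- asSeqinfo(chromSizes)
  bins <- tileGenome(si, tilewidth = config@binWidth,
                     cut.last.tile.in.chrom = TRUE)
  mcols(bins)$bin <- as.integer((start(bins) - 1L) %/% config@binWidth)
  mcols(bins)$contains_cpg <- if (is.null(cpgPositions) ||
                                  length(cpgPositions) == 0) {
    logical(length(bins))
  } else overlapsAny(bins, cpgPositions)
  mcols(bins)$blacklisted <- if (is.null(blacklist) ||
                                 length(blacklist) == 0) {
    logical(length(bins))
  } else overlapsAny(bins, blacklist)
  new("BinGrid", bins = bins, width = config@binWidth,
      backgroundChroms = config@backgroundChroms)
}

#' @describeIn buildBinGrid All bins of the grid.
#' @param grid a \linkS4class{BinGrid}.
#' @export
gridBins <- function(grid) grid@bins

#' @describeIn buildBinGrid Background bins: CpG-containing,
#'   non-blacklisted bins on the background chromosomes.
#' @export
backgroundBins <- function(grid) {
  b <- grid@bins
  keep <- mcols(b)$contains_cpg & !mcols(b)$blacklisted &
    as.character(seqnames(b)) %in% grid@backgroundChroms
  b[keep]
}

#' Merge overlapping and abutting intervals
#'
#' Collapses an interval set to the minimal sorted set of non-overlapping
#' intervals covering the same bases. Abutting intervals (end of one
#' equals start of the next, half-open) are merged, matching the
#' \code{bedtools merge} default.
#'
#' @param intervals GRanges.
#' @return GRanges, sorted, strand-insensitive.
#' @export
mergeIntervals <- function(intervals) {
  if (length(intervals) == 0) return(granges(intervals))
  reduce(granges(intervals), ignore.strand = TRUE)
}

#' All overlapping query/subject pairs with shared-base counts
#'
#' Half-open semantics: intervals that merely touch end-to-start do not
#' overlap.
#'
#' @param query,subject GRanges.
#' @return data.frame with columns \code{query_idx}, \code{subject_idx},
#'   \code{overlap_bp}.
#' @export
overlapQuery <- function(query, subject) {
  hits <- findOverlaps(query, subject, ignore.strand = TRUE)
  if (length(hits) == 0)
    return(data.frame(query_idx = integer(), subject_idx = integer(),
                      overlap_bp = integer()))
  ov <- width(pintersect(granges(query)[queryHits(hits)],
                         granges(subject)[subjectHits(hits)],
                         ignore.strand = TRUE))
  data.frame(query_idx = queryHits(hits), subject_idx = subjectHits(hits),
             overlap_bp = ov)
}

#' Write intervals as BED
#'
#' @param gr GRanges; a metadata column named in \code{name_col} becomes
#'   BED column 4.
#' @param path output path.
#' @param name_col optional metadata column for BED4 output.
#' @export
writeBed <- function(gr, path, name_col = NULL) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (!is.null(name_col)) df$name <- mcols(gr)[[name_col]]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a methylation track as bedGraph (fractional scale)
#' @param track width-1 GRanges with \code{level}.
#' @param path output path.
#' @export
writeMethylationBedGraph <- function(track, path) {
  df <- data.frame(chrom = as.character(seqnames(track)),
                   start = start(track) - 1L, end = start(track),
                   level = mcols(track)$level)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
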