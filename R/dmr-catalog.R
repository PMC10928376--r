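#' Enumerate sample comparisons from a cohort manifest
#'
#' Three comparison types are produced, mirroring the study design:
#' \describe{
#'   \item{matched}{one per patient possessing both a normal and a tumor
#'     sample (reference = normal, alternative = tumor);}
#'   \item{normal_normal}{every unordered pair of normal samples, stored
#'     in canonical (sorted) order;}
#'   \item{cross}{every (normal, tumor) pair from different patients.
#'     With \code{include_matched_in_cross = TRUE} the matched pairs are
#'     also counted, giving the all-pairs normal x tumor total.}
#' }
#'
#' @param manifest data.frame from \code{\link{readManifest}}.
#' @param include_matched_in_cross logical; include same-patient pairs in
#'   the cross set (default FALSE).
#' @return data.frame with columns \code{comparison_id, sample_ref,
#'   sample_alt, type, patient_id} (patient of the tumor for matched
#'   comparisons, NA otherwise).
#' @examples
#' m <- data.frame(
#'   sample_id = c("P1_N", "P1_T", "P2_N", "P2_T"),
#'   patient_id = c("P1", "P1", "P2", "P2"),
#'   malignancy = c("normal", "tumor", "normal", "tumor"),
#'   smoking = "never", stage = "1A", subtype = "LUAD", purity = NA)
#' table(enumerateComparisons(m)$type)
#' @export
enumerateComparisons <- function(manifest, include_matched_in_cross = FALSE) {
  normals <- manifest[manifest$malignancy == "normal", , drop = FALSE]
  tumors <- manifest[manifest$malignancy == "tumor", , drop = FALSE]
  if (anyDuplicated(normals$patient_id))
    stop("patient with two normal samples")
  rows <- list()
  # matched: patients with both a normal and a tumor
  both <- intersect(normals$patient_id, tumors$patient_id)
  for (p in both) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_ref = normals$sample_id[normals$patient_id == p],
      sample_alt = tumors$sample_id[tumors$patient_id == p],
      type = "matched", patient_id = p)
  }
  # all unordered pairs of normals, canonical order
  ns <- sort(normals$sample_id)
  if (length(ns) >= 2) {
    cmb <- utils::combn(ns, 2)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_ref = cmb[1, ], sample_alt = cmb[2, ],
      type = "normal_normal", patient_id = NA_character_)
  }
  # cross normal-tumor pairs
  if (nrow(normals) && nrow(tumors)) {
    cross <- expand.grid(ref = normals$sample_id, alt = tumors$sample_id,
                         stringsAsFactors = FALSE)
    pn <- normals$patient_id[match(cross$ref, normals$sample_id)]
    pt <- tumors$patient_id[match(cross$alt, tumors$sample_id)]
    if (!include_matched_in_cross) cross <- cross[pn != pt, , drop = FALSE]
    if (nrow(cross))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_ref = cross$ref, sample_alt = cross$alt, type = "cross",
        patient_id = NA_character_)
  }
  out <- do.call(rbind, rows)
  out$comparison_id <- paste(out$sample_ref, out$sample_alt, sep = "_vs_")
  rownames(out) <- NULL
  out[c("comparison_id", "sample_ref", "sample_alt", "type", "patient_id")]
}

#' Load a per-comparison DMR call table
#'
#' Tab-separated text with header \code{chrom, start, end, q_value} and an
#' optional signed \code{stat} column (positive = higher in the
#' alternative sample). Coordinates are 0-based half-open and must be
#' exactly one grid bin wide and grid-aligned; misaligned rows of exact
#' bin width are snapped to the nearest bin with a warning, any other
#' width is rejected with a warning.
#'
#' @param path file path.
#' @param comparison_id identifier attached to every call.
#' @param config an \linkS4class{AnalysisConfig} (bin width).
#' @return data.frame of calls: \code{comparison_id, chrom, bin, q_value,
#'   direction} (direction from the sign of \code{stat} when present,
#'   otherwise \code{"unset"}).
#' @export
loadDMRCalls <- function(path, comparison_id, config = analysisConfig()) {
  df <- read.delim(path, header = TRUE, colClasses = "character")
  need <- c("chrom", "start", "end", "q_value")
  if (!all(need %in% names(df)))
    stop("calls: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  w <- config@binWidth
  start <- as.numeric(df$start); end <- as.numeric(df$end)
  q <- as.numeric(df$q_value)
  if (anyNA(start) || anyNA(end) || anyNA(q))
    stop("calls: malformed row")
  if (any(q < 0 | q > 1)) stop("calls: q_value outside [0,1]")
  ok_width <- (end - start) == w
  if (any(!ok_width))
    warning(sum(!ok_width), " call(s) not ", w, " bp wide rejected")
  misaligned <- ok_width & (start %% w != 0)
  if (any(misaligned))
    warning(sum(misaligned), " call(s) snapped to nearest bin")
  keep <- ok_width
  dirn <- rep("unset", nrow(df))
  if ("stat" %in% names(df)) {
    s <- suppressWarnings(as.numeric(df$stat))
    dirn <- ifelse(is.na(s) | s == 0, "unset",
                   ifelse(s > 0, "hyper", "hypo"))
  }
  data.frame(comparison_id = comparison_id,
             chrom = normChrom(df$chrom[keep]),
             bin = as.integer(round(start[keep] / w)),
             q_value = q[keep],
             direction = dirn[keep])
}

# Mean methylation over the CpGs of each requested bin, from one track.
binMeans <- function(bins_gr, track) {
  hits <- findOverlaps(bins_gr, track, ignore.strand = TRUE)
  means <- rep(NA_real_, length(bins_gr))
  if (length(hits)) {
    lv <- mcols(track)$level[subjectHits(hits)]
    agg <- tapply(lv, queryHits(hits), mean)
    means[as.integer(names(agg))] <- as.numeric(agg)
  }
  means
}

# GRanges for a call table given the grid bin width.
callsToGRanges <- function(calls, width) {
  GRanges(calls$chrom,
          IRanges(calls$bin * width + 1L, width = width))
}

#' Assign DMR direction from methylation tracks
#'
#' For each call, the mean methylation over the bin's CpGs is computed in
#' the reference (normal) and alternative (tumor) tracks; a lower mean in
#' the alternative sample makes the call \code{hypo}, higher makes it
#' \code{hyper}, equal means \code{ambiguous}. The convention is relative
#' to the tumor: a hypoDMR has lost methylation in the tumor.
#'
#' @param calls call data.frame (see \code{\link{loadDMRCalls}}).
#' @param track_ref,track_alt methylation tracks (reference / alternative).
#' @param config an \linkS4class{AnalysisConfig}.
#' @return \code{calls} with \code{direction} replaced and a
#'   \code{delta_mean} column (alt minus ref).
#' @export
assignDirection <- function(calls, track_ref, track_alt,
                            config = analysisConfig()) {
  if (!nrow(calls)) {
    calls$delta_mean <- numeric(0)
    return(calls)
  }
  gr <- callsToGRanges(calls, config@binWidth)
  m_ref <- binMeans(gr, track_ref)
  m_alt <- binMeans(gr, track_alt)
  if (anyNA(m_ref) || anyNA(m_alt))
    stop("call bin without CpG coverage in a track; ",
         "bin should not be in the CpG grid")
  delta <- m_alt - m_ref
  calls$direction <- ifelse(delta < 0, "hypo",
                            ifelse(delta > 0, "hyper", "ambiguous"))
  calls$delta_mean <- delta
  calls
}

#' Calibrate the DMR Q-value threshold
#'
#' For each candidate threshold, three diagnostics are computed over the
#' matched comparisons:
#' \describe{
#'   \item{fpr_ratio}{per matched comparison, the mean number of DMRs
#'     found between that patient's normal and every other normal sample,
#'     divided by the number of DMRs in the matched comparison;}
#'   \item{shared_fraction}{the fraction of matched DMR instances whose
#'     bin is called (same threshold) in more than one matched
#'     comparison;}
#'   \item{large_change_fraction}{the fraction of matched DMRs whose
#'     absolute methylation change between the pair exceeds
#'     \code{largeChange} (default 10\%).}
#' }
#'
#' @param all_calls data.frame of calls from all comparisons (unfiltered),
#'   with a \code{delta_mean} column on matched calls when tracks are not
#'   supplied.
#' @param comparisons comparison table from
#'   \code{\link{enumerateComparisons}}.
#' @param tracks optional named list of methylation tracks by sample_id;
#'   when given, methylation changes are computed from the tracks.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return list with \code{per_comparison} (threshold x comparison rows;
#'   \code{fpr_ratio} is NA where a comparison has no DMRs at the
#'   threshold) and \code{summary} (one row per threshold, means over
#'   comparisons).
#' @export
calibrateQThreshold <- function(all_calls, comparisons, tracks = NULL,
                                config = analysisConfig()) {
  matched <- comparisons[comparisons$type == "matched", , drop = FALSE]
  nn <- comparisons[comparisons$type == "normal_normal", , drop = FALSE]
  calls <- all_calls
  if (!is.null(tracks)) {
    parts <- split(calls, calls$comparison_id)
    parts <- lapply(names(parts), function(cid) {
      cmp <- comparisons[comparisons$comparison_id == cid, ]
      if (nrow(cmp) && cmp$type == "matched")
        assignDirection(parts[[cid]], tracks[[cmp$sample_ref]],
                        tracks[[cmp$sample_alt]], config)
      else { parts[[cid]]$delta_mean <- NA_real_; parts[[cid]] }
    })
    calls <- do.call(rbind, parts)
  }
  if (is.null(calls$delta_mean)) calls$delta_mean <- NA_real_
  rows <- list()
  for (thr in sort(config@qCalibrationGrid, decreasing = TRUE)) {
    at <- calls[calls$q_value < thr, , drop = FALSE]
    matched_at <- at[at$comparison_id %in% matched$comparison_id, ,
                     drop = FALSE]
    key <- paste(matched_at$chrom, matched_at$bin)
    n_cmp_per_bin <- tapply(matched_at$comparison_id, key,
                            function(x) length(unique(x)))
    for (i in seq_len(nrow(matched))) {
      cid <- matched$comparison_id[i]
      mine <- matched_at[matched_at$comparison_id == cid, , drop = FALSE]
      n_matched <- nrow(mine)
      # normal_normal comparisons involving this patient's normal
      this_n <- matched$sample_ref[i]
      nn_ids <- nn$comparison_id[nn$sample_ref == this_n |
                                 nn$sample_alt == this_n]
      nn_counts <- vapply(nn_ids, function(id)
        sum(at$comparison_id == id), integer(1))
      fpr <- if (n_matched == 0) NA_real_ else
        mean(nn_counts) / n_matched
      shared <- if (n_matched == 0) NA_real_ else
        mean(n_cmp_per_bin[paste(mine$chrom, mine$bin)] > 1)
      large <- if (n_matched == 0 || all(is.na(mine$delta_mean)))
        NA_real_ else
        mean(abs(mine$delta_mean) > config@largeChange, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        q_threshold = thr, comparison_id = cid, n_dmrs = n_matched,
        fpr_ratio = fpr, shared_fraction = shared,
        large_change_fraction = large)
    }
  }
  per <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per, per$q_threshold), function(d)
    data.frame(q_threshold = d$q_threshold[1],
               fpr_ratio = mean(d$fpr_ratio, na.rm = TRUE),
               shared_fraction = mean(d$shared_fraction, na.rm = TRUE),
               large_change_fraction = mean(d$large_change_fraction,
                                            na.rm = TRUE))))
  summ <- summ[order(-summ$q_threshold), ]
  rownames(summ) <- NULL
  list(per_comparison = per, summary = summ)
}

#' Filter DMR calls for cataloguing
#'
#' Keeps calls with \code{q_value} strictly below the threshold, drops
#' calls on excluded chromosomes (default chrY), and drops calls in
#' blacklisted bins when a \linkS4class{BinGrid} is supplied.
#'
#' @param calls call data.frame.
#' @param grid optional \linkS4class{BinGrid} for blacklist filtering.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return filtered call data.frame.
#' @export
filterCalls <- function(calls, grid = NULL, config = analysisConfig()) {
  keep <- calls$q_value < config@qThreshold &
    !(calls$chrom %in% config@excludedDmrChroms)
  out <- calls[keep, , drop = FALSE]
  if (!is.null(grid) && nrow(out)) {
    b <- gridBins(grid)
    bl <- b[mcols(b)$blacklisted]
    if (length(bl)) {
      blKey <- paste(as.character(seqnames(bl)), mcols(bl)$bin)
      out <- out[!(paste(out$chrom, out$bin) %in% blKey), , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

#' Build the unique-DMR catalogue
#'
#' The union of called bins across all comparisons is merged into blocks
#' of genomically adjacent bins. Blocks are numbered 1..K in karyotype
#' (chrom, start) order across the genome and bins are numbered
#' 5'-to-3' within their block, yielding identifiers
#' \code{B<block>.<pos>}. IDs are a pure function of the set of called
#' bins -- permuting the comparison input order leaves them unchanged.
#'
#' @param filtered_calls call data.frame (after \code{\link{filterCalls}}),
#'   with a \code{direction} column.
#' @param comparisons comparison table; matched comparisons define
#'   patient-level recurrence.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return A \linkS4class{DMRCatalog}.
#' @export
buildCatalog <- function(filtered_calls, comparisons = NULL,
                         config = analysisConfig()) {
  w <- config@binWidth
  calls <- filtered_calls
  key <- paste(calls$chrom, calls$bin, sep = ":")
  u <- !duplicated(key)
  ub <- data.frame(chrom = calls$chrom[u], bin = calls$bin[u])
  ord <- order(karyotypeOrder(ub$chrom), ub$bin)
  ub <- ub[ord, , drop = FALSE]
  newBlock <- c(TRUE, ub$chrom[-1] != ub$chrom[-nrow(ub)] |
                       diff(ub$bin) != 1L)
  if (!nrow(ub)) newBlock <- logical(0)
  block <- cumsum(newBlock)
  pos <- stats::ave(seq_along(block), block, FUN = seq_along)
  dmr_id <- sprintf("B%d.%d", block, pos)
  gr <- GRanges(ub$chrom, IRanges(ub$bin * w + 1L, width = w))
  mcols(gr) <- DataFrame(dmr_id = dmr_id, block_id = block,
                         pos_in_block = pos)
  id_of <- setNames(dmr_id, paste(ub$chrom, ub$bin, sep = ":"))
  obs <- data.frame(dmr_id = unname(id_of[key]),
                    comparison_id = calls$comparison_id,
                    direction = calls$direction,
                    q_value = calls$q_value)
  if (is.null(comparisons))
    comparisons <- data.frame(
      comparison_id = unique(calls$comparison_id),
      sample_ref = NA_character_, sample_alt = NA_character_,
      type = "matched",
      patient_id = unique(calls$comparison_id))
  new("DMRCatalog", dmrs = gr, observations = obs,
      comparisons = comparisons)
}

#' Per-direction recurrence of catalogued DMRs
#'
#' Counts, for every unique DMR and direction, the number of matched
#' comparisons (patients) in which it was called. A bin called hypo in
#' one patient and hyper in another contributes to both directions.
#'
#' @param catalog a \linkS4class{DMRCatalog}.
#' @return data.frame \code{dmr_id, direction, n_patients}.
#' @export
recurrence <- function(catalog) {
  obs <- catalog@observations
  matched <- catalog@comparisons$comparison_id[
    catalog@comparisons$type == "matched"]
  obs <- obs[obs$comparison_id %in% matched &
             obs$direction %in% c("hypo", "hyper"), , drop = FALSE]
  if (!nrow(obs))
    return(data.frame(dmr_id = character(), direction = character(),
                      n_patients = integer()))
  agg <- stats::aggregate(comparison_id ~ dmr_id + direction, data = obs,
                          FUN = function(x) length(unique(x)))
  names(agg)[3] <- "n_patients"
  agg
}

# Patient x DMR presence (by direction) over matched comparisons.
# Returns a list of logical matrices (patients x dmr_ids), one per
# direction present.
presenceByPatient <- function(catalog) {
  obs <- catalog@observations
  cmp <- catalog@comparisons
  matched <- cmp[cmp$type == "matched", , drop = FALSE]
  obs <- obs[obs$comparison_id %in% matched$comparison_id &
             obs$direction %in% c("hypo", "hyper"), , drop = FALSE]
  obs$patient <- matched$patient_id[match(obs$comparison_id,
                                          matched$comparison_id)]
  lapply(split(obs, obs$direction), function(d) {
    pts <- matched$patient_id
    ids <- unique(d$dmr_id)
    m <- matrix(FALSE, nrow = length(pts), ncol = length(ids),
                dimnames = list(pts, ids))
    m[cbind(match(d$patient, pts), match(d$dmr_id, ids))] <- TRUE
    m
  })
}
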