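# Shared fixtures and independent per-base oracles for interval algebra.

library(GenomicRanges)

# Small manifest: n_matched patients with both samples, n_tumor_only
# extra tumor patients.
toyManifest <- function(n_matched = 3, n_tumor_only = 0,
                        smoking = NULL) {
  pts <- sprintf("P%d", seq_len(n_matched))
  extra <- sprintf("Q%d", seq_len(n_tumor_only))
  if (is.null(smoking)) smoking <- rep("never", n_matched)
  df <- rbind(
    data.frame(sample_id = paste0(pts, "_N"), patient_id = pts,
               malignancy = "normal", smoking = smoking),
    data.frame(sample_id = paste0(pts, "_T"), patient_id = pts,
               malignancy = "tumor", smoking = smoking),
    if (n_tumor_only > 0)
      data.frame(sample_id = paste0(extra, "_T"), patient_id = extra,
                 malignancy = "tumor", smoking = "unconfirmed"))
  df$stage <- "1A"; df$subtype <- "LUAD"; df$purity <- NA_real_
  df
}

# Width-1 methylation track on one chromosome.
toyTrack <- function(pos, level, chrom = "chr1", sample_id = "S") {
  gr <- GRanges(chrom, IRanges(pos, width = 1))
  mcols(gr)$level <- level
  S4Vectors::metadata(gr)$sample_id <- sample_id
  gr
}

# Per-base brute-force oracle: total shared bases between interval i of A
# and interval j of B, using explicit base sets (1-based positions).
bruteOverlapPairs <- function(a, b) {
  out <- list()
  for (i in seq_along(a)) {
    ai <- seq(start(a)[i], end(a)[i])
    for (j in seq_along(b)) {
      shared <- length(intersect(ai, seq(start(b)[j], end(b)[j])))
      if (shared > 0)
        out[[length(out) + 1L]] <- data.frame(query_idx = i,
                                              subject_idx = j,
                                              overlap_bp = shared)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(query_idx = integer(), subject_idx = integer(),
               overlap_bp = integer())
}

# Per-base brute-force merge oracle: the union base set, as runs.
bruteMergeRuns <- function(gr) {
  if (length(gr) == 0) return(data.frame(start = integer(),
                                         end = integer()))
  bases <- sort(unique(unlist(lapply(seq_along(gr), function(i)
    seq(start(gr)[i], end(gr)[i])))))
  brk <- c(TRUE, diff(bases) > 1)
  run <- cumsum(brk)
  data.frame(start = tapply(bases, run, min),
             end = tapply(bases, run, max), row.names = NULL)
}

# Random interval set on a small genome (1-based coordinates).
randomIntervals <- function(n, genome_len = 10000, max_w = 400,
                            chrom = "chr1") {
  s <- sample.int(genome_len - max_w, n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  GRanges(chrom, IRanges(s, width = w))
}

# A crafted catalogue from per-patient DMR carriage. `carriage` is a list
# dmr_key -> list(direction =, patients = chr vector). Patients are the
# matched patients of `patients_all`.
craftCatalog <- function(carriage, patients_all) {
  cmp <- data.frame(
    comparison_id = paste0(patients_all, "_cmp"),
    sample_ref = paste0(patients_all, "_N"),
    sample_alt = paste0(patients_all, "_T"),
    type = "matched", patient_id = patients_all)
  rows <- list()
  keys <- names(carriage)
  for (k in seq_along(keys)) {
    cc <- carriage[[k]]
    for (p in cc$patients)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison_id = paste0(p, "_cmp"), chrom = "chr1",
        bin = k * 10L, q_value = 1e-6, direction = cc$direction)
  }
  calls <- do.call(rbind, rows)
  buildCatalog(calls, cmp)
}
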