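#' Write a simulated dataset to disk
#'
#' Lays a dataset out exactly as the readers expect: \code{chrom.sizes},
#' \code{manifest.tsv}, \code{cpgs.bed}, \code{cgis.bed},
#' \code{transcripts.tsv}, \code{rmsk.tsv}, \code{segmentation.bed},
#' \code{blacklist.bed}, per-sample bedGraphs under \code{meth/},
#' per-comparison call tables under \code{calls/}, a machine-readable
#' truth table \code{truth.tsv}, and a provenance file recording the
#' seed.
#'
#' @param dataset list from \code{\link{simulateDataset}}.
#' @param outdir output directory.
#' @param force overwrite a non-empty directory (default FALSE: error).
#' @return \code{outdir}, invisibly.
#' @export
writeDataset <- function(dataset, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force)
    stop("output directory exists and is not empty (use force = TRUE)")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- dataset$reference
  w <- 500L
  si <- ref$seqinfo
  write.table(data.frame(chrom = seqlevels(si),
                         size = unname(seqlengths(si))),
              file.path(outdir, "chrom.sizes"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(dataset$manifest, file.path(outdir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeBed(ref$cpgs, file.path(outdir, "cpgs.bed"))
  writeBed(ref$cgis, file.path(outdir, "cgis.bed"))
  writeBed(ref$blacklist, file.path(outdir, "blacklist.bed"))
  writeBed(ref$segmentation, file.path(outdir, "segmentation.bed"),
           name_col = "state")
  tx <- ref$transcripts
  write.table(data.frame(transcript_id = mcols(tx)$transcript_id,
                         gene_id = mcols(tx)$gene_id,
                         gene_name = mcols(tx)$gene_name,
                         biotype = mcols(tx)$biotype,
                         chrom = as.character(seqnames(tx)),
                         strand = as.character(strand(tx)),
                         tx_start = start(tx) - 1L, tx_end = end(tx)),
              file.path(outdir, "transcripts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rp <- ref$repeats
  write.table(data.frame(genoName = as.character(seqnames(rp)),
                         genoStart = start(rp) - 1L, genoEnd = end(rp),
                         strand = as.character(strand(rp)),
                         repName = mcols(rp)$subfamily,
                         repClass = mcols(rp)$repeat_class,
                         repFamily = mcols(rp)$family,
                         milliDiv = round(mcols(rp)$div_p * 1000)),
              file.path(outdir, "rmsk.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(dataset$tracks)) {
    dir.create(file.path(outdir, "meth"), showWarnings = FALSE)
    for (sid in names(dataset$tracks))
      writeMethylationBedGraph(dataset$tracks[[sid]],
                               file.path(outdir, "meth",
                                         paste0(sid, ".bedGraph")))
  }
  dir.create(file.path(outdir, "calls"), showWarnings = FALSE)
  for (cid in unique(dataset$calls$comparison_id)) {
    cc <- dataset$calls[dataset$calls$comparison_id == cid, ]
    write.table(data.frame(chrom = cc$chrom, start = cc$bin * w,
                           end = cc$bin * w + w, q_value = cc$q_value,
                           stat = ifelse(cc$direction == "hyper", 1, -1)),
                file.path(outdir, "calls", paste0(cid, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(dataset$truth$planted, file.path(outdir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$truth$hotspots,
              file.path(outdir, "truth_hotspots.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("seed: ", dataset$seed),
               paste0("generated: dmrscape synthetic dataset")),
             file.path(outdir, "provenance.yaml"))
  invisible(outdir)
}

#' Validate a dataset directory
#'
#' Reads every layer of a dataset directory back through the package
#' readers, cross-checks sample/comparison consistency, and returns a
#' summary (printed when \code{verbose}).
#'
#' @param dir dataset directory.
#' @param verbose print a summary (default TRUE).
#' @return (invisibly) list of loaded components.
#' @export
validateDataset <- function(dir, verbose = TRUE) {
  si <- readChromSizes(file.path(dir, "chrom.sizes"))
  manifest <- readManifest(file.path(dir, "manifest.tsv"))
  cpgs <- readBed(file.path(dir, "cpgs.bed"))
  cgis <- readBed(file.path(dir, "cgis.bed"), kind = "cgi")
  blacklist <- readBed(file.path(dir, "blacklist.bed"),
                       kind = "blacklist")
  segmentation <- readBed(file.path(dir, "segmentation.bed"),
                          kind = "segmentation")
  transcripts <- readTranscripts(file.path(dir, "transcripts.tsv"))
  repeats <- readRmsk(file.path(dir, "rmsk.tsv"))
  tracks <- NULL
  methdir <- file.path(dir, "meth")
  if (dir.exists(methdir)) {
    files <- dir(methdir, pattern = "\\.bedGraph$", full.names = TRUE)
    ids <- sub("\\.bedGraph$", "", basename(files))
    unknown <- setdiff(ids, manifest$sample_id)
    if (length(unknown))
      stop("methylation track for unknown sample: ",
           paste(unknown, collapse = ", "))
    tracks <- setNames(
      lapply(seq_along(files),
             function(i) readMethylationBedGraph(files[i], ids[i])), ids)
  }
  calls <- NULL
  callsdir <- file.path(dir, "calls")
  if (dir.exists(callsdir)) {
    files <- dir(callsdir, pattern = "\\.tsv$", full.names = TRUE)
    ids <- sub("\\.tsv$", "", basename(files))
    calls <- do.call(rbind, lapply(seq_along(files), function(i)
      loadDMRCalls(files[i], ids[i])))
  }
  if (verbose) {
    cat("dataset at", dir, "\n")
    cat("  chromosomes:", length(seqlevels(si)), " CpGs:", length(cpgs),
        "\n")
    cat("  samples:", nrow(manifest), " tracks:", length(tracks),
        " call tables:", length(unique(calls$comparison_id)), "\n")
    cat("  transcripts:", length(transcripts), " repeats:",
        length(repeats), " CGIs:", length(cgis), "\n")
  }
  invisible(list(seqinfo = si, manifest = manifest, cpgs = cpgs,
                 cgis = cgis, blacklist = blacklist,
                 segmentation = segmentation, transcripts = transcripts,
                 repeats = repeats, tracks = tracks, calls = calls))
}

#' Evaluate pipeline recovery of planted truth
#'
#' Runs the catalogue/specificity/density layers over a simulated
#' dataset's calls and scores them against the planted ground truth:
#' \describe{
#'   \item{recurrent}{sensitivity and precision for DMRs planted in at
#'     least two patients, detected as catalogue entries with
#'     same-direction recurrence >= 2;}
#'   \item{hotspots}{sensitivity and false discoveries for planted
#'     hotspot windows, detected by the >1\%-density-in->1-patient
#'     clause at the hotspot window width;}
#'   \item{specific}{sensitivity of never-smoker- and smoker-specific
#'     planted DMRs under the category rules, and whether the observed
#'     exclusive count exceeds every non-identity permutation of the
#'     exhaustive smoking-label null;}
#'   \item{target subfamily}{the log-odds-ratio enrichment of shared
#'     hypoDMRs over the subfamily targeted for hypomethylation (planted
#'     positive).}
#' }
#'
#' @param dataset list from \code{\link{simulateDataset}}.
#' @param analysis_config an \linkS4class{AnalysisConfig}.
#' @return list of recovery metrics.
#' @export
evaluateRecovery <- function(dataset, analysis_config = analysisConfig()) {
  truth <- dataset$truth
  calls <- dataset$calls
  if (!is.null(dataset$tracks)) {
    # re-derive matched-call directions from the methylomes, the path a
    # real dataset takes
    cmp <- dataset$comparisons
    parts <- split(calls, calls$comparison_id)
    parts <- lapply(names(parts), function(cid) {
      row <- cmp[cmp$comparison_id == cid, ]
      if (nrow(row) && row$type == "matched")
        assignDirection(parts[[cid]], dataset$tracks[[row$sample_ref]],
                        dataset$tracks[[row$sample_alt]],
                        analysis_config)
      else parts[[cid]]
    })
    calls <- do.call(rbind, lapply(parts, function(p) {
      p$delta_mean <- NULL; p
    }))
  }
  filtered <- filterCalls(calls, truth$grid, analysis_config)
  catalog <- buildCatalog(filtered, dataset$comparisons, analysis_config)
  # --- recurrent layer ---
  planted <- truth$planted
  pl_n <- lengths(strsplit(planted$patients, ","))
  rec_truth <- planted[pl_n >= 2, , drop = FALSE]
  rec <- recurrence(catalog)
  dmr_key <- setNames(
    paste(as.character(seqnames(catalog@dmrs)),
          (start(catalog@dmrs) - 1L) %/% analysis_config@binWidth,
          sep = ":"),
    mcols(catalog@dmrs)$dmr_id)
  rec_found <- paste(dmr_key[rec$dmr_id[rec$n_patients >= 2]],
                     rec$direction[rec$n_patients >= 2])
  rec_want <- paste(paste(rec_truth$chrom, rec_truth$bin, sep = ":"),
                    rec_truth$direction)
  sens_rec <- if (length(rec_want)) mean(rec_want %in% rec_found) else NA
  prec_rec <- if (length(rec_found)) mean(rec_found %in% rec_want) else NA
  # --- hotspot layer ---
  matched_ids <- dataset$comparisons$comparison_id[
    dataset$comparisons$type == "matched"]
  win <- makeWindows(dataset$reference$seqinfo,
                     dataset$config@hotspotWidth)
  dens <- windowDensity(filtered[filtered$comparison_id %in% matched_ids,
                                 , drop = FALSE],
                        win, truth$grid, analysis_config)
  hs_cfg <- analysisConfig(hotspotTopN = 0L)
  found_hs <- unique(unlist(lapply(c("hypo", "hyper"), function(d)
    detectHotspots(dens, d, hs_cfg)$window)))
  want_hs <- truth$hotspots$window
  sens_hs <- if (length(want_hs)) mean(want_hs %in% found_hs) else NA
  false_hs <- length(setdiff(found_hs, want_hs))
  # --- specificity layer ---
  manifest <- dataset$manifest
  matchedp <- unique(dataset$comparisons$patient_id[
    dataset$comparisons$type == "matched"])
  never <- unique(manifest$patient_id[manifest$smoking == "never" &
                                      manifest$patient_id %in% matchedp])
  smokers <- unique(manifest$patient_id[manifest$smoking == "smoker" &
                                        manifest$patient_id %in% matchedp])
  unconfirmed <- setdiff(matchedp, c(never, smokers))
  specific <- list()
  if (length(never) >= 2 && length(smokers) >= 3) {
    rule_never <- categoryRule("never", never, smokers,
                               min_members_with_dmr = length(never),
                               ignore = unconfirmed)
    rule_smoker <- categoryRule("smoker", smokers, never,
                                min_members_with_dmr = 3L,
                                ignore = unconfirmed)
    exn <- findExclusiveDMRs(catalog, rule_never)
    exs <- findExclusiveDMRs(catalog, rule_smoker)
    senSpec <- function(ex, type) {
      want <- planted[planted$type == type, , drop = FALSE]
      if (!nrow(want)) return(NA_real_)
      got <- paste(dmr_key[ex$dmr_id], ex$direction)
      mean(paste(paste(want$chrom, want$bin, sep = ":"),
                 want$direction) %in% got)
    }
    null_smoker <- permutationNull(catalog, rule_smoker)
    idn <- apply(null_smoker$assignments, 1, function(a)
      setequal(colnames(null_smoker$assignments)[a == "smoker"],
               smokers))
    non_id <- rowSums(null_smoker$null[!idn, , drop = FALSE])
    exceed <- sum(null_smoker$observed) > max(non_id)
    specific <- list(
      never_sensitivity = senSpec(exn, "never_specific"),
      smoker_sensitivity = senSpec(exs, "smoker_specific"),
      smoker_observed = sum(null_smoker$observed),
      smoker_null_max_nonidentity = max(non_id),
      smoker_exceeds_null = exceed,
      n_permutations = null_smoker$n_permutations)
  }
  # --- targeted repeat subfamily: shared hypoDMR enrichment sign ---
  target_lor <- NA_real_
  reps <- dataset$reference$repeats
  if (length(reps) &&
      truth$target_subfamily %in% mcols(reps)$subfamily) {
    shared_hypo <- rec$dmr_id[rec$direction == "hypo" &
                              rec$n_patients >= 2]
    dmr_set <- catalog@dmrs[mcols(catalog@dmrs)$dmr_id %in% shared_hypo]
    if (length(dmr_set))
      target_lor <- repeatSubfamilyLOR(dmr_set, truth$target_subfamily,
                                       reps)$lor
  }
  c(list(recurrent_sensitivity = sens_rec,
         recurrent_precision = prec_rec,
         hotspot_sensitivity = sens_hs,
         hotspot_false_discoveries = false_hs,
         target_subfamily_lor = target_lor,
         n_unique_dmrs = length(catalog)),
    specific)
}
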