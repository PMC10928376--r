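# Internal helpers shared across modules.

# Karyotype order: chr1..chr22, chrX, chrY, chrM first, anything else
# after in alphabetical order. Used for block numbering and output sorting.
karyotypeOrder <- function(chroms) {
  canonical <- c(paste0("chr", 1:22), "chrX", "chrY", "chrM")
  u <- unique(chroms)
  known <- intersect(canonical, u)
  extra <- sort(setdiff(u, canonical))
  factor(chroms, levels = c(known, extra))
}

# Normalize chromosome names: accept with or without "chr" prefix,
# store with prefix ("MT" is mapped to "chrM").
normChrom <- function(x) {
  x <- as.character(x)
  x[x == "MT"] <- "M"
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

# Sort a GRanges by (karyotype chromosome, start).
sortGenomic <- function(gr) {
  ord <- order(karyotypeOrder(as.character(seqnames(gr))), start(gr))
  gr[ord]
}

# Build a Seqinfo from a named vector of chromosome lengths.
asSeqinfo <- function(chromSizes) {
  if (is(chromSizes, "Seqinfo")) return(chromSizes)
  stopifnot(!is.null(names(chromSizes)), all(chromSizes > 0),
            !anyDuplicated(names(chromSizes)))
  lv <- levels(karyotypeOrder(names(chromSizes)))
  Seqinfo(seqnames = lv, seqlengths = unname(chromSizes[lv]))
}

# Draw n sub-seeds from a master seed (one independent RNG stream per
# generator component, so e.g. changing the cohort does not perturb the
# reference genome).
subSeeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Clip numeric vector into [lo, hi].
clip01 <- function(x, lo = 0, hi = 1) pmin(hi, pmax(lo, x))
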