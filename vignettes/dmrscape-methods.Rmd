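---
title: "Downstream DMR analysis with dmrscape: models, parameters and design"
author: "dmrscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Downstream DMR analysis with dmrscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrscape)
```

# Scope and data model

`dmrscape` implements the downstream half of a matched tumor/normal DNA
methylation study design built on MeDIP-seq and MRE-seq: the inputs are
(i) per-comparison tables of 500-bp bins called differentially
methylated (DMRs) by an upstream statistical caller, with Q values;
(ii) per-sample per-CpG methylation tracks (bedGraph) produced by an
upstream integrative estimator; and (iii) standard annotation layers
(transcript models, CpG islands, RepeatMasker repeats, ChromHMM
segmentations, a blacklist, chromosome sizes). The upstream caller and
the per-CpG estimator are deliberately out of scope: their output
formats are this package's input contracts.

All coordinates are handled internally as 0-based half-open intervals
(BED semantics) stored in 1-based `GRanges`; a CpG's position is the
offset of the C on the plus strand. Abutting intervals merge, matching
the default of the interval toolchain this class of pipeline is usually
built on. Chromosome names are accepted with or without the `chr`
prefix and normalized to carry it.

# The analysis chain

## Comparison enumeration

From a cohort manifest, three comparison families are enumerated:
patient-matched normal/tumor pairs (one per patient with both samples),
all unordered pairs of normal samples, and all normal-tumor pairs from
different patients. For a cohort of 10 matched normals and 17 tumors
this yields 10, 45 and 160 comparisons; the all-pairs variant (170) is
exposed through `include_matched_in_cross` because either convention is
defensible and the cross set is only used descriptively.

## Q-value calibration and filtering

The DMR significance threshold is selected from the grid
1e-2..1e-5 using three diagnostics per matched comparison: a false
positive ratio (mean DMR count between that patient's normal and every
other normal, divided by the matched DMR count), the fraction of matched
DMRs shared with another matched comparison, and the fraction with an
absolute methylation change above 10%. Calls then pass a strict
`Q < 0.001` filter; chrY calls and blacklisted bins are dropped. The
strictness of the inequality matters at the boundary and is tested.

## The unique-DMR catalogue

The union of filtered called bins is merged into blocks of genomically
adjacent bins; blocks are numbered in karyotype order and bins within a
block 5'-to-3', giving identifiers `B<block>.<pos>` that are a pure
function of the called-bin set. Direction (hypo/hyper) is defined
relative to the tumor — a hypoDMR has lost methylation in the tumor —
and is derived from the methylation tracks (mean over the bin's CpGs in
each sample of the pair), not from the caller's statistic. Recurrence is
counted per direction over matched comparisons; a bin called hypo in one
patient and hyper in another keeps both observations.

## Enrichment statistics

All enrichments are natural-log odds ratios of an observed proportion
against a background proportion. The background universe for
feature-level enrichment is the set of 500-bp bins on chromosomes
1-22+X that contain a CpG and do not overlap the blacklist ("potential
DMRs"). A Haldane-Anscombe correction (+0.5 on all four cells of the
implied 2x2 table) is applied only when a cell is zero, so ordinary
LORs are reported unperturbed. Feature overlap is counted at the bin
level (the background is bins); chromatin-state composition is counted
at the base level, because a segmentation partitions bases, and bases
covered by no segment are reported as an explicit `unannotated` state so
compositions always sum to 1.

Repeat subfamily enrichment compares the fraction of a DMR set
overlapping a subfamily against the subfamily's share of total repeat
length; subfamilies are reported only when they overlap strictly more
than 5 DMRs. Repeat divergence is summarized per subfamily as the
median Jukes-Cantor distance `d = -(3/4) ln(1 - 4p/3)` over elements,
with `p` the RepeatMasker substitution proportion (milliDiv/1000);
elements with `p >= 0.75` are outside the model's domain and are
excluded with a warning. Subfamily methylation uses the unique CpGs
overlapping any element of the subfamily (a CpG shared by overlapping
elements counts once) and requires at least 10 CpGs.

Methylation levels are categorized with strict boundaries: below 30%
low, above 70% high, and the closed interval [30%, 70%] intermediate —
the closed interval matches the way the categories are conventionally
printed ("30%-70%").

## Clinicopathologic specificity and exhaustive nulls

Category-exclusive DMRs are defined by a `CategoryRule`: carried with
the same direction by at least `min_members_with_dmr` member patients,
absent from every excluded patient, ignoring patients of unconfirmed
status. The published rules translate to: never-smoker-specific = 2 of
2 never-smokers and no smoker; smoker-specific = 3-4 of 4 smokers and
no never-smoker; low-stage = 4-5 of 5; high-stage = 3 of 3;
subtype-specific = all members and no other patient. Members that share
a category with a low-DMR-count patient can be marked *lenient*: their
carriage is not required but still counts. Whether stage/subtype
exclusivity also requires direction agreement is not specified by the
design we mirror; we require it (a DMR recurring with opposite signs is
biologically a different event) and the requirement is a natural toggle
to relax.

Significance is assessed against an exhaustive label-permutation null:
all distinct assignments of the label multiset to the permutable
patients (15 for 2 never + 4 smokers; 45 patient pairs for a
two-member subtype), with the exclusive count recomputed under each.
The observed labeling is one of the enumerated assignments, so the
observed count always lies in the null's support; under label
exchangeability its rank (random tie-breaking) is uniform. Enumeration
is capped (default 1e6 assignments) with an error advising a sampling
approach beyond that; sampling is not part of the mirrored design.

## Density, hotspots and window covariates

DMR density in a window is the number of called bins divided by the
number of CpG-containing, non-blacklisted 500-bp bins in the window,
per comparison and direction; windows without CpG bins are undefined
and excluded. Windows are tiled at 10 kb, 100 kb, 1 Mb and 10 Mb,
excluding chrY and chrM. A 1-Mb window is a hotspot when its density
exceeds 1% in more than one matched comparison, or when it ranks among
the top 15 windows by maximum density across comparisons (ties at the
boundary broken by genomic order; maximum rather than mean across
comparisons, a documented and configurable choice since either reading
is consistent with the rule's usual phrasing). The top-N clause
presumes a genome-scale window count — on the toy genomes used for
validation it would flag most windows, so recovery evaluation uses the
recurrent-density clause alone (`hotspotTopN = 0`).

Window covariates (CpG and repeat density per bp, gene/transcript
densities by biotype, per-state base proportions, mean normal-sample
methylation) are correlated with per-comparison densities, the number
of comparisons above 1%, and the mean density; a feature-space PCA
(centered, scaled) summarizes the covariate structure with per-component
variance shares and feature-component correlations.

## Global methylome profiles

Per-feature mean methylation merges intervals before averaging so each
CpG contributes once. Sample ordination uses non-overlapping 1-kb
windows restricted to CpG-containing windows: windows without variation
are dropped, the matrix is centered and scaled per window, samples are
projected with `prcomp`, and each sample's Euclidean distance to its
malignancy-group centroid is computed over *all* components — no
truncation, so by rotation invariance the distance equals the distance
in the scaled original space, which is exactly what the test suite
checks against. Pearson correlation distance (1 - r) provides the
companion sample-similarity matrix.

# The synthetic cohort generator

Because the real cohort requires controlled-access sequencing data and
two upstream engines, every layer of the analysis is validated against
a self-contained generator whose defaults mirror the study design:

* **Cohort**: 10 matched normal/tumor patients plus 7 tumor-only
  patients (17 tumors, 10 normals); 2 confirmed never-smokers, 4
  confirmed smokers, 4 unconfirmed; 5 stage-1A / 3 stage-3A / 2
  unconfirmed; two 2-patient tumor subtypes.
* **Genome**: five chromosomes (chr1-3, chrX at 2 Mb; chrY at 0.4 Mb),
  CpGs at 0.008/bp background plus 1-kb island clusters at 0.08/bp, 80%
  of islands annotated as CGIs, 60% of transcript TSSs placed on CGIs;
  ~2500 repeat elements from a 9-subfamily catalogue whose abundances
  follow the real repeat landscape (Alu dominant; the ERV1 subfamilies
  LTR12C and MER52A rare); an 18-state quiescent-dominated chromatin
  mosaic; a small blacklist.
* **Planted truth**: 30 recurrent hypoDMRs and 30 recurrent hyperDMRs
  carried by 2-6 patients with a truncated-geometric (decay 0.5)
  recurrence distribution, mirroring the steeply decaying sharing
  profile of real cohorts; 8 never-smoker-specific and 8
  smoker-specific DMRs (the latter carried by all 4 smokers); 6
  subtype-specific DMRs; 15 private DMRs per patient; 2 hotspot 1-Mb
  windows with 5% of CpG bins planted in a fixed patient pair; 30% of
  recurrent hypoDMRs placed over LTR12C elements to plant a positive
  subfamily enrichment.
* **Signal model**: normal methylomes draw per-CpG levels around
  context baselines (CGI-promoter CpGs 0.12, other CGI CpGs 0.25,
  repeat CpGs 0.85, elsewhere 0.75) with Gaussian noise (sd 0.05),
  clipped to [0,1]; tumors shift planted bins by ±0.4 and lose 0.05
  over repeats globally. Calls are simulated directly — planted bins
  with `q ~ U(0, 1e-5)`, false positives per background bin at rate
  1e-3 with `q ~ U(0, 1e-3)` — because the upstream caller's statistic
  is defined in its own publication, not in the design we mirror;
  q values are generative stand-ins, not fitted quantities.

One RNG stream is drawn per component (reference / truth / methylomes /
calls) from the master seed, so changing cohort-level knobs never
perturbs the reference genome.

What the generator does *not* emulate: read-level sampling noise and
coverage-dependent call uncertainty, copy-number and purity effects,
spatially correlated methylation (PMDs), caller-specific biases, or a
realistic chromosome count. Passing tests therefore demonstrate the
correctness of the downstream logic under the stated signal model, not
the end-to-end fidelity of the upstream assays.

## Problem sizes used in validation

The standing validation conditions are the generator defaults above
(8.4-Mb genome, ~77k CpGs, ~15.5k background bins, 27 methylomes, 55
simulated comparisons). Recovery is scored over 20 independent seeds;
the exchangeability property (uniform null rank with no planted
specificity) over 200 seeds using the calls-only fast path; interval
algebra is checked against per-base brute-force oracles on 500 random
instances of up to 40 intervals on 10-kb genomes. These sizes were
chosen so each property is measured with comfortable statistical
resolution while the whole suite stays convenient to run routinely.

# Numerical and degenerate-input choices

* Methylation bedGraphs auto-detect their scale: any value above 1
  flips the whole file to the percent scale. Mixed-scale files are
  impossible by construction; values above 100 are a hard error.
* `q < threshold` comparisons are strict everywhere.
* Degenerate BED lines (start >= end) are skipped with a warning;
  malformed coordinates are hard errors. Call rows that are not exactly
  one bin wide are rejected with a warning; bin-width rows that are
  misaligned are snapped to the nearest bin.
* LORs are natural-log (the base is configurable by exponentiation; no
  published convention forced a choice) and continuity-corrected only
  at zero cells.
* A patient pair with equal bin means gets direction `ambiguous` and is
  excluded downstream.
* Subfamilies with no CpG, or fewer than 10, are excluded from
  methylation profiling; elements without a divergence estimate are
  kept but excluded from Jukes-Cantor summaries.
* Singleton groups in the centroid-distance ordination are flagged
  degenerate (distance 0 by construction).

# Worked example

```{r example, eval = FALSE}
library(dmrscape)
ds <- simulateDataset(seed = 1)
filtered <- filterCalls(ds$calls, ds$grid)
catalog <- buildCatalog(filtered, ds$comparisons)
catalog
rec <- recurrence(catalog)
table(rec$direction, rec$n_patients)
evaluateRecovery(ds)[c("recurrent_sensitivity", "hotspot_sensitivity")]
```

# Known limitations

The catalogue is bin-resolution: sub-bin boundaries are not refined.
The permutation null is exhaustive only; cohorts whose label multiset
exceeds the enumeration cap need a sampling extension. The generator's
q values are not calibrated to any error model, so threshold
*calibration* on synthetic data exercises the mechanics (monotonicity,
ratio definitions) rather than reproducing published calibration
curves. Cross (normal vs. different-patient tumor) comparisons are
enumerated but not simulated, since no downstream statistic in scope
consumes them.
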