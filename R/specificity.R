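#' Define a clinicopathologic category rule
#'
#' A rule names the member patients of a category, the patients in which
#' a category-exclusive DMR must be absent, the minimum number of members
#' that must carry the DMR, patients ignored entirely (unconfirmed
#' status), and lenient members whose carriage is not required (but
#' counted when present). The published rules are: never-smoker-specific
#' DMRs occur in both never-smokers and no smoker; smoker-specific DMRs
#' in 3-4 of the 4 smokers and no never-smoker, ignoring unconfirmed
#' patients; low-stage in 4-5 of 5 stage-1/1A patients and no stage-3
#' patient; high-stage in at least 3 of 3; subtype-specific in all
#' members of the subtype and no other patient, with members sharing a
#' category with a low-DMR patient treated leniently.
#'
#' @param label rule name.
#' @param members patient ids belonging to the category.
#' @param excluded patient ids in which the DMR must be absent.
#' @param min_members_with_dmr minimum members carrying the DMR (default
#'   all non-lenient members).
#' @param ignore patient ids ignored (neither required nor disqualifying).
#' @param lenient member ids exempt from the carriage requirement.
#' @return a \code{CategoryRule} (classed list).
#' @export
categoryRule <- function(label, members, excluded,
                         min_members_with_dmr = NULL,
                         ignore = character(), lenient = character()) {
  if (length(intersect(members, excluded)))
    stop("rule: members and excluded overlap")
  if (!all(lenient %in% members))
    stop("rule: lenient patients must be members")
  if (is.null(min_members_with_dmr))
    min_members_with_dmr <- length(setdiff(members, lenient))
  if (min_members_with_dmr > length(members))
    stop("rule: min_members_with_dmr exceeds member count")
  structure(list(label = label, members = members, excluded = excluded,
                 min_members_with_dmr = as.integer(min_members_with_dmr),
                 ignore = ignore, lenient = lenient),
            class = "CategoryRule")
}

#' Category-exclusive DMRs
#'
#' DMRs carried (with the same direction) by at least
#' \code{min_members_with_dmr} member patients -- lenient members being
#' exempt from the requirement, though their carriage still counts -- and
#' absent from every excluded patient, ignoring the ignored patients.
#' Exclusivity is assessed per direction.
#'
#' @param catalog a \linkS4class{DMRCatalog} whose comparisons carry
#'   patient ids for the matched type.
#' @param rule a \code{\link{categoryRule}}.
#' @return data.frame \code{dmr_id, direction, n_members_with_dmr}.
#' @export
findExclusiveDMRs <- function(catalog, rule) {
  matched <- catalog@comparisons[catalog@comparisons$type == "matched", ]
  known <- matched$patient_id
  refd <- c(rule$members, rule$excluded, rule$ignore)
  if (!all(refd %in% known))
    stop("rule references unknown patient(s): ",
         paste(setdiff(refd, known), collapse = ", "))
  pres <- presenceByPatient(catalog)
  out <- lapply(names(pres), function(dirn) {
    m <- pres[[dirn]]
    req <- setdiff(rule$members, rule$lenient)
    n_mem <- colSums(m[rule$members, , drop = FALSE])
    n_req <- colSums(m[req, , drop = FALSE])
    n_exc <- if (length(rule$excluded))
      colSums(m[rule$excluded, , drop = FALSE]) else
      rep(0L, ncol(m))
    # lenient members relax the floor: require min over the required set,
    # capped by how many required members exist
    floor_req <- min(rule$min_members_with_dmr, length(req))
    ok <- n_req >= floor_req & n_exc == 0
    if (!any(ok)) return(NULL)
    data.frame(dmr_id = colnames(m)[ok], direction = dirn,
               n_members_with_dmr = unname(n_mem[ok]))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(dmr_id = character(), direction = character(),
                      n_members_with_dmr = integer())
  rownames(out) <- NULL
  out
}

#' Enumerate distinct label assignments
#'
#' All distinct ways of assigning a multiset of labels to a patient
#' vector (multiset permutations). For two label values with counts
#' (k, n-k) this is choose(n, k) assignments.
#'
#' @param patients character vector of patient ids.
#' @param labels character vector (same length): the label multiset.
#' @param cap maximum number of assignments (default 1e6); exceeding it
#'   is an error suggesting a sampling approach instead.
#' @return character matrix, one row per assignment, columns named by
#'   patient.
#' @export
enumerateLabelAssignments <- function(patients, labels, cap = 1e6) {
  stopifnot(length(patients) == length(labels))
  tab <- table(labels)
  n_assign <- factorial(length(labels)) / prod(factorial(tab))
  if (n_assign > cap)
    stop("enumeration size ", n_assign, " exceeds cap; ",
         "use a sampling mode instead (not part of the published design)")
  recur <- function(remaining) {
    if (length(remaining) == 0) return(matrix(character(0), nrow = 1))
    uniq <- unique(remaining)
    do.call(rbind, lapply(uniq, function(u) {
      rest <- remaining[-match(u, remaining)]
      sub <- recur(rest)
      cbind(matrix(u, nrow = nrow(sub)), sub)
    }))
  }
  m <- recur(sort(labels))
  m <- unique(m)
  colnames(m) <- patients
  m
}

#' Exhaustive permutation null for category-exclusive counts
#'
#' The labels of the permutable patients are reassigned in every distinct
#' way; for each assignment the rule's member and excluded sets are
#' rebuilt (members = patients assigned the member label, excluded =
#' patients assigned any other label; ignored patients stay ignored) and
#' the exclusive count per direction recomputed. The observed assignment
#' is one of the enumerated ones, so the observed count always lies in
#' the null's support.
#'
#' @param catalog a \linkS4class{DMRCatalog}.
#' @param rule the true \code{\link{categoryRule}}.
#' @param member_label label value marking rule membership (default
#'   \code{rule$label}).
#' @param cap enumeration cap (see
#'   \code{\link{enumerateLabelAssignments}}).
#' @return list: \code{observed} (named per direction),
#'   \code{null} (matrix assignments x direction),
#'   \code{n_permutations}, \code{rank} (1 + number of null values
#'   strictly below observed, per direction), \code{assignments}.
#' @export
permutationNull <- function(catalog, rule, member_label = rule$label,
                            cap = 1e6) {
  permutable <- c(rule$members, rule$excluded)
  labels <- c(rep(member_label, length(rule$members)),
              rep("other", length(rule$excluded)))
  assign <- enumerateLabelAssignments(permutable, labels, cap = cap)
  dirs <- c("hypo", "hyper")
  countFor <- function(members) {
    r <- categoryRule(rule$label, members,
                      setdiff(permutable, members),
                      min_members_with_dmr =
                        min(rule$min_members_with_dmr,
                            length(setdiff(members, rule$lenient))),
                      ignore = rule$ignore,
                      lenient = intersect(rule$lenient, members))
    ex <- findExclusiveDMRs(catalog, r)
    vapply(dirs, function(d) sum(ex$direction == d), integer(1))
  }
  null <- t(apply(assign, 1, function(a)
    countFor(permutable[a == member_label])))
  colnames(null) <- dirs
  observed <- countFor(rule$members)
  rank <- vapply(dirs, function(d)
    1L + sum(null[, d] < observed[d]), integer(1))
  list(observed = observed, null = null,
       n_permutations = nrow(assign), rank = rank,
       assignments = assign)
}

#' Smoking-driven DMRs among normal samples (field effect)
#'
#' Normal-vs-normal DMR calls are assigned to never-never, smoker-smoker,
#' never-smoker, or unconfirmed comparison categories by the smoking
#' status of the two normals. Per normal sample, the number of DMRs
#' against never-smokers and against smokers is counted. The "example"
#' tier comprises DMRs found in at least three never-vs-smoker
#' comparisons spanning both never-smoker samples and absent from the
#' never-vs-never comparison(s).
#'
#' @param normal_normal_calls call data.frame restricted to
#'   normal_normal comparisons.
#' @param comparisons comparison table.
#' @param manifest cohort manifest.
#' @return list: \code{by_category} (per-DMR category table),
#'   \code{per_sample} (counts per normal sample),
#'   \code{example_tier} (DMR keys meeting the example rule).
#' @export
normalFieldEffectDMRs <- function(normal_normal_calls, comparisons,
                                  manifest) {
  nn <- comparisons[comparisons$type == "normal_normal", , drop = FALSE]
  calls <- normal_normal_calls[
    normal_normal_calls$comparison_id %in% nn$comparison_id, ,
    drop = FALSE]
  smoke <- setNames(manifest$smoking, manifest$sample_id)
  s1 <- smoke[nn$sample_ref[match(calls$comparison_id,
                                  nn$comparison_id)]]
  s2 <- smoke[nn$sample_alt[match(calls$comparison_id,
                                  nn$comparison_id)]]
  cat <- ifelse(s1 == "never" & s2 == "never", "never_never",
         ifelse(s1 == "smoker" & s2 == "smoker", "smoker_smoker",
         ifelse((s1 == "never" & s2 == "smoker") |
                (s1 == "smoker" & s2 == "never"), "never_smoker",
                "unconfirmed")))
  calls$category <- unname(cat)
  key <- paste(calls$chrom, calls$bin, sep = ":")
  # per-sample counts: DMRs vs never-smokers and vs smokers
  long <- rbind(
    data.frame(sample = nn$sample_ref[match(calls$comparison_id,
                                            nn$comparison_id)],
               other = nn$sample_alt[match(calls$comparison_id,
                                           nn$comparison_id)]),
    data.frame(sample = nn$sample_alt[match(calls$comparison_id,
                                            nn$comparison_id)],
               other = nn$sample_ref[match(calls$comparison_id,
                                           nn$comparison_id)]))
  long$other_smoking <- smoke[long$other]
  per_sample <- do.call(rbind, lapply(split(long, long$sample),
    function(x) data.frame(sample = x$sample[1],
                           vs_never = sum(x$other_smoking == "never"),
                           vs_smoker = sum(x$other_smoking == "smoker"))))
  rownames(per_sample) <- NULL
  # example tier
  never_samples <- manifest$sample_id[manifest$smoking == "never" &
                                      manifest$malignancy == "normal"]
  ns_calls <- calls[calls$category == "never_smoker", , drop = FALSE]
  ns_key <- paste(ns_calls$chrom, ns_calls$bin, sep = ":")
  ns_never <- ifelse(s1[calls$category == "never_smoker"] == "never",
                     nn$sample_ref[match(ns_calls$comparison_id,
                                         nn$comparison_id)],
                     nn$sample_alt[match(ns_calls$comparison_id,
                                         nn$comparison_id)])
  nn_keys <- unique(key[calls$category == "never_never"])
  ex <- character(0)
  if (nrow(ns_calls)) {
    byk <- split(seq_len(nrow(ns_calls)), ns_key)
    ex <- names(byk)[vapply(byk, function(ix) {
      length(unique(ns_calls$comparison_id[ix])) >= 3 &&
        all(never_samples %in% ns_never[ix])
    }, logical(1))]
    ex <- setdiff(ex, nn_keys)
  }
  list(by_category = calls, per_sample = per_sample, example_tier = ex)
}
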