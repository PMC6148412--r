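# Consensus merging of per-caller call sets: a variant site is kept when
# at least `min_callers` independent callers report it. Agreement is on
# the normalized variant key only; callers disagree on genotype far more
# often than on site, so the consensus genotype is the modal genotype of
# the supporting callers (ties resolved to het).

#' Merge one patient's per-caller call sets by consensus
#'
#' @param callsets list of call-set tibbles (as returned by
#'   [read_caller_vcf()]), all for the same patient, with distinct caller
#'   names; alternatively one tibble with a `caller` column.
#' @param min_callers minimum number of callers that must report a key for
#'   it to be retained (default 2, the "at least two of four" rule).
#' @return tibble of consensus calls with columns `patient_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `genotype`, `supporting_callers` (list column),
#'   `support_count`, sorted by (chrom, pos, ref, alt).
#' @export
consensus_merge <- function(callsets, min_callers = 2) {
  if (is.data.frame(callsets)) callsets <- split(callsets, callsets$caller)
  if (min_callers < 1) rlang::abort("min_callers must be >= 1")
  if (min_callers > length(callsets)) {
    rlang::abort(sprintf(
      "min_callers (%d) exceeds the number of call sets (%d)",
      min_callers, length(callsets)
    ))
  }
  all_calls <- dplyr::bind_rows(callsets)
  patients <- unique(all_calls$patient_id)
  if (length(patients) > 1) {
    rlang::abort(sprintf(
      "call sets mix patient ids: %s", paste(patients, collapse = ", ")
    ))
  }
  callers <- unique(all_calls$caller)
  if (length(callers) != length(callsets)) {
    rlang::abort("caller names must be distinct across call sets")
  }
  if (nrow(all_calls) == 0) {
    return(tibble::tibble(
      patient_id = character(0), chrom = character(0), pos = integer(0),
      ref = character(0), alt = character(0), genotype = character(0),
      supporting_callers = list(), support_count = integer(0)
    ))
  }
  all_calls <- normalize_keys(all_calls)

  out <- all_calls |>
    dplyr::group_by(chrom, pos, ref, alt) |>
    dplyr::summarise(
      patient_id = patients,
      genotype = modal_genotype(genotype),
      supporting_callers = list(sort(unique(caller))),
      support_count = dplyr::n_distinct(caller),
      .groups = "drop"
    ) |>
    dplyr::filter(support_count >= min_callers) |>
    dplyr::relocate(patient_id)
  sort_by_key(out)
}

# modal genotype with ties resolved to het (conservative for the
# het-centric downstream reporting)
modal_genotype <- function(g) {
  tab <- sort(table(g), decreasing = TRUE)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) "het" else top[1]
}

#' Consensus-merge a whole cohort
#'
#' Applies [consensus_merge()] independently to each patient's call sets
#' and reports the per-patient funnel (raw union size vs consensus size).
#'
#' @param per_patient_callsets named list: patient id -> list of call-set
#'   tibbles; alternatively one tibble with `caller` and `patient_id`
#'   columns.
#' @param min_callers passed to [consensus_merge()].
#' @return list with `calls` (one bound tibble of consensus calls) and
#'   `funnel` (tibble patient_id, n_union, n_consensus).
#' @export
consensus_cohort <- function(per_patient_callsets, min_callers = 2) {
  if (is.data.frame(per_patient_callsets)) {
    per_patient_callsets <- lapply(
      split(per_patient_callsets, per_patient_callsets$patient_id),
      function(df) split(df, df$caller)
    )
  }
  merged <- purrr::imap(per_patient_callsets, function(cs, pid) {
    consensus_merge(cs, min_callers = min_callers)
  })
  funnel <- purrr::imap_dfr(per_patient_callsets, function(cs, pid) {
    union_keys <- unique(key_id(normalize_keys(dplyr::bind_rows(cs))))
    tibble::tibble(
      patient_id = pid,
      n_union = length(union_keys),
      n_consensus = nrow(merged[[pid]])
    )
  })
  list(calls = dplyr::bind_rows(merged), funnel = funnel)
}
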