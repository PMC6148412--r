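# The filter cascade: population allele frequency -> functional impact
# (loss-of-function or predictor-vote damaging missense) -> phenotype gene
# criteria (ocular/known gene AND known-or-QTL) -> dominant-disease
# exclusion. Every variant leaves the cascade with a full decision trail;
# a retained candidate has PASS at every stage.

#' Cascade configuration
#'
#' @param max_af_threshold maximum allele frequency tolerated in any
#'   population database (inclusive; default 0.005).
#' @param min_pathogenic_votes minimum pathogenic calls, out of the fixed
#'   panel of `panel_size` predictors, for a missense variant to count as
#'   damaging (default 6 of 8). Missing predictions count as
#'   non-pathogenic votes.
#' @param panel_size size of the predictor panel (8: SIFT, PolyPhen2, LRT,
#'   MutationTaster, MutationAssessor, FATHMM, CADD, DANN).
#' @param min_callers consensus support required upstream (default 2).
#' @param splice_score_threshold minimum splice-impact score for a
#'   splice-region variant to count as loss-of-function (default 0.6, the
#'   recommended cutoff of the adaptive-boosting splice score).
#' @param lof_consequences consequence terms treated as loss-of-function
#'   outright.
#' @param apply_dominant_exclusion whether to run the dominant
#'   ocular-disease exclusion stage (default `TRUE`).
#' @return a `cascade_config` list.
#' @export
cascade_config <- function(max_af_threshold = 0.005,
                           min_pathogenic_votes = 6,
                           panel_size = 8,
                           min_callers = 2,
                           splice_score_threshold = 0.6,
                           lof_consequences = c("frameshift", "stop_gained",
                                                "splice_donor", "splice_acceptor"),
                           apply_dominant_exclusion = TRUE) {
  stopifnot(
    max_af_threshold > 0, max_af_threshold < 1,
    min_pathogenic_votes >= 1, min_pathogenic_votes <= panel_size,
    splice_score_threshold >= 0, splice_score_threshold <= 1
  )
  structure(
    list(
      max_af_threshold = max_af_threshold,
      min_pathogenic_votes = min_pathogenic_votes,
      panel_size = panel_size,
      min_callers = min_callers,
      splice_score_threshold = splice_score_threshold,
      lof_consequences = lof_consequences,
      apply_dominant_exclusion = apply_dominant_exclusion
    ),
    class = "cascade_config"
  )
}

#' Allele frequency from a heterozygote carrier count
#'
#' For a variant observed only in heterozygotes, the allele frequency in a
#' reference panel is `n_het / (2 * n_individuals)`. The returned value is
#' rounded to `sig_figs` significant figures for display; the raw
#' frequency is kept in the `"raw"` attribute.
#'
#' @param n_het number of heterozygous carriers (>= 0).
#' @param n_individuals number of genotyped individuals (> 0).
#' @param sig_figs significant figures for the display value (default 2).
#' @return display-rounded allele frequency with attribute `raw`.
#' @examples
#' maf_from_het_count(1, 4325)   # 0.00012
#' maf_from_het_count(2, 33359)  # 3e-05
#' @export
maf_from_het_count <- function(n_het, n_individuals, sig_figs = 2) {
  if (n_individuals <= 0) rlang::abort("n_individuals must be positive")
  if (n_het < 0 || n_het > n_individuals) {
    rlang::abort("n_het must lie in [0, n_individuals]")
  }
  raw <- n_het / (2 * n_individuals)
  out <- signif(raw, sig_figs)
  attr(out, "raw") <- raw
  out
}

# maximum allele frequency across the population databases; 0 when the
# variant is absent from all of them
variant_max_af <- function(variants) {
  af <- as.matrix(variants[.af_cols])
  af[is.na(af)] <- 0
  apply(af, 1, max)
}

#' Population-frequency filter for one annotated variant
#' @param variant one-row tibble of an annotated variant.
#' @param config a [cascade_config()].
#' @return list with `pass` and `max_af`.
#' @export
frequency_pass <- function(variant, config = cascade_config()) {
  m <- variant_max_af(variant)[1]
  list(pass = m <= config$max_af_threshold, max_af = m)
}

# pathogenic predictor votes over the fixed panel; missing predictions are
# non-pathogenic votes
pathogenic_votes <- function(variants) {
  calls <- as.matrix(variants[.predictor_cols])
  rowSums(calls == "pathogenic", na.rm = TRUE)
}

#' Functional impact class of annotated variants
#'
#' `lof` for frameshift/stop-gained/canonical-splice consequences and for
#' splice-region variants whose splice score reaches the threshold;
#' `damaging_missense` for missense variants with at least
#' `min_pathogenic_votes` pathogenic predictor calls; `none` otherwise.
#' Frameshift, stop and canonical-splice variants bypass the predictor
#' vote entirely.
#'
#' @param variants tibble of annotated variants.
#' @param config a [cascade_config()].
#' @return character vector in `{lof, damaging_missense, none}`.
#' @export
impact_class <- function(variants, config = cascade_config()) {
  votes <- pathogenic_votes(variants)
  splice <- !is.na(variants$splice_score) &
    variants$splice_score >= config$splice_score_threshold
  dplyr::case_when(
    variants$consequence %in% config$lof_consequences ~ "lof",
    variants$consequence == "splice_region" & splice ~ "lof",
    variants$consequence == "missense" & votes >= config$min_pathogenic_votes ~ "damaging_missense",
    TRUE ~ "none"
  )
}

#' Phenotype-gene filter for one variant
#'
#' A variant passes when its gene is eye-disease related (known
#' high-myopia gene or ocular-disease gene) AND is either a known
#' high-myopia gene or lies — at the variant position — inside a myopia
#' QTL interval.
#'
#' @param gene_symbol gene symbol.
#' @param chrom,pos variant position.
#' @param evidence a `gene_evidence` tibble.
#' @param qtl_index a `qtl_index`.
#' @return list with `pass`, `gene_class` (`known_hm`, `ocular`, or `NA`),
#'   `qtl_names`, `detail`.
#' @export
phenotype_pass <- function(gene_symbol, chrom, pos, evidence, qtl_index) {
  qtls <- qtl_overlap(chrom, pos, qtl_index)[[1]]
  row <- evidence[evidence$gene == toupper(gene_symbol), ]
  if (nrow(row) == 0) {
    return(list(pass = FALSE, gene_class = NA_character_, qtl_names = qtls,
                detail = "gene not in phenotype evidence table"))
  }
  eye <- row$is_known_hm[1] || row$is_ocular[1]
  anchored <- row$is_known_hm[1] || length(qtls) > 0
  if (!eye) {
    list(pass = FALSE, gene_class = NA_character_, qtl_names = qtls,
         detail = "gene not eye-disease related")
  } else if (!anchored) {
    list(pass = FALSE, gene_class = "ocular", qtl_names = qtls,
         detail = "ocular gene neither known high-myopia nor inside a MYP QTL")
  } else {
    list(pass = TRUE,
         gene_class = if (row$is_known_hm[1]) "known_hm" else "ocular",
         qtl_names = qtls,
         detail = if (row$is_known_hm[1]) "known high-myopia gene"
                  else sprintf("ocular gene in QTL %s", paste(qtls, collapse = ",")))
  }
}

#' Run the full filter cascade over annotated variants
#'
#' Stages are applied in order frequency -> impact -> phenotype-gene ->
#' dominant exclusion. Membership of the retained set is order-invariant
#' (a candidate must pass every stage); the order only determines which
#' stage a rejected variant is attributed to.
#'
#' @param variants annotation tibble (layout of
#'   [read_annotation_table()]).
#' @param evidence a `gene_evidence` tibble.
#' @param qtl_index a `qtl_index`.
#' @param config a [cascade_config()].
#' @param patient_phenotypes named list patient id -> character vector of
#'   phenotype terms (used by the dominant-exclusion stage; patients
#'   absent from the list are treated as having no recorded terms).
#' @return list with `retained` (candidate tibble carrying `max_af`,
#'   `impact`, `gene_class`, `qtl_names`, `inheritance`, `decision_trail`)
#'   and `rejected` (same layout plus `failure_stage`).
#' @export
apply_cascade <- function(variants, evidence, qtl_index,
                          config = cascade_config(),
                          patient_phenotypes = list()) {
  v <- tibble::as_tibble(variants)
  n <- nrow(v)
  v$max_af <- if (n) variant_max_af(v) else numeric(0)
  v$impact <- if (n) impact_class(v, config) else character(0)

  freq_ok <- v$max_af <= config$max_af_threshold
  impact_ok <- v$impact != "none"

  # phenotype-gene stage, vectorized: one interval query for all variants
  # and one evidence join (semantics identical to phenotype_pass())
  qtl_names <- if (n) qtl_overlap(v$chrom, v$pos, qtl_index) else list()
  ev_idx <- match(toupper(v$gene), evidence$gene)
  in_table <- !is.na(ev_idx)
  is_known <- in_table & evidence$is_known_hm[ev_idx]
  is_ocular <- in_table & evidence$is_ocular[ev_idx]
  in_qtl <- purrr::map_int(qtl_names, length) > 0
  eye <- is_known | is_ocular
  pheno_ok <- eye & (is_known | in_qtl)
  gene_class <- dplyr::case_when(
    is_known ~ "known_hm",
    is_ocular & eye ~ "ocular",
    TRUE ~ NA_character_
  )
  qtl_label <- purrr::map_chr(qtl_names, paste, collapse = ",")
  pheno_detail <- dplyr::case_when(
    !in_table ~ "gene not in phenotype evidence table",
    !eye ~ "gene not eye-disease related",
    is_known ~ "known high-myopia gene",
    in_qtl ~ sprintf("ocular gene in QTL %s", qtl_label),
    TRUE ~ "ocular gene neither known high-myopia nor inside a MYP QTL"
  )

  if (config$apply_dominant_exclusion) {
    dom_ok <- rep(TRUE, n)
    dom_detail <- rep("no dominant ocular disease on record", n)
    has_dom <- which(in_table & !is.na(evidence$dominant_disease[ev_idx]))
    for (i in has_dom) {
      res <- flag_dominant_exclusion(
        v$gene[i], patient_phenotypes[[v$patient_id[i]]] %||% character(0), evidence
      )
      dom_ok[i] <- res$decision == "KEEP"
      dom_detail[i] <- res$reason
    }
  } else {
    dom_ok <- rep(TRUE, n)
    dom_detail <- rep("dominant-exclusion stage disabled", n)
  }

  trail <- purrr::map(seq_len(n), function(i) {
    tibble::tibble(
      stage = c("frequency", "impact", "phenotype_gene", "dominant_exclusion"),
      pass = c(freq_ok[i], impact_ok[i], pheno_ok[i], dom_ok[i]),
      detail = c(
        sprintf("max_af %.6g vs threshold %.6g", v$max_af[i], config$max_af_threshold),
        sprintf("impact class: %s", v$impact[i]),
        pheno_detail[i],
        dom_detail[i]
      )
    )
  })

  v$gene_class <- gene_class
  v$qtl_names <- qtl_names
  v$inheritance <- evidence$inheritance[match(toupper(v$gene), evidence$gene)]
  v$decision_trail <- trail

  keep <- freq_ok & impact_ok & pheno_ok & dom_ok
  stage_fail <- dplyr::case_when(
    !freq_ok ~ "frequency",
    !impact_ok ~ "impact",
    !pheno_ok ~ "phenotype_gene",
    !dom_ok ~ "dominant_exclusion",
    TRUE ~ NA_character_
  )
  rejected <- v[!keep, , drop = FALSE]
  rejected$failure_stage <- stage_fail[!keep]
  list(retained = v[keep, , drop = FALSE], rejected = rejected)
}

#' Per-stage funnel counts of a cascade run
#'
#' Counts variants entering and surviving each stage in the canonical
#' order, reading stage outcomes from the decision trails.
#'
#' @param cascade result of [apply_cascade()].
#' @return tibble with `stage`, `n_in`, `n_out`.
#' @export
cascade_funnel <- function(cascade) {
  all_v <- dplyr::bind_rows(
    cascade$retained,
    dplyr::select(cascade$rejected, -failure_stage)
  )
  stages <- c("frequency", "impact", "phenotype_gene", "dominant_exclusion")
  alive <- rep(TRUE, nrow(all_v))
  out <- purrr::map_dfr(stages, function(s) {
    n_in <- sum(alive)
    pass_s <- purrr::map_lgl(all_v$decision_trail, function(tr) tr$pass[tr$stage == s])
    alive <<- alive & pass_s
    tibble::tibble(stage = s, n_in = n_in, n_out = sum(alive))
  })
  out
}

#' Summarize a retained candidate set into the cohort funnel report
#'
#' @param retained retained candidate tibble from [apply_cascade()].
#' @param cohort_size optional total number of patients screened; enables
#'   the percentage yield field.
#' @return a `cohort_summary` list: `n_variants_retained`, `n_genes`,
#'   `n_patients_with_candidate`, `patient_yield_pct` (when `cohort_size`
#'   given), `n_in_qtl`, `n_known_hm_variants`, `n_ocular_variants`,
#'   `consequence_breakdown` (splicing / frameshift / missense / other),
#'   `genes_multi_patient`.
#' @export
summarize_candidates <- function(retained, cohort_size = NULL) {
  breakdown <- c(
    splicing = sum(retained$consequence %in%
                     c("splice_donor", "splice_acceptor", "splice_region")),
    frameshift = sum(retained$consequence == "frameshift"),
    missense = sum(retained$consequence == "missense"),
    other = sum(!retained$consequence %in%
                  c("splice_donor", "splice_acceptor", "splice_region",
                    "frameshift", "missense"))
  )
  multi <- retained |>
    dplyr::group_by(gene) |>
    dplyr::summarise(n_patients = dplyr::n_distinct(patient_id), .groups = "drop") |>
    dplyr::filter(n_patients >= 2)
  out <- list(
    n_variants_retained = nrow(retained),
    n_genes = dplyr::n_distinct(retained$gene),
    n_patients_with_candidate = dplyr::n_distinct(retained$patient_id),
    patient_yield_pct = if (!is.null(cohort_size)) {
      round(100 * dplyr::n_distinct(retained$patient_id) / cohort_size, 1)
    } else {
      NA_real_
    },
    n_in_qtl = sum(purrr::map_int(retained$qtl_names, length) > 0),
    n_known_hm_variants = sum(retained$gene_class == "known_hm"),
    n_ocular_variants = sum(retained$gene_class == "ocular"),
    consequence_breakdown = breakdown,
    genes_multi_patient = sort(multi$gene)
  )
  stopifnot(
    out$n_known_hm_variants + out$n_ocular_variants == out$n_variants_retained,
    sum(breakdown) == out$n_variants_retained
  )
  structure(out, class = "cohort_summary")
}

#' @exportS3Method base::print
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Cohort candidate summary\n",
      "  variants retained : %d (%d known-HM, %d ocular-disease)\n",
      "  distinct genes    : %d\n",
      "  patients          : %d%s\n",
      "  in a MYP QTL      : %d\n",
      "  consequences      : %d splicing, %d frameshift, %d missense, %d other\n",
      "  multi-patient     : %s\n"
    ),
    x$n_variants_retained, x$n_known_hm_variants, x$n_ocular_variants,
    x$n_genes, x$n_patients_with_candidate,
    if (!is.na(x$patient_yield_pct)) sprintf(" (%.1f%% of cohort)", x$patient_yield_pct) else "",
    x$n_in_qtl,
    x$consequence_breakdown["splicing"], x$consequence_breakdown["frameshift"],
    x$consequence_breakdown["missense"], x$consequence_breakdown["other"],
    if (length(x$genes_multi_patient)) paste(x$genes_multi_patient, collapse = ", ") else "none"
  ))
  invisible(x)
}
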