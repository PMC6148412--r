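# Hypergeometric term enrichment with Benjamini-Hochberg FDR control.
# The background ("universe") is configurable: the genome-wide
# protein-coding set or a phenotype-restricted set such as the eye-disease
# gene list. Only genes with at least one annotation in the namespace
# under test count toward the universe and the draw, the standard
# enrichment convention.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability that a
#' random draw of `n` genes from a universe of `N`, of which `K` carry the
#' term, contains at least `k` term genes. Computed in log space via the
#' survival function of the hypergeometric distribution.
#'
#' @param k observed overlap (candidate genes carrying the term).
#' @param K background genes carrying the term.
#' @param n candidate set size.
#' @param N background size.
#' @return the upper-tail probability.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) ||
      any(k > pmin(K, n)) || any(K > N) || any(n > N)) {
    rlang::abort("impossible hypergeometric counts (need 0 <= k <= min(K, n), K <= N, n <= N)")
  }
  # P(X >= k) = 1 - P(X <= k-1); evaluated as the upper tail in log space
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment: with p-values sorted ascending,
#' `q_i = min_{j >= i} p_j * m / j`, clipped at 1, returned in the
#' original input order.
#'
#' @param p_values numeric vector of p-values.
#' @return adjusted values in input order.
#' @export
bh_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Term enrichment of a gene set against a background
#'
#' @param candidate_genes character vector of gene symbols.
#' @param term_annotations tibble from [read_gene_term_table()] (`term_id`,
#'   `term_name`, `namespace`, `gene`).
#' @param background_genes character vector: the gene universe.
#' @param fdr_cutoff reported in the `significant` column (default 0.05);
#'   all terms with overlap k >= 1 are returned regardless.
#' @return tibble of enrichment results (`term_id`, `term_name`,
#'   `namespace`, `k`, `K`, `n`, `N`, `p_value`, `fdr`, `significant`),
#'   BH-adjusted within each namespace, sorted by p-value.
#' @export
enrich <- function(candidate_genes, term_annotations, background_genes,
                   fdr_cutoff = 0.05) {
  candidate_genes <- unique(toupper(candidate_genes))
  background_genes <- unique(toupper(background_genes))
  ann <- dplyr::mutate(term_annotations, gene = toupper(gene))
  outside <- setdiff(candidate_genes, background_genes)
  if (length(outside) > 0) {
    rlang::warn(sprintf(
      "%d candidate gene(s) outside the background were dropped: %s",
      length(outside), paste(head(sort(outside), 10), collapse = ", ")
    ))
    candidate_genes <- intersect(candidate_genes, background_genes)
  }
  ann <- dplyr::filter(ann, gene %in% background_genes)

  res <- ann |>
    dplyr::group_by(namespace) |>
    dplyr::group_modify(function(df, grp) {
      annotated_bg <- unique(df$gene)
      N <- length(annotated_bg)
      cand <- intersect(candidate_genes, annotated_bg)
      n <- length(cand)
      per_term <- df |>
        dplyr::group_by(term_id, term_name) |>
        dplyr::summarise(
          K = dplyr::n_distinct(gene),
          k = dplyr::n_distinct(intersect(gene, cand)),
          .groups = "drop"
        ) |>
        dplyr::filter(k >= 1)
      if (nrow(per_term) == 0) return(per_term[0, ])
      per_term$n <- n
      per_term$N <- N
      per_term$p_value <- purrr::pmap_dbl(
        list(per_term$k, per_term$K), function(k, K) hypergeom_upper(k, K, n, N)
      )
      per_term$fdr <- bh_adjust(per_term$p_value)
      per_term
    }) |>
    dplyr::ungroup()
  if (nrow(res) == 0) {
    return(tibble::tibble(
      term_id = character(0), term_name = character(0), namespace = character(0),
      k = integer(0), K = integer(0), n = integer(0), N = integer(0),
      p_value = numeric(0), fdr = numeric(0), significant = logical(0)
    ))
  }
  res |>
    dplyr::mutate(significant = fdr < fdr_cutoff) |>
    dplyr::select(term_id, term_name, namespace, k, K, n, N, p_value, fdr, significant) |>
    dplyr::arrange(p_value, term_id)
}

#' Terms significant in one analysis but not in another
#'
#' Set difference on the significant term sets of two enrichment runs:
#' terms with FDR below the cutoff in `results_a` that are either absent
#' from `results_b` or not significant there. Used to contrast the
#' candidate-gene enrichment with the broader eye-disease-gene enrichment.
#'
#' @param results_a,results_b enrichment tibbles from [enrich()].
#' @param fdr_cutoff significance cutoff (default 0.05).
#' @param top_n when not `NULL`, keep at most `top_n` terms per namespace,
#'   ranked by decreasing `-log10(fdr)` (default 10).
#' @return tibble of `results_a` rows unique to analysis A, with a
#'   `neg_log10_fdr` column, ranked within namespace.
#' @export
unique_terms <- function(results_a, results_b, fdr_cutoff = 0.05, top_n = 10) {
  sig_a <- dplyr::filter(results_a, fdr < fdr_cutoff)
  sig_b_terms <- results_b$term_id[results_b$fdr < fdr_cutoff]
  out <- sig_a |>
    dplyr::filter(!term_id %in% sig_b_terms) |>
    dplyr::mutate(neg_log10_fdr = -log10(fdr)) |>
    dplyr::group_by(namespace) |>
    dplyr::arrange(dplyr::desc(neg_log10_fdr), term_id, .by_group = TRUE)
  if (!is.null(top_n)) out <- dplyr::slice_head(out, n = top_n)
  dplyr::ungroup(out)
}
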