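# Expression comparisons on eye-tissue profiles: the log2(RPKM + 0.001)
# transform, a one-sided gene-set-vs-rest test per tissue, deterministic
# hierarchical-clustering heatmap ordering, and a per-gene tissue class
# (retina-high vs retina-and-sclera) read off the linear-scale means.

#' Log-transform an RNA-seq expression matrix
#'
#' Applies `log2(value + pseudocount)` to every cell of an RNA-seq (RPKM)
#' matrix. Microarray matrices are already on a log-like normalized scale
#' and pass through unchanged.
#'
#' @param m an `expression_matrix`.
#' @param pseudocount added before the log (default 0.001).
#' @return an `expression_matrix` with transformed values (RNA-seq mode)
#'   or `m` unchanged (microarray mode).
#' @export
log_transform <- function(m, pseudocount = 0.001) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$mode != "rnaseq") return(m)
  out <- m
  out$values <- log2(m$values + pseudocount)
  out$mode <- "rnaseq"
  attr(out, "log2_transformed") <- TRUE
  out
}

#' One-sided gene-set vs rest expression test in one tissue
#'
#' For the samples of one tissue, each gene is reduced to its mean
#' expression across those samples; a Welch two-sample t-test then
#' compares the gene-set genes against all remaining genes with
#' alternative "set > rest". Genes are the exchangeable units: the test is
#' on per-gene means, not on individual samples.
#'
#' @param m an `expression_matrix` (transform first for RNA-seq data).
#' @param gene_set character vector of gene symbols.
#' @param tissue_label tissue whose samples are used.
#' @return list with `p_value`, `mean_set`, `mean_rest`, `n_set`,
#'   `n_rest`, `statistic`.
#' @export
set_vs_rest_test <- function(m, gene_set, tissue_label) {
  stopifnot(inherits(m, "expression_matrix"))
  samples <- names(m$tissue)[m$tissue == tissue_label]
  if (length(samples) == 0) {
    rlang::abort(sprintf("no samples labelled '%s'", tissue_label))
  }
  in_set <- rownames(m$values) %in% gene_set
  if (!any(in_set)) {
    rlang::abort("gene set shares no genes with the expression matrix")
  }
  gene_means <- rowMeans(m$values[, samples, drop = FALSE])
  set_vals <- gene_means[in_set]
  rest_vals <- gene_means[!in_set]
  if (length(set_vals) < 2 || length(rest_vals) < 2) {
    rlang::abort("need at least 2 genes in the set and 2 outside it")
  }
  tt <- stats::t.test(set_vals, rest_vals, alternative = "greater", var.equal = FALSE)
  list(
    p_value = unname(tt$p.value),
    mean_set = mean(set_vals),
    mean_rest = mean(rest_vals),
    n_set = length(set_vals),
    n_rest = length(rest_vals),
    statistic = unname(tt$statistic)
  )
}

#' Gene-set vs rest test across all tissues
#' @param m an `expression_matrix`.
#' @param gene_set character vector of gene symbols.
#' @return tibble with one row per tissue (`tissue`, `p_value`,
#'   `mean_set`, `mean_rest`, `n_set`, `n_rest`).
#' @export
set_vs_rest_all_tissues <- function(m, gene_set) {
  purrr::map_dfr(sort(unique(m$tissue)), function(t) {
    res <- set_vs_rest_test(m, gene_set, t)
    tibble::tibble(
      tissue = t, p_value = res$p_value, mean_set = res$mean_set,
      mean_rest = res$mean_rest, n_set = res$n_set, n_rest = res$n_rest
    )
  })
}

#' Heatmap-ready hierarchical clustering order
#'
#' Orders rows (genes) and columns (samples) by hierarchical clustering
#' with correlation distance (`1 - Pearson r`) and average linkage, the
#' common heatmap default. To make the leaf order reproducible regardless
#' of input row/column order, rows and columns are first sorted by name
#' (the deterministic tie rule) before clustering.
#'
#' @param m an `expression_matrix`.
#' @return list with `row_order` and `col_order`: character vectors of
#'   gene and sample names in display order.
#' @export
hierarchical_order <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  vals <- m$values[order(rownames(m$values)), order(colnames(m$values)), drop = FALSE]
  row_ord <- cluster_order(vals)
  col_ord <- cluster_order(t(vals))
  list(row_order = row_ord, col_order = col_ord)
}

cluster_order <- function(vals) {
  if (nrow(vals) < 3) return(rownames(vals))
  cc <- suppressWarnings(stats::cor(t(vals)))
  cc[is.na(cc)] <- 0
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  rownames(vals)[hc$order]
}

#' Classify a gene's tissue expression profile
#'
#' Operates on linear-scale values. A gene is `retina_high` when its mean
#' over the retina tissues is at least `ratio_threshold` times its mean
#' over the sclera tissues; `retina_and_sclera` when both means exceed the
#' overall matrix median; `other` otherwise.
#'
#' @param m an `expression_matrix` on the linear scale.
#' @param genes gene symbols to classify (default: all rows).
#' @param tissue_groups named list mapping the two group labels to tissue
#'   label vectors; defaults to retina = macular + peripheral retina,
#'   sclera = sclera.
#' @param ratio_threshold retina/sclera mean ratio declaring retina-high
#'   (default 2).
#' @return tibble with `gene` and `class`.
#' @export
tissue_class <- function(m, genes = rownames(m$values),
                         tissue_groups = list(
                           retina = c("macular_retina", "peripheral_retina"),
                           sclera = "sclera"
                         ),
                         ratio_threshold = 2) {
  stopifnot(inherits(m, "expression_matrix"))
  genes <- intersect(genes, rownames(m$values))
  if (length(genes) == 0) rlang::abort("no requested gene is in the matrix")
  retina_samples <- names(m$tissue)[m$tissue %in% tissue_groups$retina]
  sclera_samples <- names(m$tissue)[m$tissue %in% tissue_groups$sclera]
  if (length(retina_samples) == 0 || length(sclera_samples) == 0) {
    rlang::abort("tissue groups must each match at least one sample")
  }
  med <- stats::median(m$values)
  retina_mean <- rowMeans(m$values[genes, retina_samples, drop = FALSE])
  sclera_mean <- rowMeans(m$values[genes, sclera_samples, drop = FALSE])
  cls <- dplyr::case_when(
    retina_mean >= ratio_threshold * sclera_mean ~ "retina_high",
    retina_mean > med & sclera_mean > med ~ "retina_and_sclera",
    TRUE ~ "other"
  )
  tibble::tibble(gene = genes, class = unname(cls),
                 retina_mean = unname(retina_mean),
                 sclera_mean = unname(sclera_mean))
}
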