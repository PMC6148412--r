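# End-to-end orchestration: consensus -> filter cascade -> enrichment ->
# expression -> network, driven by one YAML/list config. Stages whose
# inputs are not configured are skipped; every run writes a run_info.json
# with package version, config hash, and seed so results are traceable.

.config_keys <- c("inputs", "params", "stages", "seed")
.input_keys <- c("vcfs", "annotations", "qtl", "gene_sets", "dominant",
                 "phenotypes", "go_annotations", "background",
                 "expression", "network_edges")

#' Run the full prioritization pipeline from one config
#'
#' @param config a YAML file path or an equivalent nested list with
#'   sections `inputs` (`annotations`, `qtl`, `gene_sets` with `known` /
#'   `hpo` / `retnet` / `omim`, optional `vcfs`, `dominant`, `phenotypes`,
#'   `go_annotations`, `background`, `expression`, `network_edges`),
#'   `params` (overrides for [cascade_config()] fields plus `fdr_cutoff`),
#'   optional `stages` (logical switches `consensus`, `enrichment`,
#'   `expression`, `network`), and optional `seed`.
#' @param out_dir report directory (created if needed).
#' @return (invisibly) list with `summary`, `retained`, `rejected`, and
#'   the per-stage result tables.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  inputs <- config$inputs %||% list()
  unknown_in <- setdiff(names(inputs), .input_keys)
  if (length(unknown_in) > 0) {
    rlang::abort(sprintf("unknown inputs key(s): %s", paste(unknown_in, collapse = ", ")))
  }
  params <- config$params %||% list()
  stages <- config$stages %||% list()

  # fail on missing files before any stage runs
  declared <- c(
    inputs$annotations, inputs$qtl, unlist(inputs$gene_sets),
    inputs$dominant, inputs$phenotypes, inputs$go_annotations,
    inputs$background, inputs$expression$matrix, inputs$expression$meta,
    inputs$expression$set, inputs$network_edges,
    vapply(inputs$vcfs %||% list(), function(v) v$path, character(1))
  )
  declared <- unname(declared[is.character(declared)])
  missing_files <- declared[!file.exists(declared)]
  if (length(missing_files) > 0) {
    rlang::abort(sprintf("declared input file(s) not found: %s",
                         paste(missing_files, collapse = ", ")))
  }
  for (req in c("annotations", "qtl", "gene_sets")) {
    if (is.null(inputs[[req]])) {
      rlang::abort(sprintf("config inputs must declare '%s'", req))
    }
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fdr_cutoff <- params$fdr_cutoff %||% 0.05
  cfg <- do.call(cascade_config, params[setdiff(names(params), "fdr_cutoff")])

  inform_stage <- function(...) rlang::inform(sprintf(...))

  annotations <- read_annotation_table(inputs$annotations)
  qtl <- read_qtl_table(inputs$qtl)
  qtl_index <- build_interval_index(qtl)
  evidence <- assemble_gene_sets(
    known_hm_genes = read_gene_set(inputs$gene_sets$known),
    hpo_genes = if (!is.null(inputs$gene_sets$hpo)) read_gene_set(inputs$gene_sets$hpo) else character(0),
    retnet_genes = if (!is.null(inputs$gene_sets$retnet)) read_gene_set(inputs$gene_sets$retnet) else character(0),
    omim_ocular_genes = if (!is.null(inputs$gene_sets$omim)) read_gene_set(inputs$gene_sets$omim) else character(0),
    dominant_table = if (!is.null(inputs$dominant)) read_dominant_table(inputs$dominant) else NULL
  )
  phenotypes <- if (!is.null(inputs$phenotypes)) {
    yaml::read_yaml(inputs$phenotypes)
  } else {
    list()
  }

  # --- consensus stage (optional): restrict annotations to variants with
  # sufficient multi-caller support
  consensus_funnel <- NULL
  if (!is.null(inputs$vcfs) && !isFALSE(stages$consensus)) {
    inform_stage("consensus: merging %d caller VCF(s)", length(inputs$vcfs))
    callsets <- purrr::map_dfr(inputs$vcfs, function(v) {
      read_caller_vcf(v$path, v$caller)
    })
    cons <- consensus_cohort(callsets, min_callers = cfg$min_callers)
    consensus_funnel <- cons$funnel
    keep_ids <- paste(cons$calls$patient_id, key_id(cons$calls))
    before <- nrow(annotations)
    annotations <- annotations[paste(annotations$patient_id, key_id(annotations)) %in% keep_ids, ]
    inform_stage("consensus: %d of %d annotated variants have >=%d-caller support",
                 nrow(annotations), before, cfg$min_callers)
  }

  # --- filter cascade
  inform_stage("cascade: filtering %d annotated variants", nrow(annotations))
  cascade <- apply_cascade(annotations, evidence, qtl_index, cfg, phenotypes)
  cohort_size <- if (length(phenotypes) > 0) length(phenotypes) else NULL
  summary <- summarize_candidates(cascade$retained, cohort_size = cohort_size)
  write_candidate_table(cascade$retained, file.path(out_dir, "candidates.tsv"))
  funnel <- cascade_funnel(cascade)
  readr::write_tsv(funnel, file.path(out_dir, "funnel.tsv"), progress = FALSE)
  jsonlite::write_json(unclass(summary), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  candidate_genes <- sort(unique(cascade$retained$gene))
  results <- list(summary = summary, retained = cascade$retained,
                  rejected = cascade$rejected, funnel = funnel,
                  consensus_funnel = consensus_funnel)

  # --- enrichment stage
  if (!is.null(inputs$go_annotations) && !is.null(inputs$background) &&
      !isFALSE(stages$enrichment)) {
    inform_stage("enrichment: %d candidate genes", length(candidate_genes))
    ann_terms <- read_gene_term_table(inputs$go_annotations)
    background <- read_gene_set(inputs$background)
    enr_cand <- enrich(candidate_genes, ann_terms, background, fdr_cutoff)
    enr_eye <- enrich(evidence$gene, ann_terms, background, fdr_cutoff)
    uniq <- unique_terms(enr_cand, enr_eye, fdr_cutoff)
    readr::write_tsv(enr_cand, file.path(out_dir, "enrichment_candidates.tsv"), progress = FALSE)
    readr::write_tsv(enr_eye, file.path(out_dir, "enrichment_eye_genes.tsv"), progress = FALSE)
    readr::write_tsv(uniq, file.path(out_dir, "enrichment_unique_terms.tsv"), progress = FALSE)
    results$enrichment <- list(candidates = enr_cand, eye_genes = enr_eye, unique = uniq)
  }

  # --- expression stage
  if (!is.null(inputs$expression) && !isFALSE(stages$expression)) {
    ex <- inputs$expression
    inform_stage("expression: testing candidate set across tissues")
    m <- read_expression_matrix(ex$matrix, ex$meta, ex$mode %||% "rnaseq")
    mt <- log_transform(m)
    set_genes <- read_gene_set(ex$set)
    tests <- set_vs_rest_all_tissues(mt, set_genes)
    classes <- tissue_class(m, genes = intersect(candidate_genes, rownames(m$values)))
    readr::write_tsv(tests, file.path(out_dir, "expression_tests.tsv"), progress = FALSE)
    readr::write_tsv(classes, file.path(out_dir, "expression_tissue_class.tsv"), progress = FALSE)
    ord <- hierarchical_order(mt)
    readr::write_tsv(
      tibble::tibble(gene = ord$row_order),
      file.path(out_dir, "expression_row_order.tsv"), progress = FALSE
    )
    results$expression <- list(tests = tests, classes = classes, order = ord)
  }

  # --- network stage
  if (!is.null(inputs$network_edges) && !isFALSE(stages$network) &&
      length(candidate_genes) > 0) {
    inform_stage("network: building FI subnetwork for %d genes", length(candidate_genes))
    net <- read_edge_list(inputs$network_edges)
    sample_counts <- cascade$retained |>
      dplyr::group_by(gene) |>
      dplyr::summarise(n = dplyr::n_distinct(patient_id), .groups = "drop")
    subnet <- build_subnetwork(candidate_genes, net,
                               sample_counts = setNames(sample_counts$n, sample_counts$gene))
    modules <- detect_modules(subnet)
    node_table <- dplyr::left_join(subnet$nodes, modules$membership, by = "gene")
    readr::write_tsv(node_table, file.path(out_dir, "network_nodes.tsv"), progress = FALSE)
    edges <- igraph::as_data_frame(subnet$graph, what = "edges")
    readr::write_tsv(tibble::as_tibble(edges), file.path(out_dir, "network_edges.tsv"), progress = FALSE)
    if (!is.null(inputs$go_annotations) && !is.null(inputs$background)) {
      principal <- module_principal_process(
        modules$membership, read_gene_term_table(inputs$go_annotations),
        read_gene_set(inputs$background), fdr_cutoff
      )
      readr::write_tsv(principal, file.path(out_dir, "network_modules.tsv"), progress = FALSE)
      results$network_modules <- principal
    }
    results$network <- list(subnetwork = subnet, modules = modules)
  }

  run_info <- list(
    package = "oculoprior",
    version = as.character(utils::packageVersion("oculoprior")),
    config_hash = rlang::hash(config),
    seed = config$seed %||% NA
  )
  jsonlite::write_json(run_info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
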