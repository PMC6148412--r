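# Functional-interaction subnetwork analysis: connect the candidate genes
# inside a larger FI network by inserting linker genes (non-candidates
# lying on short shortest paths between candidate pairs), split the
# resulting subnetwork into modules by greedy modularity maximization, and
# label each module with its principal biological process by enrichment.

#' Build a candidate subnetwork with linker genes
#'
#' Takes the induced subgraph of the FI network on the candidate genes
#' plus all linkers: for every candidate pair whose shortest-path distance
#' in the parent network is at most `max_path_len`, every intermediate
#' node of every shortest path between them is inserted as a linker.
#' Directly interacting candidate pairs contribute no linkers.
#'
#' @param candidates character vector of candidate gene symbols.
#' @param network an undirected simple `igraph` graph with named vertices
#'   (e.g. from [read_edge_list()]).
#' @param max_path_len maximum shortest-path length between candidates for
#'   linker insertion (default 2: one intermediate gene).
#' @param sample_counts optional named integer vector gene -> number of
#'   patients carrying candidate variants in that gene (display sizing).
#' @return an `fi_subnetwork`: list with `graph` (induced subgraph),
#'   `nodes` (tibble `gene`, `role` in {candidate, linker},
#'   `sample_count`), and `missing` (candidates absent from the network).
#' @export
build_subnetwork <- function(candidates, network, max_path_len = 2,
                             sample_counts = NULL) {
  candidates <- unique(toupper(candidates))
  if (length(candidates) == 0) rlang::abort("candidate set is empty")
  if (igraph::is_directed(network)) network <- igraph::as_undirected(network)
  vnames <- igraph::V(network)$name
  present <- sort(intersect(candidates, vnames))
  missing <- sort(setdiff(candidates, vnames))
  if (length(missing) > 0) {
    rlang::inform(sprintf(
      "%d candidate gene(s) absent from the network: %s",
      length(missing), paste(missing, collapse = ", ")
    ))
  }
  linkers <- character(0)
  if (length(present) >= 2) {
    d <- igraph::distances(network, v = present, to = present)
    pairs <- which(upper.tri(d) & d >= 2 & d <= max_path_len, arr.ind = TRUE)
    if (nrow(pairs) > 0) {
      for (i in seq_len(nrow(pairs))) {
        from <- present[pairs[i, 1]]
        to <- present[pairs[i, 2]]
        paths <- igraph::all_shortest_paths(network, from = from, to = to)$vpaths
        mids <- unlist(lapply(paths, function(p) {
          nm <- names(p)
          if (length(nm) > 2) nm[-c(1, length(nm))] else character(0)
        }))
        linkers <- c(linkers, mids)
      }
    }
    linkers <- sort(setdiff(unique(linkers), present))
  }
  keep <- sort(c(present, linkers))
  subg <- igraph::induced_subgraph(network, vids = keep)
  nodes <- tibble::tibble(
    gene = keep,
    role = ifelse(keep %in% present, "candidate", "linker"),
    sample_count = if (is.null(sample_counts)) {
      NA_integer_
    } else {
      as.integer(sample_counts[keep])
    }
  )
  structure(list(graph = subg, nodes = nodes, missing = missing),
            class = "fi_subnetwork")
}

#' @exportS3Method base::print
print.fi_subnetwork <- function(x, ...) {
  cat(sprintf(
    "<fi_subnetwork> %d candidates + %d linkers, %d edges, %d component(s)\n",
    sum(x$nodes$role == "candidate"), sum(x$nodes$role == "linker"),
    igraph::ecount(x$graph), igraph::count_components(x$graph)
  ))
  invisible(x)
}

#' Detect network modules by greedy modularity maximization
#'
#' Clusters the subnetwork with fast-greedy (CNM-style) modularity
#' maximization on the unweighted undirected graph. Vertices are processed
#' in lexicographic name order so the partition is deterministic; module
#' ids are relabelled by decreasing size (ties by first member name).
#'
#' @param subnetwork an `fi_subnetwork` or an `igraph` graph.
#' @return list with `membership` (tibble `gene`, `module`) and
#'   `modularity` (Q of the reported partition).
#' @export
detect_modules <- function(subnetwork) {
  g <- if (inherits(subnetwork, "fi_subnetwork")) subnetwork$graph else subnetwork
  perm <- order(igraph::V(g)$name)
  g <- igraph::permute(g, match(seq_along(perm), perm))
  if (igraph::ecount(g) == 0) {
    # modularity is undefined without edges; every node is its own module
    memb <- seq_len(igraph::vcount(g))
    q <- NA_real_
  } else {
    cl <- igraph::cluster_fast_greedy(g)
    # cut the merge dendrogram at the modularity maximum; on ties prefer
    # fewer modules (igraph's own cut can leave a spurious split when the
    # final merge changes Q by ~0)
    ks <- seq(igraph::count_components(g), igraph::vcount(g))
    memb <- NULL
    q <- -Inf
    for (k in ks) {
      memb_k <- igraph::cut_at(cl, no = k)
      q_k <- igraph::modularity(g, memb_k)
      if (q_k > q + 1e-12) {
        q <- q_k
        memb <- memb_k
      }
    }
  }
  # canonical module ids: decreasing size, ties by first member name
  info <- tibble::tibble(gene = igraph::V(g)$name, raw = as.integer(memb)) |>
    dplyr::group_by(raw) |>
    dplyr::mutate(size = dplyr::n(), first_gene = min(gene)) |>
    dplyr::ungroup()
  order_tbl <- info |>
    dplyr::distinct(raw, size, first_gene) |>
    dplyr::arrange(dplyr::desc(size), first_gene)
  relabel <- setNames(seq_len(nrow(order_tbl)), order_tbl$raw)
  membership <- info |>
    dplyr::transmute(gene, module = unname(relabel[as.character(raw)])) |>
    dplyr::arrange(module, gene)
  list(
    membership = membership,
    modularity = q
  )
}

#' Principal biological process of each module
#'
#' Runs [enrich()] per module against the configured background and
#' reports the lowest-FDR biological-process term (`namespace == "BP"`)
#' as the module's principal process. Modules without any annotated gene
#' are labelled `"none"`. Switching `background_genes` from the genome
#' universe to the eye-disease gene list asks which processes distinguish
#' a module beyond being eye-related at all.
#'
#' @param membership tibble `gene`, `module` from [detect_modules()].
#' @param term_annotations tibble from [read_gene_term_table()].
#' @param background_genes character vector: the enrichment universe.
#' @param fdr_cutoff cutoff reported in the `significant` column.
#' @return tibble with `module`, `term_id`, `term_name`, `fdr`,
#'   `significant` (one row per module).
#' @export
module_principal_process <- function(membership, term_annotations,
                                     background_genes, fdr_cutoff = 0.05) {
  bp <- dplyr::filter(term_annotations, namespace == "BP")
  purrr::map_dfr(sort(unique(membership$module)), function(mod) {
    genes <- membership$gene[membership$module == mod]
    res <- suppressWarnings(enrich(genes, bp, background_genes, fdr_cutoff))
    if (nrow(res) == 0) {
      tibble::tibble(module = mod, term_id = NA_character_, term_name = "none",
                     fdr = NA_real_, significant = FALSE)
    } else {
      top <- res[order(res$fdr, res$p_value, res$term_id), ][1, ]
      tibble::tibble(module = mod, term_id = top$term_id,
                     term_name = top$term_name, fdr = top$fdr,
                     significant = top$fdr < fdr_cutoff)
    }
  })
}
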