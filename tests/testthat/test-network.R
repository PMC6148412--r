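# Subnetwork construction with linker genes (BFS oracle), greedy
# modularity module detection, and module process labelling.

edge_graph <- function(...) {
  igraph::simplify(igraph::graph_from_data_frame(
    as.data.frame(matrix(toupper(c(...)), ncol = 2, byrow = TRUE)),
    directed = FALSE
  ))
}

test_that("a single intermediate node becomes a linker", {
  g <- edge_graph("A", "X", "X", "B", "Y", "Z")
  sub <- build_subnetwork(c("A", "B"), g)
  expect_equal(sub$nodes$gene[sub$nodes$role == "linker"], "X")
  ed <- igraph::as_data_frame(sub$graph)
  expect_setequal(paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to)),
                  c("A X", "B X"))
})

test_that("directly connected candidates need no linkers", {
  g <- edge_graph("RPGR", "CEP290", "CEP290", "Q")
  sub <- build_subnetwork(c("RPGR", "CEP290"), g)
  expect_equal(sum(sub$nodes$role == "linker"), 0)
  expect_equal(igraph::ecount(sub$graph), 1)
})

test_that("missing candidates are reported, empty candidate set errors", {
  g <- edge_graph("A", "B")
  expect_message(sub <- build_subnetwork(c("A", "B", "GHOST"), g), "GHOST")
  expect_equal(sub$missing, "GHOST")
  expect_error(build_subnetwork(character(0), g), "empty")
})

test_that("linker set equals BFS all-pairs shortest-path enumeration on random graphs", {
  for (seed in c(61, 62, 63)) {
    set.seed(seed)
    g <- igraph::sample_gnp(50, 0.08)
    igraph::V(g)$name <- sprintf("N%02d", 1:50)
    cand <- sample(igraph::V(g)$name, 6)
    sub <- build_subnetwork(cand, g, max_path_len = 2)
    # oracle: for each candidate pair at distance 2, collect every node
    # adjacent to both
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    rownames(adj) <- colnames(adj) <- igraph::V(g)$name
    d <- igraph::distances(g)
    expected <- character(0)
    cu <- toupper(cand)
    for (i in seq_along(cand)) {
      for (j in seq_along(cand)) {
        if (i < j && d[cand[i], cand[j]] == 2) {
          mids <- names(which(adj[cand[i], ] == 1 & adj[cand[j], ] == 1))
          expected <- c(expected, mids)
        }
      }
    }
    expected <- sort(setdiff(unique(toupper(expected)), cu))
    expect_equal(sort(sub$nodes$gene[sub$nodes$role == "linker"]), expected)
  }
})

test_that("increasing max_path_len never removes linkers", {
  set.seed(64)
  g <- igraph::sample_gnp(60, 0.05)
  igraph::V(g)$name <- sprintf("N%02d", 1:60)
  cand <- sample(igraph::V(g)$name, 5)
  l2 <- build_subnetwork(cand, g, max_path_len = 2)$nodes
  l3 <- build_subnetwork(cand, g, max_path_len = 3)$nodes
  expect_true(all(l2$gene[l2$role == "linker"] %in% l3$gene[l3$role == "linker"]))
})

test_that("subnetwork is invariant to candidate input order", {
  set.seed(65)
  g <- igraph::sample_gnp(40, 0.1)
  igraph::V(g)$name <- sprintf("N%02d", 1:40)
  cand <- sample(igraph::V(g)$name, 6)
  a <- build_subnetwork(cand, g)
  b <- build_subnetwork(rev(cand), g)
  expect_equal(a$nodes, b$nodes)
})

test_that("two cliques joined by a bridge split at the bridge; cliques stay whole", {
  edges <- c(utils::combn(paste0("A", 1:5), 2),
             utils::combn(paste0("B", 1:5), 2),
             "A1", "B1")
  g <- edge_graph(edges)
  mod <- detect_modules(g)
  memb <- mod$membership
  expect_equal(dplyr::n_distinct(memb$module), 2)
  a_mods <- unique(memb$module[startsWith(memb$gene, "A")])
  b_mods <- unique(memb$module[startsWith(memb$gene, "B")])
  expect_length(a_mods, 1)
  expect_length(b_mods, 1)
  expect_false(a_mods == b_mods)
  expect_gt(mod$modularity, 0.3)
})

test_that("a complete graph is one module; modules always partition the nodes", {
  g <- edge_graph(c(utils::combn(paste0("K", 1:6), 2)))
  mod <- detect_modules(g)
  expect_equal(dplyr::n_distinct(mod$membership$module), 1)
  expect_setequal(mod$membership$gene, paste0("K", 1:6))
  expect_equal(anyDuplicated(mod$membership$gene), 0)
})

test_that("planted 4-block partitions are recovered with high agreement", {
  aris <- vapply(1:20, function(s) {
    net <- generate_network(synthetic_config(seed = s))
    mod <- detect_modules(net$graph)
    truth <- net$truth$block[match(mod$membership$gene, net$truth$gene)]
    adjusted_rand(mod$membership$module, truth)
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})

test_that("module labels come from per-module enrichment, with background switching", {
  universe <- sprintf("G%03d", 1:400)
  mod_a <- universe[1:10]
  mod_b <- universe[11:20]
  eye_genes <- universe[1:200]
  ann <- dplyr::bind_rows(
    tibble::tibble(term_id = "T:A", term_name = "process alpha",
                   namespace = "BP", gene = mod_a),
    # a broad term covering most eye genes: enriched vs the genome
    # universe, not vs the eye-gene background
    tibble::tibble(term_id = "T:EYE", term_name = "broad eye process",
                   namespace = "BP", gene = c(mod_b, eye_genes[21:190])),
    # baseline annotation so the whole universe counts as annotated
    tibble::tibble(term_id = "T:BG", term_name = "housekeeping",
                   namespace = "BP", gene = universe)
  )
  membership <- tibble::tibble(
    gene = c(mod_a, mod_b, "UNANNOTATED1", "UNANNOTATED2"),
    module = c(rep(1, 10), rep(2, 10), 3, 3)
  )
  res <- module_principal_process(membership, ann, universe)
  expect_equal(res$term_name[res$module == 1], "process alpha")
  expect_equal(res$term_name[res$module == 2], "broad eye process")
  expect_equal(res$term_name[res$module == 3], "none")
  expect_true(res$significant[res$module == 2])

  # against the eye-gene background, the broad term loses significance
  res_eye <- module_principal_process(membership, ann, eye_genes)
  expect_false(res_eye$significant[res_eye$module == 2])
})
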