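# The synthetic-data generators: determinism, generator bookkeeping, and
# full cascade recovery of planted candidates and decoys.

test_that("generators are deterministic for a fixed seed", {
  c1 <- generate_cohort(synthetic_config(seed = 71))
  c2 <- generate_cohort(synthetic_config(seed = 71))
  expect_identical(c1, c2)
  e1 <- generate_expression(synthetic_config(seed = 71,
                                             expression = list(n_genes = 500, set_size = 50)))
  e2 <- generate_expression(synthetic_config(seed = 71,
                                             expression = list(n_genes = 500, set_size = 50)))
  expect_identical(e1, e2)
  n1 <- generate_network(synthetic_config(seed = 71))
  n2 <- generate_network(synthetic_config(seed = 71))
  expect_identical(igraph::as_edgelist(n1$graph), igraph::as_edgelist(n2$graph))
  a1 <- generate_term_annotations(sprintf("G%03d", 1:100), seed = 71)
  a2 <- generate_term_annotations(sprintf("G%03d", 1:100), seed = 71)
  expect_identical(a1, a2)
  # and a different seed changes the cohort
  expect_false(identical(c1$annotations, generate_cohort(synthetic_config(seed = 72))$annotations))
})

test_that("decoy class counts match the configuration exactly", {
  cfg <- synthetic_config(seed = 73, n_decoys_per_class = 3)
  cohort <- generate_cohort(cfg)
  decoys <- cohort$truth[cohort$truth$status == "decoy", ]
  counts <- table(decoys$decoy_class)
  expect_setequal(names(counts),
                  c("common_af", "low_votes", "non_eye_gene", "eye_no_qtl",
                    "dominant_mismatch", "single_caller"))
  expect_true(all(counts == 3))
  expect_equal(sum(cohort$truth$status == "true"), cfg$n_true_candidates)
  expect_equal(sum(cohort$truth$status == "background"),
               cfg$n_patients * cfg$background_variants_per_patient)
})

test_that("single-caller decoys appear in exactly one call set, others in >= 2", {
  cohort <- generate_cohort(synthetic_config(seed = 74))
  support <- cohort$callsets |>
    dplyr::count(patient_id, chrom, pos, ref, alt, name = "n_callers")
  merged <- dplyr::left_join(cohort$truth, support,
                             by = c("patient_id", "chrom", "pos", "ref", "alt"))
  single <- merged$decoy_class %in% "single_caller"
  expect_true(all(merged$n_callers[single] == 1))
  expect_true(all(merged$n_callers[!single] >= 2))
})

test_that("cascade retains exactly the planted candidates across seeds", {
  for (seed in 1:20) {
    cohort <- generate_cohort(synthetic_config(
      seed = seed, background_variants_per_patient = 10
    ))
    ev <- cohort_evidence(cohort)
    idx <- build_interval_index(cohort$qtl)

    # consensus first: the single-caller decoys must fall out here
    cons <- consensus_cohort(cohort$callsets,
                             min_callers = cohort$config$cascade$min_callers)
    cons_ids <- paste(cons$calls$patient_id, key_id(cons$calls))
    ann_ids <- paste(cohort$annotations$patient_id, key_id(cohort$annotations))
    surviving <- cohort$annotations[ann_ids %in% cons_ids, ]
    truth_ids <- paste(cohort$truth$patient_id, key_id(cohort$truth))
    dropped <- cohort$truth[!truth_ids %in% cons_ids, ]
    expect_true(all(dropped$decoy_class == "single_caller"))
    expect_equal(sum(cohort$truth$decoy_class %in% "single_caller"),
                 nrow(dropped))

    res <- apply_cascade(surviving, ev, idx, cohort$config$cascade,
                         cohort$patient_phenotypes)
    ret_ids <- paste(res$retained$patient_id, key_id(res$retained))
    true_ids <- truth_ids[cohort$truth$status == "true"]
    expect_setequal(ret_ids, true_ids)

    # every decoy that reached the cascade fails at its engineered stage
    rej_ids <- paste(res$rejected$patient_id, key_id(res$rejected))
    decoys <- cohort$truth[cohort$truth$status == "decoy" &
                             cohort$truth$decoy_class != "single_caller", ]
    decoy_ids <- paste(decoys$patient_id, key_id(decoys))
    got_stage <- res$rejected$failure_stage[match(decoy_ids, rej_ids)]
    expect_equal(got_stage, decoys$expected_failure)
  }
})

test_that("expression generator output is a valid non-negative RPKM matrix", {
  gen <- generate_expression(synthetic_config(
    seed = 75, expression = list(n_genes = 800, set_size = 100)
  ))
  expect_s3_class(gen$matrix, "expression_matrix")
  expect_true(all(gen$matrix$values >= 0))
  expect_equal(nrow(gen$matrix$values), 800)
  expect_equal(length(gen$set_genes), 100)
  expect_equal(sort(unique(gen$matrix$tissue)),
               sort(synthetic_config()$expression$tissues))
})

test_that("planted term annotations are recovered by enrichment", {
  universe <- sprintf("G%04d", 1:3000)
  target <- universe[101:125]
  ann <- generate_term_annotations(
    universe, planted = list("planted signal" = target),
    n_background_terms = 60, seed = 76
  )
  res <- enrich(target, ann, universe)
  expect_equal(res$term_name[1], "planted signal")
  expect_lt(res$fdr[1], 0.05)
})
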