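# Synthetic inputs for end-to-end testing: cohorts with planted true
# candidates and single-violation decoys, per-caller call sets, gene
# evidence files, QTL tables, expression matrices with planted set shifts
# and tissue profiles, term annotations with planted terms, and
# planted-partition FI networks. Every generator is deterministic for a
# fixed seed. Decoys violate exactly one filter criterion each, so every
# rejection path of the cascade is independently exercised.

#' Synthetic cohort configuration
#'
#' Defaults mirror the study conditions of the motivating cohort: 20
#' patients, four variant callers with a 2-of-4 consensus, a 0.005 allele
#' frequency cutoff, a 6-of-8 predictor vote, a 58 known / 651 ocular gene
#' evidence list, 26 myopia QTL regions, eye-tissue expression with a
#' 709-gene eye set, and a 4-block interaction network.
#'
#' @param n_patients cohort size (default 20).
#' @param n_true_candidates planted cascade survivors (default 20).
#' @param n_decoys_per_class decoys per violation class (default 2); the
#'   six classes are common allele frequency, insufficient predictor
#'   votes, non-eye gene, ocular gene outside every QTL, dominant-disease
#'   phenotype mismatch, and single-caller support.
#' @param background_variants_per_patient common/synonymous filler
#'   variants per patient (default 30).
#' @param n_callers number of variant callers emulated (default 4).
#' @param n_known_genes,n_ocular_genes evidence-list class sizes
#'   (defaults 58 and 651).
#' @param n_qtl number of synthetic MYP QTL regions (default 26).
#' @param seed RNG seed; a fixed seed gives byte-identical outputs.
#' @param cascade a [cascade_config()] mirrored by the generator.
#' @param expression list: `n_genes`, `set_size`, `tissues`,
#'   `eye_tissues`, `samples_per_tissue`, `set_shift_sd`, `noise_sd`,
#'   `n_planted_profiles`.
#' @param network list: `n_blocks`, `block_size`, `p_in`, `p_out`,
#'   `n_candidates`.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 20,
                             n_true_candidates = 20,
                             n_decoys_per_class = 2,
                             background_variants_per_patient = 30,
                             n_callers = 4,
                             n_known_genes = 58,
                             n_ocular_genes = 651,
                             n_qtl = 26,
                             seed = 1,
                             cascade = cascade_config(),
                             expression = list(),
                             network = list()) {
  expr_defaults <- list(
    n_genes = 19000, set_size = 709,
    tissues = c("macular_retina", "peripheral_retina", "RPE", "choroid",
                "sclera", "cornea", "optic_nerve"),
    eye_tissues = c("macular_retina", "peripheral_retina", "RPE", "choroid",
                    "sclera"),
    samples_per_tissue = 4, set_shift_sd = 2, noise_sd = 1,
    n_planted_profiles = 20
  )
  net_defaults <- list(n_blocks = 4, block_size = 15, p_in = 0.8,
                       p_out = 0.05, n_candidates = 12)
  expression <- utils::modifyList(expr_defaults, expression)
  network <- utils::modifyList(net_defaults, network)
  stopifnot(
    n_patients >= 1, n_true_candidates >= 0, n_decoys_per_class >= 0,
    n_callers >= 1, network$p_in >= 0, network$p_in <= 1,
    network$p_out >= 0, network$p_out <= 1
  )
  structure(
    list(
      n_patients = n_patients,
      n_true_candidates = n_true_candidates,
      n_decoys_per_class = n_decoys_per_class,
      background_variants_per_patient = background_variants_per_patient,
      n_callers = n_callers,
      n_known_genes = n_known_genes,
      n_ocular_genes = n_ocular_genes,
      n_qtl = n_qtl,
      seed = seed,
      cascade = cascade,
      expression = expression,
      network = network
    ),
    class = "synthetic_config"
  )
}

.decoy_classes <- c("common_af", "low_votes", "non_eye_gene", "eye_no_qtl",
                    "dominant_mismatch", "single_caller")

#' Generate a synthetic cohort with planted candidates and decoys
#'
#' Builds the complete input bundle for a cascade run: a QTL table, gene
#' evidence lists (known high-myopia / HPO / RetNet / OMIM ocular with a
#' dominant-disease sidecar), an annotation table holding planted true
#' candidates, single-violation decoys and common background variants, and
#' per-caller call sets in which every consensus-intended variant is
#' reported by at least `min_callers` callers while each single-caller
#' decoy appears in exactly one.
#'
#' @param config a [synthetic_config()].
#' @return list with `annotations`, `truth` (per planted variant: `status`
#'   `true`/`decoy`/`background`, `decoy_class`, `expected_failure`
#'   stage), `qtl`, `known_genes`, `hpo_genes`, `retnet_genes`,
#'   `omim_genes`, `dominant_table`, `patient_phenotypes`, `callsets`
#'   (one tibble, `caller` column), and `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  patients <- sprintf("P%03d", seq_len(cfg$n_patients))
  callers <- sprintf("caller%d", seq_len(cfg$n_callers))

  # --- QTL regions: two tiers of intervals across autosomes, all starting
  # at >= 100 Mb so that "outside every QTL" positions can be drawn from
  # the low arm of any chromosome
  n_qtl <- cfg$n_qtl
  qtl <- tibble::tibble(
    name = sprintf("MYPS%02d", seq_len(n_qtl)),
    chrom = as.character(((seq_len(n_qtl) - 1) %% 22) + 1),
    start = 1e8 + 3e7 * ((seq_len(n_qtl) - 1) %/% 22),
    end = 1e8 + 3e7 * ((seq_len(n_qtl) - 1) %/% 22) + 2e7
  )
  qtl_index <- build_interval_index(qtl)

  # --- gene universe with positions; ocular genes alternate between
  # inside-QTL and outside-QTL placement
  known_genes <- sprintf("HMK%03d", seq_len(cfg$n_known_genes))
  ocular_genes <- sprintf("OCG%03d", seq_len(cfg$n_ocular_genes))
  noneye_genes <- sprintf("BGG%04d", seq_len(500))

  place_in_qtl <- function(n) {
    reg <- qtl[sample.int(nrow(qtl), n, replace = TRUE), ]
    tibble::tibble(
      chrom = reg$chrom,
      pos = floor(runif(n, reg$start, reg$end - 1e4))
    )
  }
  place_outside_qtl <- function(n) {
    tibble::tibble(
      chrom = as.character(sample.int(22, n, replace = TRUE)),
      pos = floor(runif(n, 1e6, 5e7))   # below every QTL start
    )
  }
  n_oc_in <- ceiling(cfg$n_ocular_genes / 2)
  gene_pos <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(gene = known_genes), place_outside_qtl(length(known_genes))),
    dplyr::bind_cols(tibble::tibble(gene = ocular_genes[seq_len(n_oc_in)]), place_in_qtl(n_oc_in)),
    dplyr::bind_cols(tibble::tibble(gene = ocular_genes[-seq_len(n_oc_in)]),
                     place_outside_qtl(cfg$n_ocular_genes - n_oc_in)),
    dplyr::bind_cols(tibble::tibble(gene = noneye_genes), place_in_qtl(length(noneye_genes)))
  )
  ocular_in_qtl <- ocular_genes[seq_len(n_oc_in)]
  ocular_no_qtl <- ocular_genes[-seq_len(n_oc_in)]

  # the dominant-disease sidecar covers a dedicated slice of in-QTL ocular
  # genes; planted true candidates avoid those genes
  n_dom <- max(cfg$n_decoys_per_class, 1)
  dominant_genes <- ocular_in_qtl[seq_len(min(n_dom, length(ocular_in_qtl)))]
  ocular_in_qtl_free <- setdiff(ocular_in_qtl, dominant_genes)
  dominant_table <- tibble::tibble(
    gene = dominant_genes,
    dominant_disease = "synthetic dominant ocular syndrome",
    dominant_phenotypes = rep(list(c("hearing loss", "renal disease")), length(dominant_genes))
  )

  patient_phenotypes <- setNames(rep(list("high myopia"), cfg$n_patients), patients)

  bases <- c("A", "C", "G", "T")
  offset_counter <- 0L  # unique per-variant offset; avoids key collisions
  new_variant <- function(gene_df, patient, consequence, votes = NA_integer_,
                          max_af = NA_real_, splice_score = NA_real_) {
    offset_counter <<- offset_counter + 1L
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    preds <- rep(NA_character_, 8)
    if (!is.na(votes)) {
      preds <- rep("benign", 8)
      if (votes > 0) preds[sample.int(8, votes)] <- "pathogenic"
    }
    afs <- c(NA_real_, NA_real_, NA_real_)
    if (!is.na(max_af)) afs[sample.int(3, 1)] <- max_af
    tibble::tibble(
      patient_id = patient,
      chrom = gene_df$chrom, pos = gene_df$pos + offset_counter,
      ref = ref, alt = alt, genotype = "het",
      gene = gene_df$gene, consequence = consequence,
      hgvs_c = sprintf("c.%dN>N", sample.int(5000, 1)), hgvs_p = NA_character_,
      dbsnp = NA_character_,
      sift = preds[1], polyphen2 = preds[2], lrt = preds[3],
      mutation_taster = preds[4], mutation_assessor = preds[5],
      fathmm = preds[6], cadd = preds[7], dann = preds[8],
      af_1000g = afs[1], af_exac = afs[2], af_esp = afs[3],
      splice_score = splice_score
    )
  }
  gene_row <- function(g) gene_pos[gene_pos$gene == g, ]

  min_votes <- cfg$cascade$min_pathogenic_votes
  af_thr <- cfg$cascade$max_af_threshold
  rows <- list()
  truth <- list()
  add <- function(v, status, decoy_class = NA_character_, expected_failure = NA_character_) {
    rows[[length(rows) + 1]] <<- v
    truth[[length(truth) + 1]] <<- tibble::tibble(
      patient_id = v$patient_id, chrom = v$chrom, pos = v$pos,
      ref = v$ref, alt = v$alt, gene = v$gene, status = status,
      decoy_class = decoy_class, expected_failure = expected_failure
    )
  }

  # --- planted true candidates: all criteria satisfied
  true_pool <- c(known_genes, ocular_in_qtl_free)
  true_genes <- sample(true_pool, cfg$n_true_candidates, replace = FALSE)
  for (i in seq_len(cfg$n_true_candidates)) {
    patient <- sample(patients, 1)
    kind <- sample(c("missense", "lof", "splice"), 1, prob = c(0.8, 0.15, 0.05))
    v <- switch(kind,
      missense = new_variant(gene_row(true_genes[i]), patient, "missense",
                             votes = sample(min_votes:8, 1),
                             max_af = sample(c(NA_real_, runif(1, 0, af_thr)), 1)),
      lof = new_variant(gene_row(true_genes[i]), patient,
                        sample(c("frameshift", "stop_gained", "splice_donor"), 1)),
      splice = new_variant(gene_row(true_genes[i]), patient, "splice_region",
                           splice_score = runif(1, cfg$cascade$splice_score_threshold, 1))
    )
    add(v, "true")
  }

  # --- decoys: exactly one violation each
  nd <- cfg$n_decoys_per_class
  decoy_gene <- function(pool, i) pool[(i - 1) %% length(pool) + 1]
  used <- function() unique(purrr::map_chr(rows, ~ .x$gene))
  for (i in seq_len(nd)) {
    free_in_qtl <- setdiff(ocular_in_qtl_free, used())
    add(new_variant(gene_row(free_in_qtl[1]), sample(patients, 1), "missense",
                    votes = sample(min_votes:8, 1), max_af = runif(1, af_thr * 2, 0.2)),
        "decoy", "common_af", "frequency")
    free_in_qtl <- setdiff(ocular_in_qtl_free, used())
    add(new_variant(gene_row(free_in_qtl[1]), sample(patients, 1), "missense",
                    votes = sample(0:(min_votes - 1), 1)),
        "decoy", "low_votes", "impact")
    free_noneye <- setdiff(noneye_genes, used())
    add(new_variant(gene_row(free_noneye[1]), sample(patients, 1), "missense",
                    votes = sample(min_votes:8, 1)),
        "decoy", "non_eye_gene", "phenotype_gene")
    free_no_qtl <- setdiff(ocular_no_qtl, used())
    add(new_variant(gene_row(free_no_qtl[1]), sample(patients, 1), "missense",
                    votes = sample(min_votes:8, 1)),
        "decoy", "eye_no_qtl", "phenotype_gene")
    dom_free <- setdiff(dominant_genes, used())
    add(new_variant(gene_row(dom_free[1]), sample(patients, 1), "missense",
                    votes = sample(min_votes:8, 1)),
        "decoy", "dominant_mismatch", "dominant_exclusion")
    free_in_qtl <- setdiff(ocular_in_qtl_free, used())
    add(new_variant(gene_row(free_in_qtl[1]), sample(patients, 1), "missense",
                    votes = sample(min_votes:8, 1)),
        "decoy", "single_caller", "consensus")
  }

  # --- background: common synonymous variants (vectorized)
  n_bg_total <- cfg$background_variants_per_patient * cfg$n_patients
  if (n_bg_total > 0) {
    bg_genes <- sample(noneye_genes, n_bg_total, replace = TRUE)
    bg_idx <- match(bg_genes, gene_pos$gene)
    bg_ref <- sample(bases, n_bg_total, replace = TRUE)
    bg_alt <- vapply(bg_ref, function(r) sample(setdiff(bases, r), 1), character(1))
    bg <- tibble::tibble(
      patient_id = rep(patients, each = cfg$background_variants_per_patient),
      chrom = gene_pos$chrom[bg_idx],
      pos = gene_pos$pos[bg_idx] + offset_counter + seq_len(n_bg_total),
      ref = bg_ref, alt = unname(bg_alt), genotype = "het",
      gene = bg_genes, consequence = "synonymous",
      hgvs_c = sprintf("c.%dN>N", seq_len(n_bg_total)), hgvs_p = NA_character_,
      dbsnp = NA_character_,
      sift = NA_character_, polyphen2 = NA_character_, lrt = NA_character_,
      mutation_taster = NA_character_, mutation_assessor = NA_character_,
      fathmm = NA_character_, cadd = NA_character_, dann = NA_character_,
      af_1000g = runif(n_bg_total, 0.05, 0.5), af_exac = NA_real_,
      af_esp = NA_real_, splice_score = NA_real_
    )
    rows[[length(rows) + 1]] <- bg
    truth[[length(truth) + 1]] <- tibble::tibble(
      patient_id = bg$patient_id, chrom = bg$chrom, pos = bg$pos,
      ref = bg$ref, alt = bg$alt, gene = bg$gene, status = "background",
      decoy_class = NA_character_, expected_failure = NA_character_
    )
  }

  annotations <- normalize_keys(dplyr::bind_rows(rows))
  truth <- dplyr::bind_rows(truth)

  # --- per-caller call sets: single-caller decoys in exactly one caller,
  # everything else in >= min_callers callers
  single_rows <- truth[!is.na(truth$decoy_class) & truth$decoy_class == "single_caller", ]
  single_ids <- paste(key_id(single_rows), single_rows$patient_id)
  ann_ids <- paste(key_id(annotations), annotations$patient_id)
  n_support <- ifelse(
    ann_ids %in% single_ids, 1L,
    sample(cfg$cascade$min_callers:cfg$n_callers, nrow(annotations), replace = TRUE)
  )
  support <- lapply(n_support, function(k) sample(callers, k))
  rep_idx <- rep(seq_len(nrow(annotations)), lengths(support))
  callsets <- tibble::tibble(
    caller = unlist(support),
    patient_id = annotations$patient_id[rep_idx],
    chrom = annotations$chrom[rep_idx],
    pos = annotations$pos[rep_idx],
    ref = annotations$ref[rep_idx],
    alt = annotations$alt[rep_idx],
    genotype = annotations$genotype[rep_idx]
  )

  hpo <- ocular_genes[seq_along(ocular_genes) %% 3 == 0]
  retnet <- ocular_genes[seq_along(ocular_genes) %% 3 == 1]
  omim <- ocular_genes[seq_along(ocular_genes) %% 3 == 2]

  list(
    annotations = annotations,
    truth = truth,
    qtl = qtl,
    known_genes = known_genes,
    hpo_genes = hpo,
    retnet_genes = retnet,
    omim_genes = omim,
    dominant_table = dominant_table,
    patient_phenotypes = patient_phenotypes,
    callsets = callsets,
    config = cfg
  )
}

#' Assemble the gene-evidence table of a synthetic cohort
#' @param cohort result of [generate_cohort()].
#' @return a `gene_evidence` tibble.
#' @export
cohort_evidence <- function(cohort) {
  assemble_gene_sets(
    known_hm_genes = cohort$known_genes,
    hpo_genes = cohort$hpo_genes,
    retnet_genes = cohort$retnet_genes,
    omim_ocular_genes = cohort$omim_genes,
    dominant_table = cohort$dominant_table
  )
}

#' Generate a synthetic eye-tissue expression matrix
#'
#' Log-normal baseline expression with a designated eye-gene set shifted
#' upward (by `set_shift_sd` baseline standard deviations) in the eye
#' tissues, plus small planted per-gene tissue profiles: `retina_high`
#' genes are boosted in the retina tissues only, `retina_and_sclera`
#' genes in retina and sclera.
#'
#' @param config a [synthetic_config()]; the `expression` component sets
#'   the sizes.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with `matrix` (linear-scale RPKM `expression_matrix`),
#'   `set_genes` (the shifted eye set), and `class_truth` (tibble `gene`,
#'   `class` for the planted profiles).
#' @export
generate_expression <- function(config = synthetic_config(), seed = config$seed) {
  e <- config$expression
  withr::with_seed(seed, {
    genes <- sprintf("GEXP%05d", seq_len(e$n_genes))
    tissues <- rep(e$tissues, each = e$samples_per_tissue)
    samples <- sprintf("S%03d_%s", seq_along(tissues), tissues)
    baseline <- rnorm(e$n_genes, mean = 3, sd = 1.5)
    log2_vals <- matrix(
      baseline + rnorm(e$n_genes * length(samples), sd = e$noise_sd),
      nrow = e$n_genes
    )
    rownames(log2_vals) <- genes
    colnames(log2_vals) <- samples
    set_genes <- genes[seq_len(e$set_size)]
    eye_cols <- tissues %in% e$eye_tissues
    log2_vals[seq_len(e$set_size), eye_cols] <-
      log2_vals[seq_len(e$set_size), eye_cols] + e$set_shift_sd * e$noise_sd

    # planted per-gene tissue profiles, outside the eye set
    n_prof <- e$n_planted_profiles
    retina_cols <- tissues %in% c("macular_retina", "peripheral_retina")
    sclera_cols <- tissues == "sclera"
    rh_genes <- genes[e$set_size + seq_len(n_prof)]
    rs_genes <- genes[e$set_size + n_prof + seq_len(n_prof)]
    # planted profiles are noise-free in the profiled tissues: they define
    # the classes the classifier must recover exactly
    bl_rh <- baseline[e$set_size + seq_len(n_prof)]
    bl_rs <- baseline[e$set_size + n_prof + seq_len(n_prof)]
    log2_vals[rh_genes, retina_cols] <- bl_rh + 6
    log2_vals[rh_genes, sclera_cols] <- bl_rh - 4
    log2_vals[rs_genes, retina_cols | sclera_cols] <- bl_rs + 5

    m <- expression_matrix(2^log2_vals, setNames(tissues, samples), "rnaseq")
    list(
      matrix = m,
      set_genes = set_genes,
      class_truth = tibble::tibble(
        gene = c(rh_genes, rs_genes),
        class = rep(c("retina_high", "retina_and_sclera"), each = n_prof)
      )
    )
  })
}

#' Generate a gene-to-term annotation table with planted terms
#'
#' Random background terms are drawn over the whole universe; each planted
#' term annotates (most of) its designated gene set plus a small leakage
#' fraction of outside genes, giving enrichment analyses a recoverable
#' signal.
#'
#' @param universe character vector: all genes.
#' @param planted named list term name -> character vector of genes the
#'   term is planted over.
#' @param n_background_terms number of random terms (default 50).
#' @param namespace namespace for all generated terms (default `"BP"`).
#' @param leak_frac fraction of a planted term's size drawn from outside
#'   its set (default 0.02).
#' @param seed RNG seed.
#' @return tibble in the layout of [read_gene_term_table()].
#' @export
generate_term_annotations <- function(universe, planted = list(),
                                      n_background_terms = 50,
                                      namespace = "BP",
                                      leak_frac = 0.02, seed = 1) {
  withr::with_seed(seed, {
    out <- list()
    for (i in seq_len(n_background_terms)) {
      size <- sample(10:100, 1)
      out[[length(out) + 1]] <- tibble::tibble(
        term_id = sprintf("SYN:%04d", i),
        term_name = sprintf("synthetic process %d", i),
        namespace = namespace,
        gene = sample(universe, min(size, length(universe)))
      )
    }
    for (j in seq_along(planted)) {
      genes_in <- intersect(planted[[j]], universe)
      n_leak <- ceiling(leak_frac * length(genes_in))
      leak <- sample(setdiff(universe, genes_in), min(n_leak, length(universe) - length(genes_in)))
      out[[length(out) + 1]] <- tibble::tibble(
        term_id = sprintf("PLT:%04d", j),
        term_name = names(planted)[j],
        namespace = namespace,
        gene = c(genes_in, leak)
      )
    }
    dplyr::distinct(dplyr::bind_rows(out), term_id, gene, .keep_all = TRUE)
  })
}

#' Generate a planted-partition interaction network
#'
#' Stochastic block model with `n_blocks` blocks of `block_size` nodes,
#' within-block edge probability `p_in` and between-block probability
#' `p_out`. A designated candidate set is spread round-robin across
#' blocks.
#'
#' @param config a [synthetic_config()]; the `network` component sets the
#'   sizes.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with `graph` (named undirected `igraph`), `truth`
#'   (tibble `gene`, `block`), and `candidates`.
#' @export
generate_network <- function(config = synthetic_config(), seed = config$seed) {
  nt <- config$network
  withr::with_seed(seed, {
    n <- nt$n_blocks * nt$block_size
    pref <- matrix(nt$p_out, nt$n_blocks, nt$n_blocks)
    diag(pref) <- nt$p_in
    g <- igraph::sample_sbm(n, pref.matrix = pref,
                            block.sizes = rep(nt$block_size, nt$n_blocks))
    igraph::V(g)$name <- sprintf("NODE%03d", seq_len(n))
    block <- rep(seq_len(nt$n_blocks), each = nt$block_size)
    cand_idx <- unlist(lapply(seq_len(nt$n_blocks), function(b) {
      which(block == b)[seq_len(ceiling(nt$n_candidates / nt$n_blocks))]
    }))[seq_len(nt$n_candidates)]
    list(
      graph = igraph::simplify(g),
      truth = tibble::tibble(gene = igraph::V(g)$name, block = block),
      candidates = igraph::V(g)$name[sort(cand_idx)]
    )
  })
}
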