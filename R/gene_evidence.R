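# Phenotype gene evidence: the known high-myopia gene class, the broader
# ocular-disease gene class (HPO myopia term, RetNet, OMIM ocular genes),
# QTL interval membership, and the dominant-disease exclusion rule.
# The two gene classes partition their union: a gene listed as a known
# high-myopia gene is never also counted in the ocular class.

#' Assemble the phenotype gene-evidence table
#'
#' @param known_hm_genes character vector of known high-myopia gene
#'   symbols.
#' @param hpo_genes,retnet_genes,omim_ocular_genes character vectors of
#'   ocular-disease gene symbols from the three phenotype sources.
#' @param dominant_table optional tibble from [read_dominant_table()]
#'   attaching a dominant OMIM ocular disease and its characteristic
#'   phenotype terms to genes.
#' @param inheritance optional named character vector gene -> inheritance
#'   label (AR/AD/X-linked), used only for reporting.
#' @return a `gene_evidence` tibble with columns `gene`, `is_known_hm`,
#'   `is_ocular`, `dominant_disease`, `dominant_phenotypes` (list),
#'   `inheritance`; class counts are attached as attribute `counts`
#'   (n_known, n_ocular, n_total).
#' @export
assemble_gene_sets <- function(known_hm_genes,
                               hpo_genes = character(0),
                               retnet_genes = character(0),
                               omim_ocular_genes = character(0),
                               dominant_table = NULL,
                               inheritance = NULL) {
  check_symbol_case(c(known_hm_genes, hpo_genes, retnet_genes, omim_ocular_genes))
  known <- unique(toupper(known_hm_genes))
  ocular_sources <- unique(toupper(c(hpo_genes, retnet_genes, omim_ocular_genes)))
  all_genes <- sort(union(known, ocular_sources))
  ev <- tibble::tibble(
    gene = all_genes,
    is_known_hm = all_genes %in% known,
    is_ocular = (all_genes %in% ocular_sources) & !(all_genes %in% known),
    dominant_disease = NA_character_,
    dominant_phenotypes = vector("list", length(all_genes)),
    inheritance = NA_character_
  )
  ev$dominant_phenotypes <- purrr::map(ev$dominant_phenotypes, function(x) character(0))
  if (!is.null(dominant_table) && nrow(dominant_table) > 0) {
    idx <- match(ev$gene, toupper(dominant_table$gene))
    hit <- !is.na(idx)
    ev$dominant_disease[hit] <- dominant_table$dominant_disease[idx[hit]]
    ev$dominant_phenotypes[hit] <- dominant_table$dominant_phenotypes[idx[hit]]
  }
  if (!is.null(inheritance)) {
    idx <- match(ev$gene, toupper(names(inheritance)))
    ev$inheritance[!is.na(idx)] <- unname(inheritance[idx[!is.na(idx)]])
  }
  counts <- c(
    n_known = sum(ev$is_known_hm),
    n_ocular = sum(ev$is_ocular),
    n_total = nrow(ev)
  )
  stopifnot(counts["n_known"] + counts["n_ocular"] == counts["n_total"])
  attr(ev, "counts") <- counts
  class(ev) <- c("gene_evidence", class(ev))
  ev
}

# case-inconsistent duplicates ("Abca4" next to "ABCA4") indicate a
# curation error upstream; refuse rather than silently merge
check_symbol_case <- function(symbols) {
  symbols <- unique(symbols)
  up <- toupper(symbols)
  dup <- up[duplicated(up)]
  if (length(dup) > 0) {
    offenders <- symbols[up %in% dup]
    rlang::abort(sprintf(
      "case-inconsistent duplicate gene symbols: %s",
      paste(sort(offenders), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Class counts of a gene-evidence table
#' @param evidence a `gene_evidence` tibble.
#' @return named integer vector (n_known, n_ocular, n_total).
#' @export
gene_class_counts <- function(evidence) {
  attr(evidence, "counts")
}

#' Build a searchable interval index over QTL regions
#'
#' @param regions tibble of QTL regions (`name`, `chrom`, `start`, `end`,
#'   1-based inclusive), e.g. from [read_qtl_table()].
#' @return a `qtl_index` object supporting point queries via
#'   [qtl_overlap()].
#' @export
build_interval_index <- function(regions) {
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(regions)) canonical_chrom(regions$chrom) else character(0),
    ranges = IRanges::IRanges(start = regions$start, end = regions$end)
  )
  S4Vectors::mcols(gr)$name <- regions$name
  structure(list(gr = gr), class = "qtl_index")
}

#' Query QTL membership of genomic positions
#'
#' Returns, for each query position, the names of all QTL regions whose
#' interval (1-based, inclusive on both ends) contains it.
#'
#' @param chrom,pos vectors of chromosome names and 1-based positions
#'   (recycled to a common length).
#' @param index a `qtl_index` from [build_interval_index()].
#' @return a list of character vectors (sorted, deduplicated locus names),
#'   one per query.
#' @export
qtl_overlap <- function(chrom, pos, index) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(canonical_chrom(chrom), n)
  pos <- rep_len(pos, n)
  if (length(index$gr) == 0) {
    return(rep(list(character(0)), n))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  # query and index may legitimately cover disjoint chromosome sets
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, index$gr))
  out <- rep(list(character(0)), n)
  if (length(hits) > 0) {
    by_query <- split(
      S4Vectors::mcols(index$gr)$name[S4Vectors::subjectHits(hits)],
      S4Vectors::queryHits(hits)
    )
    out[as.integer(names(by_query))] <- lapply(by_query, function(x) sort(unique(x)))
  }
  out
}

#' Dominant ocular-disease exclusion decision for one gene
#'
#' A candidate in a gene that causes a dominant OMIM ocular disease is
#' excluded when none of that disease's characteristic phenotype terms
#' appear among the patient's phenotype terms (the carrier does not show
#' the disease, so a dominant pathogenic allele is implausible). Matching
#' is plain term-set intersection on curated labels; no ontology
#' reasoning.
#'
#' @param gene gene symbol.
#' @param patient_phenotype_terms character vector of the patient's
#'   phenotype terms.
#' @param evidence a `gene_evidence` tibble.
#' @return list with `decision` (`"KEEP"` or `"EXCLUDE"`) and `reason`.
#' @export
flag_dominant_exclusion <- function(gene, patient_phenotype_terms, evidence) {
  row <- evidence[evidence$gene == toupper(gene), ]
  if (nrow(row) == 0 || is.na(row$dominant_disease[1])) {
    return(list(decision = "KEEP", reason = "no dominant ocular disease on record"))
  }
  disease <- row$dominant_disease[1]
  terms <- row$dominant_phenotypes[[1]]
  matched <- intersect(tolower(terms), tolower(patient_phenotype_terms))
  if (length(terms) > 0 && length(matched) == 0) {
    list(
      decision = "EXCLUDE",
      reason = sprintf(
        "dominant disease '%s' but patient shows none of: %s",
        disease, paste(terms, collapse = ", ")
      )
    )
  } else {
    list(
      decision = "KEEP",
      reason = sprintf(
        "dominant disease '%s' phenotype satisfied (%s)",
        disease, paste(matched, collapse = ", ")
      )
    )
  }
}
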