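# Readers and writers for every external format the pipeline touches.
# All tabular IO is tab-separated; the annotation-table header is part of
# the package contract and documented bit-exactly in the README.

# fixed in-silico missense predictor panel (8 tools)
.predictor_cols <- c(
  "sift", "polyphen2", "lrt", "mutation_taster",
  "mutation_assessor", "fathmm", "cadd", "dann"
)

# population databases consulted for the allele-frequency filter
.af_cols <- c("af_1000g", "af_exac", "af_esp")

# closed consequence vocabulary
.consequence_levels <- c(
  "missense", "frameshift", "stop_gained", "splice_donor",
  "splice_acceptor", "splice_region", "synonymous", "intronic", "other"
)

.annotation_cols <- c(
  "patient_id", "chrom", "pos", "ref", "alt", "genotype", "gene",
  "consequence", "hgvs_c", "hgvs_p", "dbsnp",
  .predictor_cols, .af_cols, "splice_score"
)

#' Read one caller's single-sample VCF into a call set
#'
#' Parses a single-sample VCF 4.x file, splits multi-allelic rows into one
#' key per ALT allele, normalizes every key (left trim, anchored indels),
#' and classifies the genotype for each ALT as `het`, `hom_alt`, or `hemi`
#' (haploid GT). Homozygous-reference and fully missing genotypes emit no
#' call; a record whose FORMAT lacks GT is skipped with a warning.
#'
#' @param path path to a VCF file.
#' @param caller_name label for the variant caller that produced the file.
#' @param require_pass when `TRUE` (default) only records with FILTER
#'   `PASS` or `.` are kept.
#' @return a tibble (call set) with columns `caller`, `patient_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `genotype`, deduplicated on the key.
#' @export
read_caller_vcf <- function(path, caller_name, require_pass = TRUE) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) {
      rlang::abort(sprintf("malformed VCF '%s': %s", path, conditionMessage(e)))
    }
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) {
    return(empty_callset(caller_name, patient_id = "unknown"))
  }
  gt_mat <- tryCatch(
    suppressWarnings(vcfR::extract.gt(vcf, element = "GT")),
    error = function(e) NULL
  )
  if (is.null(gt_mat) || ncol(gt_mat) == 0) {
    rlang::abort(sprintf("VCF '%s' carries no sample genotype (GT) column", path))
  }
  if (ncol(gt_mat) > 1) {
    rlang::abort(sprintf("expected a single-sample VCF, found %d samples", ncol(gt_mat)))
  }
  patient_id <- colnames(gt_mat)[1]
  gts <- gt_mat[, 1]

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    filt <- fix[i, "FILTER"]
    if (require_pass && !is.na(filt) && !(filt %in% c("PASS", "."))) next
    gt <- gts[i]
    if (is.na(gt)) {
      rlang::warn(sprintf(
        "record %s:%s in '%s' has no GT; skipped", fix[i, "CHROM"], fix[i, "POS"], path
      ))
      next
    }
    alleles <- strsplit(gt, "[/|]")[[1]]
    if (all(alleles %in% c(".", "0"))) next
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (a in seq_along(alts)) {
      n_a <- sum(alleles == as.character(a))
      if (n_a == 0) next
      genotype <- if (length(alleles) == 1) {
        "hemi"
      } else if (n_a >= 2) {
        "hom_alt"
      } else {
        "het"
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = fix[i, "CHROM"], pos = as.numeric(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[a], genotype = genotype
      )
    }
  }
  if (length(rows) == 0) {
    return(empty_callset(caller_name, patient_id))
  }
  calls <- normalize_keys(dplyr::bind_rows(rows))
  calls <- dplyr::distinct(calls, chrom, pos, ref, alt, .keep_all = TRUE)
  out <- dplyr::mutate(calls, caller = caller_name, patient_id = patient_id, .before = 1)
  sort_by_key(out)
}

empty_callset <- function(caller_name, patient_id) {
  tibble::tibble(
    caller = character(0), patient_id = character(0), chrom = character(0),
    pos = integer(0), ref = character(0), alt = character(0),
    genotype = character(0)
  )
}

#' Read the variant annotation table
#'
#' The annotation table is a tab-separated sidecar (VEP-style content, one
#' row per patient x variant) with the exact header documented in the
#' README: `patient_id chrom pos ref alt genotype gene consequence hgvs_c
#' hgvs_p dbsnp sift polyphen2 lrt mutation_taster mutation_assessor fathmm
#' cadd dann af_1000g af_exac af_esp splice_score`. Predictor cells hold
#' `pathogenic`, `benign`, or are empty (`""`, `"-"`, `"."`) for "no
#' prediction"; frequency cells hold a number in \[0,1\] or are empty for
#' "not observed in that database".
#'
#' @param path path to the TSV file.
#' @return a tibble of annotated variants with normalized keys.
#' @export
read_annotation_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = character(), progress = FALSE)
  missing_cols <- setdiff(.annotation_cols, names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf(
      "annotation table is missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  df <- df[.annotation_cols]
  df$pos <- as.numeric(df$pos)
  for (col in c(.af_cols, "splice_score")) {
    df[[col]] <- suppressWarnings(as.numeric(dash_to_na(df[[col]])))
  }
  for (col in .predictor_cols) {
    v <- dash_to_na(df[[col]])
    bad <- !is.na(v) & !(v %in% c("pathogenic", "benign"))
    if (any(bad)) {
      rlang::abort(sprintf(
        "predictor column '%s' holds value(s) outside {pathogenic, benign, empty}: %s",
        col, paste(unique(v[bad]), collapse = ", ")
      ))
    }
    df[[col]] <- v
  }
  for (col in c("hgvs_p", "dbsnp")) df[[col]] <- dash_to_na(df[[col]])
  bad_cons <- setdiff(unique(df$consequence), .consequence_levels)
  if (length(bad_cons) > 0) {
    rlang::abort(sprintf(
      "unknown consequence term(s): %s; accepted vocabulary: %s",
      paste(bad_cons, collapse = ", "),
      paste(.consequence_levels, collapse = ", ")
    ))
  }
  df <- normalize_keys(df)
  dup <- duplicated(paste(df$patient_id, key_id(df)))
  if (any(dup)) {
    rlang::abort(sprintf(
      "duplicate (patient, variant) row(s): %s",
      paste(unique(paste(df$patient_id[dup], key_id(df)[dup])), collapse = "; ")
    ))
  }
  af_bad <- purrr::map_lgl(.af_cols, function(col) any(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1)))
  if (any(af_bad)) {
    rlang::abort("allele frequencies must lie in [0, 1]")
  }
  sort_by_key(df) |> dplyr::arrange(patient_id, .by_group = FALSE)
}

#' Write the variant annotation table
#' @param annotations tibble in the layout produced by
#'   [read_annotation_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  out <- annotations[.annotation_cols]
  for (col in c(.predictor_cols, "hgvs_p", "dbsnp")) out[[col]] <- na_to_dash(out[[col]])
  for (col in c(.af_cols, "splice_score")) {
    out[[col]] <- ifelse(is.na(out[[col]]), .na_sentinel, format(out[[col]], scientific = FALSE, trim = TRUE))
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a myopia QTL interval table
#'
#' Tab-separated columns `name`, `chrom`, `start`, `end`; 1-based inclusive
#' coordinates on GRCh37. Overlapping regions are permitted (real MYP loci
#' overlap), but one locus name may not span chromosomes.
#'
#' @param path path to the TSV file.
#' @return a tibble of validated regions.
#' @export
read_qtl_table <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccnn", progress = FALSE)
  if (nrow(df) == 0) {
    return(tibble::tibble(name = character(0), chrom = character(0),
                          start = numeric(0), end = numeric(0)))
  }
  names(df) <- c("name", "chrom", "start", "end")
  df$chrom <- canonical_chrom(df$chrom)
  bad <- which(df$start > df$end)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "QTL table line %d: start (%s) > end (%s)",
      bad[1] + 1L, format(df$start[bad[1]]), format(df$end[bad[1]])
    ))
  }
  if (any(df$start < 1)) rlang::abort("QTL start coordinates must be >= 1")
  multi <- df |>
    dplyr::distinct(name, chrom) |>
    dplyr::count(name) |>
    dplyr::filter(n > 1)
  if (nrow(multi) > 0) {
    rlang::abort(sprintf(
      "QTL locus name(s) span multiple chromosomes: %s",
      paste(multi$name, collapse = ", ")
    ))
  }
  tibble::as_tibble(df)
}

#' Write a candidate variant table
#'
#' Emits the tab-separated report layout used for the final candidates:
#' columns `Gene`, `Inheritance`, `Type`, `Patient ID`, `Position`
#' (`chrom:pos`), `Nucleotide change`, `Amino-acid change`, `dbSNP`, `QTL`
#' (comma-joined locus names, `-` when none), sorted by gene then patient.
#'
#' @param candidates retained candidate tibble from [apply_cascade()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  out <- candidates |>
    dplyr::arrange(gene, patient_id) |>
    dplyr::transmute(
      Gene = gene,
      Inheritance = na_to_dash(inheritance),
      Type = ifelse(gene_class == "known_hm", "Known HM gene", "Ocular disease gene"),
      `Patient ID` = patient_id,
      Position = paste0(chrom, ":", format(pos, scientific = FALSE, trim = TRUE)),
      `Nucleotide change` = hgvs_c,
      `Amino-acid change` = na_to_dash(hgvs_p),
      dbSNP = na_to_dash(dbsnp),
      QTL = ifelse(purrr::map_int(qtl_names, length) == 0, .na_sentinel,
                   purrr::map_chr(qtl_names, paste, collapse = ","))
    )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a candidate variant table written by [write_candidate_table()]
#' @param path path to the TSV file.
#' @return a tibble with columns `gene`, `inheritance`, `gene_class`,
#'   `patient_id`, `chrom`, `pos`, `hgvs_c`, `hgvs_p`, `dbsnp`,
#'   `qtl_names` (list column).
#' @export
read_candidate_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = character(), progress = FALSE)
  pos_split <- stringr::str_split_fixed(df$Position, ":", 2)
  tibble::tibble(
    gene = df$Gene,
    inheritance = dash_to_na(df$Inheritance),
    gene_class = ifelse(df$Type == "Known HM gene", "known_hm", "ocular"),
    patient_id = df$`Patient ID`,
    chrom = canonical_chrom(pos_split[, 1]),
    pos = as.numeric(pos_split[, 2]),
    hgvs_c = df$`Nucleotide change`,
    hgvs_p = dash_to_na(df$`Amino-acid change`),
    dbsnp = dash_to_na(df$dbSNP),
    qtl_names = purrr::map(df$QTL, function(q) {
      q <- dash_to_na(q)
      if (is.na(q)) character(0) else strsplit(q, ",", fixed = TRUE)[[1]]
    })
  )
}

#' Read an expression matrix with its sample-metadata sidecar
#'
#' @param path TSV with a `gene` column followed by one column per sample.
#' @param meta_path TSV with columns `sample_id`, `tissue`.
#' @param mode `"rnaseq"` (values are RPKM, must be non-negative) or
#'   `"microarray"` (normalized intensities, any sign).
#' @return an `expression_matrix` object (list with `values` gene x sample
#'   matrix, `tissue` named character vector, `mode`).
#' @export
read_expression_matrix <- function(path, meta_path, mode = c("rnaseq", "microarray")) {
  mode <- match.arg(mode)
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  meta <- readr::read_tsv(meta_path, col_types = "cc", progress = FALSE)
  names(meta) <- c("sample_id", "tissue")
  m <- as.matrix(df[-1])
  rownames(m) <- df$gene
  expression_matrix(m, setNames(meta$tissue, meta$sample_id), mode)
}

#' Construct an expression matrix object
#' @param values numeric gene x sample matrix with dimnames.
#' @param tissue named character vector mapping sample id to tissue label;
#'   must cover exactly the matrix columns.
#' @param mode `"rnaseq"` or `"microarray"`.
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(values, tissue, mode = c("rnaseq", "microarray")) {
  mode <- match.arg(mode)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    rlang::abort("expression matrix needs gene rownames and sample colnames")
  }
  if (!setequal(colnames(values), names(tissue))) {
    rlang::abort("sample metadata does not match matrix columns")
  }
  tissue <- tissue[colnames(values)]
  if (mode == "rnaseq" && any(values < 0)) {
    rlang::abort("RPKM values must be non-negative")
  }
  structure(list(values = values, tissue = tissue, mode = mode),
            class = "expression_matrix")
}

#' @exportS3Method base::print
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d genes x %d samples (%s); tissues: %s\n",
    nrow(x$values), ncol(x$values), x$mode,
    paste(unique(x$tissue), collapse = ", ")
  ))
  invisible(x)
}

#' Read a gene-to-term annotation table
#' @param path TSV with columns `term_id`, `term_name`, `namespace`
#'   (one of `BP`, `MF`, `CC`, `pathway`) and `gene`.
#' @return a tibble, deduplicated on (term_id, gene).
#' @export
read_gene_term_table <- function(path) {
  df <- readr::read_tsv(path, col_types = "cccc", progress = FALSE)
  names(df) <- c("term_id", "term_name", "namespace", "gene")
  bad <- setdiff(unique(df$namespace), c("BP", "MF", "CC", "pathway"))
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown annotation namespace(s): %s", paste(bad, collapse = ", ")))
  }
  dplyr::distinct(df, term_id, gene, .keep_all = TRUE)
}

#' Read a gene set file
#' @param path TSV with a `gene` column (one symbol per line) and an
#'   optional `source` column.
#' @return character vector of unique, uppercased gene symbols.
#' @export
read_gene_set <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!"gene" %in% names(df)) rlang::abort("gene set file needs a 'gene' column")
  unique(toupper(df$gene))
}

#' Read an undirected edge list into a simple graph
#' @param path TSV with two gene columns per row (a header is expected).
#' @return an undirected simple `igraph` graph (self-loops and duplicate
#'   edges removed).
#' @export
read_edge_list <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2) rlang::abort("edge list needs two columns (geneA, geneB)")
  g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
  igraph::simplify(g)
}

#' Read a dominant ocular-disease table
#' @param path TSV with columns `gene`, `disease`, `phenotypes`
#'   (comma-separated characteristic phenotype terms).
#' @return tibble with `gene`, `dominant_disease`, `dominant_phenotypes`
#'   (list column of character vectors).
#' @export
read_dominant_table <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  names(df) <- c("gene", "disease", "phenotypes")
  tibble::tibble(
    gene = toupper(df$gene),
    dominant_disease = df$disease,
    dominant_phenotypes = purrr::map(df$phenotypes, function(p) {
      trimws(strsplit(p, ",", fixed = TRUE)[[1]])
    })
  )
}

#' Write a call set as a minimal single-sample VCF
#'
#' Used by the synthetic cohort generator to materialize per-caller call
#' sets for consumption by [read_caller_vcf()].
#'
#' @param callset tibble with `patient_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `genotype`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_caller_vcf <- function(callset, path) {
  patient <- unique(callset$patient_id)
  if (length(patient) > 1) rlang::abort("a caller VCF holds one sample only")
  if (length(patient) == 0) patient <- "unknown"
  callset <- callset[order(chrom_rank(callset$chrom), callset$pos), ]
  gt <- c(het = "0/1", hom_alt = "1/1", hemi = "1")[callset$genotype]
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", patient)
  )
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
    callset$chrom, as.integer(callset$pos), callset$ref, callset$alt, gt
  )
  writeLines(c(header, body), path)
  invisible(path)
}
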