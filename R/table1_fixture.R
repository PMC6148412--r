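# In-package fixture encoding the 20 candidate variants of the motivating
# high-myopia cohort: 16 missense, 3 splicing, 1 frameshift heterozygous
# variants across 12 genes in 16 of 20 patients. Annotation values not
# printed in the source table (predictor votes, allele frequencies) are
# set to the weakest values consistent with retention; the SLC39A5
# rs756666376 row carries its published ExAC frequency and a unanimous
# 8/8 pathogenic vote. QTL intervals are constructed on GRCh37
# coordinates so that they contain exactly the QTL-labelled variant
# positions (the ADAMTS18 and P3H2 rows sit outside every interval).

.table1_rows <- function() {
  tibble::tribble(
    ~patient_id, ~gene, ~chrom, ~pos, ~hgvs_c, ~hgvs_p, ~dbsnp, ~consequence,
    "R0025", "ABCA4",    "1",  94490591,  "c.4553G>A", "p.Ser1518Asn", NA, "missense",
    "R0017", "ADAMTS18", "16", 77334288,  "c.2546G>A", "p.Gly849Asp",  NA, "missense",
    "R0031", "CEP290",   "12", 88519100,  "c.1112T>C", "p.Val371Ala",  NA, "missense",
    "R0026", "CSMD1",    "8",  2975943,   "c.6408C>G", "p.Asn2136Lys", "rs778164827", "missense",
    "R0027", "CSMD1",    "8",  3165341,   "c.3826G>A", "p.Glu1276Lys", "rs534926586", "missense",
    "R0029", "CSMD1",    "8",  3165341,   "c.3826G>A", "p.Glu1276Lys", "rs534926586", "missense",
    "R0023", "HSPG2",    "1",  22154919,  "c.12238G>A", "p.Val4080Met", NA, "missense",
    "R0011", "HSPG2",    "1",  22207207,  "c.1940G>A", "p.Arg647Gln",  NA, "missense",
    "R0031", "P3H2",     "3",  189692463, "c.1336C>T", "p.Leu446Phe",  NA, "missense",
    "R0018", "PCDH15",   "10", 55973726,  "c.1081_1082delGA", "p.Asp361LeufsTer6", NA, "frameshift",
    "R0016", "RPGR",     "X",  38147035,  "c.1832A>G", "p.Asn611Ser",  "rs774982456", "missense",
    "R0015", "RPGR",     "X",  38182648,  "c.154+4A>G", NA,            "rs764483977", "splice_region",
    "R0021", "SAG",      "2",  234217902, "c.72_75+15delATCGGTGAGTGGTGCACAA", NA, "rs771810575", "splice_donor",
    "R0019", "SEMA4A",   "1",  156146474, "c.1972C>T", "p.Arg658Trp",  "rs756847201", "missense",
    "R0012", "SEMA4A",   "1",  156126310, "c.245A>G",  "p.Glu82Gly",   NA, "missense",
    "R0020", "SLC39A5",  "12", 56629416,  "c.877G>A",  "p.Gly293Arg",  "rs756666376", "missense",
    "R0018", "USH2A",    "1",  216419965, "c.2771C>T", "p.Pro924Leu",  NA, "missense",
    "R0019", "USH2A",    "1",  216372968, "c.3811+1G>A", NA,           NA, "splice_donor",
    "R0014", "USH2A",    "1",  215821999, "c.14453C>T", "p.Pro4818Leu", "rs143344549", "missense",
    "R0015", "USH2A",    "1",  216498726, "c.1064T>C", "p.Val355Ala",  "rs746683099", "missense"
  )
}

# REF/ALT alleles for the fixture keys. SNV alleles follow the coding
# change letters; the two deletions get anchored keys.
.table1_alleles <- function(hgvs_c) {
  snv <- stringr::str_match(hgvs_c, "([ACGT])>([ACGT])$")
  ref <- snv[, 2]
  alt <- snv[, 3]
  del <- hgvs_c == "c.1081_1082delGA"
  ref[del] <- "TGA"
  alt[del] <- "T"
  big_del <- grepl("^c\\.72_75", hgvs_c)
  ref[big_del] <- "GATCGGTGAGTGGTGCACAA"
  alt[big_del] <- "G"
  list(ref = ref, alt = alt)
}

#' Known high-myopia genes of the fixture cohort
#' @return character vector of the five known high-myopia gene symbols.
#' @export
table1_known_genes <- function() {
  c("ADAMTS18", "CSMD1", "P3H2", "RPGR", "SLC39A5")
}

#' Ocular-disease genes of the fixture cohort
#' @return character vector of the seven ocular-disease gene symbols.
#' @export
table1_ocular_genes <- function() {
  c("ABCA4", "CEP290", "HSPG2", "PCDH15", "SAG", "SEMA4A", "USH2A")
}

#' Build the 20-variant cohort fixture
#'
#' Returns the complete input bundle needed to run the filter cascade on
#' the 20-variant, 12-gene, 16-patient candidate table: an annotation
#' table, myopia QTL intervals (GRCh37), phenotype gene lists, the
#' dominant-disease sidecar, and per-patient phenotype terms for the full
#' 20-patient cohort.
#'
#' @param include_col4a5_decoy when `TRUE`, appends a COL4A5-like decoy
#'   variant (dominant Alport-syndrome gene, phenotype unmet in the
#'   carrier) that the cascade must reject at the dominant-exclusion
#'   stage.
#' @param pad_evidence when `TRUE`, pads the gene lists with synthetic
#'   symbols to the full evidence-list sizes (58 known high-myopia genes,
#'   651 ocular-disease genes, 709 total).
#' @return list with `annotations`, `qtl`, `known_genes`, `hpo_genes`,
#'   `retnet_genes`, `omim_genes`, `dominant_table`, `inheritance`,
#'   `patient_phenotypes`, `patients`, `cohort_size`, plus `evidence` and
#'   `qtl_index` ready for [apply_cascade()].
#' @export
table1_fixture <- function(include_col4a5_decoy = FALSE, pad_evidence = FALSE) {
  rows <- .table1_rows()
  alleles <- .table1_alleles(rows$hgvs_c)
  votes_cycle <- c(6, 7, 8)
  ann <- tibble::tibble(
    patient_id = rows$patient_id,
    chrom = rows$chrom,
    pos = rows$pos,
    ref = alleles$ref,
    alt = alleles$alt,
    genotype = "het",
    gene = rows$gene,
    consequence = rows$consequence,
    hgvs_c = rows$hgvs_c,
    hgvs_p = rows$hgvs_p,
    dbsnp = rows$dbsnp,
    splice_score = ifelse(rows$consequence == "splice_region", 0.9, NA_real_),
    af_1000g = NA_real_,
    af_exac = ifelse(rows$dbsnp %in% "rs756666376", 0.00012, NA_real_),
    af_esp = NA_real_
  )
  # predictor panel: unanimous for the published rs756666376 row, a
  # varying compliant vote (6-8 of 8) elsewhere; non-missense rows carry
  # no predictions
  panel <- matrix(NA_character_, nrow(ann), 8,
                  dimnames = list(NULL, .predictor_cols))
  mis <- which(ann$consequence == "missense")
  for (i in seq_along(mis)) {
    v <- if (ann$dbsnp[mis[i]] %in% "rs756666376") 8L else votes_cycle[(i - 1) %% 3 + 1]
    panel[mis[i], ] <- c(rep("pathogenic", v), rep("benign", 8 - v))
  }
  ann <- dplyr::bind_cols(ann, tibble::as_tibble(panel))
  ann <- ann[.annotation_cols]

  qtl <- tibble::tribble(
    ~name,   ~chrom, ~start,      ~end,
    "MYP14", "1",    22000000,  217000000,
    "MYP12", "2",    234000000, 234500000,
    "MYP10", "8",    2900000,   3300000,
    "MYP15", "10",   55000000,  56500000,
    "MYP3",  "12",   88000000,  89000000,
    "MYP24", "12",   56000000,  57000000,
    "MYP13", "X",    38000000,  38500000,
    "MYP1",  "X",    140000000, 155000000
  )

  known <- table1_known_genes()
  hpo <- c("ABCA4", "CEP290", "COL4A5")
  retnet <- c("HSPG2", "PCDH15", "SAG")
  omim <- c("SEMA4A", "USH2A")
  if (pad_evidence) {
    n_ocular_real <- length(unique(c(hpo, retnet, omim)))
    known <- c(known, sprintf("HMK%03d", seq_len(58 - length(known))))
    omim <- c(omim, sprintf("OCG%03d", seq_len(651 - n_ocular_real)))
  }
  dominant_table <- tibble::tibble(
    gene = "COL4A5",
    dominant_disease = "Alport syndrome",
    dominant_phenotypes = list(c("hematuria", "sensorineural hearing loss",
                                 "renal failure"))
  )
  inheritance <- c(
    ABCA4 = "AR", ADAMTS18 = "AR", CEP290 = "AR", CSMD1 = NA, HSPG2 = "AR",
    P3H2 = "AR", PCDH15 = "AR", RPGR = "X-linked", SAG = "AR",
    SEMA4A = "AR/AD", SLC39A5 = "AD", USH2A = "AR", COL4A5 = "X-linked"
  )

  if (include_col4a5_decoy) {
    decoy <- tibble::tibble(
      patient_id = "R0027", chrom = "X", pos = 148000000, ref = "C", alt = "G",
      genotype = "het", gene = "COL4A5", consequence = "missense",
      hgvs_c = "c.2338C>G", hgvs_p = "p.Pro780Ala", dbsnp = NA_character_,
      sift = "pathogenic", polyphen2 = "pathogenic", lrt = "pathogenic",
      mutation_taster = "pathogenic", mutation_assessor = "pathogenic",
      fathmm = "pathogenic", cadd = "pathogenic", dann = "benign",
      af_1000g = NA_real_, af_exac = NA_real_, af_esp = NA_real_,
      splice_score = NA_real_
    )
    ann <- dplyr::bind_rows(ann, decoy[.annotation_cols])
  }

  patients <- sort(unique(c(
    .table1_rows()$patient_id,
    c("R0013", "R0022", "R0024", "R0028")  # candidate-free cohort members
  )))
  patient_phenotypes <- setNames(rep(list("high myopia"), length(patients)),
                                 patients)
  evidence <- assemble_gene_sets(
    known_hm_genes = known, hpo_genes = hpo, retnet_genes = retnet,
    omim_ocular_genes = omim, dominant_table = dominant_table,
    inheritance = inheritance
  )
  list(
    annotations = normalize_keys(ann),
    qtl = qtl,
    known_genes = known,
    hpo_genes = hpo,
    retnet_genes = retnet,
    omim_genes = omim,
    dominant_table = dominant_table,
    inheritance = inheritance,
    patient_phenotypes = patient_phenotypes,
    patients = patients,
    cohort_size = length(patients),
    evidence = evidence,
    qtl_index = build_interval_index(qtl)
  )
}

#' Write the fixture bundle to disk
#'
#' Materializes the [table1_fixture()] inputs as the plain-text files the
#' pipeline readers consume (annotation TSV, QTL TSV, gene-set TSVs,
#' dominant-disease TSV, phenotype YAML).
#'
#' @param dir output directory (created if needed).
#' @param ... passed to [table1_fixture()].
#' @return named character vector of the written paths, invisibly.
#' @export
write_table1_fixture <- function(dir, ...) {
  fx <- table1_fixture(...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    annotations = file.path(dir, "annotations.tsv"),
    qtl = file.path(dir, "qtl.tsv"),
    known = file.path(dir, "genes_known_hm.tsv"),
    hpo = file.path(dir, "genes_hpo.tsv"),
    retnet = file.path(dir, "genes_retnet.tsv"),
    omim = file.path(dir, "genes_omim.tsv"),
    dominant = file.path(dir, "dominant_diseases.tsv"),
    phenotypes = file.path(dir, "patient_phenotypes.yaml")
  )
  write_annotation_table(fx$annotations, paths["annotations"])
  readr::write_tsv(fx$qtl, paths["qtl"], progress = FALSE)
  write_set <- function(genes, source, path) {
    readr::write_tsv(tibble::tibble(gene = genes, source = source), path,
                     progress = FALSE)
  }
  write_set(fx$known_genes, "known_hm", paths["known"])
  write_set(fx$hpo_genes, "hpo", paths["hpo"])
  write_set(fx$retnet_genes, "retnet", paths["retnet"])
  write_set(fx$omim_genes, "omim", paths["omim"])
  readr::write_tsv(
    tibble::tibble(
      gene = fx$dominant_table$gene,
      disease = fx$dominant_table$dominant_disease,
      phenotypes = purrr::map_chr(fx$dominant_table$dominant_phenotypes,
                                  paste, collapse = ",")
    ),
    paths["dominant"], progress = FALSE
  )
  yaml::write_yaml(fx$patient_phenotypes, paths["phenotypes"])
  invisible(paths)
}
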