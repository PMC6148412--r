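# Shared test helpers: tiny VCF writers, random key/call-set builders,
# and an adjusted-Rand helper for partition agreement.

write_vcf_lines <- function(rows, sample = "S1", path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  writeLines(c(header, rows), path)
  path
}

random_keys <- function(n, chroms = c("1", "2", "X")) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample.int(1e6, n),
    ref = ref,
    alt = unname(alt)
  ) |> dplyr::distinct(chrom, pos, .keep_all = TRUE)
}

make_callset <- function(keys, caller, patient = "P1", genotype = "het") {
  dplyr::mutate(keys, caller = caller, patient_id = patient,
                genotype = genotype, .before = 1)
}

# minimal fully-compliant annotated variant row; override fields as needed
annotation_row <- function(...) {
  base <- tibble::tibble(
    patient_id = "P1", chrom = "1", pos = 1000L, ref = "G", alt = "A",
    genotype = "het", gene = "GENE1", consequence = "missense",
    hgvs_c = "c.1G>A", hgvs_p = NA_character_, dbsnp = NA_character_,
    sift = "pathogenic", polyphen2 = "pathogenic", lrt = "pathogenic",
    mutation_taster = "pathogenic", mutation_assessor = "pathogenic",
    fathmm = "pathogenic", cadd = "pathogenic", dann = "pathogenic",
    af_1000g = NA_real_, af_exac = NA_real_, af_esp = NA_real_,
    splice_score = NA_real_
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  # closed-form ARI fallback
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
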