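# Format readers/writers: VCF parsing, key normalization, annotation and
# QTL tables, candidate-table round trip.

test_that("VCF reading splits genotypes and multi-allelic rows correctly", {
  path <- write_vcf_lines(c(
    "1\t94490591\t.\tG\tA\t50\tPASS\t.\tGT\t0/1",
    "1\t200\t.\tA\tT,G\t50\tPASS\t.\tGT\t1/2",
    "2\t300\t.\tC\tT\t50\tPASS\t.\tGT\t0/0",
    "2\t400\t.\tC\tT\t50\tPASS\t.\tGT\t1/1",
    "X\t500\t.\tG\tC\t50\tPASS\t.\tGT\t1"
  ))
  cs <- read_caller_vcf(path, "gatk")
  expect_equal(unique(cs$caller), "gatk")
  expect_equal(unique(cs$patient_id), "S1")
  # 0/0 row dropped; multi-allelic split into two het calls
  expect_equal(nrow(cs), 5)
  hit <- cs[cs$pos == 94490591, ]
  expect_equal(hit[c("chrom", "ref", "alt", "genotype")],
               tibble::tibble(chrom = "1", ref = "G", alt = "A", genotype = "het"))
  multi <- cs[cs$pos == 200, ]
  expect_setequal(multi$alt, c("T", "G"))
  expect_true(all(multi$genotype == "het"))
  expect_equal(cs$genotype[cs$pos == 400], "hom_alt")
  expect_equal(cs$genotype[cs$pos == 500], "hemi")
})

test_that("multi-allelic decomposition matches exhaustive per-allele split on a toy VCF", {
  # 10-row toy VCF with assorted multi-allelic rows
  set.seed(42)
  rows <- c(
    "1\t10\t.\tA\tT,G\t9\tPASS\t.\tGT\t1/2",
    "1\t20\t.\tC\tG,T,A\t9\tPASS\t.\tGT\t2/3",
    "1\t30\t.\tG\tA\t9\tPASS\t.\tGT\t0/1",
    "1\t40\t.\tT\tC,A\t9\tPASS\t.\tGT\t0/2",
    "1\t50\t.\tA\tG\t9\tPASS\t.\tGT\t1/1",
    "2\t10\t.\tC\tT,G\t9\tPASS\t.\tGT\t2/2",
    "2\t20\t.\tG\tC\t9\tPASS\t.\tGT\t0/1",
    "2\t30\t.\tT\tA,C\t9\tPASS\t.\tGT\t1/2",
    "2\t40\t.\tA\tC\t9\tPASS\t.\tGT\t0/0",
    "2\t50\t.\tG\tT\t9\tPASS\t.\tGT\t./."
  )
  # independent oracle: enumerate (row, alt index) pairs where the GT
  # carries that allele index
  parse_gt <- function(row) {
    f <- strsplit(row, "\t")[[1]]
    alts <- strsplit(f[5], ",")[[1]]
    alleles <- strsplit(f[10], "[/|]")[[1]]
    purrr::map_dfr(seq_along(alts), function(a) {
      if (sum(alleles == as.character(a)) == 0) return(NULL)
      tibble::tibble(chrom = f[1], pos = as.numeric(f[2]), ref = f[4], alt = alts[a])
    })
  }
  expected <- dplyr::bind_rows(lapply(rows, parse_gt))
  # the fully missing ./. record is skipped (with a warning, since vcfR
  # reports it as an absent GT)
  cs <- suppressWarnings(read_caller_vcf(write_vcf_lines(rows), "toy"))
  expect_setequal(
    paste(cs$chrom, cs$pos, cs$ref, cs$alt),
    paste(expected$chrom, expected$pos, expected$ref, expected$alt)
  )
})

test_that("VCF records without GT are skipped with a warning; non-PASS filtered", {
  path <- write_vcf_lines(c(
    "1\t100\t.\tG\tA\t50\tPASS\t.\tDP\t12",
    "1\t200\t.\tG\tA\t50\tq10\t.\tGT\t0/1",
    "1\t300\t.\tG\tA\t50\t.\t.\tGT\t0/1"
  ))
  expect_warning(cs <- read_caller_vcf(path, "c1"), "no GT")
  expect_equal(cs$pos, 300)  # PASS-or-dot rule drops the q10 record
  cs_all <- suppressWarnings(read_caller_vcf(path, "c1", require_pass = FALSE))
  expect_setequal(cs_all$pos, c(200, 300))
})

test_that("key normalization trims anchored indels and is idempotent", {
  raw <- tibble::tibble(
    chrom = c("chr1", "1", "2", "X"),
    pos = c(100, 100, 50, 7),
    ref = c("TAG", "ATGC", "C", "GCC"),
    alt = c("TG", "ATTC", "T", "GCCC")
  )
  norm <- normalize_keys(raw)
  expect_equal(norm$chrom, c("1", "1", "2", "X"))
  # TAG>TG right-trims G then keeps anchor: pos 100 AG>A... trailing G
  # shared -> TA/T, no shared prefix trim beyond anchor
  expect_equal(norm$ref[1], "TA")
  expect_equal(norm$alt[1], "T")
  # ATGC>ATTC: shared suffix C, shared prefix AT -> G>T at pos 102
  expect_equal(norm$pos[2], 102L)
  expect_equal(norm$ref[2], "G")
  expect_equal(norm$alt[2], "T")
  # insertion GCC>GCCC -> anchor retained
  expect_equal(nchar(norm$ref[4]), 1)
  expect_identical(normalize_keys(norm), norm)
})

test_that("invalid keys and chromosomes are rejected", {
  expect_error(normalize_keys(tibble::tibble(chrom = "23", pos = 1, ref = "A", alt = "T")),
               "unsupported chromosome")
  expect_error(normalize_keys(tibble::tibble(chrom = "1", pos = 1, ref = "A", alt = "A")),
               "must differ")
  expect_error(normalize_keys(tibble::tibble(chrom = "1", pos = 1, ref = "N", alt = "A")),
               "ACGT")
  expect_error(normalize_keys(tibble::tibble(chrom = "1", pos = 0, ref = "G", alt = "A")),
               "pos")
})

test_that("QTL table reading validates and round-trips", {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    name = sprintf("MYP%d", 1:26), chrom = as.character(rep(1:13, 2)),
    start = rep(1, 26), end = rep(1.2e8, 26)
  ), path)
  qtl <- read_qtl_table(path)
  expect_equal(nrow(qtl), 26)
  expect_equal(qtl$name[14], "MYP14")

  empty <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(name = character(0), chrom = character(0),
                                  start = numeric(0), end = numeric(0)), empty)
  expect_equal(nrow(read_qtl_table(empty)), 0)

  bad <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(name = "M", chrom = "1", start = 10, end = 5), bad)
  expect_error(read_qtl_table(bad), "line 2")
})

test_that("annotation table rejects unknown consequences and duplicates", {
  ann <- annotation_row()
  p <- tempfile(fileext = ".tsv")
  write_annotation_table(ann, p)
  back <- read_annotation_table(p)
  expect_equal(back$gene, "GENE1")
  expect_equal(back$af_1000g, NA_real_)
  expect_equal(back$sift, "pathogenic")

  bad <- annotation_row(consequence = "nonsense_term")
  write_annotation_table(bad, p)
  expect_error(read_annotation_table(p), "accepted vocabulary")

  dup <- dplyr::bind_rows(ann, ann)
  readr::write_tsv(dplyr::mutate(dup, dplyr::across(dplyr::everything(), as.character)), p)
  expect_error(read_annotation_table(p), "duplicate")
})

test_that("candidate table round-trips through write/read", {
  fx <- table1_fixture()
  res <- apply_cascade(fx$annotations, fx$evidence, fx$qtl_index,
                       patient_phenotypes = fx$patient_phenotypes)
  p <- tempfile(fileext = ".tsv")
  write_candidate_table(res$retained, p)
  back <- read_candidate_table(p)
  expect_equal(nrow(back), nrow(res$retained))
  orig <- res$retained |> dplyr::arrange(gene, patient_id)
  expect_equal(back$gene, orig$gene)
  expect_equal(back$patient_id, orig$patient_id)
  expect_equal(back$chrom, orig$chrom)
  expect_equal(back$pos, orig$pos)
  expect_equal(back$hgvs_c, orig$hgvs_c)
  expect_equal(back$hgvs_p, orig$hgvs_p)
  expect_equal(back$dbsnp, orig$dbsnp)
  expect_equal(back$gene_class, orig$gene_class)
  expect_equal(back$qtl_names, orig$qtl_names)
})

test_that("reader output is independent of input row order", {
  fx <- table1_fixture()
  p1 <- tempfile(fileext = ".tsv")
  p2 <- tempfile(fileext = ".tsv")
  write_annotation_table(fx$annotations, p1)
  set.seed(7)
  write_annotation_table(fx$annotations[sample.int(nrow(fx$annotations)), ], p2)
  a1 <- read_annotation_table(p1)
  a2 <- read_annotation_table(p2)
  expect_equal(
    dplyr::arrange(a1, patient_id, chrom, pos),
    dplyr::arrange(a2, patient_id, chrom, pos)
  )
})

test_that("edge lists load as simple undirected graphs", {
  p <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    geneA = c("A", "B", "A", "C", "C"),
    geneB = c("B", "A", "A", "D", "D")
  ), p)
  g <- read_edge_list(p)
  expect_false(igraph::is_directed(g))
  expect_equal(igraph::ecount(g), 2)  # dedup + self-loop removal
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "D"))
})
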