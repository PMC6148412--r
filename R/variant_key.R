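#' Normalize variant keys
#'
#' Brings `(chrom, pos, ref, alt)` tuples into the canonical parsimonious
#' representation used throughout the pipeline: shared trailing bases are
#' trimmed first, then shared leading bases (advancing `pos`), always
#' keeping at least one base on each allele so indels retain their anchor
#' base. Chromosome names are canonicalized (no `"chr"` prefix). The
#' operation is idempotent.
#'
#' @param keys a data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return a tibble with the same columns, normalized, other columns
#'   passed through untouched.
#' @examples
#' normalize_keys(data.frame(chrom = "1", pos = 100, ref = "TAG", alt = "TG"))
#' @export
normalize_keys <- function(keys) {
  keys <- tibble::as_tibble(keys)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(keys)))
  keys$chrom <- canonical_chrom(keys$chrom)
  keys$ref <- toupper(keys$ref)
  keys$alt <- toupper(keys$alt)
  validate_alleles(keys$ref, keys$alt)
  if (any(keys$pos < 1)) rlang::abort("variant pos must be >= 1")

  norm <- purrr::pmap(
    list(keys$pos, keys$ref, keys$alt),
    function(pos, ref, alt) {
      r <- strsplit(ref, "", fixed = TRUE)[[1]]
      a <- strsplit(alt, "", fixed = TRUE)[[1]]
      # trim shared suffix
      while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
        r <- r[-length(r)]
        a <- a[-length(a)]
      }
      # trim shared prefix, advancing pos
      while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
        r <- r[-1]
        a <- a[-1]
        pos <- pos + 1
      }
      list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
    }
  )
  keys$pos <- as.integer(purrr::map_dbl(norm, "pos"))
  keys$ref <- purrr::map_chr(norm, "ref")
  keys$alt <- purrr::map_chr(norm, "alt")
  if (any(keys$ref == keys$alt)) {
    rlang::abort("ref and alt alleles must differ after normalization")
  }
  keys
}

validate_alleles <- function(ref, alt) {
  ok <- function(x) nzchar(x) & grepl("^[ACGT]+$", x)
  bad <- !ok(ref) | !ok(alt)
  if (any(bad)) {
    rlang::abort(sprintf(
      "alleles must be non-empty uppercase ACGT strings (offending: %s)",
      paste(unique(paste(ref[bad], alt[bad], sep = "/")), collapse = ", ")
    ))
  }
  if (any(ref == alt)) rlang::abort("ref and alt alleles must differ")
  invisible(TRUE)
}

# single canonical string id for a key, used for set operations
key_id <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}
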