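# Internal helpers shared across modules.

# canonical GRCh37 chromosome set (no "chr" prefix); "23"/"24" style
# numeric sex chromosomes are rejected rather than silently recoded
.chrom_levels <- c(as.character(1:22), "X", "Y", "MT")

#' Canonicalize chromosome names
#'
#' Strips a leading `"chr"` prefix and validates against the GRCh37
#' chromosome vocabulary (`1`-`22`, `X`, `Y`, `MT`). Numeric encodings of
#' sex chromosomes (`"23"`, `"24"`) are rejected loudly rather than
#' re-aliased.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector of canonical names.
#' @keywords internal
#' @noRd
canonical_chrom <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  bad <- setdiff(unique(chrom), .chrom_levels)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "unsupported chromosome name(s): %s (expected %s)",
      paste(bad, collapse = ", "),
      paste(c("1-22", "X", "Y", "MT"), collapse = ", ")
    ))
  }
  chrom
}

# integer rank used for genomic sorting
chrom_rank <- function(chrom) {
  match(chrom, .chrom_levels)
}

# sort a variant table by (chrom, pos, ref, alt)
sort_by_key <- function(df) {
  dplyr::arrange(df, chrom_rank(.data$chrom), .data$pos, .data$ref, .data$alt)
}

# display sentinel used by the candidate table ("-" when a field is absent)
.na_sentinel <- "-"

na_to_dash <- function(x) {
  x <- as.character(x)
  ifelse(is.na(x) | x == "", .na_sentinel, x)
}

dash_to_na <- function(x) {
  x <- as.character(x)
  ifelse(x %in% c(.na_sentinel, "–", ""), NA_character_, x)
}
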