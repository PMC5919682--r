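#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for all reported cohort percentages (base [round()] rounds
#' half to even, which disagrees on values such as 0.25).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(14.876, 1) # 14.9
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a denominator, rounded to one decimal
#' @param n Count.
#' @param denom Denominator.
#' @return Percentage on the 0-100 scale, one decimal, ties away from zero.
#' @export
pct <- function(n, denom) {
  if (denom == 0) return(0)
  round_half_up(100 * n / denom, 1)
}

#' Canonical variant key
#'
#' Variants are keyed by gene symbol and HGVS cDNA change (e.g.
#' `"ATM:c.8560C>T"`), the identifiers by which panel results are usually
#' reported and cross-referenced with control genotyping.
#'
#' @param gene HGNC symbol.
#' @param cdna HGVS cDNA change string.
#' @return Character vector of keys.
#' @export
variant_key <- function(gene, cdna) paste0(gene, ":", cdna)

## TSV dialect: tab separated, UTF-8, header row, "." for missing.
read_tsv_dot <- function(path, ...) {
  utils::read.delim(path, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv_dot <- function(x, path) {
  utils::write.table(x, path, sep = "\t", na = ".", quote = FALSE,
                     row.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
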