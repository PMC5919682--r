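## Exact 2x2 association tests for carrier frequencies against control
## panels and reference-population allele counts, and the
## clinicopathological association screen.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Thin, validating wrapper around [stats::fisher.test()]. The two-sided
#' p-value is the conventional minimum-likelihood sum: the total conditional
#' (hypergeometric) probability of all tables with fixed margins whose point
#' probability does not exceed that of the observed table.
#'
#' @param tab 2x2 matrix of nonnegative counts (rows: cases/controls,
#'   columns: carrier/non-carrier), or a length-4 vector `c(a, b, c, d)`
#'   filled by row.
#' @return Two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact(c(3, 118, 0, 710))
fisher_exact <- function(tab) {
  if (!is.matrix(tab)) {
    stopifnot(length(tab) == 4)
    tab <- matrix(tab, nrow = 2, byrow = TRUE)
  }
  stopifnot(dim(tab) == c(2, 2))
  if (any(tab < 0)) stopf("counts must be nonnegative")
  if (any(tab != round(tab))) stopf("counts must be integers")
  if (all(tab == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Build the carrier-level 2x2 contingency table
#'
#' @param case_carriers,n_cases Carrier count and size of the case series.
#' @param control_carriers,n_controls Carrier count and size of the control
#'   panel.
#' @return 2x2 integer matrix: rows cases/controls, columns
#'   carrier/non-carrier.
#' @export
#' @examples
#' build_carrier_table(3, 121, 0, 710)
build_carrier_table <- function(case_carriers, n_cases,
                                control_carriers, n_controls) {
  stopifnot(case_carriers >= 0, control_carriers >= 0)
  if (case_carriers > n_cases || control_carriers > n_controls)
    stopf("carrier count exceeds group size")
  matrix(c(case_carriers, n_cases - case_carriers,
           control_carriers, n_controls - control_carriers),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("cases", "controls"),
                         c("carrier", "non_carrier")))
}

#' Look up control carrier counts for a variant
#'
#' @param controls Control-counts table with columns `key`, `group`, `n`,
#'   `carriers` (one row per variant per control group).
#' @param key Variant key ([variant_key()]); a variant absent from the table
#'   is treated as 0 carriers.
#' @param group Control group label (e.g. `"healthy"`, `"cancer_panel"`).
#' @return List with `carriers` and `n` (NA carriers if the count was never
#'   genotyped in that group).
#' @export
control_carriers <- function(controls, key, group) {
  g <- controls[controls$group == group, , drop = FALSE]
  if (!nrow(g)) stopf("unknown control group '%s'", group)
  i <- match(key, g$key)
  list(carriers = if (is.na(i)) 0L else g$carriers[i], n = g$n[1])
}

#' Allele-count comparison against a reference population
#'
#' For reference populations (e.g. ExAC non-Finnish Europeans) individual
#' genotypes are unavailable, so the comparison is made on allele counts:
#' a two-sided Fisher exact test on the alt/ref allele 2x2 table.
#'
#' @param case_alt,case_total_alleles Alt allele count and total allele
#'   count (2N) in the case series.
#' @param ref_alt,ref_total_alleles Same for the reference population.
#' @return Two-sided p-value.
#' @export
compare_reference_alleles <- function(case_alt, case_total_alleles,
                                      ref_alt, ref_total_alleles) {
  stopifnot(case_alt >= 0, ref_alt >= 0,
            case_alt <= case_total_alleles, ref_alt <= ref_total_alleles)
  fisher_exact(matrix(c(case_alt, case_total_alleles - case_alt,
                        ref_alt, ref_total_alleles - ref_alt),
                      nrow = 2, byrow = TRUE))
}

#' Clinicopathological association screen
#'
#' Tests carrier status against a categorical clinicopathological feature
#' (PSA category, tumor stage, Gleason score group, ...) by collapsing the
#' feature to one-vs-rest 2x2 tables, one Fisher exact test per level. No
#' multiple-testing adjustment is applied; p-values are reported as-is.
#'
#' @param carrier_flags Logical vector, one entry per patient.
#' @param feature Vector (coerced to factor) of the same length.
#' @return Data frame with one row per feature level: the 2x2 counts
#'   (`a` carriers with level, `b` carriers without, `c` non-carriers with,
#'   `d` non-carriers without) and the Fisher `p`.
#' @export
clinicopath_association <- function(carrier_flags, feature) {
  stopifnot(length(carrier_flags) == length(feature))
  keep <- !is.na(carrier_flags) & !is.na(feature)
  carrier_flags <- carrier_flags[keep]
  feature <- factor(feature[keep])
  if (length(unique(carrier_flags)) < 2)
    stopf("degenerate margin: all patients have the same carrier status")
  if (nlevels(feature) < 2)
    stopf("degenerate margin: feature has a single level")
  out <- lapply(levels(feature), function(lv) {
    a <- sum(carrier_flags & feature == lv)
    b <- sum(carrier_flags & feature != lv)
    cc <- sum(!carrier_flags & feature == lv)
    d <- sum(!carrier_flags & feature != lv)
    data.frame(level = lv, a = a, b = b, c = cc, d = d,
               p = fisher_exact(c(a, b, cc, d)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
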