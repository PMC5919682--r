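## Variant filter cascade.
##
## All filters operate on an annotated variant table (one row per variant,
## see `annotation_columns()`) and return a logical vector: TRUE = kept.
## The cascade is conjunctive, so the kept set does not depend on the order
## in which the rules are applied; `run_cascade()` additionally produces an
## audit table naming, for every removed variant, each rule it failed.

CONSEQUENCES <- c("nonsense", "frameshift", "missense", "synonymous",
                  "splice_site", "intronic", "inframe_indel")

CLINICAL_CLASSES <- c("pathogenic", "likely_pathogenic", "vus",
                      "likely_benign", "benign", "conflicting", "absent")

#' Columns of the annotated variant table
#'
#' The annotation dialect used by all pipeline stages: one row per variant
#' (or per patient-variant pair when a `patient_id` column is present),
#' missing values written as `"."` on disk and `NA` in memory.
#'
#' @return Character vector of required column names (predictor rankscore
#'   columns `rs_<tool>` and splice call columns `sp_<tool>` included).
#' @export
annotation_columns <- function() {
  c("chrom", "pos", "ref", "alt", "gene", "transcript", "cdna", "protein",
    "consequence", "intron_distance", "depth", "vaf",
    "maf_1000g", "maf_evs", "maf_exac", "inhouse_fraction",
    "clinvar", "bic", "lovd",
    paste0("rs_", c(functional_predictors(), conservation_predictors())),
    paste0("sp_", splice_predictors()))
}

check_variant_table <- function(variants, need = c("chrom", "pos", "ref",
                                                   "alt", "gene", "cdna")) {
  stopifnot(is.data.frame(variants))
  missing_cols <- setdiff(need, names(variants))
  if (length(missing_cols))
    stopf("variant table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  invisible(variants)
}

#' Read-quality filter: coverage and alternative allele fraction
#'
#' Keeps variants with depth strictly above `min_depth` reads and an
#' alternative allele fraction within `[vaf_low, vaf_high]` (inclusive);
#' calls outside the band are treated as possible mosaicism or artifact.
#'
#' @param variants Annotated variant table with `depth` and `vaf` columns.
#' @param thresholds A [default_thresholds()] list.
#' @return Logical vector, TRUE where the variant is kept.
#' @export
#' @examples
#' v <- data.frame(depth = c(21, 20, 100), vaf = c(0.45, 0.5, 0.2))
#' filter_quality(v) # TRUE FALSE FALSE
filter_quality <- function(variants, thresholds = default_thresholds()) {
  check_variant_table(variants, c("depth", "vaf"))
  variants$depth > thresholds$min_depth &
    variants$vaf >= thresholds$vaf_low &
    variants$vaf <= thresholds$vaf_high
}

#' Population frequency (MAF) filter
#'
#' Keeps variants whose maximum minor allele frequency over the available
#' reference databases (1000 Genomes, EVS, ExAC) is at most `max_maf`
#' (inclusive). A variant absent from every database is kept: rarity cannot
#' be held against a variant never observed.
#'
#' @inheritParams filter_quality
#' @return Logical keep vector.
#' @export
filter_maf <- function(variants, thresholds = default_thresholds()) {
  check_variant_table(variants, c("maf_1000g", "maf_evs", "maf_exac"))
  m <- as.matrix(variants[, c("maf_1000g", "maf_evs", "maf_exac")])
  mode(m) <- "numeric"
  maxmaf <- apply(m, 1, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  is.na(maxmaf) | maxmaf <= thresholds$max_maf
}

#' In-house cohort frequency filter
#'
#' Removes variants present in more than `max_inhouse` (strictly) of the
#' study's own cases; such recurrent calls are platform artifacts or local
#' polymorphisms rather than rare predisposition alleles. A missing in-house
#' fraction is treated as 0 with a warning.
#'
#' @inheritParams filter_quality
#' @return Logical keep vector.
#' @export
filter_inhouse <- function(variants, thresholds = default_thresholds()) {
  check_variant_table(variants, "inhouse_fraction")
  f <- variants$inhouse_fraction
  if (anyNA(f)) {
    warnf("%d variant(s) with missing in-house fraction treated as 0",
          sum(is.na(f)))
    f[is.na(f)] <- 0
  }
  f <= thresholds$max_inhouse
}

#' Consequence filter
#'
#' Removes synonymous variants and intronic variants more than
#' `max_intron_distance` bp (strictly) away from the nearest exon-intron
#' boundary. Distance 1 is the first intronic base, so HGVS offsets such as
#' c.593-1 map directly onto `intron_distance`.
#'
#' @inheritParams filter_quality
#' @return Logical keep vector.
#' @export
filter_consequence <- function(variants, thresholds = default_thresholds()) {
  check_variant_table(variants, c("consequence", "intron_distance"))
  bad <- setdiff(unique(variants$consequence), CONSEQUENCES)
  if (length(bad)) stopf("unknown consequence value(s): %s",
                         paste(bad, collapse = ", "))
  d <- variants$intron_distance
  d[is.na(d)] <- 0
  !(variants$consequence == "synonymous" |
      (variants$consequence == "intronic" & d > thresholds$max_intron_distance))
}

#' Clinical-database assertion filter
#'
#' Removes variants asserted benign or likely benign ("not pathogenic", "of
#' no/little clinical significance") by any of the queried clinical databases
#' (ClinVar, BIC, InSiGHT/LOVD). Conflicting assertions, VUS and
#' database-absent variants are all retained for downstream review.
#'
#' @param variants Annotated variant table with `clinvar`, `bic`, `lovd`
#'   columns (values among pathogenic, likely_pathogenic, vus, likely_benign,
#'   benign, conflicting, absent; `NA` treated as absent).
#' @return Logical keep vector.
#' @export
filter_clinical <- function(variants) {
  check_variant_table(variants, c("clinvar", "bic", "lovd"))
  a <- as.matrix(variants[, c("clinvar", "bic", "lovd")])
  vals <- unique(a[!is.na(a)])
  bad <- setdiff(vals, CLINICAL_CLASSES)
  if (length(bad)) stopf("unknown clinical assertion(s): %s",
                         paste(bad, collapse = ", "))
  !apply(a, 1, function(x) any(x %in% c("benign", "likely_benign")))
}

FILTER_RULES <- c("quality", "maf", "inhouse", "consequence", "clinical")

apply_filter <- function(rule, variants, thresholds) {
  switch(rule,
    quality     = filter_quality(variants, thresholds),
    maf         = filter_maf(variants, thresholds),
    inhouse     = filter_inhouse(variants, thresholds),
    consequence = filter_consequence(variants, thresholds),
    clinical    = filter_clinical(variants),
    stopf("unknown filter rule '%s'", rule))
}

#' Merge per-caller variant lists into one table with provenance
#'
#' Variants called by several aligner/caller combinations are merged by
#' union on (chrom, pos, ref, alt): a variant called by any caller is
#' retained, and the set of supporting callers is recorded in a `caller_set`
#' column (comma separated) for review. Conflicting REF alleles at the same
#' site are a validation error.
#'
#' @param per_caller Named list of annotated variant tables, one per caller.
#' @return Single variant table with a `caller_set` column.
#' @export
merge_callers <- function(per_caller) {
  stopifnot(is.list(per_caller), length(per_caller) >= 1)
  if (is.null(names(per_caller)) || any(names(per_caller) == ""))
    names(per_caller) <- paste0("caller", seq_along(per_caller))
  tabs <- lapply(names(per_caller), function(nm) {
    v <- per_caller[[nm]]
    if (nrow(v)) check_variant_table(v, c("chrom", "pos", "ref", "alt"))
    if (nrow(v)) v$caller_set <- nm
    v
  })
  tabs <- tabs[vapply(tabs, nrow, 0L) > 0]
  if (!length(tabs)) {
    out <- per_caller[[1]][0, , drop = FALSE]
    out$caller_set <- character(0)
    return(out)
  }
  all <- do.call(rbind, tabs)
  site <- paste(all$chrom, all$pos, sep = ":")
  key <- paste(site, all$ref, all$alt, sep = ":")
  for (s in unique(site)) {
    refs <- unique(all$ref[site == s])
    if (length(refs) > 1)
      stopf("conflicting REF alleles at %s: %s", s, paste(refs, collapse = "/"))
  }
  callers <- tapply(all$caller_set, key, function(x)
    paste(sort(unique(x)), collapse = ","))
  out <- all[!duplicated(key), , drop = FALSE]
  out$caller_set <- as.character(callers[paste(out$chrom, out$pos, out$ref,
                                               out$alt, sep = ":")])
  rownames(out) <- NULL
  out
}

#' Run the full filter cascade with an audit trail
#'
#' Applies all five filters (read quality, MAF, in-house frequency,
#' consequence, clinical assertions) conjunctively. The kept set is the
#' intersection of the per-filter kept sets and is therefore invariant to
#' the order in which the rules are listed.
#'
#' @param variants Annotated variant table.
#' @param thresholds A [default_thresholds()] list.
#' @param rules Character vector of rule identifiers (a permutation or
#'   subset of `c("quality","maf","inhouse","consequence","clinical")`).
#' @return List with `kept` (rows passing every filter), `audit` (one row
#'   per removed variant: the variant key, the first failed rule in the
#'   order given, and all failed rules), and `n_removed_by_rule`.
#' @export
run_cascade <- function(variants, thresholds = default_thresholds(),
                        rules = FILTER_RULES) {
  stopifnot(all(rules %in% FILTER_RULES), !anyDuplicated(rules))
  keep_by_rule <- vapply(rules, apply_filter, logical(nrow(variants)),
                         variants = variants, thresholds = thresholds)
  keep_by_rule <- matrix(keep_by_rule, nrow = nrow(variants),
                         dimnames = list(NULL, rules))
  kept <- rowSums(!keep_by_rule) == 0
  removed <- which(!kept)
  audit <- if (!length(removed)) data.frame(
    key = character(), chrom = character(), pos = numeric(),
    failed_rule = character(), all_failed = character(),
    stringsAsFactors = FALSE
  ) else data.frame(
    key = variant_key(variants$gene[removed], variants$cdna[removed]),
    chrom = variants$chrom[removed],
    pos = variants$pos[removed],
    failed_rule = vapply(removed, function(i)
      rules[which(!keep_by_rule[i, ])[1]], character(1)),
    all_failed = vapply(removed, function(i)
      paste(rules[!keep_by_rule[i, ]], collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  list(kept = variants[kept, , drop = FALSE],
       audit = audit,
       n_removed_by_rule = colSums(!keep_by_rule))
}
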