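#' Default prioritization thresholds
#'
#' Returns the thresholds used throughout the prioritization workflow. The
#' defaults encode the published filtering and consensus rules:
#'
#' * `min_depth` (20, strict): variants require coverage above 20x.
#' * `vaf_low`/`vaf_high` (0.30/0.70, inclusive): heterozygous germline calls;
#'   alternative allele fractions outside this band suggest mosaicism or
#'   artifacts.
#' * `max_maf` (0.001, inclusive): minor allele frequency ceiling across the
#'   queried reference populations (1000 Genomes, EVS, ExAC).
#' * `max_inhouse` (0.10, strict): variants seen in more than 10% of the
#'   cohort's own cases are treated as platform artifacts or local
#'   polymorphisms.
#' * `max_intron_distance` (12, inclusive): intronic variants farther than
#'   12 bp from an exon-intron boundary are discarded.
#' * `consensus_min_calls`/`consensus_total`/`consensus_min_conservation`
#'   (12/15/3): a missense variant is "potentially pathogenic" when called
#'   pathogenic by at least 12 of the 15 in-silico predictors, at least three
#'   of them conservation tools.
#' * `splice_min_calls`/`splice_total` (3/4): a splice-region variant
#'   qualifies when at least 3 of the 4 splice predictors call the site
#'   affected.
#' * `rankscore_cutoff` (0.5, inclusive): rankscore at or above which a
#'   predictor without a categorical call is counted as pathogenic; may be
#'   overridden per tool via `rankscore_cutoffs`.
#' * `alpha` (0.05): significance level for the case-control Fisher tests
#'   (used, e.g., by the PS4 evidence check).
#'
#' @param ... Named overrides for any threshold field.
#' @return A list of class `prca_thresholds`.
#' @export
#' @examples
#' t <- default_thresholds(max_maf = 0.005)
#' t$max_maf
default_thresholds <- function(...) {
  t <- list(
    min_depth            = 20,
    vaf_low              = 0.30,
    vaf_high             = 0.70,
    max_maf              = 0.001,
    max_inhouse          = 0.10,
    max_intron_distance  = 12,
    consensus_min_calls  = 12,
    consensus_total      = 15,
    consensus_min_conservation = 3,
    consensus_denominator = c("fixed", "available"),
    splice_min_calls     = 3,
    splice_total         = 4,
    rankscore_cutoff     = 0.5,
    rankscore_cutoffs    = list(),
    alpha                = 0.05
  )
  t$consensus_denominator <- "fixed"
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(t))
    if (length(bad)) stopf("unknown threshold field(s): %s",
                           paste(bad, collapse = ", "))
    t[names(dots)] <- dots
  }
  validate_thresholds(t)
  class(t) <- "prca_thresholds"
  t
}

validate_thresholds <- function(t) {
  stopifnot(
    t$min_depth >= 0, t$vaf_low < t$vaf_high,
    t$vaf_low >= 0, t$vaf_high <= 1,
    t$max_maf >= 0, t$max_inhouse >= 0,
    t$max_intron_distance >= 0,
    t$consensus_min_calls <= t$consensus_total,
    t$consensus_min_conservation <= t$consensus_total,
    t$splice_min_calls <= t$splice_total,
    t$alpha > 0, t$alpha < 1
  )
  if (!t$consensus_denominator %in% c("fixed", "available"))
    stopf("consensus_denominator must be 'fixed' or 'available'")
  invisible(t)
}

#' Predictor panels used for missense and splice consensus calling
#'
#' The missense consensus draws on 11 functional predictors and 4
#' conservation tools; splice impact is assessed by 4 dedicated predictors.
#' Annotation tables carry one `rs_<tool>` rankscore column per missense
#' predictor and one `sp_<tool>` call column per splice predictor.
#'
#' @name predictor_panels
#' @export
functional_predictors <- function() {
  c("SIFT", "PolyPhen2", "LRT", "MutationTaster", "PROVEAN", "FATHMM",
    "CADD", "MutationAssessor", "MetaLR", "MetaSVM", "VEST3")
}

#' @rdname predictor_panels
#' @export
conservation_predictors <- function() {
  c("PhyloP", "GERP", "PhastCons", "SiPhy")
}

#' @rdname predictor_panels
#' @export
splice_predictors <- function() {
  c("HSF3", "MaxEntScan", "NNSPLICE", "NetGene2")
}
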