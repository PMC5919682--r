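## Predictor consensus: promotion of filtered variants to the
## "truncating/functionally deleterious" or "potentially pathogenic
## missense" tiers.

#' Convert a predictor rankscore to a categorical call
#'
#' Rankscores are percentile-normalized to `[0, 1]`, so a single cutoff is
#' comparable across tools; a score at or above the cutoff is called
#' pathogenic. Per-tool cutoffs may be supplied through
#' `thresholds$rankscore_cutoffs`.
#'
#' @param rankscore Numeric vector of rankscores in `[0, 1]` (NA = missing).
#' @param cutoff Inclusive pathogenicity cutoff, default 0.5.
#' @return Character vector: `"pathogenic"`, `"benign"`, or `NA` (missing).
#' @export
#' @examples
#' call_from_rankscore(c(0.9, 0.5, 0.49)) # pathogenic pathogenic benign
call_from_rankscore <- function(rankscore, cutoff = 0.5) {
  ok <- is.na(rankscore) | (rankscore >= 0 & rankscore <= 1)
  if (!all(ok)) stopf("rankscore outside [0, 1]: %s",
                      paste(rankscore[!ok], collapse = ", "))
  ifelse(is.na(rankscore), NA_character_,
         ifelse(rankscore >= cutoff, "pathogenic", "benign"))
}

#' Missense pathogenicity consensus
#'
#' A missense variant is "potentially pathogenic" when called pathogenic by
#' at least `consensus_min_calls` (12) of the `consensus_total` (15)
#' predictors, of which at least `consensus_min_conservation` (3) must be
#' conservation tools. A missing predictor output counts as not pathogenic:
#' the denominator stays fixed at 15 (an alternative
#' `consensus_denominator = "available"` mode rescales the required majority
#' to the non-missing predictors, off by default).
#'
#' @param functional_calls Named character vector over the 11 functional
#'   predictors; values `"pathogenic"`, `"benign"` or `NA`.
#' @param conservation_calls Named character vector over the 4 conservation
#'   tools, same values.
#' @param thresholds A [default_thresholds()] list.
#' @return List with `qualifies` (logical), `n_pathogenic` (total count) and
#'   `n_conservation_pathogenic`.
#' @export
#' @examples
#' f <- setNames(rep("pathogenic", 11), functional_predictors())
#' c4 <- setNames(rep("pathogenic", 4), conservation_predictors())
#' evaluate_missense_consensus(f, c4)$qualifies # TRUE
evaluate_missense_consensus <- function(functional_calls, conservation_calls,
                                        thresholds = default_thresholds()) {
  stopifnot(length(functional_calls) == length(functional_predictors()),
            length(conservation_calls) == length(conservation_predictors()))
  vals <- c(functional_calls, conservation_calls)
  bad <- setdiff(vals[!is.na(vals)], c("pathogenic", "benign", "missing"))
  if (length(bad)) stopf("unknown predictor call(s): %s",
                         paste(unique(bad), collapse = ", "))
  n_fun <- sum(functional_calls == "pathogenic", na.rm = TRUE)
  n_con <- sum(conservation_calls == "pathogenic", na.rm = TRUE)
  n_tot <- n_fun + n_con
  min_calls <- thresholds$consensus_min_calls
  if (thresholds$consensus_denominator == "available") {
    n_avail <- sum(!is.na(vals) & vals != "missing")
    min_calls <- ceiling(min_calls / thresholds$consensus_total * max(n_avail, 1))
  }
  list(qualifies = n_tot >= min_calls &&
         n_con >= thresholds$consensus_min_conservation,
       n_pathogenic = n_tot,
       n_conservation_pathogenic = n_con)
}

#' Splice impact consensus
#'
#' A splice-region variant qualifies as deleterious when at least
#' `splice_min_calls` (3) of the `splice_total` (4) splice predictors call
#' the site affected; a missing prediction counts as unaffected.
#'
#' @param calls Named character vector over the 4 splice predictors; values
#'   `"affected"`, `"unaffected"` or `NA`.
#' @param thresholds A [default_thresholds()] list.
#' @return List with `qualifies` (logical) and `n_affected`.
#' @export
evaluate_splice_consensus <- function(calls,
                                      thresholds = default_thresholds()) {
  stopifnot(length(calls) == length(splice_predictors()))
  bad <- setdiff(calls[!is.na(calls)], c("affected", "unaffected", "missing"))
  if (length(bad)) stopf("unknown splice call(s): %s",
                         paste(unique(bad), collapse = ", "))
  n <- sum(calls == "affected", na.rm = TRUE)
  list(qualifies = n >= thresholds$splice_min_calls, n_affected = n)
}

profile_from_row <- function(row, thresholds) {
  cutoff_for <- function(tool)
    thresholds$rankscore_cutoffs[[tool]] %||% thresholds$rankscore_cutoff
  get_calls <- function(tools) {
    vapply(tools, function(tool) {
      rs <- row[[paste0("rs_", tool)]]
      if (is.null(rs)) NA_character_
      else call_from_rankscore(as.numeric(rs), cutoff_for(tool))
    }, character(1))
  }
  list(functional = get_calls(functional_predictors()),
       conservation = get_calls(conservation_predictors()))
}

splice_calls_from_row <- function(row) {
  vapply(splice_predictors(), function(tool) {
    x <- row[[paste0("sp_", tool)]]
    if (is.null(x)) NA_character_ else as.character(x)
  }, character(1))
}

#' Assign pathogenicity tiers to filtered variants
#'
#' Dispatches each variant that survived the filter cascade to a tier:
#'
#' * nonsense and frameshift variants are `truncating_deleterious` outright;
#' * splice-site variants are `truncating_deleterious` when the splice
#'   consensus qualifies ([evaluate_splice_consensus()]) or when a clinical
#'   database already asserts them (likely) pathogenic;
#' * missense variants are `potentially_pathogenic_missense` when the
#'   15-predictor consensus qualifies ([evaluate_missense_consensus()]);
#'   a missense variant with no predictor profile is left unclassified with
#'   a warning;
#' * in-frame indels are unclassified unless asserted pathogenic in a
#'   clinical database (the incidental-finding route);
#' * everything else is `unclassified`.
#'
#' @param variants Filtered annotated variant table (rankscore columns
#'   `rs_<tool>`, splice call columns `sp_<tool>`, `clinvar`).
#' @param thresholds A [default_thresholds()] list.
#' @return The input table with `tier`, `basis`, `n_pathogenic`,
#'   `n_conservation_pathogenic` and `n_splice_affected` columns appended.
#' @export
assign_tier <- function(variants, thresholds = default_thresholds()) {
  check_variant_table(variants, c("consequence", "clinvar", "gene", "cdna"))
  n <- nrow(variants)
  tier <- rep("unclassified", n)
  basis <- rep(NA_character_, n)
  n_path <- rep(NA_integer_, n)
  n_cons <- rep(NA_integer_, n)
  n_spl <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    row <- variants[i, , drop = FALSE]
    cq <- row$consequence
    clv <- row$clinvar
    clv_path <- !is.na(clv) && clv %in% c("pathogenic", "likely_pathogenic")
    if (cq %in% c("nonsense", "frameshift")) {
      tier[i] <- "truncating_deleterious"
      basis[i] <- paste0("consequence=", cq)
    } else if (cq == "splice_site") {
      sc <- evaluate_splice_consensus(splice_calls_from_row(row), thresholds)
      n_spl[i] <- sc$n_affected
      if (sc$qualifies) {
        tier[i] <- "truncating_deleterious"
        basis[i] <- sprintf("splice consensus %d/%d", sc$n_affected,
                            thresholds$splice_total)
      } else if (clv_path) {
        tier[i] <- "truncating_deleterious"
        basis[i] <- sprintf("clinical assertion %s at splice site", clv)
      }
    } else if (cq == "missense") {
      p <- profile_from_row(row, thresholds)
      if (all(is.na(c(p$functional, p$conservation)))) {
        warnf("missense variant %s has no predictor profile; left unclassified",
              variant_key(row$gene, row$cdna))
      } else {
        mc <- evaluate_missense_consensus(p$functional, p$conservation,
                                          thresholds)
        n_path[i] <- mc$n_pathogenic
        n_cons[i] <- mc$n_conservation_pathogenic
        if (mc$qualifies) {
          tier[i] <- "potentially_pathogenic_missense"
          basis[i] <- sprintf("missense consensus %d/%d (%d conservation)",
                              mc$n_pathogenic, thresholds$consensus_total,
                              mc$n_conservation_pathogenic)
        }
      }
    } else if (cq == "inframe_indel" && !is.na(clv) && clv == "pathogenic") {
      tier[i] <- "truncating_deleterious"
      basis[i] <- sprintf("clinical assertion %s (in-frame indel)", clv)
    }
  }
  variants$tier <- tier
  variants$basis <- basis
  variants$n_pathogenic <- n_path
  variants$n_conservation_pathogenic <- n_cons
  variants$n_splice_affected <- n_spl
  variants
}
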