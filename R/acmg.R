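## ACMG-AMP evidence combination engine.
##
## Evidence codes are combined into a five-class verdict by the standard
## combining rules (pathogenic / likely pathogenic / benign / likely benign,
## with VUS when no rule fires or when a pathogenic-side and a benign-side
## rule fire simultaneously). The engine only combines codes; apart from the
## PS4 prevalence check it never derives codes from annotations.

#' The closed ACMG-AMP evidence vocabulary
#' @return Character vector of the 28 recognised codes.
#' @export
acmg_codes <- function() {
  c("PVS1",
    paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
    "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
}

acmg_category <- function(codes) {
  ifelse(codes == "PVS1", "PVS",
  ifelse(grepl("^PS", codes), "PS",
  ifelse(grepl("^PM", codes), "PM",
  ifelse(grepl("^PP", codes), "PP",
  ifelse(codes == "BA1", "BA",
  ifelse(grepl("^BS", codes), "BS", "BP"))))))
}

#' Construct an ACMG evidence set with provenance
#'
#' @param codes Character vector of automatically assigned evidence codes.
#' @param manual Character vector of manually added codes (e.g. PS3 from a
#'   functional study, PS4 from a case-control comparison).
#' @return Data frame of class `acmg_evidence` with `code` and `provenance`
#'   columns; duplicates collapsed (manual provenance wins).
#' @export
acmg_evidence <- function(codes = character(), manual = character()) {
  all <- c(codes, manual)
  bad <- setdiff(all, acmg_codes())
  if (length(bad)) stopf("unknown ACMG-AMP code(s): %s",
                         paste(unique(bad), collapse = ", "))
  e <- data.frame(code = c(manual, setdiff(codes, manual)),
                  provenance = c(rep("manual", length(manual)),
                                 rep("automatic", length(setdiff(codes, manual)))),
                  stringsAsFactors = FALSE)
  e <- e[!duplicated(e$code), , drop = FALSE]
  rownames(e) <- NULL
  class(e) <- c("acmg_evidence", "data.frame")
  e
}

#' Overlay manually curated evidence onto an evidence set
#'
#' Returns the union of the existing evidence and the added codes, the
#' additions carrying `manual` provenance. Idempotent: applying the same
#' overlay twice equals applying it once.
#'
#' @param evidence An [acmg_evidence()] object (or character vector of codes).
#' @param additions Character vector of codes to add.
#' @return An `acmg_evidence` object.
#' @export
apply_manual_overlay <- function(evidence, additions = character()) {
  if (is.character(evidence)) evidence <- acmg_evidence(evidence)
  bad <- setdiff(additions, acmg_codes())
  if (length(bad)) stopf("unknown ACMG-AMP code(s): %s",
                         paste(unique(bad), collapse = ", "))
  auto <- evidence$code[evidence$provenance == "automatic"]
  manual <- union(evidence$code[evidence$provenance == "manual"], additions)
  acmg_evidence(codes = auto, manual = manual)
}

## Vectorized verdict from per-category evidence counts. `ba1` is logical.
acmg_verdict_from_counts <- function(npvs, nps, npm, npp, ba1, nbs, nbp) {
  path <-
    (npvs >= 1 & (nps >= 1 | npm >= 2 | (npm >= 1 & npp >= 1) | npp >= 2)) |
    (nps >= 2) |
    (nps >= 1 & (npm >= 3 | (npm >= 2 & npp >= 2) | (npm >= 1 & npp >= 4)))
  lpath <-
    (npvs >= 1 & npm >= 1) |
    (nps >= 1 & npm >= 1) |
    (nps >= 1 & npp >= 2) |
    (npm >= 3) |
    (npm >= 2 & npp >= 2) |
    (npm >= 1 & npp >= 4)
  ben <- ba1 | nbs >= 2
  lben <- (nbs >= 1 & nbp >= 1) | nbp >= 2
  p_side <- path | lpath
  b_side <- ben | lben
  ifelse(p_side & b_side, "vus",
  ifelse(path, "pathogenic",
  ifelse(lpath, "likely_pathogenic",
  ifelse(ben, "benign",
  ifelse(lben, "likely_benign", "vus")))))
}

#' Combine ACMG-AMP evidence codes into a classification
#'
#' Implements the standard combining rules. Pathogenic requires PVS1 plus
#' supporting evidence (>=1 PS, >=2 PM, 1 PM + 1 PP, or >=2 PP), >=2 PS, or
#' 1 PS plus (>=3 PM, 2 PM + >=2 PP, or 1 PM + >=4 PP). Likely pathogenic
#' requires PVS1 + 1 PM, 1 PS + >=1 PM, 1 PS + >=2 PP, >=3 PM, 2 PM +
#' >=2 PP, or 1 PM + >=4 PP. Benign is BA1 or >=2 BS; likely benign is
#' 1 BS + 1 BP or >=2 BP. When a full pathogenic-side rule and a full
#' benign-side rule fire simultaneously the verdict is VUS (conflict); a
#' lone benign-supporting code that completes no rule (e.g. BP1 next to
#' PS4 + PM1 + PM2 + PP3) does not block a likely-pathogenic call.
#'
#' @param evidence An [acmg_evidence()] object or character vector of codes.
#' @return List with `verdict` (one of pathogenic, likely_pathogenic, vus,
#'   likely_benign, benign) and `fired_rule` (`"pathogenic_side"`,
#'   `"benign_side"`, `"conflict"` or `"none"`).
#' @export
#' @examples
#' combine_criteria(c("PM2", "BP1"))$verdict                  # "vus"
#' combine_criteria(c("PS3", "PM2", "PP3", "PP5"))$verdict    # "likely_pathogenic"
combine_criteria <- function(evidence) {
  codes <- if (is.character(evidence)) evidence else evidence$code
  bad <- setdiff(codes, acmg_codes())
  if (length(bad)) stopf("unknown ACMG-AMP code(s): %s",
                         paste(unique(bad), collapse = ", "))
  codes <- unique(codes)
  cat <- acmg_category(codes)
  verdict <- acmg_verdict_from_counts(
    npvs = sum(cat == "PVS"), nps = sum(cat == "PS"),
    npm = sum(cat == "PM"), npp = sum(cat == "PP"),
    ba1 = any(cat == "BA"), nbs = sum(cat == "BS"), nbp = sum(cat == "BP"))
  fired <- switch(verdict,
    pathogenic = , likely_pathogenic = "pathogenic_side",
    benign = , likely_benign = "benign_side",
    vus = {
      p <- acmg_verdict_from_counts(sum(cat == "PVS"), sum(cat == "PS"),
                                    sum(cat == "PM"), sum(cat == "PP"),
                                    FALSE, 0, 0)
      b <- acmg_verdict_from_counts(0, 0, 0, 0, any(cat == "BA"),
                                    sum(cat == "BS"), sum(cat == "BP"))
      if (p != "vus" && b != "vus") "conflict" else "none"
    })
  list(verdict = verdict, fired_rule = fired)
}

#' PS4: variant prevalence significantly increased in affected individuals
#'
#' The PS4 evidence code applies when the prevalence of the variant among
#' cases is significantly higher than among controls. Significance is a
#' two-sided Fisher exact test on the carrier 2x2 table at level `alpha`,
#' combined with the requirement that the case carrier fraction actually
#' exceeds the control fraction.
#'
#' @param case_carriers,n_cases Carrier count and size of the case series.
#' @param control_carriers,n_controls Carrier count and size of the control
#'   panel.
#' @param alpha Significance level (default 0.05).
#' @return Logical: whether PS4 is supported.
#' @export
#' @examples
#' evaluate_ps4(3, 121, 0, 710) # TRUE: ~2.5% of cases vs 0/710 controls
evaluate_ps4 <- function(case_carriers, n_cases, control_carriers, n_controls,
                         alpha = 0.05) {
  if (n_cases <= 0 || n_controls <= 0) stopf("group sizes must be positive")
  stopifnot(case_carriers >= 0, control_carriers >= 0,
            case_carriers <= n_cases, control_carriers <= n_controls)
  p <- fisher_exact(build_carrier_table(case_carriers, n_cases,
                                        control_carriers, n_controls))
  enriched <- case_carriers / n_cases > control_carriers / n_controls
  p < alpha && enriched
}
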