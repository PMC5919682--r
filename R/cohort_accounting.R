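## Carrier assembly, gene attribution and cohort accounting.

QUALIFYING_TIERS <- c("truncating_deleterious", "potentially_pathogenic_missense")

#' Assemble carrier assignments, applying the exclusion rules
#'
#' A patient is a carrier when they hold at least one variant in a
#' qualifying tier after two exclusions: (i) a missense variant in a
#' mismatch-repair-type gene whose matched tumor immunohistochemistry shows
#' retained protein expression (the variant is then unlikely to drive the
#' tumor), and (ii) variants flagged as incidental findings (clinically
#' reportable but unrelated to the phenotype under study). A patient
#' remains a carrier if another qualifying variant survives the exclusions.
#'
#' @param planted Data frame with one row per patient-variant pair; columns
#'   `patient_id`, `key` ([variant_key()]), `gene`, `consequence`, `tier`
#'   (and optionally `verdict`).
#' @param ihc Data frame of tumor immunohistochemistry results:
#'   `patient_id`, `gene`, `expression_retained` (logical). An IHC result
#'   for a gene in which the patient carries no variant is ignored with a
#'   warning.
#' @param incidental Data frame of incidental findings: `patient_id`, `key`.
#' @return List with `assignments` (the input rows plus `qualifying`,
#'   `excluded`, `exclusion_reason`) and `carriers` (character vector of
#'   carrier patient ids).
#' @export
assemble_carriers <- function(planted, ihc = NULL, incidental = NULL) {
  stopifnot(all(c("patient_id", "key", "gene", "consequence", "tier")
                %in% names(planted)))
  n <- nrow(planted)
  excluded <- rep(FALSE, n)
  reason <- rep(NA_character_, n)

  if (!is.null(ihc) && nrow(ihc)) {
    for (i in seq_len(nrow(ihc))) {
      if (!isTRUE(ihc$expression_retained[i])) next
      hit <- planted$patient_id == ihc$patient_id[i] &
        planted$gene == ihc$gene[i] & planted$consequence == "missense"
      if (!any(planted$patient_id == ihc$patient_id[i] &
                 planted$gene == ihc$gene[i])) {
        warnf("IHC result for %s in %s matches no variant; ignored",
              ihc$gene[i], ihc$patient_id[i])
        next
      }
      excluded[hit] <- TRUE
      reason[hit] <- "ihc_retained_expression"
    }
  }
  if (!is.null(incidental) && nrow(incidental)) {
    hit <- paste(planted$patient_id, planted$key) %in%
      paste(incidental$patient_id, incidental$key)
    excluded[hit] <- TRUE
    reason[hit] <- "incidental_finding"
  }

  planted$qualifying <- planted$tier %in% QUALIFYING_TIERS & !excluded
  planted$excluded <- excluded
  planted$exclusion_reason <- reason
  carriers <- sort(unique(planted$patient_id[planted$qualifying]))
  list(assignments = planted, carriers = carriers)
}

#' Attribute one candidate predisposition gene per carrier
#'
#' When a carrier holds several qualifying variants, a truncating/
#' functionally deleterious variant takes precedence over a co-occurring
#' potentially pathogenic missense variant. Remaining ties are broken by
#' the smaller case-control p-value (when supplied) and then
#' alphabetically.
#'
#' @param assignments Assignment table from [assemble_carriers()].
#' @param assoc Optional data frame `key`, `p` of case-control p-values
#'   used as tie-breaker.
#' @return Data frame `patient_id`, `attributed_gene`, `attributed_key`,
#'   one row per carrier.
#' @export
attribute_gene <- function(assignments, assoc = NULL) {
  q <- assignments[assignments$qualifying, , drop = FALSE]
  if (!nrow(q)) return(data.frame(patient_id = character(),
                                  attributed_gene = character(),
                                  attributed_key = character()))
  pick <- function(rows) {
    trunc <- rows[rows$tier == "truncating_deleterious", , drop = FALSE]
    cand <- if (nrow(trunc)) trunc else rows
    if (nrow(cand) > 1) {
      p <- if (!is.null(assoc)) assoc$p[match(cand$key, assoc$key)]
           else rep(NA_real_, nrow(cand))
      p[is.na(p)] <- Inf
      cand <- cand[order(p, cand$gene), , drop = FALSE]
    }
    cand[1, c("gene", "key")]
  }
  out <- do.call(rbind, lapply(split(q, q$patient_id), pick))
  data.frame(patient_id = names(split(q, q$patient_id)),
             attributed_gene = out$gene, attributed_key = out$key,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cohort summary: carrier counts and fractions
#'
#' Computes the cohort accounting with the study's denominators: the whole
#' cohort, the familial/hereditary group (A), the early-onset-or-other-
#' cancer group (B), the early-onset set (diagnosis at or before 55) and
#' the carrier set. Per-gene counts are reported both attributed (one gene
#' per carrier, truncating precedence) and raw (every carrier of a
#' qualifying variant in the gene).
#'
#' @param flags Criteria table from [classify_criteria()].
#' @param assignments Assignment table from [assemble_carriers()].
#' @param assoc Optional association table passed to [attribute_gene()].
#' @return Object of class `cohort_summary`: counts, per-gene tables and
#'   percentages (one decimal, ties away from zero).
#' @export
summarize_cohort <- function(flags, assignments, assoc = NULL) {
  carriers <- sort(unique(assignments$patient_id[assignments$qualifying]))
  n_pat <- nrow(flags)
  n_car <- length(carriers)
  fl <- flags[match(carriers, flags$patient_id), , drop = FALSE]

  attributed <- attribute_gene(assignments, assoc)
  per_gene_attr <- table(attributed$attributed_gene)
  q <- assignments[assignments$qualifying, , drop = FALSE]
  per_gene_raw <- table(unique(q[, c("patient_id", "gene")])$gene)
  trunc_genes <- sort(unique(q$gene[q$tier == "truncating_deleterious"]))

  n_A <- sum(flags$group_A)
  n_B <- sum(flags$group_B)
  n_early <- sum(flags$early_onset)
  car_A <- sum(fl$group_A, na.rm = TRUE)
  car_B <- sum(fl$group_B, na.rm = TRUE)
  car_early <- sum(fl$early_onset, na.rm = TRUE)

  gene_tbl <- function(tb, denom) {
    data.frame(gene = names(tb), n = as.integer(tb),
               pct_of_cohort = vapply(as.integer(tb), pct, 0, denom = denom),
               stringsAsFactors = FALSE, row.names = NULL)
  }

  atm_chek2 <- sum(attributed$attributed_gene %in% c("ATM", "CHEK2"))
  trunc_q <- q[q$tier == "truncating_deleterious", , drop = FALSE]
  atm_trunc_A <- length(unique(trunc_q$patient_id[
    trunc_q$gene == "ATM" &
      trunc_q$patient_id %in% flags$patient_id[flags$group_A]]))

  out <- list(
    n_patients = n_pat,
    n_carriers = n_car,
    carriers = carriers,
    pct_carriers = pct(n_car, n_pat),
    n_group_A = n_A, n_group_B = n_B, n_early_onset = n_early,
    n_carriers_A = car_A, n_carriers_B = car_B,
    n_early_onset_carriers = car_early,
    pct_carriers_A_of_carriers = pct(car_A, n_car),
    pct_carriers_B_of_carriers = pct(car_B, n_car),
    pct_carriers_of_group_A = pct(car_A, n_A),
    pct_carriers_of_group_B = pct(car_B, n_B),
    pct_early_carriers_of_carriers = pct(car_early, n_car),
    pct_early_carriers_of_early = pct(car_early, n_early),
    genes_truncating = trunc_genes,
    n_genes_truncating = length(trunc_genes),
    per_gene_attributed = gene_tbl(per_gene_attr, n_pat),
    per_gene_raw = gene_tbl(per_gene_raw, n_pat),
    attributed = attributed,
    pct_atm_chek2_of_carriers = pct(atm_chek2, n_car),
    pct_atm_truncating_of_group_A = pct(atm_trunc_A, n_A)
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients: %d carriers (%.1f%%)\n",
              x$n_patients, x$n_carriers, x$pct_carriers))
  cat(sprintf("  group A: %d patients, %d carriers (%.1f%% of carriers, %.1f%% of group)\n",
              x$n_group_A, x$n_carriers_A, x$pct_carriers_A_of_carriers,
              x$pct_carriers_of_group_A))
  cat(sprintf("  group B: %d patients, %d carriers (%.1f%% of carriers, %.1f%% of group)\n",
              x$n_group_B, x$n_carriers_B, x$pct_carriers_B_of_carriers,
              x$pct_carriers_of_group_B))
  cat(sprintf("  early onset (<=55): %d patients, %d carriers (%.1f%% of carriers)\n",
              x$n_early_onset, x$n_early_onset_carriers,
              x$pct_early_carriers_of_carriers))
  cat(sprintf("  genes with truncating/deleterious variants: %d (%s)\n",
              x$n_genes_truncating, paste(x$genes_truncating, collapse = ", ")))
  cat("  attributed genes:\n")
  g <- x$per_gene_attributed[order(-x$per_gene_attributed$n,
                                   x$per_gene_attributed$gene), ]
  for (i in seq_len(nrow(g)))
    cat(sprintf("    %-8s %2d (%.1f%% of cohort)\n",
                g$gene[i], g$n[i], g$pct_of_cohort[i]))
  invisible(x)
}
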