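## End-to-end prioritization pipeline.

obj_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' Run the full prioritization pipeline on a cohort
#'
#' Orchestrates the stages in order: filter cascade on the distinct
#' annotated variants, tier assignment by predictor consensus, ACMG-AMP
#' evidence combination (automatic codes, then the manual overlay), PS4
#' prevalence checks and carrier-level Fisher tests against the healthy
#' control panel, carrier assembly with the IHC and incidental-finding
#' exclusions, family-history criteria classification, and the cohort
#' summary. Deterministic: rerunning with the same cohort and thresholds
#' reproduces identical outputs and manifest hash.
#'
#' @param cohort A `prca_cohort` ([load_fixture_cohort()],
#'   [simulate_cohort()]).
#' @param thresholds A [default_thresholds()] list.
#' @param out_dir Optional directory; when given, all stage tables, the
#'   summary JSON and the run manifest are written there.
#' @return List of class `prca_run`: `summary` ([summarize_cohort()]
#'   object), `kept`, `audit`, `tiers`, `verdicts`, `assignments`,
#'   `flags`, `assoc` and `manifest`.
#' @export
#' @examples
#' run <- run_pipeline(load_fixture_cohort())
#' run$summary$n_carriers # 18
run_pipeline <- function(cohort, thresholds = default_thresholds(),
                         out_dir = NULL) {
  stopifnot(inherits(cohort, "prca_cohort"))
  validate_thresholds(thresholds)

  cascade <- run_cascade(cohort$variants, thresholds)
  tiers <- assign_tier(cascade$kept, thresholds)

  n_cases <- nrow(cohort$patients)
  case_carriers <- vapply(tiers$key, function(k)
    length(unique(cohort$planted$patient_id[cohort$planted$key == k])), 0L)

  healthy <- cohort$controls[cohort$controls$group == "healthy", ,
                             drop = FALSE]
  hc <- healthy$carriers[match(tiers$key, healthy$key)]
  hn <- if (nrow(healthy)) healthy$n[1] else NA_integer_

  assoc <- data.frame(key = tiers$key, case_carriers = case_carriers,
                      n_cases = n_cases, control_carriers = hc,
                      n_controls = hn, p = NA_real_,
                      stringsAsFactors = FALSE)
  ok <- !is.na(hc) & !is.na(hn)
  assoc$p[ok] <- vapply(which(ok), function(i)
    fisher_exact(build_carrier_table(case_carriers[i], n_cases, hc[i], hn)),
    0)

  ev <- cohort$evidence
  verdicts <- data.frame(key = tiers$key, stringsAsFactors = FALSE)
  verdicts$codes_auto <- ev$codes_auto[match(tiers$key, ev$key)]
  verdicts$codes_manual <- ev$codes_manual[match(tiers$key, ev$key)]
  split_codes <- function(x)
    if (is.na(x) || x == "") character() else strsplit(x, ";")[[1]]
  v_auto <- v_final <- fired <- rep(NA_character_, nrow(verdicts))
  for (i in seq_len(nrow(verdicts))) {
    auto <- split_codes(verdicts$codes_auto[i])
    man <- split_codes(verdicts$codes_manual[i])
    if (!length(auto) && !length(man)) next  # no evidence: left undetermined
    v_auto[i] <- combine_criteria(acmg_evidence(auto))$verdict
    res <- combine_criteria(apply_manual_overlay(acmg_evidence(auto), man))
    v_final[i] <- res$verdict
    fired[i] <- res$fired_rule
  }
  verdicts$verdict_auto <- v_auto
  verdicts$verdict_final <- v_final
  verdicts$fired_rule <- fired
  verdicts$ps4_supported <- NA
  verdicts$ps4_supported[ok] <- vapply(which(ok), function(i)
    evaluate_ps4(case_carriers[i], n_cases, hc[i], hn,
                 alpha = thresholds$alpha), TRUE)

  planted <- cohort$planted
  planted$tier <- tiers$tier[match(planted$key, tiers$key)]
  planted$tier[is.na(planted$tier)] <- "filtered_out"
  planted$verdict <- verdicts$verdict_final[match(planted$key, verdicts$key)]
  carriers <- assemble_carriers(planted, cohort$ihc, cohort$incidental)

  flags <- classify_criteria(cohort$patients, cohort$relatives,
                             cohort$second_primaries)
  summary <- summarize_cohort(flags, carriers$assignments,
                              assoc[!is.na(assoc$p), c("key", "p")])

  manifest <- list(
    config_hash = obj_md5(unclass(thresholds)),
    input_hash = obj_md5(list(cohort$patients, cohort$planted,
                              cohort$controls)),
    n_variants_in = nrow(cohort$variants),
    n_variants_kept = nrow(cascade$kept),
    n_removed_by_rule = as.list(cascade$n_removed_by_rule),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest$run_hash <- obj_md5(manifest[c("config_hash", "input_hash")])

  out <- structure(list(summary = summary, kept = cascade$kept,
                        audit = cascade$audit, tiers = tiers,
                        verdicts = verdicts,
                        assignments = carriers$assignments,
                        flags = flags, assoc = assoc,
                        manifest = manifest),
                   class = "prca_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_dot(cascade$kept, file.path(out_dir, "kept.tsv"))
    write_tsv_dot(cascade$audit, file.path(out_dir, "audit.tsv"))
    write_tsv_dot(tiers, file.path(out_dir, "tiers.tsv"))
    write_tsv_dot(verdicts, file.path(out_dir, "verdicts.tsv"))
    write_tsv_dot(carriers$assignments, file.path(out_dir, "assignments.tsv"))
    write_tsv_dot(flags, file.path(out_dir, "criteria.tsv"))
    s <- unclass(summary)
    jsonlite::write_json(
      s[!vapply(s, is.data.frame, TRUE)],
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.prca_run <- function(x, ...) {
  cat(sprintf("prca_run: %d variants in, %d kept, %d carriers\n",
              x$manifest$n_variants_in, x$manifest$n_variants_kept,
              x$summary$n_carriers))
  print(x$summary)
  invisible(x)
}
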