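## Packaged fixture cohort.
##
## The 121-patient study cohort is reconstructed from the published variant
## tables: the 19 carrier patients hold the tabulated variants with their
## printed criteria flags, and the remaining 102 patients are deterministic
## fillers whose family structures are chosen so that the cohort marginals
## match the printed composition (45 group A, 86 group B, 10 in both, 64
## early-onset). Indel REF/ALT alleles and the position of the incidental
## in-frame deletion are synthetic placeholders (the source tables print
## cDNA changes, not VCF alleles); downstream logic keys on gene, cDNA
## change and consequence class, never on the literal allele strings.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "prcapanel")
  if (p == "") stopf("fixture file '%s' not found in package", file)
  p
}

read_fixture_tsv <- function(file, required) {
  p <- fixture_path(file)
  x <- tryCatch(read_tsv_dot(p),
                error = function(e) stopf("fixture file '%s' unreadable: %s",
                                          file, conditionMessage(e)))
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stopf("fixture file '%s' corrupt: missing column(s) %s", file,
          paste(missing_cols, collapse = ", "))
  x
}

rel <- function(degree, cancer_type, age) {
  data.frame(degree = degree, cancer_type = cancer_type, age_at_dx = age,
             stringsAsFactors = FALSE)
}

## Family structures for the 19 carrier patients. Pedigree details beyond
## the published narratives are synthetic, constructed so that
## classify_criteria() reproduces the printed criteria flags exactly.
carrier_personas <- function() {
  list(
    ## five brothers with PrCa, twins diagnosed before 61
    HPC177 = list(age = 62, second = character(),
                  rel = rel(rep("first", 5), rep("prostate", 5),
                            c(59, 59, 66, 67, 68))),
    ## three breast cancers in the family, two at early age
    HPC395 = list(age = 60, second = character(),
                  rel = rel(c("first", "second", "second"),
                            rep("breast", 3), c(45, 50, 62))),
    ## five relatives with cancer incl. bilateral BrCa and early abdominal
    HPC447 = list(age = 58, second = character(),
                  rel = rel(c("first", "second", "second", "second", "first"),
                            c("bilateral breast", "abdominal", "colon",
                              "gastric", "lung"),
                            c(60, 48, 65, 70, 72))),
    HPC150 = list(age = 63, second = character(),
                  rel = rel(c("first", "first"), rep("prostate", 2),
                            c(58, 64))),
    ## bladder cancer as second primary; early-onset cancers in relatives
    HPC186 = list(age = 50, second = "bladder",
                  rel = rel(c("first", "second", "second"),
                            c("kidney", "sarcoma", "lung"), c(52, 54, 58))),
    ## urothelial cancer four years before the PrCa diagnosis
    HPC421 = list(age = 54, second = "urothelial", rel = rel(character(), character(), numeric())),
    HPC455 = list(age = 62, second = "multiple myeloma",
                  rel = rel(character(), character(), numeric())),
    HPC238 = list(age = 54, second = character(),
                  rel = rel(rep("first", 3), rep("prostate", 3),
                            c(60, 62, 64))),
    HPC167 = list(age = 65, second = "bladder",
                  rel = rel(character(), character(), numeric())),
    HPC400 = list(age = 52, second = character(),
                  rel = rel(c("first", "second", "second"),
                            c("lung", "kidney", "pancreatic"), c(54, 56, 58))),
    HPC20  = list(age = 53, second = character(),
                  rel = rel(c("first", "second", "first"),
                            c("sarcoma", "lung", "kidney"), c(50, 55, 60))),
    HPC3   = list(age = 58, second = character(),
                  rel = rel(c("first", "second"), rep("prostate", 2),
                            c(64, 70))),
    HPC332 = list(age = 53, second = character(),
                  rel = rel(c("second", "second", "first"),
                            c("prostate", "prostate", "colon"),
                            c(60, 64, 52))),
    HPC118 = list(age = 66, second = character(),
                  rel = rel(c("first", "first"), rep("prostate", 2),
                            c(58, 63))),
    ## three affected relatives diagnosed at or before 65, one early-onset
    HPC188 = list(age = 63, second = character(),
                  rel = rel(rep("first", 3), rep("prostate", 3),
                            c(54, 62, 65))),
    ## heavy family history of cancer with several early diagnoses
    HPC289 = list(age = 50, second = character(),
                  rel = rel(c("first", "second", "second"),
                            c("breast", "colon", "gastric"), c(42, 50, 55))),
    HPC89  = list(age = 64, second = "bladder",
                  rel = rel(character(), character(), numeric())),
    HPC371 = list(age = 62, second = character(),
                  rel = rel("second", "male breast", 58)),
    HPC394 = list(age = 62, second = "colon",
                  rel = rel(rep("first", 3), rep("prostate", 3),
                            c(57, 63, 66)))
  )
}

## Deterministic filler patients completing the printed marginals:
## 45 group A, 86 group B, 10 dual, 64 early-onset over the 121 patients.
filler_personas <- function() {
  mk <- function(n, prefix, age, second, relatives, criteria) {
    lapply(seq_len(n), function(i)
      list(id = sprintf("%s%02d", prefix, i), age = age, second = second,
           rel = relatives, criteria = criteria))
  }
  c(
    mk(29, "HPCS-A", 63, character(),
       rel(c("first", "first"), rep("prostate", 2), c(58, 64)), "A2"),
    mk(49, "HPCS-B", 50, character(),
       rel(c("first", "second", "second"),
           c("lung", "kidney", "pancreatic"), c(54, 57, 59)), "B1"),
    mk(16, "HPCS-C", 60, "bladder",
       rel(character(), character(), numeric()), "B2"),
    mk(8, "HPCS-D", 53, character(),
       rel(c("second", "second", "first"),
           c("prostate", "prostate", "colon"), c(60, 64, 52)), "A3,B1")
  )
}

## Deterministic annotation profile for the planted fixture variants.
fixture_annotation <- function(vt) {
  n <- nrow(vt)
  fun <- functional_predictors()
  con <- conservation_predictors()
  ann <- data.frame(
    chrom = as.character(vt$chrom), pos = vt$pos, ref = vt$ref, alt = vt$alt,
    gene = vt$gene, transcript = vt$transcript, cdna = vt$cdna,
    protein = vt$protein, consequence = vt$consequence,
    intron_distance = vt$intron_distance,
    depth = 60 + (seq_len(n) * 17) %% 80,
    vaf = round(0.44 + ((seq_len(n) * 7) %% 11) / 100, 2),
    maf_1000g = NA_real_, maf_evs = NA_real_, maf_exac = NA_real_,
    inhouse_fraction = NA_real_,
    clinvar = "absent", bic = NA_character_, lovd = NA_character_,
    stringsAsFactors = FALSE
  )
  for (tool in c(fun, con)) ann[[paste0("rs_", tool)]] <- NA_real_
  for (tool in splice_predictors()) ann[[paste0("sp_", tool)]] <- NA_character_

  key <- variant_key(ann$gene, ann$cdna)

  ## population frequencies: printed database sightings only
  ann$maf_exac[key == "FANCD2:c.2494+2T>C"] <- 8e-06   # one ExAC carrier
  ann$maf_evs[key == "CEP57:c.791C>G"] <- 8e-05        # one EVS carrier
  ann$maf_exac[key == "ATM:c.1595G>A"] <- 4e-04
  ann$maf_exac[key == "ATM:c.8560C>T"] <- 1e-04
  ann$maf_exac[key == "CHEK2:c.349A>G"] <- 3e-04
  ann$maf_exac[key == "CHEK2:c.695G>T"] <- 5e-05
  ann$maf_exac[key == "MSH2:c.1571G>A"] <- 1e-04
  ann$maf_exac[key == "MSH6:c.1729C>T"] <- 1e-04

  ## clinical assertions
  ann$clinvar[key == "CHEK2:c.593-1G>T"] <- "likely_pathogenic"
  ann$clinvar[key == "CHEK2:c.349A>G"] <- "likely_pathogenic"
  ann$clinvar[key == "MSH2:c.1571G>A"] <- "vus"
  ann$clinvar[key == "MSH6:c.1729C>T"] <- "vus"
  ann$clinvar[key == "MSH6:c.3846_3860del"] <- "pathogenic"

  ## predictor consensus profiles: every tabulated missense variant
  ## qualified under the 12-of-15 rule. Default profile: 10/11 functional
  ## plus 3/4 conservation pathogenic (FATHMM and SiPhy discordant).
  mis <- ann$consequence == "missense"
  for (tool in setdiff(fun, "FATHMM"))
    ann[[paste0("rs_", tool)]][mis] <- 0.82
  ann$rs_FATHMM[mis] <- 0.22
  for (tool in setdiff(con, "SiPhy"))
    ann[[paste0("rs_", tool)]][mis] <- 0.78
  ann$rs_SiPhy[mis] <- 0.30
  full <- mis & key == "CHEK2:c.349A>G"   # unanimous profile
  for (tool in c(fun, con)) ann[[paste0("rs_", tool)]][full] <- 0.90

  ## splice predictions: both splice variants called affected by 3 of 4
  spl <- ann$consequence == "splice_site"
  ann$sp_HSF3[spl] <- "affected"
  ann$sp_MaxEntScan[spl] <- "affected"
  ann$sp_NNSPLICE[spl] <- "affected"
  ann$sp_NetGene2[spl] <- "unaffected"

  ann
}

#' Load the packaged fixture cohort
#'
#' Reconstructs the 121-patient study cohort from the packaged variant
#' tables: 19 carrier patients holding the tabulated truncating/deleterious
#' and potentially pathogenic missense variants (plus one incidental
#' in-frame deletion), their printed fulfilled-criteria flags, tumor
#' immunohistochemistry flags for the mismatch-repair variants, control
#' panel carrier counts (710 healthy controls, 504 non-prostate cancer
#' cases), and 102 deterministic filler patients completing the printed
#' cohort marginals (45 group A, 86 group B, 10 dual, 64 early-onset).
#'
#' @return Object of class `prca_cohort`: a list with `patients`,
#'   `relatives`, `second_primaries`, `ihc`, `incidental`, `planted` (one
#'   annotated row per patient-variant pair), `variants` (distinct
#'   annotated variants), `evidence` (ACMG codes per variant) and
#'   `controls`.
#' @export
#' @examples
#' cohort <- load_fixture_cohort()
#' nrow(cohort$patients) # 121
load_fixture_cohort <- function() {
  tr <- read_fixture_tsv("truncating_variants.tsv",
                         c("gene", "chrom", "pos", "ref", "alt", "cdna",
                           "patient_id", "criteria", "consequence"))
  ms <- read_fixture_tsv("missense_variants.tsv",
                         c("gene", "chrom", "pos", "ref", "alt", "cdna",
                           "patient_id", "criteria", "acmg_auto",
                           "acmg_manual", "ihc_retained"))
  inc <- read_fixture_tsv("incidental_variants.tsv",
                          c("gene", "chrom", "pos", "ref", "alt", "cdna",
                            "patient_id", "consequence"))
  controls <- read_fixture_tsv("control_counts.tsv",
                               c("key", "group", "n", "carriers"))

  ms$consequence <- "missense"
  ms$intron_distance <- 0
  inc$criteria <- NULL

  shared <- c("gene", "chrom", "pos", "ref", "alt", "transcript", "cdna",
              "protein", "dbsnp", "patient_id", "consequence",
              "intron_distance")
  all_rows <- rbind(tr[, shared], ms[, shared], inc[, shared])
  all_rows$key <- variant_key(all_rows$gene, all_rows$cdna)

  ## distinct variants with deterministic annotation
  vt <- all_rows[!duplicated(all_rows$key), , drop = FALSE]
  ann <- fixture_annotation(vt)
  ann$key <- variant_key(ann$gene, ann$cdna)
  carriers_per_key <- table(all_rows$key)
  ann$inhouse_fraction <- as.numeric(carriers_per_key[ann$key]) / 121

  planted <- merge(all_rows[, c("patient_id", "key")], ann, by = "key",
                   sort = FALSE)

  ## ACMG evidence per missense variant (N/D rows carry no codes)
  ev <- ms[!duplicated(variant_key(ms$gene, ms$cdna)),
           c("gene", "cdna", "acmg_auto", "acmg_manual")]
  evidence <- data.frame(
    key = variant_key(ev$gene, ev$cdna),
    codes_auto = ev$acmg_auto,
    codes_manual = ev$acmg_manual,
    stringsAsFactors = FALSE
  )

  ## patients: tabulated carriers + deterministic fillers
  personas <- carrier_personas()
  crit <- c(tapply(tr$criteria, tr$patient_id, function(x) x[1]),
            tapply(ms$criteria, ms$patient_id, function(x) x[1]))
  crit <- crit[!duplicated(names(crit))]
  fillers <- filler_personas()

  pat <- data.frame(
    patient_id = c(names(personas), vapply(fillers, `[[`, "", "id")),
    age_at_dx = c(vapply(personas, `[[`, 0, "age"),
                  vapply(fillers, `[[`, 0, "age")),
    criteria_printed = c(as.character(crit[names(personas)]),
                         vapply(fillers, `[[`, "", "criteria")),
    stringsAsFactors = FALSE, row.names = NULL
  )

  rel_of <- function(id, p) {
    r <- p$rel
    if (nrow(r)) r$patient_id <- id
    r
  }
  relatives <- do.call(rbind, c(
    lapply(names(personas), function(id) rel_of(id, personas[[id]])),
    lapply(fillers, function(f) rel_of(f$id, f))))
  relatives <- relatives[, c("patient_id", "degree", "cancer_type",
                             "age_at_dx")]

  sp_of <- function(id, second) {
    if (!length(second) || all(second == "")) return(NULL)
    data.frame(patient_id = id, cancer_type = second,
               stringsAsFactors = FALSE)
  }
  second_primaries <- do.call(rbind, c(
    lapply(names(personas), function(id) sp_of(id, personas[[id]]$second)),
    lapply(fillers, function(f) sp_of(f$id, f$second))))

  ihc_rows <- ms[!is.na(ms$ihc_retained) & ms$ihc_retained == "yes",
                 c("patient_id", "gene")]
  ihc <- rbind(
    data.frame(patient_id = ihc_rows$patient_id, gene = ihc_rows$gene,
               expression_retained = TRUE, stringsAsFactors = FALSE),
    data.frame(patient_id = inc$patient_id, gene = inc$gene,
               expression_retained = TRUE, stringsAsFactors = FALSE))

  incidental <- data.frame(patient_id = inc$patient_id,
                           key = variant_key(inc$gene, inc$cdna),
                           stringsAsFactors = FALSE)

  controls$carriers <- suppressWarnings(as.integer(controls$carriers))

  structure(list(patients = pat, relatives = relatives,
                 second_primaries = second_primaries,
                 ihc = ihc, incidental = incidental,
                 planted = planted, variants = ann,
                 evidence = evidence, controls = controls),
            class = "prca_cohort")
}

#' @export
print.prca_cohort <- function(x, ...) {
  cat(sprintf("prca_cohort: %d patients, %d planted variant calls (%d distinct variants)\n",
              nrow(x$patients), nrow(x$planted), nrow(x$variants)))
  cat(sprintf("  control groups: %s\n",
              paste(unique(x$controls$group), collapse = ", ")))
  invisible(x)
}
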