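## Synthetic cohort and predictor-matrix simulation.

## GRCh37 anchor coordinates for the panel genes used when planting
## synthetic variants (approximate gene starts; positions are placeholders,
## downstream logic never depends on them).
panel_gene_coords <- function() {
  data.frame(
    gene = c("ATM", "BLM", "BRCA1", "BRCA2", "BRIP1", "CDH1", "CHEK2",
             "MLH1", "MSH2", "MSH6", "NBN", "PALB2", "PMS2", "PTEN",
             "RAD51C", "RAD51D", "STK11", "TP53", "FANCD2", "FANCI",
             "CEP57", "RECQL4"),
    chrom = c("11", "15", "17", "13", "17", "16", "22", "3", "2", "2", "8",
              "16", "7", "10", "17", "17", "19", "17", "3", "15", "11", "8"),
    base = c(108093000L, 91260000L, 41196000L, 32889000L, 59760000L,
             68771000L, 29083000L, 37034000L, 47630000L, 48010000L,
             90945000L, 23614000L, 6012000L, 89623000L, 56769000L,
             33426000L, 1205000L, 7571000L, 10068000L, 89787000L,
             95523000L, 145736000L),
    stringsAsFactors = FALSE
  )
}

#' Simulation parameters
#'
#' @param n_patients Number of index cases (>= 1).
#' @param per_gene_carrier_freq Named numeric vector: probability that a
#'   patient carries a (recurrent) qualifying variant in each gene.
#' @param criteria_prevalence Named weights over the six eligibility
#'   clauses used to draw each patient's family-history persona; defaults
#'   approximate the study composition (about 37% group A, 63% group B).
#' @param predictor_noise Probability that any single predictor call of a
#'   planted variant is flipped.
#' @param n_controls Size of the simulated healthy control panel.
#' @param seed Integer seed; a fixed seed gives byte-identical cohorts.
#' @return List of class `simulation_params`.
#' @export
simulation_params <- function(n_patients = 121,
                              per_gene_carrier_freq = c(ATM = 0.05),
                              criteria_prevalence = c(A1 = 0.04, A2 = 0.22,
                                                      A3 = 0.11, B1 = 0.29,
                                                      B2 = 0.13, B3 = 0.21),
                              predictor_noise = 0,
                              n_controls = 710,
                              seed = 1L) {
  stopifnot(n_patients >= 1,
            all(per_gene_carrier_freq >= 0 & per_gene_carrier_freq <= 1),
            all(criteria_prevalence >= 0),
            predictor_noise >= 0 && predictor_noise <= 1,
            n_controls >= 0)
  if (is.null(names(per_gene_carrier_freq)) && length(per_gene_carrier_freq))
    stopf("per_gene_carrier_freq must be named by gene")
  if (!all(names(criteria_prevalence) %in% c("A1", "A2", "A3", "B1", "B2", "B3")))
    stopf("criteria_prevalence names must be among A1..B3")
  structure(list(n_patients = as.integer(n_patients),
                 per_gene_carrier_freq = per_gene_carrier_freq,
                 criteria_prevalence = criteria_prevalence,
                 predictor_noise = predictor_noise,
                 n_controls = as.integer(n_controls),
                 seed = as.integer(seed)),
            class = "simulation_params")
}

## single-clause family-history templates; index-age jitter ranges are
## chosen so that exactly the template's clause fires
persona_templates <- function() {
  list(
    A1 = list(ages = 61:68, second = FALSE,
              rel = rel(rep("first", 3), rep("prostate", 3), c(70, 72, 74))),
    A2 = list(ages = 61:68, second = FALSE,
              rel = rel(c("first", "first"), rep("prostate", 2), c(58, 64))),
    A3 = list(ages = 56:60, second = FALSE,
              rel = rel(c("first", "second"), rep("prostate", 2), c(64, 70))),
    B1 = list(ages = 46:55, second = FALSE,
              rel = rel(c("first", "second", "second"),
                        c("lung", "kidney", "pancreatic"), c(52, 55, 58))),
    B2 = list(ages = 50:70, second = TRUE,
              rel = rel(character(), character(), numeric())),
    B3 = list(ages = 56:70, second = FALSE,
              rel = rel("second", "male breast", 58))
  )
}

qualifying_calls <- function() {
  fun <- setNames(rep("pathogenic", 11), functional_predictors())
  fun["FATHMM"] <- "benign"
  con <- setNames(rep("pathogenic", 4), conservation_predictors())
  con["SiPhy"] <- "benign"
  list(functional = fun, conservation = con)  # 13/15, 3 conservation
}

rankscore_for_call <- function(calls) {
  ifelse(calls == "pathogenic", 0.5 + stats::runif(length(calls)) * 0.5,
         stats::runif(length(calls)) * 0.499)
}

#' Simulate a synthetic cohort
#'
#' Draws a cohort of `n_patients` index cases with family-history personas
#' sampled from `criteria_prevalence`, plants one recurrent qualifying
#' missense variant per gene in carriers drawn independently at
#' `per_gene_carrier_freq`, perturbs each planted variant's predictor calls
#' with probability `predictor_noise`, and attaches a clean control panel
#' of `n_controls` individuals (0 carriers). The in-house cohort frequency
#' of every planted variant is computed from the simulated cohort itself.
#' The result has the same structure as [load_fixture_cohort()] and is
#' VCF-serializable via [write_cohort_vcf()].
#'
#' @param params A [simulation_params()] object.
#' @return Object of class `prca_cohort`.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_params(n_patients = 50, seed = 7))
simulate_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  n <- params$n_patients
  templates <- persona_templates()
  w <- params$criteria_prevalence
  pick <- sample(names(w), n, replace = TRUE, prob = w / sum(w))
  ids <- sprintf("SIM%04d", seq_len(n))
  ages <- vapply(pick, function(tpl) {
    r <- templates[[tpl]]$ages
    r[sample.int(length(r), 1)]
  }, 0)
  pat <- data.frame(patient_id = ids, age_at_dx = as.numeric(ages),
                    criteria_printed = pick, stringsAsFactors = FALSE,
                    row.names = NULL)
  relatives <- do.call(rbind, lapply(seq_len(n), function(i) {
    r <- templates[[pick[i]]]$rel
    if (nrow(r)) r$patient_id <- ids[i]
    r
  }))
  relatives <- relatives[, c("patient_id", "degree", "cancer_type",
                             "age_at_dx")]
  sp <- which(vapply(pick, function(tpl) templates[[tpl]]$second, TRUE))
  second_primaries <- data.frame(patient_id = ids[sp],
                                 cancer_type = rep("bladder", length(sp)),
                                 stringsAsFactors = FALSE)

  coords <- panel_gene_coords()
  genes <- names(params$per_gene_carrier_freq)
  fun <- functional_predictors()
  con <- conservation_predictors()
  planted <- NULL
  for (g in genes) {
    carriers <- ids[stats::runif(n) < params$per_gene_carrier_freq[[g]]]
    if (!length(carriers)) next
    ci <- match(g, coords$gene)
    chrom <- if (is.na(ci)) "1" else coords$chrom[ci]
    base <- if (is.na(ci)) 1e6 else coords$base[ci]
    offset <- sample.int(5000L, 1)
    calls <- qualifying_calls()
    all_calls <- c(calls$functional, calls$conservation)
    flip <- stats::runif(15) < params$predictor_noise
    flipped <- ifelse(flip, ifelse(all_calls == "pathogenic", "benign",
                                   "pathogenic"), all_calls)
    names(flipped) <- names(all_calls)
    rs <- rankscore_for_call(flipped)
    names(rs) <- names(all_calls)
    row <- data.frame(
      chrom = chrom, pos = base + offset, ref = "A", alt = "G", gene = g,
      transcript = NA_character_,
      cdna = sprintf("c.%dA>G", offset), protein = NA_character_,
      consequence = "missense", intron_distance = 0,
      depth = sample(40:150, 1), vaf = round(stats::runif(1, 0.40, 0.60), 2),
      maf_1000g = NA_real_, maf_evs = NA_real_, maf_exac = NA_real_,
      inhouse_fraction = length(carriers) / n,
      clinvar = "absent", bic = NA_character_, lovd = NA_character_,
      stringsAsFactors = FALSE
    )
    for (tool in c(fun, con))
      row[[paste0("rs_", tool)]] <- unname(rs[tool])
    for (tool in splice_predictors())
      row[[paste0("sp_", tool)]] <- NA_character_
    row$key <- variant_key(g, row$cdna)
    per_pat <- row[rep(1, length(carriers)), , drop = FALSE]
    per_pat <- cbind(patient_id = carriers, per_pat)
    planted <- rbind(planted, per_pat)
  }
  if (is.null(planted)) {
    planted <- load_empty_planted()
  }
  rownames(planted) <- NULL
  variants <- planted[!duplicated(planted$key),
                      setdiff(names(planted), "patient_id"), drop = FALSE]

  controls <- if (nrow(variants)) {
    data.frame(key = variants$key, group = "healthy",
               n = params$n_controls, carriers = 0L,
               stringsAsFactors = FALSE)
  } else {
    data.frame(key = character(), group = character(), n = integer(),
               carriers = integer(), stringsAsFactors = FALSE)
  }

  structure(list(patients = pat, relatives = relatives,
                 second_primaries = second_primaries,
                 ihc = data.frame(patient_id = character(),
                                  gene = character(),
                                  expression_retained = logical()),
                 incidental = data.frame(patient_id = character(),
                                         key = character()),
                 planted = planted, variants = variants,
                 evidence = data.frame(key = character(),
                                       codes_auto = character(),
                                       codes_manual = character()),
                 controls = controls),
            class = "prca_cohort")
}

load_empty_planted <- function() {
  cols <- c("patient_id", annotation_columns(), "key")
  out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                       stringsAsFactors = FALSE)
  out
}

#' Simulate a predictor rankscore matrix with known ground truth
#'
#' Generates `n_variants` predictor profiles: a fraction of the variants
#' qualify under the 12-of-15 (at least 3 conservation) consensus rule
#' before noise, the rest are constructed not to. Each of the 15 calls is
#' then flipped independently with probability `noise`, and the flip log is
#' returned so that recovery accuracy can be recounted independently.
#'
#' @param n_variants Number of variants (>= 1).
#' @param fraction_qualifying Probability a variant truly qualifies.
#' @param noise Per-call flip probability.
#' @param seed Integer seed.
#' @return List: `rankscores` (n x 15 matrix, columns named by tool),
#'   `calls` (post-noise categorical calls), `labels` (pre-noise
#'   ground-truth qualification), `flips` (logical n x 15 flip log).
#' @export
simulate_predictor_matrix <- function(n_variants, fraction_qualifying = 0.5,
                                      noise = 0, seed = 1L) {
  stopifnot(n_variants >= 1,
            fraction_qualifying >= 0, fraction_qualifying <= 1,
            noise >= 0, noise <= 1)
  set.seed(seed)
  tools <- c(functional_predictors(), conservation_predictors())
  n_fun <- length(functional_predictors())
  labels <- stats::runif(n_variants) < fraction_qualifying
  pick1 <- function(v) v[sample.int(length(v), 1)]  # safe for length-1 v
  calls <- matrix("benign", n_variants, 15, dimnames = list(NULL, tools))
  for (i in seq_len(n_variants)) {
    if (labels[i]) {
      n_path <- pick1(12:15)
      n_con <- pick1(max(3, n_path - n_fun):min(4, n_path))
    } else {
      n_path <- pick1(0:11)
      n_con <- if (n_path) pick1(0:min(4, n_path)) else 0L
    }
    n_f <- n_path - n_con
    calls[i, sample(n_fun, n_f)] <- "pathogenic"
    calls[i, n_fun + sample.int(4, n_con)] <- "pathogenic"
  }
  flips <- matrix(stats::runif(n_variants * 15) < noise, n_variants, 15,
                  dimnames = list(NULL, tools))
  noisy <- ifelse(flips,
                  ifelse(calls == "pathogenic", "benign", "pathogenic"),
                  calls)
  rank <- matrix(rankscore_for_call(noisy), n_variants, 15,
                 dimnames = list(NULL, tools))
  list(rankscores = rank, calls = noisy, labels = labels, flips = flips)
}
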