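# Criteria clauses, carrier assembly, attribution and cohort summary.

test_that("criteria clauses fire exactly per their definitions", {
  pat <- data.frame(patient_id = c("P1", "P2", "P3"),
                    age_at_dx = c(62, 58, 70))
  # P1: five first-degree brothers with PrCa, two before 61; P3: nobody
  relatives <- data.frame(patient_id = "P1", degree = "first",
                          cancer_type = "prostate",
                          age_at_dx = c(59, 59, 66, 67, 68))
  second <- data.frame(patient_id = "P2", cancer_type = "urothelial")
  fl <- classify_criteria(pat, relatives, second)
  expect_true(fl$A1[1] && fl$A2[1])
  expect_false(fl$A3[1] || fl$B1[1] || fl$B2[1] || fl$B3[1])
  # second primary alone gives B2 only
  expect_identical(unlist(fl[2, c("A1", "A2", "A3", "B1", "B2", "B3")],
                          use.names = FALSE),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_false(any(unlist(fl[3, c("A1", "A2", "A3", "B1", "B2", "B3")])))
})

test_that("age boundaries of the criteria are honored", {
  # A3 requires diagnosis before 61 and three-youngest average <= 65
  mk <- function(age) data.frame(patient_id = "P", age_at_dx = age)
  rel2 <- data.frame(patient_id = "P", degree = c("first", "second"),
                     cancer_type = "prostate", age_at_dx = c(64, 70))
  expect_true(classify_criteria(mk(60), rel2)$A3)
  expect_false(classify_criteria(mk(61), rel2)$A3)
  # B1 requires diagnosis before 56
  rel3 <- data.frame(patient_id = "P", degree = c("first", "second", "second"),
                     cancer_type = c("lung", "kidney", "pancreatic"),
                     age_at_dx = c(52, 55, 58))
  expect_true(classify_criteria(mk(55), rel3)$B1)
  expect_false(classify_criteria(mk(56), rel3)$B1)
  # missing ages make an age-dependent clause false, with a warning
  rel_na <- data.frame(patient_id = "P", degree = "first",
                       cancer_type = "prostate",
                       age_at_dx = c(NA_real_, NA_real_))
  expect_warning(fl <- classify_criteria(mk(NA), rel_na), "missing")
  expect_false(fl$A2)
})

test_that("B3 fires on rare types, clustering, or early-onset relatives", {
  mk <- function(types, ages, degree = "second") {
    pat <- data.frame(patient_id = "P", age_at_dx = 65)
    rel <- data.frame(patient_id = "P", degree = degree, cancer_type = types,
                      age_at_dx = ages)
    classify_criteria(pat, rel)$B3
  }
  expect_true(mk("male breast", 60))                      # rare type
  expect_true(mk(c("breast", "colon"), c(60, 62)))        # clustering
  expect_false(mk("colon", 60))                           # single, late
  expect_true(mk("colon", 44))                            # early-onset
  expect_false(mk("prostate", 44))                        # PrCa is A's domain
})

test_that("carrier assembly applies IHC and incidental exclusions", {
  cohort <- load_fixture_cohort()
  planted <- cohort$planted
  tiers <- assign_tier(run_cascade(cohort$variants)$kept)
  planted$tier <- tiers$tier[match(planted$key, tiers$key)]
  res <- assemble_carriers(planted, cohort$ihc, cohort$incidental)

  expect_identical(length(res$carriers), 18L)
  # HPC371's only variant is excluded by retained MSH2 expression
  expect_false("HPC371" %in% res$carriers)
  a371 <- res$assignments[res$assignments$patient_id == "HPC371", ]
  expect_identical(a371$exclusion_reason, "ihc_retained_expression")
  # HPC332 loses the MSH6 variant but stays a carrier through ATM
  expect_true("HPC332" %in% res$carriers)
  a332 <- res$assignments[res$assignments$patient_id == "HPC332", ]
  expect_true(a332$excluded[a332$gene == "MSH6"])
  expect_true(a332$qualifying[a332$gene == "ATM"])
  # HPC186's MSH6 in-frame deletion is excluded as incidental
  a186 <- res$assignments[res$assignments$patient_id == "HPC186", ]
  expect_identical(a186$exclusion_reason[a186$gene == "MSH6"],
                   "incidental_finding")
  expect_true("HPC186" %in% res$carriers)
})

test_that("IHC rows without a matching variant are ignored with a warning", {
  planted <- data.frame(patient_id = "P1", key = "ATM:c.1A>G", gene = "ATM",
                        consequence = "missense",
                        tier = "potentially_pathogenic_missense")
  ihc <- data.frame(patient_id = "P1", gene = "MSH2",
                    expression_retained = TRUE)
  expect_warning(res <- assemble_carriers(planted, ihc), "matches no variant")
  expect_identical(res$carriers, "P1")
})

test_that("gene attribution prefers truncating variants, then ties break", {
  asg <- data.frame(
    patient_id = c("X", "X", "Y", "Z", "Z"),
    key = c("RAD51C:c.890_899del", "ATM:c.8560C>T", "ATM:c.995A>G",
            "CHEK2:c.1A>G", "ATM:c.2A>G"),
    gene = c("RAD51C", "ATM", "ATM", "CHEK2", "ATM"),
    consequence = c("frameshift", "missense", "missense", "missense",
                    "missense"),
    tier = c("truncating_deleterious", "potentially_pathogenic_missense",
             "potentially_pathogenic_missense",
             "potentially_pathogenic_missense",
             "potentially_pathogenic_missense"))
  res <- assemble_carriers(asg)
  at <- attribute_gene(res$assignments)
  expect_identical(at$attributed_gene[at$patient_id == "X"], "RAD51C")
  expect_identical(at$attributed_gene[at$patient_id == "Y"], "ATM")
  # alphabetical tie-break without association p-values
  expect_identical(at$attributed_gene[at$patient_id == "Z"], "ATM")
  # a smaller case-control p wins over alphabetical order
  at2 <- attribute_gene(res$assignments,
                        assoc = data.frame(key = "CHEK2:c.1A>G", p = 0.001))
  expect_identical(at2$attributed_gene[at2$patient_id == "Z"], "CHEK2")
})

test_that("cohort summary reports the study denominators and fractions", {
  run <- run_pipeline(load_fixture_cohort())
  s <- run$summary
  expect_identical(s$n_carriers, 18L)
  expect_identical(s$pct_carriers, 14.9)
  expect_identical(s$n_carriers_A, 8L)
  expect_identical(s$n_carriers_B, 12L)
  expect_identical(s$n_early_onset_carriers, 7L)
  # raw ATM carrier count exceeds attributed by one (the RAD51C co-carrier)
  raw_atm <- s$per_gene_raw$n[s$per_gene_raw$gene == "ATM"]
  attr_atm <- s$per_gene_attributed$n[s$per_gene_attributed$gene == "ATM"]
  expect_identical(raw_atm, attr_atm + 1L)
})

test_that("summary percentages are scale-free under cohort duplication", {
  cohort <- load_fixture_cohort()
  run <- run_pipeline(cohort)
  flags <- run$flags
  asg <- run$assignments
  double <- function(df) {
    d2 <- df
    d2$patient_id <- paste0(d2$patient_id, "_dup")
    rbind(df, d2)
  }
  s1 <- summarize_cohort(flags, asg)
  s2 <- summarize_cohort(double(flags), double(asg))
  for (f in grep("^pct_", names(unclass(s1)), value = TRUE))
    expect_identical(s1[[f]], s2[[f]], info = f)
  expect_identical(s2$n_carriers, 2L * s1$n_carriers)
})

test_that("an empty carrier set yields zero percentages", {
  flags <- classify_criteria(data.frame(patient_id = "P1", age_at_dx = 60),
                             data.frame(patient_id = character(),
                                        degree = character(),
                                        cancer_type = character(),
                                        age_at_dx = numeric()))
  asg <- data.frame(patient_id = character(), key = character(),
                    gene = character(), consequence = character(),
                    tier = character(), qualifying = logical(),
                    excluded = logical(), exclusion_reason = character())
  s <- summarize_cohort(flags, asg)
  expect_identical(s$n_carriers, 0L)
  expect_identical(s$pct_carriers, 0)
})
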