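# Fixture cohort and synthetic simulation.

test_that("fixture cohort matches the published marginals", {
  cohort <- load_fixture_cohort()
  expect_identical(nrow(cohort$patients), 121L)
  expect_false(anyDuplicated(cohort$patients$patient_id) > 0)

  flags <- classify_criteria(cohort$patients, cohort$relatives,
                             cohort$second_primaries)
  expect_identical(sum(flags$group_A), 45L)
  expect_identical(sum(flags$group_B), 86L)
  expect_identical(sum(flags$group_A & flags$group_B), 10L)
  expect_identical(sum(flags$early_onset), 64L)

  carrier_ids <- c("HPC177", "HPC395", "HPC447", "HPC150", "HPC186",
                   "HPC421", "HPC455", "HPC238", "HPC167", "HPC400",
                   "HPC20", "HPC3", "HPC332", "HPC118", "HPC188",
                   "HPC289", "HPC89", "HPC371", "HPC394")
  expect_setequal(unique(cohort$planted$patient_id), carrier_ids)
  expect_identical(length(carrier_ids), 19L)
  expect_true(all(table(cohort$patients$patient_id[
    cohort$patients$patient_id %in% carrier_ids]) == 1))
})

test_that("tabulated carriers hold their printed variants and flags", {
  cohort <- load_fixture_cohort()
  p177 <- cohort$planted[cohort$planted$patient_id == "HPC177", ]
  expect_identical(p177$key, "ATM:c.652C>T")
  expect_identical(p177$chrom, "11")
  expect_identical(p177$pos, 108114835L)
  expect_identical(
    cohort$patients$criteria_printed[cohort$patients$patient_id == "HPC177"],
    "A1,A2")
  # HPC186 carries the RAD51C frameshift, the ATM missense and the
  # incidental MSH6 in-frame deletion
  k186 <- cohort$planted$key[cohort$planted$patient_id == "HPC186"]
  expect_setequal(k186, c("RAD51C:c.890_899del", "ATM:c.8560C>T",
                          "MSH6:c.3846_3860del"))
  expect_identical(cohort$incidental$key, "MSH6:c.3846_3860del")
  # MMR missense carriers hold retained-expression IHC flags
  expect_true(all(c("HPC371", "HPC332") %in% cohort$ihc$patient_id))
})

test_that("criteria classification reproduces every printed flag set", {
  cohort <- load_fixture_cohort()
  flags <- classify_criteria(cohort$patients, cohort$relatives,
                             cohort$second_primaries)
  derived <- apply(flags[, c("A1", "A2", "A3", "B1", "B2", "B3")], 1,
                   function(r) paste(names(r)[r], collapse = ","))
  canon <- function(x) vapply(strsplit(x, ","), function(s)
    paste(sort(s), collapse = ","), "")
  expect_identical(canon(derived), canon(cohort$patients$criteria_printed))
})

test_that("a missing fixture file raises an explicit load error", {
  expect_error(prcapanel:::read_fixture_tsv("no_such_table.tsv", "x"),
               "not found")
})

test_that("simulation is seed-deterministic and respects degenerate rates", {
  params <- simulation_params(n_patients = 200,
                              per_gene_carrier_freq = c(ATM = 0.05),
                              seed = 1)
  c1 <- simulate_cohort(params)
  c2 <- simulate_cohort(params)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(simulation_params(n_patients = 200,
                                          per_gene_carrier_freq = c(ATM = 0.05),
                                          seed = 2))
  expect_false(identical(c1$planted, c3$planted))
  # zero carrier frequency plants nothing
  c0 <- simulate_cohort(simulation_params(n_patients = 100,
                                          per_gene_carrier_freq = c(ATM = 0),
                                          seed = 1))
  expect_identical(nrow(c0$planted), 0L)
  expect_error(simulation_params(per_gene_carrier_freq = c(ATM = 1.5)))
})

test_that("simulated carrier fraction recovers the planted frequency", {
  freq <- 0.05
  n <- 2000
  cohort <- simulate_cohort(simulation_params(
    n_patients = n, per_gene_carrier_freq = c(ATM = freq), seed = 7))
  observed <- length(unique(cohort$planted$patient_id)) / n
  se <- sqrt(freq * (1 - freq) / n)
  expect_lt(abs(observed - freq), 3 * se)
})

test_that("predictor matrix labels are recovered exactly without noise", {
  sim <- simulate_predictor_matrix(300, fraction_qualifying = 0.4,
                                   noise = 0, seed = 3)
  t <- default_thresholds()
  recovered <- vapply(seq_len(300), function(i) {
    calls <- sim$calls[i, ]
    evaluate_missense_consensus(calls[functional_predictors()],
                                calls[conservation_predictors()],
                                t)$qualifies
  }, TRUE)
  expect_identical(recovered, sim$labels)
  # no variant qualifies when none is constructed to
  sim0 <- simulate_predictor_matrix(100, fraction_qualifying = 0,
                                    noise = 0, seed = 3)
  expect_false(any(sim0$labels))
})

test_that("noisy recovery accuracy equals an independent flip-log recount", {
  sim <- simulate_predictor_matrix(500, fraction_qualifying = 0.5,
                                   noise = 0.05, seed = 3)
  t <- default_thresholds()
  recovered <- vapply(seq_len(500), function(i) {
    calls <- sim$calls[i, ]
    evaluate_missense_consensus(calls[functional_predictors()],
                                calls[conservation_predictors()],
                                t)$qualifies
  }, TRUE)
  accuracy <- mean(recovered == sim$labels)
  # replay: reconstruct the pre-noise calls from the flip log, re-apply the
  # flips by hand and recount with the brute-force rule
  replayed <- vapply(seq_len(500), function(i) {
    noisy <- sim$calls[i, ]
    clean <- ifelse(sim$flips[i, ],
                    ifelse(noisy == "pathogenic", "benign", "pathogenic"),
                    noisy)
    # ground truth must match the clean profile's own consensus
    bits_clean <- as.integer(clean[c(functional_predictors(),
                                     conservation_predictors())] == "pathogenic")
    stopifnot(oracle_consensus(bits_clean) == sim$labels[i])
    bits_noisy <- as.integer(noisy[c(functional_predictors(),
                                     conservation_predictors())] == "pathogenic")
    oracle_consensus(bits_noisy) == sim$labels[i]
  }, TRUE)
  expect_identical(accuracy, mean(replayed))
  expect_lt(accuracy, 1)   # 5% call noise must cost some variants
})

test_that("planted variants round-trip through VCF write and read", {
  cohort <- load_fixture_cohort()
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(cohort, vcf_path)
  back <- read_vcf(vcf_path)
  expect_identical(nrow(back$variants), nrow(cohort$variants))
  orig <- cohort$variants[order(cohort$variants$chrom, cohort$variants$pos,
                                cohort$variants$alt), ]
  expect_identical(back$variants$chrom, orig$chrom)
  expect_identical(back$variants$pos, orig$pos)
  expect_identical(back$variants$ref, orig$ref)
  expect_identical(back$variants$alt, orig$alt)
  # genotypes: every planted patient-variant pair is a 0/1 call
  expect_identical(nrow(back$genotypes), nrow(cohort$planted))
  expect_true(all(back$genotypes$gt == "0/1"))
  sim <- simulate_cohort(simulation_params(n_patients = 30,
                                           per_gene_carrier_freq = c(CHEK2 = 0.2),
                                           seed = 5))
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(sim, p2)
  back2 <- read_vcf(p2)
  expect_identical(back2$variants$pos, sim$variants$pos)
})
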