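# Predictor consensus: rankscore calls, the 12-of-15 missense rule, the
# 3-of-4 splice rule, and tier dispatch.

test_that("rankscore calls use an inclusive cutoff and validate range", {
  expect_identical(call_from_rankscore(c(0.9, 0.5, 0.49)),
                   c("pathogenic", "pathogenic", "benign"))
  expect_identical(call_from_rankscore(NA_real_), NA_character_)
  expect_error(call_from_rankscore(1.2), "outside")
  expect_identical(call_from_rankscore(0.6, cutoff = 0.7), "benign")
})

test_that("missense consensus needs 12 of 15 calls with 3 conservation", {
  t <- default_thresholds()
  all_path <- make_profile(11, 4)
  r <- evaluate_missense_consensus(all_path$functional, all_path$conservation, t)
  expect_true(r$qualifies)
  expect_identical(r$n_pathogenic, 15L)
  expect_identical(r$n_conservation_pathogenic, 4L)

  # 12 calls but only 2 conservation: the conservation clause blocks it
  p <- make_profile(10, 2)
  r <- evaluate_missense_consensus(p$functional, p$conservation, t)
  expect_false(r$qualifies)
  expect_identical(r$n_pathogenic, 12L)

  # minimal qualifying configuration
  p <- make_profile(9, 3)
  r <- evaluate_missense_consensus(p$functional, p$conservation, t)
  expect_true(r$qualifies)

  # missing counts against qualification (denominator stays 15)
  p <- make_profile(9, 3)
  p$functional[1:4] <- NA
  r <- evaluate_missense_consensus(p$functional, p$conservation, t)
  expect_false(r$qualifies)
  expect_identical(r$n_pathogenic, 8L)
})

test_that("missense consensus agrees with brute force over all 2^15 profiles", {
  t <- default_thresholds()
  bits <- as.matrix(expand.grid(rep(list(0:1), 15)))
  agree <- vapply(seq_len(nrow(bits)), function(i) {
    b <- bits[i, ]
    p <- calls_from_bits(b)
    evaluate_missense_consensus(p$functional, p$conservation,
                                t)$qualifies == oracle_consensus(b)
  }, TRUE)
  expect_true(all(agree))
})

test_that("flipping a call benign -> pathogenic never disqualifies", {
  t <- default_thresholds()
  set.seed(11)
  for (rep in 1:10000) {
    b <- stats::rbinom(15, 1, runif(1))
    if (all(b == 1)) next
    p <- calls_from_bits(b)
    before <- evaluate_missense_consensus(p$functional, p$conservation,
                                          t)$qualifies
    if (!before) next   # only a TRUE can be lost
    j <- sample(which(b == 0), 1)
    b2 <- b; b2[j] <- 1
    p2 <- calls_from_bits(b2)
    after <- evaluate_missense_consensus(p2$functional, p2$conservation,
                                         t)$qualifies
    expect_true(after)
    if (!after) break
  }
})

test_that("splice consensus requires 3 of 4 affected calls", {
  mk <- function(n_affected) {
    setNames(c(rep("affected", n_affected),
               rep("unaffected", 4 - n_affected)), splice_predictors())
  }
  expect_true(evaluate_splice_consensus(mk(3))$qualifies)
  expect_false(evaluate_splice_consensus(mk(2))$qualifies)
  expect_true(evaluate_splice_consensus(mk(4))$qualifies)
  # missing counts as unaffected
  calls <- mk(3); calls[1] <- NA
  expect_false(evaluate_splice_consensus(calls)$qualifies)
})

test_that("tier dispatch follows consequence class and consensus", {
  t <- default_thresholds()
  expect_identical(assign_tier(make_variant(consequence = "nonsense"), t)$tier,
                   "truncating_deleterious")
  expect_identical(assign_tier(make_variant(consequence = "frameshift"), t)$tier,
                   "truncating_deleterious")
  # splice site qualifying by predictors
  v <- make_variant(consequence = "splice_site", sp_HSF3 = "affected",
                    sp_MaxEntScan = "affected", sp_NNSPLICE = "affected",
                    sp_NetGene2 = "unaffected")
  expect_identical(assign_tier(v, t)$tier, "truncating_deleterious")
  # splice site at 2/4 but with a database assertion still qualifies
  v <- make_variant(consequence = "splice_site", sp_HSF3 = "affected",
                    sp_MaxEntScan = "affected", clinvar = "likely_pathogenic")
  expect_identical(assign_tier(v, t)$tier, "truncating_deleterious")
  # splice site at 2/4 without assertion does not
  v <- make_variant(consequence = "splice_site", sp_HSF3 = "affected",
                    sp_MaxEntScan = "affected")
  expect_identical(assign_tier(v, t)$tier, "unclassified")
  # missense under/over the consensus bar
  rs <- setNames(rep(0.9, 15), paste0("rs_", c(functional_predictors(),
                                               conservation_predictors())))
  v <- do.call(make_variant, as.list(rs))
  expect_identical(assign_tier(v, t)$tier, "potentially_pathogenic_missense")
  rs[1:7] <- 0.1   # 8/15 pathogenic
  v <- do.call(make_variant, as.list(rs))
  expect_identical(assign_tier(v, t)$tier, "unclassified")
  # missense without any profile: unclassified with a warning
  expect_warning(res <- assign_tier(make_variant(), t), "no predictor profile")
  expect_identical(res$tier, "unclassified")
  # in-frame indel only via asserted-pathogenic route
  expect_identical(assign_tier(make_variant(consequence = "inframe_indel"),
                               t)$tier, "unclassified")
  expect_identical(assign_tier(make_variant(consequence = "inframe_indel",
                                            clinvar = "pathogenic"), t)$tier,
                   "truncating_deleterious")
})

test_that("fixture variants receive their published tiers", {
  cohort <- load_fixture_cohort()
  tiers <- assign_tier(run_cascade(cohort$variants)$kept)
  trunc <- tiers$key[tiers$tier == "truncating_deleterious"]
  mis <- tiers$key[tiers$tier == "potentially_pathogenic_missense"]
  # seven tabulated truncating/deleterious variants
  expect_setequal(setdiff(trunc, "MSH6:c.3846_3860del"),
                  c("ATM:c.652C>T", "CHEK2:c.593-1G>T", "FANCD2:c.2494+2T>C",
                    "FANCI:c.206del", "RAD51C:c.890_899del", "CEP57:c.791C>G",
                    "RECQL4:c.2636del"))
  # all ten tabulated missense variants qualify
  expect_identical(length(mis), 10L)
  expect_true(all(c("ATM:c.8560C>T", "CHEK2:c.349A>G", "MSH2:c.1571G>A",
                    "MSH6:c.1729C>T", "TP53:c.839G>A") %in% mis))
})
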