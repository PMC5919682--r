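# Independent oracles and small builders used across the suite.

# Two-sided Fisher p by full enumeration of the hypergeometric support:
# sum of the conditional probabilities of all tables (fixed margins) whose
# point probability does not exceed the observed one. Uses choose() only.
oracle_fisher <- function(a, b, cc, d) {
  m <- a + b; n2 <- cc + d; k <- a + cc; N <- m + n2
  if (k == 0 || k == N || m == 0 || n2 == 0) return(1)
  xs <- max(0, k - n2):min(k, m)
  probs <- choose(m, xs) * choose(n2, k - xs) / choose(N, k)
  pobs <- choose(m, a) * choose(n2, k - a) / choose(N, k)
  min(1, sum(probs[probs <= pobs * (1 + 1e-07)]))
}

# Brute-force counter for the missense consensus rule on a binary profile
# (first 11 entries functional, last 4 conservation; 1 = pathogenic call).
oracle_consensus <- function(bits) {
  total <- 0L; cons <- 0L
  for (i in seq_along(bits)) {
    if (bits[i] == 1L) {
      total <- total + 1L
      if (i > 11) cons <- cons + 1L
    }
  }
  total >= 12L && cons >= 3L
}

# Independent ACMG-AMP combining-rule oracle driven by an explicit rule
# table of minimum category counts (vectorized over rows of a count
# matrix with columns pvs, ps, pm, pp, ba, bs, bp).
oracle_acmg <- function(counts) {
  rule_hits <- function(rules) {
    hit <- rep(FALSE, nrow(counts))
    for (r in rules) {
      need <- c(pvs = 0, ps = 0, pm = 0, pp = 0)
      need[names(r)] <- r
      hit <- hit | (counts[, "pvs"] >= need["pvs"] &
                      counts[, "ps"] >= need["ps"] &
                      counts[, "pm"] >= need["pm"] &
                      counts[, "pp"] >= need["pp"])
    }
    hit
  }
  path <- rule_hits(list(
    c(pvs = 1, ps = 1), c(pvs = 1, pm = 2), c(pvs = 1, pm = 1, pp = 1),
    c(pvs = 1, pp = 2), c(ps = 2), c(ps = 1, pm = 3),
    c(ps = 1, pm = 2, pp = 2), c(ps = 1, pm = 1, pp = 4)))
  lpath <- rule_hits(list(
    c(pvs = 1, pm = 1), c(ps = 1, pm = 1), c(ps = 1, pp = 2),
    c(pm = 3), c(pm = 2, pp = 2), c(pm = 1, pp = 4)))
  ben <- counts[, "ba"] >= 1 | counts[, "bs"] >= 2
  lben <- (counts[, "bs"] >= 1 & counts[, "bp"] >= 1) | counts[, "bp"] >= 2
  p_side <- path | lpath
  b_side <- ben | lben
  ifelse(p_side & b_side, "vus",
  ifelse(path, "pathogenic",
  ifelse(lpath, "likely_pathogenic",
  ifelse(ben, "benign",
  ifelse(lben, "likely_benign", "vus")))))
}

# Full annotated-variant row with sensible defaults, overridable by name.
make_variant <- function(...) {
  row <- data.frame(
    chrom = "1", pos = 1000L, ref = "A", alt = "G", gene = "GENE1",
    transcript = NA_character_, cdna = "c.1A>G", protein = NA_character_,
    consequence = "missense", intron_distance = 0,
    depth = 100, vaf = 0.5,
    maf_1000g = NA_real_, maf_evs = NA_real_, maf_exac = NA_real_,
    inhouse_fraction = 0, clinvar = "absent",
    bic = NA_character_, lovd = NA_character_,
    stringsAsFactors = FALSE
  )
  for (tool in c(functional_predictors(), conservation_predictors()))
    row[[paste0("rs_", tool)]] <- NA_real_
  for (tool in splice_predictors())
    row[[paste0("sp_", tool)]] <- NA_character_
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

# Predictor call profile with a given number of pathogenic calls.
make_profile <- function(n_functional_path, n_conservation_path) {
  f <- setNames(rep("benign", 11), functional_predictors())
  if (n_functional_path > 0) f[seq_len(n_functional_path)] <- "pathogenic"
  cn <- setNames(rep("benign", 4), conservation_predictors())
  if (n_conservation_path > 0) cn[seq_len(n_conservation_path)] <- "pathogenic"
  list(functional = f, conservation = cn)
}

# All permutations of a short vector.
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in combinat_perms(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], p)
  out
}

calls_from_bits <- function(bits) {
  list(functional = setNames(ifelse(bits[1:11] == 1, "pathogenic", "benign"),
                             functional_predictors()),
       conservation = setNames(ifelse(bits[12:15] == 1, "pathogenic",
                                      "benign"),
                               conservation_predictors()))
}
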