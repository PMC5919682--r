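## Family-history eligibility criteria.
##
## The cohort is recruited under two groups: A (familial/hereditary
## prostate cancer) with clauses A1-A3 on prostate cancer aggregation, and
## B (early-onset disease and/or aggregation of other cancers) with clauses
## B1-B3. Each clause is evaluated from the index patient's age at
## diagnosis, the affected relatives (degree, cancer type, age at
## diagnosis), and any second primary tumors.

#' Classify patients against the A/B family-history criteria
#'
#' Evaluates, for every patient, the six eligibility clauses:
#'
#' * **A1** — at least three first-degree relatives with prostate cancer,
#'   regardless of ages (relatives are counted exclusive of the index case;
#'   set `a1_includes_index = TRUE` for the inclusive reading).
#' * **A2** — at least two first-degree relatives with prostate cancer, the
#'   average age at diagnosis of the affected set (index included) at most
#'   65, and at least one affected diagnosed before age 61.
#' * **A3** — index diagnosed before 61 with at least two first- or
#'   second-degree relatives with prostate cancer and the average of the
#'   three youngest affected (index included) at most 65.
#' * **B1** — index diagnosed before 56 with at least three first- or
#'   second-degree relatives with cancer and the average of the three
#'   youngest diagnoses (index included) at most 55.
#' * **B2** — a second primary cancer besides the prostate tumor.
#' * **B3** — a relative with an early-onset cancer of a familial type
#'   (diagnosed at or before `relative_early_onset_age`), a relative with a
#'   rare cancer type (`rare_cancers`), or clustering (two or more
#'   relatives) of cancers from `clustering_cancers`. Prostate cancer in
#'   relatives is the A group's domain and never triggers B3.
#'
#' A clause whose required ages are entirely missing evaluates to `FALSE`
#' with a warning.
#'
#' @param patients Data frame with `patient_id` and `age_at_dx`.
#' @param relatives Data frame with `patient_id`, `degree` (`"first"` or
#'   `"second"`), `cancer_type`, `age_at_dx` (NA allowed).
#' @param second_primaries Data frame with `patient_id`, `cancer_type`.
#' @param rare_cancers,clustering_cancers Cancer-type lists driving B3.
#' @param early_onset_age Age at or below which the index case counts as
#'   early-onset (default 55; B1's "before 56" trigger is the same bound).
#' @param relative_early_onset_age Age at or below which a relative's
#'   cancer counts as early-onset for B3 (default 45).
#' @param a1_includes_index Whether the index counts toward A1's three
#'   affected (default FALSE).
#' @return Data frame: `patient_id`, logical `A1`...`B3`, `group_A`,
#'   `group_B`, `early_onset`.
#' @export
classify_criteria <- function(patients, relatives,
                              second_primaries = NULL,
                              rare_cancers = c("bilateral breast",
                                               "male breast", "brain"),
                              clustering_cancers = c("breast", "colon",
                                                     "gastric"),
                              early_onset_age = 55,
                              relative_early_onset_age = 45,
                              a1_includes_index = FALSE) {
  stopifnot(all(c("patient_id", "age_at_dx") %in% names(patients)))
  if (nrow(relatives))
    stopifnot(all(c("patient_id", "degree", "cancer_type", "age_at_dx")
                  %in% names(relatives)),
              all(relatives$degree %in% c("first", "second")))
  if (is.null(second_primaries))
    second_primaries <- data.frame(patient_id = character(),
                                   cancer_type = character())

  youngest3_mean <- function(ages) {
    ages <- ages[!is.na(ages)]
    if (!length(ages)) return(NA_real_)
    mean(sort(ages)[seq_len(min(3, length(ages)))])
  }

  one <- function(pid, index_age) {
    rel <- relatives[relatives$patient_id == pid, , drop = FALSE]
    prca <- rel[rel$cancer_type == "prostate", , drop = FALSE]
    prca_fd <- prca[prca$degree == "first", , drop = FALSE]
    other <- rel[rel$cancer_type != "prostate", , drop = FALSE]

    a1_needed <- if (a1_includes_index) 2L else 3L
    A1 <- nrow(prca_fd) >= a1_needed

    A2 <- FALSE
    if (nrow(prca_fd) >= 2) {
      ages <- c(index_age, prca_fd$age_at_dx)
      if (all(is.na(ages))) {
        warnf("patient %s: A2 ages all missing; clause set FALSE", pid)
      } else {
        A2 <- mean(ages, na.rm = TRUE) <= 65 && any(ages < 61, na.rm = TRUE)
      }
    }

    A3 <- FALSE
    if (!is.na(index_age) && index_age < 61 && nrow(prca) >= 2) {
      m <- youngest3_mean(c(index_age, prca$age_at_dx))
      A3 <- !is.na(m) && m <= 65
    }

    B1 <- FALSE
    if (!is.na(index_age) && index_age < 56 && nrow(rel) >= 3) {
      m <- youngest3_mean(c(index_age, rel$age_at_dx))
      if (is.na(m)) warnf("patient %s: B1 ages all missing; clause set FALSE",
                          pid)
      else B1 <- m <= 55
    }

    B2 <- pid %in% second_primaries$patient_id

    early_rel <- any(!is.na(other$age_at_dx) &
                       other$age_at_dx <= relative_early_onset_age)
    rare_rel <- any(other$cancer_type %in% rare_cancers)
    cluster_rel <- sum(other$cancer_type %in% clustering_cancers) >= 2
    B3 <- early_rel || rare_rel || cluster_rel

    c(A1 = A1, A2 = A2, A3 = A3, B1 = B1, B2 = B2, B3 = B3)
  }

  flags <- t(mapply(one, patients$patient_id, patients$age_at_dx))
  out <- data.frame(patient_id = patients$patient_id,
                    flags, stringsAsFactors = FALSE)
  out$group_A <- out$A1 | out$A2 | out$A3
  out$group_B <- out$B1 | out$B2 | out$B3
  out$early_onset <- !is.na(patients$age_at_dx) &
    patients$age_at_dx <= early_onset_age
  rownames(out) <- NULL
  out
}
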