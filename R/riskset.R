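#' Identify ischemic stroke cases in the cohort
#'
#' A case is a cohort member whose follow-up ended with an ischemic
#' stroke; the index date is that (first) stroke date. A stroke on the
#' entry date itself counts: the boundary of "after cohort entry" is
#' resolved as on-or-after entry.
#'
#' @param cohort output of [build_cohort()].
#' @return `data.table` with `person_id`, `index_date`.
#' @export
find_cases <- function(cohort) {
  ch <- as.data.table(cohort)
  check_columns(ch, c("person_id", "exit_date", "exit_reason"), "cohort")
  out <- ch[exit_reason == "IS", .(person_id, index_date = exit_date)]
  setorder(out, person_id)
  out[]
}

#' Incidence-density sampling of matched controls
#'
#' For each case, controls are drawn from cohort members in the same
#' database and of the same sex whose age at cohort entry is within
#' `age_tol_years` of the case's, who entered on or before the case's
#' index date and are still at risk at it (follow-up ending strictly after
#' the index date — so future cases are eligible as controls strictly
#' before their own index day, and persons already censored are not).
#' When more than `n_controls` are eligible, that many are sampled
#' uniformly without replacement; persons may serve as controls for
#' several cases. Sets with no eligible control are kept and flagged.
#'
#' @param cases output of [find_cases()].
#' @param cohort output of [build_cohort()].
#' @param persons person table with `person_id`, `database`, `sex`,
#'   `birthdate`.
#' @param n_controls maximum controls per case (study design: 100).
#' @param age_tol_years age-matching caliper in years (study design: 1).
#' @param seed integer seed for the sampling (required, logged).
#' @return `data.table` with columns `set_id`, `role` (`case`/`control`),
#'   `person_id`, `index_date`, `database`; attribute `n_unmatched` counts
#'   the sets without any eligible control.
#' @export
sample_matched_sets <- function(cases, cohort, persons, n_controls = 100L,
                                age_tol_years = 1, seed) {
  if (missing(seed)) stop("a sampling seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  check_columns(persons, c("person_id", "database", "sex", "birthdate"),
                "persons")
  chx <- merge(as.data.table(cohort),
               as.data.table(persons)[, .(person_id, database, sex,
                                          birthdate)],
               by = "person_id")
  chx[, aged := as.integer(entry_date - birthdate)]
  ca <- merge(as.data.table(cases), chx, by = "person_id")
  setorder(ca, person_id, index_date)
  tol <- as.integer(round(age_tol_years * DAYS_PER_YEAR))
  ca[, `:=`(set_id = seq_len(.N), lo = aged - tol, hi = aged + tol,
            idx = index_date)]

  pool <- chx[, .(person_id, database, sex, aged, ent = entry_date,
                  exi = exit_date)]
  elig <- pool[ca, on = .(database, sex, aged >= lo, aged <= hi,
                          ent <= idx, exi > idx),
               .(set_id = i.set_id, case_id = i.person_id,
                 index_date = i.idx, database = i.database,
                 person_id = x.person_id),
               nomatch = NULL, allow.cartesian = TRUE]
  elig <- elig[person_id != case_id]
  setorder(elig, set_id, person_id)

  ctrl <- elig[, {
    ids <- person_id
    if (length(ids) > n_controls) ids <- sample(ids, n_controls)
    .(person_id = ids, index_date = index_date[1L],
      database = database[1L])
  }, by = set_id]
  ctrl[, role := "control"]
  case_rows <- ca[, .(set_id, person_id, index_date, database,
                      role = "case")]
  out <- rbindlist(list(case_rows, ctrl), use.names = TRUE)
  setorder(out, set_id, role)  # case row first within each set
  setcolorder(out, c("set_id", "role", "person_id", "index_date",
                     "database"))
  n_unmatched <- nrow(ca) - uniqueN(ctrl$set_id)
  if (n_unmatched > 0L) {
    message(sprintf("%d of %d cases could not be matched to any control",
                    n_unmatched, nrow(ca)))
  }
  setattr(out, "n_unmatched", n_unmatched)
  out[]
}
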