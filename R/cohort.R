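#' Default sentinel code lists
#'
#' The package treats outcome and censoring code lists as configuration:
#' synthetic data uses one sentinel code per concept, real deployments
#' substitute their terminology-specific lists. NSAIDs are identified by
#' the ATC prefix `M01A` on the dispensing substance code.
#'
#' @return named list: `nsaid_atc_prefix`, `is` (ischemic stroke), `cancer`
#'   (malignant cancer), `nmsc` (non-melanoma skin cancer, exempt from the
#'   cancer exclusion), `death`.
#' @export
default_code_lists <- function() {
  list(nsaid_atc_prefix = "M01A",
       is = "DX_IS",
       cancer = c("DX_CANCER", "DX_NMSC"),
       nmsc = "DX_NMSC",
       death = "DX_DEATH")
}

#' Build the new-user NSAID cohort
#'
#' Scans each person's NSAID dispensings in date order and admits the
#' first one satisfying new-user eligibility: age 18 or older at the
#' dispensing, a single enrollment span covering the 365 days up to and
#' including the dispensing, no NSAID dispensing and no malignant-cancer
#' diagnosis (non-melanoma skin cancer exempt) in the 365 days before it.
#' Cohort entry is that dispensing's date. Follow-up ends at the earliest
#' of: end of the study period, first ischemic stroke on/after entry, end
#' or interruption of enrollment, first malignant cancer diagnosis, or
#' death; date ties are broken with priority
#' IS > death > cancer > disenrollment > study end.
#'
#' @param persons table with `person_id`, `database`, `sex`, `birthdate`.
#' @param enrollment table with `person_id`, `start`, `end`
#'   (non-overlapping spans).
#' @param dispensings table with `person_id`, `substance`, `date`.
#' @param diagnoses table with `person_id`, `code`, `date`.
#' @param code_lists see [default_code_lists()].
#' @param study_window length-2 vector of dates; default July 1 1999 to
#'   December 31 2010. Configurable per database by calling once per
#'   database subset.
#' @param min_age minimum age in years at entry.
#' @param lookback_days clean lookback length (365 days = "12 months").
#' @return `data.table` with one row per cohort member: `person_id`,
#'   `entry_date`, `exit_date`, `exit_reason` (one of `study_end`, `IS`,
#'   `disenrollment`, `cancer`, `death`).
#' @export
build_cohort <- function(persons, enrollment, dispensings, diagnoses,
                         code_lists = default_code_lists(),
                         study_window = c("1999-07-01", "2010-12-31"),
                         min_age = 18, lookback_days = 365L) {
  check_columns(persons, c("person_id", "birthdate"), "persons")
  check_columns(enrollment, c("person_id", "start", "end"), "enrollment")
  check_columns(dispensings, c("person_id", "substance", "date"),
                "dispensings")
  check_columns(diagnoses, c("person_id", "code", "date"), "diagnoses")
  w0 <- as_date(study_window[1]); w1 <- as_date(study_window[2])
  enr <- as.data.table(enrollment)
  setorder(enr, person_id, start)
  overlap <- enr[, any(start <= shift(end, type = "lag"), na.rm = TRUE),
                 by = person_id][V1 == TRUE]
  if (nrow(overlap) > 0L) {
    stop("overlapping enrollment spans for person(s): ",
         paste(head(overlap$person_id, 5), collapse = ", "), call. = FALSE)
  }

  disp <- as.data.table(dispensings)
  nsaid <- disp[startsWith(substance, code_lists$nsaid_atc_prefix),
                .(person_id, date)]
  if (nrow(nsaid) == 0L) {
    return(data.table(person_id = character(),
                      entry_date = as.Date(character()),
                      exit_date = as.Date(character()),
                      exit_reason = character()))
  }
  dx <- as.data.table(diagnoses)
  cancer_codes <- setdiff(code_lists$cancer, code_lists$nmsc)

  cand <- nsaid[date >= w0 & date <= w1]
  cand <- merge(cand, as.data.table(persons)[, .(person_id, birthdate)],
                by = "person_id")
  cand[, age_ok := age_years(date, birthdate) >= min_age]
  cand[, lb := date - lookback_days]
  ## continuous enrolment: one span covering [entry - lookback, entry]
  cand[, span_ok := !is.na(
    enr[cand, on = .(person_id, start <= lb, end >= date),
        mult = "first", which = TRUE])]
  ## NSAID-free lookback [entry - 365, entry - 1]
  cand[, d1 := date - 1L]
  cand[, prior_nsaid := !is.na(
    nsaid[cand, on = .(person_id, date >= lb, date <= d1),
          mult = "first", which = TRUE])]
  ## cancer-free lookback (non-melanoma skin cancer exempt)
  cadx <- dx[code %in% cancer_codes, .(person_id, date)]
  cand[, prior_cancer := !is.na(
    cadx[cand, on = .(person_id, date >= lb, date <= d1),
         mult = "first", which = TRUE])]
  cand <- cand[age_ok & span_ok & !prior_nsaid & !prior_cancer]
  if (nrow(cand) == 0L) {
    return(data.table(person_id = character(),
                      entry_date = as.Date(character()),
                      exit_date = as.Date(character()),
                      exit_reason = character()))
  }
  setorder(cand, person_id, date)
  entry <- cand[!duplicated(person_id), .(person_id, entry_date = date)]

  compute_exit(entry, enr, dx, code_lists, w1)
}

#' Determine cohort exit date and reason
#'
#' Exit is the earliest of: end of study period, first ischemic stroke
#' diagnosis on/after entry, end of the enrollment span containing entry
#' (disenrollment/interruption), first malignant cancer diagnosis
#' (non-melanoma skin cancer exempt), or death. Date ties are broken with
#' priority IS > death > cancer > disenrollment > study end.
#'
#' @param entry `data.table` with `person_id`, `entry_date`.
#' @param enrollment enrollment spans.
#' @param diagnoses diagnosis records.
#' @param code_lists see [default_code_lists()].
#' @param study_end end of the study period (date).
#' @return `data.table` with `person_id`, `entry_date`, `exit_date`,
#'   `exit_reason`.
#' @export
compute_exit <- function(entry, enrollment, diagnoses,
                         code_lists = default_code_lists(),
                         study_end = as.Date("2010-12-31")) {
  study_end <- as_date(study_end)
  entry <- as.data.table(entry)
  enr <- as.data.table(enrollment)
  dx <- as.data.table(diagnoses)
  cancer_codes <- setdiff(code_lists$cancer, code_lists$nmsc)

  first_on_after <- function(codes) {
    h <- dx[code %in% codes, .(person_id, date)]
    res <- h[entry, on = .(person_id, date >= entry_date),
             .(d = min(x.date)), by = .EACHI]
    res$d
  }
  out <- copy(entry)
  out[, is_day := first_on_after(code_lists$is)]
  out[, death_day := first_on_after(code_lists$death)]
  out[, cancer_day := first_on_after(cancer_codes)]
  ## end of the span containing entry
  span_end <- enr[entry, on = .(person_id, start <= entry_date,
                                end >= entry_date),
                  .(d = x.end), mult = "first"]
  out[, span_end := span_end$d]

  ## earliest cause, ties broken by priority IS > death > cancer >
  ## disenrollment > study_end (columns listed in priority order)
  cause <- list(
    as.numeric(out$is_day), as.numeric(out$death_day),
    as.numeric(out$cancer_day), as.numeric(out$span_end),
    rep(as.numeric(study_end), nrow(out))
  )
  reasons <- c("IS", "death", "cancer", "disenrollment", "study_end")
  exit_num <- do.call(pmin, c(cause, list(na.rm = TRUE)))
  reason_idx <- rep(NA_integer_, nrow(out))
  for (j in rev(seq_along(cause))) {  # low priority first, high overwrites
    hitj <- !is.na(cause[[j]]) & cause[[j]] == exit_num
    reason_idx[hitj] <- j
  }
  out[, exit_date := as.Date(exit_num, origin = "1970-01-01")]
  out[, exit_reason := reasons[reason_idx]]
  out[, c("is_day", "death_day", "cancer_day", "span_end") := NULL]
  out[]
}
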