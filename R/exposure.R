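## Exposure conventions (whole days, closed intervals):
##  * a prescription supplies `duration` days starting at the dispense date,
##    so the last supplied day is start + duration - 1;
##  * "current" at an index date: supply overlaps the index or ended within
##    the 14 days before it, i.e. end >= index - 14;
##  * "recent": latest supply end in [index - 183, index - 15];
##  * "past": latest supply end before index - 183;
##  * two prescriptions are consecutive (one continuous-use episode) when
##    the gap next.start - prev.end is < 14 days.
CURRENT_GRACE_DAYS <- 14L
RECENT_MAX_DAYS    <- 183L
STITCH_GAP_DAYS    <- 14L

#' Build prescription supply episodes from dispensings
#'
#' Each dispensing becomes one supply episode. The recorded prescription
#' duration is used when present; otherwise duration is imputed from the
#' dispensed quantity assuming consumption of one DDD per day.
#'
#' @param dispensings `data.table` with columns `person_id`, `substance`,
#'   `date`, `quantity_ddd` and optionally `recorded_duration` (days, `NA`
#'   when not recorded).
#' @return `data.table` with columns `person_id`, `substance`, `start`,
#'   `end` (last supplied day), `duration` (days), keyed by person,
#'   substance, start.
#' @export
#' @examples
#' d <- data.table::data.table(person_id = "P1", substance = "M01AB05",
#'   date = as.Date("2001-03-01"), quantity_ddd = 30,
#'   recorded_duration = NA_real_)
#' prescription_episodes(d)  # ends 2001-03-30
prescription_episodes <- function(dispensings) {
  check_columns(dispensings, c("person_id", "substance", "date", "quantity_ddd"),
                "dispensings")
  d <- as.data.table(dispensings)
  if (!"recorded_duration" %in% names(d)) d[, recorded_duration := NA_real_]
  dur <- fifelse(!is.na(d$recorded_duration) & d$recorded_duration > 0,
                 as.numeric(d$recorded_duration), as.numeric(d$quantity_ddd))
  bad <- is.na(dur) | dur <= 0
  if (any(bad)) {
    stop(sprintf(paste0("%d dispensing(s) have neither a positive recorded ",
                        "duration nor a positive quantity"), sum(bad)),
         call. = FALSE)
  }
  ep <- data.table(
    person_id = d$person_id,
    substance = d$substance,
    start = as_date(d$date),
    end = as_date(d$date) + (ceiling(dur) - 1L),
    duration = ceiling(dur)
  )
  setkey(ep, person_id, substance, start)
  ep[]
}

#' Stitch prescription episodes into continuous-use episodes
#'
#' Consecutive prescriptions whose gap (next start minus previous supply
#' end, in days) is less than 14 are merged into one episode of continuous
#' use; overlapping supplies always merge. Stitching can be performed per
#' substance, per drug class (coxib/tNSAID), or over any NSAID.
#'
#' @param episodes prescription episodes from [prescription_episodes()].
#' @param scope `"substance"`, `"class"` or `"any"`.
#' @param catalogue drug catalogue (needed for `scope = "class"`).
#' @param gap_days gap threshold in days; episodes merge when the gap is
#'   strictly less than this (default 14).
#' @return `data.table` with columns `person_id`, `scope`, `substance`
#'   (the substance, class label, or `"any"`), `start`, `end`,
#'   `n_prescriptions`.
#' @export
stitch_episodes <- function(episodes, scope = c("substance", "class", "any"),
                            catalogue = default_drug_catalogue(),
                            gap_days = STITCH_GAP_DAYS) {
  scope <- match.arg(scope)
  check_columns(episodes, c("person_id", "substance", "start", "end"),
                "episodes")
  ep <- as.data.table(episodes)[, .(person_id, substance, start, end)]
  key_col <- switch(scope,
    substance = ep$substance,
    class = drug_class_of(ep$substance, catalogue),
    any = rep("any", nrow(ep))
  )
  ep[, substance := key_col]
  setorder(ep, person_id, substance, start, end)
  ## running maximum of supply ends within person x key identifies chains:
  ## a new continuous-use episode begins when the gap to everything supplied
  ## so far is >= gap_days
  ep[, grp := {
    run_end <- shift(cummax(as.integer(end)), fill = NA_integer_)
    new_ep <- is.na(run_end) | (as.integer(start) - run_end >= gap_days)
    cumsum(new_ep)
  }, by = .(person_id, substance)]
  out <- ep[, .(start = min(start), end = max(end), n_prescriptions = .N),
            by = .(person_id, substance, grp)]
  out[, grp := NULL]
  out[, scope := scope]
  setcolorder(out, c("person_id", "scope", "substance", "start", "end",
                     "n_prescriptions"))
  setorder(out, person_id, substance, start)
  out[]
}

#' Classify exposure state at an index date (one person)
#'
#' A substance is *current* when a supply episode overlaps the index date
#' or ended within the 14 days before it. The any-NSAID state is *current*
#' if any substance is current, otherwise *recent* when the latest supply
#' ended between 15 and 183 days before the index, otherwise *past*.
#'
#' @param episodes prescription (or stitched) episodes for one person:
#'   columns `substance`, `start`, `end`.
#' @param index_date the index date.
#' @return list with elements `state` (`"current"`, `"recent"` or
#'   `"past"`), `current_substances` (character), `current_multiple`
#'   (logical), `recent_any` (logical).
#' @export
classify_exposure <- function(episodes, index_date) {
  index_date <- as_date(index_date)
  ep <- as.data.table(episodes)
  ep <- ep[start <= index_date]
  if (nrow(ep) == 0L) {
    stop("no supply episode starts on or before the index date; ",
         "exposure classification requires a prior dispensing", call. = FALSE)
  }
  cur <- ep[end >= index_date - CURRENT_GRACE_DAYS]
  cur_subst <- sort(unique(cur$substance))
  if (length(cur_subst) > 0L) {
    state <- "current"
    recent <- FALSE
  } else {
    last_end <- max(ep$end)
    recent <- last_end >= index_date - RECENT_MAX_DAYS
    state <- if (recent) "recent" else "past"
  }
  list(state = state,
       current_substances = cur_subst,
       current_multiple = length(cur_subst) >= 2L,
       recent_any = state == "recent")
}

#' Classify exposure state for many subjects at once
#'
#' Vectorised counterpart of [classify_exposure()] used by the analysis
#' pipeline: given prescription episodes and a table of (person, index
#' date) pairs, returns the any-NSAID exposure state and the identity of
#' the single current substance where exactly one is current.
#'
#' @param episodes prescription episodes (all persons) from
#'   [prescription_episodes()].
#' @param subjects `data.table` with columns `person_id`, `index_date`,
#'   plus any id columns to carry through (e.g. `set_id`, `role`).
#' @param catalogue drug catalogue used to attach drug classes.
#' @return copy of `subjects` with columns `state`, `n_current`,
#'   `current_substance` (name, `NA` unless exactly one substance is
#'   current), `current_class` (`coxib`/`tNSAID`/`multiple`/`NA`),
#'   `recent_any`.
#' @export
exposure_at <- function(episodes, subjects,
                        catalogue = default_drug_catalogue()) {
  ep <- as.data.table(episodes)[, .(person_id, substance, start, end)]
  sub <- as.data.table(subjects)
  check_columns(sub, c("person_id", "index_date"), "subjects")
  sub <- copy(sub)
  sub[, idx := as_date(index_date)]
  sub[, cur_lo := idx - CURRENT_GRACE_DAYS]
  sub[, srow := .I]

  ## current substances per subject row
  cur <- ep[sub, on = .(person_id, start <= idx, end >= cur_lo),
            .(row = i.srow, substance = x.substance), nomatch = NULL]
  cur_n <- cur[, .(n_current = uniqueN(substance),
                   current_substance = if (uniqueN(substance) == 1L)
                     substance[1L] else NA_character_),
               by = row]

  ## latest supply end among episodes started on/before index
  le <- ep[sub, on = .(person_id, start <= idx),
           .(last_end = max(x.end)), by = .EACHI]
  sub[, last_end := le$last_end]
  if (anyNA(sub$last_end)) {
    stop(sum(is.na(sub$last_end)),
         " subject(s) have no supply episode on or before their index date",
         call. = FALSE)
  }
  sub[, n_current := 0L]
  sub[, current_substance := NA_character_]
  sub[cur_n$row, `:=`(n_current = cur_n$n_current,
                      current_substance = cur_n$current_substance)]
  sub[, state := fifelse(n_current > 0L, "current",
                 fifelse(last_end >= idx - RECENT_MAX_DAYS, "recent", "past"))]
  sub[, recent_any := state == "recent"]
  ## map ATC code to name and class
  sub[, current_substance := catalogue$name[match(current_substance,
                                                  catalogue$substance)]]
  sub[, current_class := fifelse(
    n_current >= 2L, "multiple",
    fifelse(n_current == 1L,
            fifelse(current_substance %in% coxib_names(), "coxib", "tNSAID"),
            NA_character_))]
  sub[, c("idx", "cur_lo", "last_end", "srow") := NULL]
  sub[]
}

#' Duration category of continuous use
#'
#' Categorises a duration of continuous NSAID use in days into the four
#' study categories: `<7`, `7-29`, `30-89`, `>=90`.
#'
#' @param days positive integer vector of durations in days.
#' @return factor with levels `"<7"`, `"7-29"`, `"30-89"`, `">=90"`.
#' @export
#' @examples
#' duration_category(c(6, 7, 29, 30, 89, 90))
duration_category <- function(days) {
  if (any(days < 1, na.rm = TRUE)) {
    stop("durations must be positive (whole days)", call. = FALSE)
  }
  cut(as.numeric(days), breaks = c(0, 6, 29, 89, Inf),
      labels = c("<7", "7-29", "30-89", ">=90"), right = TRUE)
}

#' Duration of current continuous use at an index date
#'
#' For subjects currently exposed at their index date, returns the length
#' in days of the current continuous-use (any-NSAID) episode, truncated at
#' the index date: future supply cannot contribute to exposure duration at
#' the event.
#'
#' @param stitched any-NSAID continuous-use episodes from
#'   [stitch_episodes()] with `scope = "any"`.
#' @param subjects `data.table` with `person_id`, `index_date`.
#' @return integer vector (NA where no episode is current at the index).
#' @export
current_use_duration <- function(stitched, subjects) {
  st <- as.data.table(stitched)
  sub <- as.data.table(subjects)[, .(person_id, idx = as_date(index_date))]
  sub[, cur_lo := idx - CURRENT_GRACE_DAYS]
  sub[, row := .I]
  hit <- st[sub, on = .(person_id, start <= idx, end >= cur_lo),
            .(row = i.row, start = x.start, end = x.end), nomatch = NULL]
  ## keep the latest current episode per subject (episodes are disjoint, so
  ## at most one can cover the index; ties can only arise via the 14-day
  ## grace tail meeting a new episode start, where the later episode is the
  ## current one)
  setorder(hit, row, -start)
  hit <- hit[!duplicated(row)]
  out <- rep(NA_integer_, nrow(sub))
  out[hit$row] <- as.integer(pmin(hit$end, sub$idx[hit$row]) - hit$start) + 1L
  out
}
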