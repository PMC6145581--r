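#' Baseline ischemic stroke hazard table
#'
#' Per-day baseline hazard of ischemic stroke by sex and age band used by
#' the synthetic claims generator. Defaults rise steeply with age and are
#' ~20% higher in males, broadly matching population stroke incidence in
#' an adult NSAID-initiating population.
#'
#' @param base per-day hazard for the youngest band in females.
#' @param male_ratio multiplicative male-to-female hazard ratio.
#' @param age_breaks lower bounds of the age bands in years.
#' @param multipliers per-band multipliers applied to `base`.
#' @return `data.table` with columns `sex`, `age_lo`, `age_hi`, `hazard`.
#' @export
default_hazard_table <- function(base = 2e-6, male_ratio = 1.2,
                                 age_breaks = c(18, 60, 70, 80),
                                 multipliers = c(1, 4, 8, 15)) {
  stopifnot(length(age_breaks) == length(multipliers))
  bands <- data.table(
    age_lo = age_breaks,
    age_hi = c(age_breaks[-1], 200),
    mult = multipliers
  )
  out <- rbindlist(list(
    bands[, .(sex = "F", age_lo, age_hi, hazard = base * mult)],
    bands[, .(sex = "M", age_lo, age_hi, hazard = base * male_ratio * mult)]
  ))
  out[]
}

#' Default confounder set for the synthetic claims generator
#'
#' Confounders are sampled once per person at baseline and held fixed.
#' Diagnosis-type confounders are materialised as a diagnosis record in
#' the year before the person's first NSAID dispensing; drug-type
#' confounders as a regular stream of co-medication dispensings. The
#' default log rate ratios echo the magnitude of adjusted associations
#' typically reported for these stroke risk factors.
#'
#' @return `data.table` with columns `name`, `kind` (`diagnosis`/`drug`),
#'   `code` (sentinel code emitted in the synthetic records), `prevalence`,
#'   `log_rr` (effect on the stroke hazard), `log_rr_init` (effect on the
#'   NSAID initiation rate, inducing confounding by indication).
#' @export
default_sim_confounders <- function() {
  data.table(
    name = c("stroke", "diabetes", "hypertension", "af_flutter",
             "aspirin_90d", "diuretics_90d"),
    kind = c("diagnosis", "diagnosis", "diagnosis", "diagnosis",
             "drug", "drug"),
    code = c("DX_IS", "DX_DM", "DX_HTN", "DX_AF",
             "RX_ASPIRIN", "RX_DIURETIC"),
    prevalence = c(0.013, 0.08, 0.04, 0.018, 0.15, 0.15),
    log_rr = log(c(2.6, 1.6, 1.15, 1.4, 1.8, 1.1)),
    log_rr_init = c(0, 0.3, 0.3, 0, 0.4, 0.2)
  )
}

#' Configuration of the synthetic claims simulation
#'
#' Bundles and validates every parameter of the generator. All time is in
#' whole days; intervals are closed. One seed fixes all randomness.
#'
#' @param n_persons number of persons.
#' @param study_start,study_end study period (dates).
#' @param databases character vector of database labels; persons are
#'   assigned uniformly.
#' @param drug_catalogue NSAID catalogue, see [default_drug_catalogue()].
#' @param substance_weights optional named sampling weights (by substance
#'   name) for the NSAID chosen at each treatment initiation.
#' @param female_frac probability of female sex.
#' @param age_range age range in years at `study_start` (uniform).
#' @param enrollment_head range of days before `study_start` at which
#'   enrollment begins (uniform integer), guaranteeing a 12-month lookback.
#' @param interruption_prob probability that a person's enrollment is
#'   split by an interruption gap.
#' @param interruption_gap range (days) of the interruption gap.
#' @param initiation_rate per person-day probability of starting a new
#'   NSAID treatment chain while untreated.
#' @param refill_prob probability that a prescription is refilled.
#' @param refill_gap_days integer vector of possible gaps (days) between
#'   the end of one supply and the next dispensing; sampled uniformly.
#' @param quantity_ddd integer vector of possible dispensed quantities in
#'   DDD; sampled uniformly.
#' @param recorded_duration_prob probability a dispensing carries a
#'   recorded duration (set equal to its DDD quantity).
#' @param baseline_hazard per-day stroke hazard: a single number or a
#'   table as from [default_hazard_table()].
#' @param log_rate_ratios named numeric vector of log rate ratios applied
#'   multiplicatively to the baseline hazard: names are
#'   `current_<substance name>` (e.g. `current_diclofenac`),
#'   `recent_any`, and `current_multiple`. Missing states have log RR 0.
#' @param confounders confounder table, see [default_sim_confounders()].
#' @param disenrollment_rate,cancer_rate,death_rate per person-day
#'   probabilities of the respective censoring events.
#' @param comed_interval_days dispensing cadence (days) of drug-type
#'   confounder co-medication.
#' @param seed integer seed fixing all randomness of the simulation.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_persons = 2000,
                       study_start = "2001-01-01",
                       study_end = "2004-12-31",
                       databases = "DB1",
                       drug_catalogue = default_drug_catalogue(),
                       substance_weights = NULL,
                       female_frac = 0.5,
                       age_range = c(25, 85),
                       enrollment_head = c(400, 1500),
                       interruption_prob = 0,
                       interruption_gap = c(30, 180),
                       initiation_rate = 1 / 400,
                       refill_prob = 0.6,
                       refill_gap_days = 0:20,
                       quantity_ddd = 30,
                       recorded_duration_prob = 0.2,
                       baseline_hazard = default_hazard_table(),
                       log_rate_ratios = c(recent_any = 0),
                       confounders = default_sim_confounders(),
                       disenrollment_rate = 0,
                       cancer_rate = 0,
                       death_rate = 0,
                       comed_interval_days = 75,
                       seed = 1L) {
  cfg <- list(
    n_persons = as.integer(n_persons),
    study_start = as_date(study_start), study_end = as_date(study_end),
    databases = databases,
    drug_catalogue = as.data.table(drug_catalogue),
    substance_weights = substance_weights,
    female_frac = female_frac, age_range = age_range,
    enrollment_head = as.integer(enrollment_head),
    interruption_prob = interruption_prob,
    interruption_gap = as.integer(interruption_gap),
    initiation_rate = initiation_rate,
    refill_prob = refill_prob,
    refill_gap_days = as.integer(refill_gap_days),
    quantity_ddd = as.integer(quantity_ddd),
    recorded_duration_prob = recorded_duration_prob,
    baseline_hazard = if (is.numeric(baseline_hazard) &&
                          length(baseline_hazard) == 1L) {
      data.table(sex = rep(c("F", "M"), each = 1L), age_lo = 0,
                 age_hi = 200, hazard = baseline_hazard)
    } else as.data.table(baseline_hazard),
    log_rate_ratios = log_rate_ratios,
    confounders = as.data.table(confounders),
    disenrollment_rate = disenrollment_rate,
    cancer_rate = cancer_rate, death_rate = death_rate,
    comed_interval_days = as.integer(comed_interval_days),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(female_frac = cfg$female_frac,
             interruption_prob = cfg$interruption_prob,
             initiation_rate = cfg$initiation_rate,
             refill_prob = cfg$refill_prob,
             recorded_duration_prob = cfg$recorded_duration_prob,
             disenrollment_rate = cfg$disenrollment_rate,
             cancer_rate = cfg$cancer_rate, death_rate = cfg$death_rate)
  bad <- probs < 0 | probs > 1 | !is.finite(probs)
  if (any(bad)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  if (!cfg$study_start < cfg$study_end) {
    stop("study_start must precede study_end", call. = FALSE)
  }
  if (cfg$n_persons < 0L) stop("n_persons must be >= 0", call. = FALSE)
  if (any(cfg$drug_catalogue$ddd_per_unit <= 0)) {
    stop("every substance must have DDD-per-unit > 0", call. = FALSE)
  }
  if (any(cfg$quantity_ddd <= 0)) {
    stop("quantity_ddd values must be positive", call. = FALSE)
  }
  if (any(cfg$refill_gap_days < 0)) {
    stop("refill_gap_days must be non-negative", call. = FALSE)
  }
  if (any(cfg$baseline_hazard$hazard < 0) ||
      any(cfg$baseline_hazard$hazard > 1)) {
    stop("baseline hazards must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$confounders$prevalence < 0 | cfg$confounders$prevalence > 1)) {
    stop("confounder prevalences must lie in [0, 1]", call. = FALSE)
  }
  ## probability overflow: worst-case per-day event probability must be <= 1
  max_lp <- sum(pmax(cfg$confounders$log_rr, 0)) +
    max(c(cfg$log_rate_ratios, 0))
  if (max(cfg$baseline_hazard$hazard) * exp(max_lp) > 1) {
    stop("baseline hazard times the largest rate-ratio product exceeds 1 ",
         "(per-day event probability overflow)", call. = FALSE)
  }
  if (length(cfg$seed) != 1L || is.na(cfg$seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  invisible(cfg)
}

#' Generate the synthetic population
#'
#' Draws persons (id, database, sex, birthdate), enrollment spans, and
#' fixed baseline confounder indicators. Enrollment always begins at least
#' `enrollment_head[1]` days before the study start so that a 12-month
#' clean lookback is available; with probability `interruption_prob` the
#' enrollment is split by a gap.
#'
#' @param config a [sim_config()].
#' @return list with `persons` (`person_id`, `database`, `sex`,
#'   `birthdate`, plus one 0/1 column per confounder) and `enrollment`
#'   (`person_id`, `start`, `end`).
#' @export
generate_population <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_persons
  if (n == 0L) {
    return(list(
      persons = data.table(person_id = character(), database = character(),
                           sex = character(), birthdate = as.Date(character())),
      enrollment = data.table(person_id = character(),
                              start = as.Date(character()),
                              end = as.Date(character()))
    ))
  }
  persons <- data.table(
    person_id = sprintf("P%07d", seq_len(n)),
    database = sample(config$databases, n, replace = TRUE),
    sex = fifelse(runif(n) < config$female_frac, "F", "M"),
    birthdate = config$study_start -
      as.integer(round(runif(n, config$age_range[1], config$age_range[2]) *
                       DAYS_PER_YEAR))
  )
  ## confounder flags
  for (k in seq_len(nrow(config$confounders))) {
    persons[, (config$confounders$name[k]) :=
      rbinom(n, 1L, config$confounders$prevalence[k])]
  }
  ## enrollment: start before the study, end by disenrollment or open-ended
  head_days <- config$enrollment_head
  enr_start <- config$study_start -
    sample(seq(head_days[1], head_days[2]), n, replace = TRUE)
  if (config$disenrollment_rate > 0) {
    enr_end <- enr_start + rgeom(n, config$disenrollment_rate)
  } else {
    enr_end <- rep(config$study_end + 365L, n)
  }
  enr_end <- pmin(enr_end, config$study_end + 365L)
  enr_end <- pmax(enr_end, enr_start)  # degenerate but valid single-day span
  enrollment <- data.table(person_id = persons$person_id,
                           start = enr_start, end = enr_end)
  ## optional interruption: split the span by a gap at a random cut point
  if (config$interruption_prob > 0) {
    split_it <- runif(n) < config$interruption_prob &
      as.integer(enr_end - enr_start) > 800L
    if (any(split_it)) {
      idx <- which(split_it)
      cut_at <- enr_start[idx] + 400L +
        as.integer(runif(length(idx)) *
                   (as.numeric(enr_end[idx] - enr_start[idx]) - 800))
      gap_len <- sample(seq(config$interruption_gap[1],
                            config$interruption_gap[2]),
                        length(idx), replace = TRUE)
      first_half <- data.table(person_id = persons$person_id[idx],
                               start = enr_start[idx], end = cut_at)
      second_half <- data.table(person_id = persons$person_id[idx],
                                start = cut_at + gap_len + 1L,
                                end = enr_end[idx])
      second_half <- second_half[start <= end]
      enrollment <- rbindlist(list(
        enrollment[!split_it], first_half, second_half))
    }
  }
  setorder(enrollment, person_id, start)
  list(persons = persons, enrollment = enrollment)
}

#' Generate synthetic drug dispensings
#'
#' While untreated (and after an initial 365-day clean period following
#' enrollment start), each person starts a new NSAID treatment chain with
#' a per-day probability equal to `initiation_rate` scaled by
#' `exp(sum of the person's confounder log_rr_init)` — this induces
#' confounding by indication. A chain dispenses one substance; each
#' dispensing is refilled with probability `refill_prob` after a gap drawn
#' from `refill_gap_days`. Drug-type confounders additionally emit a
#' regular stream of co-medication dispensings. All dispensings falling
#' outside an enrollment span are dropped.
#'
#' @param population output of [generate_population()].
#' @param config a [sim_config()].
#' @return `data.table` with columns `person_id`, `substance` (ATC code),
#'   `date`, `quantity_ddd`, `recorded_duration`.
#' @export
generate_dispensings <- function(population, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  persons <- population$persons
  enrollment <- population$enrollment
  n <- nrow(persons)
  empty <- data.table(person_id = character(), substance = character(),
                      date = as.Date(character()), quantity_ddd = numeric(),
                      recorded_duration = numeric())
  if (n == 0L || config$initiation_rate == 0) return(empty)

  spans <- enrollment[, .(first_start = min(start), last_end = max(end)),
                      by = person_id]
  st <- merge(persons[, .(person_id)], spans, by = "person_id", sort = FALSE)
  ## initiations cannot begin before a full clean lookback exists, nor
  ## before the study start (earlier use would block cohort entry)
  st[, cur := pmax(first_start + 365L, config$study_start)]
  st[, wend := pmin(last_end, config$study_end)]

  ## per-person initiation rate with confounding by indication
  init_lp <- rep(0, n)
  conf <- config$confounders
  for (k in seq_len(nrow(conf))) {
    if (conf$log_rr_init[k] != 0) {
      init_lp <- init_lp + persons[[conf$name[k]]] * conf$log_rr_init[k]
    }
  }
  rate <- pmin(config$initiation_rate * exp(init_lp), 1)

  cat_codes <- config$drug_catalogue$substance
  wts <- if (is.null(config$substance_weights)) {
    rep(1, length(cat_codes))
  } else {
    w <- config$substance_weights[match(config$drug_catalogue$name,
                                        names(config$substance_weights))]
    w[is.na(w)] <- 0
    as.numeric(w)
  }
  wts <- wts / sum(wts)

  chunks <- list()
  active <- which(st$cur <= st$wend & rate > 0)
  cur <- as.integer(st$cur)
  wend <- as.integer(st$wend)
  guard <- 0L
  while (length(active) > 0L && guard < 10000L) {
    guard <- guard + 1L
    na <- length(active)
    ## waiting time to next initiation
    gap0 <- rgeom(na, rate[active])
    init_day <- cur[active] + gap0
    ok <- init_day <= wend[active]
    active <- active[ok]
    if (length(active) == 0L) break
    day <- init_day[ok]
    ## one substance per chain
    sub_i <- sample.int(length(cat_codes), length(active), replace = TRUE,
                        prob = wts)
    ## refill chain, vectorised over persons still refilling
    chain_active <- seq_along(active)
    d <- day
    repeat {
      qty <- config$quantity_ddd[
        sample.int(length(config$quantity_ddd), length(chain_active),
                   replace = TRUE)]
      rec <- fifelse(runif(length(chain_active)) <
                       config$recorded_duration_prob,
                     as.numeric(qty), NA_real_)
      chunks[[length(chunks) + 1L]] <- data.table(
        pidx = active[chain_active],
        substance = cat_codes[sub_i[chain_active]],
        day = d,
        quantity_ddd = as.numeric(qty),
        recorded_duration = rec
      )
      supply_end <- d + as.integer(ceiling(fifelse(is.na(rec),
                                                   as.numeric(qty), rec))) - 1L
      refill <- runif(length(chain_active)) < config$refill_prob
      nxt <- supply_end + 1L +
        config$refill_gap_days[sample.int(length(config$refill_gap_days),
                                          length(chain_active),
                                          replace = TRUE)]
      keep_chain <- refill & nxt <= wend[active[chain_active]]
      ## persons whose chain ends resume waiting from the day after supply end
      ended <- chain_active[!keep_chain]
      cur[active[ended]] <- supply_end[!keep_chain] + 1L
      chain_active <- chain_active[keep_chain]
      if (length(chain_active) == 0L) break
      d <- nxt[keep_chain]
    }
    active <- active[cur[active] <= wend[active]]
  }

  disp <- if (length(chunks) > 0L) rbindlist(chunks) else
    data.table(pidx = integer(), substance = character(), day = integer(),
               quantity_ddd = numeric(), recorded_duration = numeric())
  disp[, person_id := persons$person_id[pidx]]
  disp[, date := as.Date(day, origin = "1970-01-01")]

  ## co-medication streams for drug-type confounders
  comed <- list()
  drug_conf <- conf[kind == "drug"]
  if (nrow(drug_conf) > 0L && nrow(disp) > 0L) {
    fd <- disp[, .(first_disp = min(date)), by = person_id]
    fd <- merge(fd, spans, by = "person_id")
    for (k in seq_len(nrow(drug_conf))) {
      flagged <- persons[persons[[drug_conf$name[k]]] == 1L, .(person_id)]
      ppl <- merge(fd, flagged, by = "person_id")
      if (nrow(ppl) == 0L) next
      ppl[, from := pmax(first_start, first_disp - 365L)]
      ppl[, to := pmin(last_end, config$study_end)]
      ppl <- ppl[from <= to]
      if (nrow(ppl) == 0L) next
      reps <- as.integer(as.numeric(ppl$to - ppl$from) %/%
                           config$comed_interval_days) + 1L
      comed[[length(comed) + 1L]] <- data.table(
        person_id = rep(ppl$person_id, reps),
        substance = drug_conf$code[k],
        date = as.Date(unlist(Map(function(f, r)
          f + config$comed_interval_days * (seq_len(r) - 1L),
          as.integer(ppl$from), reps)), origin = "1970-01-01"),
        quantity_ddd = as.numeric(config$comed_interval_days),
        recorded_duration = NA_real_
      )
    }
  }
  out <- rbindlist(c(
    list(disp[, .(person_id, substance, date, quantity_ddd,
                  recorded_duration)]),
    comed), use.names = TRUE)

  ## enforce: no dispensing outside an enrollment span
  if (nrow(out) > 0L) {
    inside <- !is.na(enrollment[out, on = .(person_id, start <= date,
                                            end >= date),
                                mult = "first", which = TRUE])
    out <- out[inside]
  }
  setorder(out, person_id, date, substance)
  out[]
}

#' Simulate ischemic stroke events and censoring diagnoses
#'
#' Each person becomes at risk at their first NSAID dispensing. The
#' per-day event probability is the baseline hazard for the person's sex
#' and current age band multiplied by `exp(` the sum of the log rate
#' ratios of the day's exposure state and of the person's confounders `)`.
#' Exposure states are derived with the same episode algebra used by the
#' analysis ([prescription_episodes()] and the current/recent/past
#' windows), so parameter recovery is a well-posed test of the estimator.
#' Death and cancer are independent per-day censoring processes emitted as
#' sentinel diagnosis codes (`DX_DEATH`, `DX_CANCER`); diagnosis-type
#' confounder flags are materialised as a record in the year before the
#' first dispensing; the first stroke is emitted as a hospital discharge
#' diagnosis (`DX_IS`).
#'
#' @param population output of [generate_population()].
#' @param dispensings output of [generate_dispensings()].
#' @param config a [sim_config()].
#' @return `data.table` of diagnoses: `person_id`, `code`, `date`,
#'   `setting`.
#' @export
simulate_events <- function(population, dispensings, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  persons <- population$persons
  enrollment <- population$enrollment
  empty <- data.table(person_id = character(), code = character(),
                      date = as.Date(character()), setting = character())
  if (nrow(persons) == 0L) return(empty)
  conf <- config$confounders

  spans <- enrollment[, .(first_start = min(start), last_end = max(end)),
                      by = person_id]
  pp <- merge(persons, spans, by = "person_id", sort = FALSE)

  ## censoring draws over the whole enrollment
  pp[, death_day := if (config$death_rate > 0)
    first_start + rgeom(.N, config$death_rate) else as.Date(NA)]
  pp[, cancer_day := if (config$cancer_rate > 0)
    first_start + rgeom(.N, config$cancer_rate) else as.Date(NA)]
  pp[, death_day := fifelse(!is.na(death_day) & death_day <= last_end,
                            death_day, as.Date(NA))]
  pp[, cancer_day := fifelse(!is.na(cancer_day) & cancer_day <= last_end,
                             cancer_day, as.Date(NA))]

  diag_chunks <- list()
  if (any(!is.na(pp$death_day))) {
    diag_chunks[["death"]] <- pp[!is.na(death_day),
      .(person_id, code = "DX_DEATH", date = death_day,
        setting = "hospital")]
  }
  if (any(!is.na(pp$cancer_day))) {
    diag_chunks[["cancer"]] <- pp[!is.na(cancer_day),
      .(person_id, code = "DX_CANCER", date = cancer_day,
        setting = "hospital")]
  }

  nsaid <- as.data.table(dispensings)[startsWith(substance, "M01A")]
  if (nrow(nsaid) > 0L) {
    ## person-level confounder linear predictor on the hazard
    conf_lp <- rep(0, nrow(pp))
    for (k in seq_len(nrow(conf))) {
      conf_lp <- conf_lp + pp[[conf$name[k]]] * conf$log_rr[k]
    }
    pp[, conf_lp := conf_lp]

    fd <- nsaid[, .(first_disp = min(date)), by = person_id]
    risk <- merge(pp, fd, by = "person_id")
    risk[, risk_end := pmin(last_end, config$study_end)]
    risk[!is.na(death_day), risk_end := pmin(risk_end, death_day)]
    risk[!is.na(cancer_day), risk_end := pmin(risk_end, cancer_day)]
    risk <- risk[first_disp <= risk_end]

    ## confounder history: diagnosis-type flags become a record in the
    ## year before the first dispensing
    dx_conf <- conf[kind == "diagnosis"]
    for (k in seq_len(nrow(dx_conf))) {
      flagged <- risk[risk[[dx_conf$name[k]]] == 1L,
                      .(person_id, first_disp, first_start)]
      if (nrow(flagged) == 0L) next
      back <- 1L + as.integer(runif(nrow(flagged)) * 365)
      dxd <- pmax(flagged$first_disp - back, flagged$first_start)
      diag_chunks[[paste0("conf_", k)]] <- data.table(
        person_id = flagged$person_id, code = dx_conf$code[k],
        date = dxd, setting = "ambulatory")
    }

    events <- simulate_first_events(risk, nsaid, config)
    if (nrow(events) > 0L) {
      diag_chunks[["is"]] <- events[, .(person_id, code = "DX_IS",
                                        date = event_day,
                                        setting = "hospital")]
    }
  }

  out <- rbindlist(diag_chunks, use.names = TRUE)
  if (nrow(out) == 0L) return(empty)
  ## keep every record inside an enrollment span
  inside <- !is.na(enrollment[out, on = .(person_id, start <= date,
                                          end >= date),
                              mult = "first", which = TRUE])
  out <- out[inside]
  setorder(out, person_id, date, code)
  out[]
}

## piecewise-constant hazard simulation of the first stroke per person.
## Exposure state changes only at stitched-episode boundaries (start,
## supply end + 15, supply end + 184) and at age-band crossings, so within
## a segment the waiting time is geometric. Stitched (continuous-use)
## substance episodes determine the state exactly: a substance is current
## on [start, end + 14] of a stitched episode (interior gaps are < 14 days
## by construction), and the latest any-NSAID supply end equals the latest
## stitched end. All day arithmetic is on integers for speed.
simulate_first_events <- function(risk, nsaid, config) {
  ep0 <- prescription_episodes(nsaid)
  ep0 <- ep0[risk[, .(person_id)], on = "person_id", nomatch = NULL]
  st <- stitch_episodes(ep0, scope = "substance")
  ep <- data.table(person_id = st$person_id, substance = st$substance,
                   start = as.integer(st$start), end = as.integer(st$end))
  rk <- data.table(person_id = risk$person_id,
                   first_disp = as.integer(risk$first_disp),
                   risk_end = as.integer(risk$risk_end),
                   birth = as.integer(risk$birthdate),
                   sex = risk$sex, conf_lp = risk$conf_lp)

  ## breakpoints (integer days)
  bp <- rbindlist(list(
    rk[, .(person_id, day = first_disp)],
    ep[, .(person_id, day = start)],
    ep[, .(person_id, day = end + 15L)],
    ep[, .(person_id, day = end + 184L)]
  ))
  ## age-band crossings inside the risk window
  hz <- as.data.table(config$baseline_hazard)
  for (e in sort(unique(hz$age_lo))) {
    bp <- rbindlist(list(bp,
      rk[, .(person_id, day = birth + as.integer(round(e * DAYS_PER_YEAR)))]))
  }
  bp <- rk[bp, on = "person_id"][day >= first_disp & day <= risk_end]
  bp <- unique(bp, by = c("person_id", "day"))
  setorder(bp, person_id, day)
  bp[, seg_end := shift(day, type = "lead") - 1L, by = person_id]
  bp[is.na(seg_end), seg_end := risk_end]
  setnames(bp, "day", "seg_start")
  bp[, len := seg_end - seg_start + 1L]
  bp <- bp[len > 0L]
  bp[, srow := .I]

  ## exposure state at each segment start
  lrr <- config$log_rate_ratios
  bp[, cur_lo := seg_start - CURRENT_GRACE_DAYS]
  cur <- ep[bp, on = .(person_id, start <= seg_start, end >= cur_lo),
            .(srow = i.srow, substance = x.substance), nomatch = NULL]
  cur <- unique(cur, by = c("srow", "substance"))
  cur_agg <- cur[, .(n_current = .N, one_sub = substance[1L]), by = srow]
  le <- ep[bp, on = .(person_id, start <= seg_start),
           .(last_end = max(x.end)), by = .EACHI]
  bp[, last_end := le$last_end]
  bp[, n_current := 0L]
  bp[, one_sub := NA_character_]
  bp[cur_agg$srow, `:=`(n_current = cur_agg$n_current,
                        one_sub = cur_agg$one_sub)]
  name_of <- setNames(config$drug_catalogue$name,
                      config$drug_catalogue$substance)
  lrr_of <- function(key) {
    v <- unname(lrr[key])
    fifelse(is.na(v), 0, as.numeric(v))
  }
  bp[, state_lp := 0]
  bp[n_current >= 2L, state_lp := lrr_of(rep("current_multiple", .N))]
  bp[n_current == 1L,
     state_lp := lrr_of(paste0("current_", name_of[one_sub]))]
  bp[n_current == 0L & !is.na(last_end) &
       last_end >= seg_start - RECENT_MAX_DAYS,
     state_lp := lrr_of(rep("recent_any", .N))]

  ## baseline hazard by sex and age band at segment start
  bp[, age := (seg_start - birth) / DAYS_PER_YEAR]
  bp <- hz[bp, on = .(sex, age_lo <= age, age_hi > age),
           .(person_id = i.person_id, seg_start = i.seg_start, len = i.len,
             conf_lp = i.conf_lp, state_lp = i.state_lp, hazard = x.hazard)]
  if (anyNA(bp$hazard)) {
    stop("baseline hazard table does not cover all ages in the population",
         call. = FALSE)
  }
  bp[, p_day := hazard * exp(conf_lp + state_lp)]
  if (any(bp$p_day > 1)) {
    stop("per-day event probability exceeds 1; reduce the baseline hazard ",
         "or the rate ratios", call. = FALSE)
  }

  setorder(bp, person_id, seg_start)
  ## geometric waiting time within each constant-hazard segment; zero
  ## hazard or astronomically long waits (integer overflow in rgeom)
  ## both mean "no event in this segment"
  g <- rep(NA_real_, nrow(bp))
  pos <- bp$p_day > 0
  g[pos] <- suppressWarnings(rgeom(sum(pos), bp$p_day[pos]))
  bp[, event_day := fifelse(!is.na(g) & g <= len - 1L,
                            seg_start + as.integer(g), NA_integer_)]
  hits <- bp[!is.na(event_day)]
  if (nrow(hits) == 0L) {
    return(data.table(person_id = character(),
                      event_day = as.Date(character())))
  }
  ev <- hits[, .(event_day = min(event_day)), by = person_id]
  ev[, event_day := as.Date(event_day, origin = "1970-01-01")]
  ev[]
}

#' Run the complete synthetic claims simulation
#'
#' Convenience wrapper chaining [generate_population()],
#' [generate_dispensings()] and [simulate_events()].
#'
#' @param config a [sim_config()].
#' @return list of class `sim_claims` with elements `persons`,
#'   `enrollment`, `dispensings`, `diagnoses`, `config`.
#' @export
#' @examples
#' cl <- simulate_claims(sim_config(n_persons = 50, seed = 7))
#' lapply(cl[1:4], nrow)
simulate_claims <- function(config) {
  pop <- generate_population(config)
  disp <- generate_dispensings(pop, config)
  dx <- simulate_events(pop, disp, config)
  structure(list(persons = pop$persons, enrollment = pop$enrollment,
                 dispensings = disp, diagnoses = dx, config = config),
            class = "sim_claims")
}

#' Write or read the four claims CSV files
#'
#' The on-disk interchange format: `persons.csv`
#' (person_id,database,sex,birthdate), `enrollment.csv`
#' (person_id,start,end), `dispensings.csv`
#' (person_id,substance,date,quantity_ddd,recorded_duration),
#' `diagnoses.csv` (person_id,code,date,setting). Dates are ISO-8601.
#'
#' @param claims a `sim_claims` list (or any list with those elements).
#' @param dir directory to write to / read from (created if needed).
#' @return `write_claims` returns `dir` invisibly; `read_claims` returns a
#'   list with the four tables.
#' @export
write_claims <- function(claims, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fwrite(claims$persons[, .(person_id, database, sex, birthdate)],
         file.path(dir, "persons.csv"))
  fwrite(claims$enrollment, file.path(dir, "enrollment.csv"))
  fwrite(claims$dispensings, file.path(dir, "dispensings.csv"))
  fwrite(claims$diagnoses, file.path(dir, "diagnoses.csv"))
  invisible(dir)
}

#' @rdname write_claims
#' @export
read_claims <- function(dir) {
  rd <- function(f, datecols, numcols = NULL) {
    x <- fread(file.path(dir, f))
    for (cc in datecols) x[, (cc) := as_date(get(cc))]
    for (cc in numcols) x[, (cc) := as.numeric(get(cc))]
    x
  }
  list(persons = rd("persons.csv", "birthdate"),
       enrollment = rd("enrollment.csv", c("start", "end")),
       dispensings = rd("dispensings.csv", "date",
                        c("quantity_ddd", "recorded_duration")),
       diagnoses = rd("diagnoses.csv", "date"))
}
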