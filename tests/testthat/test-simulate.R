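test_that("configuration is validated", {
  expect_error(sim_config(female_frac = 1.4), "probabilities")
  expect_error(sim_config(study_start = "2005-01-01",
                          study_end = "2001-01-01"), "precede")
  expect_error(sim_config(quantity_ddd = 0), "positive")
  cat0 <- default_drug_catalogue()
  cat0$ddd_per_unit[1] <- 0
  expect_error(sim_config(drug_catalogue = cat0), "DDD-per-unit")
  ## per-day probability overflow
  expect_error(sim_config(baseline_hazard = 0.9,
                          log_rate_ratios = c(recent_any = 3)),
               "overflow")
})

test_that("an empty population yields empty tables", {
  cfg <- sim_config(n_persons = 0, seed = 3)
  cl <- simulate_claims(cfg)
  expect_equal(nrow(cl$persons), 0L)
  expect_equal(nrow(cl$dispensings), 0L)
  expect_equal(nrow(cl$diagnoses), 0L)
})

test_that("the seed fixes every table exactly", {
  cfg <- small_sim_config(seed = 99)
  a <- simulate_claims(cfg)
  b <- simulate_claims(cfg)
  expect_identical(a$persons, b$persons)
  expect_identical(a$enrollment, b$enrollment)
  expect_identical(a$dispensings, b$dispensings)
  expect_identical(a$diagnoses, b$diagnoses)
  ## a different seed changes the data
  c2 <- simulate_claims(small_sim_config(seed = 100))
  expect_false(identical(a$dispensings, c2$dispensings))
})

test_that("sex is drawn at the configured fraction", {
  cfg <- sim_config(n_persons = 1000, female_frac = 0.5, seed = 5)
  pop <- generate_population(cfg)
  obs <- mean(pop$persons$sex == "F")
  expect_lt(abs(obs - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("no initiation means no dispensings; no refills means spaced fills", {
  cfg <- small_sim_config(seed = 6, initiation_rate = 0)
  pop <- generate_population(cfg)
  expect_equal(nrow(generate_dispensings(pop, cfg)), 0L)

  ## refill_prob = 0: each chain is a single fill, so consecutive NSAID
  ## dispensings of a person are separated by at least the supply length
  cfg2 <- sim_config(n_persons = 300, seed = 6, refill_prob = 0,
                     quantity_ddd = 30,
                     confounders = default_sim_confounders()[kind == "diagnosis"])
  pop2 <- generate_population(cfg2)
  d2 <- generate_dispensings(pop2, cfg2)
  gaps <- d2[startsWith(substance, "M01A")][order(person_id, date),
             .(gap = as.integer(diff(date))), by = person_id]
  expect_true(all(gaps$gap >= 30))
})

test_that("records never fall outside enrollment spans", {
  cfg <- small_sim_config(seed = 7, interruption_prob = 0.3,
                          disenrollment_rate = 1 / 2000,
                          death_rate = 1 / 8000, cancer_rate = 1 / 8000)
  cl <- simulate_claims(cfg)
  inside <- function(records) {
    ok <- cl$enrollment[records, on = .(person_id, start <= date,
                                        end >= date),
                        mult = "first", which = TRUE]
    all(!is.na(ok))
  }
  expect_true(inside(cl$dispensings))
  expect_true(inside(cl$diagnoses))
  ## enrollment spans are chronological and non-overlapping
  bad <- cl$enrollment[order(person_id, start),
                       any(start <= shift(end, type = "lag"), na.rm = TRUE),
                       by = person_id][V1 == TRUE]
  expect_equal(nrow(bad), 0L)
})

test_that("a constant 10-day refill gap stitches each chain into one episode", {
  cfg <- sim_config(n_persons = 200, seed = 8, refill_prob = 0.7,
                    refill_gap_days = 10L, quantity_ddd = 30,
                    confounders = default_sim_confounders()[kind == "diagnosis"])
  pop <- generate_population(cfg)
  disp <- generate_dispensings(pop, cfg)[startsWith(substance, "M01A")]
  st <- stitch_episodes(prescription_episodes(disp), scope = "substance")
  ## every inter-fill gap inside a chain is 10 < 14, so the number of
  ## stitched episodes equals the number of chains: consecutive stitched
  ## episodes of one person/substance are separated by >= 14 days
  st[, prev_end := shift(end), by = .(person_id, substance)]
  expect_true(all(st[!is.na(prev_end),
                     as.integer(start - prev_end) >= 14]))
  ## and total fills are conserved
  expect_equal(sum(st$n_prescriptions), nrow(disp))
})

test_that("null event counts follow the configured hazard", {
  p_day <- 1e-4
  cfg <- sim_config(n_persons = 2000, seed = 9, baseline_hazard = p_day,
                    study_start = "2000-01-01", study_end = "2005-12-31",
                    initiation_rate = 1 / 100,
                    confounders = data.table(
                      name = character(), kind = character(),
                      code = character(), prevalence = numeric(),
                      log_rr = numeric(), log_rr_init = numeric()))
  pop <- generate_population(cfg)
  disp <- generate_dispensings(pop, cfg)
  dx <- simulate_events(pop, disp, cfg)
  n_events <- nrow(dx[code == "DX_IS"])
  ## independent expectation: per person at risk from first dispensing to
  ## the end of enrollment/study, P(event) = 1 - (1 - p)^days
  spans <- pop$enrollment[, .(e_end = max(end)), by = person_id]
  fd <- disp[startsWith(substance, "M01A"), .(fd = min(date)), by = person_id]
  rw <- merge(fd, spans, by = "person_id")
  days <- as.integer(pmin(rw$e_end, as.Date("2005-12-31")) - rw$fd) + 1L
  expected <- sum(1 - (1 - p_day)^days)
  expect_lt(abs(n_events - expected), 3 * sqrt(expected))
})

test_that("zero hazard produces no events", {
  ## drop the stroke-history confounder, whose records share the IS code
  cfg <- small_sim_config(seed = 10, baseline_hazard = 0,
                          confounders =
                            default_sim_confounders()[name != "stroke"])
  cl <- simulate_claims(cfg)
  expect_equal(nrow(cl$diagnoses[code == "DX_IS"]), 0L)
})

test_that("a current-use rate ratio shows up in crude person-day incidence", {
  ## single-substance world with a strong effect; the oracle classifies
  ## every at-risk person-day directly from the raw supply episodes
  true_rr <- 2.5
  cfg <- sim_config(
    n_persons = 500, seed = 11, baseline_hazard = 2e-4,
    study_start = "2001-01-01", study_end = "2002-12-31",
    drug_catalogue = default_drug_catalogue()[name == "diclofenac"],
    log_rate_ratios = c(current_diclofenac = log(true_rr)),
    confounders = default_sim_confounders()[0])
  pop <- generate_population(cfg)
  disp <- generate_dispensings(pop, cfg)
  dx <- simulate_events(pop, disp, cfg)
  ep <- prescription_episodes(disp)
  events <- dx[code == "DX_IS", .(person_id, date)]
  spans <- pop$enrollment[, .(e_end = max(end)), by = person_id]

  tally <- c(current = 0, other = 0)
  etally <- c(current = 0, other = 0)
  for (pid in unique(ep$person_id)) {
    e <- ep[person_id == pid]
    d0 <- as.integer(min(e$start))
    ev <- events[person_id == pid]
    d1 <- as.integer(min(spans[person_id == pid, e_end],
                         as.Date("2002-12-31"),
                         if (nrow(ev)) ev$date else as.Date("2100-01-01")))
    days <- d0:d1
    cur <- rep(FALSE, length(days))
    for (k in seq_len(nrow(e))) {
      cur <- cur | (days >= as.integer(e$start[k]) &
                    days <= as.integer(e$end[k]) + 14L)
    }
    tally <- tally + c(sum(cur), sum(!cur))
    if (nrow(ev) == 1L) {
      was_cur <- cur[match(as.integer(ev$date), days)]
      etally <- etally + c(was_cur, !was_cur)
    }
  }
  irr <- (etally["current"] / tally["current"]) /
    (etally["other"] / tally["other"])
  se_log <- sqrt(1 / etally["current"] + 1 / etally["other"])
  expect_lt(abs(log(irr) - log(true_rr)), 3 * se_log)
})

test_that("claims tables round-trip through CSV", {
  cl <- simulate_claims(small_sim_config(seed = 12))
  dir <- tempfile("claims")
  write_claims(cl, dir)
  expect_setequal(list.files(dir), c("persons.csv", "enrollment.csv",
                                     "dispensings.csv", "diagnoses.csv"))
  back <- read_claims(dir)
  expect_equal(back$persons,
               cl$persons[, .(person_id, database, sex, birthdate)])
  expect_equal(back$dispensings, cl$dispensings)
  expect_equal(back$diagnoses, cl$diagnoses)
  unlink(dir, recursive = TRUE)
})
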