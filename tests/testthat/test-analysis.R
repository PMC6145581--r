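## a small simulated study shared across the tests in this file
make_study <- function(seed = 50, databases = "DB1") {
  cl <- simulate_claims(small_sim_config(
    seed = seed, databases = databases,
    log_rate_ratios = c(current_diclofenac = log(1.5))))
  ch <- build_cohort(cl$persons, cl$enrollment, cl$dispensings,
                     cl$diagnoses,
                     study_window = c("2001-01-01", "2003-12-31"))
  eps <- prescription_episodes(cl$dispensings[startsWith(substance, "M01A")])
  cases <- find_cases(ch)
  ms <- suppressMessages(
    sample_matched_sets(cases, ch, cl$persons, n_controls = 10,
                        seed = seed + 1))
  cov <- assess_covariates(ms, ch, cl$diagnoses, cl$dispensings)
  list(claims = cl, cohort = ch, episodes = eps, cases = cases,
       ms = ms, cov = cov)
}

st <- make_study()

test_that("the design matrix codes mutually exclusive exposure states", {
  dsg <- build_design(st$ms, st$episodes, st$cov, model = "class")
  Xe <- dsg$X[, dsg$exposure_cols]
  expect_true(all(rowSums(Xe) <= 1))          # past = all-zero reference
  expect_setequal(dsg$exposure_cols,
                  c("current_coxib", "current_tnsaid", "current_multiple",
                    "recent_any"))
  expect_equal(sum(dsg$y), uniqueN(st$ms$set_id))
  ## substance model has one column per catalogue member
  dsg2 <- build_design(st$ms, st$episodes, model = "substance")
  expect_true(all(paste0("current_", default_drug_catalogue()$name) %in%
                  colnames(dsg2$X)))
})

test_that("report percentages are recomputable from the printed counts", {
  pr <- suppressWarnings(run_primary(st$ms, st$episodes, st$cov))
  rep <- pr$report
  n_cases <- sum(st$ms$role == "case")
  n_controls <- sum(st$ms$role == "control")
  expect_equal(rep$pct_cases, percent_of(rep$n_cases, n_cases))
  expect_equal(rep$pct_controls, percent_of(rep$n_controls, n_controls))
  ## adjusted fit keeps every a-priori covariate
  apri <- intersect(default_covariate_catalogue()[tier == "a_priori", name],
                    colnames(pr$design$X))
  expect_true(all(apri %in% pr$fit_adjusted$or_table$term))
  ## eliminated candidates are all from the candidate tier
  cand <- default_covariate_catalogue()[tier == "candidate", name]
  expect_true(all(pr$elimination$removed %in% cand))
})

test_that("characteristics percentages use report-style rounding", {
  expect_equal(percent_of(24685, 49118), 50.3)
  expect_equal(percent_of(97, 49118), 0.2)
  expect_equal(percent_of(0, 49118), 0)
  expect_true(is.na(percent_of(1, 0)))
  tab <- summarize_characteristics(st$cov)
  expect_true(all(tab$pct_cases >= 0 & tab$pct_cases <= 100, na.rm = TRUE))
  i <- which(tab$characteristic == "diabetes")
  expect_equal(tab$n_cases[i], sum(st$cov[role == "case", diabetes]))
  expect_equal(tab$pct_cases[i],
               percent_of(tab$n_cases[i], sum(st$cov$role == "case")))
})

test_that("pooled sets equal the sum over databases", {
  st2 <- make_study(seed = 60, databases = c("GePaRD", "THIN"))
  pr <- suppressWarnings(
    run_primary(st2$ms, st2$episodes, st2$cov, by_database = TRUE))
  per_db <- sum(vapply(pr$per_database,
                       function(r) r$fit_adjusted$n_sets_used, numeric(1)))
  expect_equal(pr$fit_adjusted$n_sets_used, per_db)
})

test_that("duration analysis uses 7-29 days as reference", {
  da <- suppressWarnings(run_duration_analysis(st$ms, st$episodes, st$cov))
  expect_setequal(da$report$term,
                  c("dur_lt7", "dur_30_89", "dur_ge90", "dur_7_29_reference"))
  expect_false("dur_7_29_reference" %in% da$fit$or_table$term)
  ## relabelling the reference inverts the odds ratio (1:1 toy design)
  X1 <- matrix(c(1, 0, 0, 1, 1, 0, 0, 0), ncol = 1,
               dimnames = list(NULL, "catB"))
  y <- rep(c(1, 0), 4); sets <- rep(1:4, each = 2)
  f1 <- fit_clogit(X1, y, sets)
  f2 <- fit_clogit(1 - X1, y, sets)  # swap reference
  expect_equal(unname(f1$coefficients), -unname(f2$coefficients),
               tolerance = 1e-8)
})

test_that("sex strata keep sets intact; empty strata are reported", {
  sex_of <- merge(st$ms, st$claims$persons[, .(person_id, sex)],
                  by = "person_id", sort = FALSE)
  setorder(sex_of, set_id, role, person_id)
  ms_sorted <- copy(st$ms); setorder(ms_sorted, set_id, role, person_id)
  res <- suppressWarnings(
    run_stratified(ms_sorted, st$episodes, st$cov, sex_of$sex))
  n_used <- sum(vapply(res, function(r) r$n_sets, numeric(1)))
  ## sets are sex-matched, so every modelled set survives stratification
  total <- suppressWarnings(run_primary(ms_sorted, st$episodes,
                                        st$cov))$fit_adjusted$n_sets_used
  expect_equal(n_used, total)

  ## stratifying on a covariate can break sets but never exceeds the total
  dm <- st$cov[ms_sorted, on = c("set_id", "person_id"), diabetes]
  res2 <- suppressWarnings(
    run_stratified(ms_sorted, st$episodes, st$cov, dm))
  expect_lte(sum(vapply(res2, function(r) r$n_sets, numeric(1))), total)
})

test_that("sub-cohort filters restrict to flagged persons", {
  ## flag diabetes via the sim confounder and filter on it
  flt <- suppressMessages(suppressWarnings(
    run_subcohort(st$cohort, st$claims$persons, st$claims$diagnoses,
                  st$claims$dispensings, "diabetes", st$episodes,
                  n_controls = 5, seed = 99)))
  ids <- unique(flt$design$subjects$person_id)
  dxdm <- unique(st$claims$diagnoses[code == "DX_DM", person_id])
  expect_true(all(ids %in% dxdm))
  expect_error(
    run_subcohort(st$cohort, st$claims$persons, st$claims$diagnoses,
                  st$claims$dispensings, "oral_contraceptives_90d",
                  st$episodes, n_controls = 5, seed = 99),
    "matches nobody")
  expect_error(
    run_subcohort(st$cohort, st$claims$persons, st$claims$diagnoses,
                  st$claims$dispensings, "not_a_covariate", st$episodes,
                  n_controls = 5, seed = 99),
    "unknown filter")
})

test_that("one seed fixes the whole pipeline output", {
  cfg <- small_sim_config(seed = 70)
  r1 <- suppressMessages(suppressWarnings(
    run_ncc_pipeline(cfg, n_controls = 5)))
  r2 <- suppressMessages(suppressWarnings(
    run_ncc_pipeline(cfg, n_controls = 5)))
  expect_identical(r1$primary$report, r2$primary$report)
  expect_identical(r1$matched_sets, r2$matched_sets)
})

test_that("pipeline artifacts are written when out_dir is given", {
  cfg <- small_sim_config(seed = 80)
  dir <- tempfile("run")
  r <- suppressMessages(suppressWarnings(
    run_ncc_pipeline(cfg, n_controls = 5, out_dir = dir)))
  expect_true(all(c("cohort.csv", "matched_sets.csv", "covariates.csv",
                    "fit_results.csv", "elimination_trace.csv",
                    "report.csv", "run_manifest.txt") %in% list.files(dir)))
  manifest <- readLines(file.path(dir, "run_manifest.txt"))
  expect_true(any(grepl("^seed: 80$", manifest)))
  expect_true(any(grepl("n_unmatched_cases", manifest)))
  unlink(dir, recursive = TRUE)
})

test_that("forest export flattens strata", {
  fits <- list(male = suppressWarnings(run_primary(
    st$ms, st$episodes, st$cov))$fit_adjusted)
  fd <- forest_data(fits, terms = "current_tnsaid")
  expect_equal(names(fd), c("stratum", "term", "or", "lcl", "ucl"))
  expect_equal(fd$stratum, "male")
})

test_that("exposure levels without users are reported, not silently dropped", {
  pr <- suppressMessages(suppressWarnings(
    run_primary(st$ms, st$episodes, st$cov, model = "substance")))
  rep <- pr$report
  ## every catalogue substance has a report row
  expect_true(all(paste0("current_", default_drug_catalogue()$name) %in%
                  rep$term))
  empty <- rep[n_cases == 0 & n_controls == 0]
  if (nrow(empty) > 0) {
    expect_true(all(is.na(empty$or_adjusted)))
  }
  ## one-sided levels (exposed controls but no exposed cases) are flagged
  ## not-estimable rather than fitted
  one_sided <- rep[term %in% pr$not_estimable]
  expect_true(all(is.na(one_sided$or_adjusted)))
})

test_that("age groups at index use the default bands", {
  ms <- data.table(set_id = 1L, role = c("case", "control"),
                   person_id = c("A", "B"), index_date = D("2002-06-01"))
  persons <- data.table(person_id = c("A", "B"),
                        birthdate = D(c("1941-06-01", "1960-01-01")))
  expect_equal(age_group_at_index(ms, persons), c("60-69", "18-59"))
  expect_equal(age_group_at_index(
    data.table(set_id = 1L, role = "case", person_id = "A",
               index_date = D("2025-01-01")), persons[1]), "80+")
})
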