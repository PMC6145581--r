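#' Run the full nested case-control pipeline
#'
#' End-to-end orchestration: simulate claims (or accept pre-built claims
#' tables), construct the new-user cohort, derive prescription episodes,
#' find cases, sample matched controls by incidence-density sampling,
#' assess covariates, and fit the matched and adjusted models. One seed
#' fixes the simulation and the control sampling, so every report cell is
#' reproducible.
#'
#' @param config a [sim_config()]; ignored when `claims` is supplied.
#' @param claims optional pre-built claims list (`persons`, `enrollment`,
#'   `dispensings`, `diagnoses`).
#' @param n_controls controls per case (study design: 100).
#' @param seed seed for control sampling (and, through `config`, the
#'   simulation); defaults to `config$seed`.
#' @param model `"class"` or `"substance"`.
#' @param study_window passed to [build_cohort()]; defaults to the
#'   simulation's study period when `config` is given.
#' @param catalogue_cov covariate catalogue.
#' @param out_dir optional directory; when given, writes `cohort.csv`,
#'   `matched_sets.csv`, `covariates.csv`, `fit_results.csv`,
#'   `elimination_trace.csv`, `report.csv` and a `run_manifest.txt` log.
#' @param by_database fit per database in addition to pooled.
#' @return list of class `ncc_pipeline`: `claims`, `cohort`, `episodes`,
#'   `cases`, `matched_sets`, `covariates`, `primary` (see
#'   [run_primary()]), `n_unmatched`, `seed`.
#' @export
#' @examples
#' \donttest{
#' cfg <- sim_config(n_persons = 500, seed = 42,
#'                   baseline_hazard = 1e-4)
#' res <- run_ncc_pipeline(cfg, n_controls = 10)
#' res$primary$report
#' }
run_ncc_pipeline <- function(config = sim_config(), claims = NULL,
                             n_controls = 100L, seed = NULL,
                             model = c("class", "substance"),
                             study_window = NULL,
                             catalogue_cov = default_covariate_catalogue(),
                             out_dir = NULL, by_database = FALSE) {
  model <- match.arg(model)
  if (is.null(claims)) {
    claims <- simulate_claims(config)
    if (is.null(study_window)) {
      study_window <- c(config$study_start, config$study_end)
    }
    if (is.null(seed)) seed <- config$seed
  }
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  if (is.null(study_window)) {
    study_window <- c("1999-07-01", "2010-12-31")
  }
  cohort <- build_cohort(claims$persons, claims$enrollment,
                         claims$dispensings, claims$diagnoses,
                         study_window = study_window)
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  nsaid <- as.data.table(claims$dispensings)[startsWith(substance, "M01A")]
  episodes <- prescription_episodes(nsaid)
  cases <- find_cases(cohort)
  if (nrow(cases) == 0L) stop("no cases observed", call. = FALSE)
  ms <- sample_matched_sets(cases, cohort, claims$persons,
                            n_controls = n_controls, seed = seed)
  n_unmatched <- attr(ms, "n_unmatched")
  ## unmatched sets carry no information; modelling uses matched sets only
  cov <- assess_covariates(ms, cohort, claims$diagnoses, claims$dispensings,
                           catalogue = catalogue_cov)
  primary <- run_primary(ms, episodes, cov, catalogue_cov, model = model,
                         by_database = by_database)

  out <- structure(list(
    claims = claims, cohort = cohort, episodes = episodes, cases = cases,
    matched_sets = ms, covariates = cov, primary = primary,
    n_unmatched = n_unmatched, seed = seed
  ), class = "ncc_pipeline")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    fwrite(cohort, file.path(out_dir, "cohort.csv"))
    fwrite(ms, file.path(out_dir, "matched_sets.csv"))
    fwrite(cov, file.path(out_dir, "covariates.csv"))
    fwrite(primary$fit_adjusted$or_table,
           file.path(out_dir, "fit_results.csv"))
    fwrite(primary$elimination, file.path(out_dir, "elimination_trace.csv"))
    fwrite(primary$report, file.path(out_dir, "report.csv"))
    manifest <- c(
      sprintf("seed: %d", as.integer(seed)),
      sprintf("n_persons: %d", nrow(claims$persons)),
      sprintf("n_cohort: %d", nrow(cohort)),
      sprintf("n_cases: %d", nrow(cases)),
      sprintf("n_unmatched_cases: %d", n_unmatched),
      sprintf("n_sets_used: %d", primary$fit_adjusted$n_sets_used),
      sprintf("n_sets_dropped: %d", primary$fit_adjusted$n_sets_dropped),
      sprintf("eliminated: %s",
              paste(primary$elimination$removed, collapse = ", "))
    )
    writeLines(manifest, file.path(out_dir, "run_manifest.txt"))
  }
  out
}

#' @export
print.ncc_pipeline <- function(x, ...) {
  cat(sprintf(paste0(
    "Nested case-control pipeline: %d persons, %d cohort members,\n",
    "  %d cases (%d unmatched), %d matched sets used; seed %d\n"),
    nrow(x$claims$persons), nrow(x$cohort), nrow(x$cases), x$n_unmatched,
    x$primary$fit_adjusted$n_sets_used, as.integer(x$seed)))
  print(x$primary)
  invisible(x)
}

#' Export forest-plot data
#'
#' Flattens fitted exposure odds ratios (optionally across strata) into a
#' tidy table ready for plotting or CSV export.
#'
#' @param fits named list of [fit_clogit()] results (names = strata), or a
#'   single fit.
#' @param terms restrict to these terms (default: all).
#' @return `data.table` with `stratum`, `term`, `or`, `lcl`, `ucl`.
#' @export
forest_data <- function(fits, terms = NULL) {
  if (inherits(fits, "ncc_clogit")) fits <- list(pooled = fits)
  out <- rbindlist(lapply(names(fits), function(nm) {
    tab <- fits[[nm]]$or_table[, .(term, or, lcl, ucl)]
    tab[, stratum := nm]
    tab
  }))
  if (!is.null(terms)) out <- out[term %in% terms]
  setcolorder(out, c("stratum", "term"))
  out[]
}
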