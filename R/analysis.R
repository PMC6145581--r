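#' Build the matched design matrix
#'
#' Codes each matched-set member's exposure at the index date into
#' mutually exclusive indicator columns, with past use of any NSAID as the
#' absorbed reference level:
#' * `model = "class"`: `current_coxib`, `current_tnsaid`,
#'   `current_multiple`, `recent_any`;
#' * `model = "substance"`: `current_<name>` per substance,
#'   `current_multiple`, `recent_any`.
#'
#' Subjects current on two or more substances are represented by the
#' separate `current_multiple` indicator and never contribute to a
#' single-substance (or single-class) contrast. Covariate columns are
#' appended when a covariate table is supplied.
#'
#' @param matched_sets long table from [sample_matched_sets()].
#' @param episodes prescription episodes from [prescription_episodes()]
#'   (NSAIDs only).
#' @param covariates optional covariate table from [assess_covariates()].
#' @param model `"class"` or `"substance"`.
#' @param catalogue drug catalogue.
#' @return list of class `ncc_design`: `X` (matrix), `y` (case
#'   indicator), `sets`, `exposure_cols`, `covariate_cols`, `subjects`
#'   (the row-aligned subject table with exposure state).
#' @export
build_design <- function(matched_sets, episodes, covariates = NULL,
                         model = c("class", "substance"),
                         catalogue = default_drug_catalogue()) {
  model <- match.arg(model)
  ms <- as.data.table(matched_sets)
  sub <- exposure_at(episodes, ms, catalogue = catalogue)

  if (model == "class") {
    lev <- c("current_coxib", "current_tnsaid")
    Xe <- cbind(
      current_coxib = as.numeric(sub$current_class %in% "coxib"),
      current_tnsaid = as.numeric(sub$current_class %in% "tNSAID")
    )
  } else {
    nm <- catalogue$name
    Xe <- vapply(nm, function(s)
      as.numeric(sub$n_current == 1L & sub$current_substance %in% s),
      numeric(nrow(sub)))
    colnames(Xe) <- paste0("current_", nm)
  }
  Xe <- cbind(Xe,
              current_multiple = as.numeric(sub$n_current >= 2L),
              recent_any = as.numeric(sub$recent_any))
  exposure_cols <- colnames(Xe)

  covariate_cols <- character()
  if (!is.null(covariates)) {
    cv <- as.data.table(covariates)
    idcols <- c("set_id", "person_id", "role", "index_date")
    covariate_cols <- setdiff(names(cv), idcols)
    cv <- cv[sub[, .(set_id, person_id)], on = c("set_id", "person_id")]
    Xc <- as.matrix(cv[, ..covariate_cols])
    if (anyNA(Xc)) stop("covariates missing for some subjects", call. = FALSE)
    Xe <- cbind(Xe, Xc)
  }
  structure(list(X = Xe, y = as.numeric(sub$role == "case"),
                 sets = sub$set_id, exposure_cols = exposure_cols,
                 covariate_cols = covariate_cols, subjects = sub),
            class = "ncc_design")
}

#' Counts and percentages by exposure term and role
#'
#' @keywords internal
exposure_counts <- function(design) {
  X <- design$X[, design$exposure_cols, drop = FALSE]
  y <- design$y
  n_cases <- sum(y == 1)
  n_controls <- sum(y == 0)
  data.table(
    term = design$exposure_cols,
    n_cases = as.integer(colSums(X[y == 1, , drop = FALSE])),
    pct_cases = round_half_up(
      100 * colSums(X[y == 1, , drop = FALSE]) / max(n_cases, 1L), 1),
    n_controls = as.integer(colSums(X[y == 0, , drop = FALSE])),
    pct_controls = round_half_up(
      100 * colSums(X[y == 0, , drop = FALSE]) / max(n_controls, 1L), 1)
  )
}

#' Primary analysis: matched and adjusted odds ratios
#'
#' Fits the matched-only model (exposure indicators against past use of
#' any NSAID) and the adjusted model (exposure plus a-priori confounders,
#' with candidate confounders passed through protected backward
#' elimination), pooled across databases and optionally per database.
#'
#' @param matched_sets long matched-set table.
#' @param episodes NSAID prescription episodes.
#' @param covariates covariate table from [assess_covariates()].
#' @param catalogue_cov covariate catalogue (supplies the tiers).
#' @param model `"class"` or `"substance"`.
#' @param drug_catalogue NSAID catalogue.
#' @param by_database also fit each database separately.
#' @param alpha_stay backward-elimination stay threshold.
#' @return list of class `ncc_primary`: `report` (a table with counts,
#'   percentages, matched and adjusted ORs with CIs), `fit_matched`,
#'   `fit_adjusted`, `elimination` (trace), `per_database` (optional list
#'   of per-database results).
#' @export
run_primary <- function(matched_sets, episodes, covariates,
                        catalogue_cov = default_covariate_catalogue(),
                        model = c("class", "substance"),
                        drug_catalogue = default_drug_catalogue(),
                        by_database = FALSE, alpha_stay = 0.05) {
  model <- match.arg(model)
  ms <- as.data.table(matched_sets)
  if (nrow(ms) == 0L) stop("no matched sets supplied", call. = FALSE)

  design <- build_design(ms, episodes, covariates, model = model,
                         catalogue = drug_catalogue)
  ## indicator columns with a one-sided zero cell have no finite MLE:
  ## exclude them from the fits, leave their report rows not estimable
  sep <- quasi_separated_columns(design$X, design$y)
  not_estimable <- colnames(design$X)[sep]
  if (length(not_estimable) > 0L) {
    message("not estimable (one-sided zero cell): ",
            paste(not_estimable, collapse = ", "))
  }
  expo <- setdiff(design$exposure_cols, not_estimable)
  fit_m <- suppressWarnings(
    fit_clogit(design$X[, expo, drop = FALSE], design$y, design$sets))
  a_priori <- setdiff(intersect(
    catalogue_cov[tier == "a_priori", name], design$covariate_cols),
    not_estimable)
  candidates <- setdiff(intersect(
    catalogue_cov[tier == "candidate", name], design$covariate_cols),
    not_estimable)
  be <- backward_eliminate(
    design$X[, c(expo, a_priori, candidates), drop = FALSE],
    design$y, design$sets,
    a_priori_columns = c(expo, a_priori),
    candidate_columns = candidates, alpha_stay = alpha_stay)
  fit_a <- be$fit

  counts <- exposure_counts(design)
  rep_m <- fit_m$or_table[, .(term, or_matched = or, lcl_matched = lcl,
                              ucl_matched = ucl)]
  rep_a <- fit_a$or_table[term %in% design$exposure_cols,
                          .(term, or_adjusted = or, lcl_adjusted = lcl,
                            ucl_adjusted = ucl)]
  report <- Reduce(function(a, b) merge(a, b, by = "term", all.x = TRUE,
                                        sort = FALSE),
                   list(counts, rep_m, rep_a))
  out <- list(report = report, fit_matched = fit_m, fit_adjusted = fit_a,
              elimination = be$trace,
              retained_candidates = be$retained_candidates,
              not_estimable = not_estimable,
              model = model, design = design)
  if (by_database) {
    out$per_database <- lapply(split(seq_len(nrow(ms)), ms$database),
      function(ix) {
        sel <- ms[ix]
        cv <- as.data.table(covariates)[set_id %in% unique(sel$set_id)]
        run_primary(sel, episodes, cv, catalogue_cov, model,
                    drug_catalogue, by_database = FALSE,
                    alpha_stay = alpha_stay)
      })
  }
  class(out) <- "ncc_primary"
  out
}

#' @export
print.ncc_primary <- function(x, ...) {
  cat(sprintf("Primary %s-level analysis, %d matched sets used\n",
              x$model, x$fit_adjusted$n_sets_used))
  tab <- copy(x$report)
  num <- setdiff(names(tab), c("term", "n_cases", "n_controls",
                               "pct_cases", "pct_controls"))
  tab[, (num) := lapply(.SD, function(v) round_half_up(v, 2)),
      .SDcols = num]
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Duration-of-use analysis
#'
#' Recodes exposure among current users of any NSAID into duration
#' categories of the current continuous-use episode (truncated at the
#' index date), with short use of 7-29 days as the reference. Recent and
#' past use keep their own indicators (`recent_any`, `past_any`) so the
#' reference is purely "current, 7-29 days". The adjustment set is the
#' same as the primary analysis (a-priori plus surviving candidates).
#'
#' @param matched_sets long matched-set table.
#' @param episodes NSAID prescription episodes.
#' @param covariates covariate table.
#' @param adjust_cols covariate columns to adjust for (e.g. the primary
#'   model's retained set); default all a-priori covariates.
#' @param catalogue_cov covariate catalogue.
#' @return list with `report` (counts and adjusted ORs by duration
#'   category) and `fit`.
#' @export
run_duration_analysis <- function(matched_sets, episodes, covariates,
                                  adjust_cols = NULL,
                                  catalogue_cov =
                                    default_covariate_catalogue()) {
  ms <- as.data.table(matched_sets)
  sub <- exposure_at(episodes, ms)
  any_eps <- stitch_episodes(episodes, scope = "any")
  dur <- current_use_duration(any_eps, sub)
  dcat <- rep(NA_character_, nrow(sub))
  cur <- sub$state == "current"
  dcat[cur] <- as.character(duration_category(dur[cur]))

  Xe <- cbind(
    dur_lt7 = as.numeric(cur & dcat == "<7"),
    dur_30_89 = as.numeric(cur & dcat == "30-89"),
    dur_ge90 = as.numeric(cur & dcat == ">=90"),
    recent_any = as.numeric(sub$state == "recent"),
    past_any = as.numeric(sub$state == "past")
  )
  exposure_cols <- colnames(Xe)
  cv <- as.data.table(covariates)
  if (is.null(adjust_cols)) {
    adjust_cols <- intersect(catalogue_cov[tier == "a_priori", name],
                             names(cv))
  }
  cvm <- cv[sub[, .(set_id, person_id)], on = c("set_id", "person_id")]
  X <- cbind(Xe, as.matrix(cvm[, ..adjust_cols]))
  yy <- as.numeric(sub$role == "case")
  keep_cols <- !quasi_separated_columns(X, yy)
  fit <- suppressWarnings(fit_clogit(X[, keep_cols, drop = FALSE], yy,
                                     sub$set_id))
  y <- sub$role == "case"
  counts <- data.table(
    term = c(exposure_cols[1:3], "dur_7_29_reference"),
    n_cases = c(as.integer(colSums(Xe[y, 1:3, drop = FALSE])),
                sum(cur & dcat == "7-29" & y)),
    n_controls = c(as.integer(colSums(Xe[!y, 1:3, drop = FALSE])),
                   sum(cur & dcat == "7-29" & !y))
  )
  report <- merge(counts,
                  fit$or_table[, .(term, or, lcl, ucl)],
                  by = "term", all.x = TRUE, sort = FALSE)
  list(report = report, fit = fit)
}

#' Stratified analysis
#'
#' Restricts matched-set members to one stratum of a subject-level
#' variable, keeps only sets that retain their case and at least one
#' control, and refits the adjusted model. Strata reuse the pooled
#' model's adjustment set for comparability (no re-elimination within
#' stratum).
#'
#' @param matched_sets long matched-set table.
#' @param episodes NSAID prescription episodes.
#' @param covariates covariate table.
#' @param stratum_values named vector/1-column table: value of the
#'   stratifying variable per subject row of `matched_sets` (e.g. a
#'   covariate column, sex, or an age group).
#' @param model `"class"` or `"substance"`.
#' @param adjust_cols covariate columns to adjust for; the stratifying
#'   covariate itself is removed automatically.
#' @param catalogue_cov covariate catalogue.
#' @param drug_catalogue NSAID catalogue.
#' @return named list, one element per stratum level: `fit`, `n_sets`,
#'   `report`; strata with no usable sets yield `NULL` with a message.
#' @export
run_stratified <- function(matched_sets, episodes, covariates,
                           stratum_values, model = c("class", "substance"),
                           adjust_cols = NULL,
                           catalogue_cov = default_covariate_catalogue(),
                           drug_catalogue = default_drug_catalogue()) {
  model <- match.arg(model)
  ms <- as.data.table(matched_sets)
  stopifnot(length(stratum_values) == nrow(ms))
  cv <- as.data.table(covariates)
  if (is.null(adjust_cols)) {
    adjust_cols <- intersect(catalogue_cov[tier == "a_priori", name],
                             names(cv))
  }
  out <- list()
  for (lev in sort(unique(stratum_values))) {
    sel <- ms[stratum_values == lev]
    ok_sets <- sel[, .(has_case = any(role == "case"),
                       has_ctrl = any(role == "control")), by = set_id]
    keep_sets <- ok_sets[has_case & has_ctrl, set_id]
    sel <- sel[set_id %in% keep_sets]
    if (nrow(sel) == 0L) {
      message("stratum ", lev, ": no usable sets")
      out[[as.character(lev)]] <- NULL
      next
    }
    adj <- setdiff(adjust_cols, as.character(lev))
    design <- build_design(sel, episodes,
                           cv[sel[, .(set_id, person_id)],
                              on = c("set_id", "person_id")],
                           model = model, catalogue = drug_catalogue)
    cols <- c(design$exposure_cols, intersect(adj, design$covariate_cols))
    Xs <- design$X[, cols, drop = FALSE]
    cols <- cols[!quasi_separated_columns(Xs, design$y)]
    fit <- suppressWarnings(
      fit_clogit(design$X[, cols, drop = FALSE], design$y, design$sets))
    out[[as.character(lev)]] <- list(
      fit = fit, n_sets = fit$n_sets_used,
      report = fit$or_table[term %in% design$exposure_cols])
  }
  out
}

#' Characteristics table for cases and matched controls
#'
#' Counts and percentages of each covariate among cases and among control
#' rows (denominators: total cases, total control rows). Percentages are
#' rounded half-up to one decimal, the table style of epidemiological
#' reports.
#'
#' @param covariates covariate table from [assess_covariates()] (any
#'   table with `role` plus 0/1 covariate columns).
#' @return `data.table` with `characteristic`, `n_cases`, `pct_cases`,
#'   `n_controls`, `pct_controls`.
#' @export
summarize_characteristics <- function(covariates) {
  cv <- as.data.table(covariates)
  check_columns(cv, "role", "covariates")
  idcols <- c("set_id", "person_id", "role", "index_date")
  vars <- setdiff(names(cv), idcols)
  n_cases <- sum(cv$role == "case")
  n_controls <- sum(cv$role == "control")
  out <- rbindlist(lapply(vars, function(v) {
    nc <- sum(cv[role == "case"][[v]])
    nk <- sum(cv[role == "control"][[v]])
    data.table(characteristic = v,
               n_cases = nc,
               pct_cases = percent_of(nc, n_cases),
               n_controls = nk,
               pct_controls = percent_of(nk, n_controls))
  }))
  out[]
}

#' Percentage of a count, report-style rounding
#'
#' `100 * count / denominator`, rounded half-up to one decimal; zero
#' counts give 0.0 and a zero denominator gives `NA`.
#'
#' @param count,denominator non-negative counts.
#' @param digits decimal places (default 1).
#' @return numeric percentage(s).
#' @export
#' @examples
#' percent_of(24685, 49118)  # 50.3
#' percent_of(97, 49118)     # 0.2
percent_of <- function(count, denominator, digits = 1) {
  out <- round_half_up(100 * count / denominator, digits)
  den <- rep_len(denominator, length(out))
  out[!is.finite(den) | den <= 0] <- NA_real_
  out
}

#' Age group at the index date
#'
#' Default age strata for stratified analyses: 18-59, 60-69, 70-79, 80+
#' years at the index date (configurable breaks).
#'
#' @param matched_sets long matched-set table (`person_id`, `index_date`).
#' @param persons person table supplying `birthdate`.
#' @param breaks lower bounds of the age bands in years.
#' @return character vector of age-group labels per subject row.
#' @export
age_group_at_index <- function(matched_sets, persons,
                               breaks = c(18, 60, 70, 80)) {
  ms <- as.data.table(matched_sets)
  bd <- as.data.table(persons)[, .(person_id, birthdate)]
  x <- bd[ms, on = "person_id"]
  age <- age_years(x$index_date, x$birthdate)
  labs <- paste0(breaks, "-", c(breaks[-1] - 1, Inf))
  labs[length(labs)] <- paste0(breaks[length(breaks)], "+")
  labs[findInterval(age, breaks)]
}

#' Sub-cohort analysis
#'
#' Restricts the cohort to members flagged on any of the given baseline
#' covariates (e.g. osteoarthritis / rheumatoid arthritis / inflammatory
#' polyarthritis, or RA plus RA-treatment drugs), then re-runs the full
#' nested case-control pipeline — case finding, risk-set sampling,
#' covariate assessment and model fitting — within the sub-cohort.
#'
#' @param cohort full cohort from [build_cohort()].
#' @param persons,diagnoses,dispensings claims tables.
#' @param filter_covariates character vector of covariate names; persons
#'   with any of them equal to 1 at baseline form the sub-cohort.
#' @param episodes NSAID prescription episodes.
#' @param n_controls,seed passed to [sample_matched_sets()].
#' @param catalogue_cov covariate catalogue.
#' @param model `"class"` or `"substance"`.
#' @return as [run_primary()], with the sub-cohort size attached.
#' @export
run_subcohort <- function(cohort, persons, diagnoses, dispensings,
                          filter_covariates, episodes,
                          n_controls = 100L, seed,
                          catalogue_cov = default_covariate_catalogue(),
                          model = c("class", "substance")) {
  model <- match.arg(model)
  ch <- as.data.table(cohort)
  ## assess the filter covariates at entry (index = entry for baseline vars)
  base <- ch[, .(set_id = .I, role = "case", person_id,
                 index_date = entry_date)]
  cat_f <- default_covariate_catalogue()[name %in% filter_covariates]
  if (nrow(cat_f) < length(filter_covariates)) {
    stop("unknown filter covariate(s): ",
         paste(setdiff(filter_covariates, cat_f$name), collapse = ", "),
         call. = FALSE)
  }
  flags <- assess_covariates(base, ch, diagnoses, dispensings, cat_f)
  keep_ids <- flags[rowSums(as.matrix(
    flags[, ..filter_covariates])) > 0, person_id]
  subch <- ch[person_id %in% keep_ids]
  if (nrow(subch) == 0L) {
    stop("sub-cohort filter matches nobody", call. = FALSE)
  }
  cases <- find_cases(subch)
  ms <- sample_matched_sets(cases, subch, persons,
                            n_controls = n_controls, seed = seed)
  cov <- assess_covariates(ms, subch, diagnoses, dispensings,
                           catalogue = catalogue_cov)
  res <- run_primary(ms, episodes, cov, catalogue_cov, model = model)
  res$n_subcohort <- nrow(subch)
  res
}
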