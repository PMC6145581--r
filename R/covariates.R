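#' Default covariate catalogue
#'
#' The study's confounder scheme. Diagnosis covariates are assessed in the
#' twelve months before cohort entry (`baseline_12m_before_entry`,
#' implemented as `[entry - 365, entry]`); "prior use" drug covariates in
#' the same baseline window; concurrent drug covariates in the 90 days (or
#' 30 days for acute treatments) before the index date, excluding the
#' index day itself (`[index - k, index - 1]`). The `a_priori` tier is
#' always retained in adjusted models; `candidate` covariates are subject
#' to backward elimination. Aspirin and CYP2C9 inhibitors appear twice,
#' once per concurrent window, as distinct covariates.
#'
#' Code lists are configuration, not code: the defaults are the sentinel
#' codes emitted by the synthetic claims generator; real deployments
#' replace them with terminology-specific lists. Lifestyle covariates
#' (smoking, obesity, alcohol abuse) are recorded-diagnosis proxies.
#'
#' @return `data.table` with columns `name`, `kind`
#'   (`diagnosis`/`drug`), `window` (`baseline_12m_before_entry`,
#'   `rx_90d_before_index`, `rx_30d_before_index`), `tier`
#'   (`a_priori`/`candidate`), `codes` (list column of character vectors).
#' @export
default_covariate_catalogue <- function() {
  spec <- rbindlist(list(
    ## a-priori diagnosis history, baseline window
    list("stroke",               "diagnosis", "baseline_12m_before_entry", "a_priori", "DX_IS"),
    list("tia",                  "diagnosis", "baseline_12m_before_entry", "a_priori", "DX_TIA"),
    list("ami",                  "diagnosis", "baseline_12m_before_entry", "a_priori", "DX_AMI"),
    list("heart_failure",        "diagnosis", "baseline_12m_before_entry", "a_priori", "DX_HF"),
    list("af_flutter",           "diagnosis", "baseline_12m_before_entry", "a_priori", "DX_AF"),
    list("diabetes",             "diagnosis", "baseline_12m_before_entry", "a_priori", "DX_DM"),
    list("hyperlipidemia",       "diagnosis", "baseline_12m_before_entry", "a_priori", "DX_HLP"),
    list("hypertension",         "diagnosis", "baseline_12m_before_entry", "a_priori", "DX_HTN"),
    list("smoking",              "diagnosis", "baseline_12m_before_entry", "a_priori", "DX_SMOKING"),
    ## a-priori prior drug use, baseline window
    list("ace_at2",              "drug", "baseline_12m_before_entry", "a_priori", "RX_ACE_AT2"),
    list("calcium_channel_blockers", "drug", "baseline_12m_before_entry", "a_priori", "RX_CCB"),
    list("beta_blockers",        "drug", "baseline_12m_before_entry", "a_priori", "RX_BB"),
    list("cardiac_glycosides",   "drug", "baseline_12m_before_entry", "a_priori", "RX_GLYCO"),
    list("other_antihypertensives", "drug", "baseline_12m_before_entry", "a_priori", "RX_OTHER_HTN"),
    ## a-priori concurrent drug use
    list("lipid_modifying_90d",  "drug", "rx_90d_before_index", "a_priori", "RX_LIPID"),
    list("aspirin_90d",          "drug", "rx_90d_before_index", "a_priori", "RX_ASPIRIN"),
    list("aspirin_30d",          "drug", "rx_30d_before_index", "a_priori", "RX_ASPIRIN"),
    list("anticoagulants_90d",   "drug", "rx_90d_before_index", "a_priori", "RX_ANTICOAG"),
    list("platelet_inhibitors_90d", "drug", "rx_90d_before_index", "a_priori", "RX_PLATELET"),
    ## candidate diagnosis history
    list("ischemic_heart_disease", "diagnosis", "baseline_12m_before_entry", "candidate", "DX_IHD"),
    list("other_cardiovascular", "diagnosis", "baseline_12m_before_entry", "candidate", "DX_OTHER_CVD"),
    list("peripheral_arterial",  "diagnosis", "baseline_12m_before_entry", "candidate", "DX_PAD"),
    list("alcohol_abuse",        "diagnosis", "baseline_12m_before_entry", "candidate", "DX_ALCOHOL"),
    list("obesity",              "diagnosis", "baseline_12m_before_entry", "candidate", "DX_OBESITY"),
    list("other_cerebrovascular", "diagnosis", "baseline_12m_before_entry", "candidate", "DX_OTHER_CBV"),
    list("migraine",             "diagnosis", "baseline_12m_before_entry", "candidate", "DX_MIGRAINE"),
    list("osteoarthritis",       "diagnosis", "baseline_12m_before_entry", "candidate", "DX_OA"),
    list("ra_polyarthritis",     "diagnosis", "baseline_12m_before_entry", "candidate", "DX_RA"),
    list("chronic_liver_disease", "diagnosis", "baseline_12m_before_entry", "candidate", "DX_LIVER"),
    list("kidney_failure",       "diagnosis", "baseline_12m_before_entry", "candidate", "DX_KIDNEY"),
    list("coagulation_disorders", "diagnosis", "baseline_12m_before_entry", "candidate", "DX_COAG"),
    ## candidate drug use
    list("ra_drugs",             "drug", "baseline_12m_before_entry", "candidate", "RX_RA_DRUG"),
    list("diuretics_90d",        "drug", "rx_90d_before_index", "candidate", "RX_DIURETIC"),
    list("nitrates_90d",         "drug", "rx_90d_before_index", "candidate", "RX_NITRATE"),
    list("cyp2c9_inhibitors_90d", "drug", "rx_90d_before_index", "candidate", "RX_CYP2C9"),
    list("cyp2c9_inhibitors_30d", "drug", "rx_30d_before_index", "candidate", "RX_CYP2C9"),
    list("glucocorticoids_90d",  "drug", "rx_90d_before_index", "candidate", "RX_GLUCO"),
    list("postmenopausal_hormones_90d", "drug", "rx_90d_before_index", "candidate", "RX_PMH"),
    list("oral_contraceptives_90d", "drug", "rx_90d_before_index", "candidate", "RX_OC")
  ))
  setnames(spec, c("name", "kind", "window", "tier", "code"))
  spec[, codes := as.list(code)]
  spec[, code := NULL]
  if (anyDuplicated(spec$name)) stop("covariate names must be unique")
  spec[]
}

## window bounds relative to entry/index, closed intervals
covariate_window_bounds <- function(window, entry_date, index_date) {
  switch(window,
    baseline_12m_before_entry = list(lo = entry_date - 365L, hi = entry_date),
    rx_90d_before_index = list(lo = index_date - 90L, hi = index_date - 1L),
    rx_30d_before_index = list(lo = index_date - 30L, hi = index_date - 1L),
    stop("unknown covariate window: ", window, call. = FALSE)
  )
}

#' Assess binary covariates for matched-set members
#'
#' Computes every covariate in the catalogue for each matched-set member.
#' Diagnosis covariates look for a code-list diagnosis in
#' `[entry - 365, entry]`; baseline drug covariates for a dispensing in
#' the same window; concurrent drug covariates for a dispensing in
#' `[index - 90, index - 1]` or `[index - 30, index - 1]`. Baseline
#' covariates depend only on the person's entry, so they are identical
#' across sets; concurrent covariates vary with the index date.
#'
#' @param matched_sets long table from [sample_matched_sets()] (`set_id`,
#'   `role`, `person_id`, `index_date`).
#' @param cohort cohort table supplying `entry_date` per person.
#' @param diagnoses diagnosis records.
#' @param dispensings dispensing records.
#' @param catalogue covariate catalogue, see
#'   [default_covariate_catalogue()].
#' @return `data.table` with `set_id`, `role`, `person_id`, `index_date`
#'   and one 0/1 column per covariate.
#' @export
assess_covariates <- function(matched_sets, cohort, diagnoses, dispensings,
                              catalogue = default_covariate_catalogue()) {
  ms <- as.data.table(matched_sets)
  check_columns(ms, c("set_id", "role", "person_id", "index_date"),
                "matched_sets")
  sub <- merge(ms[, .(set_id, role, person_id, index_date)],
               as.data.table(cohort)[, .(person_id, entry_date)],
               by = "person_id", sort = FALSE)
  setorder(sub, set_id, role, person_id)
  sub[, srow := .I]
  dx <- as.data.table(diagnoses)[, .(person_id, code, date)]
  rx <- as.data.table(dispensings)[, .(person_id, code = substance, date)]

  for (k in seq_len(nrow(catalogue))) {
    nm <- catalogue$name[k]
    src <- if (catalogue$kind[k] == "diagnosis") dx else rx
    src_k <- src[code %in% catalogue$codes[[k]]]
    b <- covariate_window_bounds(catalogue$window[k], sub$entry_date,
                                 sub$index_date)
    tmp <- copy(sub[, .(person_id, srow)])
    tmp[, `:=`(lo = b$lo, hi = b$hi)]
    hit <- src_k[tmp, on = .(person_id, date >= lo, date <= hi),
                 mult = "first", which = TRUE]
    sub[, (nm) := as.integer(!is.na(hit))]
  }
  sub[, c("entry_date", "srow") := NULL]
  setcolorder(sub, c("set_id", "role", "person_id", "index_date"))
  sub[]
}
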