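library(data.table)

D <- function(x) as.Date(x)

## minimal dispensing row(s)
disp_row <- function(person_id, substance, date, quantity = 30,
                     recorded = NA_real_) {
  data.table(person_id = person_id, substance = substance, date = D(date),
             quantity_ddd = as.numeric(quantity),
             recorded_duration = recorded)
}

dx_row <- function(person_id, code, date, setting = "hospital") {
  data.table(person_id = person_id, code = code, date = D(date),
             setting = setting)
}

person_row <- function(person_id, sex = "F", birthdate = "1940-06-15",
                       database = "DB1") {
  data.table(person_id = person_id, database = database, sex = sex,
             birthdate = D(birthdate))
}

enr_row <- function(person_id, start, end) {
  data.table(person_id = person_id, start = D(start), end = D(end))
}

## independent brute-force conditional log-likelihood (plain loops, no
## shared code with the implementation)
brute_loglik <- function(beta, X, y, sets) {
  total <- 0
  for (s in unique(sets)) {
    rows <- which(sets == s)
    etas <- numeric(length(rows))
    for (k in seq_along(rows)) {
      etas[k] <- sum(X[rows[k], ] * beta)
    }
    case_eta <- etas[y[rows] == 1]
    total <- total + case_eta - log(sum(exp(etas)))
  }
  total
}

## derivative-free maximiser of the conditional likelihood
dfree_clogit <- function(X, y, sets, p) {
  nll <- function(b) -brute_loglik(b, X, y, sets)
  if (p == 1L) {
    return(optimize(nll, c(-15, 15), tol = 1e-10)$minimum)
  }
  o <- optim(rep(0, p), nll, method = "Nelder-Mead",
             control = list(reltol = 1e-14, maxit = 10000))
  o <- optim(o$par, nll, method = "Nelder-Mead",
             control = list(reltol = 1e-14, maxit = 10000))
  o$par
}

## random well-posed matched design with continuous covariates
random_design <- function(n_sets = 5, p = 2, controls = 1:4) {
  m <- sample(controls, n_sets, replace = TRUE)
  X <- matrix(round(rnorm(sum(m + 1) * p), 2), ncol = p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  list(X = X,
       y = unlist(lapply(m, function(mm) c(1, rep(0, mm)))),
       sets = rep(seq_len(n_sets), m + 1))
}

## 1:1 binary-exposure design from discordant/concordant pair counts
pair_design <- function(case_exposed, control_exposed, concordant) {
  n <- case_exposed + control_exposed + concordant
  x <- c(rbind(
    c(rep(1, case_exposed), rep(0, control_exposed), rep(1, concordant)),
    c(rep(0, case_exposed), rep(1, control_exposed), rep(1, concordant))
  ))
  list(X = matrix(x, ncol = 1, dimnames = list(NULL, "exposed")),
       y = rep(c(1, 0), n),
       sets = rep(seq_len(n), each = 2))
}

## the three-person sampling fixture: one female case, one eligible female
## control, one male (ineligible)
toy1_fixture <- function() {
  persons <- rbind(
    person_row("P1", sex = "F", birthdate = "1941-01-01"),
    person_row("P2", sex = "F", birthdate = "1941-06-01"),
    person_row("P3", sex = "M", birthdate = "1941-01-01")
  )
  cohort <- data.table(
    person_id = c("P1", "P2", "P3"),
    entry_date = D(c("2000-07-01", "2000-07-01", "2000-07-01")),
    exit_date = D(c("2001-05-15", "2004-12-31", "2004-12-31")),
    exit_reason = c("IS", "study_end", "study_end")
  )
  list(persons = persons, cohort = cohort)
}

## small, fast simulation configuration for integration tests
small_sim_config <- function(seed = 1, ...) {
  args <- list(n_persons = 1500, seed = seed, baseline_hazard = 6e-5,
               study_start = "2001-01-01", study_end = "2003-12-31")
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
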