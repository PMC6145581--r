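test_that("conditional log-likelihood has its closed form at beta = 0", {
  d <- random_design(n_sets = 4, p = 2, controls = c(2, 3))
  m_s <- table(d$sets) - 1
  expect_equal(conditional_loglik(c(0, 0), d$X, d$y, d$sets),
               -sum(log(m_s + 1)))
  ## 3 sets of 1:100
  X <- matrix(rbinom(3 * 101, 1, 0.3), ncol = 1)
  y <- rep(c(1, rep(0, 100)), 3)
  sets <- rep(1:3, each = 101)
  expect_equal(conditional_loglik(0, X, y, sets), -3 * log(101))
})

test_that("likelihood is constant in beta when all rows of a set match", {
  X <- matrix(1, nrow = 4, ncol = 1)
  y <- c(1, 0, 0, 0)
  sets <- rep(1, 4)
  lls <- vapply(c(-2, 0, 1, 3), function(b)
    conditional_loglik(b, X, y, sets), numeric(1))
  expect_equal(lls, rep(-log(4), 4))
})

test_that("likelihood matches an independent brute-force evaluation", {
  set.seed(5)
  d <- random_design(n_sets = 4, p = 2)
  beta <- c(0.3, -0.2)
  expect_equal(conditional_loglik(beta, d$X, d$y, d$sets),
               brute_loglik(beta, d$X, d$y, d$sets), tolerance = 1e-12)
})

test_that("analytic gradient and information match finite differences", {
  set.seed(6)
  d <- random_design(n_sets = 5, p = 3)
  beta <- c(0.4, -0.3, 0.1)
  ll <- conditional_loglik(beta, d$X, d$y, d$sets, derivatives = TRUE)
  h <- 1e-6
  for (j in 1:3) {
    e <- rep(0, 3); e[j] <- h
    num <- (conditional_loglik(beta + e, d$X, d$y, d$sets) -
            conditional_loglik(beta - e, d$X, d$y, d$sets)) / (2 * h)
    expect_equal(unname(attr(ll, "gradient")[j]), num, tolerance = 1e-5)
    gp <- attr(conditional_loglik(beta + e, d$X, d$y, d$sets,
                                  derivatives = TRUE), "gradient")
    gm <- attr(conditional_loglik(beta - e, d$X, d$y, d$sets,
                                  derivatives = TRUE), "gradient")
    expect_equal(unname(attr(ll, "information")[, j]),
                 unname(-(gp - gm) / (2 * h)), tolerance = 1e-4)
  }
})

test_that("observed information is positive semi-definite (concavity)", {
  set.seed(7)
  for (r in 1:10) {
    d <- random_design(n_sets = 5, p = 2)
    beta <- rnorm(2)
    ll <- conditional_loglik(beta, d$X, d$y, d$sets, derivatives = TRUE)
    ev <- eigen(attr(ll, "information"), symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev > -1e-8))
  }
})

test_that("1:1 discordant-pair closed form holds exactly", {
  d <- pair_design(case_exposed = 10, control_exposed = 5, concordant = 20)
  fit <- fit_clogit(d$X, d$y, d$sets)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), log(10 / 5), tolerance = 1e-8)
  expect_equal(unname(fit$or_table$or), 2, tolerance = 1e-7)
  ## grid-search oracle over the brute-force likelihood
  grid <- optimize(function(b) -brute_loglik(b, d$X, d$y, d$sets),
                   c(-5, 5), tol = 1e-10)$minimum
  expect_equal(unname(fit$coefficients), grid, tolerance = 1e-6)
})

test_that("columns constant within every set are dropped, fit proceeds", {
  set.seed(8)
  d <- random_design(n_sets = 6, p = 1)
  X <- cbind(d$X, flat = 1)  # constant column
  expect_warning(fit <- fit_clogit(X, d$y, d$sets), "no within-set variation")
  expect_true(is.na(fit$coefficients["flat"]))
  expect_false(is.na(fit$coefficients["x1"]))
  ## estimates are unchanged relative to the fit without the column
  ref <- fit_clogit(d$X, d$y, d$sets)
  expect_equal(fit$coefficients[["x1"]], ref$coefficients[["x1"]],
               tolerance = 1e-10)
})

test_that("estimates are invariant to set relabelling", {
  set.seed(9)
  d <- random_design(n_sets = 5, p = 2)
  f1 <- fit_clogit(d$X, d$y, d$sets)
  relab <- c("zebra", "ant", "moth", "bee", "wasp")[d$sets]
  f2 <- fit_clogit(d$X, d$y, relab)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-12)
})

test_that("Newton optimum matches survival::clogit", {
  skip_if_not_installed("survival")
  library(survival)
  set.seed(10)
  d <- random_design(n_sets = 30, p = 3, controls = 2:5)
  fit <- fit_clogit(d$X, d$y, d$sets)
  df <- data.frame(y = d$y, d$X, set = d$sets)
  sv <- survival::clogit(y ~ x1 + x2 + x3 + strata(set), data = df)
  expect_equal(unname(fit$coefficients), unname(coef(sv)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(sv)))),
               tolerance = 1e-6)
})

test_that("sets without a case or without controls are excluded", {
  d <- pair_design(4, 2, 2)
  ## append a set with no case and a singleton set
  X <- rbind(d$X, matrix(c(1, 0, 1), ncol = 1))
  y <- c(d$y, 0, 0, 1)
  sets <- c(d$sets, 100, 100, 101)
  fit <- fit_clogit(X, y, sets)
  expect_equal(fit$n_sets_dropped, 2L)
  expect_equal(fit$n_sets_used, 8L)
  ref <- fit_clogit(d$X, d$y, d$sets)
  expect_equal(fit$coefficients, ref$coefficients, tolerance = 1e-10)
})

test_that("separation is detected and flagged", {
  ## exposure perfectly predicts case status across many 1:1 sets
  d <- pair_design(case_exposed = 12, control_exposed = 0, concordant = 0)
  fit <- suppressWarnings(fit_clogit(d$X, d$y, d$sets))
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("Wald intervals follow the log-scale formula", {
  w <- wald_interval(0.6931, 0.2)
  expect_equal(round(unname(w[1, ]), 2), c(2.00, 1.35, 2.96))
  ## degenerate CI at se = 0
  w0 <- wald_interval(log(1.5), 0)
  expect_equal(unname(w0[1, "lcl"]), unname(w0[1, "ucl"]))
  expect_equal(unname(w0[1, "or"]), 1.5)
  ## monotone in the level
  w99 <- wald_interval(0.6931, 0.2, level = 0.99)
  expect_lt(w99[1, "lcl"], w[1, "lcl"])
  expect_gt(w99[1, "ucl"], w[1, "ucl"])
  expect_error(wald_interval(0, 1, level = 1.2), "level")
  expect_error(wald_interval(0, -1), "se")
})

test_that("point estimates reconstruct from Wald CI limits", {
  expect_equal(point_estimate_from_ci(1.19, 1.78, digits = 2), 1.46)
  expect_equal(point_estimate_from_ci(1.20, 1.32, digits = 2), 1.26)
  expect_equal(point_estimate_from_ci(0.85, 0.85), 0.85)
  expect_error(point_estimate_from_ci(-1, 2), "positive")
  expect_error(point_estimate_from_ci(2, 1), "lcl")
})

test_that("backward elimination removes null candidates, protects tiers", {
  set.seed(12)
  ## 120 1:1 sets; x1 has a real effect, x2 is pure noise
  n <- 120
  X <- cbind(x1 = rbinom(2 * n, 1, 0.4), x2 = rbinom(2 * n, 1, 0.5))
  sets <- rep(seq_len(n), each = 2)
  ## case selected within set with probability softmax(1.2 * x1)
  y <- numeric(2 * n)
  for (s in seq_len(n)) {
    i <- which(sets == s)
    pr <- exp(1.2 * X[i, "x1"]); pr <- pr / sum(pr)
    y[i[sample.int(2, 1, prob = pr)]] <- 1
  }
  be <- backward_eliminate(X, y, sets, a_priori_columns = "x1",
                           candidate_columns = "x2")
  expect_true("x2" %in% be$trace$removed)
  expect_false("x1" %in% be$trace$removed)

  ## alpha_stay = 1 never removes anything
  be1 <- backward_eliminate(X, y, sets, a_priori_columns = "x1",
                            candidate_columns = "x2", alpha_stay = 1.0)
  expect_equal(nrow(be1$trace), 0L)
  expect_equal(be1$retained_candidates, "x2")
})

test_that("one-sided zero cells are detected as structurally inestimable", {
  X <- cbind(a = c(1, 0, 0, 0), b = c(0, 1, 0, 1), z = c(0.3, 1, 2, 0.1))
  y <- c(1, 0, 1, 0)
  qs <- quasi_separated_columns(X, y)
  ## a: only a case exposed; b: only controls exposed; z: continuous
  expect_identical(unname(qs), c(TRUE, TRUE, FALSE))
  ## a balanced column is estimable
  expect_false(quasi_separated_columns(matrix(c(1, 0, 0, 1), ncol = 1),
                                       c(1, 0, 1, 0)))
})
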