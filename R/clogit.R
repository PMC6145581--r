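#' Conditional log-likelihood for 1:M matched sets
#'
#' The Breslow conditional likelihood for matched case-control sets with
#' exactly one case per set:
#' \deqn{\ell(\beta) = \sum_s \left[ x_{case,s}\beta -
#'   \log \sum_{j \in s} e^{x_j \beta} \right]}
#' where the inner sum runs over the case and its controls. With one case
#' per set this is exact (no tie handling is needed). The gradient and the
#' observed information are computed analytically.
#'
#' @param beta numeric coefficient vector.
#' @param X numeric design matrix (rows = subjects).
#' @param y logical/0-1 case indicator (exactly one per set).
#' @param sets integer/character set identifier per row.
#' @param derivatives if `TRUE`, return gradient and information as
#'   attributes.
#' @return log-likelihood value; with `derivatives = TRUE`, attributes
#'   `gradient` (score vector) and `information` (observed information
#'   matrix, i.e. negative Hessian).
#' @export
conditional_loglik <- function(beta, X, y, sets, derivatives = FALSE) {
  if (any(!is.finite(beta))) stop("non-finite beta", call. = FALSE)
  X <- as.matrix(X)
  y <- as.numeric(y)
  g <- match(sets, unique(sets))
  G <- max(g)
  eta <- drop(X %*% beta)
  ## stable per-set log-sum-exp (groups ordered 1..G)
  mx <- vapply(split(eta, g), max, numeric(1))
  stopifnot(length(mx) == G)
  w <- exp(eta - mx[g])
  denom <- rowsum(w, g, reorder = TRUE)[, 1L]
  lse <- mx + log(denom)
  ll <- sum(eta[y == 1]) - sum(lse)
  if (!derivatives) return(ll)
  p <- w / denom[g]
  grad <- drop(crossprod(X, y - p))
  xbar <- rowsum(X * p, g, reorder = TRUE)
  info <- crossprod(X, X * p) - crossprod(xbar)
  attr(ll, "gradient") <- grad
  attr(ll, "information") <- info
  ll
}

## order-stable set -> 1..G index (first appearance order)
set_index <- function(sets) match(sets, unique(sets))

#' Fit conditional logistic regression by Newton-Raphson
#'
#' Maximises the Breslow conditional likelihood from `beta = 0` with
#' Newton-Raphson and step-halving. Sets without a case or without
#' controls are excluded (counted in `n_sets_dropped`); columns with no
#' variation within any usable set carry no information and are dropped
#' with a warning, reported as not estimable (`NA` coefficient).
#' Separation is flagged when any coefficient exceeds 20 in absolute
#' value; the fit is then marked non-converged.
#'
#' @param X design matrix (or data.frame of numeric columns).
#' @param y case indicator (one case per set).
#' @param sets set identifier per row.
#' @param tol convergence tolerance on the maximal absolute score.
#' @param max_iter maximum Newton iterations.
#' @param level confidence level for the Wald intervals.
#' @return object of class `ncc_clogit`: list with `coefficients`, `se`,
#'   `loglik`, `loglik_null`, `converged`, `separation`, `n_sets_used`,
#'   `n_sets_dropped`, `dropped_columns`, and `or_table` (term, beta, se,
#'   or, lcl, ucl, n_sets).
#' @export
fit_clogit <- function(X, y, sets, tol = 1e-8, max_iter = 50L,
                       level = 0.95) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), length(sets) == nrow(X),
            all(y %in% c(0, 1)))

  ## usable sets: exactly one case and at least one control
  g <- set_index(sets)
  n_case <- rowsum(y, g)[, 1L]
  n_rows <- rowsum(rep(1, length(g)), g)[, 1L]
  usable <- which(n_case == 1 & n_rows >= 2)
  keep <- g %in% usable
  n_dropped <- length(unique(g)) - length(usable)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  g <- set_index(g[keep])
  if (length(y) == 0L) {
    stop("no informative matched sets (each needs one case and >= 1 control)",
         call. = FALSE)
  }

  ## columns without within-set variation are not estimable
  first_of_set <- !duplicated(g)
  col_var <- vapply(seq_len(ncol(X)), function(j) {
    ref <- X[first_of_set, j][g]  # first value of each set, broadcast
    any(X[, j] != ref)
  }, logical(1))
  dropped_cols <- colnames(X)[!col_var]
  if (length(dropped_cols) > 0L) {
    warning("dropping column(s) with no within-set variation: ",
            paste(dropped_cols, collapse = ", "), call. = FALSE)
  }
  all_terms <- colnames(X)
  Xf <- X[, col_var, drop = FALSE]

  beta <- rep(0, ncol(Xf))
  ll <- conditional_loglik(beta, Xf, y, g, derivatives = TRUE)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  if (ncol(Xf) > 0L) {
    repeat {
      iter <- iter + 1L
      grad <- attr(ll, "gradient")
      info <- attr(ll, "information")
      if (max(abs(grad)) < tol) { converged <- TRUE; break }
      if (iter > max_iter) break
      step <- tryCatch(solve(info, grad), error = function(e) NULL)
      if (is.null(step)) { separation <- TRUE; break }
      ## step-halving: never accept a decrease in the log-likelihood
      h <- 1
      repeat {
        cand <- beta + h * step
        ll_new <- conditional_loglik(cand, Xf, y, g, derivatives = TRUE)
        if (as.numeric(ll_new) >= as.numeric(ll) - 1e-12 || h < 1e-10) break
        h <- h / 2
      }
      beta <- cand
      ll <- ll_new
      if (max(abs(beta)) > 20) { separation <- TRUE; converged <- FALSE; break }
    }
  } else {
    converged <- TRUE
  }
  info <- attr(ll, "information")
  se <- rep(NA_real_, ncol(Xf))
  if (ncol(Xf) > 0L) {
    vc <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(vc)) se <- sqrt(pmax(diag(vc), 0))
  }

  coef_full <- setNames(rep(NA_real_, length(all_terms)), all_terms)
  se_full <- coef_full
  coef_full[colnames(Xf)] <- beta
  se_full[colnames(Xf)] <- se
  ci <- wald_interval(coef_full, se_full, level = level)
  or_table <- data.table(
    term = all_terms, beta = as.numeric(coef_full),
    se = as.numeric(se_full),
    or = ci[, "or"], lcl = ci[, "lcl"], ucl = ci[, "ucl"],
    n_sets = length(usable)
  )
  structure(list(
    coefficients = coef_full, se = se_full,
    loglik = as.numeric(ll),
    loglik_null = conditional_loglik(rep(0, ncol(Xf)), Xf, y, g),
    converged = converged && !separation, separation = separation,
    n_sets_used = length(usable), n_sets_dropped = n_dropped,
    dropped_columns = dropped_cols, or_table = or_table,
    level = level, iterations = iter
  ), class = "ncc_clogit")
}

#' @export
print.ncc_clogit <- function(x, ...) {
  cat(sprintf(
    "Conditional logistic fit: %d sets (%d dropped), loglik %.4f, %s\n",
    x$n_sets_used, x$n_sets_dropped, x$loglik,
    if (x$converged) "converged" else
      if (x$separation) "SEPARATION" else "NOT converged"))
  tab <- copy(x$or_table)
  num <- c("beta", "se", "or", "lcl", "ucl")
  tab[, (num) := lapply(.SD, function(v) round(v, 4)), .SDcols = num]
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Detect structurally inestimable binary columns
#'
#' A 0/1 column whose positive values occur only among cases or only among
#' controls has its conditional MLE at plus/minus infinity (a guaranteed
#' one-sided zero cell). Such columns are best excluded from the fit and
#' reported as not estimable.
#'
#' @param X design matrix.
#' @param y case indicator.
#' @return logical vector, `TRUE` for columns with a one-sided zero cell.
#' @export
quasi_separated_columns <- function(X, y) {
  X <- as.matrix(X)
  vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    if (!all(v %in% c(0, 1))) return(FALSE)
    s1 <- sum(v[y == 1]); s0 <- sum(v[y == 0])
    xor(s1 == 0, s0 == 0)
  }, logical(1))
}

#' Wald odds-ratio confidence interval
#'
#' @param beta log odds ratio(s).
#' @param se standard error(s), `>= 0`.
#' @param level confidence level in (0, 1).
#' @return matrix with columns `or`, `lcl`, `ucl`:
#'   `exp(beta -/+ z * se)`.
#' @export
#' @examples
#' wald_interval(log(2), 0.2)
wald_interval <- function(beta, se, level = 0.95) {
  if (length(level) != 1L || !is.finite(level) || level <= 0 || level >= 1) {
    stop("level must be a single number in (0, 1)", call. = FALSE)
  }
  if (any(se < 0, na.rm = TRUE)) stop("se must be >= 0", call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  cbind(or = exp(beta), lcl = exp(beta - z * se), ucl = exp(beta + z * se))
}

#' Reconstruct a point estimate from Wald CI limits
#'
#' A Wald interval is symmetric on the log scale, so the point estimate is
#' the geometric mean of its limits: `exp((log lcl + log ucl) / 2)`. A
#' quality-control utility for checking published odds ratios against
#' their printed confidence limits.
#'
#' @param lcl,ucl positive confidence limits, `lcl <= ucl`.
#' @param digits optional rounding of the result (`NULL` = none).
#' @return the implied point estimate.
#' @export
#' @examples
#' point_estimate_from_ci(1.19, 1.78)  # 1.46
point_estimate_from_ci <- function(lcl, ucl, digits = NULL) {
  if (any(lcl <= 0) || any(ucl <= 0)) {
    stop("confidence limits must be positive", call. = FALSE)
  }
  if (any(lcl > ucl)) stop("lcl must be <= ucl", call. = FALSE)
  est <- exp((log(lcl) + log(ucl)) / 2)
  if (!is.null(digits)) est <- round_half_up(est, digits)
  est
}

#' Backward elimination with protected columns
#'
#' Starting from the full model, repeatedly refits and removes the
#' candidate column with the largest two-sided Wald p-value at or above
#' `alpha_stay`, until every remaining candidate has `p < alpha_stay`.
#' Exposure and a-priori confounder columns are never removed. Candidates
#' that are not estimable (no within-set variation) are removed first,
#' recorded with `NA` p-value.
#'
#' @param X design matrix.
#' @param y case indicator.
#' @param sets set identifiers.
#' @param a_priori_columns protected column names (exposure terms plus
#'   a-priori confounders).
#' @param candidate_columns column names subject to elimination.
#' @param alpha_stay stay threshold on the Wald p-value.
#' @param ... passed to [fit_clogit()].
#' @return list with `fit` (final [fit_clogit()] object) and `trace`
#'   (`data.table` of `removed`, `p_at_removal` in removal order).
#' @export
backward_eliminate <- function(X, y, sets, a_priori_columns,
                               candidate_columns, alpha_stay = 0.05, ...) {
  X <- as.matrix(X)
  stopifnot(all(c(a_priori_columns, candidate_columns) %in% colnames(X)),
            length(intersect(a_priori_columns, candidate_columns)) == 0L)
  active <- candidate_columns
  trace <- list()
  repeat {
    cols <- c(a_priori_columns, active)
    fit <- suppressWarnings(fit_clogit(X[, cols, drop = FALSE], y, sets, ...))
    ## drop non-estimable candidates outright
    dead <- intersect(fit$dropped_columns, active)
    if (length(dead) > 0L) {
      for (d in dead) {
        trace[[length(trace) + 1L]] <- data.table(removed = d,
                                                  p_at_removal = NA_real_)
      }
      active <- setdiff(active, dead)
      next
    }
    if (length(active) == 0L) break
    z <- fit$coefficients[active] / fit$se[active]
    p <- 2 * pnorm(-abs(z))
    worst <- which.max(p)
    if (length(worst) == 0L) break
    if (p[worst] >= alpha_stay) {
      trace[[length(trace) + 1L]] <- data.table(
        removed = active[worst], p_at_removal = as.numeric(p[worst]))
      active <- active[-worst]
    } else break
  }
  trace <- if (length(trace) > 0L) rbindlist(trace) else
    data.table(removed = character(), p_at_removal = numeric())
  list(fit = fit, trace = trace, retained_candidates = active)
}
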