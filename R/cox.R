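# Cox proportional-hazards fits on start-stop data.
#
# Fitting is delegated to survival::coxph (partial likelihood, Efron or
# Breslow ties, case weights, cluster-robust variance); this file owns the
# start-stop interface, the fit summary object, and the closed-form score
# test used by the confounding diagnostics.

#' Fit a Cox proportional-hazards model on counting-process rows
#'
#' Maximises the (weighted) Cox partial likelihood over risk sets defined by
#' `start < t <= stop`.  The robust (sandwich) variance is computed from
#' score residuals grouped by `patient_id`, so intervals and clones of one
#' patient share a grouping unit.
#'
#' @param rows counting-process rows with columns `start`, `stop`,
#'   `status` (binary; see [cause_specific_view()]), `patient_id`, an
#'   optional `weight` column, and the covariate columns named in
#'   `covariates`.
#' @param covariates character vector of covariate column names (e.g.
#'   `"treated"` alone for a univariable treatment model).
#' @param ties `"efron"` (default; daily data produce many ties) or
#'   `"breslow"`.
#' @param use_weights use the `weight` column as case weights.
#' @param robust compute the patient-clustered robust variance.
#' @return an object of class `ccw_coxfit`: list with `coef`, `var`,
#'   `robust_var` (or `NULL`), `loglik`, `iter`, `converged`, `monotone`
#'   (likelihood-monotonicity flag), `ties`, `n`, `nevent`.
#' @examples
#' cohort <- generate_cohort(default_config(), n = 300, seed = 2)
#' rows <- cause_specific_view(to_counting_process(cohort), "death")
#' fit <- fit_cox(rows, "treated")
#' hazard_ratio(fit, "treated")
#' @export
fit_cox <- function(rows, covariates, ties = c("efron", "breslow"),
                    use_weights = FALSE, robust = TRUE) {
  ties <- match.arg(ties)
  if (!"status" %in% names(rows))
    stop("rows need a binary 'status' column; see cause_specific_view()")
  if (sum(rows$status) == 0) stop("no events in the data")
  missing_cov <- setdiff(covariates, names(rows))
  if (length(missing_cov))
    stop("covariate column(s) not found: ",
         paste(missing_cov, collapse = ", "))
  xmat <- as.matrix(rows[, covariates, drop = FALSE])
  if (any(!is.finite(xmat))) stop("non-finite covariate values")
  weights <- if (use_weights) rows$weight else NULL
  if (!is.null(weights) && any(weights < 0)) stop("negative weights")

  fml <- as.formula(paste(
    "survival::Surv(start, stop, status) ~",
    paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    if (robust)
      survival::coxph(fml, data = rows, weights = weights,
                      ties = ties, robust = TRUE,
                      cluster = patient_id, x = FALSE, y = FALSE)
    else
      survival::coxph(fml, data = rows, weights = weights,
                      ties = ties, robust = FALSE, x = FALSE, y = FALSE),
    warning = function(w) {
      if (grepl("beta may be infinite|did not converge|out of iterations",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  if (any(is.na(beta)))
    stop("degenerate covariate (no variation within any risk set): ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  monotone <- any(abs(beta) > 15)
  if (monotone) {
    warning("monotone partial likelihood; coefficient capped at |15|")
    beta <- pmin(pmax(beta, -15), 15)
  }
  rvar <- if (robust) fit$var else NULL
  mvar <- if (robust && !is.null(fit$naive.var)) fit$naive.var else fit$var
  structure(
    list(coef = beta,
         var = mvar,
         robust_var = rvar,
         loglik = fit$loglik[length(fit$loglik)],
         iter = fit$iter,
         converged = is.null(fit$info) && !monotone,
         monotone = monotone,
         ties = ties,
         n = fit$n, nevent = fit$nevent,
         covariates = covariates),
    class = "ccw_coxfit")
}

#' Hazard ratio and Wald confidence interval from a Cox fit
#'
#' Exponentiates a coefficient and its 95% Wald interval,
#' `exp(coef +/- 1.96 * SE)`, using the robust standard error when the fit
#' carries one.
#'
#' @param fit a [fit_cox()] result.
#' @param name coefficient name (default: the first).
#' @param level confidence level.
#' @return named numeric vector `c(hr, lower, upper, log_hr, se)`.
#' @export
hazard_ratio <- function(fit, name = fit$covariates[1], level = 0.95) {
  stopifnot(inherits(fit, "ccw_coxfit"))
  j <- match(name, names(fit$coef))
  if (is.na(j)) stop("unknown coefficient: ", name)
  v <- if (!is.null(fit$robust_var)) fit$robust_var else fit$var
  se <- sqrt(v[j, j])
  zq <- qnorm(1 - (1 - level) / 2)
  b <- fit$coef[[j]]
  c(hr = exp(b), lower = exp(b - zq * se), upper = exp(b + zq * se),
    log_hr = b, se = se)
}

#' @export
print.ccw_coxfit <- function(x, ...) {
  cat("<ccw_coxfit> ", x$nevent, " events / ", x$n, " rows; ties = ",
      x$ties, if (x$monotone) "; MONOTONE" else "", "\n", sep = "")
  for (nm in names(x$coef)) {
    hr <- hazard_ratio(x, nm)
    cat(sprintf("  %-14s HR %6.3f [%5.3f, %6.3f]  (log-HR %+.4f, SE %.4f)\n",
                nm, hr[["hr"]], hr[["lower"]], hr[["upper"]],
                hr[["log_hr"]], hr[["se"]]))
  }
  invisible(x)
}

#' Cox score test at the null
#'
#' Closed-form score statistic for a single covariate at `beta = 0` with
#' Breslow risk-set accounting:
#' `U = sum over events of w_i (x_i - xbar_j)` and
#' `V = sum_j d_j * weighted var of x in risk set j`; the statistic
#' `U^2 / V` is referred to a chi-squared distribution with 1 df.  Used as
#' an association diagnostic (e.g. confirming confounding between a
#' baseline covariate and a cause-specific hazard).
#'
#' @param rows counting-process rows with `status` (see
#'   [cause_specific_view()]) and optional `weight`.
#' @param covariate single covariate column name.
#' @return list with `statistic`, `df`, `p_value`, `U`, `V`.
#' @export
score_test_null <- function(rows, covariate) {
  if (!"status" %in% names(rows))
    stop("rows need a binary 'status' column")
  x <- rows[[covariate]]
  if (is.null(x)) stop("covariate column not found: ", covariate)
  w <- rows$weight %||% rep(1, nrow(rows))
  ev_times <- sort(unique(rows$stop[rows$status > 0 & w > 0]))
  U <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- rows$start < t & rows$stop >= t
    wr <- w[at_risk]; xr <- x[at_risk]
    wsum <- sum(wr)
    xbar <- sum(wr * xr) / wsum
    vbar <- sum(wr * (xr - xbar)^2) / wsum
    ev <- rows$stop == t & rows$status > 0
    U <- U + sum(w[ev] * (x[ev] - xbar))
    V <- V + sum(w[ev]) * vbar
  }
  stat <- if (V > 0) U^2 / V else 0
  list(statistic = stat, df = 1,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       U = U, V = V)
}
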