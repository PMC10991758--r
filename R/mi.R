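# Multiple imputation of the inflammatory markers and Rubin pooling.
#
# Chained equations with Bayesian-linear-regression draws, written for the
# five-marker missingness pattern of this cohort: each marker is imputed on
# its analysis transform (log scale; square root for lymphocytes) from all
# other baseline covariates, the other markers' current imputations, the
# event-type indicators and the Nelson-Aalen cumulative all-cause hazard at
# the event day (event information guards against congeniality bias in
# survival imputation).

marker_transform <- function(m, v) {
  if (m == "lymph") sqrt(v) else log(v)
}
marker_back <- function(m, v) {
  if (m == "lymph") v^2 else exp(v)
}

# Nelson-Aalen cumulative hazard of any terminal event, evaluated at each
# patient's event day.
nelson_aalen_at <- function(cohort) {
  status <- as.numeric(cohort$event_type != "censored")
  t_ev <- sort(unique(cohort$event_day[status == 1]))
  haz <- vapply(t_ev, function(s)
    sum(cohort$event_day == s & status == 1) / sum(cohort$event_day >= s),
    numeric(1))
  ch <- cumsum(haz)
  idx <- findInterval(cohort$event_day, t_ev)
  c(0, ch)[idx + 1L]
}

# One Bayesian linear-regression draw (the classic "norm" step): draw the
# residual variance from its scaled inverse-chi-squared posterior, the
# coefficients from their normal posterior, then impute with added noise.
bayes_lm_draw <- function(X_obs, y_obs, X_mis) {
  p <- ncol(X_obs)
  XtX <- crossprod(X_obs) + diag(1e-6, p)
  R <- chol(XtX)
  beta_hat <- backsolve(R, forwardsolve(t(R), crossprod(X_obs, y_obs)))
  rss <- sum((y_obs - X_obs %*% beta_hat)^2)
  df <- max(length(y_obs) - p, 1)
  sigma2 <- rss / rchisq(1, df)
  beta <- beta_hat + backsolve(R, rnorm(p)) * sqrt(sigma2)
  drop(X_mis %*% beta) + rnorm(nrow(X_mis), sd = sqrt(sigma2))
}

#' Multiple imputation of missing inflammatory markers
#'
#' Chained-equations imputation of the five inflammatory markers.  Each
#' cycle visits the markers with missing values in turn and redraws the
#' missing entries from a Bayesian linear regression of the transformed
#' marker on the other baseline covariates (age, sex, Charlson index, wave
#' indicators), the other markers' current transformed imputations, the
#' event-type indicators and the Nelson-Aalen cumulative hazard at the
#' event day.  Values are back-transformed to the original scale.  With no
#' missing values the result is `m` identical copies of the input.
#'
#' @param cohort a cohort `data.frame` (possibly with `NA` markers).
#' @param m number of completed datasets (default 5).
#' @param seed integer seed; the imputation is deterministic given
#'   `(cohort, m, seed)`.
#' @param maxit chained-equation cycles per copy (default 5).
#' @return an object of class `imputation_set`: list with `cohorts` (list
#'   of `m` completed cohorts), `m`, `seed`, `maxit`, and `missing_pattern`
#'   (per-marker missing counts).
#' @export
impute_cohort <- function(cohort, m = 5L, seed = 1L, maxit = 5L) {
  if (m < 2L) stop("m must be at least 2")
  miss <- lapply(setNames(MARKERS, MARKERS),
                 function(mk) which(is.na(cohort[[mk]])))
  n_miss <- lengths(miss)
  targets <- names(n_miss)[n_miss > 0]
  for (mk in targets)
    if (n_miss[[mk]] == nrow(cohort))
      stop("marker ", mk, " is entirely missing")

  if (length(targets) == 0L) {
    return(structure(list(cohorts = rep(list(cohort), m), m = m,
                          seed = seed, maxit = maxit,
                          missing_pattern = n_miss),
                     class = "imputation_set"))
  }

  set.seed(seed)
  na_ch <- nelson_aalen_at(cohort)
  fixed <- cbind(age10 = cohort$age / 10, sex = cohort$sex,
                 cci = cohort$cci,
                 wave2 = as.numeric(cohort$wave == 2),
                 wave3 = as.numeric(cohort$wave == 3),
                 ev_death = as.numeric(cohort$event_type == "death"),
                 ev_home = as.numeric(cohort$event_type == "home"),
                 ev_transfer = as.numeric(cohort$event_type == "transfer"),
                 na_cumhaz = na_ch)
  tr <- vapply(MARKERS, function(mk) marker_transform(mk, cohort[[mk]]),
               numeric(nrow(cohort)))

  cohorts <- vector("list", m)
  for (copy in seq_len(m)) {
    cur <- tr
    for (mk in targets) {                      # initialise from observed
      obs <- cur[, mk][!is.na(cur[, mk])]
      cur[miss[[mk]], mk] <- sample(obs, n_miss[[mk]], replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (mk in targets) {
        others <- setdiff(MARKERS, mk)
        X <- cbind(1, fixed, cur[, others, drop = FALSE])
        rows_mis <- miss[[mk]]
        rows_obs <- setdiff(seq_len(nrow(cohort)), rows_mis)
        cur[rows_mis, mk] <- bayes_lm_draw(
          X[rows_obs, , drop = FALSE], tr[rows_obs, mk],
          X[rows_mis, , drop = FALSE])
      }
    }
    done <- cohort
    for (mk in targets)
      done[[mk]][miss[[mk]]] <- marker_back(mk, cur[miss[[mk]], mk])
    cohorts[[copy]] <- done
  }
  structure(list(cohorts = cohorts, m = m, seed = seed, maxit = maxit,
                 missing_pattern = n_miss),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("<imputation_set> m =", x$m, "copies; missing per marker:\n")
  print(x$missing_pattern)
  invisible(x)
}

#' Rubin's rules for pooling multiply imputed estimates
#'
#' Combines `m` per-copy estimates (on the log hazard ratio scale for Cox
#' models) and their variances: pooled estimate is the mean, within
#' variance `W` the mean variance, between variance `B` the variance of the
#' estimates, total variance `T = W + (1 + 1/m) B`, with Barnard-Rubin
#' small-sample degrees of freedom (reducing to the classic
#' `(m - 1)/lambda^2` when `dfcom = Inf`).
#'
#' @param estimates numeric vector of per-copy estimates.
#' @param variances numeric vector of per-copy squared standard errors.
#' @param dfcom complete-data residual degrees of freedom (default `Inf`).
#' @param level confidence level.
#' @return a list of class `pooled_estimate`: `estimate`, `W`, `B`, `Tvar`,
#'   `se`, `df`, `ci` (on the estimate scale), `m`.
#' @export
pool_rubin <- function(estimates, variances, dfcom = Inf, level = 0.95) {
  m <- length(estimates)
  if (length(variances) != m) stop("estimates and variances differ in length")
  if (m < 2L) stop("pooling needs at least 2 estimates")
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- var(estimates)
  Tvar <- W + (1 + 1 / m) * B
  if (B > 0 && Tvar > 0) {
    lambda <- (1 + 1 / m) * B / Tvar
    df_old <- (m - 1) / lambda^2
    df <- if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      1 / (1 / df_old + 1 / df_obs)
    } else df_old
  } else {
    df <- Inf
  }
  tq <- qt(1 - (1 - level) / 2, df)
  structure(list(estimate = qbar, W = W, B = B, Tvar = Tvar,
                 se = sqrt(Tvar), df = df,
                 ci = qbar + c(-1, 1) * tq * sqrt(Tvar), m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "<pooled_estimate> %.4f (se %.4f) CI [%.4f, %.4f]; W %.5f B %.5f\n",
    x$estimate, x$se, x$ci[1], x$ci[2], x$W, x$B))
  invisible(x)
}
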