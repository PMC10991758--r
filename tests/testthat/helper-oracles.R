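# Independent oracles used across the suite.

# Brute-force day-by-day multistate occupancy bookkeeping: walks every
# integer day, updating state-occupancy probabilities from the weighted
# risk set and per-cause event counts of that day.
occupancy_oracle <- function(stop, cause, weights = NULL, start = NULL) {
  w <- if (is.null(weights)) rep(1, length(stop)) else weights
  st <- if (is.null(start)) rep(0, length(stop)) else start
  causes <- sort(unique(cause[!cause %in% c("censored", "none")]))
  days <- seq_len(max(stop))
  surv <- numeric(length(days))
  cifs <- matrix(0, length(days), length(causes),
                 dimnames = list(NULL, causes))
  s_cur <- 1
  cif_cur <- stats::setNames(rep(0, length(causes)), causes)
  for (d in days) {
    at_risk <- st < d & stop >= d
    n_d <- sum(w[at_risk])
    if (n_d > 0) {
      d_tot <- 0
      for (k in causes) {
        d_k <- sum(w[stop == d & cause == k])
        cif_cur[k] <- cif_cur[k] + s_cur * d_k / n_d
        d_tot <- d_tot + d_k
      }
      s_cur <- s_cur * (1 - d_tot / n_d)
    }
    surv[d] <- s_cur
    cifs[d, ] <- cif_cur
  }
  list(days = days, surv = surv, cif = cifs, causes = causes)
}

# Explicit Breslow partial log-likelihood for a single covariate.
breslow_loglik <- function(beta, start, stop, status, x, weights = NULL) {
  w <- if (is.null(weights)) rep(1, length(stop)) else weights
  ll <- 0
  for (t in unique(stop[status == 1])) {
    ev <- which(stop == t & status == 1)
    rs <- which(start < t & stop >= t)
    ll <- ll + sum(w[ev] * beta * x[ev]) -
      sum(w[ev]) * log(sum(w[rs] * exp(beta * x[rs])))
  }
  ll
}

# Golden-section/grid maximiser of the explicit partial likelihood.
oracle_cox_coef <- function(start, stop, status, x, weights = NULL) {
  stats::optimize(function(b)
    -breslow_loglik(b, start, stop, status, x, weights),
    interval = c(-10, 10), tol = 1e-9)$minimum
}

# Random small competing-risks dataset (plain time/cause vectors).
random_competing <- function(n, maxday = 8) {
  list(day = sample(seq_len(maxday), n, replace = TRUE),
       type = sample(c("death", "home", "transfer", "censored"), n,
                     replace = TRUE))
}

# Deterministic toy cohort with valid covariates; event/treatment structure
# supplied by the caller.
toy_cohort <- function(event_day, event_type,
                       treatment_day = rep(NA_integer_, length(event_day)),
                       admin_end = max(event_day)) {
  n <- length(event_day)
  data.frame(
    patient_id = seq_len(n),
    age = 60 + seq_len(n) %% 20,
    sex = seq_len(n) %% 2,
    cci = seq_len(n) %% 4,
    crp = 50 + 5 * seq_len(n), ldh = 300 + 3 * seq_len(n),
    ddimer = 600 + 10 * seq_len(n), lymph = 900 + 8 * seq_len(n),
    ferritin = 500 + 6 * seq_len(n),
    wave = 1 + seq_len(n) %% 3,
    treatment_day = as.integer(treatment_day),
    event_day = as.integer(event_day),
    event_type = event_type)
}

# Random valid cohort (covariates deterministic, events random) for
# property tests that need the full cohort schema.
random_cohort <- function(n, maxday = 10, admin_end = maxday,
                          p_treat = 0.3) {
  day <- sample(seq_len(maxday), n, replace = TRUE)
  type <- sample(c("death", "home", "transfer"), n, replace = TRUE)
  cens <- stats::runif(n) < 0.15
  day[cens] <- admin_end
  type[cens] <- "censored"
  trt <- ifelse(stats::runif(n) < p_treat,
                pmin(sample(seq_len(maxday), n, replace = TRUE), day),
                NA_integer_)
  toy_cohort(day, type, as.integer(trt), admin_end = admin_end)
}
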