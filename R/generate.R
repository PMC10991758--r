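# Discrete-time cohort simulator.

# Standardised design matrix used by the generator's linear predictors.
# Labs enter on the log scale; each column is centred/scaled by the
# parameters of `config`, so hazard intercepts stay interpretable as the
# hazards of a reference patient.
generator_design <- function(cohort, config) {
  cv <- config$covariates
  lab_z <- function(m) {
    p <- cv$labs[[m]]
    (log(cohort[[m]]) - p$meanlog) / sqrt(p$sdlog^2 + p$loading^2)
  }
  cbind(
    age_z = (cohort$age - cv$age_mean) / cv$age_sd,
    sex = cohort$sex - cv$male_prop,
    cci_z = (cohort$cci - cv$cci_center) / cv$cci_scale,
    crp_z = lab_z("crp"), ldh_z = lab_z("ldh"), ddimer_z = lab_z("ddimer"),
    lymph_z = lab_z("lymph"), ferritin_z = lab_z("ferritin"),
    wave2 = as.numeric(cohort$wave == 2),
    wave3 = as.numeric(cohort$wave == 3))
}

lin_pred <- function(z, coef) {
  if (length(coef) == 0) return(rep(0, nrow(z)))
  keep <- intersect(names(coef), colnames(z))
  if (length(keep) < length(coef))
    stop("unknown covariate(s) in coefficient vector: ",
         paste(setdiff(names(coef), colnames(z)), collapse = ", "))
  drop(z[, keep, drop = FALSE] %*% coef[keep])
}

draw_baseline <- function(config, n) {
  cv <- config$covariates
  sev <- rnorm(n)                      # shared latent severity factor
  lab <- function(m) {
    p <- cv$labs[[m]]
    exp(p$meanlog + p$loading * sev + rnorm(n, sd = p$sdlog))
  }
  data.frame(
    patient_id = seq_len(n),
    age = rnorm(n, cv$age_mean, cv$age_sd),
    sex = rbinom(n, 1, cv$male_prop),
    cci = rpois(n, exp(cv$cci_log_mean + cv$cci_severity * sev)),
    crp = lab("crp"), ldh = lab("ldh"), ddimer = lab("ddimer"),
    lymph = lab("lymph"), ferritin = lab("ferritin"),
    wave = sample.int(length(cv$wave_probs), n, replace = TRUE,
                      prob = cv$wave_probs))
}

#' Simulate a hospital cohort
#'
#' Draws `n` patients from the baseline covariate model of `config` and runs
#' the day-by-day competing-event simulation on days `1..admin_end`: each
#' day a still-hospitalised, still-untreated patient may initiate treatment
#' (daily logistic hazard with decaying intercept), then at most one
#' terminal event among in-hospital death, discharge home and transfer is
#' drawn from the cause-specific daily hazards, multiplied by the treatment
#' effect for patients treated on an earlier day.  Patients event-free at
#' `admin_end` are administratively censored on that day.
#'
#' @param config a [cohort_config()].
#' @param n number of patients (default `config$n`).
#' @param seed integer seed (default `config$seed`); identical
#'   `(config, n, seed)` yield an identical cohort.
#' @return a cohort `data.frame` with columns
#'   `patient_id, age, sex, cci, crp, ldh, ddimer, lymph, ferritin, wave,
#'   treatment_day, event_day, event_type`; `treatment_day` is `NA` for
#'   never-treated patients and `event_type` is one of
#'   `"death", "home", "transfer", "censored"`.
#' @examples
#' cohort <- generate_cohort(default_config(), n = 200, seed = 7)
#' table(cohort$event_type)
#' @export
generate_cohort <- function(config, n = config$n, seed = config$seed) {
  validate_config(config)
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("n must be a positive integer")
  set.seed(seed)

  cohort <- draw_baseline(config, n)
  z <- generator_design(cohort, config)

  lp <- vapply(CAUSES,
               function(k) lin_pred(z, config$hazards[[k]]$coef),
               numeric(n))
  base <- vapply(CAUSES, function(k) config$hazards[[k]]$log_base,
                 numeric(1))
  log_hr <- config$treatment$log_hr[CAUSES]
  ini <- config$treatment$init
  lp_trt <- lin_pred(z, ini$coef)
  if (any(!is.finite(lp)) || any(!is.finite(lp_trt)))
    stop("non-finite hazard linear predictor; check hazard coefficients")

  treatment_day <- rep(NA_integer_, n)
  event_day <- rep(NA_integer_, n)
  event_type <- rep(NA_character_, n)
  at_risk <- rep(TRUE, n)

  for (day in seq_len(config$admin_end)) {
    idx <- which(at_risk)
    if (length(idx) == 0L) break
    # treatment initiation (untreated patients, within the initiation window)
    untreated <- idx[is.na(treatment_day[idx])]
    if (day > (ini$end_day %||% config$admin_end)) untreated <- integer(0)
    if (length(untreated) > 0L) {
      p_init <- plogis(ini$intercept - ini$decay * (day - 1) +
                         lp_trt[untreated])
      init <- untreated[runif(length(untreated)) < p_init]
      treatment_day[init] <- day
    }
    # terminal event draw; treatment effective from the day after initiation
    on_trt <- !is.na(treatment_day[idx]) & treatment_day[idx] < day
    h <- exp(sweep(lp[idx, , drop = FALSE], 2, base, `+`) +
               outer(on_trt, log_hr))
    p_any <- 1 - exp(-rowSums(h))
    hit <- runif(length(idx)) < p_any
    if (any(hit)) {
      hi <- idx[hit]
      hmat <- h[hit, , drop = FALSE]
      u <- runif(length(hi)) * rowSums(hmat)
      cum <- t(apply(hmat, 1, cumsum))
      cause <- CAUSES[max.col(u <= cum, ties.method = "first")]
      event_day[hi] <- day
      event_type[hi] <- cause
      at_risk[hi] <- FALSE
    }
  }
  open <- is.na(event_day)
  event_day[open] <- config$admin_end
  event_type[open] <- "censored"
  # initiation drawn on the event day is kept (treatment_day == event_day);
  # it contributes no treated person-time under the next-day convention.

  cohort$treatment_day <- treatment_day
  cohort$event_day <- event_day
  cohort$event_type <- event_type
  validate_cohort(cohort, admin_end = config$admin_end)
  cohort
}

#' Inject missingness into the inflammatory markers
#'
#' Sets a configurable fraction of each inflammatory marker (CRP, LDH,
#' D-dimer, lymphocyte count, ferritin) to `NA`.  Under MCAR every value is
#' masked independently with the configured rate; under MAR the masking
#' probability depends on fully observed covariates (age and pandemic wave)
#' through a logistic model whose intercept is solved per marker so that the
#' expected missingness fraction on this cohort equals the configured rate.
#'
#' @param cohort a cohort `data.frame`.
#' @param config a [cohort_config()]; `config$missing` holds mechanism,
#'   rates and MAR coefficients.
#' @param seed optional seed; when `NULL` the current RNG state is used.
#' @return the cohort with `NA`s in the selected marker entries; no other
#'   column is touched.
#' @export
inject_missingness <- function(cohort, config, seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  ms <- config$missing
  if (any(ms$rates < 0 | ms$rates > 1))
    stop("missingness rates must lie in [0, 1]")
  n <- nrow(cohort)
  z <- generator_design(cohort, config)
  for (m in names(ms$rates)) {
    rate <- ms$rates[[m]]
    if (rate <= 0) next
    if (ms$mechanism == "MCAR" || rate >= 1) {
      p <- rep(rate, n)
    } else {
      eta <- lin_pred(z, ms$coef)
      alpha <- uniroot(function(a) mean(plogis(a + eta)) - rate,
                       interval = c(-30, 30), tol = 1e-10)$root
      p <- plogis(alpha + eta)
    }
    cohort[[m]][runif(n) < p] <- NA_real_
  }
  cohort
}
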