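# Cohort validation, summaries and CSV round-trip.

#' Validate a patient-level cohort
#'
#' Checks the cohort schema and its invariants: required columns, event days
#' in `[1, admin_end]`, event types among
#' `death / home / transfer / censored`, administrative censoring only at
#' `admin_end`, `treatment_day <= event_day` when present, and positive
#' observed lab values.
#'
#' @param cohort a cohort `data.frame`.
#' @param admin_end administrative end of follow-up (default 45).
#' @return `cohort`, invisibly; errors on violation.
#' @export
validate_cohort <- function(cohort, admin_end = 45L) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(cohort) == 0L) stop("cohort is empty")
  if (anyDuplicated(cohort$patient_id))
    stop("duplicated patient_id")
  if (!all(cohort$event_type %in% EVENT_TYPES))
    stop("unknown event_type value(s)")
  if (any(cohort$event_day < 1L | cohort$event_day > admin_end))
    stop("event_day outside [1, admin_end]")
  cens <- cohort$event_type == "censored"
  if (any(cohort$event_day[cens] != admin_end))
    stop("administrative censoring must occur at admin_end")
  trt <- !is.na(cohort$treatment_day)
  if (any(cohort$treatment_day[trt] > cohort$event_day[trt]))
    stop("treatment_day after event_day")
  if (any(cohort$treatment_day[trt] < 1L))
    stop("treatment_day must be >= 1")
  for (m in MARKERS) {
    v <- cohort[[m]]
    if (any(!is.na(v) & v <= 0)) stop("non-positive value in ", m)
  }
  invisible(cohort)
}

#' Event and treatment margins of a cohort
#'
#' Counts and fractions of each terminal event type plus the derived
#' margins used for generator calibration: fraction discharged (home or
#' transfer), fraction of discharges that went home, fraction ever treated,
#' and fraction treated within the grace period.
#'
#' @param cohort a cohort `data.frame`.
#' @param grace grace-period cutoff in days for the "treated early" margin.
#' @return a list of class `event_table` with `counts`, `fractions` (both
#'   named by event type) and scalar margins `discharged`,
#'   `home_among_discharged`, `ever_treated`, `treated_by_grace`.
#' @export
event_table <- function(cohort, grace = 2L) {
  if (nrow(cohort) == 0L) stop("cohort is empty")
  n <- nrow(cohort)
  counts <- vapply(EVENT_TYPES,
                   function(k) sum(cohort$event_type == k), numeric(1))
  discharged <- counts[["home"]] + counts[["transfer"]]
  treated <- !is.na(cohort$treatment_day)
  structure(
    list(n = n,
         counts = counts,
         fractions = counts / n,
         discharged = discharged / n,
         home_among_discharged =
           if (discharged > 0) counts[["home"]] / discharged else NA_real_,
         ever_treated = mean(treated),
         treated_by_grace = mean(treated &
                                   cohort$treatment_day <= grace),
         grace = grace),
    class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("n =", x$n, "\n")
  for (k in names(x$counts))
    cat(sprintf("  %-9s %6d (%5.1f%%)\n", k, x$counts[[k]],
                100 * x$fractions[[k]]))
  cat(sprintf("  discharged %.1f%%; home among discharged %.1f%%\n",
              100 * x$discharged, 100 * x$home_among_discharged))
  cat(sprintf("  ever treated %.1f%%; treated by day %d: %.1f%%\n",
              100 * x$ever_treated, x$grace, 100 * x$treated_by_grace))
  invisible(x)
}

#' Write / read a cohort as CSV
#'
#' The on-disk schema is one row per patient with header
#' `patient_id,age,sex,cci,crp,ldh,ddimer,lymph,ferritin,wave,treatment_day,
#' event_day,event_type`; empty fields encode missing values.  A write
#' followed by a read is lossless (up to 15 significant digits on the
#' continuous covariates).
#'
#' @param cohort a cohort `data.frame`.
#' @param path file path.
#' @param admin_end follow-up horizon used for validation on read.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the
#'   validated cohort.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort, admin_end = max(cohort$event_day))
  out <- cohort[, COHORT_COLUMNS]
  for (m in c(MARKERS, "age"))   # full precision, empty field = missing
    out[[m]] <- ifelse(is.na(out[[m]]), "", sprintf("%.15g", out[[m]]))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, admin_end = 45L) {
  cohort <- read.csv(path, stringsAsFactors = FALSE,
                     colClasses = c(patient_id = "integer",
                                    sex = "integer", cci = "integer",
                                    wave = "integer",
                                    treatment_day = "integer",
                                    event_day = "integer",
                                    event_type = "character"))
  validate_cohort(cohort, admin_end = admin_end)
  cohort
}

#' Baseline covariates on the analysis scale
#'
#' Returns the baseline covariate matrix used by the regression models:
#' age (per 10 years), sex, Charlson index, log-transformed CRP, LDH,
#' D-dimer and ferritin, square-root-transformed lymphocyte count, and wave
#' indicator columns.  The log and square-root transformations tame the
#' right skew of the inflammatory markers.
#'
#' @param cohort a cohort `data.frame` (or clone dataset carrying the same
#'   covariate columns).
#' @return a numeric matrix with one row per input row and columns
#'   `age10, sex, cci, log_crp, log_ldh, log_ddimer, sqrt_lymph,
#'   log_ferritin, wave2, wave3`.
#' @export
baseline_covariates <- function(cohort) {
  cbind(age10 = cohort$age / 10,
        sex = as.numeric(cohort$sex),
        cci = as.numeric(cohort$cci),
        log_crp = log(cohort$crp),
        log_ldh = log(cohort$ldh),
        log_ddimer = log(cohort$ddimer),
        sqrt_lymph = sqrt(cohort$lymph),
        log_ferritin = log(cohort$ferritin),
        wave2 = as.numeric(cohort$wave == 2),
        wave3 = as.numeric(cohort$wave == 3))
}

#' @rdname baseline_covariates
#' @export
covariate_names <- function() {
  c("age10", "sex", "cci", "log_crp", "log_ldh", "log_ddimer",
    "sqrt_lymph", "log_ferritin", "wave2", "wave3")
}
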