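# Counting-process (start-stop) views of a cohort.

counting_row_frame <- function(cohort, start, stop, treated, cause, idx) {
  covs <- baseline_covariates(cohort)[idx, , drop = FALSE]
  data.frame(patient_id = cohort$patient_id[idx],
             start = start, stop = stop,
             treated = as.integer(treated), cause = cause,
             weight = 1, covs, row.names = NULL)
}

#' Start-stop counting-process representation of a cohort
#'
#' Splits each patient's follow-up into half-open intervals `(start, stop]`
#' with a time-varying treatment indicator.  Never-treated patients (and
#' patients whose treatment began on their event day, which contributes no
#' treated person-time under the effect-from-next-day convention) yield one
#' untreated interval `(0, event_day]`; a patient treated on day `t` with
#' `t < event_day` yields `(0, t]` untreated plus `(t, event_day]` treated.
#' The terminal cause sits on the final interval; all other intervals carry
#' cause `"none"`.
#'
#' @param cohort a cohort `data.frame`.
#' @return a `data.frame` of counting-process rows with columns
#'   `patient_id, start, stop, treated, cause, weight` plus the
#'   [baseline_covariates()] columns.
#' @examples
#' cohort <- generate_cohort(default_config(), n = 50, seed = 1)
#' rows <- to_counting_process(cohort)
#' # person-time is conserved:
#' all(tapply(rows$stop - rows$start, rows$patient_id, sum) ==
#'     cohort$event_day[order(cohort$patient_id)])
#' @export
to_counting_process <- function(cohort) {
  validate_cohort(cohort, admin_end = max(cohort$event_day))
  trt <- !is.na(cohort$treatment_day)
  split_idx <- which(trt & cohort$treatment_day < cohort$event_day)
  single_idx <- setdiff(seq_len(nrow(cohort)), split_idx)

  single <- counting_row_frame(
    cohort, start = 0,
    stop = cohort$event_day[single_idx],
    treated = 0L,
    cause = ifelse(cohort$event_type[single_idx] == "censored", "none",
                   cohort$event_type[single_idx]),
    idx = single_idx)
  if (length(split_idx) == 0L) return(single)

  pre <- counting_row_frame(
    cohort, start = 0, stop = cohort$treatment_day[split_idx],
    treated = 0L, cause = "none", idx = split_idx)
  post <- counting_row_frame(
    cohort, start = cohort$treatment_day[split_idx],
    stop = cohort$event_day[split_idx], treated = 1L,
    cause = ifelse(cohort$event_type[split_idx] == "censored", "none",
                   cohort$event_type[split_idx]),
    idx = split_idx)
  rows <- rbind(single, pre, post)
  rows[order(rows$patient_id, rows$start), , drop = FALSE]
}

#' Baseline-misclassified (immortal-time-biased) view of a cohort
#'
#' The deliberately biased treatment coding: one interval `(0, event_day]`
#' per patient with `treated = 1` for every patient who ever initiated
#' treatment, attributing the pre-treatment (immortal) person-time to the
#' treated group.  Event days and causes are untouched; only the treatment
#' attribution differs from [to_counting_process()].
#'
#' @inheritParams to_counting_process
#' @return a `data.frame` of counting-process rows, one per patient.
#' @export
misclassify_baseline <- function(cohort) {
  validate_cohort(cohort, admin_end = max(cohort$event_day))
  counting_row_frame(
    cohort, start = 0, stop = cohort$event_day,
    treated = as.integer(!is.na(cohort$treatment_day)),
    cause = ifelse(cohort$event_type == "censored", "none",
                   cohort$event_type),
    idx = seq_len(nrow(cohort)))
}

#' Cause-specific view of counting-process rows
#'
#' Recodes the competing-risks rows for a cause-specific analysis of one
#' endpoint: rows ending in the target cause get `status = 1`; events of
#' any other cause become censorings at the same day (`status = 0`).
#'
#' @param rows counting-process rows from [to_counting_process()],
#'   [misclassify_baseline()] or the emulation.
#' @param cause one of `"death"`, `"home"`, `"transfer"`.
#' @return `rows` with an added binary `status` column.
#' @export
cause_specific_view <- function(rows, cause) {
  if (!cause %in% CAUSES)
    stop("unknown cause: ", cause)
  rows$status <- as.integer(rows$cause == cause)
  rows
}

#' Write counting-process rows as CSV
#'
#' Exports rows in the start-stop CSV dialect
#' `patient_id,start,stop,treated,cause,weight,<covariates...>`.
#'
#' @param rows counting-process rows.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_counting_process <- function(rows, path) {
  write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
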