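# Right-continuous step curves and weighted product-limit estimators.

#' Right-continuous step curve
#'
#' A step function defined by strictly increasing jump times, the value
#' attained at (and after) each jump, and the value before the first jump.
#' Survival curves start at 1 and are non-increasing; cumulative-incidence
#' curves start at 0 and are non-decreasing.
#'
#' @param time strictly increasing jump times (days).
#' @param value value at and after each jump.
#' @param v0 value before the first jump.
#' @return an object of class `step_curve`.
#' @export
step_curve <- function(time, value, v0) {
  if (length(time) != length(value))
    stop("time and value must have equal length")
  if (is.unsorted(time, strictly = TRUE))
    stop("jump times must be strictly increasing")
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 v0 = as.numeric(v0)),
            class = "step_curve")
}

#' Evaluate a step curve
#'
#' Right-continuous evaluation: at a jump time the post-jump value is
#' returned; before the first jump, the initial value; after the last jump,
#' the final value.
#'
#' @param curve a [step_curve()].
#' @param t evaluation times (vectorised), `t >= 0`.
#' @return numeric vector of curve values.
#' @export
curve_at <- function(curve, t) {
  stopifnot(inherits(curve, "step_curve"))
  idx <- findInterval(t, curve$time)
  c(curve$v0, curve$value)[idx + 1L]
}

#' @export
print.step_curve <- function(x, ...) {
  cat("<step_curve> ", length(x$time), " jumps; value ",
      format(x$v0), " -> ", format(if (length(x$value))
        x$value[length(x$value)] else x$v0), "\n", sep = "")
  invisible(x)
}

#' @export
plot.step_curve <- function(x, ..., xlab = "days", ylab = "probability",
                            xmax = NULL) {
  xmax <- xmax %||% if (length(x$time)) max(x$time) else 1
  tt <- c(0, rep(x$time, each = 2), xmax)
  vv <- c(rep(c(x$v0, x$value), each = 2))
  plot(tt, vv[seq_along(tt)], type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Export a step curve as a two-column data frame
#'
#' @param x a [step_curve()].
#' @param row.names,optional,... ignored (S3 signature).
#' @return `data.frame` with columns `time` and `value` (the value from
#'   each time onward, starting at time 0).
#' @export
as.data.frame.step_curve <- function(x, row.names = NULL,
                                     optional = FALSE, ...) {
  data.frame(time = c(0, x$time), value = c(x$v0, x$value))
}

# Shared risk-set bookkeeping.  Rows are (start, stop] intervals with an
# optional cause at stop; a subject is at risk at time t iff
# start < t <= stop, so at a tied day events precede censorings.
risk_table <- function(start, stop, is_event, weights) {
  ev_times <- sort(unique(stop[is_event & weights > 0]))
  n_at <- vapply(ev_times,
                 function(t) sum(weights[start < t & stop >= t]),
                 numeric(1))
  list(times = ev_times, n = n_at)
}

check_surv_args <- function(stop, weights, start) {
  if (length(stop) == 0L) stop("empty input")
  if (any(weights < 0)) stop("negative weight")
  if (any(stop <= start)) stop("stop must exceed start")
  if (any(stop <= 0)) stop("event times must be positive")
}

#' Weighted Kaplan-Meier product-limit estimator
#'
#' Computes the product-limit estimate of the event-free survival function
#' \deqn{\hat S(t) = \prod_{t_j \le t} (1 - d_j / n_j)}
#' with weighted event counts \eqn{d_j} and weighted risk sets \eqn{n_j}.
#' Rows may carry entry times (`start`), enabling the estimator on
#' counting-process data with piecewise-constant weights; at a tied day,
#' events precede censorings in the risk-set accounting.  With all weights
#' equal the estimate matches the unweighted estimator, and the estimate is
#' invariant to rescaling all weights.
#'
#' @param time event/censoring times (interval ends), `> start`.
#' @param status 1 for an event at `time`, 0 for censoring.
#' @param weights non-negative observation weights (default all 1).
#' @param start entry times (default 0); intervals are `(start, time]`.
#' @return a [step_curve()] of `S(t)` starting at 1.
#' @export
kaplan_meier <- function(time, status, weights = NULL, start = NULL) {
  n <- length(time)
  weights <- weights %||% rep(1, n)
  start <- start %||% rep(0, n)
  status <- as.numeric(status)
  check_surv_args(time, weights, start)
  rt <- risk_table(start, time, status > 0, weights)
  if (length(rt$times) == 0L)
    return(step_curve(numeric(0), numeric(0), 1))
  d <- vapply(rt$times,
              function(t) sum(weights[time == t & status > 0]),
              numeric(1))
  if (any(rt$n <= 0))
    stop("empty risk set at an event time with positive weight")
  step_curve(rt$times, cumprod(1 - d / rt$n), 1)
}

#' Naive one-minus-Kaplan-Meier cumulative incidence
#'
#' The deliberately biased estimator of a cause-specific cumulative
#' incidence: competing events are treated as right-censored observations
#' and `1 - KM` of the target cause is returned.  In the presence of
#' competing events it over-estimates the cumulative incidence, lying at or
#' above the Aalen-Johansen estimate everywhere.
#'
#' @param time event/censoring times.
#' @param cause character vector of causes; `"censored"`/`"none"` denote
#'   censoring.
#' @param target_cause the cause whose incidence is estimated.
#' @param weights non-negative weights.
#' @param start optional entry times.
#' @return a [step_curve()] of the naive cumulative incidence.
#' @export
one_minus_km <- function(time, cause, target_cause, weights = NULL,
                         start = NULL) {
  km <- kaplan_meier(time, as.numeric(cause == target_cause),
                     weights = weights, start = start)
  step_curve(km$time, 1 - km$value, 0)
}

#' Weighted Aalen-Johansen estimator of cumulative incidence
#'
#' Nonparametric multistate estimator of the cause-specific cumulative
#' incidence functions under competing risks:
#' \deqn{\widehat{CIF}_k(t) = \sum_{t_j \le t} \hat S(t_j-) \, d_{kj}/n_j}
#' with the overall event-free product-limit survival \eqn{\hat S}.  Rows
#' may be counting-process intervals `(start, time]` with per-interval
#' weights, as produced by the clone-censor-weight emulation (the weight of
#' an interval enters both the risk set and the event count at times inside
#' it).  With a single cause the target CIF equals `1 - KM`; at every time
#' the cause CIFs and the overall survival sum to one.
#'
#' @inheritParams one_minus_km
#' @param cause character vector of causes at `time`;
#'   `"censored"`/`"none"` denote censoring.
#' @return an object of class `cif_set`: list with `cif` (named list of
#'   [step_curve()]s, one per observed cause), `surv` (overall event-free
#'   survival [step_curve()]) and `causes`.
#' @export
aalen_johansen <- function(time, cause, weights = NULL, start = NULL) {
  n <- length(time)
  weights <- weights %||% rep(1, n)
  start <- start %||% rep(0, n)
  check_surv_args(time, weights, start)
  cause <- as.character(cause)
  causes <- sort(unique(cause[!cause %in% c("censored", "none")]))
  is_event <- cause %in% causes
  rt <- risk_table(start, time, is_event, weights)
  if (length(rt$times) == 0L) {
    empty <- step_curve(numeric(0), numeric(0), 0)
    return(structure(list(cif = setNames(rep(list(empty), length(causes)),
                                         causes),
                          surv = step_curve(numeric(0), numeric(0), 1),
                          causes = causes),
                     class = "cif_set"))
  }
  if (any(rt$n <= 0))
    stop("empty risk set at an event time with positive weight")
  d_k <- vapply(causes, function(k) {
    vapply(rt$times, function(t) sum(weights[time == t & cause == k]),
           numeric(1))
  }, numeric(length(rt$times)))
  d_k <- matrix(d_k, nrow = length(rt$times),
                dimnames = list(NULL, causes))
  d_tot <- rowSums(d_k)
  surv <- cumprod(1 - d_tot / rt$n)
  s_minus <- c(1, head(surv, -1))
  cif <- lapply(causes, function(k)
    step_curve(rt$times, cumsum(s_minus * d_k[, k] / rt$n), 0))
  structure(list(cif = setNames(cif, causes),
                 surv = step_curve(rt$times, surv, 1),
                 causes = causes),
            class = "cif_set")
}

#' @export
print.cif_set <- function(x, ...) {
  cat("<cif_set> causes:", paste(x$causes, collapse = ", "), "\n")
  tend <- if (length(x$surv$time)) max(x$surv$time) else 0
  for (k in x$causes)
    cat(sprintf("  CIF_%s(%g) = %.4f\n", k, tend,
                curve_at(x$cif[[k]], tend)))
  cat(sprintf("  S(%g) = %.4f\n", tend, curve_at(x$surv, tend)))
  invisible(x)
}
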