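# Propensity-score and censoring weights, and balance diagnostics.
#
# Logistic fitting is delegated to stats::glm (binomial IRLS); this file
# owns the weight constructions and the standardized-difference diagnostic.

#' Fit a logistic model
#'
#' Maximum-likelihood logistic regression of a binary outcome on a
#' covariate matrix, used for the treatment propensity model and the pooled
#' daily censoring models.  Separation (fitted probabilities collapsing to
#' 0/1 or exploding coefficients) raises an error rather than returning an
#' unusable model.
#'
#' @param outcome binary vector (one element per patient/row).
#' @param covariates numeric matrix or data.frame of predictors (an
#'   intercept is added).
#' @return an object of class `propensity_model`: list with `coef`,
#'   `fitted` (probabilities), `converged`, and the design column names.
#' @export
fit_logistic <- function(outcome, covariates = NULL) {
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary")
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  x <- if (is.null(covariates) || NCOL(covariates) == 0L)
    matrix(numeric(0), nrow = length(y), ncol = 0)
  else as.matrix(covariates)
  X <- cbind(`(Intercept)` = 1, x)
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(), control = list(epsilon = 1e-10,
                                                      maxit = 100)))
  p <- fit$fitted.values
  if (any(abs(coef(fit)) > 20, na.rm = TRUE) ||
      any(p < 1e-10) || any(p > 1 - 1e-10))
    stop("separation detected in logistic model")
  if (any(is.na(coef(fit))))
    stop("collinear predictors in logistic model")
  structure(list(coef = coef(fit), fitted = p,
                 converged = fit$converged,
                 columns = colnames(X)),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("<propensity_model> fitted range [",
      sprintf("%.3f", min(x$fitted)), ", ",
      sprintf("%.3f", max(x$fitted)), "]\n", sep = "")
  print(round(x$coef, 4))
  invisible(x)
}

#' Inverse-probability-of-treatment weights
#'
#' Converts fitted propensity scores into IPT weights.  Stabilized weights
#' are `p / PS` for the treated and `(1 - p) / (1 - PS)` for the untreated,
#' with `p` the marginal treated fraction (so their mean is close to 1);
#' unstabilized weights are `1 / PS` and `1 / (1 - PS)`.  Propensity scores
#' are floored/ceiled at `1e-6` and weights truncated at the requested
#' percentile.
#'
#' @param model a [fit_logistic()] propensity model (treatment-ever on
#'   baseline covariates).
#' @param treated binary vector of observed treatment (same order as the
#'   model's rows).
#' @param stabilized use stabilized weights (default `TRUE`).
#' @param truncation percentile (in (0, 100]) at which weights are capped;
#'   100 disables truncation.
#' @return numeric vector of weights.
#' @export
iptw_weights <- function(model, treated, stabilized = TRUE,
                         truncation = 99) {
  stopifnot(inherits(model, "propensity_model"))
  ps <- pmin(pmax(model$fitted, 1e-6), 1 - 1e-6)
  tr <- as.numeric(treated)
  p_marg <- mean(tr)
  w <- ifelse(tr == 1, 1 / ps, 1 / (1 - ps))
  if (stabilized) w <- w * ifelse(tr == 1, p_marg, 1 - p_marg)
  if (truncation < 100) {
    cap <- quantile(w, truncation / 100, names = FALSE)
    w <- pmin(w, cap)
  }
  w
}

#' Inverse-probability-of-censoring weights for artificial censoring
#'
#' For each arm of a clone dataset, fits a pooled daily logistic model for
#' remaining artificially uncensored on days `1..grace` given baseline
#' covariates (with a day intercept), and converts the fitted daily
#' probabilities into cumulative clone weights
#' `w(t) = 1 / prod_{s <= min(t, grace)} P(uncensored at s | X, arm)`.
#' Weights are constant after the grace period and truncated at the 99th
#' percentile within arm and day.  Days on which an arm has no artificial
#' censoring contribute probability 1 exactly.
#'
#' @param clones a [clone_and_censor()] dataset.
#' @param covariates character vector of covariate column names used in the
#'   censoring models (default [covariate_names()]); may be `NULL` for a
#'   covariate-free model.
#' @param grace grace period in days (default from the clone attributes).
#' @param truncation percentile cap on the cumulative weights.
#' @return matrix (`nrow(clones)` x `grace`) of cumulative weights per day,
#'   with attribute `models` (per-arm fitted coefficient lists).
#' @export
ipcw_artificial_censoring <- function(clones, covariates = covariate_names(),
                                      grace = attr(clones, "grace"),
                                      truncation = 99) {
  stopifnot(inherits(clones, "clone_dataset"))
  grace <- as.integer(grace)
  n <- nrow(clones)
  W <- matrix(1, n, grace)
  models <- list()
  xall <- if (length(covariates))
    as.matrix(clones[, covariates, drop = FALSE]) else NULL

  for (arm in c("treated", "control")) {
    in_arm <- clones$arm == arm
    prob <- matrix(1, sum(in_arm), grace)      # P(uncensored at day s | X)
    art_day <- ifelse(clones$outcome[in_arm] == "artificial",
                      clones$fu_day[in_arm], Inf)
    fu <- clones$fu_day[in_arm]
    risk_rows <- list(); risk_day <- list(); risk_y <- list()
    for (s in seq_len(grace)) {
      at_risk <- fu >= s
      if (!any(at_risk)) next
      y <- as.numeric(art_day[at_risk] != s)
      if (all(y == 0))
        stop("all clones of the ", arm,
             " arm are artificially censored at day ", s)
      if (any(y == 0)) {
        risk_rows[[length(risk_rows) + 1L]] <- which(at_risk)
        risk_day[[length(risk_day) + 1L]] <- s
        risk_y[[length(risk_y) + 1L]] <- y
      }
    }
    if (length(risk_day) && is.null(xall)) {
      # covariate-free pooled model with day intercepts is saturated: the
      # fitted daily probabilities are the observed uncensored fractions
      models[[arm]] <- list(coef = NULL, columns = NULL,
                            days = unlist(risk_day),
                            daily = vapply(risk_y, mean, numeric(1)))
      for (j in seq_along(risk_day))
        prob[risk_rows[[j]], risk_day[[j]]] <- mean(risk_y[[j]])
    } else if (length(risk_day)) {
      rows <- unlist(risk_rows)
      days <- rep(unlist(risk_day), lengths(risk_rows))
      y <- unlist(risk_y)
      X <- matrix(1, length(rows), 1, dimnames = list(NULL, "(Intercept)"))
      if (length(risk_day) > 1L) {
        dd <- sort(unique(days))[-1]
        D <- vapply(dd, function(s) as.numeric(days == s),
                    numeric(length(days)))
        colnames(D) <- paste0("day", dd)
        X <- cbind(X, D)
      }
      idx_arm <- which(in_arm)
      X <- cbind(X, xall[idx_arm[rows], , drop = FALSE])
      fit <- suppressWarnings(
        glm.fit(X, y, family = binomial(),
                control = list(epsilon = 1e-10, maxit = 100)))
      if (any(is.na(coef(fit))))
        stop("collinear predictors in censoring model (", arm, " arm)")
      models[[arm]] <- list(coef = coef(fit), columns = colnames(X),
                            days = unlist(risk_day))
      for (j in seq_along(risk_day)) {
        s <- risk_day[[j]]
        sel <- days == s
        prob[risk_rows[[j]], s] <- pmin(pmax(fit$fitted.values[sel],
                                             1e-6), 1)
      }
    } else {
      models[[arm]] <- list(coef = NULL, columns = NULL, days = integer(0))
    }
    cum <- 1 / prob
    if (grace > 1L)
      for (s in 2:grace) cum[, s] <- cum[, s - 1L] * cum[, s]
    if (truncation < 100) {
      for (s in seq_len(grace)) {
        cap <- quantile(cum[, s], truncation / 100, names = FALSE)
        cum[, s] <- pmin(cum[, s], cap)
      }
    }
    W[in_arm, ] <- cum
  }
  attr(W, "models") <- models
  attr(W, "grace") <- grace
  W
}

#' Standardized mean differences between two groups
#'
#' Covariate balance diagnostic
#' `SMD = (mean1 - mean2) / sqrt((var1 + var2) / 2)`, with weighted means
#' and variances when weights are supplied; binary covariates use the
#' proportion-based variance `p (1 - p)`.
#'
#' @param data data.frame or matrix holding the covariate columns.
#' @param group binary/logical vector (or two-level factor) defining the
#'   two groups.
#' @param covariates covariate column names (default: all columns of
#'   `data`).
#' @param weights optional non-negative observation weights.
#' @return named numeric vector of SMDs.
#' @export
standardized_differences <- function(data, group,
                                     covariates = colnames(data),
                                     weights = NULL) {
  g <- if (is.factor(group) || is.character(group))
    as.numeric(factor(group)) - 1 else as.numeric(group)
  if (length(unique(g)) != 2L) stop("group must define exactly two groups")
  weights <- weights %||% rep(1, length(g))
  vapply(covariates, function(nm) {
    x <- as.numeric(data[[nm]] %||% data[, nm])
    st <- lapply(c(0, 1), function(lv) {
      w <- weights[g == lv]; v <- x[g == lv]
      mu <- weighted.mean(v, w)
      var_w <- if (all(x %in% c(0, 1))) mu * (1 - mu)
      else sum(w * (v - mu)^2) / sum(w) * sum(w) / (sum(w) - 1)
      list(mu = mu, var = var_w)
    })
    pooled <- sqrt((st[[1]]$var + st[[2]]$var) / 2)
    if (pooled == 0) {
      if (st[[1]]$mu == st[[2]]$mu) return(0)
      stop("zero pooled variance with unequal means for ", nm)
    }
    (st[[2]]$mu - st[[1]]$mu) / pooled
  }, numeric(1))
}
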