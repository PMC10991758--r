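cox_rows <- function(stop, status, x, start = rep(0, length(stop)),
                     weight = rep(1, length(stop))) {
  data.frame(patient_id = seq_along(stop), start = start, stop = stop,
             status = status, grp = x, weight = weight)
}

test_that("label-symmetric data give a zero coefficient", {
  rows <- cox_rows(stop = c(1, 1, 2, 2, 3, 3), status = rep(1, 6),
                   x = c(0, 1, 0, 1, 0, 1))
  fit <- fit_cox(rows, "grp", robust = FALSE)
  expect_equal(unname(fit$coef), 0, tolerance = 1e-8)
  st <- score_test_null(rows, "grp")
  expect_equal(st$statistic, 0, tolerance = 1e-10)
})

test_that("coefficient matches brute-force partial-likelihood maximization", {
  # 6 subjects, alternating groups, all events, Breslow ties
  rows <- cox_rows(stop = 1:6, status = rep(1, 6),
                   x = c(1, 0, 1, 0, 1, 0))
  fit <- fit_cox(rows, "grp", ties = "breslow", robust = FALSE)
  oracle <- oracle_cox_coef(rows$start, rows$stop, rows$status, rows$grp)
  expect_equal(unname(fit$coef), oracle, tolerance = 1e-6)
  # random small datasets, including start-stop rows and case weights
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    stop_t <- sample(1:10, n)              # distinct times
    start_t <- pmax(stop_t - sample(1:5, n, replace = TRUE), 0)
    status <- rbinom(n, 1, 0.8)
    if (sum(status) < 2) next
    x <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2) next
    w <- sample(1:3, n, replace = TRUE)
    rows <- cox_rows(stop_t, status, x, start = start_t, weight = w)
    fit <- try(suppressWarnings(
      fit_cox(rows, "grp", ties = "breslow", use_weights = TRUE,
              robust = FALSE)), silent = TRUE)
    if (inherits(fit, "try-error") || fit$monotone) next # degenerate toys
    oracle <- oracle_cox_coef(start_t, stop_t, status, x, w)
    if (abs(oracle) > 9) next
    expect_equal(unname(fit$coef), oracle, tolerance = 1e-5)
  }
})

test_that("unit weights equal omitted weights; Efron = Breslow untied", {
  set.seed(12)
  co <- generate_cohort(default_config(), n = 150, seed = 13)
  rows <- cause_specific_view(to_counting_process(co), "death")
  f1 <- fit_cox(rows, "treated", use_weights = TRUE)   # weight column = 1
  f2 <- fit_cox(rows, "treated", use_weights = FALSE)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-12)
  expect_equal(f1$robust_var, f2$robust_var, tolerance = 1e-12)
  # untied data: ties method is irrelevant
  rows2 <- cox_rows(stop = 1:8, status = rep(1, 8),
                    x = c(1, 0, 0, 1, 1, 0, 1, 0))
  fe <- fit_cox(rows2, "grp", ties = "efron", robust = FALSE)
  fb <- fit_cox(rows2, "grp", ties = "breslow", robust = FALSE)
  expect_equal(fe$coef, fb$coef, tolerance = 1e-10)
})

test_that("fits are invariant to time shifts and id relabeling", {
  set.seed(14)
  co <- generate_cohort(default_config(), n = 120, seed = 15)
  rows <- cause_specific_view(to_counting_process(co), "death")
  f0 <- fit_cox(rows, "treated")
  shifted <- rows
  shifted$start <- shifted$start + 7
  shifted$stop <- shifted$stop + 7
  f1 <- fit_cox(shifted, "treated")
  expect_equal(f0$coef, f1$coef, tolerance = 1e-10)
  relab <- rows
  relab$patient_id <- relab$patient_id + 1000
  f2 <- fit_cox(relab, "treated")
  expect_equal(f0$coef, f2$coef, tolerance = 1e-12)
  expect_equal(f0$robust_var, f2$robust_var, tolerance = 1e-12)
})

test_that("hazard_ratio applies the Wald construction", {
  rows <- cox_rows(stop = c(1, 2, 3, 4, 5, 6), status = rep(1, 6),
                   x = c(1, 0, 1, 0, 0, 1))
  fit <- fit_cox(rows, "grp", robust = FALSE)
  hr <- hazard_ratio(fit, "grp")
  se <- sqrt(fit$var[1, 1])
  expect_equal(hr[["hr"]], exp(fit$coef[["grp"]]))
  expect_equal(hr[["lower"]], exp(fit$coef[["grp"]] - qnorm(0.975) * se))
  expect_equal(hr[["upper"]], exp(fit$coef[["grp"]] + qnorm(0.975) * se))
  expect_true(hr[["lower"]] <= hr[["hr"]] && hr[["hr"]] <= hr[["upper"]])
  expect_error(hazard_ratio(fit, "nope"), "unknown")
})

test_that("degenerate and monotone likelihoods are flagged", {
  rows <- cox_rows(stop = 1:4, status = rep(1, 4), x = rep(1, 4))
  expect_error(fit_cox(rows, "grp", robust = FALSE), "degenerate")
  # perfectly separating covariate: monotone likelihood
  rows2 <- cox_rows(stop = c(1, 2, 3, 11, 12, 13), status = rep(1, 6),
                    x = c(1, 1, 1, 0, 0, 0))
  expect_warning(fit <- fit_cox(rows2, "grp", robust = FALSE), "monotone")
  expect_true(fit$monotone)
  expect_lte(abs(unname(fit$coef)), 15)
})

test_that("score test equals gradient^2 / information at the null", {
  set.seed(16)
  d <- random_competing(25)
  status <- as.numeric(d$type == "death")
  x <- rbinom(25, 1, 0.5)
  rows <- cox_rows(d$day, status, x)
  st <- score_test_null(rows, "grp")
  eps <- 1e-5
  grad <- (breslow_loglik(eps, rows$start, rows$stop, status, x) -
             breslow_loglik(-eps, rows$start, rows$stop, status, x)) /
    (2 * eps)
  info <- -(breslow_loglik(eps, rows$start, rows$stop, status, x) -
              2 * breslow_loglik(0, rows$start, rows$stop, status, x) +
              breslow_loglik(-eps, rows$start, rows$stop, status, x)) /
    eps^2
  expect_equal(st$statistic, grad^2 / info, tolerance = 1e-4)
  # statistic grows with group imbalance in event times
  sep <- function(shift) {
    rows <- cox_rows(c(1:5, (1:5) + shift), status = rep(1, 10),
                     x = rep(c(1, 0), each = 5))
    score_test_null(rows, "grp")$statistic
  }
  expect_true(sep(0) < sep(3) && sep(3) < sep(8))
})

test_that("parameter recovery: start-stop coding estimates the true log-HR", {
  cfg <- randomized_config(log_hr = c(death = log(0.7), home = 0,
                                      transfer = 0))
  co <- generate_cohort(cfg, n = 10000, seed = 17)
  rows <- cause_specific_view(to_counting_process(co), "death")
  fit <- fit_cox(rows, "treated", robust = FALSE)
  # single-draw Monte-Carlo check at ~3 SE
  expect_lt(abs(fit$coef[["treated"]] - log(0.7)),
            3 * sqrt(fit$var[1, 1]))
})
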