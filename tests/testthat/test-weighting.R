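test_that("fit_logistic recovers closed-form and symmetric solutions", {
  # intercept-only model: logit of the observed rate
  y <- rep(c(1, 0), c(3, 7))
  m <- fit_logistic(y)
  expect_equal(unname(m$coef), log(0.3 / 0.7), tolerance = 1e-8)
  # antisymmetric balanced design: zero slope
  x <- c(-2, -1, 1, 2, -2, -1, 1, 2)
  y2 <- c(1, 1, 0, 0, 0, 0, 1, 1)
  m2 <- fit_logistic(y2, cbind(x = x))
  expect_equal(unname(m2$coef[["x"]]), 0, tolerance = 1e-8)
  # brute-force likelihood grid on one-covariate data
  set.seed(31)
  x3 <- rnorm(60)
  y3 <- rbinom(60, 1, plogis(0.4 + 0.9 * x3))
  m3 <- fit_logistic(y3, cbind(x = x3))
  loglik <- function(a, b) sum(y3 * (a + b * x3) - log1p(exp(a + b * x3)))
  opt <- optim(c(0, 0), function(p) -loglik(p[1], p[2]))
  expect_equal(unname(m3$coef), opt$par, tolerance = 1e-3)
  # separation is flagged
  expect_error(fit_logistic(c(0, 0, 1, 1), cbind(x = c(-2, -1, 1, 2))),
               "separation")
  expect_error(fit_logistic(rep(1, 5)), "both outcome classes")
})

test_that("iptw weights satisfy the pseudo-population identities", {
  set.seed(32)
  co <- generate_cohort(default_config(), n = 5000, seed = 33)
  treated <- as.numeric(!is.na(co$treatment_day))
  ps <- fit_logistic(treated, baseline_covariates(co))
  w_st <- iptw_weights(ps, treated, stabilized = TRUE, truncation = 100)
  w_un <- iptw_weights(ps, treated, stabilized = FALSE, truncation = 100)
  expect_lt(abs(mean(w_st) - 1), 0.02)
  expect_lt(abs(sum(w_un) / (2 * nrow(co)) - 1), 0.05)
  # truncation at the 100th percentile changes nothing
  expect_equal(w_st, iptw_weights(ps, treated, TRUE, truncation = 100))
  expect_true(all(iptw_weights(ps, treated, TRUE, truncation = 95) <=
                    quantile(w_st, 0.95) + 1e-12))
  # constant propensity at the marginal rate: all stabilized weights 1
  ps0 <- fit_logistic(treated)
  expect_equal(unname(iptw_weights(ps0, treated, TRUE, 100)),
               rep(1, nrow(co)), tolerance = 1e-10)
})

test_that("iptw balances the default confounded cohort", {
  co <- generate_cohort(default_config(), n = 5000, seed = 34)
  treated <- as.numeric(!is.na(co$treatment_day))
  covs <- as.data.frame(baseline_covariates(co))
  smd_before <- standardized_differences(covs, treated)
  ps <- fit_logistic(treated, covs)
  w <- iptw_weights(ps, treated)
  smd_after <- standardized_differences(covs, treated, weights = w)
  expect_gt(max(abs(smd_before)), 0.1)     # confounding is real
  expect_lt(max(abs(smd_after)), 0.1)      # and removed by weighting
})

test_that("standardized differences match closed forms", {
  d <- data.frame(x = c(1, 1, 1, 0, 0, 0))
  expect_equal(unname(standardized_differences(
    data.frame(x = rep(1:3, 2)), c(0, 0, 0, 1, 1, 1))), 0)
  # means 1 vs 0 with unit variances
  set.seed(35)
  g <- rep(c(0, 1), each = 4000)
  x <- rnorm(8000, mean = g, sd = 1)
  smd <- standardized_differences(data.frame(x = x), g)
  expect_equal(unname(smd), 1, tolerance = 0.06)
  # binary covariates use proportion variance
  xb <- c(rep(1, 30), rep(0, 70), rep(1, 50), rep(0, 50))
  gb <- rep(c(0, 1), each = 100)
  smd_b <- standardized_differences(data.frame(x = xb), gb)
  expect_equal(unname(smd_b),
               (0.5 - 0.3) / sqrt((0.3 * 0.7 + 0.5 * 0.5) / 2),
               tolerance = 1e-10)
  expect_error(standardized_differences(
    data.frame(x = c(1, 1, 2, 2)), c(0, 0, 1, 1)), "zero pooled variance")
})

test_that("censoring weights reproduce hand computations", {
  # covariate-free: half of control clones deviate on day 1 -> weight 2
  co <- toy_cohort(event_day = rep(10, 8), event_type = rep("death", 8),
                   treatment_day = c(1, 1, NA, NA, 1, 1, NA, NA))
  clones <- clone_and_censor(co, trial_protocol(grace = 1))
  W <- ipcw_artificial_censoring(clones, covariates = NULL, grace = 1,
                                 truncation = 100)
  ctl <- clones$arm == "control"
  surviving <- ctl & clones$outcome != "artificial"
  expect_equal(unname(W[surviving, 1]), rep(2, 4))
  trt <- clones$arm == "treated" & clones$outcome != "artificial"
  expect_equal(unname(W[trt, 1]), rep(2, 4))
  # an arm without artificial censoring keeps weight 1 everywhere:
  # day-1 deaths sit in both arms, compliant day-1 initiators complete the
  # treated arm untouched
  co2 <- toy_cohort(event_day = c(1, 1, 10, 10),
                    event_type = c("death", "death", "home", "home"),
                    treatment_day = c(NA, NA, 1L, 1L))
  clones2 <- clone_and_censor(co2, trial_protocol(grace = 2))
  expect_false(any(clones2$outcome[clones2$arm == "treated"] ==
                     "artificial"))
  W2 <- ipcw_artificial_censoring(clones2, NULL, grace = 2)
  expect_true(all(W2[clones2$arm == "treated", ] == 1))
  # an arm whose clones all deviate within grace cannot be reweighted
  co3 <- toy_cohort(event_day = rep(10, 4), event_type = rep("home", 4),
                    treatment_day = rep(1L, 4))
  clones3 <- clone_and_censor(co3, trial_protocol(grace = 2))
  expect_error(ipcw_artificial_censoring(clones3, NULL, grace = 2),
               "all clones")
})

test_that("weighted clone count tracks the cohort size per day", {
  # pseudo-population identity on a larger simulated cohort
  co <- generate_cohort(default_config(), n = 4000, seed = 36)
  prot <- trial_protocol()
  clones <- clone_and_censor(co, prot)
  W <- ipcw_artificial_censoring(clones, covariate_names(),
                                 grace = prot$grace, truncation = 100)
  src_event <- co$event_day[match(clones$patient_id, co$patient_id)]
  for (arm in c("treated", "control")) {
    sel <- clones$arm == arm
    for (s in seq_len(prot$grace)) {
      uncens <- sel & (clones$outcome != "artificial" |
                         clones$fu_day > s)
      alive <- uncens & clones$fu_day >= s
      # reweighted survivors stand in for every clone whose source patient
      # was still in hospital on day s
      n_expected <- sum(sel & src_event >= s)
      expect_lt(abs(sum(W[alive, s]) / n_expected - 1), 0.05)
    }
  }
})
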