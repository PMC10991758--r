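test_that("clone_and_censor applies the deviation rules", {
  co <- toy_cohort(event_day = c(10, 30, 1, 20),
                   event_type = c("death", "home", "death", "home"),
                   treatment_day = c(1, NA, NA, 5))
  clones <- clone_and_censor(co, trial_protocol(grace = 2))
  expect_equal(nrow(clones), 2 * nrow(co))
  g <- function(id, arm) clones[clones$patient_id == id &
                                  clones$arm == arm, ]
  # treated day 1, death day 10: treated clone keeps the death,
  # control clone censored at initiation
  expect_equal(g(1, "treated")$outcome, "death")
  expect_equal(g(1, "treated")$fu_day, 10L)
  expect_equal(g(1, "control")$outcome, "artificial")
  expect_equal(g(1, "control")$fu_day, 1L)
  # never treated, home day 30: control keeps event, treated censored at
  # the grace end
  expect_equal(g(2, "control")$outcome, "home")
  expect_equal(g(2, "control")$fu_day, 30L)
  expect_equal(g(2, "treated")$outcome, "artificial")
  expect_equal(g(2, "treated")$fu_day, 2L)
  # event within the grace window: kept in both arms
  expect_equal(g(3, "treated")$outcome, "death")
  expect_equal(g(3, "control")$outcome, "death")
  expect_equal(g(3, "treated")$fu_day, 1L)
  # initiation after the grace period censors no control clone
  expect_equal(g(4, "control")$outcome, "home")
  expect_equal(g(4, "control")$fu_day, 20L)
  expect_equal(g(4, "treated")$outcome, "artificial")
})

test_that("clone datasets satisfy their structural invariants", {
  set.seed(41)
  co <- random_cohort(200, maxday = 15, admin_end = 15)
  prot <- trial_protocol(grace = 2, admin_end = 15)
  clones <- clone_and_censor(co, prot)
  expect_equal(nrow(clones), 2 * nrow(co))
  expect_true(all(clones$fu_day <=
                    co$event_day[match(clones$patient_id, co$patient_id)]))
  # baseline covariates identical across a patient's clones
  for (colnm in c("age10", "log_crp", "sqrt_lymph")) {
    v <- tapply(clones[[colnm]], clones$patient_id,
                function(x) diff(range(x)))
    expect_true(all(v == 0))
  }
  # exact baseline balance between arms (cloning)
  smd <- standardized_differences(clones, clones$arm == "treated",
                                  covariates = covariate_names())
  expect_equal(unname(smd), rep(0, length(smd)))
})

test_that("emulation equals an unadjusted Cox fit under day-1 randomization", {
  # exactly half the patients get a day-1 dose, the rest never initiate,
  # and no events fall inside the 1-day grace window: the censoring
  # weights are the same constant in both arms, so the weighted arm
  # contrast reduces algebraically to the unadjusted ever-treated Cox fit
  co <- generate_cohort(default_config(), n = 1200, seed = 42)
  co <- co[co$event_day > 1, ]
  co$patient_id <- seq_len(nrow(co))
  co <- co[seq_len(2 * (nrow(co) %/% 2)), ]
  co$treatment_day <- rep(c(1L, NA_integer_), nrow(co) / 2)
  prot <- trial_protocol(grace = 1)
  emu <- emulate_trial(co, prot, covariates = NULL, causes = "death")
  expect_equal(unique(round(c(emu$weights), 10)), 2)
  rows <- misclassify_baseline(co)  # correct here: treated iff day-1 dose
  fit <- fit_cox(cause_specific_view(rows, "death"), "treated")
  expect_equal(unname(hazard_ratio(emu$fits$death, "arm")[["log_hr"]]),
               unname(fit$coef[["treated"]]), tolerance = 1e-6)
})

test_that("fast bootstrap path agrees with the full fit", {
  co <- generate_cohort(default_config(), n = 800, seed = 43)
  prot <- trial_protocol()
  emu <- emulate_trial(co, prot, causes = "death", compute_cif = FALSE)
  fast <- ccwsim:::emulation_log_hr(co, prot, covariate_names(), "death")
  expect_equal(unname(emu$fits$death$coef[["arm"]]), fast,
               tolerance = 1e-10)
})

test_that("weighted AJ curves and Cox fits come out of one emulation", {
  co <- generate_cohort(default_config(), n = 1000, seed = 44)
  emu <- emulate_trial(co, trial_protocol())
  expect_named(emu$fits, c("death", "home", "transfer"))
  expect_named(emu$cif, c("treated", "control"))
  for (arm in names(emu$cif)) {
    cs <- emu$cif[[arm]]
    tend <- max(cs$surv$time)
    tot <- curve_at(cs$surv, tend) +
      sum(vapply(cs$cif, curve_at, numeric(1), t = tend))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("bootstrap CIs are reproducible, centred and stable", {
  co <- generate_cohort(default_config(), n = 500, seed = 45)
  prot <- trial_protocol(n_boot = 60, seed = 9)
  b1 <- bootstrap_ci(co, prot, "death")
  b2 <- bootstrap_ci(co, prot, "death")
  expect_identical(b1, b2)                       # seeded determinism
  expect_true(b1$ci[1] <= b1$estimate && b1$estimate <= b1$ci[2])
  expect_equal(b1$n_failed, 0)
  expect_error(bootstrap_ci(co, trial_protocol(n_boot = 1), "death"),
               "at least 2")
})
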