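test_that("curve_at evaluates right-continuously", {
  cv <- step_curve(c(2, 5), c(0.8, 0.3), v0 = 1)
  expect_equal(curve_at(cv, c(0, 1.99)), c(1, 1))        # before first jump
  expect_equal(curve_at(cv, c(2, 5)), c(0.8, 0.3))       # at a jump
  expect_equal(curve_at(cv, c(4, 100)), c(0.8, 0.3))     # between / after
  expect_error(step_curve(c(3, 2), c(1, 1), 1), "increasing")
})

test_that("kaplan_meier matches hand computations and edge cases", {
  expect_equal(curve_at(kaplan_meier(c(1, 2, 3), c(1, 1, 1)), 3), 0)
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(curve_at(km, 4), (3 / 4) * (1 / 2))       # = 0.375
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
  expect_error(kaplan_meier(1:3, c(1, 1, 1), weights = c(1, -1, 1)),
               "negative")
})

test_that("weights: scale invariance and replication equivalence", {
  set.seed(1)
  for (rep in 1:5) {
    d <- random_competing(15)
    status <- as.numeric(d$type == "death")
    w_int <- sample(1:4, 15, replace = TRUE)
    km1 <- kaplan_meier(d$day, status, weights = w_int)
    km2 <- kaplan_meier(d$day, status, weights = 2.7 * w_int)
    expect_equal(km1, km2, tolerance = 1e-12)
    # integer weights == replicated rows
    idx <- rep(seq_along(d$day), w_int)
    km3 <- kaplan_meier(d$day[idx], status[idx])
    expect_equal(km1, km3, tolerance = 1e-12)
    aj1 <- aalen_johansen(d$day, d$type, weights = w_int)
    aj3 <- aalen_johansen(d$day[idx], d$type[idx])
    expect_equal(aj1, aj3, tolerance = 1e-12)
  }
})

test_that("aalen_johansen matches hand computation and conserves mass", {
  aj <- aalen_johansen(c(1, 2), c("death", "home"))
  expect_equal(curve_at(aj$cif$death, 10), 0.5)
  expect_equal(curve_at(aj$cif$home, 10), 0.5)
  # three causes, no censoring: CIFs exhaust the unit mass
  set.seed(2)
  d <- list(day = sample(1:6, 30, replace = TRUE),
            type = sample(c("death", "home", "transfer"), 30,
                          replace = TRUE))
  aj2 <- aalen_johansen(d$day, d$type)
  tot <- sum(vapply(aj2$cif, curve_at, numeric(1), t = 6))
  expect_equal(tot, 1, tolerance = 1e-12)
  # CIFs + survival sum to one at every jump time
  for (t in aj2$surv$time) {
    s <- curve_at(aj2$surv, t) +
      sum(vapply(aj2$cif, curve_at, numeric(1), t = t))
    expect_equal(s, 1, tolerance = 1e-10)
  }
})

test_that("single-cause Aalen-Johansen reduces to one minus KM", {
  set.seed(3)
  day <- sample(1:7, 25, replace = TRUE)
  type <- sample(c("death", "censored"), 25, replace = TRUE)
  aj <- aalen_johansen(day, type)
  km <- one_minus_km(day, type, "death")
  expect_equal(aj$cif$death, km, tolerance = 1e-12)
})

test_that("estimators agree with survfit on right-censored data", {
  # independent cross-check against the survival package
  set.seed(4)
  day <- sample(1:9, 40, replace = TRUE)
  type <- sample(c("death", "home", "censored"), 40, replace = TRUE)
  sf <- survival::survfit(
    survival::Surv(day, factor(type, c("censored", "death", "home"))) ~ 1)
  aj <- aalen_johansen(day, type)
  at <- sf$time
  expect_equal(curve_at(aj$cif$death, at),
               unname(sf$pstate[, "death"]), tolerance = 1e-10)
  expect_equal(curve_at(aj$cif$home, at),
               unname(sf$pstate[, "home"]), tolerance = 1e-10)
  km <- kaplan_meier(day, as.numeric(type == "death"))
  sfk <- survival::survfit(
    survival::Surv(day, type == "death") ~ 1)
  expect_equal(curve_at(km, sfk$time), unname(sfk$surv),
               tolerance = 1e-10)
})

test_that("brute-force occupancy oracle agrees on random small datasets", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:20, 1)
    d <- random_competing(n)
    w <- stats::runif(n, 0.2, 3)
    aj <- aalen_johansen(d$day, d$type, weights = w)
    orc <- occupancy_oracle(d$day, d$type, weights = w)
    for (k in aj$causes)
      expect_equal(curve_at(aj$cif[[k]], orc$days),
                   unname(orc$cif[, k]), tolerance = 1e-12)
    expect_equal(curve_at(aj$surv, orc$days), orc$surv,
                 tolerance = 1e-12)
  }
})

test_that("naive one-minus-KM dominates the Aalen-Johansen CIF", {
  set.seed(6)
  for (rep in 1:20) {
    d <- random_competing(sample(4:25, 1))
    if (!any(d$type == "death")) next
    naive <- one_minus_km(d$day, d$type, "death")
    aj <- aalen_johansen(d$day, d$type)
    tt <- 0:8
    expect_true(all(curve_at(naive, tt) >=
                      curve_at(aj$cif$death, tt) - 1e-12))
  }
})
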