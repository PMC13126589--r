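test_that("Kaplan-Meier matches hand product-limit values", {
  km <- km_fit(c(2, 4, 6, 8), c(1, 1, 1, 1))
  expect_equal(km$curve$surv, c(0.75, 0.5, 0.25, 0), tolerance = 1e-12)
  expect_identical(km$median, 4)
  # censoring between events: risk sets 3 then 1
  km2 <- km_fit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$curve$surv, c(2 / 3, 2 / 3, 0))
  expect_identical(km2$median, 3)
  # all censored: flat curve, undefined median
  km3 <- km_fit(c(5, 7, 9), c(0, 0, 0))
  expect_true(all(km3$curve$surv == 1))
  expect_true(is.na(km3$median))
  expect_error(km_fit(numeric(0), integer(0)), "empty")
  expect_error(km_fit(c(1, -2), c(1, 1)), "negative")
})

test_that("Kaplan-Meier agrees with a naive recomputation on random data", {
  withr::with_seed(7, {
    times <- round(rexp(60, 0.1), 1)
    events <- rbinom(60, 1, 0.7)
  })
  km <- km_fit(times, events)
  for (i in seq_len(nrow(km$curve)))
    expect_equal(km$curve$surv[i],
                 oracle_km_surv(times, events, km$curve$time[i]))
  # pointwise log(-log) limits match survfit's conf.type = "log-log"
  sf <- summary(survival::survfit(
    survival::Surv(times, events) ~ 1, conf.type = "log-log"),
    times = km$curve$time)
  expect_equal(km$curve$surv, sf$surv, tolerance = 1e-10)
  idx <- !is.na(km$curve$lower)
  expect_equal(km$curve$lower[idx], sf$lower[idx], tolerance = 1e-8)
  expect_equal(km$curve$upper[idx], sf$upper[idx], tolerance = 1e-8)
})

test_that("log-rank matches the O-E / variance oracle and its contracts", {
  t1 <- c(1, 2, 3, 4); t2 <- c(3, 4, 5, 6)
  lr <- logrank_test(c(t1, t2), rep(1, 8), rep(c("A", "B"), each = 4))
  o <- oracle_logrank2(t1, rep(1, 4), t2, rep(1, 4))
  expect_equal(lr$chi2, o$chi2, tolerance = 1e-10)
  expect_equal(lr$p, o$p, tolerance = 1e-10)
  expect_identical(lr$df, 1L)
  # identical groups: chi2 = 0, p = 1
  lr0 <- logrank_test(rep(c(1, 2, 3), 2), rep(1, 6),
                      rep(c("A", "B"), each = 3))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  # symmetry under group relabeling
  lr_sw <- logrank_test(c(t1, t2), rep(1, 8), rep(c("B", "A"), each = 4))
  expect_equal(lr_sw$chi2, lr$chi2, tolerance = 1e-12)
  # three groups -> df = 2; single group errors
  lr3 <- logrank_test(1:9, rep(1, 9), rep(c("A", "B", "C"), 3))
  expect_identical(lr3$df, 2L)
  expect_error(logrank_test(1:3, rep(1, 3), rep("A", 3)), "two")
})

test_that("Cox fits match a brute-force partial-likelihood oracle", {
  time <- c(4, 3, 1, 1, 2, 2, 3, 5)
  event <- c(1, 1, 1, 0, 1, 1, 0, 1)
  x <- c(0, 0, 1, 1, 1, 0, 1, 0)
  dat <- data.frame(time = time, event = event, x = x)
  for (ties in c("efron", "breslow")) {
    fit <- cox_fit(dat, "time", "event", "x", ties = ties)
    expect_true(fit$converged)
    expect_equal(fit$terms$coefficient,
                 oracle_cox_beta(time, event, x, ties), tolerance = 1e-4)
    expect_equal(fit$terms$hazard_ratio, exp(fit$terms$coefficient))
  }
  # symmetric data: coefficient ~ 0, HR ~ 1
  sym <- data.frame(time = rep(c(1, 2, 3, 4), 2), event = 1,
                    x = rep(0:1, each = 4))
  fsym <- cox_fit(sym, "time", "event", "x")
  expect_lt(abs(fsym$terms$coefficient), 1e-6)
  # recoding 0<->1 flips the sign exactly
  flip <- dat; flip$x <- 1 - flip$x
  f1 <- cox_fit(dat, "time", "event", "x")
  f2 <- cox_fit(flip, "time", "event", "x")
  expect_equal(f1$terms$coefficient, -f2$terms$coefficient,
               tolerance = 1e-8)
  expect_error(cox_fit(data.frame(time = 1:3, event = 0, x = 1:3),
                       "time", "event", "x"), "no events")
})

test_that("monotone likelihood is flagged, not silent", {
  # complete separation: all events in one group before any in the other
  dat <- data.frame(time = c(1, 2, 3, 10, 11, 12), event = 1,
                    x = rep(c(1, 0), each = 3))
  fit <- cox_fit(dat, "time", "event", "x")
  expect_false(fit$converged)
  expect_true(length(fit$messages) > 0)
})

test_that("backward selection drops noise and is order-invariant", {
  withr::with_seed(12, {
    n <- 500
    grp <- rbinom(n, 1, 0.5)
    noise <- rbinom(n, 1, 0.5)
    time <- rexp(n, 0.1 * exp(log(0.4) * grp))
    dat <- data.frame(time = time, event = 1, grp = grp, noise = noise)
  })
  sel <- backward_select(dat, "time", "event", c("grp", "noise"))
  expect_identical(sel$selection_trace, "noise")
  expect_identical(sel$terms$name, "grp")
  sel2 <- backward_select(dat, "time", "event", c("noise", "grp"))
  expect_identical(sel2$terms$name, sel$terms$name)
  expect_equal(sel2$terms$coefficient, sel$terms$coefficient)
  # strong predictors only: nothing removed
  expect_length(backward_select(dat, "time", "event", "grp"
  )$selection_trace, 0)
  # pure-noise model: noise removed first in >= 90/100 seeds
  hits <- vapply(1:100, function(s) {
    withr::with_seed(1000 + s, {
      grp <- rbinom(500, 1, 0.5); noise <- rbinom(500, 1, 0.5)
      tm <- rexp(500, 0.1 * exp(log(0.4) * grp))
      d <- data.frame(time = tm, event = 1, grp = grp, noise = noise)
    })
    bs <- backward_select(d, "time", "event", c("grp", "noise"))
    identical(bs$selection_trace, "noise")
  }, logical(1))
  expect_gte(sum(hits), 90)
})

test_that("Schoenfeld power follows the closed form", {
  expect_equal(schoenfeld_power(1, 100, 0.5), pnorm(qnorm(0.025)),
               tolerance = 1e-12)
  # frozen oracle value for HR 0.443, 59/106 allocation, 66 events
  expect_equal(schoenfeld_power(0.443, 66, 59 / 106), 0.90755,
               tolerance = 1e-4)
  # |ln HR| symmetry and monotonicity in the event count
  expect_equal(schoenfeld_power(0.5, 80, 0.4),
               schoenfeld_power(2, 80, 0.4), tolerance = 1e-12)
  pw <- vapply(c(20, 40, 80, 160), schoenfeld_power,
               numeric(1), hazard_ratio = 0.6, prop_group1 = 0.5)
  expect_true(all(diff(pw) > 0))
})

test_that("baseline tables use uncorrected Pearson chi-square", {
  co <- cohort(patient_df(8,
                          arm = rep(c("PTX_BEV", "PTX"), each = 4),
                          age_ge_65 = c(1, 1, 0, 0, 1, 1, 0, 0),
                          visceral = 1L),
               panel = two_locus_panel())
  tab <- baseline_table(co, "arm", c("age_ge_65", "visceral"))
  expect_equal(tab$p[tab$covariate == "age_ge_65"][1], 1)  # equal props
  expect_true(all(is.na(tab$p[tab$covariate == "visceral"])))  # one level
  # uniform 2x2
  expect_equal(epistasurv:::pearson_chisq(matrix(10, 2, 2))$p, 1)
})
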