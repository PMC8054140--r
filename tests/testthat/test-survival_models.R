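test_that("KM estimator matches the product-limit by hand", {
  # 6 patients: event at 2, censor at 3, events at 4 and 5, censor 6, event 7
  time <- c(2, 3, 4, 5, 6, 7)
  event <- c(1, 0, 1, 1, 0, 1)
  km <- km_curve(time, event)
  expect_equal(km$surv[km$time == 2], 5 / 6)
  expect_equal(km$surv[km$time == 4], 5 / 6 * 3 / 4)
  expect_equal(km$surv[km$time == 5], 5 / 6 * 3 / 4 * 2 / 3)
  expect_equal(km$surv[km$time == 7], 0)
  expect_true(all(diff(km$surv) <= 0))
  expect_error(km_curve(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM with no events stays flat at 1", {
  km <- km_curve(c(3, 5, 9), c(0, 0, 0))
  expect_true(all(km$surv == 1))
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(41)
  t <- rexp(50)
  km <- km_curve(t, rep(1, 50))
  expect_equal(km$surv, 1 - ecdf(t)(km$time), tolerance = 1e-12)
})

test_that("log-rank is zero for identical groups and label-invariant", {
  time <- rep(c(2, 4, 6, 8), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  group <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
  set.seed(42)
  t2 <- rexp(60); e2 <- rbinom(60, 1, 0.8); g2 <- rep(0:1, 30)
  relab <- c("0" = "B", "1" = "A")[as.character(g2)]
  expect_equal(logrank_test(t2, e2, g2)$p, logrank_test(t2, e2, relab)$p)
  expect_warning(lr0 <- logrank_test(c(1, 2), c(0, 0), c("a", "b")),
                 "no events")
  expect_equal(lr0$p, 1)
})

test_that("Cox score test at beta = 0 equals the log-rank statistic", {
  set.seed(43)
  n <- 80
  t <- round(rexp(n), 6)  # continuous: no ties
  e <- rbinom(n, 1, 0.9)
  g <- rbinom(n, 1, 0.5)
  d <- data.frame(time = t, event = e, g = g)
  fit <- cox_fit(d, "time", "event", "g")
  sc <- summary(fit$fit)$sctest["test"]
  lr <- logrank_test(t, e, g)
  expect_equal(unname(sc), lr$chisq, tolerance = 1e-6)
})

test_that("Cox recovers a planted hazard ratio without censoring", {
  set.seed(44)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, rate = 0.05 * exp(log(2) * x))
  d <- data.frame(time = t, event = 1, x = x)
  fit <- cox_fit(d, "time", "event", "x")
  hr <- fit$table$hr[fit$table$term == "x"]
  expect_lt(abs(hr - 2) / 2, 0.10)
})

test_that("constant covariates and full separation are rejected or dropped", {
  d <- data.frame(time = rexp(20), event = 1, x = 1)
  expect_error(cox_fit(d, "time", "event", "x"))
  # monotone likelihood: covariate perfectly splits early/late deaths
  d2 <- data.frame(time = c(1:10, 101:110), event = 1,
                   z = rep(c(1, 0), each = 10),
                   ok = rbinom(20, 1, 0.5))
  expect_warning(fit <- cox_fit(d2, "time", "event", c("z", "ok")),
                 "monotone")
  expect_equal(fit$dropped, "z")
  expect_false("z" %in% fit$table$term)
})

test_that("univariable screen keeps strong covariates and flags failures", {
  set.seed(45)
  n <- 300
  strong <- rbinom(n, 1, 0.5)
  noise <- rnorm(n)
  t <- rexp(n, 0.05 * exp(log(3) * strong))
  d <- data.frame(time = t, event = 1, strong = strong, noise = noise)
  sc <- univariable_screen(d, "time", "event", c("strong", "noise"))
  expect_true("strong" %in% sc$selected)
  expect_equal(nrow(sc$table), 2)
  expect_error(univariable_screen(d, "time", "event", character()),
               "no covariates")
})

test_that("pure-noise covariates pass the screen at about the nominal rate", {
  set.seed(46)
  hits <- replicate(200, {
    n <- 60
    d <- data.frame(time = rexp(n), event = 1, x = rnorm(n))
    length(univariable_screen(d, "time", "event", "x")$selected)
  })
  expect_lt(abs(mean(hits) - 0.05), 0.05)
})

test_that("interaction model reports the product term and rejects bad input", {
  set.seed(47)
  cfg <- sim_config(n_patients = 600, seed = 47)
  arm <- rbinom(600, 1, 0.5); bio <- rbinom(600, 1, 0.4)
  sv <- simulate_survival(arm, bio, cfg)
  d <- data.frame(time = sv$time, event = sv$event, biomarker = bio,
                  arm = arm, age = rnorm(600, 64, 9))
  im <- interaction_model(d, "time", "event", adjusters = "age")
  expect_equal(im$interaction$term, "biomarker:arm")
  expect_length(im$km_strata, 4)
  expect_true(all(c("hr", "p") %in% names(im$interaction)))

  d_const <- d; d_const$biomarker <- 1
  expect_error(interaction_model(d_const, "time", "event"), "stratum")
  d_empty <- d[!(d$biomarker == 1 & d$arm == 1), ]
  expect_error(interaction_model(d_empty, "time", "event"),
               "empty biomarker x arm stratum")
})

test_that("resampling validation is seed-reproducible and summarized correctly", {
  set.seed(48)
  cfg <- sim_config(n_patients = 222, seed = 48)
  arm <- rbinom(222, 1, 0.5); bio <- rbinom(222, 1, 0.41)
  sv <- simulate_survival(arm, bio, cfg)
  d <- data.frame(time = sv$time, event = sv$event, arm = arm,
                  subgroup = bio)
  r1 <- resample_validation(d, "time", "event", n_repeats = 30, seed = 7)
  r2 <- resample_validation(d, "time", "event", n_repeats = 30, seed = 7)
  expect_identical(r1$p_values, r2$p_values)
  expect_length(r1$p_values, 30)
  expect_lte(r1$lower_quartile, r1$median)
  expect_gte(r1$upper_quartile, r1$median)
  expect_equal(r1$p_values[r1$representative$split_id],
               r1$representative$validation_p)
})

test_that("a planted subgroup-restricted arm benefit yields small split p-values", {
  cfg <- sim_config(n_patients = 222, seed = 49)
  set.seed(49)
  arm <- rbinom(222, 1, 0.5); bio <- rbinom(222, 1, 0.41)
  sv <- simulate_survival(arm, bio, cfg)
  d <- data.frame(time = sv$time, event = sv$event, arm = arm,
                  subgroup = bio)
  r <- resample_validation(d, "time", "event", n_repeats = 100, seed = 7)
  expect_lt(r$median, 0.05)
})
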