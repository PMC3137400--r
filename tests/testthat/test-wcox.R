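suppressPackageStartupMessages(library(survival))

test_that("the fitter maximises the partial likelihood found by brute force", {
  # six-subject fixture: ages 2..7, events 1,1,0,1,0,0, binary x
  d <- data.frame(time = 2:7, status = c(1, 1, 0, 1, 0, 0),
                  x = c(1, 0, 1, 0, 1, 0))
  fit <- wcoxph(Surv(time, status) ~ x, d)
  b_oracle <- oracle_beta(d$time, d$status, d$x)
  expect_lt(abs(coef(fit)[["x"]] - b_oracle), 1e-6)
  expect_lt(abs(coef(fit)[["x"]] - coef(coxph(Surv(time, status) ~ x, d,
                                              ties = "breslow"))[["x"]]),
            1e-6)
  # the reported log-likelihood is the brute-force value at the optimum
  expect_equal(fit$loglik[["fitted"]],
               oracle_pl(coef(fit)[["x"]], d$time, d$status, d$x))
})

test_that("weighted fits agree with the brute-force weighted oracle", {
  for (seed in 1:8) {
    d <- rand_fixture(seed, n = 25 + seed)
    fit <- wcoxph(Surv(time, status) ~ x, d, weights = d$w)
    expect_lt(abs(coef(fit)[["x"]] -
                    oracle_beta(d$time, d$status, d$x, d$w)), 1e-6)
  }
})

test_that("integer-weight fits equal duplicated-subject fits (Breslow)", {
  d <- rand_fixture(3, n = 20, weighted = FALSE)
  d$w2 <- 2
  dup <- rbind(d, d)
  f_w <- wcoxph(Surv(time, status) ~ x, d, weights = d$w2)
  f_d <- wcoxph(Surv(time, status) ~ x, dup)
  expect_equal(coef(f_w), coef(f_d), tolerance = 1e-9)
  expect_equal(f_w$loglik[["fitted"]], f_d$loglik[["fitted"]],
               tolerance = 1e-9)
})

test_that("unweighted fits match the survival package to high precision,
           for both tie methods and several covariates", {
  cfg <- sim_config(n_families = 80, seed = 41)
  rec <- build_cohort(ascertain(simulate_families(cfg), cfg))
  car <- rec[rec$carrier == "carrier", ]
  f <- Surv(exit_age, event) ~ bmi5 + sex + smoke20 + alcohol20
  for (tie in c("breslow", "efron")) {
    mine <- wcoxph(f, car, ties = tie, cluster = ~family_id)
    ref <- coxph(f, car, ties = tie, cluster = family_id)
    expect_lt(max(abs(coef(mine) - coef(ref))), 1e-6)
    expect_lt(max(abs(mine$naive.var - ref$naive.var)), 1e-8)
    expect_lt(max(abs(mine$var - ref$var)), 1e-8)
  }
  # and a weighted fit against survival's weighted implementation
  wt <- compute_weights(car, default_carrier_incidence())
  mine_w <- wcoxph(f, car, weights = wt, cluster = ~family_id)
  ref_w <- coxph(f, car, weights = wt$weights, ties = "breslow",
                 cluster = family_id)
  expect_lt(max(abs(coef(mine_w) - coef(ref_w))), 1e-6)
  expect_lt(max(abs(mine_w$var - ref_w$var)), 1e-8)
})

test_that("the Newton path never decreases the partial likelihood", {
  for (seed in c(2, 5, 9)) {
    d <- rand_fixture(seed, n = 40)
    fit <- wcoxph(Surv(time, status) ~ x, d, weights = d$w)
    expect_true(all(diff(fit$engine$ll_trace) > -1e-10))
    expect_true(fit$converged)
  }
})

test_that("separation is reported rather than silently diverging", {
  d <- data.frame(time = 1:8, status = c(1, 1, 1, 1, 0, 0, 0, 0),
                  x = c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_error(wcoxph(Surv(time, status) ~ x, d), "separation")
})

test_that("degenerate inputs are rejected with clear messages", {
  d <- rand_fixture(1, n = 20)
  d$z <- 1
  expect_error(wcoxph(Surv(time, status) ~ z, d), "constant")
  d1 <- d; d1$time[d1$status == 1] <- 5
  expect_error(wcoxph(Surv(time, status) ~ x, d1), "2 distinct event ages")
  expect_error(wcoxph(Surv(time, status) ~ x, d, weights = rep(-1, 20)),
               "non-negative")
})

test_that("hazard ratios for the exposure are invariant to affine recoding
           of adjustment covariates", {
  cfg <- sim_config(n_families = 60, seed = 42)
  rec <- build_cohort(ascertain(simulate_families(cfg), cfg))
  car <- rec[rec$carrier == "carrier", ]
  car$smoke_num <- as.integer(car$smoke20 == "ever")
  car$smoke_rec <- 10 - 3 * car$smoke_num
  f1 <- wcoxph(Surv(exit_age, event) ~ bmi5 + smoke_num, car)
  f2 <- wcoxph(Surv(exit_age, event) ~ bmi5 + smoke_rec, car)
  expect_equal(coef(f1)[["bmi5"]], coef(f2)[["bmi5"]], tolerance = 1e-7)
  expect_equal(sqrt(vcov(f1)["bmi5", "bmi5"]),
               sqrt(vcov(f2)["bmi5", "bmi5"]), tolerance = 1e-7)
})

test_that("with one subject per cluster the sandwich is the textbook robust
           variance, and cluster duplication scales it exactly", {
  d <- rand_fixture(6, n = 35, weighted = FALSE)
  d$family_id <- paste0("solo", seq_len(nrow(d)))
  mine <- wcoxph(Surv(time, status) ~ x, d, cluster = ~family_id)
  ref <- coxph(Surv(time, status) ~ x, d, ties = "breslow", robust = TRUE)
  expect_lt(abs(mine$var[1, 1] - ref$var[1, 1]), 1e-10)
  # duplicating every family k times scales the robust variance by 1/k
  k <- 3
  dk <- do.call(rbind, lapply(seq_len(k), function(i) {
    di <- d; di$family_id <- paste0(di$family_id, "_copy", i); di
  }))
  mk <- wcoxph(Surv(time, status) ~ x, dk, cluster = ~family_id)
  expect_equal(mk$var[1, 1], mine$var[1, 1] / k, tolerance = 1e-10)
  expect_equal(coef(mk), coef(mine), tolerance = 1e-9)
})

test_that("simulated within-family frailty inflates robust over naive
           standard errors on average", {
  # risk AND exposure cluster in families: shared frailty plus a
  # family-shared BMI component (the setting the clustered sandwich is for)
  ratios <- vapply(1:30, function(seed) {
    cfg <- sim_config(n_families = 100, frailty_sd = 0.8,
                      bmi_family_sd = 2.5,
                      clinic_min_affected = 0, relative_recruit_prob = 1,
                      seed = 500 + seed)
    rec <- build_cohort(simulate_families(cfg))
    car <- rec[rec$carrier == "carrier", ]
    fit <- wcoxph(Surv(exit_age, event) ~ bmi5, car, cluster = ~family_id)
    sqrt(fit$var[1, 1] / fit$naive.var[1, 1])
  }, numeric(1))
  expect_gt(mean(ratios), 1)
})

test_that("the Schoenfeld machinery matches cox.zph and has one residual
           row per event", {
  cfg <- sim_config(n_families = 70, seed = 43)
  rec <- build_cohort(ascertain(simulate_families(cfg), cfg))
  car <- rec[rec$carrier == "carrier", ]
  f <- Surv(exit_age, event) ~ bmi5 + sex
  mine <- wcoxph(f, car)
  st <- schoenfeld_test(mine, transform = "identity")
  cz <- cox.zph(coxph(f, car, ties = "breslow"), transform = "identity")
  expect_equal(st$chisq[1:2], unname(cz$table[1:2, "chisq"]),
               tolerance = 1e-6)
  expect_equal(st$chisq[3], unname(cz$table["GLOBAL", "chisq"]),
               tolerance = 1e-6)
  res <- residuals(mine, type = "schoenfeld")
  expect_equal(nrow(res), mine$nevent)
  expect_identical(colnames(res), c("bmi5", "sexmale"))
  # minimal structural case: one covariate, two events
  d2 <- data.frame(time = c(1, 2, 3, 4), status = c(1, 1, 0, 0),
                   x = c(0.5, -1, 2, 0))
  f2 <- wcoxph(Surv(time, status) ~ x, d2)
  expect_equal(nrow(residuals(f2, type = "schoenfeld")), 2)
  expect_error(schoenfeld_test(f2), "at least 10 events")
})

test_that("a hazard ratio reversing mid-follow-up is detected by the
           proportional-hazards test", {
  set.seed(99)
  n <- 3000
  x <- rnorm(n)
  # piecewise effect: beta = +0.6 before t = 50, -0.6 after
  u <- runif(n)
  h0 <- 0.02
  t1 <- -log(u) / (h0 * exp(0.6 * x))
  t <- ifelse(t1 <= 50, t1,
              50 + (t1 - 50) * exp(0.6 * x) / exp(-0.6 * x))
  cens <- runif(n, 0, 120)
  d <- data.frame(time = pmin(t, cens), status = as.integer(t <= cens), x = x)
  fit <- wcoxph(Surv(time, status) ~ x, d)
  st <- schoenfeld_test(fit)
  expect_lt(st$p[1], 0.01)
})

test_that("interaction Wald tests are symmetric in the term pair", {
  cfg <- sim_config(n_families = 90, seed = 44)
  rec <- build_cohort(ascertain(simulate_families(cfg), cfg))
  f <- Surv(exit_age, event) ~ bmi5 + carrier + sex
  a <- wald_interaction(f, rec, c("bmi5", "carrier"), cluster = ~family_id)
  b <- wald_interaction(f, rec, c("carrier", "bmi5"), cluster = ~family_id)
  expect_equal(a$chisq, b$chisq, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
  expect_error(wald_interaction(f, rec, c("bmi5", "smoke20")),
               "main effects")
})

test_that("summary, confint, predict and residual methods are coherent", {
  cfg <- sim_config(n_families = 60, seed = 45)
  rec <- build_cohort(ascertain(simulate_families(cfg), cfg))
  car <- rec[rec$carrier == "carrier", ]
  wt <- compute_weights(car, default_carrier_incidence())
  fit <- wcoxph(Surv(exit_age, event) ~ bmi5 + sex, car, weights = wt,
                cluster = ~family_id)
  s <- summary(fit)$coefficients
  expect_equal(unname(s[, "HR"]), unname(exp(coef(fit))))
  expect_true(all(s[, "lower"] < s[, "HR"] & s[, "HR"] < s[, "upper"]))
  ci <- confint(fit)
  expect_equal(unname(exp(ci[, 1])), unname(s[, "lower"]))
  # robust covariance is symmetric positive semi-definite
  expect_true(isSymmetric(fit$var))
  expect_true(all(eigen(fit$var, symmetric = TRUE)$values > -1e-12))
  # linear predictor reproduces X beta on new data
  lp <- unname(predict(fit, newdata = car[1:5, ]))
  Xb <- coef(fit)[["bmi5"]] * car$bmi5[1:5] +
    coef(fit)[["sexmale"]] * (car$sex[1:5] == "male")
  expect_equal(lp, Xb, tolerance = 1e-12)
  expect_equal(unname(predict(fit, newdata = car[1:5, ], type = "risk")),
               exp(lp))
  # weighted score residuals sum to zero at the optimum
  expect_lt(max(abs(colSums(residuals(fit, type = "score")))), 1e-6)
  # martingale residuals sum to ~0 for unweighted fits
  fu <- wcoxph(Surv(exit_age, event) ~ bmi5 + sex, car)
  expect_lt(abs(sum(residuals(fu, type = "martingale"))), 1e-8)
})
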