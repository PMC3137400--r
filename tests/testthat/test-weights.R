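# records spanning a single stratum with prescribed counts
stratum_records <- function(n, d, age = 3) {
  data.frame(subject_id = seq_len(n), family_id = seq_len(n),
             attained_age = rep(age, n), exit_age = rep(age, n),
             event = rep(c(1L, 0L), c(d, n - d)))
}

test_that("weights follow the defining sampling-fraction formulas", {
  # p = 0.10 via a single stratum: rate = -log(0.9)/5
  tab <- incidence_table(0, 5, -log(0.9) / 5)
  wt <- compute_weights(stratum_records(20, 10), tab)
  expect_equal(wt$strata$w_affected[1], 0.1 * 20 / 10)
  expect_equal(wt$strata$w_unaffected[1], 0.9 * 20 / 10)
  # weighted affected proportion equals p
  expect_equal(sum(wt$weights[1:10]) / 20, 0.1)
  # mean weight one
  expect_equal(mean(wt$weights), 1)
})

test_that("a sample already matching the population gets unit weights", {
  p <- 0.25
  tab <- incidence_table(0, 5, -log(1 - p) / 5)
  wt <- compute_weights(stratum_records(16, 4), tab)   # d/n = 0.25 = p
  expect_equal(unname(wt$weights), rep(1, 16))
})

test_that("degenerate strata fall back to unit weights with a flag", {
  tab <- incidence_table(0, 5, 0.05)                   # p > 0
  wt <- compute_weights(stratum_records(8, 0), tab)    # d = 0
  expect_equal(unname(wt$weights), rep(1, 8))
  expect_true(wt$strata$fallback[1])
  wt2 <- compute_weights(stratum_records(8, 8), tab)   # d = n
  expect_equal(unname(wt2$weights), rep(1, 8))
  expect_true(wt2$strata$fallback[1])
})

test_that("an external table implying certainty of disease is an error", {
  tab <- incidence_table(0, 5, 1e4)                    # p numerically 1
  expect_error(compute_weights(stratum_records(10, 5), tab),
               "affected proportion 1")
})

test_that("calibration invariants hold on every non-degenerate stratum of
           random cohorts", {
  for (seed in 1:20) {
    cfg <- sim_config(n_families = 120, seed = seed)
    rec <- build_cohort(ascertain(simulate_families(cfg), cfg))
    car <- rec[rec$carrier == "carrier", ]
    wt <- compute_weights(car, default_carrier_incidence())
    s <- wt$strata
    live <- which(s$n > 0 & s$d > 0 & s$d < s$n & !s$fallback)
    for (k in live) {
      expect_lt(abs(s$d[k] * s$w_affected[k] +
                      (s$n[k] - s$d[k]) * s$w_unaffected[k] - s$n[k]), 1e-10)
      expect_lt(abs(s$d[k] * s$w_affected[k] / s$n[k] - s$p[k]), 1e-10)
    }
    # every record carries the weight of its stratum and status
    k_rec <- wt$stratum
    w_exp <- ifelse(car$event == 1, s$w_affected[k_rec],
                    s$w_unaffected[k_rec])
    expect_equal(wt$weights, w_exp)
  }
})

test_that("raising every external rate never lowers an affected weight", {
  cfg <- sim_config(n_families = 150, seed = 31)
  rec <- build_cohort(ascertain(simulate_families(cfg), cfg))
  car <- rec[rec$carrier == "carrier", ]
  lo <- default_carrier_incidence()
  hi <- incidence_table(lo$age_lo, lo$age_hi, lo$rate * 1.5,
                        group = "carrier")
  w_lo <- compute_weights(car, lo)$strata$w_affected
  w_hi <- compute_weights(car, hi)$strata$w_affected
  ok <- !is.na(w_lo) & !is.na(w_hi)
  expect_true(all(w_hi[ok] >= w_lo[ok] - 1e-12))
})

test_that("non-carrier weighting is the same machinery on the population
           table", {
  cfg <- sim_config(n_families = 120, seed = 32)
  rec <- build_cohort(ascertain(simulate_families(cfg), cfg))
  nc <- rec[rec$carrier == "noncarrier", ]
  tab <- default_population_incidence()
  a <- attach_noncarrier_weights(nc, tab)
  b <- compute_weights(nc, tab)
  expect_identical(a$strata, b$strata)
  expect_identical(a$weights, b$weights)
  # all-zero population rates: p = 0 everywhere, every record at weight 1
  # through the d = 0 fallback or the p = 0 calibration
  zero <- incidence_table(tab$age_lo, tab$age_hi, rep(0, nrow(tab)))
  wz <- attach_noncarrier_weights(nc[nc$event == 0, ], zero)
  expect_true(all(wz$weights == 1))
})

test_that("degenerate strata can be merged upward into estimable groups", {
  tab <- incidence_table(c(0, 5), c(5, 10), c(0.01, 0.01))
  rec <- rbind(stratum_records(6, 0, age = 3),      # d = 0: degenerate
               stratum_records(10, 4, age = 8))
  rec$subject_id <- seq_len(nrow(rec)); rec$family_id <- rec$subject_id
  wt <- compute_weights(rec, tab, merge_degenerate = TRUE)
  # merged group spans both strata: n = 16, d = 4, p at the upper bound
  p2 <- expected_affected_proportion(tab, 2)
  expect_equal(wt$strata$w_affected[1], p2 * 16 / 4)
  expect_equal(wt$strata$w_affected[2], p2 * 16 / 4)
  expect_equal(wt$strata$w_unaffected[1], (1 - p2) * 16 / 12)
})

test_that("exit-age stratification remains available as an option", {
  cfg <- sim_config(n_families = 80, seed = 33)
  rec <- build_cohort(ascertain(simulate_families(cfg), cfg))
  car <- rec[rec$carrier == "carrier", ]
  tab <- default_carrier_incidence()
  w_att <- compute_weights(car, tab)
  w_exit <- compute_weights(car, tab, stratify_by = "exit_age")
  expect_identical(w_att$stratify_by, "attained_age")
  expect_identical(w_exit$stratify_by, "exit_age")
  # cases are grouped at diagnosis age under exit-age stratification
  i <- which(car$event == 1 & car$exit_age < car$attained_age)
  expect_gt(length(i), 0)
  expect_true(any(w_exit$stratum[i] != w_att$stratum[i]))
})
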