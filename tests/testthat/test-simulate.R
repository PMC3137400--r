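test_that("a fixed seed makes simulation and ascertainment byte-identical", {
  cfg <- sim_config(n_families = 40, seed = 1)
  a <- simulate_families(cfg)
  b <- simulate_families(cfg)
  expect_identical(a, b)
  expect_identical(ascertain(a, cfg), ascertain(b, cfg))
})

test_that("zero disease hazard produces no carrier cases", {
  zero <- incidence_table(seq(0, 85, 5), seq(5, 90, 5), rep(0, 18),
                          group = "carrier")
  cfg <- sim_config(n_families = 40, carrier_incidence = zero, seed = 2)
  subj <- simulate_families(cfg)
  expect_true(all(is.na(subj$crc_age[subj$carrier == "carrier"])))
})

test_that("offspring of a carrier x non-carrier couple are carriers with
           probability 1/2 (Mendelian transmission)", {
  cfg <- sim_config(n_families = 400, seed = 3)
  subj <- simulate_families(cfg)
  kids <- subj[!is.na(subj$carrier_parent), ]
  # among lineage children whose lineage parent carries the mutation
  k1 <- kids[kids$carrier_parent == "carrier", ]
  n <- nrow(k1)
  expect_gt(n, 500)
  frac <- mean(k1$carrier == "carrier")
  tol <- 4 * sqrt(0.25 / n)
  expect_lt(abs(frac - 0.5), tol)
  # no carrier children from two non-carrier parents (no de novo mutation)
  k0 <- kids[kids$carrier_parent == "noncarrier", ]
  expect_true(all(k0$carrier == "noncarrier"))
})

test_that("simulated event ages reproduce the piecewise-exponential survival", {
  # covariates at reference, no competing censoring, follow-up past age 90
  cfg <- sim_config(n_families = 500, beta_bmi5 = 0,
                    beta_covariates = c(sex = 0, smoke20 = 0, alcohol20 = 0),
                    censoring_rates = c(polypectomy = 0, other_cancer = 0,
                                        death = 0),
                    recruitment_age_range = c(95, 99),
                    missing_bmi_prob = 0, seed = 4)
  subj <- simulate_families(cfg)
  car <- subj[subj$carrier == "carrier", ]
  tab <- cfg$carrier_incidence
  # empirical cumulative incidence at 70 vs 1 - exp(-Lambda(70))
  p70 <- 1 - exp(-cumulative_hazard(tab, 70))
  phat <- mean(!is.na(car$crc_age) & car$crc_age <= 70)
  expect_lt(abs(phat - p70), 4 * sqrt(p70 * (1 - p70) / nrow(car)))
  # Kaplan-Meier at every stratum bound vs the closed-form survival
  km <- survival::survfit(
    survival::Surv(ifelse(is.na(car$crc_age), car$last_contact_age,
                          car$crc_age),
                   as.integer(!is.na(car$crc_age))) ~ 1)
  for (a in c(30, 40, 50, 60, 70, 80)) {
    S_true <- exp(-cumulative_hazard(tab, a))
    i <- max(which(km$time <= a))
    se <- km$std.err[i] * km$surv[i]   # Greenwood, survival scale
    expect_lt(abs(km$surv[i] - S_true), 4 * pmax(se, 1e-3))
  }
})

test_that("clinic ascertainment without selection is the identity", {
  cfg <- sim_config(n_families = 25, clinic_min_affected = 0,
                    relative_recruit_prob = 1, seed = 5)
  subj <- simulate_families(cfg)
  expect_identical(ascertain(subj, cfg), subj)
})

test_that("ascertainment fails loudly when no family qualifies", {
  zero <- incidence_table(seq(0, 85, 5), seq(5, 90, 5), rep(0, 18),
                          group = "carrier")
  zero_pop <- incidence_table(seq(0, 85, 5), seq(5, 90, 5), rep(0, 18))
  cfg <- sim_config(n_families = 20, carrier_incidence = zero,
                    noncarrier_incidence = zero_pop,
                    clinic_min_affected = 3, seed = 6)
  subj <- simulate_families(cfg)
  expect_error(ascertain(subj, cfg), "clinic_min_affected")
})

test_that("ascertained cohorts over-represent affected subjects and are an
           unaltered subset of the simulated cohort", {
  cfg <- sim_config(n_families = 500, seed = 7)
  subj <- simulate_families(cfg)
  asc <- ascertain(subj, cfg)
  sim_car <- subj[subj$carrier == "carrier", ]
  asc_car <- asc[asc$carrier == "carrier", ]
  expect_gt(mean(!is.na(asc_car$crc_age)), mean(!is.na(sim_car$crc_age)))
  # subset with no attribute (other than the proband flag) altered
  expect_true(all(asc$subject_id %in% subj$subject_id))
  cols <- setdiff(names(subj), "is_proband")
  merged <- subj[match(asc$subject_id, subj$subject_id), cols]
  rownames(merged) <- NULL
  expect_identical(asc[, cols], merged)
  # exactly one proband per retained family, and probands are affected
  pb <- asc[asc$is_proband, ]
  expect_identical(sort(unique(asc$family_id)), sort(pb$family_id))
  expect_true(all(!is.na(pb$crc_age)))
})

test_that("population-mode probands are recently diagnosed cases", {
  cfg <- sim_config(n_families = 400, ascertainment_mode = "population",
                    population_diagnosis_window = 5, seed = 8)
  subj <- simulate_families(cfg)
  asc <- ascertain(subj, cfg)
  pb <- asc[asc$is_proband, ]
  expect_gt(nrow(pb), 0)
  lag <- pb$last_contact_age - pb$crc_age
  expect_true(all(lag >= 0 & lag <= 5))
})

test_that("cohort tables round-trip through delimited text with a truth file", {
  cfg <- sim_config(n_families = 15, seed = 9)
  subj <- simulate_families(cfg)
  f <- tempfile(fileext = ".tsv")
  write_cohort(subj, f, config = cfg)
  back <- read_cohort(f)
  expect_equal(back$crc_age, subj$crc_age)
  expect_equal(back$weight20_kg, subj$weight20_kg)
  expect_identical(back$subject_id, subj$subject_id)
  truth <- readLines(paste0(f, ".truth.txt"))
  expect_true(any(grepl("beta_bmi5", truth)))
  expect_true(any(grepl("seed\t9", truth)))
  unlink(c(f, paste0(f, ".truth.txt")))
})
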