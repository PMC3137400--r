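#' Configuration for the family-cohort simulator
#'
#' Collects every knob of the synthetic cohort generator: pedigree structure,
#' genotype transmission, the piecewise-constant age-specific hazards for
#' carriers and non-carriers, log hazard ratios for BMI and the lifestyle
#' covariates, competing censoring processes, and the proband-driven
#' ascertainment scheme. Defaults emulate a multi-centre family registry of
#' mismatch-repair mutation families: founder generation conditioned on one
#' carrier, autosomal-dominant transmission, CRC penetrance for carriers of
#' roughly 45% to age 70, early-adult BMI around 22.5 (s.d. 3.8) kg/m^2, and
#' clinic ascertainment of multiple-case families.
#'
#' @param n_families Number of independent families to simulate.
#' @param founder_carrier_prob Probability that a founder couple carries the
#'   mutation (1 conditions every family on a carrier founder).
#' @param offspring_lambda Poisson mean number of children per couple.
#' @param generations Number of generations (founders = generation 1).
#' @param carrier_incidence,noncarrier_incidence [incidence_table()]s giving
#'   the baseline age-specific disease hazard by genotype.
#' @param beta_bmi5 Log hazard ratio per 5 kg/m^2 of BMI at age 20.
#' @param beta_covariates Named numeric vector of log hazard ratios for
#'   \code{sex} (male vs female), \code{smoke20} (ever vs never) and
#'   \code{alcohol20} (ever vs never); missing names mean zero.
#' @param bmi_mean,bmi_sd Mean and individual-level s.d. (kg/m^2) of BMI at
#'   age 20; draws are truncated to [14, 45].
#' @param bmi_family_sd S.d. of an additional family-shared component of BMI
#'   (default 0, i.e. BMI independent within families; positive values make
#'   the exposure cluster in families, as body size does in practice, so that
#'   within-family correlation of risk propagates into the exposure
#'   estimate's sampling variance). Total BMI variance is
#'   \code{bmi_sd^2 + bmi_family_sd^2}.
#' @param censoring_rates Named per-person-year rates for the competing
#'   censoring causes \code{polypectomy}, \code{other_cancer}, \code{death}.
#' @param recruitment_age_range Ages (years) between which the age at last
#'   contact (recruitment) is drawn uniformly.
#' @param ascertainment_mode \code{"clinic"} (multiple-case families via a
#'   family cancer clinic) or \code{"population"} (families of a recently
#'   diagnosed case reported to a population cancer registry).
#' @param clinic_min_affected Minimum number of observed disease cases for a
#'   family to reach the clinic (0 disables selection entirely).
#' @param population_diagnosis_window Years before recruitment within which a
#'   population proband's diagnosis must fall.
#' @param relative_recruit_prob Probability that each non-proband relative
#'   enrols.
#' @param missing_bmi_prob Probability that a subject's weight at age 20 is
#'   missing (such subjects are excluded when the analysis cohort is built).
#' @param frailty_sd S.d. of a shared family-level log-normal frailty on the
#'   log hazard scale (0 = none; used to study robust-variance behaviour).
#' @param seed Integer seed; when non-NULL the generator is fully
#'   deterministic.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_families = 300,
                       founder_carrier_prob = 1,
                       offspring_lambda = 3,
                       generations = 3,
                       carrier_incidence = default_carrier_incidence(),
                       noncarrier_incidence = default_population_incidence(),
                       beta_bmi5 = log(1.30),
                       beta_covariates = c(sex = 0.25, smoke20 = 0.25,
                                           alcohol20 = 0),
                       bmi_mean = 22.5,
                       bmi_sd = 3.8,
                       bmi_family_sd = 0,
                       censoring_rates = c(polypectomy = 0.003,
                                           other_cancer = 0.0025,
                                           death = 0.0005),
                       recruitment_age_range = c(20, 80),
                       ascertainment_mode = c("clinic", "population"),
                       clinic_min_affected = 2,
                       population_diagnosis_window = 5,
                       relative_recruit_prob = 0.8,
                       missing_bmi_prob = 0.10,
                       frailty_sd = 0,
                       seed = NULL) {
  ascertainment_mode <- match.arg(ascertainment_mode)
  stopifnot(inherits(carrier_incidence, "incidence_table"),
            inherits(noncarrier_incidence, "incidence_table"))
  probs <- c(founder_carrier_prob, relative_recruit_prob, missing_bmi_prob)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (any(censoring_rates < 0)) stop("censoring rates must be >= 0")
  if (bmi_sd <= 0) stop("bmi_sd must be > 0")
  if (bmi_family_sd < 0) stop("bmi_family_sd must be >= 0")
  if (generations < 1) stop("generations must be >= 1")
  if (n_families < 1) stop("n_families must be >= 1")
  if (frailty_sd < 0) stop("frailty_sd must be >= 0")
  cr <- c(polypectomy = 0, other_cancer = 0, death = 0)
  cr[names(censoring_rates)] <- censoring_rates
  cfg <- list(n_families = as.integer(n_families),
              founder_carrier_prob = founder_carrier_prob,
              offspring_lambda = offspring_lambda,
              generations = as.integer(generations),
              carrier_incidence = carrier_incidence,
              noncarrier_incidence = noncarrier_incidence,
              beta_bmi5 = beta_bmi5,
              beta_covariates = beta_covariates,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd,
              bmi_family_sd = bmi_family_sd,
              censoring_rates = cr,
              recruitment_age_range = recruitment_age_range,
              ascertainment_mode = ascertainment_mode,
              clinic_min_affected = as.integer(clinic_min_affected),
              population_diagnosis_window = population_diagnosis_window,
              relative_recruit_prob = relative_recruit_prob,
              missing_bmi_prob = missing_bmi_prob,
              frailty_sd = frailty_sd,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Mutation frequencies and covariate distributions used by the generator.
# Gene mix follows the relative frequency of the four mismatch-repair genes in
# large carrier registries (MLH1/MSH2 most common, PMS2 rare).
.sim_gene_probs <- c(MLH1 = 0.38, MSH2 = 0.49, MSH6 = 0.09, PMS2 = 0.04)
.sim_country_probs <- c(ANZ = 0.72, USA = 0.22, CAN = 0.06)
.sim_site_probs <- c(right = 0.54, left = 0.18, rectosigmoid = 0.05,
                     rectum = 0.12, unknown = 0.11)

#' Simulate multi-generation families segregating a rare dominant mutation
#'
#' Generates pedigrees with Mendelian transmission (offspring of a
#' carrier x non-carrier couple are carriers with probability 1/2), covariates
#' drawn independently of genotype, disease ages drawn by inversion from the
#' genotype's piecewise-exponential hazard multiplied by
#' \eqn{\exp(\beta_{bmi5}(BMI-bmi\_mean)/5 + \sum\beta_c x_c)}, and competing
#' censoring ages (polypectomy, other cancer, death) drawn independently per
#' cause. Only the earliest event that occurs before last contact is retained
#' as observable history; every subject has an age at last contact.
#'
#' @param config A [sim_config()].
#' @return A data frame with one row per subject and the columns
#'   \code{subject_id}, \code{family_id}, \code{carrier}, \code{gene},
#'   \code{sex}, \code{country}, \code{height_m}, \code{weight20_kg},
#'   \code{smoke20}, \code{alcohol20}, \code{crc_age}, \code{crc_verified},
#'   \code{tumour_site}, \code{polypectomy_age}, \code{other_cancer_age},
#'   \code{death_age}, \code{last_contact_age}, \code{is_proband}, plus the
#'   simulation-metadata column \code{carrier_parent} (lineage parent's
#'   carrier status, NA for founders and married-in spouses; used to verify
#'   Mendelian transmission and omitted from files written by
#'   [write_cohort()]).
#' @seealso [ascertain()] to apply proband-driven selection.
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nf <- config$n_families

  fam_gene <- sample(names(.sim_gene_probs), nf, replace = TRUE,
                     prob = .sim_gene_probs)
  fam_country <- sample(names(.sim_country_probs), nf, replace = TRUE,
                        prob = .sim_country_probs)
  fam_carrier_founder <- stats::runif(nf) < config$founder_carrier_prob

  # Pedigree bookkeeping: grow generation by generation, vectorised across
  # families. A "couple" is a lineage member plus a married-in non-carrier
  # spouse; children inherit the mutation from a carrier lineage parent with
  # probability 1/2.
  fam <- integer(0); carrier <- logical(0); sex <- character(0)
  parent_carrier <- character(0)   # lineage parent's status; NA for founders
                                   # and married-in spouses
  founder_sex <- ifelse(stats::runif(nf) < 0.5, "male", "female")
  fam <- c(fam, seq_len(nf), seq_len(nf))
  carrier <- c(carrier, fam_carrier_founder, rep(FALSE, nf))
  sex <- c(sex, founder_sex, ifelse(founder_sex == "male", "female", "male"))
  parent_carrier <- c(parent_carrier, rep(NA_character_, 2 * nf))

  couple_fam <- seq_len(nf)          # families of current-generation couples
  couple_carrier <- fam_carrier_founder
  g <- 1L
  while (g < config$generations && length(couple_fam) > 0) {
    nkid <- stats::rpois(length(couple_fam), config$offspring_lambda)
    kid_fam <- rep(couple_fam, nkid)
    kid_parent_carrier <- rep(couple_carrier, nkid)
    nk <- length(kid_fam)
    kid_carrier <- kid_parent_carrier & (stats::runif(nk) < 0.5)
    kid_sex <- ifelse(stats::runif(nk) < 0.5, "male", "female")
    fam <- c(fam, kid_fam); carrier <- c(carrier, kid_carrier)
    sex <- c(sex, kid_sex)
    parent_carrier <- c(parent_carrier,
                        ifelse(kid_parent_carrier, "carrier", "noncarrier"))
    g <- g + 1L
    if (g < config$generations && nk > 0) {
      # each child acquires a married-in non-carrier spouse
      fam <- c(fam, kid_fam); carrier <- c(carrier, rep(FALSE, nk))
      sex <- c(sex, ifelse(kid_sex == "male", "female", "male"))
      parent_carrier <- c(parent_carrier, rep(NA_character_, nk))
    }
    couple_fam <- kid_fam; couple_carrier <- kid_carrier
  }

  n <- length(fam)
  o <- order(fam)
  fam <- fam[o]; carrier <- carrier[o]; sex <- sex[o]
  parent_carrier <- parent_carrier[o]

  # covariates, independent of genotype
  smoke <- ifelse(stats::runif(n) < 0.48, "ever", "never")
  alcohol <- ifelse(stats::runif(n) < 0.65, "ever", "never")
  height <- ifelse(sex == "male",
                   stats::rnorm(n, 1.78, 0.07), stats::rnorm(n, 1.63, 0.06))
  height <- pmax(height, 1.2)
  bmi <- stats::rnorm(n, config$bmi_mean, config$bmi_sd)
  if (config$bmi_family_sd > 0) {
    bfam <- stats::rnorm(nf, 0, config$bmi_family_sd)
    bmi <- bmi + bfam[fam]
  }
  bmi <- pmin(pmax(bmi, 14), 45)
  weight <- bmi * height^2

  bc <- config$beta_covariates
  getb <- function(nm) if (nm %in% names(bc)) bc[[nm]] else 0
  eta <- config$beta_bmi5 * (bmi - config$bmi_mean) / 5 +
    getb("sex") * (sex == "male") +
    getb("smoke20") * (smoke == "ever") +
    getb("alcohol20") * (alcohol == "ever")
  if (config$frailty_sd > 0) {
    fr <- stats::rnorm(nf, 0, config$frailty_sd)
    eta <- eta + fr[fam]
  }
  rr <- exp(eta)

  crc <- rep(NA_real_, n)
  if (any(carrier))
    crc[carrier] <- rpwexp(config$carrier_incidence, rr[carrier])
  if (any(!carrier))
    crc[!carrier] <- rpwexp(config$noncarrier_incidence, rr[!carrier])

  rexp_or_na <- function(rate) {
    if (rate > 0) stats::rexp(n, rate) else rep(NA_real_, n)
  }
  polyp <- rexp_or_na(config$censoring_rates[["polypectomy"]])
  other <- rexp_or_na(config$censoring_rates[["other_cancer"]])
  death <- rexp_or_na(config$censoring_rates[["death"]])
  lc <- stats::runif(n, config$recruitment_age_range[1],
                     config$recruitment_age_range[2])

  # observable history: only the first event before last contact is kept
  ev <- cbind(crc, polyp, other, death)
  ev_min <- suppressWarnings(apply(ev, 1, min, na.rm = TRUE))
  ev_min[!is.finite(ev_min)] <- Inf
  keep <- !is.na(ev) & ev <= pmin(ev_min, lc)
  crc <- ifelse(keep[, 1], crc, NA_real_)
  polyp <- ifelse(keep[, 2], polyp, NA_real_)
  other <- ifelse(keep[, 3], other, NA_real_)
  death <- ifelse(keep[, 4], death, NA_real_)

  affected <- !is.na(crc)
  verified <- ifelse(affected,
                     ifelse(stats::runif(n) < 0.9, "verified", "self_report"),
                     NA_character_)
  site <- rep(NA_character_, n)
  if (any(affected))
    site[affected] <- sample(names(.sim_site_probs), sum(affected),
                             replace = TRUE, prob = .sim_site_probs)
  weight[stats::runif(n) < config$missing_bmi_prob] <- NA_real_

  data.frame(
    subject_id = paste0("F", formatC(fam, width = 4, flag = "0"), "_",
                        stats::ave(fam, fam, FUN = seq_along)),
    family_id = paste0("F", formatC(fam, width = 4, flag = "0")),
    carrier = ifelse(carrier, "carrier", "noncarrier"),
    gene = ifelse(carrier, fam_gene[fam], "none"),
    sex = sex,
    country = fam_country[fam],
    height_m = height,
    weight20_kg = weight,
    smoke20 = smoke,
    alcohol20 = alcohol,
    crc_age = crc,
    crc_verified = verified,
    tumour_site = site,
    polypectomy_age = polyp,
    other_cancer_age = other,
    death_age = death,
    last_contact_age = lc,
    is_proband = FALSE,
    carrier_parent = parent_carrier,
    stringsAsFactors = FALSE
  )
}

#' Apply proband-driven ascertainment to a simulated cohort
#'
#' Reproduces the non-random, phenotype-driven sampling the weighted-cohort
#' correction exists to fix. In clinic mode, only families with at least
#' \code{clinic_min_affected} observed disease cases are retained and one
#' affected member is marked as proband (with \code{clinic_min_affected = 0}
#' no selection is applied at all). In population mode, a family is retained
#' when it contains a case diagnosed within
#' \code{population_diagnosis_window} years of recruitment (i.e. of the age at
#' last contact); that case becomes the proband. Non-proband relatives are
#' retained independently with probability \code{relative_recruit_prob}. No
#' subject attribute other than the proband flag is altered.
#'
#' @param subjects Data frame from [simulate_families()].
#' @param config The [sim_config()] used to simulate (supplies the
#'   ascertainment parameters; when it carries a seed, selection is
#'   deterministic).
#' @return The retained subset of \code{subjects}, proband rows flagged.
#' @export
ascertain <- function(subjects, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 1000003L)
  mode <- config$ascertainment_mode

  if (mode == "clinic" && config$clinic_min_affected == 0L) {
    out <- subjects
    if (config$relative_recruit_prob < 1) {
      keep <- stats::runif(nrow(out)) < config$relative_recruit_prob
      out <- out[keep, , drop = FALSE]
    }
    rownames(out) <- NULL
    return(out)
  }

  affected <- !is.na(subjects$crc_age)
  if (mode == "clinic") {
    n_aff <- tapply(affected, subjects$family_id, sum)
    ok_fam <- names(n_aff)[n_aff >= config$clinic_min_affected]
    eligible <- affected
  } else {
    recent <- affected &
      (subjects$last_contact_age - subjects$crc_age) <=
        config$population_diagnosis_window &
      subjects$last_contact_age >= subjects$crc_age
    n_rec <- tapply(recent, subjects$family_id, sum)
    ok_fam <- names(n_rec)[n_rec > 0]
    eligible <- recent
  }
  if (length(ok_fam) == 0)
    stop("no simulated family survives ascertainment (mode=", mode,
         ", clinic_min_affected=", config$clinic_min_affected,
         ", population_diagnosis_window=", config$population_diagnosis_window,
         "): increase penetrance, family size or n_families")

  sel <- subjects[subjects$family_id %in% ok_fam, , drop = FALSE]
  elig <- eligible[subjects$family_id %in% ok_fam]
  # one proband per family, drawn among its eligible affected members
  idx <- split(seq_len(nrow(sel)), sel$family_id)
  proband_rows <- vapply(idx, function(i) {
    cand <- i[elig[i]]
    if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  }, integer(1))
  sel$is_proband <- seq_len(nrow(sel)) %in% proband_rows
  keep <- sel$is_proband |
    (stats::runif(nrow(sel)) < config$relative_recruit_prob)
  out <- sel[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate and ascertain in one step
#'
#' Convenience wrapper: [simulate_families()] followed by [ascertain()].
#' @inheritParams ascertain
#' @export
simulate_study_cohort <- function(config) {
  ascertain(simulate_families(config), config)
}

#' Marginal age-specific incidence implied by a simulation configuration
#'
#' The external rates used by the weighted-cohort correction describe the
#' population the sample was drawn from: the probability that a subject of a
#' given attained age is an observed case. For cohorts generated by
#' [sim_config()] that probability is known exactly up to a covariate
#' expectation, and this function computes it, giving the "correctly
#' specified" external table for simulation studies of the correction.
#'
#' With baseline disease hazard \eqn{\lambda_0(t)}, subject relative risk
#' \eqn{W = e^\eta} (covariates and optional family frailty), and total
#' competing censoring rate \eqn{\mu} (polypectomy + other cancer + death,
#' which terminate observable history before disease), the probability of
#' being an observed case by age \eqn{a} is the competing-risks cumulative
#' incidence
#' \deqn{F^*(a) = E\Big[\int_0^a W\lambda_0(u)\,
#'   e^{-W\Lambda_0(u) - \mu u}\,du\Big],}
#' evaluated by Monte Carlo over the covariate distribution; the age integral
#' has a closed form within each stratum (the baseline hazard is constant
#' there), so the quadrature is exact given the draws. The returned table
#' holds the piecewise-constant rates
#' \eqn{\lambda_k} whose net transform reproduces \eqn{F^*} at every stratum
#' bound, i.e. \eqn{1 - \exp(-\sum_{j\le k}\lambda_j\Delta_j) = F^*(hi_k)},
#' so [expected_affected_proportion()] of the result is exactly \eqn{F^*}.
#' With \code{observed = FALSE} the competing censoring is ignored and the
#' result is the net marginal incidence of the disease process itself.
#'
#' @param config A [sim_config()].
#' @param carrier Marginal rates for carriers (TRUE, default) or
#'   non-carriers.
#' @param observed Account for the competing censoring processes that stop a
#'   case being observed (default TRUE; this is the calibration target of
#'   [compute_weights()]).
#' @param M Monte Carlo draws for the covariate expectation.
#' @param mc_seed Seed for the draws (kept separate from \code{config$seed}
#'   so the table does not depend on which cohort replicate is generated;
#'   the caller's random stream is left untouched).
#' @return An [incidence_table()] on the same strata as the genotype's
#'   baseline table.
#' @export
marginal_incidence_table <- function(config, carrier = TRUE, observed = TRUE,
                                     M = 2e5, mc_seed = 20200501) {
  stopifnot(inherits(config, "sim_config"))
  base <- if (carrier) config$carrier_incidence else config$noncarrier_incidence
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(mc_seed)
  sex <- stats::runif(M) < 0.5
  smoke <- stats::runif(M) < 0.48
  alcohol <- stats::runif(M) < 0.65
  bmi_tot_sd <- sqrt(config$bmi_sd^2 + config$bmi_family_sd^2)
  bmi <- pmin(pmax(stats::rnorm(M, config$bmi_mean, bmi_tot_sd), 14), 45)
  bc <- config$beta_covariates
  getb <- function(nm) if (nm %in% names(bc)) bc[[nm]] else 0
  eta <- config$beta_bmi5 * (bmi - config$bmi_mean) / 5 +
    getb("sex") * sex + getb("smoke20") * smoke + getb("alcohol20") * alcohol
  if (config$frailty_sd > 0)
    eta <- eta + stats::rnorm(M, 0, config$frailty_sd)
  W <- exp(eta)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  else rm(".Random.seed", envir = .GlobalEnv)

  width <- base$age_hi - base$age_lo
  mu <- if (observed) sum(config$censoring_rates) else 0
  H0lo <- cumulative_hazard(base, base$age_lo)
  # exact within-stratum integral of W lambda e^{-W L0(u) - mu u}:
  #   W lambda / (W lambda + mu) * e^{-W L0(lo) - mu lo} *
  #     (1 - e^{-(W lambda + mu) width})
  dF <- vapply(seq_len(nrow(base)), function(k) {
    lam <- base$rate[k]
    if (lam == 0) return(0)
    a <- W * lam
    mean(a / (a + mu) * exp(-W * H0lo[k] - mu * base$age_lo[k]) *
           (1 - exp(-(a + mu) * width[k])))
  }, numeric(1))
  Fstar <- c(0, cumsum(dF))
  rate <- pmax(-diff(log(1 - Fstar)), 0) / width
  incidence_table(base$age_lo, base$age_hi, rate,
                  group = paste0(attr(base, "group"),
                                 if (observed) "_observed_marginal"
                                 else "_marginal"))
}

#' Write / read a subject table as delimited text
#'
#' One row per subject, columns exactly as produced by [simulate_families()];
#' missing ages are written as empty cells. `write_cohort` also writes a
#' sidecar "truth" file recording the generating configuration (including the
#' seed and the true log hazard ratios) when a config is supplied.
#'
#' @param subjects Subject data frame.
#' @param path Output file (tab-delimited).
#' @param config Optional [sim_config()]; written to \code{<path>.truth.txt}.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(subjects, path, config = NULL) {
  subjects <- subjects[, setdiff(names(subjects), "carrier_parent"),
                       drop = FALSE]
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  if (!is.null(config)) {
    truth <- c(
      paste0("seed\t", if (is.null(config$seed)) "NA" else config$seed),
      paste0("beta_bmi5\t", format(config$beta_bmi5, digits = 15)),
      paste0("beta_", names(config$beta_covariates), "\t",
             format(config$beta_covariates, digits = 15)),
      paste0("n_families\t", config$n_families),
      paste0("ascertainment_mode\t", config$ascertainment_mode))
    writeLines(truth, paste0(path, ".truth.txt"))
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.delim(path, sep = "\t", header = TRUE, na.strings = c("", "NA"),
                         stringsAsFactors = FALSE)
  num <- c("height_m", "weight20_kg", "crc_age", "polypectomy_age",
           "other_cancer_age", "death_age", "last_contact_age")
  for (v in intersect(num, names(x))) x[[v]] <- as.numeric(x[[v]])
  if ("is_proband" %in% names(x)) x$is_proband <- as.logical(x$is_proband)
  x
}
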