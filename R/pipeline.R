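#' Run the full weighted-cohort study pipeline
#'
#' Orchestrates the complete analysis for a subject table (real or
#' simulated): builds the analysis cohort under the study's censoring rules,
#' computes ascertainment weights within each analysis subgroup against the
#' relevant external incidence table, fits weighted Cox models with
#' family-clustered robust variance, and emits one report row per estimate
#' (HR per 5 kg/m^2 or per WHO category vs normal, robust 95% CI, p, n,
#' person-years, events). Weights are recomputed within every subgroup
#' because sampling fractions depend on the sample analysed.
#'
#' @param subjects Subject table (schema of [simulate_families()]), or NULL
#'   to simulate from \code{config$simulation}.
#' @param config List with components:
#'   \describe{
#'   \item{carrier_incidence, population_incidence}{[incidence_table()]s (or
#'     file paths) supplying the external rates.}
#'   \item{analyses}{Character vector from \code{carriers_continuous},
#'     \code{carriers_who}, \code{noncarriers_continuous},
#'     \code{noncarriers_who}, \code{per_gene}, \code{heterodimers},
#'     \code{per_site}, \code{sex_specific}, \code{interactions}.}
#'   \item{verified_only, neoplasia_outcome}{Sensitivity flags (default
#'     FALSE).}
#'   \item{adjust}{Adjustment covariates for the multivariable models
#'     (default \code{c("sex", "country", "smoke20", "alcohol20")}; gene is
#'     added automatically for all-carrier analyses).}
#'   \item{merge_degenerate}{Weighting option, see [compute_weights()].}
#'   \item{simulation}{Optional [sim_config()] used when \code{subjects} is
#'     NULL.}
#'   \item{seed}{Integer seed for any randomness (simulation).}
#'   \item{out_dir}{Optional directory; when set, report, weight tables and a
#'     reproducibility manifest are written there.}
#'   }
#' @return List of class \code{"wcohort_study"}: \code{report} (data frame),
#'   \code{records}, \code{summary} (descriptive table), \code{manifest}.
#' @export
run_study <- function(subjects = NULL, config = list()) {
  cfg <- config
  if (is.null(cfg$analyses))
    cfg$analyses <- c("carriers_continuous", "carriers_who",
                      "noncarriers_continuous", "noncarriers_who")
  known <- c("carriers_continuous", "carriers_who", "noncarriers_continuous",
             "noncarriers_who", "per_gene", "heterodimers", "per_site",
             "sex_specific", "interactions")
  bad <- setdiff(cfg$analyses, known)
  if (length(bad)) stop("unknown analyses: ", paste(bad, collapse = ", "))
  if (is.null(cfg$verified_only)) cfg$verified_only <- FALSE
  if (is.null(cfg$neoplasia_outcome)) cfg$neoplasia_outcome <- FALSE
  if (is.null(cfg$adjust)) cfg$adjust <- c("sex", "country", "smoke20",
                                           "alcohol20")
  if (is.null(cfg$merge_degenerate)) cfg$merge_degenerate <- FALSE
  ci <- cfg$carrier_incidence
  if (is.character(ci)) ci <- read_incidence_table(ci, group = "carrier")
  pi_ <- cfg$population_incidence
  if (is.character(pi_)) pi_ <- read_incidence_table(pi_, group = "population")

  if (is.null(subjects)) {
    sim <- cfg$simulation
    if (is.null(sim)) sim <- sim_config(seed = cfg$seed)
    if (!is.null(cfg$seed)) sim$seed <- as.integer(cfg$seed)
    subjects <- simulate_study_cohort(sim)
    # for simulated cohorts the correctly specified external rates are the
    # generator's own marginal observed-case rates
    if (is.null(ci)) ci <- marginal_incidence_table(sim, carrier = TRUE)
    if (is.null(pi_)) pi_ <- marginal_incidence_table(sim, carrier = FALSE)
  }
  if (is.null(ci)) ci <- default_carrier_incidence()
  if (is.null(pi_)) pi_ <- default_population_incidence()

  outcome <- if (cfg$neoplasia_outcome) "neoplasia" else "crc"
  records <- build_cohort(subjects, outcome_mode = outcome,
                          verified_only = cfg$verified_only)

  rows <- list()
  weight_tables <- list()
  add_row <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)

  # fit HR per 5 kg/m^2 (or WHO categories) in a subgroup, with subgroup
  # weights; emit not-estimable rows instead of failing
  fit_subgroup <- function(analysis, label, sub, table, exposure = "bmi5",
                           adjust = cfg$adjust) {
    n <- nrow(sub); ev <- sum(sub$event); py <- sum(sub$exit_age)
    if (n == 0 || ev < 2) {
      add_row(analysis = analysis, subgroup = label, term = exposure,
              n = n, person_years = py, events = ev,
              HR = NA_real_, lower = NA_real_, upper = NA_real_,
              p = NA_real_, note = "not estimable (<2 events)")
      return(invisible(NULL))
    }
    adjust <- adjust[vapply(adjust, function(v)
      length(unique(sub[[v]])) > 1, logical(1))]
    wt <- compute_weights(sub, table,
                          merge_degenerate = cfg$merge_degenerate)
    weight_tables[[paste(analysis, label, sep = ":")]] <<- wt
    rhs <- paste(c(exposure, adjust), collapse = " + ")
    f <- stats::as.formula(paste("survival::Surv(exit_age, event) ~", rhs))
    fit <- tryCatch(
      wcoxph(f, sub, weights = wt, cluster = ~family_id),
      error = function(e) e)
    note <- ""
    if (inherits(fit, "error") && length(adjust) > 0 &&
        grepl("separation", conditionMessage(fit))) {
      # sparse-event subgroups can separate on an adjustment dummy; report
      # the unadjusted estimate rather than no estimate, and say so
      f0 <- stats::as.formula(paste("survival::Surv(exit_age, event) ~",
                                    exposure))
      fit0 <- tryCatch(wcoxph(f0, sub, weights = wt, cluster = ~family_id),
                       error = function(e) e)
      if (!inherits(fit0, "error")) {
        fit <- fit0
        note <- "unadjusted (separation under full adjustment)"
      }
    }
    if (inherits(fit, "error")) {
      add_row(analysis = analysis, subgroup = label, term = exposure,
              n = n, person_years = py, events = ev,
              HR = NA_real_, lower = NA_real_, upper = NA_real_,
              p = NA_real_, note = paste("not estimable:",
                                         conditionMessage(fit)))
      return(invisible(NULL))
    }
    s <- summary(fit)$coefficients
    keep <- grep(paste0("^", exposure), rownames(s), value = TRUE)
    for (tm in keep)
      add_row(analysis = analysis, subgroup = label, term = tm,
              n = n, person_years = py, events = ev,
              HR = s[tm, "HR"], lower = s[tm, "lower"],
              upper = s[tm, "upper"], p = s[tm, "p"], note = note)
    invisible(fit)
  }

  carriers <- records[records$carrier == "carrier", , drop = FALSE]
  noncarr <- records[records$carrier == "noncarrier", , drop = FALSE]
  adj_carrier <- unique(c(cfg$adjust, "gene"))

  for (an in cfg$analyses) {
    switch(an,
      carriers_continuous = fit_subgroup(an, "carriers", carriers, ci,
                                         adjust = adj_carrier),
      carriers_who = fit_subgroup(an, "carriers", carriers, ci,
                                  exposure = "who_category",
                                  adjust = adj_carrier),
      noncarriers_continuous = fit_subgroup(an, "noncarriers", noncarr, pi_),
      noncarriers_who = fit_subgroup(an, "noncarriers", noncarr, pi_,
                                     exposure = "who_category"),
      per_gene = for (g in c("MLH1", "MSH2", "MSH6", "PMS2"))
        fit_subgroup(an, g, carriers[carriers$gene == g, , drop = FALSE], ci),
      heterodimers = {
        fit_subgroup(an, "MutLalpha (MLH1+PMS2)",
                     carriers[carriers$gene %in% c("MLH1", "PMS2"), ,
                              drop = FALSE], ci)
        fit_subgroup(an, "MutSalpha (MSH2+MSH6)",
                     carriers[carriers$gene %in% c("MSH2", "MSH6"), ,
                              drop = FALSE], ci)
      },
      per_site = {
        # disease at other sites censors at the diagnosis age
        site_groups <- list(right = "right",
                            left_rectosigmoid = c("left", "rectosigmoid"),
                            rectum = "rectum")
        for (lbl in names(site_groups)) {
          sub <- carriers
          other <- sub$event == 1 & !(sub$tumour_site %in% site_groups[[lbl]])
          sub$event[other] <- 0L
          sub$censor_reason[other] <- "other_site"
          fit_subgroup(an, lbl, sub, ci, adjust = adj_carrier)
        }
      },
      sex_specific = for (sx in c("female", "male"))
        fit_subgroup(an, paste0("carriers_", sx),
                     carriers[carriers$sex == sx, , drop = FALSE], ci,
                     adjust = setdiff(adj_carrier, "sex")),
      interactions = {
        # carriers weighted against the carrier table, non-carriers against
        # the population table, in one joint model
        w_all <- numeric(nrow(records))
        w_all[records$carrier == "carrier"] <-
          compute_weights(carriers, ci,
                          merge_degenerate = cfg$merge_degenerate)$weights
        w_all[records$carrier == "noncarrier"] <-
          compute_weights(noncarr, pi_,
                          merge_degenerate = cfg$merge_degenerate)$weights
        base <- stats::as.formula(paste(
          "survival::Surv(exit_age, event) ~ bmi5 + carrier +",
          paste(cfg$adjust, collapse = " + ")))
        it <- tryCatch(
          wald_interaction(base, records, c("bmi5", "carrier"),
                           weights = w_all, cluster = ~family_id),
          error = function(e) e)
        if (inherits(it, "error")) {
          add_row(analysis = an, subgroup = "carrier x bmi5",
                  term = "interaction", n = nrow(records),
                  person_years = sum(records$exit_age),
                  events = sum(records$event), HR = NA_real_,
                  lower = NA_real_, upper = NA_real_, p = NA_real_,
                  note = paste("not estimable:", conditionMessage(it)))
        } else {
          add_row(analysis = an, subgroup = "carrier x bmi5",
                  term = "interaction", n = nrow(records),
                  person_years = sum(records$exit_age),
                  events = sum(records$event), HR = NA_real_,
                  lower = NA_real_, upper = NA_real_, p = it$p,
                  note = paste0("Wald chisq=", signif(it$chisq, 4),
                                " df=", it$df))
        }
      })
  }

  report <- do.call(rbind, rows)
  manifest <- list(
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    analyses = cfg$analyses,
    outcome_mode = outcome,
    verified_only = cfg$verified_only,
    weights_recomputed_per_subgroup = TRUE,
    exclusions = attr(records, "exclusions"),
    n_records = nrow(records),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("wcohort")),
    timestamp = format(Sys.time(), tz = "UTC"))

  out <- list(report = report, records = records,
              summary = summarize_cohort(records),
              weight_tables = weight_tables, manifest = manifest)
  class(out) <- "wcohort_study"

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report, file.path(cfg$out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_records(records, file.path(cfg$out_dir, "records.tsv"))
    for (nm in names(weight_tables))
      write_weight_table(weight_tables[[nm]],
                         file.path(cfg$out_dir,
                                   paste0("weights_", gsub("[^A-Za-z0-9]+", "_",
                                                           nm), ".tsv")))
    writeLines(paste(names(manifest),
                     vapply(manifest, function(v)
                       paste(format(unlist(v)), collapse = ","), ""),
                     sep = "\t"),
               file.path(cfg$out_dir, "manifest.txt"))
  }
  out
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[sort(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.wcohort_study <- function(x, ...) {
  cat("Weighted-cohort study:", nrow(x$report), "report rows,",
      x$manifest$n_records, "records\n")
  print(x$report, digits = 3)
  invisible(x)
}

#' Descriptive summary of an analysis cohort
#'
#' Counts and means by carrier status and affection status: sex, gene,
#' country, smoking and alcohol at age 20, BMI, plus verification-source and
#' tumour-site tallies for cases.
#'
#' @param records \code{cohort_records} (or an empty data frame).
#' @return Data frame with one row per statistic x group; empty input yields
#'   an empty data frame.
#' @export
summarize_cohort <- function(records) {
  if (nrow(records) == 0)
    return(data.frame(group = character(0), statistic = character(0),
                      value = numeric(0)))
  grp <- interaction(records$carrier,
                     ifelse(records$event == 1, "affected", "unaffected"),
                     sep = ".", drop = TRUE)
  out <- list()
  add <- function(g, s, v) out[[length(out) + 1L]] <<- data.frame(
    group = g, statistic = s, value = v, stringsAsFactors = FALSE)
  for (g in levels(grp)) {
    r <- records[grp == g, , drop = FALSE]
    add(g, "n", nrow(r))
    add(g, "n_female", sum(r$sex == "female"))
    add(g, "mean_bmi20", mean(r$bmi20))
    add(g, "sd_bmi20", stats::sd(r$bmi20))
    add(g, "mean_exit_age", mean(r$exit_age))
    add(g, "person_years", sum(r$exit_age))
    add(g, "n_smoke_ever", sum(r$smoke20 == "ever"))
    add(g, "n_alcohol_ever", sum(r$alcohol20 == "ever"))
    for (gene in setdiff(unique(records$gene), NA))
      add(g, paste0("n_gene_", gene), sum(r$gene == gene))
  }
  cases <- records[records$event == 1, , drop = FALSE]
  if (nrow(cases)) {
    for (v in setdiff(unique(cases$crc_verified), NA))
      add("cases", paste0("n_verified_", v), sum(cases$crc_verified == v,
                                                 na.rm = TRUE))
    for (s in setdiff(unique(cases$tumour_site), NA))
      add("cases", paste0("n_site_", s), sum(cases$tumour_site == s,
                                             na.rm = TRUE))
  }
  do.call(rbind, out)
}
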