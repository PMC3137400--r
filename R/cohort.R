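#' Body mass index from weight and height
#'
#' BMI at age 20 is weight at age 20 in kilograms divided by height in metres
#' squared.
#'
#' @param weight20_kg Weight in kg; must be > 0.
#' @param height_m Height in metres; must be > 0.
#' @param subject_id Optional ids used in error messages.
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(72, 1.80)   # 22.22
#' @export
compute_bmi <- function(weight20_kg, height_m, subject_id = NULL) {
  bad <- !is.na(weight20_kg) & !is.na(height_m) &
    (weight20_kg <= 0 | height_m <= 0)
  if (any(bad)) {
    who <- if (is.null(subject_id)) which(bad) else subject_id[bad]
    stop("non-positive weight or height for subject(s): ",
         paste(utils::head(who, 5), collapse = ", "))
  }
  weight20_kg / height_m^2
}

#' WHO body-mass-index category
#'
#' Categories: underweight (<= 18.49), normal (18.50-24.99), overweight
#' (25.00-29.99), obese (>= 30.00), all in kg/m^2. BMI is rounded to two
#' decimals before interval lookup, so the printed category boundaries are
#' exhaustive.
#'
#' @details The WHO cut-points leave nominal gaps (18.49 vs 18.50, 24.99 vs
#' 25.00). Rounding BMI to 2 decimals (IEEE round-half-to-even, as
#' \code{round()} does) before lookup makes the four printed intervals cover
#' every positive BMI: e.g. 18.494 rounds to 18.49 (underweight) and 18.496
#' to 18.50 (normal).
#'
#' @param bmi20 BMI in kg/m^2, > 0.
#' @return Factor with levels underweight, normal, overweight, obese
#'   (reference level \code{normal}, matching how categorical models are
#'   reported).
#' @examples
#' who_category(c(18.49, 18.50, 24.99, 25, 30))
#' @export
who_category <- function(bmi20) {
  if (any(!is.na(bmi20) & bmi20 <= 0)) stop("bmi20 must be > 0")
  b <- round(bmi20, 2)
  cat <- ifelse(b <= 18.49, "underweight",
         ifelse(b <= 24.99, "normal",
         ifelse(b <= 29.99, "overweight", "obese")))
  factor(cat, levels = c("normal", "underweight", "overweight", "obese"))
}

#' Build analysis-ready risk intervals from a subject table
#'
#' Applies the study's exposure definitions, exclusions, and censoring rules.
#' Time at risk starts at birth and ends at the age of the first of: disease
#' diagnosis, another cancer, polypectomy, death, or last contact. Subjects
#' missing height or weight at age 20 are excluded (counted in the attached
#' exclusion log); subjects with no event or contact age at all are an error.
#'
#' @param subjects Subject data frame (the schema written by
#'   [simulate_families()]; real data in the same shape is accepted).
#' @param outcome_mode \code{"crc"}: the disease itself is the event and
#'   polypectomy censors (polypectomy may reduce subsequent risk, so follow-up
#'   must stop there); \code{"neoplasia"}: disease and polyp are combined as
#'   the outcome, so the event is the earlier of the two ages and polypectomy
#'   no longer censors.
#' @param verified_only If TRUE, subjects whose disease report is
#'   self/relative-reported (not independently verified) are excluded before
#'   building records.
#' @return A data frame of class \code{"cohort_records"}, one row per
#'   retained subject: \code{subject_id}, \code{family_id}, \code{carrier},
#'   \code{gene}, \code{exit_age}, \code{attained_age} (age at last contact,
#'   the age by which disease status is known; used to stratify the
#'   ascertainment weights), \code{event}, \code{censor_reason},
#'   \code{bmi20}, \code{bmi5} (= bmi20/5, the unit in which hazard ratios are
#'   reported), \code{who_category}, \code{sex}, \code{country},
#'   \code{smoke20}, \code{alcohol20}, \code{crc_verified},
#'   \code{tumour_site}, \code{is_proband}. Attribute \code{exclusions} is a
#'   named count vector (\code{missing_bmi}, \code{unverified}).
#' @examples
#' cfg <- sim_config(n_families = 20, seed = 1)
#' build_cohort(simulate_families(cfg))
#' @export
build_cohort <- function(subjects, outcome_mode = c("crc", "neoplasia"),
                         verified_only = FALSE) {
  outcome_mode <- match.arg(outcome_mode)
  need <- c("subject_id", "family_id", "carrier", "sex",
            "height_m", "weight20_kg", "crc_age", "polypectomy_age",
            "other_cancer_age", "death_age", "last_contact_age")
  miss <- setdiff(need, names(subjects))
  if (length(miss))
    stop("subject table lacks required fields: ", paste(miss, collapse = ", "))
  x <- subjects
  if (!"gene" %in% names(x)) x$gene <- "none"

  n_unverified <- 0L
  if (verified_only) {
    drop <- !is.na(x$crc_age) & !is.na(x$crc_verified) &
      x$crc_verified != "verified"
    n_unverified <- sum(drop)
    x <- x[!drop, , drop = FALSE]
  }

  missing_bmi <- is.na(x$weight20_kg) | is.na(x$height_m)
  n_missing <- sum(missing_bmi)
  x <- x[!missing_bmi, , drop = FALSE]

  if (outcome_mode == "crc") {
    event_age <- x$crc_age
    cens <- cbind(polypectomy = x$polypectomy_age,
                  other_cancer = x$other_cancer_age,
                  death = x$death_age,
                  last_contact = x$last_contact_age)
  } else {
    event_age <- pmin(x$crc_age, x$polypectomy_age, na.rm = TRUE)
    event_age[is.na(x$crc_age) & is.na(x$polypectomy_age)] <- NA_real_
    cens <- cbind(other_cancer = x$other_cancer_age,
                  death = x$death_age,
                  last_contact = x$last_contact_age)
  }
  all_ages <- cbind(event = event_age, cens)
  no_age <- apply(all_ages, 1, function(r) all(is.na(r)))
  if (any(no_age))
    stop("subject(s) with no event or contact age: ",
         paste(utils::head(x$subject_id[no_age], 5), collapse = ", "))

  cens_min <- suppressWarnings(apply(cens, 1, min, na.rm = TRUE))
  cens_min[!is.finite(cens_min)] <- Inf
  # tie between event and censoring at the same age: the event wins
  is_event <- !is.na(event_age) & event_age <= cens_min
  exit_age <- ifelse(is_event, event_age, cens_min)
  reason <- rep("none", nrow(x))
  if (any(!is_event)) {
    ci <- apply(cens[!is_event, , drop = FALSE], 1, which.min)
    reason[!is_event] <- colnames(cens)[ci]
  }

  bmi <- compute_bmi(x$weight20_kg, x$height_m, x$subject_id)
  rec <- data.frame(
    subject_id = x$subject_id,
    family_id = x$family_id,
    carrier = x$carrier,
    gene = x$gene,
    exit_age = exit_age,
    attained_age = x$last_contact_age,
    event = as.integer(is_event),
    censor_reason = reason,
    bmi20 = bmi,
    bmi5 = bmi / 5,
    who_category = who_category(bmi),
    sex = x$sex,
    country = if ("country" %in% names(x)) x$country else "unknown",
    smoke20 = if ("smoke20" %in% names(x)) x$smoke20 else "never",
    alcohol20 = if ("alcohol20" %in% names(x)) x$alcohol20 else "never",
    crc_verified = if ("crc_verified" %in% names(x)) x$crc_verified
                   else NA_character_,
    tumour_site = if ("tumour_site" %in% names(x)) x$tumour_site
                  else NA_character_,
    is_proband = if ("is_proband" %in% names(x)) x$is_proband else FALSE,
    stringsAsFactors = FALSE
  )
  rownames(rec) <- NULL
  attr(rec, "exclusions") <- c(missing_bmi = n_missing,
                               unverified = n_unverified)
  attr(rec, "outcome_mode") <- outcome_mode
  class(rec) <- c("cohort_records", "data.frame")
  rec
}

#' Write cohort records and their exclusion log
#' @param records A \code{cohort_records} data frame.
#' @param path Output file (tab-delimited); the exclusion counts go to
#'   \code{<path>.exclusions.txt}.
#' @export
write_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  ex <- attr(records, "exclusions")
  writeLines(paste0(names(ex), "\t", ex), paste0(path, ".exclusions.txt"))
  invisible(path)
}
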