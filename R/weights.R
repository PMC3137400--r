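#' Per-age-stratum sampling weights for an ascertained cohort
#'
#' The weighted-cohort correction for phenotype-driven sampling: within each
#' 5-year age stratum, affected and unaffected subjects are reweighted so
#' that the weighted proportion of affected subjects equals the proportion
#' expected from external age-specific incidence rates. Subjects are
#' stratified by attained age (age at last contact, the age by which disease
#' status is known) by default: the external expectation
#' \eqn{p_k} is the population probability of being an observed case by the
#' stratum's upper bound ([expected_affected_proportion()] of the supplied
#' table), which is a statement about subjects of that attained age. With
#' \eqn{n_k} sampled subjects in stratum k and \eqn{d_k} of them affected,
#' the weights on non-degenerate strata are
#' \deqn{w^{aff}_k = p_k n_k / d_k, \qquad
#'       w^{unaff}_k = (1-p_k) n_k / (n_k - d_k),}
#' which satisfy \eqn{d_k w^{aff}_k + (n_k-d_k) w^{unaff}_k = n_k} (mean
#' weight one) and \eqn{d_k w^{aff}_k / n_k = p_k} (calibration).
#'
#' Degenerate strata: with no affected subjects (\eqn{d_k = 0}) all weights in
#' the stratum are set to 1 and the stratum is flagged; with no unaffected
#' subjects (\eqn{d_k = n_k}) the affected weight is set to 1 and flagged.
#' Optionally (\code{merge_degenerate = TRUE}) degenerate strata are merged
#' upward into the next-older stratum until non-degenerate. An external table
#' implying \eqn{p_k = 1} while unaffected subjects are present is an error.
#'
#' @param records \code{cohort_records} from [build_cohort()] (or any data
#'   frame with \code{event} and the chosen stratification age).
#' @param table [incidence_table()] of external age-specific rates for the
#'   group the records belong to (carrier rates for carriers; general
#'   population rates stand in for non-carriers, mutations being rare). For
#'   simulated cohorts the correctly specified table is
#'   [marginal_incidence_table()] of the generating configuration.
#' @param stratify_by Age used to place subjects into strata:
#'   \code{"attained_age"} (default; both affected and unaffected are grouped
#'   by the age at which their status was ascertained, so the calibration
#'   target is well defined) or \code{"exit_age"} (age at event or censoring,
#'   i.e. cases grouped by diagnosis age; provided for comparison, but the
#'   affected share among exits depends on the censoring processes and no
#'   incidence table alone calibrates it).
#' @param merge_degenerate Merge degenerate strata upward instead of flagging
#'   (default FALSE).
#' @return A list of class \code{"weight_table"}: \code{strata} (data frame
#'   with \code{age_lo}, \code{age_hi}, \code{n}, \code{d}, \code{p},
#'   \code{w_affected}, \code{w_unaffected}, \code{fallback}) and
#'   \code{weights}, the per-record weight vector aligned with \code{records}.
#' @examples
#' cfg <- sim_config(n_families = 60, seed = 3)
#' rec <- build_cohort(simulate_study_cohort(cfg))
#' carriers <- rec[rec$carrier == "carrier", ]
#' compute_weights(carriers, default_carrier_incidence())
#' @export
compute_weights <- function(records, table,
                            stratify_by = c("attained_age", "exit_age"),
                            merge_degenerate = FALSE) {
  stopifnot(inherits(table, "incidence_table"))
  stratify_by <- match.arg(stratify_by)
  if (!all(c(stratify_by, "event") %in% names(records)))
    stop("records must have ", stratify_by, " and event columns")
  K <- nrow(table)
  # stratum containing the classification age; final stratum open-ended
  k_rec <- findInterval(records[[stratify_by]], table$age_lo)
  k_rec <- pmin(pmax(k_rec, 1L), K)
  p <- expected_affected_proportion(table)

  n_k <- tabulate(k_rec, nbins = K)
  d_k <- tabulate(k_rec[records$event == 1], nbins = K)

  if (merge_degenerate) {
    # merge each degenerate occupied stratum into the next-older stratum
    grp <- seq_len(K)
    for (k in seq_len(K - 1)) {
      kk <- grp[k]
      nn <- sum(n_k[grp == kk]); dd <- sum(d_k[grp == kk])
      if (nn > 0 && (dd == 0 || dd == nn)) grp[grp == kk] <- grp[k + 1]
    }
    map <- grp
  } else {
    map <- seq_len(K)
  }
  groups <- sort(unique(map))
  w_aff <- w_un <- rep(NA_real_, K)
  fallback <- rep(FALSE, K)
  for (g in groups) {
    ks <- which(map == g)
    nn <- sum(n_k[ks]); dd <- sum(d_k[ks])
    pk <- p[max(ks)]   # expectation at the merged group's upper bound
    if (nn == 0) next
    if (pk >= 1 && dd < nn)
      stop("incidence table '", attr(table, "group"),
           "' implies affected proportion 1 in stratum ending at age ",
           table$age_hi[max(ks)], " but unaffected subjects are present")
    if (dd == 0) {
      w_aff[ks] <- 1; w_un[ks] <- 1; fallback[ks] <- TRUE
    } else if (dd == nn) {
      w_aff[ks] <- 1; w_un[ks] <- NA_real_; fallback[ks] <- TRUE
    } else {
      w_aff[ks] <- pk * nn / dd
      w_un[ks] <- (1 - pk) * nn / (nn - dd)
    }
  }

  w <- ifelse(records$event == 1, w_aff[k_rec], w_un[k_rec])
  strata <- data.frame(age_lo = table$age_lo, age_hi = table$age_hi,
                       n = n_k, d = d_k, p = p,
                       w_affected = w_aff, w_unaffected = w_un,
                       fallback = fallback)
  out <- list(strata = strata, weights = w, stratum = k_rec,
              group = attr(table, "group"),
              stratify_by = stratify_by,
              merged = merge_degenerate)
  class(out) <- "weight_table"
  out
}

#' @rdname compute_weights
#' @param population_table [incidence_table()] of general-population rates,
#'   used for non-carriers on the assumption that carrier rarity makes
#'   population rates an adequate stand-in for non-carrier rates.
#' @export
attach_noncarrier_weights <- function(records, population_table,
                                      stratify_by = c("attained_age",
                                                      "exit_age"),
                                      merge_degenerate = FALSE) {
  compute_weights(records, population_table, stratify_by = stratify_by,
                  merge_degenerate = merge_degenerate)
}

#' @export
print.weight_table <- function(x, ...) {
  occ <- x$strata[x$strata$n > 0, ]
  cat("Ascertainment weight table (", x$group, "), ",
      nrow(occ), " occupied strata, ", length(x$weights), " records\n",
      sep = "")
  print.data.frame(occ, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a weight table as delimited text for audit
#' @param x A \code{weight_table}.
#' @param path Output file.
#' @export
write_weight_table <- function(x, path) {
  utils::write.table(x$strata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
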