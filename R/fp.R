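#' Fractional-polynomial transformation of a positive exposure
#'
#' Builds the covariate columns of a fractional polynomial: one column
#' \eqn{x^p} per power (with \eqn{x^0 \equiv \log x}), a repeated power
#' contributing \eqn{x^p} and \eqn{x^p \log x}. The exposure is pre-scaled by
#' its sample geometric mean so that power selection is invariant to the
#' measurement unit.
#'
#' @param x Positive exposure values.
#' @param powers Numeric powers drawn from the conventional set
#'   \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}; length 1 or 2 (degree), repeats
#'   allowed.
#' @param scale Scaling origin; default the geometric mean of \code{x}.
#' @return Matrix with one column per term and attributes \code{powers},
#'   \code{scale}.
#' @examples
#' fp_transform(c(20, 25, 30), powers = c(2, 2))
#' @export
fp_transform <- function(x, powers, scale = exp(mean(log(x)))) {
  if (any(!is.na(x) & x <= 0)) stop("fractional polynomials need a positive exposure")
  if (length(powers) < 1 || length(powers) > 2)
    stop("degree must be 1 or 2")
  z <- x / scale
  one <- function(p) if (p == 0) log(z) else z^p
  if (length(powers) == 2 && powers[1] == powers[2]) {
    out <- cbind(one(powers[1]), one(powers[1]) * log(z))
  } else {
    out <- do.call(cbind, lapply(powers, one))
  }
  colnames(out) <- paste0("fp", seq_along(powers))
  attr(out, "powers") <- powers
  attr(out, "scale") <- scale
  out
}

#' The conventional fractional-polynomial power set
#' @export
fp_powers <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Compare the best fractional polynomial of the exposure against linearity
#'
#' Fits a weighted Cox model for every degree-1 (and optionally degree-2)
#' fractional-polynomial transform of the exposure, keeps the fit with the
#' highest weighted partial log-likelihood, and reports a Wald test of the
#' best transform's added terms against the straight-line model: the linear
#' model is augmented with the best FP's term(s) and the added coefficients
#' are jointly tested. Being a nested model comparison, the test uses the
#' model-based (inverse-information) variance by default -- the Wald analogue
#' of the deviance comparison; the clustered robust variance is available via
#' \code{variance = "robust"}. If the best-fitting transform is the linear
#' one itself, the comparison p-value is 1 by construction.
#'
#' @param records Data frame of analysis records.
#' @param exposure Name of the (positive) exposure column, default
#'   \code{"bmi20"}.
#' @param adjust Character vector of adjustment covariates (columns of
#'   \code{records}).
#' @param weights,cluster Passed to [wcoxph()].
#' @param degree 1 (default) or 2.
#' @param variance Variance for the comparison Wald test: \code{"model"}
#'   (default) or \code{"robust"}.
#' @param time,status Column names of exit age and event indicator.
#' @return List of class \code{"fp_comparison"}: \code{report} (one row per
#'   candidate: powers, log-likelihood), \code{best_powers},
#'   \code{best_fit}, \code{linear_fit}, and \code{wald} (\code{chisq},
#'   \code{df}, \code{p} for non-linearity).
#' @export
best_fp_vs_linear <- function(records, exposure = "bmi20",
                              adjust = character(0),
                              weights = NULL, cluster = NULL,
                              degree = 1,
                              variance = c("model", "robust"),
                              time = "exit_age", status = "event") {
  stopifnot(degree %in% c(1, 2))
  variance <- match.arg(variance)
  x <- records[[exposure]]
  if (is.null(x)) stop("no column '", exposure, "' in records")
  gm <- exp(mean(log(x)))

  pset <- fp_powers()
  cands <- lapply(pset, function(p) p)
  if (degree == 2) {
    for (i in seq_along(pset)) for (j in i:length(pset))
      cands <- c(cands, list(c(pset[i], pset[j])))
  }

  rhs_adj <- if (length(adjust)) paste(c("", adjust), collapse = " + ") else ""
  fit_with <- function(mat) {
    dat <- records
    for (k in seq_len(ncol(mat))) dat[[colnames(mat)[k]]] <- mat[, k]
    f <- stats::as.formula(paste0(
      "survival::Surv(", time, ", ", status, ") ~ ",
      paste(colnames(mat), collapse = " + "), rhs_adj))
    wcoxph(f, dat, weights = weights, cluster = cluster)
  }

  fits <- vector("list", length(cands))
  ll <- rep(NA_real_, length(cands))
  for (i in seq_along(cands)) {
    mat <- fp_transform(x, cands[[i]], scale = gm)
    fits[[i]] <- tryCatch(fit_with(mat), error = function(e) NULL)
    if (!is.null(fits[[i]])) ll[i] <- fits[[i]]$loglik[["fitted"]]
  }
  if (all(is.na(ll))) stop("no fractional-polynomial model could be fitted")
  best <- which.max(ll)
  best_powers <- cands[[best]]

  linear_idx <- which(vapply(cands, function(p)
    length(p) == 1 && p == 1, logical(1)))
  linear_fit <- fits[[linear_idx]]

  if (length(best_powers) == 1 && best_powers == 1) {
    wald <- list(chisq = 0, df = 1, p = 1)
    best_fit <- linear_fit
  } else {
    # augment the linear model with the best transform's terms and test them;
    # a plain power-1 column inside the best FP duplicates the linear term and
    # is not an "added" term, so it is dropped from the tested set
    bmat <- fp_transform(x, best_powers, scale = gm)
    if (length(best_powers) == 2 && any(best_powers == 1) &&
        !all(best_powers == 1)) {
      bmat <- bmat[, which(best_powers != 1), drop = FALSE]
    } else if (length(best_powers) == 2 && all(best_powers == 1)) {
      bmat <- bmat[, 2, drop = FALSE]    # keep only z * log z
    }
    colnames(bmat) <- paste0("fpbest", seq_len(ncol(bmat)))
    lmat <- fp_transform(x, 1, scale = gm)
    colnames(lmat) <- "fplin"
    aug <- fit_with(cbind(lmat, bmat))
    wald <- wald_test(aug, grep("^fpbest", names(aug$coefficients),
                                value = TRUE),
                      variance = variance)
    wald <- wald[c("chisq", "df", "p")]
    best_fit <- fits[[best]]
  }

  report <- data.frame(
    powers = vapply(cands, function(p) paste(p, collapse = ","), ""),
    loglik = ll)
  out <- list(report = report, best_powers = best_powers,
              best_fit = best_fit, linear_fit = linear_fit,
              wald = wald, scale = gm)
  class(out) <- "fp_comparison"
  out
}

#' @export
print.fp_comparison <- function(x, ...) {
  cat("Fractional-polynomial comparison (scale =", format(x$scale, digits = 4),
      ")\n")
  cat("  best powers: (", paste(x$best_powers, collapse = ", "), ")\n",
      sep = "")
  cat("  non-linearity Wald test: chisq =",
      format(x$wald$chisq, digits = 4), "df =", x$wald$df,
      "p =", format(x$wald$p, digits = 4), "\n")
  invisible(x)
}
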