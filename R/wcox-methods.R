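#' @export
print.wcoxph <- function(x, digits = max(3, getOption("digits") - 3), ...) {
  cat("Weighted Cox proportional-hazards fit (", x$ties, " ties)\n", sep = "")
  cat("  n = ", x$n, ", events = ", x$nevent,
      ", clusters = ", x$n_cluster, "\n", sep = "")
  s <- summary(x)
  print(round(s$coefficients, digits))
  cat("Weighted partial log-likelihood: ",
      format(x$loglik[["fitted"]], digits = digits + 2),
      " (null ", format(x$loglik[["null"]], digits = digits + 2),
      "), ", x$iter, " iterations\n", sep = "")
  invisible(x)
}

#' Summarise a weighted Cox fit
#'
#' Hazard ratios with robust 95% confidence intervals
#' \eqn{\exp(\hat\beta \pm 1.96\,SE_{robust})} and two-sided Wald p-values.
#'
#' @param object A [wcoxph()] fit.
#' @param conf.level Confidence level (default 0.95).
#' @param ... Unused.
#' @export
summary.wcoxph <- function(object, conf.level = 0.95, ...) {
  b <- object$coefficients
  se_r <- sqrt(diag(object$var))
  se_n <- sqrt(diag(object$naive.var))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  tab <- cbind(coef = b, `HR` = exp(b), `robust se` = se_r,
               `naive se` = se_n,
               lower = exp(b - z * se_r), upper = exp(b + z * se_r),
               z = b / se_r, p = 2 * stats::pnorm(-abs(b / se_r)))
  out <- list(coefficients = tab, n = object$n, nevent = object$nevent,
              n_cluster = object$n_cluster, loglik = object$loglik,
              conf.level = conf.level, call = object$call)
  class(out) <- "summary.wcoxph"
  out
}

#' @export
print.summary.wcoxph <- function(x, digits = 4, ...) {
  cat("n =", x$n, " events =", x$nevent, " clusters =", x$n_cluster, "\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.wcoxph <- function(object, ...) object$coefficients

#' @export
#' @param type \code{"robust"} (clustered sandwich, default) or
#'   \code{"naive"} (inverse information).
#' @rdname robust_vcov
vcov.wcoxph <- function(object, type = c("robust", "naive"), ...) {
  type <- match.arg(type)
  if (type == "robust") object$var else object$naive.var
}

#' @export
confint.wcoxph <- function(object, parm, level = 0.95, ...) {
  b <- object$coefficients
  se <- sqrt(diag(object$var))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(b - z * se, b + z * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2)),
                        "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
logLik.wcoxph <- function(object, ...) {
  structure(object$loglik[["fitted"]], df = length(object$coefficients),
            class = "logLik")
}

#' Residuals of a weighted Cox fit
#'
#' @param object A [wcoxph()] fit.
#' @param type \code{"score"} (weight-multiplied score residuals, n x p, the
#'   building block of the sandwich variance), \code{"schoenfeld"} (per-event
#'   covariate residuals \eqn{x_i - \bar x(t_i)}), \code{"scaled_schoenfeld"}
#'   (Schoenfeld residuals premultiplied by \eqn{d\,A^{-1}} and shifted by
#'   \eqn{\hat\beta}), or \code{"martingale"}.
#' @param ... Unused.
#' @return Residual matrix (rows in increasing-age order for
#'   \code{schoenfeld} types, original subject order otherwise); event ages
#'   attached as attribute \code{time} for the Schoenfeld types.
#' @export
residuals.wcoxph <- function(object,
                             type = c("score", "schoenfeld",
                                      "scaled_schoenfeld", "martingale"),
                             ...) {
  type <- match.arg(type)
  eng <- object$engine
  if (type == "score") {
    sc <- object$score_residuals
    out <- sc
    out[eng$ord, ] <- sc                 # back to input order
    return(out)
  }
  if (type == "martingale") {
    H0g <- cumsum(ifelse(eng$ev_g, eng$dw_g / eng$S0, 0))
    mres <- eng$d_s - exp(eng$eta) * H0g[eng$grp]
    out <- numeric(length(mres)); out[eng$ord] <- mres
    return(out)
  }
  ev_rows <- which(eng$d_s == 1)
  res <- eng$X_s[ev_rows, , drop = FALSE] - eng$m[eng$grp[ev_rows], , drop = FALSE]
  colnames(res) <- names(eng$beta)
  if (type == "scaled_schoenfeld") {
    d <- length(ev_rows)
    res <- d * res %*% object$naive.var +
      matrix(eng$beta, d, eng$p, byrow = TRUE)
    colnames(res) <- names(eng$beta)
  }
  attr(res, "time") <- eng$t_s[ev_rows]
  res
}

#' @export
predict.wcoxph <- function(object, newdata = NULL,
                           type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    lp <- numeric(object$n)
    lp[object$engine$ord] <- object$engine$eta
  } else {
    tt <- stats::delete.response(stats::terms(object$formula))
    mf <- stats::model.frame(tt, newdata)
    X <- stats::model.matrix(tt, mf)
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
    lp <- drop(X[, names(object$coefficients), drop = FALSE] %*%
                 object$coefficients)
  }
  if (type == "risk") exp(lp) else lp
}

#' Diagnostic plot of scaled Schoenfeld residuals against age
#'
#' One panel per covariate with a lowess trend; a flat trend supports
#' proportional hazards.
#'
#' @param x A [wcoxph()] fit.
#' @param terms Covariates to plot (default all).
#' @param ... Passed to [plot()].
#' @export
plot.wcoxph <- function(x, terms = names(x$coefficients), ...) {
  res <- residuals(x, type = "scaled_schoenfeld")
  tm <- attr(res, "time")
  old <- graphics::par(mfrow = c(1, length(terms)))
  on.exit(graphics::par(old))
  for (v in terms) {
    graphics::plot(tm, res[, v], xlab = "age at event",
                   ylab = paste("scaled Schoenfeld:", v), ...)
    graphics::lines(stats::lowess(tm, res[, v]), col = 2)
    graphics::abline(h = x$coefficients[v], lty = 2)
  }
  invisible(x)
}

#' Proportional-hazards test from scaled Schoenfeld residuals
#'
#' Tests, per covariate and globally, whether the scaled Schoenfeld residuals
#' trend with survival time (age). The statistic is the exact score test for
#' adding a term \eqn{x_j \cdot g(t)} to the fitted model, evaluated at the
#' fitted coefficients: with per-event-time covariance \eqn{V(t_i)} and
#' weighted Schoenfeld residual sums \eqn{s_i},
#' \deqn{T = U_\theta' \,\mathrm{Var}(U_\theta)^{-1}\, U_\theta, \quad
#'  U_\theta = \sum_i g_i s_i,}
#' \deqn{\mathrm{Var}(U_\theta) = \sum_i g_i^2 V(t_i)
#'   - \Big(\sum_i g_i V(t_i)\Big) A^{-1} \Big(\sum_i g_i V(t_i)\Big),}
#' which for unit weights coincides with the survival-time score test of
#' \code{survival::cox.zph}.
#'
#' @param fit A converged [wcoxph()] fit with at least 10 events.
#' @param transform Time transform \code{g}: \code{"identity"} (default; the
#'   residuals are examined against survival time itself), \code{"log"}, or
#'   \code{"rank"}.
#' @param global Also report the global (all covariates) test.
#' @return Data frame with one row per covariate (and optionally GLOBAL):
#'   \code{chisq}, \code{df}, \code{p}.
#' @export
schoenfeld_test <- function(fit, transform = c("identity", "log", "rank"),
                            global = TRUE) {
  stopifnot(inherits(fit, "wcoxph"))
  transform <- match.arg(transform)
  eng <- fit$engine
  if (fit$nevent < 10)
    stop("the proportional-hazards test needs at least 10 events (have ",
         fit$nevent, ")")
  if (fit$nevent < eng$p)
    stop("fewer events than covariates")
  gdx <- which(eng$ev_g)                    # event-time groups
  tg <- eng$t_s[eng$first][gdx]
  gt <- switch(transform,
               identity = tg,
               log = log(tg),
               rank = rank(tg))
  dw <- eng$dw_g[gdx]
  gt <- gt - sum(gt * dw) / sum(dw)         # centre (numerics only)

  p <- eng$p
  # per-group covariance V_g and residual sum s_g
  m <- eng$m[gdx, , drop = FALSE]
  s_g <- eng$swx_g[gdx, , drop = FALSE] - dw * m
  # rebuild V_g from the engine's final-state sums
  V_list <- wcox_event_covariances(eng, gdx)
  A11 <- matrix(0, p, p); A01 <- matrix(0, p, p); A00 <- matrix(0, p, p)
  for (i in seq_along(gdx)) {
    Vg <- dw[i] * V_list[[i]]
    A00 <- A00 + Vg
    A01 <- A01 + gt[i] * Vg
    A11 <- A11 + gt[i]^2 * Vg
  }
  Utheta <- colSums(gt * s_g)
  Vtheta <- A11 - A01 %*% solve(A00, A01)
  Vtheta <- (Vtheta + t(Vtheta)) / 2

  terms <- names(eng$beta)
  chisq <- df <- pval <- numeric(0)
  for (j in seq_len(p)) {
    chisq <- c(chisq, Utheta[j]^2 / Vtheta[j, j])
    df <- c(df, 1); pval <- c(pval, stats::pchisq(utils::tail(chisq, 1), 1,
                                                  lower.tail = FALSE))
  }
  out <- data.frame(term = terms, chisq = chisq, df = df, p = pval,
                    stringsAsFactors = FALSE)
  if (global && p >= 1) {
    cg <- drop(crossprod(Utheta, solve(Vtheta, Utheta)))
    out <- rbind(out, data.frame(term = "GLOBAL", chisq = cg, df = p,
                                 p = stats::pchisq(cg, p, lower.tail = FALSE)))
  }
  rownames(out) <- NULL
  out
}

# Per-event-time covariance matrices V(t_g) = S2/S0 - (S1/S0)(S1/S0)' at the
# fitted coefficients, for the requested tie groups.
wcox_event_covariances <- function(eng, gdx) {
  p <- eng$p
  r <- eng$r
  X_s <- eng$X_s
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  S2u <- X_s[, pairs[, 1], drop = FALSE] * X_s[, pairs[, 2], drop = FALSE] * r
  S2 <- revcumsum(S2u)[eng$first, , drop = FALSE]
  lapply(seq_along(gdx), function(i) {
    g <- gdx[i]
    V <- matrix(0, p, p)
    V[pairs] <- S2[g, ] / eng$S0[g]
    V[pairs[, 2:1, drop = FALSE]] <- V[pairs]
    V - tcrossprod(eng$m[g, ])
  })
}

#' Wald test of a set of coefficients
#'
#' Joint Wald chi-square test that the named coefficients are zero, using the
#' clustered robust variance (default) or the model-based variance.
#'
#' @param fit A [wcoxph()] fit.
#' @param terms Coefficient names (or a regular expression when
#'   \code{regex = TRUE}).
#' @param regex Interpret \code{terms} as a regular expression.
#' @param variance \code{"robust"} (default) or \code{"model"} (inverse
#'   information; the likelihood-scale choice for nested model comparisons).
#' @return List with \code{chisq}, \code{df}, \code{p}, \code{terms}.
#' @export
wald_test <- function(fit, terms, regex = FALSE,
                      variance = c("robust", "model")) {
  stopifnot(inherits(fit, "wcoxph"))
  variance <- match.arg(variance)
  nm <- names(fit$coefficients)
  sel <- if (regex) grep(terms, nm, value = TRUE) else terms
  if (!all(sel %in% nm))
    stop("unknown coefficient(s): ", paste(setdiff(sel, nm), collapse = ", "))
  if (length(sel) == 0) stop("no coefficients selected")
  b <- fit$coefficients[sel]
  V <- if (variance == "robust") fit$var[sel, sel, drop = FALSE]
       else fit$naive.var[sel, sel, drop = FALSE]
  stat <- drop(crossprod(b, solve(V, b)))
  list(chisq = stat, df = length(sel),
       p = stats::pchisq(stat, length(sel), lower.tail = FALSE),
       terms = sel)
}

#' Wald interaction test between two model terms
#'
#' Refits the model with the product term \code{a:b} added and Wald-tests the
#' interaction coefficients (robust variance). Both main effects must already
#' be in the model formula.
#'
#' @param formula Base model formula (with a [survival::Surv()] response).
#' @param data,weights,cluster,... Passed to [wcoxph()].
#' @param term Character pair \code{c(a, b)} naming the interacting
#'   variables; order is immaterial.
#' @return List with the interaction fit and \code{chisq}, \code{df},
#'   \code{p} for the product term(s).
#' @export
wald_interaction <- function(formula, data, term, weights = NULL,
                             cluster = NULL, ...) {
  stopifnot(length(term) == 2)
  vars <- all.vars(formula[[3]])
  if (!all(term %in% vars))
    stop("both interaction variables must appear as main effects: ",
         paste(setdiff(term, vars), collapse = ", "))
  term <- sort(term)
  f2 <- stats::update(formula,
                      paste("~ . +", term[1], ":", term[2]))
  fit <- wcoxph(f2, data, weights = weights, cluster = cluster, ...)
  base_fit <- wcoxph(formula, data, weights = weights, cluster = cluster, ...)
  base_cols <- names(base_fit$coefficients)
  int_cols <- setdiff(names(fit$coefficients), base_cols)
  wt <- wald_test(fit, int_cols)
  c(list(fit = fit), wt)
}
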