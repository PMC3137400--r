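#' Control parameters for the weighted Cox fitter
#'
#' @param eps Convergence threshold on the relative change in the weighted
#'   partial log-likelihood.
#' @param tol_beta Alternative convergence threshold on the largest absolute
#'   coefficient update.
#' @param max_iter Maximum Newton-Raphson iterations.
#' @param separation_limit Absolute coefficient size beyond which a monotone
#'   likelihood (complete separation) is declared.
#' @return List of class \code{"wcoxph_control"}.
#' @export
wcoxph_control <- function(eps = 1e-9, tol_beta = 1e-8, max_iter = 50,
                           separation_limit = 15) {
  stopifnot(eps > 0, tol_beta > 0, max_iter >= 1)
  structure(list(eps = eps, tol_beta = tol_beta, max_iter = max_iter,
                 separation_limit = separation_limit),
            class = "wcoxph_control")
}

revcumsum <- function(x) {
  if (is.matrix(x)) {
    x[] <- apply(x, 2, function(col) rev(cumsum(rev(col))))
    x
  } else rev(cumsum(rev(x)))
}

#' Weighted Cox proportional-hazards regression with clustered robust variance
#'
#' Maximises the weighted Cox partial likelihood
#' \deqn{\ell(\beta) = \sum_{i:\,event} w_i\Big[x_i'\beta -
#'   \log \sum_{j:\,t_j \ge t_i} w_j e^{x_j'\beta}\Big]}
#' (Breslow handling of ties; Efron available) by Newton-Raphson with
#' step-halving, with age as the time scale and entry at birth (no left
#' truncation). The weights are externally supplied sampling weights, e.g.
#' the per-age-stratum ascertainment weights of [compute_weights()]. The
#' variance reported by default is the Huber-White sandwich
#' \eqn{A^{-1} B A^{-1}}, where \eqn{A} is the observed information and
#' \eqn{B} sums, over clusters (families), outer products of the
#' weight-multiplied score residuals aggregated within cluster, so that any
#' correlation of risk between family members is absorbed.
#'
#' @param formula Model formula with a [survival::Surv()] response, e.g.
#'   \code{Surv(exit_age, event) ~ bmi5 + sex + country}.
#' @param data Data frame (typically \code{cohort_records}).
#' @param weights Sampling weights: a numeric vector, the name of a column of
#'   \code{data}, or a \code{weight_table} from [compute_weights()]. Default
#'   all 1.
#' @param cluster Cluster identifier for the robust variance: a one-sided
#'   formula (\code{~family_id}), a column name, or a vector. Default: the
#'   \code{family_id} column when present, else each subject its own cluster.
#' @param ties \code{"breslow"} (default; consistent under external weights)
#'   or \code{"efron"}.
#' @param control A [wcoxph_control()].
#' @param df_cluster_correction Multiply the sandwich by g/(g-1) (g =
#'   number of clusters). Default FALSE.
#' @param init Starting coefficients (default zero).
#' @return Object of class \code{"wcoxph"} with components
#'   \code{coefficients}, \code{var} (robust), \code{naive.var},
#'   \code{loglik} (null and fitted weighted partial log-likelihood),
#'   \code{score_residuals}, \code{schoenfeld} (per-event residuals and event
#'   ages), \code{iter}, \code{converged}, \code{n}, \code{nevent}, and the
#'   sorted model ingredients needed by the method functions.
#' @examples
#' cfg <- sim_config(n_families = 80, seed = 11)
#' rec <- build_cohort(simulate_study_cohort(cfg))
#' carriers <- rec[rec$carrier == "carrier", ]
#' wt <- compute_weights(carriers, default_carrier_incidence())
#' fit <- wcoxph(survival::Surv(exit_age, event) ~ bmi5 + sex, carriers,
#'               weights = wt, cluster = ~family_id)
#' summary(fit)
#' @export
wcoxph <- function(formula, data, weights = NULL, cluster = NULL,
                   ties = c("breslow", "efron"),
                   control = wcoxph_control(),
                   df_cluster_correction = FALSE,
                   init = NULL) {
  ties <- match.arg(ties)
  cl <- match.call()

  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv") || attr(y, "type") != "right")
    stop("the response must be a right-censored survival::Surv(time, status) object")
  time <- y[, 1]; status <- y[, 2]
  X <- stats::model.matrix(stats::terms(formula), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) == 0L) stop("the model must contain at least one covariate")
  n <- nrow(X)

  const <- apply(X, 2, function(v) max(v) - min(v) == 0)
  if (any(const))
    stop("covariate(s) constant across all subjects: ",
         paste(colnames(X)[const], collapse = ", "))
  if (length(unique(time[status == 1])) < 2)
    stop("at least 2 distinct event ages are required")

  # weights -------------------------------------------------------------
  if (is.null(weights)) {
    w <- rep(1, n)
  } else if (inherits(weights, "weight_table")) {
    if (length(weights$weights) != nrow(data))
      stop("weight_table does not match the data (", length(weights$weights),
           " weights vs ", nrow(data), " rows)")
    w <- weights$weights
  } else if (is.character(weights) && length(weights) == 1L) {
    w <- data[[weights]]
  } else {
    w <- weights
  }
  omit <- attr(mf, "na.action")     # rows dropped by na.omit
  used <- setdiff(seq_len(nrow(data)), as.integer(omit))
  if (length(w) == nrow(data) && nrow(data) != n) w <- w[used]
  if (length(w) != n) stop("weights length does not match the model rows")
  if (any(is.na(w) | w < 0)) stop("weights must be non-negative and non-missing")

  # cluster -------------------------------------------------------------
  if (is.null(cluster)) {
    clus <- if ("family_id" %in% names(data)) data$family_id else seq_len(nrow(data))
  } else if (inherits(cluster, "formula")) {
    clus <- data[[all.vars(cluster)[1]]]
  } else if (is.character(cluster) && length(cluster) == 1L &&
             cluster %in% names(data)) {
    clus <- data[[cluster]]
  } else {
    clus <- cluster
  }
  if (length(clus) == nrow(data) && nrow(data) != n) clus <- clus[used]
  if (length(clus) != n) stop("cluster length does not match the model rows")

  eng <- wcox_engine(time, status, X, w, ties = ties, control = control,
                     init = init)
  if (eng$separation)
    stop("monotone partial likelihood: coefficient(s) diverging (separation); ",
         "iteration trace: ", paste(signif(eng$ll_trace, 6), collapse = " -> "))
  if (!eng$converged)
    warning("Newton-Raphson did not converge in ", control$max_iter,
            " iterations; trace: ",
            paste(signif(eng$ll_trace, 6), collapse = " -> "))

  sc <- wcox_score_residuals(eng)
  Ainv <- eng$Ainv
  Uclus <- rowsum(sc, group = as.character(clus[eng$ord]))
  B <- crossprod(Uclus)
  robust <- Ainv %*% B %*% Ainv
  g <- nrow(Uclus)
  if (df_cluster_correction && g > 1) robust <- robust * g / (g - 1)
  robust <- (robust + t(robust)) / 2
  dimnames(robust) <- dimnames(Ainv)

  fit <- list(coefficients = eng$beta,
              var = robust,
              naive.var = Ainv,
              loglik = c(null = eng$ll0, fitted = eng$ll),
              score_residuals = sc,
              n = n, nevent = sum(status == 1),
              n_cluster = g,
              iter = eng$iter, converged = eng$converged,
              ties = ties,
              engine = eng,
              cluster = as.character(clus[eng$ord]),
              call = cl, formula = formula,
              control = control,
              df_cluster_correction = df_cluster_correction)
  class(fit) <- "wcoxph"
  fit
}

# Core Newton-Raphson maximiser of the weighted partial likelihood.
# Returns everything downstream methods need, in time-sorted order.
wcox_engine <- function(time, status, X, w, ties = "breslow",
                        control = wcoxph_control(), init = NULL) {
  n <- length(time); p <- ncol(X)
  ord <- order(time)
  t_s <- time[ord]; d_s <- status[ord]
  X_s <- X[ord, , drop = FALSE]; w_s <- w[ord]

  grp <- cumsum(!duplicated(t_s))           # tie group per row (sorted)
  first <- which(!duplicated(t_s))          # first row of each group
  G <- length(first)
  dw_g <- as.vector(rowsum(w_s * d_s, grp)) # weighted events per group
  nd_g <- as.vector(rowsum(d_s, grp))       # event count per group
  ev_g <- dw_g > 0
  swx_g <- rowsum((w_s * d_s) * X_s, grp)   # G x p weighted event covariates

  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)
  ll_trace <- numeric(0)
  ll_old <- -Inf; ll0 <- NA_real_
  converged <- FALSE; separation <- FALSE
  iter <- 0L
  quant <- NULL

  compute <- function(beta) {
    eta <- drop(X_s %*% beta)
    r <- w_s * exp(eta)
    S0 <- revcumsum(r)[first]
    S1 <- revcumsum(r * X_s)[first, , drop = FALSE]
    S2u <- matrix(0, n, p * (p + 1) / 2)
    idx <- 1L
    pairs <- matrix(0L, p * (p + 1) / 2, 2)
    for (a in seq_len(p)) for (b in a:p) {
      S2u[, idx] <- r * X_s[, a] * X_s[, b]
      pairs[idx, ] <- c(a, b)
      idx <- idx + 1L
    }
    S2 <- revcumsum(S2u)[first, , drop = FALSE]

    if (ties == "efron") {
      res <- efron_terms(r, eta, X_s, w_s, d_s, grp, first, S0, S1, S2,
                         pairs, dw_g, nd_g, swx_g)
      return(res)
    }
    m <- S1 / S0                                   # G x p
    ll <- sum((w_s * d_s) * eta) - sum(dw_g[ev_g] * log(S0[ev_g]))
    U <- colSums(swx_g[ev_g, , drop = FALSE]) -
      colSums(dw_g[ev_g] * m[ev_g, , drop = FALSE])
    Vflat <- S2 / S0                                # G x p(p+1)/2
    A <- matrix(0, p, p)
    wg <- dw_g[ev_g]
    A[pairs] <- colSums(wg * Vflat[ev_g, , drop = FALSE])
    A[pairs[, 2:1, drop = FALSE]] <- A[pairs]
    mm <- m[ev_g, , drop = FALSE]
    A <- A - crossprod(mm, wg * mm)
    list(ll = ll, U = U, A = A, m = m, S0 = S0, eta = eta, r = r)
  }

  q <- compute(beta)
  ll0 <- if (is.null(init) || all(beta == 0)) q$ll else compute(rep(0, p))$ll
  ll_old <- q$ll
  ll_trace <- c(ll_trace, ll_old)
  repeat {
    iter <- iter + 1L
    step <- tryCatch(solve(q$A, q$U), error = function(e)
      stop("singular information matrix in Newton-Raphson"))
    beta_new <- beta + step
    q_new <- compute(beta_new)
    halvings <- 0L
    while ((!is.finite(q_new$ll) || q_new$ll < ll_old) && halvings < 20L) {
      step <- step / 2
      beta_new <- beta + step
      q_new <- compute(beta_new)
      halvings <- halvings + 1L
    }
    ll_trace <- c(ll_trace, q_new$ll)
    done <- (abs(q_new$ll - ll_old) <=
               control$eps * (abs(ll_old) + control$eps)) ||
      max(abs(step)) < control$tol_beta
    beta <- beta_new; q <- q_new
    if (max(abs(beta)) > control$separation_limit) { separation <- TRUE; break }
    if (done) { converged <- TRUE; break }
    if (iter >= control$max_iter) break
    ll_old <- q$ll
  }

  Ainv <- solve(q$A)
  dimnames(Ainv) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  list(beta = beta, ll = q$ll, ll0 = ll0, U = q$U, A = q$A, Ainv = Ainv,
       iter = iter, converged = converged, separation = separation,
       ll_trace = ll_trace,
       ord = ord, t_s = t_s, d_s = d_s, X_s = X_s, w_s = w_s,
       grp = grp, first = first, dw_g = dw_g, nd_g = nd_g, swx_g = swx_g,
       ev_g = ev_g, m = q$m, S0 = q$S0, eta = q$eta, r = q$r,
       ties = ties, p = p)
}

# Efron tie handling: within a group of d tied events the l-th event (l =
# 0..d-1) sees the denominator S0 - (l/d) * S0d, with S0d, S1d, S2d summed
# over the tied events; weighted sums follow the same fractions applied to
# the event-weight total, as in standard implementations.
efron_terms <- function(r, eta, X_s, w_s, d_s, grp, first, S0, S1, S2,
                        pairs, dw_g, nd_g, swx_g) {
  p <- ncol(X_s)
  G <- length(first)
  ev_g <- dw_g > 0
  ll <- sum((w_s * d_s) * eta)
  U <- colSums(swx_g[ev_g, , drop = FALSE])
  A <- matrix(0, p, p)
  m_out <- matrix(0, G, p)
  for (g in which(ev_g)) {
    rows <- which(grp == g & d_s == 1)
    d <- length(rows)
    S0d <- sum(r[rows]); S1d <- colSums(r[rows] * X_s[rows, , drop = FALSE])
    S2d_flat <- colSums(matrix(r[rows] * X_s[rows, pairs[, 1], drop = FALSE] *
                                 X_s[rows, pairs[, 2], drop = FALSE],
                               nrow = d))
    wbar <- dw_g[g] / d
    macc <- rep(0, p)
    for (l in seq_len(d) - 1L) {
      S0l <- S0[g] - (l / d) * S0d
      S1l <- S1[g, ] - (l / d) * S1d
      S2l <- S2[g, ] - (l / d) * S2d_flat
      ml <- S1l / S0l
      ll <- ll - wbar * log(S0l)
      U <- U - wbar * ml
      Al <- matrix(0, p, p)
      Al[pairs] <- S2l / S0l
      Al[pairs[, 2:1, drop = FALSE]] <- Al[pairs]
      A <- A + wbar * (Al - tcrossprod(ml))
      macc <- macc + ml / d
    }
    m_out[g, ] <- macc
  }
  list(ll = ll, U = U, A = A, m = m_out, S0 = S0, eta = eta, r = r)
}

# Weight-multiplied score residuals (n x p, time-sorted order), whose
# within-cluster sums feed the sandwich B matrix. For subject j:
#   U_j = d_j w_j (x_j - m(t_j)) - w_j e^{eta_j} [x_j G1(t_j) - G2(t_j)]
# with G1(t) = sum_{event times <= t} dw/S0 and G2(t) the matching
# sum of dw * S1 / S0^2. (Breslow form; also used for Efron fits, where it
# is the standard approximation.)
wcox_score_residuals <- function(eng) {
  p <- eng$p
  G1g <- cumsum(ifelse(eng$ev_g, eng$dw_g / eng$S0, 0))
  G2g <- apply(ifelse(eng$ev_g, eng$dw_g / eng$S0, 0) * eng$m, 2, cumsum)
  if (p == 1L) G2g <- matrix(G2g, ncol = 1)
  gj <- eng$grp                       # group of each sorted row
  G1 <- G1g[gj]
  G2 <- G2g[gj, , drop = FALSE]
  mj <- eng$m[gj, , drop = FALSE]
  r_exp <- eng$w_s * exp(eng$eta)
  sc <- (eng$d_s * eng$w_s) * (eng$X_s - mj) - r_exp * (eng$X_s * G1 - G2)
  colnames(sc) <- names(eng$beta)
  sc
}

#' Recompute the clustered sandwich variance of a fitted model
#'
#' The sandwich \eqn{A^{-1} B A^{-1}} with the weight-multiplied score
#' residuals summed within cluster before the outer product. With one subject
#' per cluster and unit weights this is the standard (unclustered) robust
#' variance.
#'
#' @param fit A [wcoxph()] fit.
#' @param cluster Optional replacement cluster vector (original subject
#'   order).
#' @param df_cluster_correction Apply the g/(g-1) small-sample factor.
#' @return Robust covariance matrix.
#' @export
robust_vcov <- function(fit, cluster = NULL, df_cluster_correction = FALSE) {
  stopifnot(inherits(fit, "wcoxph"))
  clus <- if (is.null(cluster)) fit$cluster else as.character(cluster[fit$engine$ord])
  Uclus <- rowsum(fit$score_residuals, group = clus)
  B <- crossprod(Uclus)
  V <- fit$naive.var %*% B %*% fit$naive.var
  g <- nrow(Uclus)
  if (df_cluster_correction && g > 1) V <- V * g / (g - 1)
  V <- (V + t(V)) / 2
  dimnames(V) <- dimnames(fit$naive.var)
  V
}
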