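# Independent oracles used across the suite.

# Brute-force weighted partial log-likelihood (Breslow ties): direct double
# loop over events and risk sets, no shared code with the package engine.
oracle_pl <- function(beta, time, status, x, w = rep(1, length(time))) {
  ll <- 0
  for (i in which(status == 1)) {
    rs <- which(time >= time[i])
    ll <- ll + w[i] * (x[i] * beta - log(sum(w[rs] * exp(x[rs] * beta))))
  }
  ll
}

# Golden-section maximisation on a bracket found by grid search.
golden_max <- function(f, lo, hi, tol = 1e-9) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d_)
  while (abs(b - a) > tol) {
    if (fc > fd) { b <- d_; d_ <- c_; fd <- fc
                   c_ <- b - gr * (b - a); fc <- f(c_) }
    else         { a <- c_; c_ <- d_; fc <- fd
                   d_ <- a + gr * (b - a); fd <- f(d_) }
  }
  (a + b) / 2
}

# argmax of the brute-force weighted partial likelihood over beta
oracle_beta <- function(time, status, x, w = rep(1, length(time))) {
  grid <- seq(-6, 6, by = 0.05)
  vals <- vapply(grid, oracle_pl, numeric(1),
                 time = time, status = status, x = x, w = w)
  b0 <- grid[which.max(vals)]
  golden_max(function(b) oracle_pl(b, time, status, x, w),
             b0 - 0.1, b0 + 0.1, tol = 1e-10)
}

# small random survival fixture with a single binary-or-continuous covariate
rand_fixture <- function(seed, n = 30, weighted = TRUE) {
  set.seed(seed)
  x <- if (seed %% 2 == 0) rbinom(n, 1, 0.5) else rnorm(n)
  time <- round(rexp(n, 0.1) + 0.5, 3)
  status <- rbinom(n, 1, 0.6)
  if (sum(status) < 3) status[sample.int(n, 3)] <- 1
  w <- if (weighted) round(runif(n, 0.2, 3), 3) else rep(1, n)
  fam <- paste0("f", sample.int(max(2, n %/% 3), n, replace = TRUE))
  data.frame(time = time, status = status, x = x, w = w, family_id = fam)
}

# default generating configuration used in replicated simulation tests
null_sim_config <- function(seed, n_families = 150) {
  sim_config(n_families = n_families, beta_bmi5 = 0,
             beta_covariates = c(sex = 0, smoke20 = 0, alcohol20 = 0),
             clinic_min_affected = 0, relative_recruit_prob = 1,
             seed = seed)
}
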