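#' Construct an age-specific incidence table
#'
#' An incidence table holds a piecewise-constant age-specific hazard: ordered,
#' contiguous age strata \code{(age_lo, age_hi]} with an event rate per
#' person-year in each. Tables serve two roles: they parameterise the
#' piecewise-exponential event-time draw in [simulate_families()], and they
#' supply the external population expectation against which ascertainment
#' weights are calibrated in [compute_weights()].
#'
#' @param age_lo,age_hi Numeric vectors of stratum bounds in years. Strata must
#'   be contiguous from 0 and non-overlapping. The last stratum is treated as
#'   open-ended when assigning subjects, but its stated width is used when
#'   accumulating cumulative hazard.
#' @param rate Events per person-year within each stratum; non-negative.
#' @param group Label for the population the rates describe (e.g. "carrier",
#'   "population").
#' @return An object of class \code{"incidence_table"}: a data frame with
#'   columns \code{age_lo}, \code{age_hi}, \code{rate} and a \code{group}
#'   attribute.
#' @examples
#' incidence_table(c(0, 40), c(40, 70), c(0, 0.01), group = "carrier")
#' @export
incidence_table <- function(age_lo, age_hi, rate, group = "population") {
  if (length(age_lo) != length(age_hi) || length(age_lo) != length(rate))
    stop("age_lo, age_hi and rate must have equal length")
  if (length(age_lo) == 0L) stop("incidence table must have at least one stratum")
  o <- order(age_lo)
  age_lo <- age_lo[o]; age_hi <- age_hi[o]; rate <- rate[o]
  if (age_lo[1] != 0)
    stop("strata must start at age 0")
  if (any(age_hi <= age_lo))
    stop("each stratum must have age_hi > age_lo")
  if (length(age_lo) > 1 && any(abs(age_lo[-1] - age_hi[-length(age_hi)]) > 1e-8))
    stop("strata must be contiguous (age_lo[k+1] == age_hi[k])")
  if (any(rate < 0) || any(!is.finite(rate)))
    stop("rates must be finite and >= 0")
  tab <- data.frame(age_lo = age_lo, age_hi = age_hi, rate = rate)
  attr(tab, "group") <- group
  class(tab) <- c("incidence_table", "data.frame")
  tab
}

#' Read an incidence table from delimited text
#'
#' Expects columns \code{age_lo}, \code{age_hi}, \code{rate} (any additional
#' columns are ignored). Both comma- and tab-delimited files are accepted.
#'
#' @param path File path.
#' @param group Group label to attach.
#' @return An [incidence_table()].
#' @export
read_incidence_table <- function(path, group = "population") {
  x <- utils::read.delim(path, sep = "", header = TRUE,
                         stringsAsFactors = FALSE)
  if (ncol(x) == 1L)  # maybe comma-delimited
    x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_lo", "age_hi", "rate")
  if (!all(need %in% names(x)))
    stop("incidence file must have columns age_lo, age_hi, rate: ", path)
  incidence_table(x$age_lo, x$age_hi, x$rate, group = group)
}

#' @export
print.incidence_table <- function(x, ...) {
  cat("Age-specific incidence table (", attr(x, "group"), "), ",
      nrow(x), " strata, ages ", x$age_lo[1], "-", x$age_hi[nrow(x)],
      "\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Cumulative hazard of a piecewise-constant incidence table
#'
#' @param table An [incidence_table()].
#' @param age Ages (years) at which to evaluate; the rate of the final stratum
#'   is extrapolated beyond its upper bound.
#' @return Cumulative hazard at each age.
#' @export
cumulative_hazard <- function(table, age) {
  stopifnot(inherits(table, "incidence_table"))
  width <- table$age_hi - table$age_lo
  cumH <- c(0, cumsum(table$rate * width))      # at stratum lower bounds
  k <- findInterval(age, c(table$age_lo, Inf), rightmost.closed = FALSE)
  k <- pmin(pmax(k, 1L), nrow(table))
  cumH[k] + table$rate[k] * pmax(age - table$age_lo[k], 0)
}

#' Expected affected proportion by the end of an age stratum
#'
#' The population probability of being affected by the upper bound of stratum
#' \code{k}: the cumulative incidence \eqn{p_k = 1 - \exp(-\sum_{j \le k}
#' \lambda_j \Delta_j)} implied by the piecewise-constant rates, ignoring
#' competing risks. This is the calibration target for the per-stratum
#' sampling weights.
#'
#' @param table An [incidence_table()].
#' @param k Stratum index (1-based); defaults to all strata.
#' @return Probability vector, one per requested stratum.
#' @examples
#' tab <- incidence_table(c(0, 5), c(5, 10), c(0.01, 0.02))
#' expected_affected_proportion(tab)  # 1-exp(-0.05), 1-exp(-0.15)
#' @export
expected_affected_proportion <- function(table, k = seq_len(nrow(table))) {
  stopifnot(inherits(table, "incidence_table"))
  if (any(k < 1L | k > nrow(table)))
    stop("stratum index outside table (1..", nrow(table), ")")
  width <- table$age_hi - table$age_lo
  cumH <- cumsum(table$rate * width)
  1 - exp(-cumH[k])
}

#' Draw event ages from a piecewise-exponential hazard
#'
#' Inversion sampling: with subject-specific multiplicative relative risk
#' \code{rr}, the event age solves \eqn{rr \cdot \Lambda(t) = E}, \eqn{E \sim
#' Exp(1)}. Subjects whose total hazard is exhausted without an event get
#' \code{NA} (the final stratum's rate is extrapolated indefinitely unless it
#' is zero).
#'
#' @param table An [incidence_table()].
#' @param rr Vector of relative risks (one draw per element).
#' @return Event ages (years), \code{NA} where no event occurs.
#' @keywords internal
rpwexp <- function(table, rr) {
  n <- length(rr)
  width <- table$age_hi - table$age_lo
  cumH <- c(0, cumsum(table$rate * width))   # at bounds 0, hi_1, ..., hi_K
  e <- stats::rexp(n) / rr                   # target baseline cumulative hazard
  K <- nrow(table)
  # stratum in which e falls
  k <- findInterval(e, cumH, rightmost.closed = FALSE)   # in 1..K+1
  t <- rep(NA_real_, n)
  inside <- k <= K
  ki <- k[inside]
  t[inside] <- table$age_lo[ki] + (e[inside] - cumH[ki]) / table$rate[ki]
  # beyond the table: extrapolate final stratum's rate if positive
  beyond <- !inside
  if (any(beyond) && table$rate[K] > 0) {
    t[beyond] <- table$age_hi[K] + (e[beyond] - cumH[K + 1]) / table$rate[K]
  }
  t
}

#' Default age-specific incidence tables for simulation
#'
#' Illustrative 5-year tables in the shape used throughout: a high-risk carrier
#' table with cumulative incidence to age 70 of roughly 40% (the reported range
#' for mismatch-repair mutation carriers is 40-70%), and a general-population
#' table with lifetime cumulative incidence of a few percent. Real analyses
#' supply their own external rate tables; these defaults exist so the simulator
#' and examples run out of the box.
#'
#' @return An [incidence_table()].
#' @export
default_carrier_incidence <- function() {
  lo <- seq(0, 85, by = 5)
  hi <- lo + 5
  rate <- c(0, 0, 0, 0, 0.001, 0.002, 0.005, 0.008, 0.012, 0.015,
            0.018, 0.020, 0.020, 0.020, 0.018, 0.015, 0.012, 0.010)
  incidence_table(lo, hi, rate, group = "carrier")
}

#' @rdname default_carrier_incidence
#' @export
default_population_incidence <- function() {
  lo <- seq(0, 85, by = 5)
  hi <- lo + 5
  rate <- c(0, 0, 0, 0, 1e-5, 2e-5, 5e-5, 1e-4, 2e-4, 4e-4,
            7e-4, 1e-3, 1.3e-3, 1.6e-3, 1.9e-3, 2.2e-3, 2.4e-3, 2.5e-3)
  incidence_table(lo, hi, rate, group = "population")
}
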