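#' Zero-inflated log-normal duration distributions
#'
#' Stage durations in the simulator are modelled as log-normal, optionally
#' with a point mass at exactly zero minutes.  Only median and interquartile
#' range are published for each care stage, so the family is pinned down by
#' quantile matching: `mu` anchors the median, `sigma` comes from the IQR
#' ratio, and a zero mass absorbs stages whose printed median or lower
#' quartile is 0.
#'
#' @param mu location on the log-minute scale.
#' @param sigma scale on the log-minute scale, `>= 0`.
#' @param zero_mass probability in `[0, 1]` of an exact zero duration
#'   (`zero_mass = 1` encodes a degenerate point mass at zero).
#' @return An object of class `lognormal_params`.
#' @seealso [fit_lognormal_from_quantiles()], [fit_zero_inflated()],
#'   [fit_latency_model()]
#' @export
lognormal_params <- function(mu, sigma, zero_mass = 0) {
  stopifnot(is.numeric(mu), length(mu) == 1L,
            is.numeric(sigma), length(sigma) == 1L,
            is.numeric(zero_mass), length(zero_mass) == 1L)
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (zero_mass < 0 || zero_mass > 1) stop("'zero_mass' must be in [0, 1]")
  structure(list(mu = mu, sigma = sigma, zero_mass = zero_mass),
            class = "lognormal_params")
}

#' @export
print.lognormal_params <- function(x, ...) {
  cat(sprintf("zero-inflated log-normal: mu = %.4f, sigma = %.4f, zero_mass = %.3f\n",
              x$mu, x$sigma, x$zero_mass))
  cat(sprintf("  median = %.2f min, IQR = [%.2f, %.2f] min\n",
              qdur(0.5, x), qdur(0.25, x), qdur(0.75, x)))
  invisible(x)
}

#' Quantile function of a zero-inflated log-normal
#'
#' `Q(p) = 0` for `p <= zero_mass`, otherwise the log-normal quantile of the
#' rescaled probability `(p - zero_mass) / (1 - zero_mass)`.  Monotone
#' nondecreasing in `p`.
#'
#' @param p probabilities in `[0, 1]`.
#' @param params a [lognormal_params()] object.
#' @return Durations in minutes.
#' @export
qdur <- function(p, params) {
  stopifnot(inherits(params, "lognormal_params"), all(p >= 0 & p <= 1))
  if (params$zero_mass >= 1) return(rep(0, length(p)))
  out <- numeric(length(p))
  pos <- p > params$zero_mass
  out[pos] <- stats::qlnorm((p[pos] - params$zero_mass) / (1 - params$zero_mass),
                            meanlog = params$mu, sdlog = params$sigma)
  out
}

#' Distribution function of a zero-inflated log-normal
#'
#' @param q durations in minutes.
#' @inheritParams qdur
#' @return `P(X <= q)`.
#' @export
pdur <- function(q, params) {
  stopifnot(inherits(params, "lognormal_params"))
  if (params$zero_mass >= 1) return(as.numeric(q >= 0))
  params$zero_mass + (1 - params$zero_mass) *
    stats::plnorm(pmax(q, 0), meanlog = params$mu, sdlog = params$sigma) *
    (q >= 0)
}

#' Sample durations from a zero-inflated log-normal
#'
#' Draws use the session RNG; seed with [set.seed()] for reproducibility.
#'
#' @param n number of draws.
#' @inheritParams qdur
#' @return `n` nonnegative durations in minutes.
#' @export
rdur <- function(n, params) {
  stopifnot(inherits(params, "lognormal_params"))
  if (params$zero_mass >= 1) return(rep(0, n))
  x <- stats::rlnorm(n, meanlog = params$mu, sdlog = params$sigma)
  if (params$zero_mass > 0) {
    x[stats::runif(n) < params$zero_mass] <- 0
  }
  x
}

#' Fit a log-normal from a printed median and IQR
#'
#' Quantile-matching fit: `mu = log(median)` so the analytic median is
#' reproduced exactly, and `sigma = log(q3 / q1) / (2 * qnorm(0.75))` so the
#' fitted IQR ratio matches the printed one.  Any asymmetry of the printed
#' IQR around the median on the log scale is absorbed by the median
#' anchoring.
#'
#' @param median,q1,q3 printed median and quartiles in minutes, with
#'   `0 < q1 <= median <= q3`.
#' @return A [lognormal_params()] object with `zero_mass = 0`.
#' @examples
#' fit_lognormal_from_quantiles(167, 108, 254)
#' @export
fit_lognormal_from_quantiles <- function(median, q1, q3) {
  if (!is.finite(median) || !is.finite(q1) || !is.finite(q3))
    stop("quantiles must be finite")
  if (q1 <= 0 || median <= 0 || q3 <= 0)
    stop("quantiles must be strictly positive; use fit_zero_inflated() for zero-median stages")
  if (!(q1 <= median && median <= q3))
    stop("quantiles must satisfy q1 <= median <= q3")
  sigma <- log(q3 / q1) / (2 * stats::qnorm(0.75))
  lognormal_params(mu = log(median), sigma = sigma, zero_mass = 0)
}

#' Fit a zero-inflated log-normal from quantiles with zeros
#'
#' Handles stages whose printed median and/or lower quartile is 0 minutes
#' (durations are nonnegative, so at least that much probability sits exactly
#' at zero).  Cases:
#' \itemize{
#'   \item `q3 = 0`: degenerate point mass at zero (`zero_mass = 1`).
#'   \item `median = 0`: `zero_mass = 0.5`; the continuous log-normal part is
#'     anchored so its own median equals `q3`, which places the mixture 75th
#'     percentile at `q3` exactly.  Its `sigma` is not identified by a single
#'     quantile and defaults to 1 (a typical log-IQR spread for care stages).
#'   \item `median > 0, q1 = 0`: `zero_mass = 0.25`; the continuous part is
#'     solved in closed form so the mixture median and 75th percentile equal
#'     the printed `median` and `q3`.
#' }
#'
#' @param median,q1,q3 printed quantiles in minutes with `median = 0` or
#'   `q1 = 0`, `q3 >= median`.
#' @param sigma0 log-scale spread used when only one positive quantile is
#'   available (the `median = 0` case).
#' @return A [lognormal_params()] object.
#' @examples
#' fit_zero_inflated(0, 0, 97)   # "0 [0-97]" care stage
#' @export
fit_zero_inflated <- function(median, q1, q3, sigma0 = 1) {
  if (median < 0 || q1 < 0 || q3 < 0) stop("quantiles must be nonnegative")
  if (q1 > median || q3 < median)
    stop("quantiles must satisfy q1 <= median <= q3")
  if (median > 0 && q1 > 0)
    stop("no zero quantile; use fit_lognormal_from_quantiles()")
  if (q3 == 0) return(lognormal_params(mu = 0, sigma = 0, zero_mass = 1))
  if (median == 0) {
    # mixture Q(0.75) = continuous Q(0.5) when zero_mass = 0.5
    return(lognormal_params(mu = log(q3), sigma = sigma0, zero_mass = 0.5))
  }
  # median > 0, q1 = 0: put exactly a quartile of mass at zero, then the
  # mixture median/p75 hit the continuous part at p = 1/3 and 2/3
  z <- stats::qnorm(2 / 3)
  sigma <- log(q3 / median) / (2 * z)
  mu <- log(median) + z * sigma  # = (log(median) + log(q3)) / 2
  lognormal_params(mu = mu, sigma = sigma, zero_mass = 0.25)
}

#' Fit the dashboard-to-prioritizer transfer-latency distribution
#'
#' Record transfer latencies are published only as two exceedance
#' probabilities (the share of transfers completed within 5 and within 10
#' minutes).  A log-normal is solved from the two quantile constraints:
#' `sigma = log(10/5) / (qnorm(p10) - qnorm(p5))`,
#' `mu = log(5) - qnorm(p5) * sigma`, so that `F(5) = p_within_5` and
#' `F(10) = p_within_10` hold analytically.
#'
#' @param p_within_5,p_within_10 probabilities with
#'   `0 < p_within_5 < p_within_10 < 1`.
#' @return A [lognormal_params()] object with `zero_mass = 0`.
#' @examples
#' fit_latency_model(0.83, 0.94)
#' @export
fit_latency_model <- function(p_within_5, p_within_10) {
  if (!(p_within_5 > 0 && p_within_10 < 1))
    stop("probabilities must lie strictly inside (0, 1)")
  if (p_within_5 >= p_within_10)
    stop("'p_within_5' must be strictly smaller than 'p_within_10'")
  z5 <- stats::qnorm(p_within_5)
  z10 <- stats::qnorm(p_within_10)
  sigma <- (log(10) - log(5)) / (z10 - z5)
  mu <- log(5) - z5 * sigma
  lognormal_params(mu = mu, sigma = sigma, zero_mass = 0)
}
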