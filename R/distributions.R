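# Shared probability machinery: beta-binomial pmf/tails, log-sum-exp,
# exact binomial tails in log space, Clopper-Pearson intervals.

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Beta-binomial log density
#'
#' Parameterized by mean `mu` and overdispersion `rho` in `[0, 1)`;
#' `rho = 0` reduces exactly to the binomial.
#'
#' @param x,size Counts and trials.
#' @param mu Mean success probability.
#' @param rho Overdispersion.
#' @export
dbetabinom_log <- function(x, size, mu, rho = 0) {
  if (rho <= 0) return(stats::dbinom(x, size, mu, log = TRUE))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
}

#' Upper tail P(X >= v) of the beta-binomial, in log space
#'
#' Direct summation of the pmf for moderate `d`; for very deep counts the
#' summation is truncated once terms fall 40 nats below the running total
#' (documented stable log-space accumulation).
#'
#' @param v Observed count.  @param d Trials.
#' @param mu Mean.  @param rho Overdispersion (0 = binomial).
#' @param log.p Return log p-value.
#' @export
pbetabinom_upper <- function(v, d, mu, rho = 0, log.p = FALSE) {
  if (d < 0 || v < 0 || v > d) stop("need 0 <= v <= d")
  if (v == 0) return(if (log.p) 0 else 1)
  if (rho <= 0) {
    lp <- stats::pbinom(v - 1, d, mu, lower.tail = FALSE, log.p = TRUE)
    return(if (log.p) lp else exp(lp))
  }
  ks <- v:d
  if (length(ks) <= 200000L) {
    lp <- logsumexp(dbetabinom_log(ks, d, mu, rho))
  } else {
    lp <- -Inf
    for (start in seq(v, d, by = 200000L)) {
      kk <- start:min(start + 199999L, d)
      chunk <- logsumexp(dbetabinom_log(kk, d, mu, rho))
      lp <- logsumexp(c(lp, chunk))
      if (chunk < lp - 40) break
    }
  }
  lp <- min(lp, 0)
  if (log.p) lp else exp(lp)
}

#' Exact Clopper-Pearson interval for a binomial proportion
#' @param v,d Successes and trials.
#' @param conf Confidence level.
#' @return Numeric `c(lower, upper)`.
#' @export
clopper_pearson <- function(v, d, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (v == 0) 0 else stats::qbeta(a, v, d - v + 1)
  hi <- if (v == d) 1 else stats::qbeta(1 - a, v + 1, d - v)
  c(lower = lo, upper = hi)
}
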