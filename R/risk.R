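## Poisson machinery linking the per-comparison false-positive rate alpha,
## the comparison count T, the expected false-positive count mu, and the
## operational upper bound U at confidence beta.

#' Number of pairwise comparisons in a database search
#'
#' A stain-to-database search of a database of \eqn{N} profiles performs
#' \eqn{T = N} comparisons; a database-to-database search (every profile
#' against every other) performs \eqn{T = N(N-1)/2}.
#'
#' @param n_profiles database size (\eqn{\ge 1}; \eqn{\ge 2} for
#'   database-to-database mode).
#' @param mode \code{"stain"} or \code{"db"}.
#' @return integer-valued comparison count \eqn{T}.
#' @export
comparisons_count <- function(n_profiles, mode = c("stain", "db")) {
  mode <- match.arg(mode)
  if (n_profiles < 1) stop("n_profiles must be at least 1")
  t <- switch(mode,
              stain = n_profiles,
              db = n_profiles * (n_profiles - 1) / 2)
  if (t < 1) stop("search performs no comparisons (database too small)")
  t
}

#' Poisson cumulative distribution function
#'
#' Probability that a Poisson(\eqn{\mu}) count is at most \eqn{U}.  Thin
#' wrapper over \code{stats::ppois}, which evaluates the regularized
#' incomplete gamma function and is stable for \eqn{\mu} well beyond
#' \eqn{10^4} (naive term-by-term summation is not).
#'
#' @param U nonnegative integer.
#' @param mu nonnegative Poisson mean.
#' @return cumulative probability.
#' @export
poisson_cdf <- function(U, mu) {
  stopifnot(U >= 0, mu >= 0)
  stats::ppois(U, mu)
}

#' Smallest upper bound on the false-positive count at a confidence level
#'
#' The smallest integer \eqn{U} such that a Poisson(\eqn{\mu}) count stays
#' at or below \eqn{U} with probability at least \eqn{\beta}, e.g. with
#' \eqn{\mu = 10} the count is 15 or lower in 95\% of searches and 18 or
#' lower in 99\%.
#'
#' @param mu expected number of false positives, \eqn{\ge 0}.
#' @param beta confidence level in (0, 1).
#' @return integer \eqn{U_\beta}.
#' @export
upper_bound <- function(mu, beta) {
  stopifnot(mu >= 0, beta > 0, beta < 1)
  stats::qpois(beta, mu)
}

#' Expected false positives consistent with an upper bound
#'
#' Inverts \eqn{\beta = F(U; \mu)}: the Poisson mean at which the count
#' stays at or below \eqn{U} with probability exactly \eqn{\beta}.  The
#' CDF is continuous and strictly decreasing in \eqn{\mu}, so the root is
#' found by bisection (via \code{stats::uniroot}) on a generous bracket,
#' to absolute tolerance 1e-10.
#'
#' @param U nonnegative integer upper bound.
#' @param beta confidence level in (0, 1).
#' @return the Poisson mean \eqn{\mu = F^{-1}(U, \beta)}.
#' @export
mu_from_upper_bound <- function(U, beta) {
  stopifnot(U >= 0, beta > 0, beta < 1)
  upper <- U + 20 * sqrt(U + 1) + 20
  stats::uniroot(function(mu) stats::ppois(U, mu) - beta,
                 interval = c(0, upper), tol = 1e-10)$root
}

#' Per-comparison false-positive rate from the risk budget
#'
#' \eqn{\alpha = \mu / T}: the expected false-positive count spread evenly
#' over the \eqn{T} pairwise comparisons of the search.
#'
#' @param mu expected number of false positives.
#' @param T number of pairwise comparisons, \eqn{\ge 1}.
#' @return per-comparison rate \eqn{\alpha}.
#' @export
per_comparison_alpha <- function(mu, T) {
  stopifnot(mu >= 0)
  if (T < 1) stop("T must be at least 1")
  mu / T
}

#' Probability of at least one false positive
#'
#' \eqn{P(X \ge 1) = 1 - e^{-\mu}} for a Poisson(\eqn{\mu}) count; used to
#' express the risk of any adventitious match in a single search.
#'
#' @param mu expected number of false positives.
#' @return probability in [0, 1).
#' @export
prob_at_least_one <- function(mu) {
  stopifnot(mu >= 0)
  -expm1(-mu)
}

#' Risk specification for a database search
#'
#' Resolves a laboratory's risk budget into the per-comparison
#' false-positive rate \eqn{\alpha} that the dynamic threshold enforces.
#' The budget is given either directly as the expected false-positive
#' count \eqn{\mu}, or as an upper bound \eqn{U} on the count to be
#' respected with probability \eqn{\beta} (in which case
#' \eqn{\mu = F^{-1}(U, \beta)} by Poisson inversion).
#'
#' @param n_profiles database size.
#' @param mode \code{"stain"} (stain-to-database) or \code{"db"}
#'   (database-to-database).
#' @param mu expected false positives; supply either this or \code{U} and
#'   \code{beta}.
#' @param U,beta upper bound on the false-positive count and the
#'   confidence with which it must hold.
#' @param T override for the comparison count (e.g. to budget a whole
#'   batch of stain searches as one risk unit); defaults to
#'   \code{\link{comparisons_count}(n_profiles, mode)}.
#' @return object of class \code{risk_spec} with fields \code{mode},
#'   \code{n_profiles}, \code{T}, \code{mu}, \code{U}, \code{beta},
#'   \code{alpha}.
#' @export
risk_spec <- function(n_profiles, mode = c("stain", "db"),
                      mu = NULL, U = NULL, beta = NULL, T = NULL) {
  mode <- match.arg(mode)
  if (is.null(T)) T <- comparisons_count(n_profiles, mode)
  if (is.null(mu)) {
    if (is.null(U) || is.null(beta)) {
      stop("supply either `mu` or both `U` and `beta`")
    }
    mu <- mu_from_upper_bound(U, beta)
  } else if (!is.null(U)) {
    stop("supply either `mu` or (`U`, `beta`), not both")
  }
  structure(list(mode = mode, n_profiles = n_profiles, T = T,
                 mu = mu, U = U, beta = beta,
                 alpha = per_comparison_alpha(mu, T)),
            class = "risk_spec")
}

#' @export
print.risk_spec <- function(x, ...) {
  cat(sprintf("Risk specification (%s search, %g profiles)\n",
              x$mode, x$n_profiles))
  if (!is.null(x$U)) {
    cat(sprintf("  at most U = %d false positives with probability %.3g\n",
                x$U, x$beta))
  }
  cat(sprintf("  T = %g comparisons, mu = %.6g expected FPs, alpha = %.4g\n",
              x$T, x$mu, x$alpha))
  invisible(x)
}

#' Poisson bound table
#'
#' For each expected false-positive count \eqn{\mu}, the smallest upper
#' bounds respected with 95\% and 99\% probability.
#'
#' @param mu numeric vector of expected false-positive counts.
#' @return data.frame with columns \code{mu}, \code{U95}, \code{U99}.
#' @export
poisson_bound_table <- function(mu = c(0.01, 0.05, 0.1, 1, 5, 10, 20, 50, 100)) {
  data.frame(mu = mu,
             U95 = vapply(mu, upper_bound, numeric(1), beta = 0.95),
             U99 = vapply(mu, upper_bound, numeric(1), beta = 0.99))
}
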