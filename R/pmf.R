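## Discretized log10 LR probability mass functions and their convolution.
##
## A loglr_pmf is a *sub*-probability mass function: its bins carry the
## probability that two unrelated random persons share an equal genotype
## (at every locus of the loci set) AND that the resulting total log10 LR
## falls in the bin.  The total mass is therefore the full-match
## probability of the loci set, always <= 1.

#' Construct a discretized log10 LR mass function
#'
#' Bin \eqn{n} (0-based) represents \eqn{\log_{10} LR = n\Delta}.  Only
#' nonnegative log LR values occur, because the equal-genotype likelihood
#' ratio is at least one.
#'
#' @param mass numeric vector of nonnegative bin masses; its length is the
#'   FFT array length (a power of two in typical use).
#' @param delta bin width in log10 LR units.
#' @param loci character vector naming the loci the mass function covers.
#' @return object of class \code{loglr_pmf} with fields \code{mass},
#'   \code{delta}, \code{loci}, \code{total_mass} and \code{max_bin} (the
#'   highest occupied 0-based bin, used by the aliasing guard).
#' @export
loglr_pmf <- function(mass, delta, loci = character()) {
  stopifnot(is.numeric(mass), length(mass) >= 1L, delta > 0)
  if (any(mass < 0)) stop("negative mass in loglr_pmf")
  nz <- which(mass > 0)
  structure(list(mass = mass,
                 delta = delta,
                 loci = loci,
                 total_mass = sum(mass),
                 max_bin = if (length(nz)) max(nz) - 1L else 0L),
            class = "loglr_pmf")
}

#' @export
print.loglr_pmf <- function(x, ...) {
  cat(sprintf(paste0("log10 LR mass function: %d loci [%s]\n",
                     "  delta = %g, length = %d, total mass = %.6g\n",
                     "  support <= %.4g log10 LR\n"),
              length(x$loci), paste(x$loci, collapse = ", "),
              x$delta, length(x$mass), x$total_mass, x$max_bin * x$delta))
  invisible(x)
}

#' @export
as.data.frame.loglr_pmf <- function(x, ..., drop_zero = TRUE) {
  keep <- if (drop_zero) which(x$mass > 0) else seq_along(x$mass)
  data.frame(log10_lr = (keep - 1) * x$delta, mass = x$mass[keep])
}

## Deterministic binning: round-half-away-from-zero of x/delta, with a
## 1e-12 pre-snap absorbing floating noise just below a .5 boundary.
## All x are >= 0 here.
bin_index <- function(x, delta) {
  as.integer(floor(x / delta + 0.5 + 1e-12))
}

## All genotypes of a locus with their Balding-Nichols quantities.
## Columns: i, j (ladder indices, i <= j), prob (unconditional genotype
## probability), match (conditional match probability), mass (equal-pair
## probability, prob * match), loglr (log10 of 1/match).
enumerate_genotypes <- function(table, locus, theta = 0.01) {
  check_theta(theta)
  p <- locus_entry(table, locus)$freq
  k <- length(p)
  i <- rep.int(seq_len(k), times = k - seq_len(k) + 1L)
  j <- unlist(lapply(seq_len(k), function(a) a:k), use.names = FALSE)
  hom <- i == j
  prob <- bn_genotype_prob(p[i], p[j], hom, theta)
  match <- bn_match_prob(p[i], p[j], hom, theta)
  data.frame(i = i, j = j, hom = hom, prob = prob, match = match,
             mass = prob * match, loglr = -log10(match))
}

#' Probability that two unrelated persons share an equal genotype
#'
#' The product of the unconditional genotype probability and the
#' conditional match probability; summed over all genotypes of a locus it
#' gives the locus's full-match probability (always below one).
#'
#' @inheritParams genotype_probability
#' @return probability in (0, 1).
#' @export
equal_genotype_mass <- function(g, table, theta = 0.01) {
  conditional_match_probability(g, table, theta) *
    genotype_probability(g, table, theta)
}

#' Single-locus log10 LR mass function
#'
#' Enumerates every genotype of the locus, places its equal-pair
#' probability at the bin of its log10 equal-genotype likelihood ratio,
#' and sums genotypes landing in the same bin ("clumping").  The result is
#' a sub-probability mass function whose total mass is the locus's
#' full-match probability.
#'
#' @param locus locus name.
#' @param table a p_min-corrected \code{\link{freq_table}}.
#' @param theta coancestry coefficient.
#' @param delta bin width in log10 LR units (default 0.001).
#' @param n_fft array length; a power of two keeps the FFT fast
#'   (default \code{2^16}).
#' @return a \code{\link{loglr_pmf}}.
#' @export
single_locus_pmf <- function(locus, table, theta = 0.01,
                             delta = 0.001, n_fft = 65536L) {
  gt <- enumerate_genotypes(table, locus, theta)
  bins <- bin_index(gt$loglr, delta)
  if (any(bins >= n_fft)) {
    stop(sprintf("aliasing: locus %s needs bin %d but array length is %d",
                 locus, max(bins), n_fft))
  }
  mass <- numeric(n_fft)
  acc <- tapply(gt$mass, bins, sum)
  mass[as.integer(names(acc)) + 1L] <- acc
  loglr_pmf(mass, delta, locus)
}

check_same_grid <- function(pmfs) {
  d <- vapply(pmfs, function(p) p$delta, numeric(1))
  n <- vapply(pmfs, function(p) length(p$mass), integer(1))
  if (length(unique(d)) != 1L || length(unique(n)) != 1L) {
    stop("all mass functions must share the same bin width and array length")
  }
}

check_aliasing <- function(pmfs) {
  n <- length(pmfs[[1L]]$mass)
  need <- sum(vapply(pmfs, function(p) p$max_bin, integer(1)))
  if (need >= n) {
    stop(sprintf(paste0("aliasing: combined support needs %d bins but the ",
                        "array length is %d; increase `length`"), need + 1L, n))
  }
}

#' Convolve log10 LR mass functions by FFT
#'
#' The mass function of the total log10 LR over the union of the inputs'
#' loci: each input is Fourier-transformed, the characteristic functions
#' are multiplied point-wise, and the product is inverse-transformed.  An
#' aliasing guard verifies that the combined support fits the array before
#' transforming.  Tiny negative values produced by floating-point
#' round-off (magnitude below 1e-12) are clamped to zero; anything more
#' negative raises an internal-consistency error.
#'
#' @param pmfs list of \code{\link{loglr_pmf}} objects on a common grid.
#' @return a \code{\link{loglr_pmf}} over the union of the input loci.
#'   Its total mass is the product of the input total masses.
#' @seealso \code{\link{convolve_direct}} for the brute-force reference.
#' @export
convolve_fft <- function(pmfs) {
  if (!is.list(pmfs) || inherits(pmfs, "loglr_pmf")) pmfs <- list(pmfs)
  if (length(pmfs) == 0L) stop("empty input: nothing to convolve")
  if (length(pmfs) == 1L) return(pmfs[[1L]])
  check_same_grid(pmfs)
  check_aliasing(pmfs)
  n <- length(pmfs[[1L]]$mass)
  phi <- stats::fft(pmfs[[1L]]$mass)
  for (k in 2:length(pmfs)) {
    phi <- phi * stats::fft(pmfs[[k]]$mass)
  }
  mass <- Re(stats::fft(phi, inverse = TRUE)) / n
  neg <- mass < 0
  if (any(mass[neg] < -1e-12)) {
    stop("FFT convolution produced mass below -1e-12; inconsistent inputs")
  }
  mass[neg] <- 0
  loglr_pmf(mass, pmfs[[1L]]$delta,
            unique(unlist(lapply(pmfs, function(p) p$loci))))
}

#' Convolve log10 LR mass functions by direct summation
#'
#' Reference implementation of the convolution, accumulating products of
#' nonzero bins directly.  Exact up to floating-point addition order; it
#' serves as the oracle against which \code{\link{convolve_fft}} is
#' checked, and is practical for a handful of small loci.
#'
#' @inheritParams convolve_fft
#' @return a \code{\link{loglr_pmf}}; for an empty list, the convolution
#'   identity (all mass at bin zero).
#' @export
convolve_direct <- function(pmfs) {
  if (!is.list(pmfs) || inherits(pmfs, "loglr_pmf")) pmfs <- list(pmfs)
  if (length(pmfs) == 0L) {
    stop("empty input: grid unknown; pass at least one mass function")
  }
  if (length(pmfs) == 1L) return(pmfs[[1L]])
  check_same_grid(pmfs)
  check_aliasing(pmfs)
  n <- length(pmfs[[1L]]$mass)
  acc <- pmfs[[1L]]$mass
  for (k in 2:length(pmfs)) {
    nxt <- pmfs[[k]]$mass
    nz_a <- which(acc > 0)
    nz_b <- which(nxt > 0)
    out <- numeric(n)
    for (b in nz_b) {
      idx <- nz_a + (b - 1L)
      out[idx] <- out[idx] + acc[nz_a] * nxt[b]
    }
    acc <- out
  }
  loglr_pmf(acc, pmfs[[1L]]$delta,
            unique(unlist(lapply(pmfs, function(p) p$loci))))
}

#' Expected false-positive rate implied by a log10 LR threshold
#'
#' The probability that two unrelated persons fully match at the mass
#' function's loci set with a total log10 LR at or above the threshold:
#' the tail mass from bin \code{round(threshold/delta)} upward.
#'
#' @param pmf a \code{\link{loglr_pmf}}.
#' @param log_lr_threshold nonnegative log10 LR value.
#' @return per-comparison false-positive probability \eqn{\alpha};
#'   nonincreasing in the threshold, zero beyond the support.
#' @export
alpha_from_threshold <- function(pmf, log_lr_threshold) {
  stopifnot(inherits(pmf, "loglr_pmf"), log_lr_threshold >= 0)
  k <- bin_index(log_lr_threshold, pmf$delta)
  if (k > pmf$max_bin) return(0)
  sum(pmf$mass[(k + 1L):length(pmf$mass)])
}

#' Log10 LR threshold achieving a target false-positive rate
#'
#' The smallest grid value \eqn{k\Delta} whose tail mass does not exceed
#' \code{alpha}; the round trip
#' \code{alpha_from_threshold(pmf, threshold_from_alpha(pmf, a)) <= a}
#' always holds.  If \code{alpha} already covers the whole sub-distribution
#' no filtering is needed and 0 is returned.
#'
#' @param pmf a \code{\link{loglr_pmf}}.
#' @param alpha target per-comparison false-positive rate, > 0.
#' @return log10 LR threshold on the grid.
#' @export
threshold_from_alpha <- function(pmf, alpha) {
  stopifnot(inherits(pmf, "loglr_pmf"), alpha > 0)
  if (alpha >= pmf$total_mass) return(0)
  m <- pmf$mass[seq_len(pmf$max_bin + 1L)]
  tails <- rev(cumsum(rev(m)))          # tails[k+1] = tail mass from bin k
  k_star <- which(tails <= alpha)[1L] - 1L
  # alpha below the top atom's mass: no support bin qualifies, so the
  # threshold sits one bin above the largest attainable value.
  if (is.na(k_star)) k_star <- pmf$max_bin + 1L
  k_star * pmf$delta
}

#' Memoized multi-locus mass functions
#'
#' Convolved mass functions depend only on the loci set (order ignored),
#' the frequency table, theta and the grid, so each distinct overlapping
#' loci set encountered during a database search needs one convolution
#' only.  The cache also memoizes the single-locus building blocks.
#'
#' @param table a p_min-corrected \code{\link{freq_table}}.
#' @param theta coancestry coefficient.
#' @param delta bin width.
#' @param n_fft array length.
#' @return object of class \code{pmf_cache} with functions
#'   \code{$get(loci)} returning the convolved \code{\link{loglr_pmf}} and
#'   \code{$stats()} returning hit/miss counts.
#' @export
pmf_cache <- function(table, theta = 0.01, delta = 0.001, n_fft = 65536L) {
  store <- new.env(parent = emptyenv())
  locus_store <- new.env(parent = emptyenv())
  hits <- 0L
  misses <- 0L
  get_locus <- function(l) {
    if (is.null(locus_store[[l]])) {
      locus_store[[l]] <- single_locus_pmf(l, table, theta, delta, n_fft)
    }
    locus_store[[l]]
  }
  get <- function(loci) {
    loci <- sort(unique(as.character(loci)))
    key <- paste(loci, collapse = "|")
    if (!is.null(store[[key]])) {
      hits <<- hits + 1L
      return(store[[key]])
    }
    misses <<- misses + 1L
    pmf <- convolve_fft(lapply(loci, get_locus))
    store[[key]] <- pmf
    pmf
  }
  structure(list(get = get,
                 stats = function() c(hits = hits, misses = misses)),
            class = "pmf_cache")
}

## Conditional moments of a sub-probability mass function: mean, variance
## and skewness of log10 LR given a full match.
pmf_moments <- function(pmf) {
  x <- (seq_along(pmf$mass) - 1) * pmf$delta
  w <- pmf$mass / pmf$total_mass
  mu <- sum(w * x)
  v <- sum(w * (x - mu)^2)
  skew <- if (v > 0) sum(w * (x - mu)^3) / v^1.5 else NA_real_
  list(mean = mu, var = v, sd = sqrt(v), skewness = skew)
}
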