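## Desk-scale validation machinery: calibration against Poisson bounds,
## ROC comparison of filtering methods, Monte-Carlo convergence of the FFT
## distributions, gap/skewness analysis against a Gaussian baseline, and
## relatives' pass-through counting.

#' Two-sided Poisson band
#'
#' \code{L} is the largest integer with \eqn{P(X < L) \le (1-level)/2} and
#' \code{U} the smallest with \eqn{P(X \le U) \ge 1-(1-level)/2}, so the
#' band \code{[L, U]} holds at least \code{level} of the mass.
#'
#' @param mu Poisson mean.
#' @param level band coverage (default 0.95).
#' @return named vector \code{c(L, U)}.
#' @export
poisson_band <- function(mu, level = 0.95) {
  tail <- (1 - level) / 2
  c(L = stats::qpois(tail, mu), U = stats::qpois(1 - tail, mu))
}

## Shared threshold memo: thresholds per loci-set key for a vector of
## alphas, building transient convolutions from memoized single-locus
## mass functions.
make_threshold_memo <- function(table, theta, delta, n_fft) {
  locus_store <- new.env(parent = emptyenv())
  thr_store <- new.env(parent = emptyenv())
  get_locus <- function(l) {
    if (is.null(locus_store[[l]])) {
      locus_store[[l]] <- single_locus_pmf(l, table, theta, delta, n_fft)
    }
    locus_store[[l]]
  }
  function(mkey, alphas) {
    hit <- thr_store[[mkey]]
    if (!is.null(hit)) return(hit)
    loci <- strsplit(mkey, "|", fixed = TRUE)[[1L]]
    pmf <- convolve_fft(lapply(loci, get_locus))
    thr <- vapply(alphas, function(a) threshold_from_alpha(pmf, a), numeric(1))
    thr_store[[mkey]] <- thr
    thr
  }
}

#' Calibration of observed against expected false positives
#'
#' Repeated batched stain-to-database searches under a shared Dirichlet
#' subpopulation: each batch draws a fresh subpopulation, a fresh database
#' and fresh degraded stains (copies of database members), applies the
#' dynamic threshold for each target \eqn{\mu}, and counts the adventitious
#' matches (full matches to non-donors) that clear it.  Observed counts are
#' compared to the target and to the two-sided Poisson band.
#'
#' The stain locus count must suit the comparison budget: calibration is
#' only observable while \eqn{\alpha = \mu/T} stays well below the total
#' match probability of the stains' loci sets.  Once \eqn{\alpha} exceeds
#' that total, the threshold floors at zero, every full match is reported,
#' and the observed count sits (correctly, but uninformatively) below the
#' target.  At the default desk scale (\eqn{T = 5\times10^6} comparisons
#' per batch) three-locus stains keep all loci subsets in the observable
#' regime; four-locus subsets of a realistic panel have median match
#' probability below \eqn{\mu/T} already at \eqn{\mu = 10}, which
#' reproduces the conservative saturation regime rather than calibration.
#'
#' @param table a p_min-corrected \code{\link{freq_table}}.
#' @param mu_targets expected false-positive counts to calibrate at.
#' @param db_size,n_stains database and stain counts per batch.
#' @param n_batches number of independent batches.
#' @param stain_loci locus count of the degraded stains (see Details).
#' @param theta coancestry coefficient (Dirichlet draw and LR model).
#' @param delta,n_fft grid for the threshold mass functions.
#' @param seed RNG seed; the report is a pure function of its arguments.
#' @return object of class \code{calibration_report}: list with
#'   \code{batches} (mu, batch, observed, L, U, in_band) and
#'   \code{summary} (per mu: mean observed, standard error, band coverage).
#' @export
run_calibration <- function(table, mu_targets = c(1, 5, 10),
                            db_size = 5000L, n_stains = 1000L,
                            n_batches = 50L, stain_loci = 3L,
                            theta = 0.01, delta = 0.001, n_fft = 32768L,
                            seed = 1L) {
  set.seed(seed)
  T_cmp <- n_stains * db_size
  alphas <- mu_targets / T_cmp
  lut <- loglr_lookup(table, theta)
  memo <- make_threshold_memo(table, theta, delta, n_fft)
  rows <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    subpop <- dirichlet_subpop_frequencies(table, theta)
    db <- sample_profiles(subpop, db_size, ids = paste0("DB", seq_len(db_size)))
    donor_idx <- sample.int(db_size, n_stains, replace = n_stains > db_size)
    stains <- degrade_profiles(ps_subset(db, donor_idx), stain_loci)
    m <- find_matches(stains, db, lut)
    m <- m[m$candidate != donor_idx[m$stain], , drop = FALSE]  # drop true matches
    observed <- integer(length(mu_targets))
    if (nrow(m) > 0L) {
      keys <- unique(m$mkey)
      thr <- vapply(keys, memo, numeric(length(mu_targets)), alphas = alphas)
      thr <- matrix(thr, nrow = length(mu_targets))
      for (j in seq_along(mu_targets)) {
        observed[j] <- sum(m$log10_lr >= thr[j, match(m$mkey, keys)])
      }
    }
    rows[[b]] <- data.frame(mu = mu_targets, batch = b, observed = observed)
  }
  batches <- do.call(rbind, rows)
  bands <- t(vapply(batches$mu, poisson_band, numeric(2)))
  batches$L <- bands[, 1L]
  batches$U <- bands[, 2L]
  batches$in_band <- batches$observed >= batches$L & batches$observed <= batches$U
  summary <- do.call(rbind, lapply(split(batches, batches$mu), function(d) {
    data.frame(mu = d$mu[1L],
               mean_observed = mean(d$observed),
               se = stats::sd(d$observed) / sqrt(nrow(d)),
               coverage = mean(d$in_band),
               n_batches = nrow(d))
  }))
  rownames(summary) <- NULL
  structure(list(batches = batches, summary = summary,
                 T = T_cmp, seed = seed),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Calibration over %d batches, T = %g comparisons per batch\n",
              max(x$batches$batch), x$T))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

## Empirical ROC from a score vector: points at every distinct cutoff.
## FPR is reported per comparison (n_comparisons) and the AUC is computed
## on the axis normalized to the maximum observed FPR, which equals the
## AUC over the pool of adventitious matches.
roc_points <- function(score, is_true, n_comparisons) {
  if (!any(is_true) || all(is_true)) {
    stop("ROC needs at least one true and one false match; ",
         "enlarge the study so both occur")
  }
  o <- order(score, decreasing = TRUE)
  score <- score[o]
  is_true <- is_true[o]
  n_tp <- sum(is_true)
  n_fp <- sum(!is_true)
  tp <- cumsum(is_true)
  fp <- cumsum(!is_true)
  last <- !duplicated(score, fromLast = TRUE)   # one point per distinct cutoff
  tpr <- c(0, tp[last] / n_tp)
  fpr_rel <- c(0, fp[last] / n_fp)
  auc <- sum(diff(fpr_rel) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  data.frame(threshold = c(Inf, score[last]),
             tpr = tpr, fpr = fpr_rel * n_fp / n_comparisons,
             fpr_rel = fpr_rel, auc = auc)
}

#' ROC comparison of the three filtering methods
#'
#' Simulates a degraded-stain search study (stain donors present in the
#' database) and ranks every detected full match under the three filtering
#' methods: shared-locus count, total log10 LR (static), and the
#' loci-set-specific tail probability of the match's own log10 LR (the
#' quantity the dynamic threshold cuts on; sweeping the risk target
#' \eqn{\alpha} traverses exactly this ranking).  True positives are
#' matches to the stain's donor.  The locus-count curve is a step function
#' over the few possible counts; the LR-based curves are smooth.
#'
#' @param table a p_min-corrected \code{\link{freq_table}}.
#' @param db_size database size.
#' @param stains_per_count stains simulated per locus count.
#' @param locus_counts stain locus counts (default 3:7).
#' @param theta coancestry coefficient.
#' @param delta,n_fft grid for the tail-probability scores.
#' @param seed RNG seed.
#' @return object of class \code{roc_report}: list of per-method ROC
#'   point data.frames (\code{curves}) and an \code{auc} named vector.
#' @export
run_roc <- function(table, db_size = 5000L, stains_per_count = 200L,
                    locus_counts = 3:7, theta = 0.01,
                    delta = 0.001, n_fft = 32768L, seed = 1L) {
  set.seed(seed)
  lut <- loglr_lookup(table, theta)
  subpop <- dirichlet_subpop_frequencies(table, theta)
  db <- sample_profiles(subpop, db_size, ids = paste0("DB", seq_len(db_size)))
  all_matches <- lapply(locus_counts, function(k) {
    donor_idx <- sample.int(db_size, stains_per_count,
                            replace = stains_per_count > db_size)
    stains <- degrade_profiles(ps_subset(db, donor_idx), k)
    m <- find_matches(stains, db, lut)
    m$is_true <- m$candidate == donor_idx[m$stain]
    m
  })
  m <- do.call(rbind, all_matches)
  ## dynamic score: tail probability of the match's log10 LR in its own
  ## loci-set distribution (smaller = stronger)
  locus_pmfs <- new.env(parent = emptyenv())
  pmf_of <- new.env(parent = emptyenv())
  get_pmf <- function(key) {
    hit <- pmf_of[[key]]
    if (!is.null(hit)) return(hit)
    loci <- strsplit(key, "|", fixed = TRUE)[[1L]]
    pmfs <- lapply(loci, function(l) {
      if (is.null(locus_pmfs[[l]])) {
        locus_pmfs[[l]] <- single_locus_pmf(l, table, theta, delta, n_fft)
      }
      locus_pmfs[[l]]
    })
    p <- convolve_fft(pmfs)
    pmf_of[[key]] <- p
    p
  }
  m$alpha_star <- vapply(seq_len(nrow(m)), function(i) {
    alpha_from_threshold(get_pmf(m$mkey[i]), m$log10_lr[i])
  }, numeric(1))
  n_cmp <- db_size * length(locus_counts) * stains_per_count
  curves <- list(
    "locus-count" = roc_points(m$n_shared, m$is_true, n_cmp),
    "static-lr" = roc_points(m$log10_lr, m$is_true, n_cmp),
    "dynamic-lr" = roc_points(-log10(pmax(m$alpha_star, 1e-300)),
                              m$is_true, n_cmp))
  structure(list(curves = curves,
                 auc = vapply(curves, function(d) d$auc[1L], numeric(1)),
                 matches = m[, c("n_shared", "log10_lr", "alpha_star", "is_true")],
                 seed = seed),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat("ROC comparison of match-filtering methods\n")
  for (nm in names(x$auc)) cat(sprintf("  AUC %-12s %.4f\n", nm, x$auc[[nm]]))
  invisible(x)
}

## Urn-scheme draw of one further allele for each of n partial genotype
## records.  `seen` is an n x m matrix of already-drawn allele indices;
## the next allele is i with probability (c_i*theta + (1-theta)*p_i) /
## (1 + (m-1)*theta) where c_i counts allele i among the m seen.
urn_draw <- function(seen, p, theta) {
  n <- nrow(seen)
  m <- ncol(seen)
  out <- integer(n)
  key <- do.call(paste, c(as.data.frame(seen), sep = "_"))
  for (g in split(seq_len(n), key)) {
    cnt <- tabulate(seen[g[1L], ], nbins = length(p))
    q <- (cnt * theta + (1 - theta) * p) / (1 + (m - 1) * theta)
    out[g] <- sample.int(length(p), length(g), replace = TRUE, prob = q)
  }
  out
}

## Monte-Carlo sampler of matching-genotype log10 LRs at one locus:
## person 1's genotype and person 2's two alleles are drawn by the
## Dirichlet urn scheme (so dependence across draws carries theta), and
## pairs are kept only when the genotypes are equal.  Returns `n_keep`
## accepted log10 LR values.
mc_matching_loglr <- function(locus, table, theta, n_keep, lut) {
  p <- locus_entry(table, locus)$freq
  loglr <- lut[[locus]]
  acc <- numeric(0)
  ## acceptance rate = the locus's full-match probability
  rate <- max(sum(enumerate_genotypes(table, locus, theta)$mass), 1e-4)
  while (length(acc) < n_keep) {
    n <- ceiling((n_keep - length(acc)) / rate * 1.2) + 100L
    a1 <- sample.int(length(p), n, replace = TRUE, prob = p)
    a2 <- urn_draw(cbind(a1), p, theta)
    a3 <- urn_draw(cbind(a1, a2), p, theta)
    ## early rejection: a3 must belong to person 1's genotype
    ok <- a3 == a1 | a3 == a2
    if (!any(ok)) next
    a4 <- urn_draw(cbind(a1, a2, a3)[ok, , drop = FALSE], p, theta)
    g1a <- pmin(a1[ok], a2[ok]); g1b <- pmax(a1[ok], a2[ok])
    g2a <- pmin(a3[ok], a4);     g2b <- pmax(a3[ok], a4)
    eq <- g1a == g2a & g1b == g2b
    if (any(eq)) acc <- c(acc, loglr[cbind(g1a[eq], g1b[eq])])
  }
  acc[seq_len(n_keep)]
}

#' Monte-Carlo convergence of the FFT distribution
#'
#' Samples total log10 LRs of fully matching unrelated profile pairs by
#' simulation (per-locus Dirichlet urn draws with rejection on genotype
#' equality, summed across loci) and compares the empirical distribution
#' to the FFT-convolved mass function conditioned on a full match.
#' Similarity is summarized by the Wasserstein-1 distance normalized by
#' the FFT distribution's standard deviation.
#'
#' @param loci loci set to convolve.
#' @param table a p_min-corrected \code{\link{freq_table}}.
#' @param theta coancestry coefficient.
#' @param n_trials number of matching pairs to sample (>= 10^4 advised).
#' @param delta,n_fft grid.
#' @param seed RNG seed.
#' @return list with FFT and Monte-Carlo means and standard deviations,
#'   the normalized Wasserstein distance, and \code{n_trials}.
#' @export
mc_convergence <- function(loci, table, theta = 0.01, n_trials = 1e5,
                           delta = 0.001, n_fft = 32768L, seed = 1L) {
  if (length(loci) == 0L) stop("empty loci set")
  set.seed(seed)
  lut <- loglr_lookup(table, theta)
  pmf <- convolve_fft(lapply(loci, single_locus_pmf, table = table,
                             theta = theta, delta = delta, n_fft = n_fft))
  mom <- pmf_moments(pmf)
  per_locus <- vapply(loci, mc_matching_loglr, numeric(n_trials),
                      table = table, theta = theta, n_keep = n_trials,
                      lut = lut)
  total <- rowSums(matrix(per_locus, nrow = n_trials))
  ## Wasserstein-1 on the common grid: integral of |CDF difference|.
  ## MC totals are binned after summation, so they can spill a bin or two
  ## past the FFT support (which bins per locus before summation); clamp
  ## both the grid and the samples to the array.
  n_bins <- min(pmf$max_bin + 4L, length(pmf$mass))
  mc_bins <- pmin(bin_index(total, delta), n_bins - 1L)
  mc_counts <- tabulate(mc_bins + 1L, nbins = n_bins)
  cdf_mc <- cumsum(mc_counts) / n_trials
  cdf_fft <- cumsum(pmf$mass[seq_len(n_bins)]) / pmf$total_mass
  w1 <- sum(abs(cdf_mc - cdf_fft)) * delta
  list(loci = loci,
       fft_mean = mom$mean, fft_sd = mom$sd,
       mc_mean = mean(total), mc_sd = stats::sd(total),
       wasserstein = w1, norm_wasserstein = w1 / mom$sd,
       n_trials = n_trials)
}

#' Zero-probability gaps of a mass function
#'
#' Maximal runs of zero-mass bins strictly inside the support envelope
#' (between the first and last occupied bin) whose width exceeds
#' \code{min_gap}; such gaps are log10 LR values that are combinatorially
#' impossible for the loci set, a feature continuous approximations erase.
#'
#' @param pmf a \code{\link{loglr_pmf}} with positive total mass.
#' @param min_gap minimum gap width to report, in log10 LR units
#'   (default 0.04); must be at least one bin.
#' @param tol bins with mass at or below \code{tol * total_mass} count as
#'   empty.  FFT round-off deposits masses of relative order 1e-16 in
#'   structurally empty bins, so an exact zero test would hide every gap
#'   of an FFT-convolved mass function; the default 1e-9 sits far above
#'   that noise floor and far below any genuinely occupied bin's share.
#' @return data.frame with columns \code{start}, \code{end} (log10 LR of
#'   the first and last zero bin of the gap) and \code{width}
#'   (\code{n_zero_bins * delta}); zero rows if the support is dense.
#' @export
gap_analysis <- function(pmf, min_gap = 0.04, tol = 1e-9) {
  stopifnot(inherits(pmf, "loglr_pmf"))
  if (pmf$total_mass <= 0) stop("empty mass function")
  if (min_gap < pmf$delta) stop("min_gap must be at least one bin width")
  nz <- which(pmf$mass > tol * pmf$total_mass)
  env <- pmf$mass[nz[1L]:nz[length(nz)]]
  r <- rle(env <= tol * pmf$total_mass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  zero <- which(r$values)
  width <- r$lengths[zero] * pmf$delta
  keep <- width > min_gap
  data.frame(start = (nz[1L] - 1L + starts[zero][keep] - 1L) * pmf$delta,
             end = (nz[1L] - 1L + ends[zero][keep] - 1L) * pmf$delta,
             width = width[keep])
}

#' Discrete tails against a Gaussian baseline
#'
#' Computes the conditional mean, variance and skewness of the mass
#' function, fits a Normal with the same mean and variance scaled to the
#' same total mass, and compares tail masses at \eqn{mean + k\sigma} for
#' \eqn{k = 1..4}.  A positive skewness with heavier discrete tails shows
#' where the symmetric continuous approximation underestimates the
#' false-positive risk.
#'
#' @param pmf a \code{\link{loglr_pmf}} with positive mass and variance.
#' @return list with \code{mean}, \code{sd}, \code{skewness} and a
#'   data.frame \code{tails} (k, threshold, discrete, gaussian).
#' @export
gaussian_tail_comparison <- function(pmf) {
  stopifnot(inherits(pmf, "loglr_pmf"))
  if (pmf$total_mass <= 0) stop("empty mass function")
  mom <- pmf_moments(pmf)
  if (mom$var <= 0) stop("zero-variance mass function")
  k <- 1:4
  thr <- mom$mean + k * mom$sd
  discrete <- vapply(thr, function(t) alpha_from_threshold(pmf, t), numeric(1))
  gaussian <- pmf$total_mass *
    stats::pnorm(thr, mom$mean, mom$sd, lower.tail = FALSE)
  list(mean = mom$mean, sd = mom$sd, skewness = mom$skewness,
       tails = data.frame(k = k, threshold = thr,
                          discrete = discrete, gaussian = gaussian))
}

#' Relatives' pass-through under the dynamic threshold
#'
#' Builds a database of unrelated profiles plus one parent-child and one
#' full-sibling relative of every stain donor, searches degraded stains
#' (donors included in the database) and counts, per relationship and per
#' stain locus count, the raw full matches ("detected") and those clearing
#' the dynamic threshold ("reviewed").  The threshold is calibrated to
#' \code{mu} expected unrelated false positives over the batch's
#' comparisons against the unrelated database.
#'
#' @param table a p_min-corrected \code{\link{freq_table}}.
#' @param db_size number of unrelated database profiles.
#' @param n_stains number of stains per locus count.
#' @param locus_counts stain locus counts (default 3:6).
#' @param mu expected unrelated false positives per batch.
#' @param theta coancestry coefficient.
#' @param delta,n_fft grid.
#' @param seed RNG seed.
#' @return data.frame with columns \code{relationship}, \code{n_loci},
#'   \code{detected}, \code{reviewed}.
#' @export
relatives_passthrough <- function(table, db_size = 2000L, n_stains = 200L,
                                  locus_counts = 3:6, mu = 1, theta = 0.01,
                                  delta = 0.001, n_fft = 32768L, seed = 1L) {
  set.seed(seed)
  lut <- loglr_lookup(table, theta)
  memo <- make_threshold_memo(table, theta, delta, n_fft)
  alpha <- mu / (n_stains * db_size)
  subpop <- dirichlet_subpop_frequencies(table, theta)
  db <- sample_profiles(subpop, db_size, ids = paste0("DB", seq_len(db_size)))
  donor_idx <- sample.int(db_size, n_stains, replace = n_stains > db_size)
  donors <- ps_subset(db, donor_idx)
  parents <- simulate_relatives(donors, "parent-child", subpop)
  siblings <- simulate_relatives(donors, "full-sibling", subpop)
  ## database searched = unrelated profiles + injected relatives
  full_db <- profile_set(
    c(db$ids, parents$ids, siblings$ids), db$loci,
    cbind(db$a1, parents$a1, siblings$a1),
    cbind(db$a2, parents$a2, siblings$a2),
    c(db$origin, parents$origin, siblings$origin),
    c(db$donor, parents$donor, siblings$donor))
  rel_of <- function(stain, candidate) {
    donor <- donors$ids[stain]
    cand_donor <- full_db$donor[candidate]
    ifelse(candidate == donor_idx[stain], "self",
           ifelse(!is.na(cand_donor) & cand_donor == donor,
                  full_db$origin[candidate], "unrelated"))
  }
  rows <- list()
  for (k in locus_counts) {
    stains <- degrade_profiles(donors, k)
    m <- find_matches(stains, full_db, lut)
    m$relationship <- rel_of(m$stain, m$candidate)
    m <- m[m$relationship != "self", , drop = FALSE]
    if (nrow(m) > 0L) {
      keys <- unique(m$mkey)
      thr <- vapply(keys, memo, numeric(1), alphas = alpha)
      m$reviewed <- m$log10_lr >= thr[match(m$mkey, keys)]
    }
    for (rel in c("unrelated", "parent-child", "full-sibling")) {
      d <- m[m$relationship == rel, , drop = FALSE]
      rows[[paste(rel, k)]] <- data.frame(
        relationship = rel, n_loci = k,
        detected = nrow(d),
        reviewed = if (nrow(d)) sum(d$reviewed) else 0L)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
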