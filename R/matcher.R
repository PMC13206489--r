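## Pairwise comparison engine: exact-match loci sets, total log10 LR, and
## locus-count / static-LR / dynamic-LR filtering.

#' Compare two profiles
#'
#' The shared loci set M is the set of loci typed in both profiles; the
#' pair is a full match when the (unordered) genotypes are equal at every
#' locus of M and M is non-empty.  Matching is exact: wildcard or
#' one-mismatch searching is out of scope.
#'
#' @param a,b \code{\link{profile_set}}s; the first profile of each is
#'   compared.
#' @return list with \code{shared_loci} (character) and \code{full_match}
#'   (logical).
#' @export
compare_profiles <- function(a, b) {
  common <- intersect(a$loci, b$loci)
  ia <- match(common, a$loci)
  ib <- match(common, b$loci)
  ta <- !is.na(a$a1[ia, 1L])
  tb <- !is.na(b$a1[ib, 1L])
  shared <- common[ta & tb]
  if (length(shared) == 0L) {
    return(list(shared_loci = character(), full_match = FALSE))
  }
  ia <- match(shared, a$loci)
  ib <- match(shared, b$loci)
  eq <- a$a1[ia, 1L] == b$a1[ib, 1L] & a$a2[ia, 1L] == b$a2[ib, 1L]
  list(shared_loci = shared, full_match = all(eq))
}

## Per-locus log10 LR lookup tables: for each locus a K x K matrix giving
## log10 LRE of genotype (i, j).
loglr_lookup <- function(table, theta = 0.01) {
  out <- lapply(names(table), function(l) {
    gt <- enumerate_genotypes(table, l, theta)
    k <- length(table[[l]]$freq)
    m <- matrix(NA_real_, k, k)
    m[cbind(gt$i, gt$j)] <- gt$loglr
    m
  })
  names(out) <- names(table)
  out
}

#' Total log10 likelihood ratio of a full match
#'
#' The sum over the shared loci of the per-locus log10 equal-genotype
#' likelihood ratios; invariant under locus ordering.  Calling it on a
#' pair that is not a full match is a contract violation and raises an
#' error.
#'
#' @param a,b \code{\link{profile_set}}s (first profile of each).
#' @param table a p_min-corrected \code{\link{freq_table}}.
#' @param theta coancestry coefficient.
#' @return total log10 LR (nonnegative).
#' @export
total_log10_lr <- function(a, b, table, theta = 0.01) {
  cmp <- compare_profiles(a, b)
  if (!cmp$full_match) stop("profiles are not a full match on their shared loci")
  ia <- match(cmp$shared_loci, a$loci)
  sum(vapply(seq_along(cmp$shared_loci), function(k) {
    l <- cmp$shared_loci[k]
    gt <- enumerate_genotypes(table, l, theta)
    i <- a$a1[ia[k], 1L]; j <- a$a2[ia[k], 1L]
    gt$loglr[gt$i == i & gt$j == j]
  }, numeric(1)))
}

## Vectorized raw match finder.  Returns one row per full match:
## stain (index), candidate (index), n_shared, mkey (canonical loci-set
## key), log10_lr.  `lut` is loglr_lookup(table, theta).
find_matches <- function(stains, db, lut) {
  row_map <- match(stains$loci, db$loci)
  if (anyNA(row_map)) {
    stop("stain loci absent from database profiles: ",
         paste(stains$loci[is.na(row_map)], collapse = ", "))
  }
  if (any(!(stains$loci %in% names(lut)))) {
    stop("stain loci absent from frequency table")
  }
  n_db <- n_profiles(db)
  db_full <- !anyNA(db$a1)
  out <- vector("list", n_profiles(stains))
  for (s in seq_len(n_profiles(stains))) {
    typed <- which(!is.na(stains$a1[, s]))
    if (length(typed) == 0L) next
    loci_s <- stains$loci[typed]
    ## per-locus stain log10 LRs (the LR of a full match only depends on
    ## the stain's own genotypes)
    loglr_s <- vapply(seq_along(typed), function(k) {
      lut[[loci_s[k]]][stains$a1[typed[k], s], stains$a2[typed[k], s]]
    }, numeric(1))
    mism <- logical(n_db)
    shared <- integer(n_db)
    eqs <- if (!db_full) vector("list", length(typed)) else NULL
    for (k in seq_along(typed)) {
      r <- row_map[typed[k]]
      d1 <- db$a1[r, ]
      tk <- !is.na(d1)
      eq <- tk & d1 == stains$a1[typed[k], s] &
        db$a2[r, ] == stains$a2[typed[k], s]
      mism <- mism | (tk & !eq)
      shared <- shared + tk
      if (!db_full) eqs[[k]] <- eq
    }
    hit <- which(!mism & shared > 0L)
    if (length(hit) == 0L) next
    if (db_full) {
      mkey <- paste(sort(loci_s), collapse = "|")
      out[[s]] <- data.frame(stain = s, candidate = hit,
                             n_shared = length(typed), mkey = mkey,
                             log10_lr = sum(loglr_s),
                             stringsAsFactors = FALSE)
    } else {
      eqm <- vapply(eqs, function(e) e[hit], logical(length(hit)))
      eqm <- matrix(eqm, nrow = length(hit))
      ord <- order(loci_s)
      out[[s]] <- data.frame(
        stain = s, candidate = hit, n_shared = as.integer(rowSums(eqm)),
        mkey = apply(eqm[, ord, drop = FALSE], 1L, function(e)
          paste(loci_s[ord][e], collapse = "|")),
        log10_lr = as.numeric(eqm %*% loglr_s),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(stain = integer(), candidate = integer(),
                      n_shared = integer(), mkey = character(),
                      log10_lr = numeric(), stringsAsFactors = FALSE)
  }
  res
}

#' Search stains against a database
#'
#' Finds every full match between each stain and the database profiles and
#' applies one of three filtering methods:
#' \describe{
#'   \item{\code{"dynamic-lr"}}{per-match threshold
#'     \code{threshold_from_alpha(pmf(M), alpha)} where M is the match's
#'     shared loci set and \code{alpha} comes from the risk specification;
#'     thresholds are computed once per distinct M via a
#'     \code{\link{pmf_cache}}.}
#'   \item{\code{"static-lr"}}{fixed log10 LR threshold.}
#'   \item{\code{"locus-count"}}{review when at least \code{min_loci} loci
#'     are shared.}
#' }
#'
#' @param stains,db \code{\link{profile_set}}s; database profiles may be
#'   partially typed, in which case the shared loci set is the typed
#'   intersection.
#' @param table a p_min-corrected \code{\link{freq_table}}.
#' @param spec a \code{\link{risk_spec}} (required for
#'   \code{"dynamic-lr"}); its \code{alpha} drives the thresholds.
#' @param method filtering method.
#' @param theta coancestry coefficient (must match the value used for any
#'   supplied cache).
#' @param lr_threshold static log10 LR threshold (for \code{"static-lr"}).
#' @param min_loci minimum shared locus count (for \code{"locus-count"}).
#' @param delta,n_fft grid for dynamic thresholds.
#' @param cache optional \code{\link{pmf_cache}} to reuse across searches.
#' @return data.frame sorted by decreasing log10 LR with columns
#'   \code{stain_id}, \code{candidate_id}, \code{n_shared_loci},
#'   \code{loci}, \code{log10_lr}, \code{threshold}, \code{decision}
#'   (\code{"review"} or \code{"reject"}) and \code{method}.
#' @export
search_profiles <- function(stains, db, table,
                            method = c("dynamic-lr", "static-lr", "locus-count"),
                            spec = NULL, theta = 0.01,
                            lr_threshold = NULL, min_loci = NULL,
                            delta = 0.001, n_fft = 65536L, cache = NULL) {
  method <- match.arg(method)
  lut <- loglr_lookup(table, theta)
  m <- find_matches(stains, db, lut)
  m$stain_id <- stains$ids[m$stain]
  m$candidate_id <- db$ids[m$candidate]
  if (method == "dynamic-lr") {
    if (is.null(spec)) stop("dynamic-lr filtering needs a risk_spec")
    if (is.null(cache)) cache <- pmf_cache(table, theta, delta, n_fft)
    keys <- unique(m$mkey)
    thr <- vapply(keys, function(k) {
      threshold_from_alpha(cache$get(strsplit(k, "|", fixed = TRUE)[[1L]]),
                           spec$alpha)
    }, numeric(1))
    m$threshold <- unname(thr[match(m$mkey, keys)])
    m$decision <- ifelse(m$log10_lr >= m$threshold, "review", "reject")
  } else if (method == "static-lr") {
    if (is.null(lr_threshold)) stop("static-lr filtering needs lr_threshold")
    m$threshold <- lr_threshold
    m$decision <- ifelse(m$log10_lr >= lr_threshold, "review", "reject")
  } else {
    if (is.null(min_loci)) stop("locus-count filtering needs min_loci")
    m$threshold <- NA_real_
    m$decision <- ifelse(m$n_shared >= min_loci, "review", "reject")
  }
  m <- m[order(-m$log10_lr), ]
  data.frame(stain_id = m$stain_id, candidate_id = m$candidate_id,
             n_shared_loci = m$n_shared,
             loci = gsub("|", ",", m$mkey, fixed = TRUE),
             log10_lr = m$log10_lr, threshold = m$threshold,
             decision = m$decision, method = method,
             row.names = NULL, stringsAsFactors = FALSE)
}
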