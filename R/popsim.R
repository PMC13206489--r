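## Synthetic data: Dirichlet-structured subpopulation frequencies, random
## STR profiles, degraded stains and Mendelian relatives.

#' Construct a profile set
#'
#' Profiles are stored column-wise: two L x n integer matrices of ladder
#' indices (canonical order, \code{a1 <= a2} element-wise), with \code{NA}
#' at loci a profile is not typed at.  Ladder indices refer to a
#' \code{\link{freq_table}} with the same loci.
#'
#' @param ids character vector of sample ids (length n).
#' @param loci character vector of locus names (length L).
#' @param a1,a2 L x n integer matrices of allele ladder indices.
#' @param origin per-profile label (e.g. \code{"unrelated"},
#'   \code{"stain-donor"}, \code{"parent-child"}, \code{"full-sibling"}).
#' @param donor per-profile id of the source individual (relatives and
#'   stains), \code{NA} otherwise.
#' @return object of class \code{profile_set}.
#' @export
profile_set <- function(ids, loci, a1, a2, origin = "unrelated",
                        donor = NA_character_) {
  n <- length(ids)
  stopifnot(nrow(a1) == length(loci), ncol(a1) == n,
            identical(dim(a1), dim(a2)))
  if (any(a1 > a2, na.rm = TRUE)) stop("allele pairs must be canonical (a1 <= a2)")
  if (any(is.na(a1) != is.na(a2))) stop("half-typed genotype in profile set")
  structure(list(ids = as.character(ids), loci = as.character(loci),
                 a1 = a1, a2 = a2,
                 origin = rep_len(origin, n),
                 donor = rep_len(donor, n)),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  typed <- colSums(!is.na(x$a1))
  cat(sprintf("Profile set: %d profiles, %d loci (typed loci per profile: %d-%d)\n",
              length(x$ids), length(x$loci), min(typed), max(typed)))
  cat("  origins:", paste(sprintf("%s=%d", names(table(x$origin)),
                                  as.integer(table(x$origin))),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Number of profiles in a set
#' @param ps a \code{\link{profile_set}}.
#' @return integer count.
#' @export
n_profiles <- function(ps) length(ps$ids)

#' Extract a subset of profiles
#' @param ps a \code{\link{profile_set}}.
#' @param idx integer or logical index over profiles.
#' @return a \code{\link{profile_set}}.
#' @export
ps_subset <- function(ps, idx) {
  profile_set(ps$ids[idx], ps$loci,
              ps$a1[, idx, drop = FALSE], ps$a2[, idx, drop = FALSE],
              ps$origin[idx], ps$donor[idx])
}

#' @export
as.data.frame.profile_set <- function(x, ..., table = NULL) {
  rows <- lapply(seq_along(x$ids), function(i) {
    typed <- which(!is.na(x$a1[, i]))
    data.frame(sample_id = x$ids[i],
               locus = x$loci[typed],
               allele1 = x$a1[typed, i],
               allele2 = x$a2[typed, i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(table)) {
    out$allele1 <- mapply(function(l, a) table[[l]]$alleles[a],
                          out$locus, out$allele1)
    out$allele2 <- mapply(function(l, a) table[[l]]$alleles[a],
                          out$locus, out$allele2)
  }
  out
}

#' Write profiles as long-format CSV
#'
#' Columns \code{sample_id,locus,allele1,allele2}, allele labels resolved
#' through the frequency table's ladders.
#'
#' @param ps a \code{\link{profile_set}}.
#' @param table the \code{\link{freq_table}} the set was generated from.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_profiles <- function(ps, table, path) {
  utils::write.csv(as.data.frame(ps, table = table), path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read profiles from long-format CSV
#'
#' @param path CSV with columns \code{sample_id,locus,allele1,allele2}.
#' @param table \code{\link{freq_table}} providing the ladders; alleles
#'   absent from a ladder raise an error.
#' @return a \code{\link{profile_set}} over all loci of \code{table}.
#' @export
read_profiles <- function(path, table) {
  df <- utils::read.csv(path, colClasses = c(allele1 = "character",
                                             allele2 = "character"),
                        fileEncoding = "UTF-8")
  ids <- unique(df$sample_id)
  loci <- ft_loci(table)
  n <- length(ids)
  a1 <- matrix(NA_integer_, length(loci), n, dimnames = list(loci, NULL))
  a2 <- a1
  for (l in unique(df$locus)) {
    d <- df[df$locus == l, ]
    if (anyDuplicated(d$sample_id)) stop("locus ", l, " repeated within a profile")
    col <- match(d$sample_id, ids)
    i1 <- allele_index(table, l, d$allele1)
    i2 <- allele_index(table, l, d$allele2)
    a1[l, col] <- pmin(i1, i2)
    a2[l, col] <- pmax(i1, i2)
  }
  profile_set(ids, loci, a1, a2)
}

#' Generate a synthetic allele-frequency table
#'
#' Emits a frequency table with the statistical shape of real autosomal
#' STR panels.  Allele frequencies at an STR locus are unimodal across
#' repeat lengths (stepwise mutation keeps most chromosomes near the
#' modal repeat count), so each ladder's frequencies follow a discretized
#' bell over the ladder perturbed by lognormal noise, leaving a few
#' common alleles, a middle range, and a handful of rare alleles in the
#' flanks that fall below \eqn{p_{min}} at realistic sample sizes.
#' Ladder sizes and bell widths are spread across loci, spanning
#' low-diversity markers (TPOX-like: few alleles, one dominant) up to
#' highly polymorphic ones (SE33-like: many alleles, high
#' heterozygosity).  Allele labels are repeat numbers with occasional
#' ".3" microvariants.
#'
#' @param n_loci number of loci.
#' @param n_alleles range (length-2) of ladder sizes, spread linearly
#'   across loci so the panel is heterogeneous by construction.
#' @param n_typed number of typed individuals (drives \eqn{p_{min}}).
#' @param spread range of bell standard deviations as a fraction of the
#'   ladder size; small values give skewed, low-diversity loci.
#' @param noise_sd standard deviation of the lognormal perturbation.
#' @param loci optional locus names (default \code{"L01"...}).
#' @return a raw (uncorrected) \code{\link{freq_table}}; callers should
#'   apply \code{\link{apply_pmin}} before modelling.
#' @export
synth_freq_table <- function(n_loci = 24L, n_alleles = c(6L, 20L),
                             n_typed = 1000L, spread = c(0.16, 0.40),
                             noise_sd = 0.5,
                             loci = sprintf("L%02d", seq_len(n_loci))) {
  stopifnot(n_loci >= 1, length(loci) == n_loci)
  k <- round(seq(n_alleles[1L], n_alleles[2L], length.out = n_loci))
  sd_frac <- seq(spread[1L], spread[2L], length.out = n_loci)
  rows <- lapply(seq_len(n_loci), function(i) {
    center <- stats::runif(1, 0.35, 0.65) * k[i]
    w <- stats::dnorm(seq_len(k[i]), center, sd_frac[i] * k[i]) *
      exp(stats::rnorm(k[i], 0, noise_sd))
    p <- w / sum(w)
    base <- seq.int(6L, length.out = k[i])
    labels <- as.character(base)
    micro <- stats::runif(k[i]) < 0.1
    labels[micro] <- paste0(base[micro], ".3")
    data.frame(locus = loci[i], allele = labels, frequency = p,
               n_typed = n_typed, stringsAsFactors = FALSE)
  })
  freq_table(do.call(rbind, rows))
}

#' Draw skewed subpopulation frequencies (Dirichlet model)
#'
#' Using the general population's frequencies as baseline, each locus's
#' subpopulation frequencies are drawn from a Dirichlet with concentration
#' \eqn{\alpha_i = p_i(1-\theta)/\theta}, the stationary Balding-Nichols
#' parameterization.  Its first two moments reproduce the coancestry
#' model: the mean equals the baseline and
#' \eqn{Var(q_i) = \theta p_i(1-p_i)}, so two individuals drawn from one
#' such subpopulation have exactly the Balding-Nichols pairwise match
#' probabilities when averaged over draws.  \eqn{\theta = 0} returns the
#' table unchanged.
#'
#' @param table a p_min-corrected \code{\link{freq_table}}.
#' @param theta coancestry coefficient in [0, 1).
#' @return a \code{\link{freq_table}} with the same ladders and skewed
#'   frequencies summing to one per locus.
#' @export
dirichlet_subpop_frequencies <- function(table, theta = 0.01) {
  check_theta(theta)
  if (theta == 0) return(table)
  out <- table
  c0 <- (1 - theta) / theta
  for (l in names(table)) {
    g <- stats::rgamma(length(table[[l]]$freq), shape = table[[l]]$freq * c0)
    if (sum(g) == 0) g[] <- 1        # numerically degenerate draw
    out[[l]]$freq <- g / sum(g)
  }
  out
}

#' Sample random profiles from allele frequencies
#'
#' Two alleles per locus are drawn independently from the locus's
#' frequencies (Hardy-Weinberg within the generating population) and
#' stored in canonical order.
#'
#' @param freqs a \code{\link{freq_table}} (typically a subpopulation draw).
#' @param n number of profiles.
#' @param loci loci to type; defaults to all loci of \code{freqs}.
#' @param ids sample ids (default \code{"S1"...}).
#' @param origin origin label for the new profiles.
#' @return a \code{\link{profile_set}} over \code{loci}.
#' @export
sample_profiles <- function(freqs, n, loci = ft_loci(freqs),
                            ids = paste0("S", seq_len(n)),
                            origin = "unrelated") {
  if (length(loci) == 0L) stop("empty loci set")
  missing_l <- setdiff(loci, ft_loci(freqs))
  if (length(missing_l)) stop("loci not in table: ", paste(missing_l, collapse = ", "))
  L <- length(loci)
  a1 <- matrix(NA_integer_, L, n, dimnames = list(loci, NULL))
  a2 <- a1
  for (l in loci) {
    p <- freqs[[l]]$freq
    draws <- matrix(sample.int(length(p), 2L * n, replace = TRUE, prob = p),
                    nrow = 2L)
    a1[l, ] <- pmin(draws[1L, ], draws[2L, ])
    a2[l, ] <- pmax(draws[1L, ], draws[2L, ])
  }
  profile_set(ids, loci, a1, a2, origin = origin)
}

#' Degrade profiles by random locus dropout
#'
#' Keeps a uniformly random subset of each profile's typed loci of exactly
#' \code{target_loci} loci; surviving genotypes are unmodified.  Random
#' dropout (rather than amplicon-size-ordered dropout) also covers locus
#' sets arising from old or exotic typing kits.
#'
#' @param ps a \code{\link{profile_set}}.
#' @param target_loci number of loci to retain, recycled over profiles;
#'   must not exceed any profile's typed locus count.
#' @return a \code{\link{profile_set}} with dropped loci set to \code{NA}.
#' @export
degrade_profiles <- function(ps, target_loci) {
  n <- n_profiles(ps)
  target <- rep_len(as.integer(target_loci), n)
  if (any(target < 1)) stop("target_loci must be at least 1")
  for (i in seq_len(n)) {
    typed <- which(!is.na(ps$a1[, i]))
    if (target[i] > length(typed)) {
      stop("profile ", ps$ids[i], " has only ", length(typed), " typed loci")
    }
    drop <- setdiff(typed, typed[sample.int(length(typed), target[i])])
    ps$a1[drop, i] <- NA_integer_
    ps$a2[drop, i] <- NA_integer_
  }
  ps
}

#' Simulate relatives of profile donors
#'
#' Mendelian identity-by-descent simulation.  Parent-child pairs share
#' exactly one allele IBD at every locus (the transmitted donor allele is
#' chosen uniformly; the other allele is drawn from the frequency pool).
#' Full siblings draw an IBD state per locus with probabilities 0.25 /
#' 0.5 / 0.25 for sharing 2 / 1 / 0 alleles; shared alleles are copied
#' from the donor and the remainder drawn independently from the
#' frequencies.  Relatives are generated from the full donor profiles; any
#' stain degradation is applied separately afterwards.
#'
#' @param donors a \code{\link{profile_set}} of fully typed donors.
#' @param relationship \code{"parent-child"} or \code{"full-sibling"}.
#' @param freqs \code{\link{freq_table}} supplying the non-IBD allele pool
#'   (the donors' generating subpopulation).
#' @return a \code{\link{profile_set}} with one relative per donor,
#'   \code{origin} set to the relationship and \code{donor} to the donor id.
#' @export
simulate_relatives <- function(donors,
                               relationship = c("parent-child", "full-sibling"),
                               freqs) {
  relationship <- match.arg(relationship)
  if (any(is.na(donors$a1))) stop("donors must be typed at all loci")
  n <- n_profiles(donors)
  L <- length(donors$loci)
  a1 <- matrix(NA_integer_, L, n, dimnames = list(donors$loci, NULL))
  a2 <- a1
  for (li in seq_len(L)) {
    l <- donors$loci[li]
    p <- freqs[[l]]$freq
    d1 <- donors$a1[li, ]
    d2 <- donors$a2[li, ]
    pick <- stats::runif(n) < 0.5          # which donor allele is transmitted
    shared1 <- ifelse(pick, d1, d2)
    if (relationship == "parent-child") {
      ibd <- rep(1L, n)
    } else {
      ibd <- sample(c(0L, 1L, 2L), n, replace = TRUE,
                    prob = c(0.25, 0.5, 0.25))
    }
    new1 <- sample.int(length(p), n, replace = TRUE, prob = p)
    new2 <- sample.int(length(p), n, replace = TRUE, prob = p)
    r1 <- ifelse(ibd == 2L, d1, ifelse(ibd == 1L, shared1, new1))
    r2 <- ifelse(ibd == 2L, d2, ifelse(ibd == 1L, new1, new2))
    a1[li, ] <- pmin(r1, r2)
    a2[li, ] <- pmax(r1, r2)
  }
  profile_set(paste0(donors$ids, "-", relationship), donors$loci, a1, a2,
              origin = relationship, donor = donors$ids)
}

#' Simulation configuration
#'
#' @param seed RNG seed; a fixed seed makes every generated study
#'   byte-identical.
#' @param theta coancestry coefficient used both for the Dirichlet
#'   subpopulation draw and (downstream) the LR model.
#' @param db_size number of reference profiles in the database.
#' @param n_stains number of crime-scene stains.
#' @param stain_loci candidate stain locus counts; each stain's count is
#'   drawn uniformly from this vector (a single value fixes it).
#' @param relatives character vector among \code{"parent-child"},
#'   \code{"full-sibling"}: relatives to attach to each stain donor.
#' @param stain_source \code{"db"} (stain donors are database members, so
#'   every stain has a guaranteed true match) or \code{"new"} (donors are
#'   separate individuals absent from the database).
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L, theta = 0.01, db_size = 1000L,
                       n_stains = 100L, stain_loci = 3:9,
                       relatives = character(),
                       stain_source = c("db", "new")) {
  stain_source <- match.arg(stain_source)
  bad <- setdiff(relatives, c("parent-child", "full-sibling"))
  if (length(bad)) stop("unknown relationship(s): ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), theta = theta,
                 db_size = as.integer(db_size),
                 n_stains = as.integer(n_stains),
                 stain_loci = as.integer(stain_loci),
                 relatives = relatives, stain_source = stain_source),
            class = "sim_config")
}

#' Generate a complete synthetic search study
#'
#' One Dirichlet subpopulation frequency draw is shared by the database,
#' the stains and the relatives, mirroring the coancestry structure the LR
#' model assumes.  Stain donors are then sampled (from the database or as
#' fresh individuals), relatives are attached to the full donor profiles,
#' and finally the stains are degraded to their target locus counts.  The
#' whole study is a pure function of \code{(config, table)}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param table a p_min-corrected \code{\link{freq_table}}.
#' @return list with elements \code{db}, \code{stains}, \code{relatives}
#'   (named list of \code{\link{profile_set}}s), \code{subpop} (the drawn
#'   frequency table) and \code{config}.
#' @export
generate_study <- function(config, table) {
  stopifnot(inherits(config, "sim_config"), inherits(table, "freq_table"))
  set.seed(config$seed)
  subpop <- dirichlet_subpop_frequencies(table, config$theta)
  db <- sample_profiles(subpop, config$db_size,
                        ids = paste0("DB", seq_len(config$db_size)))
  if (config$stain_source == "db") {
    donor_idx <- sample.int(config$db_size, config$n_stains,
                            replace = config$n_stains > config$db_size)
    donors <- ps_subset(db, donor_idx)
  } else {
    donors <- sample_profiles(subpop, config$n_stains,
                              ids = paste0("DONOR", seq_len(config$n_stains)))
  }
  relatives <- lapply(stats::setNames(config$relatives, config$relatives),
                      function(rel) simulate_relatives(donors, rel, subpop))
  targets <- if (length(config$stain_loci) == 1L) {
    rep(config$stain_loci, config$n_stains)
  } else {
    sample(config$stain_loci, config$n_stains, replace = TRUE)
  }
  stains <- degrade_profiles(donors, targets)
  stains$ids <- paste0("STAIN", seq_len(config$n_stains))
  stains$origin <- rep("stain-donor", config$n_stains)
  stains$donor <- donors$ids
  list(db = db, stains = stains, relatives = relatives,
       subpop = subpop, config = config)
}
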