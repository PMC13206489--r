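#' Single-locus genotype
#'
#' A genotype is an unordered pair of allele labels at one locus.  The pair
#' is stored in canonical ladder order (index of the first allele not above
#' the second) once resolved against a frequency table.
#'
#' @param locus locus name.
#' @param a1,a2 allele labels (coerced to character).
#' @return An object of class \code{genotype}.
#' @export
genotype <- function(locus, a1, a2) {
  structure(list(locus = as.character(locus),
                 alleles = c(as.character(a1), as.character(a2))),
            class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat(sprintf("%s: %s/%s\n", x$locus, x$alleles[1L], x$alleles[2L]))
  invisible(x)
}

## Resolve a genotype to ladder indices in canonical (i <= j) order.
resolve_genotype <- function(g, table) {
  idx <- allele_index(table, g$locus, g$alleles)
  sort(idx)
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta >= 1) {
    stop("theta must be a single value in [0, 1)")
  }
  theta
}

## ---- Vectorized Balding-Nichols kernels -----------------------------------
## p1, p2: allele frequencies; hom: logical, p1 == p2 refer to the same
## allele.  All three recycle to a common length.

## Probability that a random unrelated person carries the genotype:
## homozygote  theta*p + (1-theta)*p^2
## heterozygote 2*(1-theta)*p1*p2
bn_genotype_prob <- function(p1, p2, hom, theta) {
  ifelse(hom,
         theta * p1 + (1 - theta) * p1^2,
         2 * (1 - theta) * p1 * p2)
}

## Conditional match probability P(g | g, H0), NRC II Recommendation 4.10:
## homozygote  (3t + (1-t)p)(2t + (1-t)p) / ((1+t)(1+2t))
## heterozygote 2(t + (1-t)p1)(t + (1-t)p2) / ((1+t)(1+2t))
bn_match_prob <- function(p1, p2, hom, theta) {
  d <- (1 + theta) * (1 + 2 * theta)
  ifelse(hom,
         (3 * theta + (1 - theta) * p1) * (2 * theta + (1 - theta) * p1) / d,
         2 * (theta + (1 - theta) * p1) * (theta + (1 - theta) * p2) / d)
}

## ---- Genotype-level API ----------------------------------------------------

#' Probability that a random unrelated person has a genotype
#'
#' Balding-Nichols genotype frequency with coancestry coefficient
#' \eqn{\theta}: \eqn{\theta p + (1-\theta)p^2} for homozygotes and
#' \eqn{2(1-\theta)p_i p_j} for heterozygotes.  At \eqn{\theta = 0} this
#' reduces to Hardy-Weinberg proportions.
#'
#' @param g a \code{\link{genotype}}.
#' @param table a p_min-corrected \code{\link{freq_table}}.
#' @param theta coancestry coefficient in \code{[0, 1)}; forensic practice
#'   commonly uses 0.01 (0.03 for more conservative reporting).
#' @return probability in (0, 1].
#' @export
genotype_probability <- function(g, table, theta = 0.01) {
  check_theta(theta)
  idx <- resolve_genotype(g, table)
  p <- locus_entry(table, g$locus)$freq
  bn_genotype_prob(p[idx[1L]], p[idx[2L]], idx[1L] == idx[2L], theta)
}

#' Conditional match probability under the defense hypothesis
#'
#' Probability that a random unrelated person carries genotype \eqn{g}
#' given that \eqn{g} has already been observed once, with shared ancestry
#' \eqn{\theta} (NRC II Recommendation 4.10).  Always at least as large as
#' \code{\link{genotype_probability}} when \eqn{\theta > 0}.
#'
#' @inheritParams genotype_probability
#' @return probability in (0, 1].
#' @export
conditional_match_probability <- function(g, table, theta = 0.01) {
  check_theta(theta)
  idx <- resolve_genotype(g, table)
  p <- locus_entry(table, g$locus)$freq
  bn_match_prob(p[idx[1L]], p[idx[2L]], idx[1L] == idx[2L], theta)
}

#' Equal-genotype likelihood ratio
#'
#' The likelihood ratio for two equal genotypes: the probability of the
#' observation under "same source" (1) divided by its probability under
#' "unrelated source" (the conditional match probability).  Its reciprocal
#' identity \code{lre(g) * conditional_match_probability(g) == 1} holds for
#' every genotype, and \code{log10(lre(g)) >= 0} always.
#'
#' @inheritParams genotype_probability
#' @return likelihood ratio, \eqn{\ge 1}.
#' @export
lre <- function(g, table, theta = 0.01) {
  1 / conditional_match_probability(g, table, theta)
}
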