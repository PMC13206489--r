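#' Construct an allele-frequency table
#'
#' An allele-frequency table holds, for each STR locus, the allele ladder
#' (the set of allele labels observed in the reference population), the
#' allele frequencies aligned to that ladder, and the number of typed
#' individuals \eqn{N} from which the frequencies were estimated.  Allele
#' labels are opaque strings so that microvariants such as \code{"9.3"}
#' survive round-trips unchanged.
#'
#' Raw tables are stored as loaded: no renormalization or rare-allele
#' correction is applied until \code{\link{apply_pmin}} is called.
#'
#' @param df data.frame with columns \code{locus}, \code{allele},
#'   \code{frequency}, \code{n_typed} (one row per allele; \code{n_typed}
#'   constant within a locus).
#' @return An object of class \code{freq_table}: a named list of loci, each
#'   a list with elements \code{alleles} (character), \code{freq} (numeric),
#'   \code{n_typed} (integer) and \code{p_min} (\eqn{5/2N}).  The attribute
#'   \code{corrected} records whether \code{\link{apply_pmin}} has been run.
#' @seealso \code{\link{read_freq_table}}, \code{\link{apply_pmin}}
#' @export
freq_table <- function(df) {
  required <- c("locus", "allele", "frequency", "n_typed")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("frequency table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$locus <- as.character(df$locus)
  df$allele <- as.character(df$allele)
  df$frequency <- as.numeric(df$frequency)
  df$n_typed <- as.numeric(df$n_typed)
  if (anyNA(df$frequency) || any(df$frequency < 0) || any(df$frequency > 1)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  if (anyNA(df$n_typed) || any(df$n_typed <= 0)) {
    stop("n_typed must be a positive count")
  }
  if (anyDuplicated(df[, c("locus", "allele")])) {
    stop("duplicate (locus, allele) rows in frequency table")
  }
  loci <- split(df, factor(df$locus, levels = unique(df$locus)))
  out <- lapply(loci, function(d) {
    if (nrow(d) < 2L) {
      stop("locus ", d$locus[1L], " has fewer than 2 alleles")
    }
    if (length(unique(d$n_typed)) != 1L) {
      stop("n_typed differs within locus ", d$locus[1L])
    }
    n <- d$n_typed[1L]
    list(alleles = d$allele,
         freq = d$frequency,
         n_typed = n,
         p_min = 5 / (2 * n))
  })
  structure(out, class = "freq_table", corrected = FALSE)
}

#' Read an allele-frequency table from CSV
#'
#' The canonical dialect is long format: one row per allele with header
#' \code{locus,allele,frequency,n_typed}, UTF-8 encoded.
#'
#' @param path path to a CSV file.
#' @return A \code{\link{freq_table}} with raw (uncorrected) frequencies.
#' @export
read_freq_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c(allele = "character"),
                        fileEncoding = "UTF-8")
  freq_table(df)
}

#' Write an allele-frequency table to CSV
#'
#' @param table a \code{\link{freq_table}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_freq_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' @export
as.data.frame.freq_table <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(l) {
    data.frame(locus = l,
               allele = x[[l]]$alleles,
               frequency = x[[l]]$freq,
               n_typed = x[[l]]$n_typed,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.freq_table <- function(x, ...) {
  state <- if (isTRUE(attr(x, "corrected"))) "p_min-corrected" else "raw"
  cat(sprintf("Allele-frequency table (%s): %d loci\n", state, length(x)))
  for (l in names(x)) {
    cat(sprintf("  %-10s %2d alleles, N = %g, p_min = %.5g\n",
                l, length(x[[l]]$alleles), x[[l]]$n_typed, x[[l]]$p_min))
  }
  invisible(x)
}

#' Locus names of a frequency table
#' @param table a \code{\link{freq_table}}.
#' @return character vector of locus names.
#' @export
ft_loci <- function(table) names(table)

#' Apply the minimum-allele-frequency correction
#'
#' Frequencies below the conservative floor \eqn{p_{min} = 5/2N} (where
#' \eqn{N} is the number of individuals typed at the locus) are raised to
#' \eqn{p_{min}}, guarding against rare alleles unobserved in the reference
#' sample.  Each locus is then renormalized to sum to one, so that all
#' downstream genotype probabilities are proper.  The operation is
#' idempotent: corrected tables are returned unchanged.
#'
#' @param table a \code{\link{freq_table}}.
#' @return The corrected table, with attributes \code{corrected = TRUE} and
#'   \code{n_rare}, a named integer vector counting floored alleles per
#'   locus.
#' @export
apply_pmin <- function(table) {
  stopifnot(inherits(table, "freq_table"))
  # renormalization can push a floored frequency fractionally below the
  # floor again, so idempotence is by construction: corrected tables are
  # final.
  if (isTRUE(attr(table, "corrected"))) return(table)
  n_rare <- integer(length(table))
  names(n_rare) <- names(table)
  out <- table
  for (l in names(table)) {
    loc <- table[[l]]
    if (loc$n_typed <= 0) stop("n_typed must be positive at locus ", l)
    rare <- loc$freq < loc$p_min
    n_rare[[l]] <- sum(rare)
    p <- pmax(loc$freq, loc$p_min)
    out[[l]]$freq <- p / sum(p)
  }
  attr(out, "corrected") <- TRUE
  attr(out, "n_rare") <- n_rare
  out
}

## Frequencies for one locus, failing loudly on unknown loci/alleles.
locus_entry <- function(table, locus) {
  loc <- table[[locus]]
  if (is.null(loc)) stop("locus not in frequency table: ", locus)
  loc
}

## Map allele labels to ladder indices at a locus.
allele_index <- function(table, locus, alleles) {
  loc <- locus_entry(table, locus)
  idx <- match(as.character(alleles), loc$alleles)
  if (anyNA(idx)) {
    stop("allele(s) not in ladder of ", locus, ": ",
         paste(alleles[is.na(idx)], collapse = ", "))
  }
  idx
}
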