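test_that("bin_index rounds half away from zero with noise absorption", {
  expect_identical(dynlr:::bin_index(0, 0.001), 0L)
  expect_identical(dynlr:::bin_index(0.0014, 0.001), 1L)
  expect_identical(dynlr:::bin_index(0.0015, 0.001), 2L)
  expect_identical(dynlr:::bin_index(0.3010, 0.001), 301L)
  # 0.0005 - eps, noise just under the boundary, still lands in bin 1
  expect_identical(dynlr:::bin_index(0.0005 - 1e-16, 0.001), 1L)
  expect_identical(dynlr:::bin_index(c(0, 0.001, 0.002), 0.001), 0:2)
})

test_that("a 10-allele ladder yields 55 genotypes", {
  set.seed(9)
  p <- as.numeric(rmultinom(1, 1000, rep(1, 10))) / 1000
  df <- data.frame(locus = "L", allele = as.character(seq_len(10)),
                   frequency = p, n_typed = 500)
  gt <- dynlr:::enumerate_genotypes(apply_pmin(freq_table(df)), "L")
  expect_identical(nrow(gt), 55L)
  expect_identical(sum(gt$hom), 10L)
  expect_equal(sum(gt$prob), 1)                 # genotypes partition
  expect_true(all(gt$mass > 0 & gt$mass < 1))
  expect_true(all(gt$loglr >= 0))
})

test_that("single-locus mass function matches exact dyadic arithmetic", {
  # two equifrequent alleles, theta 0: genotypes aa/ab/bb with
  # probabilities 1/4, 1/2, 1/4 and equal match probabilities, so
  # log10 LR = log10(4) for the homozygotes and log10(2) for the het.
  ft <- toy_table()
  pmf <- single_locus_pmf("A", ft, theta = 0)
  d <- as.data.frame(pmf)
  expect_equal(d$log10_lr, c(0.301, 0.602))
  expect_equal(d$mass, c(0.25, 0.125))          # 1/2*1/2 and 2 * 1/4*1/4
  expect_equal(pmf$total_mass, 0.375)
  expect_identical(pmf$max_bin, 602L)
})

test_that("tail inversion conventions on the toy locus", {
  pmf <- single_locus_pmf("A", toy_table(), theta = 0)
  expect_equal(alpha_from_threshold(pmf, 0), 0.375)
  expect_equal(alpha_from_threshold(pmf, 0.5), 0.125)
  expect_equal(alpha_from_threshold(pmf, 0.7), 0)      # beyond support
  expect_equal(threshold_from_alpha(pmf, 0.5), 0)      # budget covers all
  expect_equal(threshold_from_alpha(pmf, 0.2), 0.302)  # drops the 0.25 atom
  expect_equal(threshold_from_alpha(pmf, 0.125), 0.302)
  expect_equal(threshold_from_alpha(pmf, 0.1), 0.603)  # drops everything
  # round trip is conservative for any alpha
  for (a in c(0.5, 0.3, 0.2, 0.125, 0.1, 0.01)) {
    expect_lte(alpha_from_threshold(pmf, threshold_from_alpha(pmf, a)), a)
  }
})

test_that("alpha_from_threshold is nonincreasing in the threshold", {
  ft <- fixture_panel()
  pmf <- convolve_fft(lapply(ft_loci(ft)[1:3], single_locus_pmf, table = ft))
  thr <- seq(0, (pmf$max_bin + 5) * pmf$delta, length.out = 200)
  a <- vapply(thr, alpha_from_threshold, numeric(1), pmf = pmf)
  expect_true(all(diff(a) <= 0))
  expect_equal(a[1], pmf$total_mass)
  expect_equal(a[length(a)], 0)
})

test_that("two-copy convolution equals brute-force pair enumeration", {
  ft <- two_locus_table()
  pmf <- single_locus_pmf("B", ft, theta = 0.01)
  conv <- convolve_fft(list(pmf, pmf))
  # brute force over all 6 x 6 genotype pairs of the locus
  gt <- dynlr:::enumerate_genotypes(ft, "B", theta = 0.01)
  pair_loglr <- outer(gt$loglr, gt$loglr, "+")
  pair_mass <- outer(gt$mass, gt$mass)
  # accumulate into bins the same way single_locus_pmf does, except sums
  # of per-genotype bin indices (binning commutes with convolution on the
  # grid: the convolution adds bin indices, not raw log LRs)
  bins <- outer(dynlr:::bin_index(gt$loglr, 0.001),
                dynlr:::bin_index(gt$loglr, 0.001), "+")
  expected <- numeric(length(conv$mass))
  for (k in seq_along(bins)) {
    expected[bins[k] + 1L] <- expected[bins[k] + 1L] + pair_mass[k]
  }
  expect_lt(max(abs(conv$mass - expected)), 1e-12)
  expect_equal(conv$total_mass, pmf$total_mass^2)
})

test_that("FFT and direct convolution agree to near machine precision", {
  ft <- fixture_panel()
  loci <- ft_loci(ft)
  pmfs <- lapply(loci[1:4], single_locus_pmf, table = ft, n_fft = 32768L)
  f <- convolve_fft(pmfs)
  d <- convolve_direct(pmfs)
  expect_lt(max(abs(f$mass - d$mass)), 1e-12)
  expect_equal(f$delta, d$delta)
  expect_setequal(f$loci, d$loci)
})

test_that("sub-probability product law holds", {
  ft <- fixture_panel()
  pmfs <- lapply(ft_loci(ft)[1:5], single_locus_pmf, table = ft)
  conv <- convolve_fft(pmfs)
  expect_equal(conv$total_mass,
               prod(vapply(pmfs, function(p) p$total_mass, numeric(1))),
               tolerance = 1e-12)
})

test_that("conditional means add across loci", {
  ft <- fixture_panel()
  pmfs <- lapply(ft_loci(ft)[1:4], single_locus_pmf, table = ft)
  conv <- convolve_fft(pmfs)
  m_sum <- sum(vapply(pmfs, function(p) dynlr:::pmf_moments(p)$mean,
                      numeric(1)))
  expect_equal(dynlr:::pmf_moments(conv)$mean, m_sum, tolerance = 1e-9)
  # conditional variances add too (independent loci)
  v_sum <- sum(vapply(pmfs, function(p) dynlr:::pmf_moments(p)$var,
                      numeric(1)))
  expect_equal(dynlr:::pmf_moments(conv)$var, v_sum, tolerance = 1e-9)
})

test_that("aliasing and grid mismatches are refused", {
  ft <- fixture_panel()
  small <- lapply(ft_loci(ft)[1:6], single_locus_pmf, table = ft,
                  n_fft = 4096L)
  expect_error(convolve_fft(small), "aliasing")
  expect_error(convolve_direct(small), "aliasing")
  a <- single_locus_pmf(ft_loci(ft)[1], ft, n_fft = 8192L)
  b <- single_locus_pmf(ft_loci(ft)[2], ft, n_fft = 16384L)
  expect_error(convolve_fft(list(a, b)), "same bin width and array length")
  expect_error(single_locus_pmf(ft_loci(ft)[1], ft, n_fft = 128L),
               "aliasing")
  expect_error(convolve_fft(list()), "empty")
})

test_that("pmf_cache memoizes by loci set regardless of order", {
  ft <- fixture_panel()
  cache <- pmf_cache(ft)
  loci <- ft_loci(ft)[1:3]
  p1 <- cache$get(loci)
  p2 <- cache$get(rev(loci))
  expect_identical(p1, p2)
  s <- cache$stats()
  expect_identical(s[["misses"]], 1L)
  expect_identical(s[["hits"]], 1L)
  expect_equal(p1$mass,
               convolve_fft(lapply(sort(loci), single_locus_pmf,
                                   table = ft))$mass)
})

test_that("negative mass is rejected at construction", {
  expect_error(loglr_pmf(c(0.1, -0.2), 0.001), "negative mass")
})
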