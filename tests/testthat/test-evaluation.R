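test_that("poisson_band follows the stated two-sided convention", {
  b <- poisson_band(10)
  expect_identical(b, c(L = 4, U = 17))
  expect_gte(ppois(b[["U"]], 10) - ppois(b[["L"]] - 1, 10), 0.95)
  b0 <- poisson_band(0.1)
  expect_identical(b0[["L"]], 0)
  # the band widens with the level
  b99 <- poisson_band(10, level = 0.99)
  expect_lte(b99[["L"]], b[["L"]])
  expect_gte(b99[["U"]], b[["U"]])
})

test_that("gap_analysis finds exactly the constructed gaps", {
  # atoms at bins 100 and 200 with nothing between: one gap of 99 bins
  mass <- numeric(1024)
  mass[101] <- 0.3
  mass[201] <- 0.1
  pmf <- loglr_pmf(mass, 0.001)
  g <- gap_analysis(pmf)
  expect_identical(nrow(g), 1L)
  expect_equal(g$start, 0.101)
  expect_equal(g$end, 0.199)
  expect_equal(g$width, 0.099)
  # gaps below min_gap are suppressed; dense support reports none
  expect_identical(nrow(gap_analysis(pmf, min_gap = 0.1)), 0L)
  dense <- loglr_pmf(c(0, rep(0.1, 5)), 0.001)
  expect_identical(nrow(gap_analysis(dense)), 0L)
  # leading/trailing zeros are outside the envelope, not gaps
  expect_error(gap_analysis(pmf, min_gap = 0.0001), "at least one bin")
})

test_that("the toy locus pair has the expected combinatorial gaps", {
  # two independent copies of the toy locus: support at log10 LR
  # {0.602, 0.903, 1.204} (bins 602, 903, 1204); two gaps of width 0.3
  pmf1 <- single_locus_pmf("A", toy_table(), theta = 0)
  pmf <- convolve_fft(list(pmf1, pmf1))
  g <- gap_analysis(pmf, min_gap = 0.2)
  expect_identical(nrow(g), 2L)
  expect_equal(g$width, c(0.3, 0.3))
  expect_equal(pmf$total_mass, 0.375^2)
})

test_that("gaussian_tail_comparison matches hand-computed moments", {
  # two atoms: masses 0.3 at 0.1 and 0.1 at 0.5 (conditional 3/4, 1/4)
  mass <- numeric(2048)
  mass[101] <- 0.3
  mass[501] <- 0.1
  pmf <- loglr_pmf(mass, 0.001)
  res <- gaussian_tail_comparison(pmf)
  expect_equal(res$mean, 0.75 * 0.1 + 0.25 * 0.5)
  expect_equal(res$sd, sqrt(0.75 * 0.25) * 0.4)
  # discrete tail at mean + 1 sd: only the far atom remains
  expect_equal(res$tails$discrete[1], 0.1)
  expect_equal(res$tails$gaussian[1],
               0.4 * pnorm(res$tails$threshold[1], res$mean, res$sd,
                           lower.tail = FALSE))
  # all-at-one-bin mass function has zero variance
  one <- numeric(16); one[5] <- 0.2
  expect_error(gaussian_tail_comparison(loglr_pmf(one, 0.001)),
               "zero-variance")
})

test_that("multi-locus distributions are right-skewed with heavy tails", {
  ft <- panel24()
  pmf <- convolve_fft(lapply(ft_loci(ft)[1:4], single_locus_pmf, table = ft,
                             n_fft = 32768L))
  res <- gaussian_tail_comparison(pmf)
  expect_gt(res$skewness, 0)
  # the discrete far tail exceeds the fitted Gaussian's
  expect_gt(res$tails$discrete[4], res$tails$gaussian[4])
})

test_that("roc_points is exact on separable and degenerate scores", {
  # perfectly separable
  r <- dynlr:::roc_points(c(5, 4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE, FALSE),
                          n_comparisons = 100)
  expect_equal(r$auc[1], 1)
  # perfectly anti-separable
  r2 <- dynlr:::roc_points(c(1, 2, 3, 4, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE),
                           n_comparisons = 100)
  expect_equal(r2$auc[1], 0)
  # constant score: one diagonal step, AUC 1/2
  r3 <- dynlr:::roc_points(rep(1, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
                           n_comparisons = 100)
  expect_equal(r3$auc[1], 0.5)
  expect_true(all(diff(r3$fpr) >= 0))
})

test_that("roc_points agrees with pROC on random scores", {
  set.seed(31)
  is_true <- runif(400) < 0.3
  score <- rnorm(400) + is_true
  ours <- dynlr:::roc_points(score, is_true, n_comparisons = 1000)$auc[1]
  theirs <- as.numeric(pROC::auc(pROC::roc(response = is_true,
                                           predictor = score, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("permuted scores give AUC near one half", {
  set.seed(32)
  is_true <- sample(c(TRUE, FALSE), 4000, replace = TRUE)
  score <- rnorm(4000)
  auc <- dynlr:::roc_points(score, is_true, 4000)$auc[1]
  expect_equal(auc, 0.5, tolerance = 0.05)
})

test_that("run_roc is reproducible and internally consistent", {
  ft <- fixture_panel()
  r1 <- run_roc(ft, db_size = 2000L, stains_per_count = 100L,
                locus_counts = 3:4, seed = 9L)
  r2 <- run_roc(ft, db_size = 2000L, stains_per_count = 100L,
                locus_counts = 3:4, seed = 9L)
  expect_identical(r1$auc, r2$auc)
  expect_named(r1$auc, c("locus-count", "static-lr", "dynamic-lr"))
  expect_true(all(r1$auc >= 0 & r1$auc <= 1))
  # every match's dynamic score is a valid tail probability
  expect_true(all(r1$matches$alpha_star >= 0 &
                  r1$matches$alpha_star <= 1))
  # curves rise from (0,0) to (max fpr, 1)
  for (cv in r1$curves) {
    expect_equal(cv$tpr[1], 0)
    expect_equal(cv$tpr[nrow(cv)], 1)
    expect_true(all(diff(cv$fpr_rel) >= 0))
  }
})

test_that("run_calibration output structure and purity", {
  ft <- fixture_panel()
  r1 <- run_calibration(ft, mu_targets = c(1, 4), db_size = 400L,
                        n_stains = 100L, n_batches = 3L, seed = 13L)
  r2 <- run_calibration(ft, mu_targets = c(1, 4), db_size = 400L,
                        n_stains = 100L, n_batches = 3L, seed = 13L)
  expect_identical(r1$batches, r2$batches)
  expect_identical(nrow(r1$batches), 6L)
  expect_identical(r1$summary$mu, c(1, 4))
  expect_true(all(r1$batches$observed >= 0))
  expect_identical(r1$T, 400L * 100L)
  # bands come from poisson_band
  expect_equal(unique(r1$batches[r1$batches$mu == 4, c("L", "U")]),
               data.frame(L = qpois(0.025, 4), U = qpois(0.975, 4)),
               ignore_attr = TRUE)
})

test_that("relatives pass the threshold more often than strangers", {
  ft <- panel24()
  out <- relatives_passthrough(ft, db_size = 400L, n_stains = 100L,
                               locus_counts = c(4L, 6L), mu = 1,
                               seed = 17L)
  expect_setequal(out$relationship,
                  c("unrelated", "parent-child", "full-sibling"))
  expect_true(all(out$reviewed <= out$detected))
  # siblings are detected (raw full matches) far more often than
  # parent-child at equal locus counts, and both more than chance alone
  sib <- out[out$relationship == "full-sibling", ]
  par <- out[out$relationship == "parent-child", ]
  expect_true(all(sib$detected >= par$detected))
  expect_gt(sum(sib$detected), 0)
})
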