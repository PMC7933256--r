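test_that("Spearman correlation handles monotone, antitone and tied data", {
  expect_equal(spearmanTest(1:4, c(10, 20, 30, 40))$r, 1)
  expect_equal(spearmanTest(1:4, c(4, 3, 2, 1))$r, -1)
  expect_error(spearmanTest(1:5, rep(2, 5)), "constant")
  expect_error(spearmanTest(1:4, 1:5), "equal length")
})

test_that("exact Spearman permutation p matches a brute-force enumeration
           oracle, including under ties", {
  set.seed(91)
  cases <- list(
    list(x = c(3, 1, 4, 1, 5, 9, 2), y = c(2, 7, 1, 8, 2, 8, 1)),  # ties
    list(x = stats::rnorm(6), y = stats::rnorm(6)),
    list(x = c(1, 2, 2, 3, 4), y = c(5, 5, 4, 3, 1)))
  for (cs in cases) {
    res <- spearmanTest(cs$x, cs$y)
    expect_equal(res$method, "exact permutation")
    expect_equal(res$p, bruteSpearmanP(cs$x, cs$y), tolerance = 1e-12)
    expect_equal(res$r, stats::cor(cs$x, cs$y, method = "spearman"),
                 tolerance = 1e-12)
  }
  ## tie-free case: agrees with the classical exact distribution in cor.test
  x <- c(2, 9, 1, 5, 7, 3); y <- c(1, 8, 3, 4, 9, 2)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = TRUE))
  expect_equal(spearmanTest(x, y)$p, ct$p.value, tolerance = 1e-12)
})

test_that("large-sample Spearman uses the t approximation", {
  set.seed(92)
  x <- stats::rnorm(50); y <- x + stats::rnorm(50)
  res <- spearmanTest(x, y)
  expect_equal(res$method, "t approximation")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-9)
})

test_that("Pearson correlation matches the closed-form product-moment
           formula", {
  expect_equal(pearsonTest(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearsonTest(1:10, -(1:10))$r, -1)
  set.seed(93)
  x <- stats::rnorm(5); y <- stats::rnorm(5)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonTest(x, y)$r, hand, tolerance = 1e-12)
})

test_that("Student's t test matches the pooled-variance hand computation", {
  res <- tTest2(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)

  same <- tTest2(c(2, 4, 6), c(2, 4, 6), paired = TRUE)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(tTest2(c(1, 2, 3), c(0, 1, 2), paired = TRUE), "degenerate")
  expect_error(tTest2(1, c(1, 2)), "at least 2")

  ## Welch flag against stats::t.test
  set.seed(94)
  a <- stats::rnorm(8); b <- stats::rnorm(12, sd = 3)
  expect_equal(tTest2(a, b, equalVariance = FALSE)$p,
               stats::t.test(a, b)$p.value, tolerance = 1e-12)
})

test_that("Wilcoxon rank-sum matches exact enumeration of group
           assignments", {
  res <- wilcoxonTest(c(1, 2, 3), c(4, 5, 6), mode = "rank_sum")
  expect_equal(res$statistic, 6)          # most extreme rank sum
  expect_equal(res$p, 0.1, tolerance = 1e-12)  # 2 / choose(6, 3)

  ## tie-free case agrees with stats::wilcox.test exact p (W = U + offset)
  set.seed(95)
  a <- stats::rnorm(5); b <- stats::rnorm(6)
  res2 <- wilcoxonTest(a, b, mode = "rank_sum")
  wt <- stats::wilcox.test(a, b, exact = TRUE)
  expect_equal(res2$p, wt$p.value, tolerance = 1e-12)
})

test_that("Wilcoxon signed-rank matches full sign-pattern enumeration", {
  set.seed(96)
  a <- stats::rnorm(8); b <- a + stats::rnorm(8)
  res <- wilcoxonTest(a, b, mode = "signed_rank")
  ## independent oracle: enumerate all 2^n sign assignments directly
  d <- a - b; d <- d[d != 0]; rk <- rank(abs(d)); n <- length(d)
  Vall <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    Vall[m + 1] <- sum(rk[signs == 1])
  }
  V <- sum(rk[d > 0])
  pOracle <- 2 * min(mean(Vall <= V), mean(Vall >= V))
  expect_equal(res$statistic, V)
  expect_equal(res$p, pOracle, tolerance = 1e-12)
  expect_equal(res$p, stats::wilcox.test(a, b, paired = TRUE,
                                         exact = TRUE)$p.value,
               tolerance = 1e-12)

  expect_error(wilcoxonTest(c(1, 2), c(1, 2), mode = "signed_rank"),
               "zero")
})

test_that("chi-square matches the direct sum over cells", {
  res0 <- chiSquareTest(rbind(c(10, 10), c(10, 10)))
  expect_equal(res0$chisq, 0)
  expect_equal(res0$p, 1)

  res1 <- chiSquareTest(rbind(c(20, 0), c(0, 20)))
  expect_equal(res1$chisq, 40, tolerance = 1e-12)
  expect_equal(res1$df, 1)

  set.seed(97)
  tab <- matrix(rpois(8, 12), nrow = 2)
  res <- chiSquareTest(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  hand <- 0
  for (i in 1:2) for (j in 1:4) hand <- hand + (tab[i, j] - E[i, j])^2 / E[i, j]
  expect_equal(res$chisq, hand, tolerance = 1e-12)
  expect_error(chiSquareTest(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("the association report is complete, flagged and
           order-invariant", {
  tab <- generateCohortTable(n = 40, seed = 11)
  rep1 <- lvaAssociation(tab)
  expect_s3_class(rep1, "associationReport")
  expect_equal(nrow(rep1$countCorrelations), 9L)  # 6 D + LAV + ASI + LAS
  expect_equal(nrow(rep1$pairwiseCorrelations), choose(9, 2))
  expect_equal(nrow(rep1$groupContrasts), 6L)

  set.seed(12)
  perm <- sample(nrow(tab))
  rep2 <- lvaAssociation(tab[perm, ])
  expect_equal(rep2$countCorrelations, rep1$countCorrelations)
  expect_equal(rep2$burden, rep1$burden)
  expect_equal(rep2$groupContrasts, rep1$groupContrasts)
})

test_that("degenerate cohorts yield not-computable entries instead of
           errors", {
  tab <- generateCohortTable(n = 12, seed = 13)
  lvaCols <- paste0("lva_", segmentNames())
  tab[, lvaCols] <- 0L
  tab$lva_segment_count <- 0L
  rep0 <- lvaAssociation(tab)
  expect_true(all(is.na(rep0$countCorrelations$r)))
  expect_true(all(!rep0$groupContrasts$computable))
})

test_that("an effect cohort yields a positive significant deformation
           burden association", {
  tab <- generateCohortTable(n = 100, seed = 21)
  rep1 <- lvaAssociation(tab)
  expect_gt(rep1$burden$r, 0)
  expect_lt(rep1$burden$p, 0.05)
})

test_that("cohort tables are validated strictly", {
  tab <- generateCohortTable(n = 10, seed = 14)
  bad <- tab; bad$lva_segment_count[1] <- bad$lva_segment_count[1] + 1L
  expect_error(validateCohortTable(bad), "label sum")
  bad2 <- tab; bad2$patient[2] <- bad2$patient[1]
  expect_error(validateCohortTable(bad2), "duplicated")
  expect_error(validateCohortTable(tab[, -2]), "missing columns")
})
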