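# Rank tests, exact tests, correlations, BH-FDR, median CIs, group tables.
# Enumeration oracles live in helper-oracles.R.

test_that("Wilcoxon matches exact enumeration on small samples", {
  tr <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tr$p, 0.1, tolerance = 1e-12)
  expect_equal(tr$p, enumWilcoxP(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)
  set.seed(31)
  for (i in 1:10) {
    x <- round(rnorm(sample(3:6, 1)), 3)
    y <- round(rnorm(sample(3:6, 1), 0.5), 3)
    if (length(x) + length(y) > 12 || anyDuplicated(c(x, y))) next
    expect_equal(wilcoxonRankSum(x, y)$p, enumWilcoxP(x, y),
                 tolerance = 1e-10)
  }
})

test_that("Wilcoxon approximation is close to exact at n = 8 vs 8", {
  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(8)
    y <- rnorm(8, 0.4)
    approxP <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(approxP - enumWilcoxP(x, y)), 0.02)
  }
})

test_that("identical samples give a near-one Wilcoxon p", {
  x <- c(1, 2, 3, 4, 5)
  expect_gte(wilcoxonRankSum(x, x)$p, 0.99)
  expect_error(wilcoxonRankSum(numeric(0), 1:3), "invalid-input")
})

test_that("Kruskal-Wallis behaves like Wilcoxon for two groups", {
  set.seed(7)
  x <- rnorm(12)
  y <- rnorm(12, 0.8)
  pKW <- kruskalWallisTest(list(x, y))$p
  pW <- suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
  expect_lt(abs(pKW - pW), 0.02)
  expect_equal(kruskalWallisTest(list(c(2, 2, 2), c(2, 2)))$statistic,
               0, ignore_attr = TRUE)
  expect_error(kruskalWallisTest(list(1:3)), "invalid-input")
})

test_that("Kruskal-Wallis p is close to a permutation oracle", {
  set.seed(11)
  groups <- list(rnorm(5), rnorm(5, 0.8), rnorm(5, 1.2))
  pKW <- kruskalWallisTest(groups)$p
  pooled <- unlist(groups)
  gl <- rep(1:3, each = 5)
  stat <- function(gl) kruskal.test(split(pooled, gl))$statistic
  obs <- stat(gl)
  perms <- replicate(10000, stat(sample(gl)))
  pPerm <- mean(perms >= obs - 1e-12)
  expect_lt(abs(pKW - pPerm), 0.03)
})

test_that("Fisher 2x2 matches hypergeometric enumeration", {
  tab <- matrix(c(1, 11, 9, 3), 2, 2)
  expect_equal(fisherExactTest(tab)$p, enumFisherP(tab),
               tolerance = 1e-10)
  set.seed(13)
  for (i in 1:8) {
    tab <- matrix(rpois(4, 5), 2, 2)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      next
    expect_equal(fisherExactTest(tab)$p, enumFisherP(tab),
                 tolerance = 1e-9)
  }
})

test_that("degenerate Fisher tables are a no-test with p = 1", {
  tr <- fisherExactTest(matrix(c(3, 5, 0, 0), 2, 2))
  expect_equal(tr$p, 1)
  expect_error(fisherExactTest(matrix(0, 2, 2)), "all-zero")
})

test_that("Monte-Carlo r x c Fisher p agrees with full enumeration", {
  tab <- matrix(c(3, 1, 2, 2, 1, 4), 2, 3)
  # enumerate all 2x3 tables with the observed margins
  r <- rowSums(tab); cs <- colSums(tab)
  logFact <- lfactorial
  prTab <- function(t1) {
    t2 <- cs - t1
    if (any(t2 < 0)) return(NA_real_)
    exp(sum(logFact(r)) + sum(logFact(cs)) - logFact(sum(tab)) -
          sum(logFact(c(t1, t2))))
  }
  pObs <- prTab(tab[1, ])
  tot <- 0
  for (a in 0:min(r[1], cs[1]))
    for (b in 0:min(r[1] - a, cs[2])) {
      cc <- r[1] - a - b
      if (cc > cs[3]) next
      p <- prTab(c(a, b, cc))
      if (!is.na(p) && p <= pObs * (1 + 1e-7)) tot <- tot + p
    }
  pMC <- fisherExactTest(tab, B = 100000, seed = 10)$p
  expect_lt(abs(pMC - tot), 0.01)
})

test_that("Spearman follows the closed form and monotone invariance", {
  set.seed(17)
  x <- rnorm(6)
  y <- rnorm(6)
  rho <- spearmanCorrelation(x, y)$statistic
  d <- rank(x) - rank(y)
  expect_equal(unname(rho), 1 - 6 * sum(d^2) / (6 * 35), tolerance = 1e-12)
  expect_equal(unname(spearmanCorrelation(x, exp(x))$statistic), 1)
  expect_equal(unname(spearmanCorrelation(x, -x)$statistic), -1)
  expect_error(spearmanCorrelation(x, rep(1, 6)), "undefined-correlation")
  expect_error(spearmanCorrelation(1:3, 1:3), "invalid-input")
})

test_that("BH adjustment matches the step-up definition", {
  stepUp <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(1, q)[order(o)]
  }
  expect_equal(bhAdjust(rep(0.03, 5))$q, rep(0.03, 5))
  set.seed(19)
  for (i in 1:10) {
    p <- runif(10)
    adj <- bhAdjust(p)
    expect_equal(adj$q, stepUp(p), tolerance = 1e-12)
    expect_identical(adj$significant, adj$q < 0.10)
    # monotone in p
    o <- order(p)
    expect_true(all(diff(adj$q[o]) >= -1e-12))
  }
  expect_equal(bhAdjust(numeric(0) + 0.5)$threshold, 0.10)
  expect_error(bhAdjust(c(0.2, 1.4)), "invalid-input")
})

test_that("median CI reproduces the printed inflammatory-group PSA", {
  clin <- loadClinicalCSV(clinicalFixturePath())
  iv <- clin[clin$metabotype == "IV", ]
  expect_equal(nrow(iv), 7L)
  ci <- medianCI(iv$psa)
  expect_equal(ci$median, 738)
  expect_true(ci$lower <= 738 && ci$upper >= 738)
})

test_that("median CI handles degenerate inputs and has coverage", {
  ci <- medianCI(rep(4.2, 6))
  expect_equal(c(ci$lower, ci$median, ci$upper), rep(4.2, 3))
  expect_error(medianCI(numeric(0)), "invalid-input")
  set.seed(23)
  hits <- vapply(1:10000, function(i) {
    ci <- medianCI(rnorm(20))
    ci$lower <= 0 && ci$upper >= 0
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("group-vs-rest comparison flags the planted directions", {
  hits <- vapply(1:10, function(s) {
    coh <- generateCohort(cohortConfig(seed = 500 + s))
    g <- coh$clinical$metabotype_true
    res <- compareGroupVsRest(coh$truth, g, "IV")
    gA <- res[res$feature == "GlycA", ]
    gB <- res[res$feature == "GlycB", ]
    hi <- res[res$feature == "histidine", ]
    isTRUE(gA$significant) && gA$direction > 0 &&
      isTRUE(gB$significant) && gB$direction > 0 &&
      isTRUE(hi$significant) && hi$direction < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("constant features are excluded with a flag", {
  set.seed(3)
  X <- cbind(flatFeat = rep(1, 20), good = rnorm(20))
  res <- compareGroupVsRest(X, rep(c("a", "b"), 10), "a")
  expect_equal(res$note[res$feature == "flatFeat"], "constant-feature")
  expect_true(is.na(res$p[res$feature == "flatFeat"]))
  res1 <- compareGroupVsRest(X, c("a", rep("b", 19)), "a")
  expect_match(attr(res1, "warning"), "fewer than 2")
  expect_error(compareGroupVsRest(X, rep("b", 20), "a"), "empty")
})

test_that("cohort summary reproduces the printed group shares", {
  clin <- loadClinicalCSV(clinicalFixturePath())
  # printed NCCN classification (not the derived mapper) shapes the table
  clin$risk_group <- clin$nccn_printed
  sm <- summarizeCohort(clin, clin$metabotype)
  expect_equal(unname(sm$n[sm$groups == "IV"]), 7)
  nccn <- sm$rows$nccn
  expect_equal(unname(nccn$counts["Very high", "IV"]), 5)
  expect_equal(unname(nccn$percent["Very high", "IV"]), 71.4)
  gl <- sm$rows$gleason
  expect_equal(unname(gl$counts["5 + 5", "IV"]), 3)
  expect_equal(unname(gl$percent["5 + 5", "IV"]), 42.9)
  anc <- sm$rows$ancestry
  expect_equal(unname(anc$percent["Black", "IV"]), 42.9)
  # percentages per group sum to ~100
  sums <- colSums(nccn$percent, na.rm = TRUE)
  expect_true(all(abs(sums[sm$n > 0] - 100) <= 0.2))
  expect_equal(sm$rows$psa$perGroup$IV$median, 738)
  # empty input
  empty <- summarizeCohort(data.frame(), character(0))
  expect_length(empty$rows, 0L)
})
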