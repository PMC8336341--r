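# Proximity learning, embedding, Ward tree, k selection, severity ordering.

test_that("proximity matrix satisfies its invariants on random data", {
  set.seed(10)
  X <- matrix(rnorm(12 * 4), 12, 4)
  P <- kodamaProximity(X, iterations = 20, seed = 2)
  expect_equal(P, t(P))
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(unname(diag(P)), rep(1, 12))
})

test_that("well-separated blobs give block-structured proximity", {
  set.seed(1)
  X <- rbind(matrix(rnorm(10 * 5), 10, 5),
             matrix(rnorm(10 * 5, mean = 10), 10, 5))
  P <- kodamaProximity(X, iterations = 100, seed = 7)
  within <- c(P[1:10, 1:10][upper.tri(diag(10))],
              P[11:20, 11:20][upper.tri(diag(10))])
  expect_gte(mean(within), 0.9)
  expect_lte(mean(P[1:10, 11:20]), 0.1)
})

test_that("a duplicated sample co-classifies with its twin", {
  set.seed(1)
  X <- rbind(matrix(rnorm(10 * 5), 10, 5),
             matrix(rnorm(10 * 5, mean = 10), 10, 5))
  X2 <- rbind(X, X[1, , drop = FALSE])
  P <- kodamaProximity(X2, iterations = 50, seed = 3)
  expect_gte(P[1, 21], 0.99)
})

test_that("proximity learning is deterministic under a fixed seed", {
  set.seed(2)
  X <- matrix(rnorm(15 * 6), 15, 6)
  expect_identical(kodamaProximity(X, iterations = 25, seed = 9),
                   kodamaProximity(X, iterations = 25, seed = 9))
  expect_error(kodamaProximity(X[1:5, ]), "too-few-samples")
})

test_that("all-ones proximity embeds to coincident points", {
  P <- matrix(1, 9, 9)
  sc <- kodamaScores(P)
  expect_equal(dim(sc), c(9L, 2L))
  expect_lt(max(dist(sc)), 1e-9)
})

test_that("embedded distances track the learned dissimilarity", {
  # moderate separations give a graded proximity; a perfectly binary
  # proximity would cap the rank correlation through ties alone
  tpl <- lapply(defaultEffectTemplate(), function(v) v * 0.4)
  coh <- generateCohort(cohortConfig(seed = 77, effectTemplate = tpl))
  Xp <- prepareFeatures(coh$truth)
  P <- kodamaProximity(Xp, iterations = 60, seed = 4)
  rho <- suppressWarnings(
    cor(as.vector(dist(kodamaScores(P))), as.vector(as.dist(1 - P)),
        method = "spearman"))
  expect_gte(rho, 0.8)
})

test_that("Ward tree matches a brute-force Lance-Williams recursion", {
  lwWard <- function(X) {
    # naive Ward.D2 agglomeration oracle
    n <- nrow(X)
    D <- as.matrix(dist(X))
    active <- seq_len(n)
    size <- rep(1, n)
    heights <- numeric(n - 1)
    for (m in seq_len(n - 1)) {
      sub <- D[active, active, drop = FALSE]
      sub[lower.tri(sub, diag = TRUE)] <- Inf
      ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      i <- active[ij[1]]; j <- active[ij[2]]
      heights[m] <- D[i, j]
      ni <- size[i]; nj <- size[j]
      for (kx in setdiff(active, c(i, j))) {
        nk <- size[kx]
        D[i, kx] <- D[kx, i] <- sqrt(((ni + nk) * D[i, kx]^2 +
          (nj + nk) * D[j, kx]^2 - nk * D[i, j]^2) / (ni + nj + nk))
      }
      size[i] <- ni + nj
      active <- setdiff(active, j)
    }
    sort(heights)
  }
  set.seed(6)
  for (n in c(5, 8)) {
    X <- matrix(rnorm(n * 3), n, 3)
    tree <- wardTree(X)
    expect_equal(sort(tree$height), lwWard(X), tolerance = 1e-8)
    expect_true(all(diff(sort(tree$height)) >= -1e-12))
  }
})

test_that("Ward tree base cases and permutation invariance", {
  X <- rbind(c(0, 0), c(3, 4))
  tree <- wardTree(X)
  expect_equal(tree$height, 5)
  expect_error(wardTree(X[1, , drop = FALSE]), "invalid-input")
  set.seed(8)
  X <- matrix(rnorm(14), 7, 2)
  perm <- sample(7)
  t1 <- wardTree(X)
  t2 <- wardTree(X[perm, ])
  expect_equal(sort(t1$height), sort(t2$height), tolerance = 1e-10)
  for (k in 2:4) {
    # same partition up to label names
    p1 <- cutree(t1, k)
    p2 <- cutree(t2, k)[order(perm)]
    expect_equal(unname(outer(p1, p1, "==")), unname(outer(p2, p2, "==")))
  }
})

test_that("median silhouette picks the planted number of clusters", {
  set.seed(2)
  ctr <- matrix(c(0, 0, 6, 0, 0, 6, 6, 6), 4, 2, byrow = TRUE)
  X4 <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(15 * 2), 15, 2), 2, ctr[i, ], "+")))
  sel <- chooseKBySilhouette(X4, wardTree(X4))
  expect_equal(sel$k, 4)
  expect_true(all(sel$medians >= -1 & sel$medians <= 1))
  expect_named(sel$medians, as.character(2:10))
  set.seed(3)
  X2 <- rbind(matrix(rnorm(30), 15, 2),
              matrix(rnorm(30, mean = 8), 15, 2))
  expect_equal(chooseKBySilhouette(X2, wardTree(X2))$k, 2)
})

test_that("kmax shrinks with a warning when n is small", {
  set.seed(5)
  X <- matrix(rnorm(16), 8, 2)
  expect_warning(sel <- chooseKBySilhouette(X, wardTree(X)), "kmax")
  expect_lte(sel$k, 7)
})

test_that("metabotype ordering follows severity, then PSA, then size", {
  labels <- rep(c("a", "b", "c", "d"), times = c(10, 10, 11, 7))
  risk <- c(rep("low", 10),
            rep(c("very_high", "low"), times = c(2, 8)),
            rep(c("very_high", "low"), times = c(4, 7)),
            rep(c("very_high", "metastatic"), times = c(6, 1)))
  psa <- rep(5, length(labels))
  out <- orderMetabotypes(labels, risk, psa)
  expect_equal(as.character(unique(out[labels == "a"])), "I")
  expect_equal(as.character(unique(out[labels == "b"])), "II")
  expect_equal(as.character(unique(out[labels == "c"])), "III")
  expect_equal(as.character(unique(out[labels == "d"])), "IV")
  # permutation of input cluster ids leaves the output invariant
  relabel <- c(a = "z", b = "q", c = "m", d = "k")[labels]
  expect_equal(as.character(orderMetabotypes(relabel, risk, psa)),
               as.character(out))
  # equal severity and PSA: larger cluster gets the smaller numeral
  lab2 <- rep(c("x", "y"), times = c(4, 8))
  out2 <- orderMetabotypes(lab2, rep("low", 12), rep(1, 12))
  expect_equal(as.character(unique(out2[lab2 == "y"])), "I")
  expect_equal(as.character(unique(out2[lab2 == "x"])), "II")
  expect_error(orderMetabotypes(lab2, c(NA, rep("low", 11))), "missing")
})

test_that("end-to-end discovery recovers the planted metabotypes", {
  skip_if_not(hasMclust)
  coh <- generateCohort(cohortConfig(seed = 42))
  clin <- withRisk(coh$clinical)
  mt <- discoverMetabotypes(coh$truth, clinical = clin, seed = 3)
  expect_s4_class(mt, "MetabotypeResult")
  expect_equal(chosenK(mt), 4L)
  expect_gte(mclust::adjustedRandIndex(metabotypeLabels(mt),
                                       clin$metabotype_true), 0.9)
  # severity ordering puts the planted IV group last
  tab <- table(metabotypeLabels(mt), clin$metabotype_true)
  expect_gte(tab["IV", "IV"], 13)
  # determinism of the full path
  mt2 <- discoverMetabotypes(coh$truth, clinical = clin, seed = 3)
  expect_identical(metabotypeLabels(mt), metabotypeLabels(mt2))
  expect_identical(proximityMatrix(mt), proximityMatrix(mt2))
})
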