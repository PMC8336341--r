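# Unsupervised metabotype discovery: proximity learning by iterative
# cross-validated accuracy maximisation (KODAMA-style, k-nearest-neighbour
# core classifier), metric MDS of the learned dissimilarity, Ward (D2)
# dendrogram, median-silhouette choice of k in [2, 10], and severity-ordered
# roman-numeral labels.

#' Prepare a feature matrix for proximity learning
#'
#' Per-feature median imputation of missing values, a variance-stabilising
#' \code{log(1 + x / median)} transform and autoscaling (zero mean, unit SD).
#' The three inflammation marker features (GlycA, GlycB, protein amides)
#' are excluded from the clustering input by default; constant features are
#' dropped.
#'
#' @param features a feature table from \code{\link{buildFeatureTable}} or a
#'   samples x features matrix.
#' @param excludeMarkers logical; drop GlycA/GlycB/protein_amides columns.
#' @return autoscaled samples x features matrix.
#' @export
prepareFeatures <- function(features, excludeMarkers = TRUE) {
  X <- featureMatrix(features)
  if (excludeMarkers)
    X <- X[, !colnames(X) %in% c("GlycA", "GlycB", "protein_amides"),
           drop = FALSE]
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    if (anyNA(v)) v[is.na(v)] <- median(v, na.rm = TRUE)
    med <- median(v)
    if (med > 0) v <- log1p(v / med)
    X[, j] <- v
  }
  sds <- apply(X, 2, sd)
  X <- X[, sds > 0, drop = FALSE]
  scale(X)
}

# k-NN prediction of labels for `test` indices from `train` indices, using
# the precomputed distance matrix `D` and neighbour ordering `ord` (row i:
# all other samples sorted by distance from i).  Votes are discounted
# linearly by neighbour rank (k, ..., 1; triangular kernel) -- majority-like
# smoothing inside a cluster while the farthest (potentially cross-cluster)
# neighbours cannot outvote a tight local neighbourhood; ties go to the nearest tied class.
.knnPredict <- function(D, ord, labels, train, test, k) {
  inTrain <- logical(nrow(ord))
  inTrain[train] <- TRUE
  kk <- min(k, length(train))
  w <- rev(seq_len(kk))
  lev <- unique(labels)
  code <- match(labels, lev)
  nT <- length(test)
  # neighbour label codes: nT x kk matrix of the k nearest training points
  L <- matrix(0L, nT, kk)
  for (t in seq_len(nT)) {
    nb <- ord[test[t], ]
    L[t, ] <- code[nb[inTrain[nb]][seq_len(kk)]]
  }
  S <- matrix(0, nT, length(lev))
  rows <- seq_len(nT)
  for (j in seq_len(kk))
    S[cbind(rows, L[, j])] <- S[cbind(rows, L[, j])] + w[j]
  top <- max.col(S, ties.method = "first")
  # ties go to the nearest tied class
  for (t in rows) {
    tied <- which(S[t, ] == S[t, top[t]])
    if (length(tied) > 1L)
      top[t] <- L[t, which(L[t, ] %in% tied)[1L]]
  }
  lev[top]
}

#' Learn a co-classification proximity matrix
#'
#' Over \code{iterations} randomised restarts, a label assignment (initially
#' random over at most 20 classes) is refined by iterating a 10-fold
#' cross-validated k-nearest-neighbour self-prediction -- fit on 90\%,
#' predict the held-out 10\%, adopt the predictions as the new labels --
#' until the cross-validated accuracy stops improving (at most
#' \code{maxCycles} cycles).  Final labels of each restart are accumulated
#' into co-membership frequencies; the averaged matrix is returned.
#'
#' @param X autoscaled samples x features matrix (no missing values).
#' @param iterations randomised restarts (default 100).
#' @param innerCvFolds cross-validation folds (default 10).
#' @param seed integer seed; fixes the whole procedure.
#' @param k neighbours for the core classifier (default 10).
#' @param maxCycles refinement cycles per restart (default 20).
#' @param initClasses initial random classes (default: one distinct class
#'   per sample, which keeps far-apart clusters from coalescing onto one
#'   label by chance).
#' @return symmetric n x n proximity matrix in [0, 1] with unit diagonal.
#' @export
kodamaProximity <- function(X, iterations = 100, innerCvFolds = 10,
                            seed = 1L, k = 10, maxCycles = 20,
                            initClasses = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 8L) stop("too-few-samples: proximity learning needs n >= 8")
  set.seed(as.integer(seed))
  if (is.null(initClasses)) initClasses <- n
  D <- as.matrix(dist(X))
  ord <- t(apply(D + diag(Inf, n), 1L, order))[, seq_len(n - 1L),
                                               drop = FALSE]
  P <- matrix(0, n, n)
  for (it in seq_len(iterations)) {
    labels <- as.character(sample.int(initClasses, n,
                                      replace = initClasses < n))
    bestAcc <- -1
    bestLabels <- labels
    for (cycle in seq_len(maxCycles)) {
      # fresh folds every cycle: jiggling the held-out sets anneals away
      # metastable sub-cluster label pockets
      folds <- sample(rep(seq_len(innerCvFolds), length.out = n))
      pred <- character(n)
      for (f in seq_len(innerCvFolds)) {
        test <- which(folds == f)
        if (!length(test)) next
        train <- which(folds != f)
        pred[test] <- .knnPredict(D, ord, labels, train, test, k)
      }
      acc <- mean(pred == labels)
      stable <- identical(pred, labels)
      labels <- pred
      if (acc >= bestAcc) {
        bestAcc <- acc
        bestLabels <- labels
      }
      if (stable) break
    }
    eq <- outer(bestLabels, bestLabels, "==")
    P <- P + eq
  }
  P <- P / iterations
  diag(P) <- 1
  dimnames(P) <- list(rownames(X), rownames(X))
  P
}

#' Score embedding of a proximity matrix
#'
#' Classical metric multidimensional scaling of the dissimilarity
#' \code{1 - P}.  Only the pairwise score distances are meaningful (the
#' embedding has the usual rotation/reflection freedom).  The default two
#' dimensions mirror the usual score plot; clustering uses a fuller
#' embedding (see \code{\link{discoverMetabotypes}}) because k
#' near-equidistant clusters need k - 1 dimensions to stay separated (in
#' 2-D, two of four equidistant clusters can be projected on top of each
#' other).
#'
#' @param P proximity matrix from \code{\link{kodamaProximity}}.
#' @param ndim embedding dimensions (default 2); dimensions beyond the
#'   positive-eigenvalue rank are zero-padded.
#' @return n x ndim score matrix.
#' @export
kodamaScores <- function(P, ndim = 2) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("invalid-input: P must be square")
  D <- 1 - P
  diag(D) <- 0
  ndim <- min(ndim, nrow(P) - 1L)
  sc <- suppressWarnings(cmdscale(D, k = ndim))
  if (ncol(sc) < ndim)
    sc <- cbind(sc, matrix(0, nrow(P), ndim - ncol(sc)))
  rownames(sc) <- rownames(P)
  colnames(sc) <- paste0("score", seq_len(ncol(sc)))
  sc
}

#' Ward dendrogram of the score embedding
#'
#' Agglomerative Ward clustering (D2 convention: squared Euclidean
#' within-cluster variance increase) on the score coordinates.
#'
#' @param scores n x 2 score matrix.
#' @return an \code{hclust} object.
#' @export
wardTree <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop("invalid-input: need at least 2 samples")
  hclust(dist(scores), method = "ward.D2")
}

#' Choose the cluster number by median silhouette
#'
#' Cuts the Ward tree at each k in [kmin, kmax], computes per-sample
#' silhouette widths on Euclidean distances in score space and takes the
#' median; returns the k maximising the median.  Ties go to the smallest
#' k; medians within \code{tol} of the maximum count as tied (a parsimony
#' rule: sub-0.01 differences in median silhouette are not meaningful
#' evidence for extra clusters).
#'
#' @param scores n x 2 score matrix.
#' @param tree the \code{hclust} tree from \code{\link{wardTree}}.
#' @param kmin,kmax candidate range (defaults 2 and 10).
#' @param tol tie tolerance on the median silhouette (default 0.01).
#' @return list: \code{k}, \code{medians} (named numeric over candidates).
#' @export
chooseKBySilhouette <- function(scores, tree, kmin = 2, kmax = 10,
                                tol = 0.01) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n <= kmax) {
    warning("n <= kmax; shrinking kmax to n - 1")
    kmax <- n - 1L
  }
  d <- dist(scores)
  ks <- seq.int(kmin, kmax)
  meds <- vapply(ks, function(k) {
    cl <- cutree(tree, k = k)
    sil <- cluster::silhouette(cl, d)
    median(sil[, "sil_width"])
  }, numeric(1))
  names(meds) <- ks
  list(k = ks[which(meds >= max(meds) - tol)[1L]], medians = meds)
}

#' Order cluster labels by clinical severity
#'
#' Renumbers clusters as metabotypes I..k, ascending in the proportion of
#' very-high-risk plus metastatic members; ties are broken by ascending
#' median PSA, then by descending cluster size.
#'
#' @param labels cluster assignment (integer or factor), one per sample.
#' @param riskGroups character/factor of NCCN-like risk groups per sample
#'   (values among very_low/low/intermediate/high/very_high/metastatic).
#' @param psa numeric PSA per sample (optional, used for tie-breaks).
#' @return factor of roman-numeral metabotype labels, levels I..k.
#' @export
orderMetabotypes <- function(labels, riskGroups, psa = NULL) {
  labels <- as.character(labels)
  if (anyNA(riskGroups)) {
    stop("missing risk groups for sample(s): ",
         paste(which(is.na(riskGroups)), collapse = ", "))
  }
  if (is.null(psa)) psa <- rep(0, length(labels))
  cl <- unique(labels)
  sev <- vapply(cl, function(g)
    mean(riskGroups[labels == g] %in% c("very_high", "metastatic")),
    numeric(1))
  medPsa <- vapply(cl, function(g) median(psa[labels == g]), numeric(1))
  size <- vapply(cl, function(g) sum(labels == g), numeric(1))
  o <- order(sev, medPsa, -size)
  roman <- as.character(utils::as.roman(seq_along(cl)))
  map <- setNames(roman, cl[o])
  factor(map[labels], levels = roman)
}

#' Discover metabotypes in a feature table
#'
#' End-to-end unsupervised stratification: feature preparation
#' (\code{\link{prepareFeatures}}), proximity learning, 2-D scores, Ward
#' dendrogram, median-silhouette choice of k and severity-ordered labels
#' (when clinical risk groups are supplied; otherwise clusters are numbered
#' by decreasing size).
#'
#' @param features feature table (SummarizedExperiment) or samples x
#'   features matrix.
#' @param clinical optional data.frame with columns \code{risk_group} and
#'   \code{psa} aligned with the samples.
#' @param excludeMarkers drop GlycA/GlycB/protein_amides before clustering
#'   (default TRUE).
#' @param iterations,seed,kmin,kmax passed to the underlying steps.
#' @return a \linkS4class{MetabotypeResult}.
#' @export
discoverMetabotypes <- function(features, clinical = NULL,
                                excludeMarkers = TRUE, iterations = 100,
                                seed = 1L, kmin = 2, kmax = 10) {
  X <- prepareFeatures(features, excludeMarkers = excludeMarkers)
  P <- kodamaProximity(X, iterations = iterations, seed = seed)
  sc <- kodamaScores(P)
  # cluster in a fuller embedding: k near-equidistant clusters need k - 1
  # dimensions, so a 2-D projection can superpose two of them
  emb <- kodamaScores(P, ndim = min(nrow(P) - 1L, kmax + 1L))
  tree <- wardTree(emb)
  sel <- chooseKBySilhouette(emb, tree, kmin = kmin, kmax = kmax)
  cl <- cutree(tree, k = sel$k)
  labels <- if (!is.null(clinical)) {
    orderMetabotypes(cl, clinical$risk_group, clinical$psa)
  } else {
    sizes <- table(cl)
    o <- order(-as.numeric(sizes))
    roman <- as.character(utils::as.roman(seq_along(sizes)))
    factor(setNames(roman, names(sizes)[o])[as.character(cl)],
           levels = roman)
  }
  new("MetabotypeResult", proximity = P, scores = sc, dendrogram = tree,
      k = as.integer(sel$k), silhouettes = sel$medians, labels = labels)
}
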