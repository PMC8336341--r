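# PLS discriminant analysis: NIPALS PLS2 against one-hot class labels,
# R2/Q2 by the standard definitions, and nested (double) 10-fold
# cross-validation separating component selection from accuracy estimation.

.oneHot <- function(labels) {
  labels <- factor(labels)
  Y <- matrix(0, length(labels), nlevels(labels),
              dimnames = list(NULL, levels(labels)))
  Y[cbind(seq_along(labels), as.integer(labels))] <- 1
  Y
}

#' Fit a PLS2 model
#'
#' NIPALS partial least squares of autoscaled X against centred one-hot
#' class indicators.  Deterministic; successive score vectors are mutually
#' orthogonal.
#'
#' @param X samples x features matrix.
#' @param labels class label per sample (>= 2 classes).
#' @param ncomp number of latent components
#'   (\code{<= min(n - 1, p)}).
#' @return list with class \code{"plsModel"}: weights/loadings/scores,
#'   centering/scaling vectors, regression coefficients and class levels.
#' @export
plsFit <- function(X, labels, ncomp = 2) {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("invalid-input: need at least 2 classes")
  n <- nrow(X)
  p <- ncol(X)
  if (ncomp > min(n - 1L, p))
    stop("invalid-input: ncomp exceeds min(n - 1, p)")
  mx <- colMeans(X)
  sx <- apply(X, 2, sd)
  sx[sx == 0] <- 1
  Xs <- scale(X, center = mx, scale = sx)
  Y <- .oneHot(labels)
  my <- colMeans(Y)
  Ys <- scale(Y, center = my, scale = FALSE)
  E <- Xs
  F_ <- Ys
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Q <- matrix(0, ncol(Y), ncomp)
  TT <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    u <- F_[, which.max(colSums(F_^2))]
    for (it in seq_len(500)) {
      w <- crossprod(E, u)
      w <- w / sqrt(sum(w^2))
      tt <- E %*% w
      q <- crossprod(F_, tt) / sum(tt^2)
      uNew <- F_ %*% q / sum(q^2)
      if (sum((uNew - u)^2) < 1e-12 * sum(u^2)) {
        u <- uNew
        break
      }
      u <- uNew
    }
    pl <- crossprod(E, tt) / sum(tt^2)
    E <- E - tcrossprod(tt, pl)
    F_ <- F_ - tcrossprod(tt, q)
    W[, a] <- w
    P[, a] <- pl
    Q[, a] <- q
    TT[, a] <- tt
  }
  Wstar <- W %*% solve(crossprod(P, W))
  B <- Wstar %*% t(Q)
  structure(list(ncomp = ncomp, weights = W, loadings = P, yloadings = Q,
                 scores = TT, coefficients = B, xCenter = mx, xScale = sx,
                 yCenter = my, levels = levels(labels)),
            class = "plsModel")
}

#' Predict one-hot responses and classes from a PLS model
#'
#' @param model a \code{"plsModel"} from \code{\link{plsFit}}.
#' @param X samples x features matrix.
#' @return list: \code{yhat} (predicted one-hot scores), \code{class}
#'   (argmax class; ties resolved to the lexicographically first class and
#'   flagged in \code{tied}).
#' @export
plsPredict <- function(model, X) {
  X <- as.matrix(X)
  Xs <- scale(X, center = model$xCenter, scale = model$xScale)
  yhat <- Xs %*% model$coefficients
  yhat <- sweep(yhat, 2, model$yCenter, "+")
  colnames(yhat) <- model$levels
  idx <- lapply(seq_len(nrow(yhat)), function(i)
    which(yhat[i, ] == max(yhat[i, ])))
  tied <- vapply(idx, length, integer(1)) > 1L
  cls <- model$levels[vapply(idx, `[[`, integer(1), 1L)]
  list(yhat = yhat, class = cls, tied = tied)
}

#' R2 and Q2 by the standard definitions
#'
#' \code{R2 = 1 - SSres / SStot} on fitted (training) predictions;
#' \code{Q2 = 1 - PRESS / SStot} on cross-validated (held-out) predictions.
#' Both are computed over the centred one-hot response matrix.
#'
#' @param Yobs observed one-hot matrix (or a factor of labels).
#' @param Yhat predicted one-hot matrix of equal shape.
#' @return the coefficient, a single number.
#' @export
r2q2 <- function(Yobs, Yhat) {
  if (is.factor(Yobs) || is.character(Yobs)) Yobs <- .oneHot(Yobs)
  Yobs <- as.matrix(Yobs)
  Yhat <- as.matrix(Yhat)
  ssTot <- sum(scale(Yobs, scale = FALSE)^2)
  if (ssTot == 0) stop("undefined-metric: zero total variance")
  1 - sum((Yobs - Yhat)^2) / ssTot
}

.stratifiedFolds <- function(labels, nfolds) {
  labels <- factor(labels)
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep(seq_len(nfolds), length.out = length(idx))[
      sample.int(length(idx))]
  }
  fold
}

#' Double (nested) cross-validated PLS-DA performance
#'
#' Outer 10-fold cross-validation gives unbiased class predictions; inside
#' each outer training set an inner 10-fold cross-validation selects the
#' number of components from \code{ncompGrid} by accuracy (ties to fewer
#' components).  Accuracy is pooled over the outer folds; the 95\% interval
#' is the 2.5/97.5 percentile over \code{repeats} repetitions with
#' reshuffled folds.  Q2 comes from the outer-fold (held-out) predictions
#' and R2 from a full-data fit at the modal selected component number.
#'
#' @param X samples x features matrix.
#' @param labels class label per sample.
#' @param outer,inner fold counts (defaults 10/10; shrunk with a warning
#'   when a class is smaller than the fold count).
#' @param ncompGrid candidate component numbers (default 1:5).
#' @param repeats repetitions for the accuracy interval (default 20).
#' @param seed integer seed.
#' @return list: \code{accuracy}, \code{accuracyCI}, \code{R2}, \code{Q2},
#'   \code{ncomp} (modal), \code{perRepeat}, \code{predictions} (first
#'   repeat, per-sample outer-fold predictions).
#' @export
doubleCV <- function(X, labels, outer = 10, inner = 10, ncompGrid = 1:5,
                     repeats = 20, seed = 1L) {
  X <- as.matrix(X)
  labels <- factor(labels)
  n <- nrow(X)
  minClass <- min(table(labels))
  if (minClass < 2L)
    stop("stratified-fold failure: every class needs >= 2 members; ",
         "merge or drop singleton classes")
  if (minClass < outer) {
    warning("smallest class (", minClass, ") < outer folds; shrinking")
    outer <- max(2L, minClass)
  }
  inner <- max(2L, min(inner, minClass - 1L, outer))
  ncompGrid <- ncompGrid[ncompGrid <= min(n - ceiling(n / outer) - 1L,
                                          ncol(X))]
  if (!length(ncompGrid)) ncompGrid <- 1L
  set.seed(as.integer(seed))
  accs <- numeric(repeats)
  q2s <- numeric(repeats)
  ncompSel <- integer(0)
  predFirst <- NULL
  for (rep_ in seq_len(repeats)) {
    foldId <- .stratifiedFolds(labels, outer)
    predClass <- character(n)
    predY <- matrix(NA_real_, n, nlevels(labels))
    for (f in seq_len(outer)) {
      test <- which(foldId == f)
      train <- which(foldId != f)
      innerFold <- .stratifiedFolds(labels[train], inner)
      innerAcc <- vapply(ncompGrid, function(nc) {
        hits <- 0L
        for (g in seq_len(inner)) {
          iTest <- train[innerFold == g]
          iTrain <- train[innerFold != g]
          if (length(unique(labels[iTrain])) < 2L) next
          nc2 <- min(nc, length(iTrain) - 1L)
          m <- plsFit(X[iTrain, , drop = FALSE], labels[iTrain], nc2)
          pr <- plsPredict(m, X[iTest, , drop = FALSE])
          hits <- hits + sum(pr$class == as.character(labels[iTest]))
        }
        hits / length(train)
      }, numeric(1))
      ncBest <- ncompGrid[which.max(innerAcc)]
      ncompSel <- c(ncompSel, ncBest)
      m <- plsFit(X[train, , drop = FALSE], labels[train],
                  min(ncBest, length(train) - 1L))
      pr <- plsPredict(m, X[test, , drop = FALSE])
      predClass[test] <- pr$class
      predY[test, ] <- pr$yhat
    }
    accs[rep_] <- mean(predClass == as.character(labels))
    q2s[rep_] <- r2q2(labels, predY)
    if (rep_ == 1L)
      predFirst <- data.frame(observed = as.character(labels),
                              predicted = predClass,
                              stringsAsFactors = FALSE)
  }
  ncompModal <- as.integer(names(sort(table(ncompSel),
                                      decreasing = TRUE))[1])
  full <- plsFit(X, labels, min(ncompModal, n - 1L))
  R2 <- r2q2(labels, plsPredict(full, X)$yhat)
  list(accuracy = mean(accs),
       accuracyCI = unname(quantile(accs, c(0.025, 0.975))),
       R2 = R2, Q2 = mean(q2s), ncomp = ncompModal, perRepeat = accs,
       predictions = predFirst)
}
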