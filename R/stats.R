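# The statistical layer: rank tests, exact tests, correlations, BH-FDR at
# 10%, order-statistic median CIs, metabotype-vs-rest comparison tables and
# the clinical summary table.  Standard tests are delegated to base R
# behind a uniform TestResult surface.

.testResult <- function(variable, test, statistic, p, q = NA_real_,
                        direction = NA_real_, medians = NULL, note = NULL) {
  structure(list(variable = variable, test = test,
                 statistic = unname(statistic), p = unname(p), q = q,
                 direction = direction, medians = medians, note = note),
            class = "testResult")
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided; exact enumeration when the pooled size is at most 12 and
#' there are no ties, otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param x,y numeric samples.
#' @return a \code{testResult} list (statistic W, p, direction = sign of
#'   median difference).
#' @export
wilcoxonRankSum <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("invalid-input: both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 12L && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  .testResult("x vs y", "wilcoxon_rank_sum", wt$statistic, wt$p.value,
              direction = sign(median(x) - median(y)),
              medians = c(median(x), median(y)))
}

#' Kruskal-Wallis rank-sum test
#'
#' Chi-square approximation with tie correction.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return a \code{testResult} list.
#' @export
kruskalWallisTest <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  if (length(groups) < 2L)
    stop("invalid-input: need at least 2 non-empty groups")
  if (length(unique(unlist(groups))) == 1L)
    return(.testResult("groups", "kruskal_wallis", 0, 1,
                       note = "all observations equal"))
  kt <- kruskal.test(groups)
  .testResult("groups", "kruskal_wallis", kt$statistic, kt$p.value)
}

#' Fisher's exact test
#'
#' 2x2 tables get the exact two-sided hypergeometric p (sum of tables at
#' most as probable as the observed one); larger r x c tables use a seeded
#' Monte-Carlo p (default 100,000 draws).  Rows/columns with zero margins
#' are dropped first; a table that degenerates to a single row or column is
#' no test (p = 1).
#'
#' @param tab matrix of non-negative integer counts.
#' @param B Monte-Carlo draws for r x c tables.
#' @param seed seed for the Monte-Carlo p.
#' @return a \code{testResult} list.
#' @export
fisherExactTest <- function(tab, B = 100000, seed = 1L) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("invalid-input: counts must be non-negative integers")
  if (sum(tab) == 0) stop("invalid-input: all-zero table")
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(.testResult("table", "fisher_exact", NA_real_, 1,
                       note = "degenerate table; no test"))
  if (nrow(tab) == 2L && ncol(tab) == 2L) {
    ft <- fisher.test(tab)
    return(.testResult("table", "fisher_exact", ft$estimate, ft$p.value))
  }
  set.seed(as.integer(seed))
  ft <- fisher.test(tab, simulate.p.value = TRUE, B = as.integer(B))
  .testResult("table", "fisher_exact_mc", NA_real_, ft$p.value,
              note = sprintf("Monte-Carlo p, B = %d", B))
}

#' Spearman rank correlation
#'
#' rho on mid-ranks with the t approximation for the p-value.
#'
#' @param x,y equal-length numeric vectors (n >= 4).
#' @return a \code{testResult} list (statistic = rho).
#' @export
spearmanCorrelation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 4L) stop("invalid-input: need n >= 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined-correlation: constant input vector")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  .testResult("x~y", "spearman", ct$estimate, ct$p.value,
              direction = sign(ct$estimate))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment with monotonicity enforcement; the shipped
#' significance threshold is an FDR of 10\%.
#'
#' @param p numeric p-values in [0, 1].
#' @param threshold significance threshold on q (default 0.10).
#' @return list: \code{q} (adjusted values), \code{significant} (logical
#'   flags at \code{q < threshold}), \code{threshold}.
#' @export
bhAdjust <- function(p, threshold = 0.10) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("invalid-input: p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  list(q = q, significant = q < threshold, threshold = threshold)
}

#' Median with a distribution-free confidence interval
#'
#' The CI comes from binomial order statistics: the smallest symmetric rank
#' pair whose binomial coverage reaches \code{level}.  When n is too small
#' for the nominal coverage the full sample range is returned with
#' \code{fullRange = TRUE}.
#'
#' @param values numeric vector (n >= 1).
#' @param level nominal coverage (default 0.95).
#' @return list: \code{median}, \code{lower}, \code{upper},
#'   \code{fullRange}.
#' @export
medianCI <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (!n) stop("invalid-input: empty vector")
  s <- sort(values)
  m <- median(values)
  if (n == 1L)
    return(list(median = m, lower = s[1], upper = s[1], fullRange = TRUE))
  for (r in floor((n + 1) / 2):1) {
    cover <- pbinom(n - r, n, 0.5) - pbinom(r - 1L, n, 0.5)
    if (cover >= level)
      return(list(median = m, lower = s[r], upper = s[n + 1L - r],
                  fullRange = FALSE))
  }
  list(median = m, lower = s[1], upper = s[n], fullRange = TRUE)
}

#' Compare one metabotype against all others, feature by feature
#'
#' Per-feature two-sided Wilcoxon rank-sum test of the target group versus
#' the rest, Benjamini-Hochberg adjustment across features (FDR threshold
#' 10\%), and the direction of the median difference.  Constant features
#' are excluded with a flag; results are sorted by q.
#'
#' @param features feature table (SummarizedExperiment) or samples x
#'   features matrix.
#' @param labels group label per sample.
#' @param target the group to contrast against the rest.
#' @param threshold FDR threshold (default 0.10).
#' @return data.frame: feature, median_target, median_rest, direction,
#'   p, q, significant, note; attribute \code{"warning"} when the target
#'   group has fewer than 2 members.
#' @export
compareGroupVsRest <- function(features, labels, target,
                               threshold = 0.10) {
  X <- featureMatrix(features)
  labels <- as.character(labels)
  inT <- labels == target
  if (!any(inT)) stop("invalid-input: target group is empty")
  res <- lapply(colnames(X), function(f) {
    x <- X[inT, f]
    y <- X[!inT, f]
    if (sd(c(x, y), na.rm = TRUE) == 0 || all(is.na(x)) || all(is.na(y)))
      return(data.frame(feature = f, median_target = median(x, na.rm = TRUE),
                        median_rest = median(y, na.rm = TRUE),
                        direction = NA_real_, p = NA_real_,
                        note = "constant-feature"))
    tr <- wilcoxonRankSum(x, y)
    data.frame(feature = f, median_target = tr$medians[1],
               median_rest = tr$medians[2], direction = tr$direction,
               p = tr$p, note = "")
  })
  out <- do.call(rbind, res)
  tested <- !is.na(out$p)
  out$q <- NA_real_
  out$significant <- NA
  if (any(tested)) {
    adj <- bhAdjust(out$p[tested], threshold = threshold)
    out$q[tested] <- adj$q
    out$significant[tested] <- adj$significant
  }
  out <- out[order(out$q), ]
  rownames(out) <- NULL
  if (sum(inT) < 2L)
    attr(out, "warning") <- "target group has fewer than 2 members"
  out
}

.pctRound <- function(x) {
  # one decimal, half away from zero (matches printed table formatting)
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

#' Clinical summary table per metabotype
#'
#' Per-group counts and percentages for the categorical rows (NCCN risk
#' class, Gleason score, ancestry and, when present, diabetes /
#' hypertension / smoker) and median [95\% CI] for the numeric rows (age,
#' PSA), with one across-group p-value per row (Fisher's exact test for
#' categorical rows, Kruskal-Wallis for numeric rows).
#'
#' @param clinical data.frame of clinical records (see
#'   \code{\link{loadClinicalCSV}}); must carry \code{risk_group}.
#' @param labels metabotype label per row of \code{clinical}.
#' @return a list of per-row summaries: each categorical entry holds a
#'   counts matrix, a percentage matrix and p; each numeric entry holds
#'   median/lower/upper per group and p.
#' @export
summarizeCohort <- function(clinical, labels) {
  labels <- as.character(labels)
  if (nrow(clinical) == 0L)
    return(list(groups = character(0), rows = list()))
  if (length(labels) != nrow(clinical))
    stop("invalid-input: labels must cover all clinical rows")
  groups <- if (all(labels %in% as.character(utils::as.roman(1:20)))) {
    intersect(as.character(utils::as.roman(1:20)), unique(labels))
  } else sort(unique(labels))
  catRow <- function(values) {
    tab <- table(factor(values), factor(labels, levels = groups))
    pct <- prop.table(tab, margin = 2) * 100
    pct[is.nan(pct)] <- NA
    p <- tryCatch(fisherExactTest(unclass(tab))$p, error = function(e)
      NA_real_)
    list(type = "categorical", counts = unclass(tab),
         percent = .pctRound(unclass(pct)), p = p)
  }
  numRow <- function(values) {
    per <- lapply(groups, function(g) {
      v <- values[labels == g]
      if (!length(v) || all(is.na(v)))
        list(median = NA_real_, lower = NA_real_, upper = NA_real_)
      else medianCI(v)
    })
    names(per) <- groups
    p <- tryCatch(
      kruskalWallisTest(split(values, factor(labels, levels = groups)))$p,
      error = function(e) NA_real_)
    list(type = "numeric", perGroup = per, p = p)
  }
  rows <- list()
  if (!is.null(clinical$risk_group))
    rows$nccn <- catRow(clinical$risk_group)
  if (!is.null(clinical$gleason_primary))
    rows$gleason <- catRow(paste(clinical$gleason_primary, "+",
                                 clinical$gleason_secondary))
  if (!is.null(clinical$age)) rows$age <- numRow(clinical$age)
  if (!is.null(clinical$ancestry)) rows$ancestry <- catRow(clinical$ancestry)
  if (!is.null(clinical$psa)) rows$psa <- numRow(clinical$psa)
  for (flag in c("diabetes", "hypertension", "smoker"))
    if (!is.null(clinical[[flag]]))
      rows[[flag]] <- catRow(ifelse(clinical[[flag]], "Yes", "No"))
  ns <- vapply(groups, function(g) sum(labels == g), numeric(1))
  list(groups = groups, n = ns, rows = rows)
}
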