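# Group-comparison and correlation statistics: two-tailed Mann-Whitney,
# Spearman correlation, Fisher's exact test, and a tidy batch driver for
# feature-by-group comparisons.

#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration when `n_x + n_y <= 20` and there are no ties; otherwise
#' the normal approximation with tie and continuity corrections. The reported
#' U statistic counts (x, y) pairs with x > y.
#'
#' @param x,y numeric samples (non-empty).
#' @return list `U, p_value, exact`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) .err("both samples must be non-empty")
  no_ties <- !anyDuplicated(c(x, y))
  use_exact <- (length(x) + length(y) <= 20L) && no_ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE, alternative = "two.sided"))
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = use_exact)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, with the p-value from the t
#' approximation; pairs with a missing member are dropped and counted.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list `r, p_value, n` (r is `NA` with a warning for a constant
#'   input).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) .err("x and y must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) .err("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    .warnf("constant input; Spearman correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Fisher's exact test
#'
#' Two-sided p-value by the point-probability criterion: the sum of the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table. Supports 2x2 and small r x c
#' tables (total count <= 200; larger tables should use a chi-square test).
#'
#' @param table matrix of non-negative integer counts.
#' @return p-value in (0, 1].
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    .err("counts must be non-negative integers")
  }
  if (sum(table) > 200) {
    .err("table total %d exceeds the enumeration bound (200); use a chi-square test",
         sum(table))
  }
  stats::fisher.test(table)$p.value
}

#' Batch feature-by-group comparison
#'
#' One test per feature column between the two grouping levels, with
#' significance stars at the conventional figure-legend levels (0.05, 0.01,
#' 0.001, 0.0001).
#'
#' @param features data.frame/matrix, observations in rows, features in
#'   columns.
#' @param grouping factor/character with exactly 2 levels, aligned with the
#'   rows of `features`.
#' @param test currently `"mann_whitney"`.
#' @return tidy data.frame: `feature, test, statistic, p_value, n_group1,
#'   n_group2, n_missing, stars`.
#' @export
compare_feature_by_group <- function(features, grouping, test = "mann_whitney") {
  test <- match.arg(test, "mann_whitney")
  features <- as.data.frame(features)
  grouping <- droplevels(as.factor(grouping))
  if (nlevels(grouping) != 2L) .err("grouping must have exactly 2 levels")
  if (length(grouping) != nrow(features)) .err("grouping length must match feature rows")
  lv <- levels(grouping)
  rows <- lapply(names(features), function(nm) {
    v <- features[[nm]]
    x <- v[grouping == lv[1] & !is.na(v)]
    y <- v[grouping == lv[2] & !is.na(v)]
    res <- if (length(x) && length(y)) mann_whitney(x, y) else list(U = NA_real_, p_value = NA_real_)
    data.frame(feature = nm, test = test,
               statistic = res$U, p_value = res$p_value,
               n_group1 = length(x), n_group2 = length(y),
               n_missing = sum(is.na(v)),
               stars = .stars(res$p_value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
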