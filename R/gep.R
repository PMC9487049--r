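# Immune gene-expression profiling: housekeeping normalization, log2
# transform, per-gene two-group differential expression with BH correction,
# and gene-set signature scores.

#' Housekeeping-gene normalization
#'
#' Each value becomes the ratio of the raw count to the geometric mean of the
#' housekeeping-gene counts of the same sample. Raw counts are floored at 1
#' before use, so downstream log2 is always defined; per-sample
#' self-normalization differs from a cohort-mean rescaling only by a
#' per-cohort constant on the log2 scale and changes neither fold changes nor
#' score differences.
#'
#' @param matrix an `expr_matrix` with `scale = "raw_counts"`.
#' @return an `expr_matrix` with `scale = "normalized"`.
#' @export
normalize_housekeeping <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$scale != "raw_counts") .err("normalization expects raw counts (scale is '%s')", matrix$scale)
  if (length(matrix$housekeeping) == 0L) .err("no housekeeping genes flagged")
  v <- matrix$values
  hk_raw <- v[matrix$housekeeping, , drop = FALSE]
  zero_hk <- colSums(hk_raw) == 0
  if (any(zero_hk)) {
    .warnf("sample(s) with all-zero housekeeping counts (floored to 1): %s",
           paste(colnames(v)[zero_hk], collapse = ", "))
  }
  v <- pmax(v, 1)
  factors <- apply(v[matrix$housekeeping, , drop = FALSE], 2, geomean)
  norm <- sweep(v, 2, factors, "/")
  expr_matrix(norm, matrix$housekeeping, scale = "normalized")
}

#' Log2 transform of a normalized matrix
#'
#' @param matrix an `expr_matrix` with `scale = "normalized"` and strictly
#'   positive values (guaranteed by the normalization's flooring).
#' @return an `expr_matrix` with `scale = "log2"`.
#' @export
log2_transform <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$scale != "normalized") .err("log2 transform expects normalized data (scale is '%s')", matrix$scale)
  if (any(matrix$values <= 0)) .err("non-positive value encountered; normalize first")
  expr_matrix(log2(matrix$values), matrix$housekeeping, scale = "log2")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjustment (monotone, capped at 1, input order preserved),
#' delegated to [stats::p.adjust()] after validating the input range.
#'
#' @param p_values numeric vector in `[0, 1]` (NA allowed; NA stays NA and
#'   does not count toward the number of tests).
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) .err("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Two-group differential expression on log2 data
#'
#' Per endogenous gene, ordinary least squares of the log2 value on the binary
#' HPV-status indicator — equivalent to an equal-variance two-sample t-test.
#' The log2 fold change is the positive-group minus negative-group mean; the
#' p-value comes from the coefficient's t statistic on `n - 2` degrees of
#' freedom; BH adjustment runs across all genes with a valid p-value; a gene
#' is called a DEG when `|log2FC| > lfc_threshold` and adjusted p < `alpha`.
#' Housekeeping genes are excluded from testing; genes with zero residual
#' variance get a missing p-value and are excluded from the BH family with a
#' warning.
#'
#' @param matrix an `expr_matrix` with `scale = "log2"`.
#' @param group_labels named character vector, sample -> "positive"/"negative",
#'   covering every sample in the matrix; >= 2 samples per group.
#' @param lfc_threshold,alpha DEG-calling thresholds (defaults 1 and 0.05).
#' @return data.frame `gene, log2_fold_change, p_value, adjusted_p, is_deg`.
#' @export
differential_expression <- function(matrix, group_labels,
                                    lfc_threshold = 1, alpha = 0.05) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$scale != "log2") .err("differential expression expects log2 data (scale is '%s')", matrix$scale)
  samples <- colnames(matrix$values)
  missing_s <- setdiff(samples, names(group_labels))
  if (length(missing_s)) .err("no group label for sample(s): %s", paste(missing_s, collapse = ", "))
  g <- group_labels[samples]
  if (!all(g %in% c("positive", "negative"))) .err("group labels must be 'positive'/'negative'")
  n1 <- sum(g == "positive"); n0 <- sum(g == "negative")
  if (n1 < 2L || n0 < 2L) .err("each group needs at least 2 samples (have %d / %d)", n1, n0)
  endo <- setdiff(rownames(matrix$values), matrix$housekeeping)
  x <- matrix$values[endo, , drop = FALSE]
  x1 <- x[, g == "positive", drop = FALSE]
  x0 <- x[, g == "negative", drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  lfc <- m1 - m0
  df <- n1 + n0 - 2L
  ss <- rowSums((x1 - m1)^2) + rowSums((x0 - m0)^2)
  se <- sqrt((ss / df) * (1 / n1 + 1 / n0))
  tstat <- lfc / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se == 0
  if (any(degenerate)) {
    .warnf("%d gene(s) with zero residual variance excluded from testing", sum(degenerate))
    p[degenerate] <- NA_real_
  }
  padj <- bh_adjust(p)
  data.frame(gene = endo,
             log2_fold_change = lfc,
             p_value = p,
             adjusted_p = padj,
             is_deg = !is.na(padj) & abs(lfc) > lfc_threshold & padj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Signature score
#'
#' Per-sample arithmetic mean of log2 normalized expression over the
#' signature's member genes present in the matrix (unweighted; proprietary
#' panel weights are not modeled).
#'
#' @param matrix an `expr_matrix` with `scale = "log2"`.
#' @param signature a `signature_set`.
#' @param samples samples to score (default: all).
#' @return data.frame `sample_id, signature, score, n_genes, n_missing`.
#' @export
signature_score <- function(matrix, signature, samples = colnames(matrix$values)) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(signature, "signature_set"))
  if (matrix$scale != "log2") .err("signature scoring expects log2 data (scale is '%s')", matrix$scale)
  present <- intersect(signature$genes, rownames(matrix$values))
  if (length(present) == 0L) {
    .err("no member gene of signature '%s' present in the matrix", signature$name)
  }
  sub <- matrix$values[present, samples, drop = FALSE]
  data.frame(sample_id = samples,
             signature = signature$name,
             score = colMeans(sub),
             n_genes = length(present),
             n_missing = length(signature$genes) - length(present),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Score a collection of signatures
#'
#' @param matrix an `expr_matrix` (`log2` scale).
#' @param signatures named list of `signature_set`s.
#' @return samples x signatures numeric matrix of scores.
#' @export
signature_scores <- function(matrix, signatures) {
  out <- vapply(signatures, function(s) signature_score(matrix, s)$score,
                numeric(ncol(matrix$values)))
  rownames(out) <- colnames(matrix$values)
  out
}

#' Ratio between two signature scores
#'
#' On the log2 scale a signature "ratio" is the score difference
#' (the log2 of the linear ratio); it is antisymmetric in its arguments.
#'
#' @param score_a,score_b single rows as returned by [signature_score()]
#'   (same sample).
#' @return numeric, `score_a - score_b`.
#' @export
signature_ratio <- function(score_a, score_b) {
  if (nrow(score_a) != nrow(score_b) ||
      !all(score_a$sample_id == score_b$sample_id)) {
    .err("signature ratio requires scores for the same sample(s)")
  }
  score_a$score - score_b$score
}
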