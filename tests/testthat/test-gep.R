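# Housekeeping normalization, log2 transform, differential expression,
# BH adjustment, and signature scores.

toy_matrix <- function() {
  vals <- rbind(
    HK1 = c(4, 9, 16),
    HK2 = c(16, 4, 4),
    GENE1 = c(24, 12, 40),
    GENE2 = c(8, 6, 8))
  colnames(vals) <- c("s1", "s2", "s3")
  expr_matrix(vals, c("HK1", "HK2"))
}

test_that("housekeeping normalization divides by the per-sample HK geomean", {
  em <- toy_matrix()
  nm <- normalize_housekeeping(em)
  # sample s1: geomean(4, 16) = 8; GENE1 24 -> 3
  expect_equal(nm$values["GENE1", "s1"], 3)
  expect_equal(nm$scale, "normalized")
  # per-sample geomean of normalized HK values is exactly 1
  hk <- nm$values[nm$housekeeping, , drop = FALSE]
  expect_equal(unname(apply(hk, 2, function(v) exp(mean(log(v))))), rep(1, 3))
  # flooring: zero counts behave as 1
  vals <- em$values; vals["GENE2", "s1"] <- 0
  nm2 <- normalize_housekeeping(expr_matrix(vals, em$housekeeping))
  expect_equal(nm2$values["GENE2", "s1"], 1 / 8)
  # independently coded recomputation on a generated fixture
  groups <- setNames(rep(c("positive", "negative"), c(24, 15)), sprintf("P%02d", 1:39))
  ex <- generate_expression(expression_params(), groups, seed = 12)
  nm3 <- normalize_housekeeping(ex$matrix)
  v <- pmax(ex$matrix$values, 1)
  fac <- exp(colMeans(log(v[ex$matrix$housekeeping, ])))
  expect_equal(nm3$values, sweep(v, 2, fac, "/"))
})

test_that("log2 transform tracks scale and inverts 2^x", {
  nm <- normalize_housekeeping(toy_matrix())
  lg <- log2_transform(nm)
  expect_equal(lg$values["GENE1", "s1"], log2(3), tolerance = 1e-12)
  expect_equal(lg$scale, "log2")
  expect_error(log2_transform(toy_matrix()), "normalized")
  expect_error(normalize_housekeeping(lg), "raw counts")
  expect_equal(2^lg$values, nm$values, tolerance = 1e-12)
})

test_that("two-group DE matches the closed-form pooled t-test", {
  vals <- rbind(HK = rep(1, 6),
                g1 = c(0, 1, 2, 2, 3, 4),
                g2 = rep(2, 6))
  colnames(vals) <- sprintf("s%d", 1:6)
  em <- expr_matrix(vals, "HK", scale = "log2")
  groups <- setNames(rep(c("negative", "positive"), each = 3), colnames(vals))
  de <- suppressWarnings(differential_expression(em, groups))
  r1 <- de[de$gene == "g1", ]
  expect_equal(r1$log2_fold_change, 2)
  # pooled t = 2 / (1 * sqrt(2/3)) = 2.449..., p two-sided on df = 4
  expect_equal(r1$p_value, 2 * pt(-2 / sqrt(2 / 3), df = 4), tolerance = 1e-12)
  expect_equal(r1$p_value, 0.0705, tolerance = 1e-3)
  # zero-variance gene excluded with missing p
  expect_true(is.na(de$p_value[de$gene == "g2"]))
  # swapping labels negates the fold change and keeps p
  swapped <- setNames(ifelse(groups == "positive", "negative", "positive"), names(groups))
  de2 <- suppressWarnings(differential_expression(em, swapped))
  expect_equal(de2$log2_fold_change[de2$gene == "g1"], -2)
  expect_equal(de2$p_value[de2$gene == "g1"], r1$p_value)
  # identical groups give no DEGs
  vals3 <- rbind(HK = rep(1, 6), g = c(1, 2, 3, 1, 2, 3))
  colnames(vals3) <- colnames(vals)
  em3 <- expr_matrix(vals3, "HK", scale = "log2")
  de3 <- differential_expression(em3, groups)
  expect_equal(de3$log2_fold_change, 0)
  expect_false(any(de3$is_deg))
  tiny <- setNames(rep(c("positive", "negative"), c(5, 1)), colnames(vals))
  expect_error(differential_expression(em, tiny), "at least 2")
})

test_that("DE agrees with an independent per-gene linear model fit", {
  groups <- setNames(rep(c("positive", "negative"), c(8, 7)), sprintf("s%02d", 1:15))
  ex <- generate_expression(expression_params(n_genes = 80, n_housekeeping = 10,
                                              n_de_genes = 8), groups, seed = 91)
  m <- log2_transform(normalize_housekeeping(ex$matrix))
  de <- differential_expression(m, groups)
  ind <- factor(groups[colnames(m$values)], levels = c("negative", "positive"))
  for (g in sample(de$gene, 10)) {
    fit <- summary(lm(m$values[g, ] ~ ind))
    expect_equal(de$log2_fold_change[de$gene == g],
                 unname(coef(fit)[2, 1]), tolerance = 1e-10)
    expect_equal(de$p_value[de$gene == g],
                 unname(coef(fit)[2, 4]), tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.02)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^2
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("DE p-values are null-uniform and BH controls false DEG calls", {
  groups <- setNames(rep(c("positive", "negative"), c(10, 9)), sprintf("s%02d", 1:19))
  pooled <- c(); fp <- c()
  for (i in 1:6) {
    ex <- generate_expression(expression_params(n_genes = 300, n_housekeeping = 30,
                                                n_de_genes = 0), groups, seed = 600 + i)
    m <- log2_transform(normalize_housekeeping(ex$matrix))
    de <- differential_expression(m, groups)
    pooled <- c(pooled, de$p_value)
    fp <- c(fp, mean(de$is_deg))
  }
  expect_gt(ks.test(pooled, "punif")$p.value, 0.01)
  expect_lte(mean(fp), 0.05)
})

test_that("signature scores are mean log2 values with ratio antisymmetry", {
  m <- log2_transform(normalize_housekeeping(toy_matrix()))
  sA <- signature_score(m, signature_set("A", "cell_type", c("GENE1", "GENE2")))
  expect_equal(sA$score,
               unname(colMeans(m$values[c("GENE1", "GENE2"), ])))
  # single-gene signature returns that gene's value
  s1 <- signature_score(m, signature_set("B", "pathway", "GENE1"))
  expect_equal(s1$score, unname(m$values["GENE1", ]))
  # missing genes reported; fully absent signature errors with its name
  sM <- signature_score(m, signature_set("C", "cell_type", c("GENE1", "NOPE")))
  expect_equal(unique(sM$n_missing), 1L)
  expect_error(signature_score(m, signature_set("ghost", "cell_type", "NOPE")),
               "ghost")
  expect_equal(signature_ratio(sA, s1), -signature_ratio(s1, sA))
  expect_equal(signature_ratio(sA, sA), rep(0, 3))
})

test_that("injected signature direction is recovered on synthetic data", {
  groups <- setNames(rep(c("positive", "negative"), c(12, 12)), sprintf("s%02d", 1:24))
  ex <- generate_expression(expression_params(n_genes = 200, n_housekeeping = 20,
                                              n_de_genes = 20,
                                              log2fc_range = c(1.5, 2)),
                            groups, seed = 321)
  m <- log2_transform(normalize_housekeeping(ex$matrix))
  up <- ex$truth$gene[ex$truth$log2fc > 0]
  if (length(up) >= 2) {
    sc <- signature_score(m, signature_set("up", "cell_type", up))
    expect_gt(mean(sc$score[groups == "positive"]),
              mean(sc$score[groups == "negative"]))
  }
})
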