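# Median dichotomization, Kaplan-Meier, log-rank, Cox, and the survival
# screen.

test_that("median dichotomization follows the le-median-is-low tie rule", {
  g <- dichotomize_by_median(setNames(c(1, 2, 3, 4), letters[1:4]))
  expect_equal(attr(g, "cutoff"), 2.5)
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  g2 <- dichotomize_by_median(setNames(c(1, 2, 2, 3), letters[1:4]))
  expect_equal(attr(g2, "cutoff"), 2)
  expect_equal(as.character(g2), c("low", "low", "low", "high"))
  # invariant under strictly increasing transforms
  set.seed(44)
  for (i in 1:20) {
    v <- setNames(rnorm(11), paste0("p", 1:11))
    f <- sample(list(function(x) exp(x), function(x) x^3, function(x) atan(x)), 1)[[1]]
    expect_equal(as.character(dichotomize_by_median(v)),
                 as.character(dichotomize_by_median(f(v))))
  }
  # missing values excluded and reported
  v <- setNames(c(1, NA, 3, 4), paste0("p", 1:4))
  g3 <- dichotomize_by_median(v)
  expect_equal(attr(g3, "n_missing"), 1L)
  expect_equal(length(g3), 3L)
  expect_error(dichotomize_by_median(c(a = NA_real_, b = NA_real_)), "non-missing")
})

test_that("Kaplan-Meier estimate matches the hand product-limit computation", {
  km <- km_estimate(c(5, 10, 15), c(1, 0, 1))
  expect_equal(km_surv_at(km, c(0, 4.9, 5, 14.9, 15)),
               c(1, 1, 2 / 3, 2 / 3, 0))
  # all censored: S = 1 everywhere
  km2 <- km_estimate(c(3, 6), c(0, 0))
  expect_true(all(km2$surv == 1))
  # no censoring: S(t) equals the empirical survivor function
  set.seed(13)
  tt <- sample(1:50, 12)
  km3 <- km_estimate(tt, rep(1, 12))
  for (t0 in c(0, sort(tt))) {
    expect_equal(km_surv_at(km3, t0), mean(tt > t0))
  }
  # KM bounded in [0, 1] and non-increasing
  set.seed(14)
  km4 <- km_estimate(rexp(40, 0.05), rbinom(40, 1, 0.7))
  expect_true(all(km4$surv >= 0 & km4$surv <= 1))
  expect_true(all(diff(km4$surv) <= 1e-12))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank test matches a hand observed-minus-expected computation", {
  # groups A: times 1 (event), 3 (event); B: 2 (event), 4 (censored)
  time <- c(1, 3, 2, 4); event <- c(1, 1, 1, 0)
  grp <- c("A", "A", "B", "B")
  # hand computation: event times 1,2,3
  # t=1: risk 4 (2A,2B), 1 event in A; E_A = 1*2/4 = 0.5, V = 2*2*1*3/(16*3)=0.25
  # t=2: risk 3 (1A,2B), 1 event in B; E_A = 1/3, V = 1*2*1*2/(9*2) = 2/9
  # t=3: risk 2 (1A,1B), 1 event in A; E_A = 1/2, V = 1*1*1*1/(4*1) = 0.25
  oa <- 2; ea <- 0.5 + 1 / 3 + 0.5; vv <- 0.25 + 2 / 9 + 0.25
  chi <- (oa - ea)^2 / vv
  res <- logrank_test(time, event, grp)
  expect_equal(res$chi_square, chi, tolerance = 1e-9)
  expect_equal(res$p_value, pchisq(chi, 1, lower.tail = FALSE), tolerance = 1e-9)
  # label swap leaves the statistic unchanged
  res2 <- logrank_test(time, event, ifelse(grp == "A", "B", "A"))
  expect_equal(res2$chi_square, res$chi_square)
  # identical groups: chi-square ~ 0, p ~ 1
  t2 <- rep(c(2, 5, 9), 2); e2 <- rep(c(1, 1, 0), 2)
  res3 <- logrank_test(t2, e2, rep(c("A", "B"), each = 3))
  expect_lt(res3$chi_square, 1e-9)
  expect_equal(res3$p_value, 1, tolerance = 1e-6)
  expect_error(logrank_test(time, event, rep("A", 4)), "2 non-empty groups")
})

test_that("Cox fit recovers a known hazard ratio and flags degeneracies", {
  set.seed(70)
  n <- 200
  grp <- rep(c(0, 1), each = n)
  t_event <- c(rexp(n, 0.02), rexp(n, 0.04)) # HR = 2
  cens <- runif(2 * n, 30, 90)
  time <- pmin(t_event, cens); event <- as.integer(t_event <= cens)
  cx <- cox_univariate(time, event, factor(grp))
  expect_gt(cx$hazard_ratio, 1.5)
  expect_lt(cx$hazard_ratio, 2.6)
  expect_true(cx$ci_lower <= cx$hazard_ratio && cx$hazard_ratio <= cx$ci_upper)
  expect_error(cox_univariate(time, event, rep("A", 2 * n)), "identical")
  # no ties: Efron equals Breslow
  set.seed(71)
  tt <- sort(runif(30, 1, 100)); ee <- rbinom(30, 1, 0.8); gg <- rbinom(30, 1, 0.5)
  if (length(unique(gg)) == 2 && sum(ee) > 0) {
    fe <- survival::coxph(survival::Surv(tt, ee) ~ gg, ties = "efron")
    fb <- survival::coxph(survival::Surv(tt, ee) ~ gg, ties = "breslow")
    expect_equal(coef(fe), coef(fb), tolerance = 1e-9)
    expect_equal(cox_univariate(tt, ee, factor(gg))$hazard_ratio,
                 unname(exp(coef(fe))), tolerance = 1e-9)
  }
  # complete separation flagged, not silently returned
  expect_warning(
    cxm <- cox_univariate(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0),
                          factor(c("a", "a", "a", "b", "b", "b"))),
    "monotone")
  expect_true(cxm$monotone_likelihood)
})

test_that("survival screen handles null, injected, and degenerate inputs", {
  set.seed(80)
  n <- 39
  ids <- sprintf("P%02d", 1:n)
  # injected feature: exponential hazard doubled for high values
  z <- rnorm(n)
  rate <- 0.02 * exp(0.9 * z)
  t_event <- rexp(n, rate)
  sv <- data.frame(patient_id = ids,
                   dfs_time = round(pmin(t_event, 72), 1),
                   dfs_event = as.integer(t_event <= 72))
  feats <- data.frame(injected = z, noise = rnorm(n), row.names = ids)
  scr <- suppressWarnings(survival_screen(feats, sv))
  expect_equal(nrow(scr), 2L)
  expect_true(all(c("logrank_p", "hazard_ratio", "logrank_p_bh") %in% names(scr)))
  expect_true(all(scr$ci_lower <= scr$hazard_ratio & scr$hazard_ratio <= scr$ci_upper,
                  na.rm = TRUE))
  # degenerate: two patients, one event -> completes with warnings, no crash
  sv2 <- data.frame(patient_id = c("a", "b", "c", "d"),
                    dfs_time = c(0, 10, 12, 20), dfs_event = c(1, 0, 1, 0))
  f2 <- data.frame(v = c(1, 2, 3, 4), row.names = c("a", "b", "c", "d"))
  w <- capture_warnings(scr2 <- survival_screen(f2, sv2))
  expect_true(any(grepl("shifted", w)))
  expect_equal(nrow(scr2), 1L)
})

test_that("null survival screen flags about 5% of variables", {
  set.seed(90)
  hits <- c()
  for (i in 1:15) {
    n <- 40
    ids <- sprintf("P%02d", 1:n)
    rate <- 0.02
    t_event <- rexp(n, rate); cens <- runif(n, 36, 72)
    sv <- data.frame(patient_id = ids,
                     dfs_time = round(pmin(t_event, cens), 1),
                     dfs_event = as.integer(t_event <= cens))
    feats <- as.data.frame(matrix(rnorm(n * 8), n,
                                  dimnames = list(ids, paste0("v", 1:8))))
    scr <- suppressWarnings(survival_screen(feats, sv))
    hits <- c(hits, scr$logrank_p < 0.05)
  }
  expect_lt(mean(hits, na.rm = TRUE), 0.12)
})

test_that("injected survival effects are detected at default effect size", {
  ch_det <- vapply(1:10, function(i) {
    set.seed(700 + i)
    n <- 39
    ids <- sprintf("P%02d", 1:n)
    z <- rnorm(n)
    rate <- 0.03 * exp(1 * z)
    t_event <- rexp(n, rate); cens <- runif(n, 36, 72)
    sv <- data.frame(patient_id = ids,
                     dfs_time = round(pmin(t_event, cens), 1),
                     dfs_event = as.integer(t_event <= cens))
    feats <- data.frame(injected = z, row.names = ids)
    scr <- suppressWarnings(survival_screen(feats, sv))
    scr$logrank_p[1] < 0.05
  }, logical(1))
  expect_gte(mean(ch_det), 0.8)
})
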