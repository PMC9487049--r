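# Disease-free-survival analysis: median dichotomization, Kaplan-Meier,
# log-rank (Mantel-Cox) and univariate Cox proportional hazards. The survival
# machinery stands on the survival package; this module supplies the
# dichotomization, validation and screening conventions around it.

#' Dichotomize a variable at its median
#'
#' Values at or below the median go to `"low"`, values above to `"high"`
#' (`le_median_is_low` tie rule); the median is the midpoint of the two
#' central order statistics for even n. Missing values are excluded and
#' reported via the `n_missing` attribute. The split is invariant under any
#' strictly increasing transform of the values.
#'
#' @param values named numeric vector (names = patient IDs).
#' @param tie_rule only `"le_median_is_low"` is implemented.
#' @return named factor with levels `low`, `high` (missing-value entries
#'   dropped), attributes `cutoff` and `n_missing`.
#' @export
dichotomize_by_median <- function(values, tie_rule = "le_median_is_low") {
  tie_rule <- match.arg(tie_rule, "le_median_is_low")
  ok <- !is.na(values)
  if (sum(ok) < 2L) .err("need at least 2 non-missing values to dichotomize")
  v <- values[ok]
  med <- stats::median(v)
  grp <- factor(ifelse(v <= med, "low", "high"), levels = c("low", "high"))
  names(grp) <- names(v)
  structure(grp, cutoff = med, n_missing = sum(!ok))
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function (via
#' [survival::survfit()]): S(0) = 1, steps only at event times, censored
#' subjects leave the risk set after their time.
#'
#' @param time follow-up times (months, >= 0).
#' @param event event indicators (1 = death/relapse, 0 = censored).
#' @return object of class `km_curve`: data.frame `time, n_risk, n_event,
#'   n_censor, surv` plus a `surv_at(t)` evaluator in attribute `surv_at`.
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) .err("negative survival time")
  if (length(time) == 0L) .err("empty group")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  sfun <- stats::stepfun(curve$time, c(1, curve$surv), right = FALSE)
  structure(curve, class = c("km_curve", "data.frame"), surv_at = sfun)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d time point(s), %d event(s)\n",
              nrow(x), sum(x$n_event)))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Months", ylab = "DFS probability", ...) {
  graphics::plot(attr(x, "surv_at"), do.points = FALSE, ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Survival probability at given times
#'
#' @param curve a `km_curve`.
#' @param t times.
#' @return S(t).
#' @export
km_surv_at <- function(curve, t) attr(curve, "surv_at")(t)

#' Two-group log-rank (Mantel-Cox) test
#'
#' @param time,event follow-up times and event indicators.
#' @param group two-level grouping (e.g. low/high).
#' @return list `chi_square, df, p_value` (p is `NA` with a warning when no
#'   events occurred).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2L) .err("log-rank test requires exactly 2 non-empty groups")
  if (any(time < 0)) .err("negative survival time")
  if (sum(event) == 0L) {
    .warnf("no events observed; log-rank p-value is undefined")
    return(list(chi_square = 0, df = 1L, p_value = NA_real_))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chi_square = sd$chisq, df = 1L,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards model for a binary covariate
#'
#' Partial-likelihood fit with Efron tie handling; HR = exp(coef), 95% CI =
#' exp(coef +/- 1.96 SE), Wald p. A monotone likelihood (all events on one
#' side) is flagged rather than silently returned.
#'
#' @param time,event follow-up times and event indicators.
#' @param group binary covariate; the hazard ratio is for the second level
#'   vs the first.
#' @return list `hazard_ratio, ci_lower, ci_upper, p_value, n, n_events,
#'   monotone_likelihood`.
#' @export
cox_univariate <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) .err("covariate is identical for all subjects")
  if (sum(event) == 0L) .err("no events observed; Cox model undefined")
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ group, ties = "efron"))
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(diag(fit$var))[1]
  monotone <- !is.finite(beta) || abs(beta) > 15 || !is.finite(se) || se > 100
  if (monotone) {
    .warnf("monotone partial likelihood: hazard ratio is not identifiable (reported as infinite)")
  }
  list(hazard_ratio = exp(beta),
       ci_lower = exp(beta - 1.96 * se),
       ci_upper = exp(beta + 1.96 * se),
       p_value = 2 * stats::pnorm(-abs(beta / se)),
       n = length(time), n_events = sum(event),
       monotone_likelihood = monotone)
}

#' Median-split survival screen over immune variables
#'
#' For each immune variable (signature score, density, percentage, ...):
#' dichotomize patients at the median, then Kaplan-Meier / log-rank /
#' univariate Cox of high vs low. Raw p-values are reported without
#' multiplicity correction, matching the screening convention this package
#' reproduces; a BH-adjusted column is emitted alongside for transparency.
#' Subjects with DFS time 0 are shifted to 0.01 months with a warning to
#' avoid a degenerate risk set.
#'
#' @param features data.frame/matrix, patients in rows (rownames = patient
#'   IDs), one column per immune variable.
#' @param survival_data data.frame `patient_id, dfs_time, dfs_event`.
#' @param subset optional logical/character vector selecting patients (e.g.
#'   one HPV-status or sex stratum).
#' @param config an [analysis_config()] (tie rule).
#' @return data.frame, one row per variable: `variable, cutoff, n_low,
#'   n_high, n_events, logrank_p, hazard_ratio, ci_lower, ci_upper, cox_p,
#'   logrank_p_bh`.
#' @export
survival_screen <- function(features, survival_data, subset = NULL,
                            config = analysis_config()) {
  features <- as.data.frame(features)
  if (ncol(features) < 1L) .err("no variables to screen")
  sv <- survival_data
  rownames(sv) <- sv$patient_id
  ids <- intersect(rownames(features), sv$patient_id)
  if (!is.null(subset)) {
    ids <- if (is.character(subset)) intersect(ids, subset) else ids[subset[ids]]
  }
  if (length(ids) < 4L) .err("too few patients (%d) for a survival screen", length(ids))
  sv <- sv[ids, ]
  time <- sv$dfs_time
  if (any(time == 0)) {
    .warnf("%d subject(s) with DFS time 0 shifted to 0.01 months", sum(time == 0))
    time[time == 0] <- 0.01
  }
  rows <- lapply(names(features), function(nm) {
    v <- stats::setNames(features[ids, nm], ids)
    grp <- try(dichotomize_by_median(v, config$median_tie_rule), silent = TRUE)
    if (inherits(grp, "try-error") || nlevels(droplevels(grp)) < 2L) {
      return(data.frame(variable = nm, cutoff = NA_real_, n_low = NA_integer_,
                        n_high = NA_integer_, n_events = NA_integer_,
                        logrank_p = NA_real_, hazard_ratio = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        cox_p = NA_real_, stringsAsFactors = FALSE))
    }
    keep <- names(grp)
    tt <- time[match(keep, ids)]
    ee <- sv$dfs_event[match(keep, ids)]
    lr <- logrank_test(tt, ee, grp)
    cx <- tryCatch(cox_univariate(tt, ee, grp),
                   error = function(e) list(hazard_ratio = NA_real_,
                                            ci_lower = NA_real_, ci_upper = NA_real_,
                                            p_value = NA_real_))
    data.frame(variable = nm, cutoff = attr(grp, "cutoff"),
               n_low = sum(grp == "low"), n_high = sum(grp == "high"),
               n_events = sum(ee),
               logrank_p = lr$p_value,
               hazard_ratio = cx$hazard_ratio,
               ci_lower = cx$ci_lower, ci_upper = cx$ci_upper,
               cox_p = cx$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$logrank_p_bh <- bh_adjust(out$logrank_p)
  out
}
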