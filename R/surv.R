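#' Kaplan-Meier product-limit estimate
#'
#' Wraps the standard product-limit estimator and returns the curve as a
#' tibble. The median is the first event time at which the survival
#' function drops to 0.5 or below (`NA` if it never does). Without
#' censoring the curve equals the empirical survival function.
#'
#' @param time Non-negative follow-up times (months).
#' @param event Event indicator (1 = event, 0 = censored).
#' @return A tibble of class `wm_km`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, with attribute `median`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) rlang::abort("Need >= 1 subject.")
  if (any(time < 0)) rlang::abort("Negative survival times.")
  if (!all(event %in% c(0, 1))) rlang::abort("`event` must be 0/1.")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
  med <- km_median(out)
  attr(out, "median") <- med
  class(out) <- c("wm_km", class(out))
  out
}

km_median <- function(curve) {
  drop <- curve$time[curve$n_event > 0 & curve$survival <= 0.5]
  if (length(drop)) min(drop) else NA_real_
}

# KM survival probability at a fixed time (step function, right continuous).
km_surv_at <- function(time, event, t0) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- c(1, fit$surv)
  tt <- c(0, fit$time)
  s[max(which(tt <= t0))]
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected log-rank chi-square with hypergeometric
#' variance (tie-corrected), with `g - 1` degrees of freedom.
#'
#' @param time,event As in [km_estimate()].
#' @param group Grouping vector with >= 2 levels.
#' @return A list: `chi2`, `df`, `p_value`, and `per_group` tibble with
#'   observed and expected event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) rlang::abort("Need >= 2 groups.")
  if (any(tabulate(group) < 1L)) rlang::abort("Every group needs >= 1 subject.")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(
    chi2 = unname(fit$chisq),
    df = df,
    p_value = stats::pchisq(fit$chisq, df = df, lower.tail = FALSE),
    per_group = tibble::tibble(
      group = levels(group),
      n = as.vector(fit$n),
      observed = as.vector(fit$obs),
      expected = as.vector(fit$exp)
    )
  )
}

#' Univariate Cox proportional-hazards regression
#'
#' Maximizes the Breslow partial likelihood (Efron tie handling available)
#' and reports the hazard ratio with a Wald 95% confidence interval.
#'
#' @param time,event As in [km_estimate()].
#' @param covariate Numeric covariate, finite and non-constant.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A one-row tibble: `beta`, `se`, `hr`, `conf_low`, `conf_high`,
#'   `wald_p`, `n`, `n_events`, `converged`.
#' @export
cox_univariate <- function(time, event, covariate, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (!all(is.finite(covariate))) rlang::abort("`covariate` must be finite.")
  if (stats::sd(covariate) == 0) rlang::abort("`covariate` is constant.")
  if (sum(event) < 2) rlang::abort("Need >= 2 events.")
  fit <- survival::coxph(survival::Surv(time, event) ~ covariate,
                         ties = ties,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1L, 1L]))
  converged <- is.finite(beta) && is.finite(se) &&
    fit$iter < 50 && abs(beta) < 15
  tibble::tibble(
    beta = beta,
    se = se,
    hr = exp(beta),
    conf_low = exp(beta - 1.96 * se),
    conf_high = exp(beta + 1.96 * se),
    wald_p = 2 * stats::pnorm(-abs(beta / se)),
    n = fit$n,
    n_events = fit$nevent,
    converged = converged
  )
}

#' Cumulative/dynamic time-dependent AUC
#'
#' Discrimination of a continuous marker for events occurring by a fixed
#' horizon, using the Kaplan-Meier-based cumulative/dynamic estimator:
#' for each cutoff `c`,
#' `Sens(c) = (1 - S(t | M > c)) P(M > c) / (1 - S(t))` and
#' `Spec(c) = S(t | M <= c) P(M <= c) / S(t)`, with subgroup Kaplan-Meier
#' curves, swept over all observed cutoffs; the AUC is the trapezoidal area
#' under the resulting ROC curve. Without censoring this reduces exactly to
#' the binary AUC with cases defined by `T <= horizon`.
#'
#' @param marker Numeric risk marker (higher = higher risk).
#' @param time,event As in [km_estimate()].
#' @param horizon Evaluation time, in the follow-up range.
#' @return A list: `auc`, `horizon`, and `roc` tibble (`cutoff`, `tpr`, `fpr`).
#' @export
time_dependent_auc <- function(marker, time, event, horizon) {
  n <- length(marker)
  stopifnot(length(time) == n, length(event) == n)
  s_t <- km_surv_at(time, event, horizon)
  if (s_t <= 0 || s_t >= 1) {
    rlang::abort("Overall survival at the horizon is 0 or 1; AUC undefined.")
  }
  cuts <- sort(unique(marker))
  pts <- purrr::map_dfr(cuts, function(cc) {
    hi <- marker > cc
    if (!any(hi) || all(hi)) {
      return(tibble::tibble(cutoff = cc, tpr = NA_real_, fpr = NA_real_))
    }
    s_hi <- km_surv_at(time[hi], event[hi], horizon)
    s_lo <- km_surv_at(time[!hi], event[!hi], horizon)
    sens <- (1 - s_hi) * mean(hi) / (1 - s_t)
    spec <- s_lo * mean(!hi) / s_t
    tibble::tibble(cutoff = cc,
                   tpr = min(max(sens, 0), 1),
                   fpr = min(max(1 - spec, 0), 1))
  })
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  # traverse in threshold-sweep order (high cutoff -> low), the natural ROC
  # path; sorting by FPR instead lets floating-point noise in the KM-based
  # rates break the traversal
  roc <- dplyr::arrange(
    dplyr::bind_rows(tibble::tibble(cutoff = Inf, tpr = 0, fpr = 0),
                     pts,
                     tibble::tibble(cutoff = -Inf, tpr = 1, fpr = 1)),
    dplyr::desc(.data$cutoff))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(auc = auc, horizon = horizon, roc = roc)
}

#' Correlation with significance test
#'
#' Pearson or Spearman (midrank) correlation with the usual t
#' approximation for the p-value.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A one-row tibble: `estimate`, `p_value`, `method`, `n`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L) {
    rlang::abort("`x` and `y` must have equal length >= 3.")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("Correlation undefined for a constant vector.")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  tibble::tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
                 method = method, n = length(x))
}

#' Rank-based group comparison
#'
#' Wilcoxon rank-sum for two groups, Kruskal-Wallis for three or more —
#' the standard report-table comparisons, wrapped for convenience.
#'
#' @param values Numeric vector.
#' @param group Grouping vector.
#' @return A one-row tibble: `statistic`, `p_value`, `test`, `n_groups`.
#' @export
compare_groups <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) rlang::abort("Need >= 2 groups.")
  if (nlevels(group) == 2L) {
    ht <- suppressWarnings(stats::wilcox.test(values ~ group))
    test <- "wilcoxon"
  } else {
    ht <- stats::kruskal.test(values ~ group)
    test <- "kruskal-wallis"
  }
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 test = test, n_groups = nlevels(group))
}
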