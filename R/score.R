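#' Per-patient WM_Score from the DEG expression matrix
#'
#' Principal-component scoring of the pattern-discriminating genes: DEG
#' rows are z-scored across samples and the standardized samples x genes
#' matrix is decomposed by SVD; each patient's score is the sum of the
#' first two principal-component coordinates, `WM_Score = PC1 + PC2`. Each
#' component's sign is fixed so the sum of its gene loadings is positive
#' (principal components are otherwise sign-indeterminate; anchoring on the
#' majority loading direction is stable under small changes to the gene
#' set, which the largest-single-loading convention is not). A zero loading
#' sum falls back to making the largest-magnitude loading positive.
#'
#' @param x_degs Genes x samples matrix restricted to the DEG signature
#'   (>= 2 genes, >= 3 samples). Constant gene rows are dropped with a
#'   warning.
#' @return An object of class `wm_scored`: list with `scores` (tibble:
#'   `sample_id`, `pc1`, `pc2`, `wm_score`), `loadings` (genes x 2,
#'   unit-norm columns), `explained_variance` (proportions for PC1, PC2),
#'   and `cutpoint`/`group` slots filled by [optimal_cutpoint()] /
#'   [dichotomize()].
#' @export
compute_wm_score <- function(x_degs) {
  check_expression_matrix(x_degs, "x_degs")
  if (ncol(x_degs) < 3L) rlang::abort("Need >= 3 samples.")
  z <- zscore_rows(x_degs, on_constant = "drop")
  if (nrow(z) < 2L) rlang::abort("Need >= 2 non-constant DEG rows.")
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  if (length(pc$sdev) < 2L || pc$sdev[2L] < 1e-12) {
    rlang::abort("Standardized DEG matrix has rank < 2; cannot take PC1 + PC2.")
  }
  rot <- pc$rotation[, 1:2, drop = FALSE]
  scores <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    s <- sum(rot[, j])
    if (s == 0) s <- rot[which.max(abs(rot[, j])), j]
    if (s < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  structure(list(
    scores = tibble::tibble(
      sample_id = colnames(x_degs),
      pc1 = unname(scores[, 1L]),
      pc2 = unname(scores[, 2L]),
      wm_score = unname(scores[, 1L] + scores[, 2L])
    ),
    loadings = rot,
    explained_variance = ev,
    cutpoint = NULL,
    group = NULL
  ), class = "wm_scored")
}

#' Survival-optimal cutpoint by maximally selected log-rank statistic
#'
#' Scans every distinct score value whose induced split (`score > c` vs
#' `score <= c`) leaves at least `minprop` of the cohort on each side, and
#' returns the cut maximizing the absolute standardized log-rank statistic
#' (ties broken toward the smaller cutpoint). The selected statistic is
#' maximally selected and therefore optimistically biased; it is used here
#' only to define the grouping, not as a test.
#'
#' @param scores Numeric score per sample.
#' @param time,event Survival data aligned with `scores`.
#' @param minprop Minimum fraction of samples per side (default 0.1).
#' @return A list: `cutpoint`, `statistic` (standardized log-rank at the
#'   cut), `n_candidates`, and `candidates` tibble (`cutpoint`, `z`).
#' @export
optimal_cutpoint <- function(scores, time, event, minprop = 0.1) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  if (n < 10L) rlang::abort("Need >= 10 samples for cutpoint selection.")
  vals <- sort(unique(scores))
  min_side <- max(1L, ceiling(minprop * n))
  feasible <- vals[vapply(vals, function(cc) {
    nh <- sum(scores > cc)
    nh >= min_side && (n - nh) >= min_side
  }, logical(1L))]
  if (!length(feasible)) rlang::abort("No feasible cutpoint candidate.")
  z <- vapply(feasible, function(cc) logrank_z(time, event, scores > cc),
              numeric(1L))
  ok <- is.finite(z)
  if (!any(ok)) rlang::abort("Log-rank statistic undefined at every candidate.")
  feasible <- feasible[ok]; z <- z[ok]
  best <- which.max(abs(z))  # first maximum = smallest cutpoint on ties
  list(cutpoint = feasible[[best]],
       statistic = z[[best]],
       n_candidates = length(feasible),
       candidates = tibble::tibble(cutpoint = feasible, z = z))
}

# Standardized log-rank statistic (O - E) / sqrt(V) for the TRUE group.
logrank_z <- function(time, event, in_group) {
  dt <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t0 in dt) {
    at_risk <- time >= t0
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & in_group)
    d <- sum(time == t0 & event == 1)
    d1 <- sum(time == t0 & event == 1 & in_group)
    o <- o + d1
    e <- e + d * n1 / n_t
    if (n_t > 1) {
      v <- v + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
    }
  }
  if (v <= 0) return(NA_real_)
  (o - e) / sqrt(v)
}

#' Dichotomize scores at a cutpoint
#'
#' High group if and only if the score strictly exceeds the cutpoint
#' (scores equal to the cutpoint are low).
#'
#' @param scores Numeric scores.
#' @param cutpoint Finite cut value.
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize <- function(scores, cutpoint) {
  if (!is.finite(cutpoint)) rlang::abort("`cutpoint` must be finite.")
  factor(ifelse(scores > cutpoint, "high", "low"), levels = c("low", "high"))
}

#' Attach a survival-optimal grouping to a scored cohort
#'
#' Convenience composition of [optimal_cutpoint()] and [dichotomize()] on a
#' [compute_wm_score()] result.
#'
#' @param scored A `wm_scored` object.
#' @param clinical Tibble with `sample_id`, `time`, `event` covering the
#'   scored samples.
#' @param minprop Passed to [optimal_cutpoint()].
#' @return The `wm_scored` object with `cutpoint`, `cut_statistic` and a
#'   `group` column added to `$scores`.
#' @export
apply_cutpoint <- function(scored, clinical, minprop = 0.1) {
  stopifnot(inherits(scored, "wm_scored"))
  idx <- match(scored$scores$sample_id, clinical$sample_id)
  if (anyNA(idx)) rlang::abort("Clinical table does not cover all scored samples.")
  cp <- optimal_cutpoint(scored$scores$wm_score,
                         clinical$time[idx], clinical$event[idx],
                         minprop = minprop)
  scored$cutpoint <- cp$cutpoint
  scored$cut_statistic <- cp$statistic
  scored$scores$group <- dichotomize(scored$scores$wm_score, cp$cutpoint)
  scored
}

#' @export
print.wm_scored <- function(x, ...) {
  cat(sprintf("<wm_scored> %d samples; PC1+PC2 explain %.1f%% of variance",
              nrow(x$scores), 100 * sum(x$explained_variance)))
  if (!is.null(x$cutpoint)) {
    cat(sprintf("; cutpoint %.3f (%d high / %d low)", x$cutpoint,
                sum(x$scores$group == "high"), sum(x$scores$group == "low")))
  }
  cat("\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wm_scored <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.wm_scored <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_genes = nrow(x$loadings),
    var_pc1 = x$explained_variance[[1L]],
    var_pc2 = x$explained_variance[[2L]],
    cutpoint = if (is.null(x$cutpoint)) NA_real_ else x$cutpoint,
    n_high = if (is.null(x$scores$group)) NA_integer_ else
      sum(x$scores$group == "high")
  )
}
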