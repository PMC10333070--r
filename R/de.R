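#' Empirical-Bayes moderated two-group t-test
#'
#' Per-gene two-group comparison with variance shrinkage: gene-wise
#' residual variances are shrunk toward a common prior variance `s0_sq`
#' with `d0` prior degrees of freedom, both estimated from the data by
#' method of moments on the log residual variances (a scaled-F fit with
#' closed-form trigamma inversion by Newton iteration). The moderated t
#' statistic is referred to a t distribution with `d0 + d_g` degrees of
#' freedom. `d0 = 0` recovers the ordinary equal-variance t-test; as
#' `d0 -> Inf` the statistic approaches a z-score with fixed variance
#' `s0_sq`.
#'
#' @param x Genes x samples numeric matrix (log scale).
#' @param groups Two-level factor (or coercible) over samples; the log fold
#'   change is the second level minus the first.
#' @param d0,s0_sq Optional prior degrees of freedom and prior variance;
#'   estimated from the data when `NULL`. `d0` may be `0` or `Inf`.
#' @return A tibble of class `wm_de`, one row per gene: `gene`, `mean_a`,
#'   `mean_b`, `log_fc`, `t`, `df_total`, `p_value`, `p_adjusted`
#'   (Benjamini-Hochberg). The fitted prior is stored in attributes `d0`
#'   and `s0_sq`.
#' @export
moderated_t_test <- function(x, groups, d0 = NULL, s0_sq = NULL) {
  check_expression_matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) rlang::abort("`groups` must have exactly 2 levels.")
  if (length(groups) != ncol(x)) {
    rlang::abort("`groups` must have one entry per sample.")
  }
  na <- sum(groups == levels(groups)[1L])
  nb <- sum(groups == levels(groups)[2L])
  if (na < 2L || nb < 2L) rlang::abort("Each group needs >= 2 samples.")

  a <- x[, groups == levels(groups)[1L], drop = FALSE]
  b <- x[, groups == levels(groups)[2L], drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  dg <- na + nb - 2L
  s2 <- (rowSums((a - mean_a)^2) + rowSums((b - mean_b)^2)) / dg

  if (is.null(d0) || is.null(s0_sq)) {
    prior <- estimate_variance_prior(s2, dg)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s0_sq)) s0_sq <- prior$s0_sq
  }
  if (d0 < 0 || s0_sq < 0) rlang::abort("Prior parameters must be non-negative.")

  s2_post <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else {
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  tstat <- (mean_b - mean_a) / se
  df_total <- d0 + dg
  p <- 2 * stats::pt(-abs(tstat), df = df_total)

  out <- tibble::tibble(
    gene = rownames(x),
    mean_a = unname(mean_a),
    mean_b = unname(mean_b),
    log_fc = unname(mean_b - mean_a),
    t = unname(tstat),
    df_total = df_total,
    p_value = unname(p),
    p_adjusted = bh_adjust(unname(p))
  )
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "groups") <- levels(groups)
  class(out) <- c("wm_de", class(out))
  out
}

# Method-of-moments fit of the scaled-F variance prior on log variances
# (matching the empirical-Bayes formulation used for microarray DE).
estimate_variance_prior <- function(s2, dg) {
  s2 <- pmax(s2, 1e-300)
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  e_bar <- mean(e)
  n <- length(e)
  excess <- mean((e - e_bar)^2) * n / (n - 1) - trigamma(dg / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(e_bar)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Solve trigamma(y) = x by Newton iteration on 1/y scaling (monotone,
# convex); tolerance 1e-8 on the step.
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg adjustment
#'
#' Thin validated wrapper around the standard step-up FDR adjustment.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, monotone non-decreasing in rank.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    rlang::abort("p-values must be finite and in [0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}

#' Intersect differential-expression tables
#'
#' Genes significant in every supplied contrast (p-value at or below the
#' threshold; the boundary is inclusive), in the gene order of the first
#' table — the Venn-style intersection that feeds the scoring stage.
#'
#' @param tables List of [moderated_t_test()] results over a shared gene
#'   universe (typically the reference cluster against each other cluster).
#' @param p_threshold Significance threshold on p-values (default 0.005).
#' @param adjusted Use BH-adjusted p-values instead of raw (default
#'   `FALSE`, matching the raw-p convention).
#' @return Character vector of gene symbols.
#' @export
intersect_degs <- function(tables, p_threshold = 0.005, adjusted = FALSE) {
  if (!length(tables)) rlang::abort("Need >= 1 contrast table.")
  universe <- tables[[1L]]$gene
  for (tb in tables[-1L]) {
    if (!identical(sort(tb$gene), sort(universe))) {
      rlang::abort("Contrast tables do not share a gene universe.")
    }
  }
  col <- if (adjusted) "p_adjusted" else "p_value"
  sig <- lapply(tables, function(tb) tb$gene[tb[[col]] <= p_threshold])
  Reduce(intersect, c(list(universe), sig))
}

#' @exportS3Method generics::glance
glance.wm_de <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    d0 = attr(x, "d0"),
    s0_sq = attr(x, "s0_sq"),
    n_sig_raw_005 = sum(x$p_value <= 0.005),
    n_sig_adj_05 = sum(x$p_adjusted <= 0.05)
  )
}
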