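#' Single-sample gene-set enrichment (ssGSEA)
#'
#' Per-sample, rank-based enrichment score for each gene set: genes are
#' ordered by decreasing expression within the sample and the score is the
#' integral of the difference between the weighted in-set empirical CDF
#' (weights `rank^tau`) and the uniform out-of-set CDF over the ordered
#' list. Monotone per-sample transformations of the expression leave the
#' scores unchanged. Ties are broken deterministically by adding a
#' `1e-9 * gene index` perturbation before ranking.
#'
#' @param x Genes x samples numeric matrix (log scale).
#' @param gene_sets Named list of character vectors of gene symbols.
#' @param tau Rank-weight exponent (canonical 0.25).
#' @param normalize Divide all scores by the global score range (default
#'   `TRUE`; turned off for the ESTIMATE-style composites).
#' @return A sets x samples numeric matrix of class `wm_enrichment`, with
#'   attributes `method`, `tau` and `dropped` (sets with no matched genes,
#'   dropped with a warning).
#' @export
ssgsea_scores <- function(x, gene_sets, tau = 0.25, normalize = TRUE) {
  check_expression_matrix(x)
  sets <- match_gene_sets(gene_sets, rownames(x))
  n_genes <- nrow(x)
  perturb <- 1e-9 * seq_len(n_genes)

  score_one <- function(values, in_set) {
    ord <- order(values + perturb, decreasing = TRUE)
    in_ord <- in_set[ord]
    # rank value of the gene at each ordered position (largest value -> N)
    rnk <- (n_genes:1)
    w <- rnk^tau
    w[!in_ord] <- 0
    step_in <- cumsum(w) / sum(w)
    n_out <- n_genes - sum(in_ord)
    step_out <- cumsum(!in_ord) / n_out
    sum(step_in - step_out)
  }

  scores <- matrix(NA_real_, length(sets), ncol(x),
                   dimnames = list(names(sets), colnames(x)))
  for (s in seq_along(sets)) {
    in_set <- rownames(x) %in% sets[[s]]
    scores[s, ] <- apply(x, 2L, score_one, in_set = in_set)
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  structure(scores, class = c("wm_enrichment", "matrix"),
            method = "ssgsea", tau = tau,
            dropped = attr(sets, "dropped"))
}

# Intersect gene sets with the measured genes; drop empty ones with warning.
match_gene_sets <- function(gene_sets, universe) {
  if (is.null(names(gene_sets))) rlang::abort("`gene_sets` must be named.")
  matched <- lapply(gene_sets, function(g) intersect(toupper(g), universe))
  empty <- names(matched)[lengths(matched) == 0L]
  if (length(empty) == length(matched)) {
    rlang::abort("No gene set has any gene in the expression matrix.")
  }
  if (length(empty)) {
    rlang::warn(sprintf("Dropping %d gene set(s) with no matched genes: %s",
                        length(empty), paste(empty, collapse = ", ")))
    matched <- matched[lengths(matched) > 0L]
  }
  if (any(lengths(matched) >= length(universe))) {
    rlang::abort("A gene set covers every measured gene; scores are undefined.")
  }
  attr(matched, "dropped") <- empty
  matched
}

#' GSVA-style enrichment scores
#'
#' Estimates, per gene, a Gaussian-kernel expression CDF across samples
#' (bandwidth = per-gene SD / 4), converts the CDF values to per-sample
#' ranks, and runs a Kolmogorov-Smirnov-like random walk down the ranked
#' list with the symmetric rank statistic `|rank - (N+1)/2|` as in-set
#' weight. With `mx_diff = TRUE` the score is the sum of the maximum
#' positive and maximum negative walk deviations; otherwise the deviation
#' largest in magnitude.
#'
#' @param x Genes x samples numeric matrix; at least two samples (the
#'   cross-sample density is part of the method).
#' @param gene_sets Named list of character vectors.
#' @param mx_diff Score definition, see above.
#' @return A sets x samples matrix of class `wm_enrichment`.
#' @export
gsva_scores <- function(x, gene_sets, mx_diff = TRUE) {
  check_expression_matrix(x)
  if (ncol(x) < 2L) {
    rlang::abort("GSVA-style scoring needs >= 2 samples; use ssgsea_scores().")
  }
  sets <- match_gene_sets(gene_sets, rownames(x))
  n_genes <- nrow(x); n_samp <- ncol(x)

  # per-gene kernel CDF evaluated at each sample's own value
  z <- matrix(NA_real_, n_genes, n_samp, dimnames = dimnames(x))
  for (i in seq_len(n_genes)) {
    v <- x[i, ]
    h <- stats::sd(v) / 4
    z[i, ] <- if (h > 0) {
      rowMeans(stats::pnorm(outer(v, v, "-") / h))
    } else {
      rep(0.5, n_samp)
    }
  }

  perturb <- 1e-9 * seq_len(n_genes)
  score_one <- function(zv, in_set) {
    ord <- order(zv + perturb, decreasing = TRUE)
    in_ord <- in_set[ord]
    w <- abs(seq_len(n_genes) - (n_genes + 1) / 2)
    w[!in_ord] <- 0
    walk <- cumsum(w) / sum(w) - cumsum(!in_ord) / (n_genes - sum(in_ord))
    if (mx_diff) max(walk, 0) + min(walk, 0) else walk[which.max(abs(walk))]
  }

  scores <- matrix(NA_real_, length(sets), n_samp,
                   dimnames = list(names(sets), colnames(x)))
  for (s in seq_along(sets)) {
    in_set <- rownames(x) %in% sets[[s]]
    scores[s, ] <- apply(z, 2L, score_one, in_set = in_set)
  }
  structure(scores, class = c("wm_enrichment", "matrix"),
            method = "gsva", mx_diff = mx_diff,
            dropped = attr(sets, "dropped"))
}

#' ESTIMATE-style immune and stromal scores
#'
#' Unnormalized ssGSEA scores of an immune and a stromal signature, plus
#' their sum as the combined score. Tumour purity (a platform-specific
#' calibration) is deliberately not computed.
#'
#' @param x Genes x samples numeric matrix.
#' @param immune_set,stromal_set Character vectors of signature genes.
#' @return A tibble: `sample_id`, `immune`, `stromal`, `estimate`.
#' @export
estimate_scores <- function(x, immune_set, stromal_set) {
  sc <- ssgsea_scores(x, list(immune = immune_set, stromal = stromal_set),
                      normalize = FALSE)
  tibble::tibble(
    sample_id = colnames(sc),
    immune = sc["immune", ],
    stromal = sc["stromal", ],
    estimate = sc["immune", ] + sc["stromal", ]
  )
}

#' Tidy an enrichment matrix into long form
#'
#' @param x A `wm_enrichment` matrix.
#' @param ... Unused.
#' @return A tibble: `gene_set`, `sample_id`, `score`.
#' @exportS3Method generics::tidy
tidy.wm_enrichment <- function(x, ...) {
  m <- unclass(x)
  attr(m, "method") <- NULL; attr(m, "tau") <- NULL
  attr(m, "mx_diff") <- NULL; attr(m, "dropped") <- NULL
  tibble::tibble(
    gene_set = rep(rownames(m), times = ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    score = as.vector(m)
  )
}
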