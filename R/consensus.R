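#' Resampling-based consensus clustering
#'
#' Monti-style consensus clustering of samples on a feature panel (for
#' example the 26-writer panel). Each iteration subsamples a fraction of
#' the samples without replacement, clusters them, and the consensus index
#' of a sample pair is the fraction of co-sampled iterations in which the
#' pair co-clustered. Final labels come from hierarchical clustering of
#' `1 - consensus`.
#'
#' Genes are z-scored before the sample-sample distance (1 - Pearson
#' correlation); the base clusterer is hierarchical agglomeration with
#' average linkage cut at `k` (`method = "kmeans"` is available as an
#' alternative).
#'
#' @param x Genes x samples numeric matrix, already restricted to the
#'   feature panel of interest.
#' @param k Number of clusters (2 .. n_samples - 1).
#' @param n_iter Number of subsampling iterations (default 500).
#' @param sample_frac Fraction of samples per iteration (default 0.8).
#' @param seed Integer seed; the full iteration stream is reproducible.
#' @param method Base clusterer, `"hclust"` (default) or `"kmeans"`.
#' @param exhaustive If `TRUE`, enumerate every subsample of size
#'   `ceiling(sample_frac * n)` instead of drawing randomly (small n only).
#' @return An object of class `wm_consensus`: list with `k`, `consensus`
#'   (n x n), `indicator_counts` (times co-sampled), `labels` (renumbered by
#'   descending cluster size), `cdf` (tibble over a grid on `[0, 1]`) and
#'   `pac` (proportion of ambiguous clustering, CDF(0.9) - CDF(0.1)).
#' @export
consensus_matrix <- function(x, k, n_iter = 500, sample_frac = 0.8,
                             seed = 1L, method = c("hclust", "kmeans"),
                             exhaustive = FALSE) {
  method <- match.arg(method)
  check_expression_matrix(x)
  n <- ncol(x)
  if (k < 2 || k > n - 1) {
    rlang::abort(sprintf("`k` must be in [2, %d]; got %s.", n - 1, k))
  }
  z <- zscore_rows(x)  # errors on constant rows, naming the gene
  m <- ceiling(sample_frac * n)
  if (m < k) rlang::abort("Subsample size smaller than `k`.")

  if (exhaustive) {
    if (choose(n, m) > 1e4) {
      rlang::abort("Exhaustive enumeration is limited to choose(n, m) <= 10000.")
    }
    subsets <- utils::combn(n, m, simplify = FALSE)
  } else {
    set.seed(as.integer(seed))
    subsets <- lapply(seq_len(n_iter), function(i) sort(sample.int(n, m)))
  }

  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  for (idx in subsets) {
    zi <- z[, idx, drop = FALSE]
    lab <- if (method == "hclust") {
      stats::cutree(stats::hclust(cor_dist(zi), method = "average"), k)
    } else {
      stats::kmeans(t(zi), centers = k, nstart = 5)$cluster
    }
    same <- outer(lab, lab, `==`) * 1
    co_cluster[idx, idx] <- co_cluster[idx, idx] + same
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
  }
  consensus <- ifelse(co_sample > 0, co_cluster / pmax(co_sample, 1), 0)
  diag(consensus) <- 1
  dimnames(consensus) <- list(colnames(x), colnames(x))
  dimnames(co_sample) <- dimnames(consensus)

  labels <- consensus_labels(consensus, k)
  vals <- consensus[upper.tri(consensus)]
  grid <- seq(0, 1, by = 0.01)
  cdf <- tibble::tibble(value = grid,
                        cdf = vapply(grid, function(g) mean(vals <= g),
                                     numeric(1L)))
  pac <- mean(vals <= 0.9) - mean(vals <= 0.1)

  structure(list(
    k = as.integer(k), consensus = consensus, indicator_counts = co_sample,
    labels = labels, cdf = cdf, pac = pac,
    n_iter = length(subsets), sample_frac = sample_frac, method = method
  ), class = "wm_consensus")
}

# Final labels: hierarchical clustering of 1 - consensus, renumbered so
# that cluster 1 is the largest.
consensus_labels <- function(consensus, k) {
  d <- stats::as.dist(1 - consensus)
  lab <- stats::cutree(stats::hclust(d, method = "average"), k)
  renumber_by_size(lab)
}

renumber_by_size <- function(lab) {
  sizes <- table(lab)
  new_order <- names(sizes)[order(-sizes, as.integer(names(sizes)))]
  out <- match(as.character(lab), new_order)
  names(out) <- names(lab)
  out
}

#' Consensus clustering over a range of k
#'
#' @inheritParams consensus_matrix
#' @param k_range Integer vector of consecutive k values (e.g. `2:6`).
#' @return A named list of [consensus_matrix()] results, class
#'   `wm_consensus_sweep`.
#' @export
consensus_sweep <- function(x, k_range = 2:6, n_iter = 500, sample_frac = 0.8,
                            seed = 1L, method = c("hclust", "kmeans")) {
  method <- match.arg(method)
  if (!length(k_range)) rlang::abort("`k_range` must be non-empty.")
  res <- lapply(k_range, function(k) {
    consensus_matrix(x, k, n_iter = n_iter, sample_frac = sample_frac,
                     seed = seed, method = method)
  })
  names(res) <- paste0("k", k_range)
  structure(res, class = "wm_consensus_sweep")
}

#' Select the number of clusters by PAC with a delta-area elbow
#'
#' The proportion of ambiguous clustering (PAC) is the consensus-CDF mass
#' between 0.1 and 0.9 over the upper-triangle consensus indices. Every k
#' whose PAC lies within `pac_tol` of the minimum is treated as equally
#' stable (when clusters are nested, several k can be near-perfectly
#' stable at once), and among those candidates the largest k that still
#' yields an appreciable relative gain in consensus-CDF area
#' (`delta_area >= min_gain`) is selected — the Monti-style elbow. When no
#' candidate clears the gain threshold the smallest candidate k wins, so
#' exact PAC ties without any stability gain resolve toward smaller k.
#'
#' @param results A [consensus_sweep()] result or list of `wm_consensus`
#'   over consecutive k.
#' @param pac_tol PAC values within this distance of the minimum count as
#'   tied (default 0.01).
#' @param min_gain Minimum relative delta-area gain for preferring a larger
#'   k (default 0.05).
#' @return A list with `k` (selected) and `criteria` (tibble: k, pac,
#'   cdf_area, delta_area).
#' @export
select_k <- function(results, pac_tol = 0.01, min_gain = 0.05) {
  if (!length(results)) rlang::abort("Empty k range.")
  ks <- unname(vapply(results, function(r) r$k, integer(1L)))
  pac <- unname(vapply(results, function(r) r$pac, numeric(1L)))
  area <- vapply(results, function(r) {
    # trapezoid over the stored CDF grid
    with(r$cdf, sum(diff(value) * (utils::head(cdf, -1) + utils::tail(cdf, -1)) / 2))
  }, numeric(1L))
  area <- unname(area)
  ord <- order(ks)
  ks <- ks[ord]; pac <- pac[ord]; area <- area[ord]
  delta <- c(NA_real_, diff(area) / utils::head(area, -1))
  # gain of the smallest k in range is undefined; it is always admissible
  gain <- ifelse(is.na(delta), Inf, delta)
  cand <- which(pac <= min(pac) + pac_tol)
  good <- cand[gain[cand] >= min_gain]
  best <- if (length(good)) ks[max(good)] else ks[min(cand)]
  list(k = best,
       criteria = tibble::tibble(k = ks, pac = pac, cdf_area = area,
                                 delta_area = delta))
}

#' Extract cluster labels from a consensus result
#'
#' Labels are deterministic given the consensus matrix and are renumbered by
#' descending cluster size (cluster 1 is the largest).
#'
#' @param result A `wm_consensus` (or a `wm_consensus_sweep` together with `k`).
#' @param k When `result` is a sweep, which k to extract.
#' @return Named integer vector of cluster labels per sample.
#' @export
assign_clusters <- function(result, k = NULL) {
  if (inherits(result, "wm_consensus_sweep")) {
    if (is.null(k)) rlang::abort("Supply `k` to pick a sweep entry.")
    entry <- paste0("k", k)
    if (!entry %in% names(result)) {
      rlang::abort(sprintf("No consensus result for k = %s.", k))
    }
    result <- result[[entry]]
  }
  stopifnot(inherits(result, "wm_consensus"))
  result$labels
}

#' @export
print.wm_consensus <- function(x, ...) {
  cat(sprintf("<wm_consensus> k = %d, n = %d, %d iterations, PAC = %.3f\n",
              x$k, ncol(x$consensus), x$n_iter, x$pac))
  invisible(x)
}
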