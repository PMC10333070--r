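#' Binary sample x gene mutation matrix
#'
#' Collapses a MAF-lite mutation table to a binary matrix: 1 if the sample
#' carries at least one mutation of the counted classes in the gene.
#'
#' @param mutations Tibble with `sample_id`, `gene_symbol`, `variant_class`
#'   (see [read_mutation_table()]).
#' @param samples Optional sample universe (includes unmutated samples as
#'   all-zero rows); defaults to the samples present in the table.
#' @param genes Optional gene universe; defaults to the genes present.
#' @param classes Variant classes that count (default [non_silent_classes()]).
#' @return Integer 0/1 matrix, samples x genes.
#' @export
mutation_matrix <- function(mutations, samples = NULL, genes = NULL,
                            classes = non_silent_classes()) {
  bad <- setdiff(unique(mutations$variant_class), variant_classes())
  if (length(bad)) {
    rlang::abort(sprintf("Unknown variant_class value(s): %s. Accepted: %s",
                         paste(bad, collapse = ", "),
                         paste(variant_classes(), collapse = ", ")))
  }
  hits <- mutations[mutations$variant_class %in% classes, , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(mutations$sample_id))
  if (is.null(genes)) genes <- sort(unique(mutations$gene_symbol))
  m <- matrix(0L, length(samples), length(genes),
              dimnames = list(samples, genes))
  hits <- hits[hits$sample_id %in% samples & hits$gene_symbol %in% genes, ]
  if (nrow(hits)) {
    m[cbind(match(hits$sample_id, samples), match(hits$gene_symbol, genes))] <- 1L
  }
  m
}

#' Per-gene and cohort mutation frequencies
#'
#' @param mut Binary samples x genes matrix from [mutation_matrix()].
#' @return A list: `per_gene` tibble (`gene_symbol`, `n_mutated`,
#'   `frequency`) and `cohort_fraction`, the fraction of samples with at
#'   least one mutation in any panel gene.
#' @export
mutation_frequency <- function(mut) {
  if (nrow(mut) < 1L) rlang::abort("Need >= 1 sample.")
  list(
    per_gene = tibble::tibble(
      gene_symbol = colnames(mut),
      n_mutated = unname(colSums(mut)),
      frequency = unname(colSums(mut) / nrow(mut))
    ),
    cohort_fraction = mean(rowSums(mut) > 0)
  )
}

#' Tumour mutational burden per sample
#'
#' Counts non-silent mutation records per sample; with a capture size in
#' megabases the count becomes a density per Mb.
#'
#' @param mutations MAF-lite tibble.
#' @param samples Optional sample universe (unmutated samples get burden 0).
#' @param per_mb_size Optional capture size in Mb.
#' @param classes Classes counted as non-silent.
#' @return A tibble: `sample_id`, `n_nonsilent`, `tmb`.
#' @export
compute_tmb <- function(mutations, samples = NULL, per_mb_size = NULL,
                        classes = non_silent_classes()) {
  bad <- setdiff(unique(mutations$variant_class), variant_classes())
  if (length(bad)) {
    rlang::abort(sprintf("Unknown variant_class value(s): %s",
                         paste(bad, collapse = ", ")))
  }
  if (is.null(samples)) samples <- sort(unique(mutations$sample_id))
  hits <- mutations[mutations$variant_class %in% classes &
                      mutations$sample_id %in% samples, , drop = FALSE]
  counts <- table(factor(hits$sample_id, levels = samples))
  tibble::tibble(
    sample_id = samples,
    n_nonsilent = as.integer(counts),
    tmb = if (is.null(per_mb_size)) as.numeric(counts)
          else as.numeric(counts) / per_mb_size
  )
}

#' Pairwise mutation co-occurrence by Fisher's exact test
#'
#' For every pair of genes mutated in at least `min_mutated` samples,
#' tests the 2x2 co-mutation table with a two-sided Fisher exact test.
#' The reported odds ratio is the sample odds ratio with a Haldane 0.5
#' continuity correction when any cell is zero. Pairs are labelled
#' co-occurring (OR > 1) or mutually exclusive (OR < 1) at BH-adjusted
#' q < 0.05.
#'
#' @param mut Binary samples x genes matrix.
#' @param min_mutated Minimum mutated samples per gene (default 3).
#' @return A tibble: `gene_a`, `gene_b`, `n_both`, `n_a_only`, `n_b_only`,
#'   `n_neither`, `odds_ratio`, `p_value`, `q_value`, `label`.
#' @export
cooccurrence_fisher <- function(mut, min_mutated = 3) {
  keep <- colnames(mut)[colSums(mut) >= min_mutated]
  if (length(keep) < 2L) {
    rlang::abort(sprintf("Fewer than 2 genes mutated in >= %d samples.",
                         min_mutated))
  }
  pairs <- utils::combn(keep, 2L, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    a <- mut[, pr[[1L]]]; b <- mut[, pr[[2L]]]
    n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
    n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
    tab <- matrix(c(n11, n10, n01, n00), 2L)
    p <- min(stats::fisher.test(tab)$p.value, 1)  # guard fp overshoot at 1
    cells <- c(n11, n10, n01, n00)
    if (any(cells == 0)) cells <- cells + 0.5
    or <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
    tibble::tibble(gene_a = pr[[1L]], gene_b = pr[[2L]],
                   n_both = n11, n_a_only = n10, n_b_only = n01,
                   n_neither = n00, odds_ratio = or, p_value = p)
  })
  rows$q_value <- bh_adjust(rows$p_value)
  rows$label <- dplyr::case_when(
    rows$q_value < 0.05 & rows$odds_ratio > 1 ~ "co_occurring",
    rows$q_value < 0.05 & rows$odds_ratio < 1 ~ "exclusive",
    TRUE ~ "ns"
  )
  dplyr::arrange(rows, .data$p_value)
}
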