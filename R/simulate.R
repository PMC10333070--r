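#' Configuration for a synthetic gastric-cancer-like cohort
#'
#' Bundles the parameters of the synthetic-cohort generator. Defaults
#' emulate the structure of a merged microarray gastric-cancer cohort:
#' log2-scale expression, four latent writer-expression patterns with
#' proportions close to the 329/308/204/210 split reported for such
#' cohorts, pattern-specific blocks of differentially expressed genes,
#' right-censored survival driven by a latent risk score under proportional
#' hazards, and a sparse writer-panel mutation layer with one planted
#' co-occurring gene pair.
#'
#' @param n_samples Cohort size (default 400).
#' @param n_background_genes Unstructured noise genes (default 1500).
#' @param n_patterns Number of latent writer patterns (default 4; the
#'   default `writer_mean_matrix` is only defined for 4).
#' @param pattern_proportions Mixing proportions, summing to 1.
#' @param writer_mean_matrix `n_patterns` x 26 matrix of writer means on the
#'   log2 scale. The default gives each pattern a signature of +/-
#'   `writer_effect` over modification-class blocks, with the last pattern
#'   the immune-activated, best-prognosis analogue.
#' @param writer_effect Magnitude of the default writer signatures (1.5).
#' @param deg_block_size Genes per pattern-specific DEG block (150).
#' @param deg_effect Log2 shift of a block within its own pattern (1.0).
#' @param noise_sd Gaussian noise SD on the log2 scale (1.0).
#' @param surv_shape,surv_scale Baseline Weibull shape and scale (months);
#'   defaults 1.2 and 60 give a median around four years.
#' @param risk_coefficient Log hazard ratio per SD of the latent score (0.8).
#' @param censoring_rate Target fraction censored (0.3).
#' @param mutation_rate Background per-writer mutation probability (0.012,
#'   so roughly a quarter of samples carry a background panel mutation;
#'   with the planted pair's marginals included about a third of samples
#'   carry >= 1 panel mutation).
#' @param cooccur_pair Two writer symbols with planted co-occurrence
#'   (default CSTF3 and RBM15).
#' @param cooccur_marginal Marginal mutation probability of each planted
#'   gene (0.08).
#' @param cooccur_or Planted odds ratio between the pair (8).
#' @param seed Master seed governing every stage.
#' @return A list of class `wm_cohort_config`.
#' @export
cohort_config <- function(n_samples = 400,
                          n_background_genes = 1500,
                          n_patterns = 4,
                          pattern_proportions = c(0.31, 0.29, 0.20, 0.20),
                          writer_mean_matrix = NULL,
                          writer_effect = 1.5,
                          deg_block_size = 150,
                          deg_effect = 1.0,
                          noise_sd = 1.0,
                          surv_shape = 1.2,
                          surv_scale = 60,
                          risk_coefficient = 0.8,
                          censoring_rate = 0.3,
                          mutation_rate = 0.012,
                          cooccur_pair = c("CSTF3", "RBM15"),
                          cooccur_marginal = 0.08,
                          cooccur_or = 8,
                          seed = 1L) {
  if (n_samples < 1 || n_patterns < 1) {
    rlang::abort("Degenerate config: need >=1 sample and >=1 pattern.")
  }
  if (length(pattern_proportions) != n_patterns ||
      abs(sum(pattern_proportions) - 1) > 1e-8 ||
      any(pattern_proportions <= 0)) {
    rlang::abort("`pattern_proportions` must be positive and sum to 1.")
  }
  if (noise_sd <= 0) rlang::abort("`noise_sd` must be > 0.")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    rlang::abort("`censoring_rate` must be in [0, 1).")
  }
  if (mutation_rate < 0 || mutation_rate > 1 ||
      cooccur_marginal < 0 || cooccur_marginal > 1) {
    rlang::abort("Mutation rates must be in [0, 1].")
  }
  if (!is.finite(risk_coefficient)) rlang::abort("`risk_coefficient` must be finite.")
  if (cooccur_or < 0) rlang::abort("`cooccur_or` must be >= 0.")
  if (is.null(writer_mean_matrix)) {
    if (n_patterns != 4) {
      rlang::abort("Default writer signatures are defined for 4 patterns only;
supply `writer_mean_matrix`.")
    }
    writer_mean_matrix <- default_writer_means(writer_effect)
  }
  if (!is.matrix(writer_mean_matrix) ||
      nrow(writer_mean_matrix) != n_patterns ||
      ncol(writer_mean_matrix) != 26L) {
    rlang::abort("`writer_mean_matrix` must be n_patterns x 26.")
  }
  structure(list(
    n_samples = as.integer(n_samples),
    n_background_genes = as.integer(n_background_genes),
    n_patterns = as.integer(n_patterns),
    pattern_proportions = pattern_proportions,
    writer_mean_matrix = writer_mean_matrix,
    deg_block_size = as.integer(deg_block_size),
    deg_effect = deg_effect,
    noise_sd = noise_sd,
    surv_shape = surv_shape,
    surv_scale = surv_scale,
    risk_coefficient = risk_coefficient,
    censoring_rate = censoring_rate,
    mutation_rate = mutation_rate,
    cooccur_pair = toupper(cooccur_pair),
    cooccur_marginal = cooccur_marginal,
    cooccur_or = cooccur_or,
    seed = as.integer(seed)
  ), class = "wm_cohort_config")
}

# Default pattern signatures: +/- effect over modification-class blocks.
# Pattern 4 (the cluster-D analogue) is distinguished on the editing/APA
# axis; patterns come out mutually non-collinear so correlation distance
# separates them.
default_writer_means <- function(effect = 1.5) {
  reg <- writer_registry()
  cls <- as.character(reg$mod_class)
  sig <- function(up, dn) {
    v <- numeric(26L)
    v[cls %in% up] <- effect
    v[cls %in% dn] <- -effect
    v
  }
  m <- rbind(
    sig("m6A", "m1A"),
    sig("APA", "AtoI"),
    sig("m1A", "m6A"),
    sig("AtoI", "APA")
  )
  colnames(m) <- reg$gene_symbol
  m
}

#' Simulate a writer-patterned expression matrix
#'
#' Draws per-sample latent patterns at the configured proportions, writer
#' rows around their pattern-specific means, one DEG block per pattern
#' shifted by `deg_effect` within that pattern only, and unstructured
#' background genes, all with Gaussian noise on the log2 scale.
#'
#' @param config A [cohort_config()].
#' @return A list with `expression` (genes x samples matrix) and
#'   `true_pattern` (integer vector per sample).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "wm_cohort_config"))
  n <- config$n_samples
  p <- config$n_patterns
  set.seed(derive_seed(config$seed, 1L))
  counts <- floor(config$pattern_proportions * n)
  counts[1L] <- counts[1L] + (n - sum(counts))
  pattern <- sample(rep(seq_len(p), counts))
  sample_ids <- sprintf("S%04d", seq_len(n))

  writers <- config$writer_mean_matrix[pattern, , drop = FALSE]  # n x 26
  writers <- t(writers) + matrix(stats::rnorm(26L * n, 0, config$noise_sd),
                                 26L, n)
  rownames(writers) <- colnames(config$writer_mean_matrix)
  if (is.null(rownames(writers))) rownames(writers) <- writer_genes()

  bs <- config$deg_block_size
  stromal_pt <- min(2L, p)
  blocks <- lapply(seq_len(p), function(pt) {
    m <- matrix(stats::rnorm(bs * n, 0, config$noise_sd), bs, n)
    m[, pattern == pt] <- m[, pattern == pt] + config$deg_effect
    if (pt == p && p > 1L) {
      # reference (immune) block: its second half is suppressed under the
      # stromal pattern, giving the block two discriminating axes
      lower <- seq.int(floor(bs / 2) + 1L, bs)
      m[lower, pattern == stromal_pt] <-
        m[lower, pattern == stromal_pt] - config$deg_effect
    }
    rownames(m) <- sprintf("DEG%d_%03d", pt, seq_len(bs))
    m
  })

  nb <- config$n_background_genes
  background <- matrix(stats::rnorm(nb * n, 0, config$noise_sd), nb, n,
                       dimnames = list(sprintf("BG_%04d", seq_len(nb)), NULL))

  x <- rbind(writers, do.call(rbind, blocks), background)
  colnames(x) <- sample_ids
  list(expression = x, true_pattern = pattern)
}

#' Simulate right-censored survival from a latent risk score
#'
#' Event times follow a Weibull baseline with multiplicative hazard
#' `exp(beta * z)` where `z` is the standardized score; censoring is an
#' independent exponential whose rate is tuned so the expected censored
#' fraction matches `censoring_rate`.
#'
#' @param true_score Numeric latent score, one per sample.
#' @param config A [cohort_config()].
#' @param sample_ids Optional sample ids (default `S0001`...).
#' @return A tibble: `sample_id`, `time` (months), `event` (0/1).
#' @export
simulate_survival <- function(true_score, config,
                              sample_ids = sprintf("S%04d", seq_along(true_score))) {
  stopifnot(inherits(config, "wm_cohort_config"))
  if (!all(is.finite(true_score))) rlang::abort("`true_score` must be finite.")
  n <- length(true_score)
  set.seed(derive_seed(config$seed, 2L))
  z <- if (stats::sd(true_score) > 0) as.numeric(scale(true_score)) else true_score
  mult <- exp(config$risk_coefficient * z)
  u <- stats::runif(n)
  t_event <- config$surv_scale * (-log(u) / mult)^(1 / config$surv_shape)
  if (config$censoring_rate <= 0) {
    return(tibble::tibble(sample_id = sample_ids, time = t_event,
                          event = rep(1, n)))
  }
  # pick the exponential rate whose expected censored fraction hits target
  target <- config$censoring_rate
  f <- function(log_lambda) mean(1 - exp(-exp(log_lambda) * t_event)) - target
  log_lambda <- stats::uniroot(f, c(-20, 10))$root
  t_cens <- stats::rexp(n, rate = exp(log_lambda))
  tibble::tibble(
    sample_id = sample_ids,
    time = pmin(t_event, t_cens),
    event = as.numeric(t_event <= t_cens)
  )
}

#' Simulate a sparse writer-panel mutation table
#'
#' Background writers mutate independently at `mutation_rate`; the planted
#' pair is drawn from the 2x2 distribution with the configured marginals and
#' odds ratio. Each mutated sample-gene pair receives one non-silent variant
#' record; an additional thin layer of silent records exercises the
#' silent/non-silent split downstream.
#'
#' @param config A [cohort_config()].
#' @param sample_ids Optional sample ids.
#' @return A tibble: `sample_id`, `gene_symbol`, `variant_class`.
#' @export
simulate_mutations <- function(config,
                               sample_ids = sprintf("S%04d", seq_len(config$n_samples))) {
  stopifnot(inherits(config, "wm_cohort_config"))
  n <- length(sample_ids)
  set.seed(derive_seed(config$seed, 3L))
  genes <- writer_genes()
  pair <- config$cooccur_pair
  if (!all(pair %in% genes)) rlang::abort("`cooccur_pair` must be writer symbols.")
  p_cell <- cooccur_cell_probs(config$cooccur_marginal, config$cooccur_marginal,
                               config$cooccur_or)
  draw <- sample.int(4L, n, replace = TRUE, prob = p_cell)  # 11,10,01,00
  mut <- matrix(0L, n, length(genes), dimnames = list(sample_ids, genes))
  for (g in setdiff(genes, pair)) {
    mut[, g] <- stats::rbinom(n, 1L, config$mutation_rate)
  }
  mut[, pair[1L]] <- as.integer(draw %in% c(1L, 2L))
  mut[, pair[2L]] <- as.integer(draw %in% c(1L, 3L))

  idx <- which(mut == 1L, arr.ind = TRUE)
  classes <- character(0)
  if (nrow(idx)) {
    classes <- sample(c("missense", "frameshift_del", "nonsense", "splice_site"),
                      nrow(idx), replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1))
  }
  records <- tibble::tibble(
    sample_id = sample_ids[idx[, 1L]],
    gene_symbol = genes[idx[, 2L]],
    variant_class = classes
  )
  # thin silent layer, independent of the non-silent calls
  sil <- which(matrix(stats::rbinom(n * length(genes), 1L,
                                    0.2 * config$mutation_rate),
                      n, length(genes)) == 1L, arr.ind = TRUE)
  if (nrow(sil)) {
    records <- dplyr::bind_rows(records, tibble::tibble(
      sample_id = sample_ids[sil[, 1L]],
      gene_symbol = genes[sil[, 2L]],
      variant_class = "silent"
    ))
  }
  dplyr::arrange(records, .data$sample_id, .data$gene_symbol)
}

# Joint probability (both mutated) for given marginals and odds ratio,
# returned as the 4 cell probabilities (11, 10, 01, 00).
cooccur_cell_probs <- function(p1, p2, theta) {
  if (theta == 1) {
    p11 <- p1 * p2
  } else {
    a <- theta - 1
    b <- -(theta * (p1 + p2) + 1 - p1 - p2)
    cc <- theta * p1 * p2
    disc <- b^2 - 4 * a * cc
    if (disc < 0) rlang::abort("Infeasible (odds ratio, marginals) combination.")
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
    ok <- roots[roots >= lo - 1e-12 & roots <= hi + 1e-12]
    if (!length(ok)) rlang::abort("Infeasible (odds ratio, marginals) combination.")
    p11 <- min(max(ok[[1L]], lo), hi)
  }
  p <- c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)
  if (any(p < -1e-12)) rlang::abort("Infeasible (odds ratio, marginals) combination.")
  pmax(p, 0)
}

#' Simulate a complete synthetic cohort
#'
#' Composes [simulate_expression()], a latent risk score, survival and the
#' mutation layer under a single master seed, and plants gene sets: one per
#' DEG block, an immune signature enriched in the last (best-prognosis)
#' pattern and a stromal signature enriched in pattern 2. The latent
#' `true_score` is the standardized PC1 + PC2 of the reference pattern's
#' z-scored DEG block, oriented so the reference pattern scores lowest —
#' the quantity the downstream scoring stage is designed to recover.
#'
#' @param config A [cohort_config()].
#' @return An object of class `wm_cohort`: list with `expression`,
#'   `true_pattern`, `true_score`, `clinical`, `mutations`, `gene_sets`,
#'   `reference_pattern` and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "wm_cohort_config"))
  sim <- simulate_expression(config)
  x <- sim$expression
  pattern <- sim$true_pattern
  ref <- config$n_patterns  # immune-activated, best-prognosis analogue

  block_genes <- lapply(seq_len(config$n_patterns), function(pt) {
    sprintf("DEG%d_%03d", pt, seq_len(config$deg_block_size))
  })
  ref_block <- x[block_genes[[ref]], , drop = FALSE]
  sc <- compute_wm_score(ref_block)$scores$wm_score
  true_score <- as.numeric(scale(sc))
  if (mean(true_score[pattern == ref]) > 0) true_score <- -true_score

  clinical <- simulate_survival(true_score, config,
                                sample_ids = colnames(x))
  mutations <- simulate_mutations(config, sample_ids = colnames(x))

  sets <- stats::setNames(block_genes,
                          sprintf("DEG_BLOCK_%d", seq_len(config$n_patterns)))
  n_sig <- min(30L, config$deg_block_size)
  sets$PLANTED_IMMUNE <- block_genes[[ref]][seq_len(n_sig)]
  sets$PLANTED_STROMAL <- block_genes[[min(2L, config$n_patterns)]][seq_len(n_sig)]

  structure(list(
    expression = x,
    true_pattern = pattern,
    true_score = true_score,
    clinical = clinical,
    mutations = mutations,
    gene_sets = sets,
    reference_pattern = ref,
    config = config
  ), class = "wm_cohort")
}

#' @export
print.wm_cohort <- function(x, ...) {
  cat(sprintf(
    "<wm_cohort> %d genes x %d samples, %d patterns (sizes: %s), seed %d\n",
    nrow(x$expression), ncol(x$expression), x$config$n_patterns,
    paste(tabulate(x$true_pattern), collapse = "/"), x$config$seed))
  invisible(x)
}
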