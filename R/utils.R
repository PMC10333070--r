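# Internal helpers shared across modules.

# Validate a genes x samples expression matrix: numeric, finite, named,
# unique ids. Returns the matrix invisibly so callers can pipe through.
check_expression_matrix <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    rlang::abort(sprintf("`%s` must be a numeric genes x samples matrix.", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    rlang::abort(sprintf("`%s` must carry gene rownames and sample colnames.", arg))
  }
  if (anyDuplicated(rownames(x))) {
    rlang::abort(sprintf("`%s` has duplicated gene ids.", arg))
  }
  if (anyDuplicated(colnames(x))) {
    rlang::abort(sprintf("`%s` has duplicated sample ids.", arg))
  }
  if (!all(is.finite(x))) {
    rlang::abort(sprintf("`%s` contains non-finite values.", arg))
  }
  invisible(x)
}

# Per-gene z-scoring across samples; errors on constant rows, naming them.
zscore_rows <- function(x, on_constant = c("error", "drop")) {
  on_constant <- match.arg(on_constant)
  sds <- apply(x, 1L, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad)) {
    if (on_constant == "error") {
      rlang::abort(sprintf(
        "Constant expression row(s): %s",
        paste(rownames(x)[utils::head(bad, 5L)], collapse = ", ")
      ))
    }
    rlang::warn(sprintf("Dropping %d constant gene row(s).", length(bad)))
    x <- x[-bad, , drop = FALSE]
    sds <- sds[-bad]
  }
  (x - rowMeans(x)) / sds
}

# 1 - Pearson correlation distance between columns (samples).
cor_dist <- function(x) {
  stats::as.dist(1 - stats::cor(x))
}

# Deterministic per-stage seed derived from a master seed; stays < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) * 7919L
}
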