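# Shared fixture builders; everything is generated in code at test time.

tiny_expr <- function(n_genes = 10, n_samples = 6, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, sd = sd), n_genes, n_samples,
         dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                         sprintf("S%03d", seq_len(n_samples))))
}

# Two well-separated sample blobs on a handful of features.
blob_expr <- function(sizes = c(10, 10), shift = 6, n_genes = 8, seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  x <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n))))
  grp <- rep(seq_along(sizes), sizes)
  half <- seq_len(floor(n_genes / 2))
  x[half, grp == 2] <- x[half, grp == 2] + shift
  x[-half, grp == 2] <- x[-half, grp == 2] - shift
  list(x = x, group = grp)
}

# Adjusted Rand index, written independently of any package code.
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sc <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  e <- sa * sb / choose(n, 2)
  (sc - e) / ((sa + sb) / 2 - e)
}

# A small cohort + pipeline run shared across test files (computed once).
.fixture_cache <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_cache$co)) {
    .fixture_cache$co <- simulate_cohort(cohort_config(
      n_samples = 200, n_background_genes = 300, deg_block_size = 60,
      seed = 99))
  }
  .fixture_cache$co
}

small_report <- function() {
  if (is.null(.fixture_cache$rep)) {
    .fixture_cache$rep <- run_wm_pipeline(small_cohort(), k_range = 2:5,
                                          n_iter = 50, seed = 5)
  }
  .fixture_cache$rep
}
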