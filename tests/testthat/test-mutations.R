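test_that("mutation matrix is binary, honours universes and the silent split", {
  tbl <- tibble::tibble(
    sample_id = c("s1", "s1", "s2", "s3", "s3"),
    gene_symbol = c("METTL3", "WTAP", "METTL3", "ADAR", "ADAR"),
    variant_class = c("missense", "silent", "frameshift_del", "missense",
                      "nonsense"))
  m <- mutation_matrix(tbl, samples = c("s1", "s2", "s3", "s4"),
                       genes = c("METTL3", "WTAP", "ADAR"))
  expect_equal(dim(m), c(4L, 3L))
  expect_equal(unname(m["s1", ]), c(1L, 0L, 0L))  # silent WTAP not counted
  expect_equal(unname(m["s3", "ADAR"]), 1L)       # two records, still binary
  expect_equal(unname(rowSums(m)["s4"]), 0L)
  expect_error(mutation_matrix(dplyr::mutate(tbl, variant_class = "odd")),
               "Unknown")
})

test_that("mutation frequencies cover per-gene and cohort fractions", {
  m <- matrix(0L, 4, 2, dimnames = list(paste0("s", 1:4), c("A", "B")))
  f0 <- mutation_frequency(m)
  expect_true(all(f0$per_gene$frequency == 0))
  expect_equal(f0$cohort_fraction, 0)

  m["s2", "A"] <- 1L
  f1 <- mutation_frequency(m)
  expect_equal(f1$per_gene$frequency[f1$per_gene$gene_symbol == "A"], 0.25)
  expect_equal(f1$cohort_fraction, 0.25)
})

test_that("planted mutation rates are recovered within binomial bounds", {
  cfg <- cohort_config(seed = 70)
  mut <- simulate_mutations(cfg)
  m <- mutation_matrix(mut, samples = sprintf("S%04d", 1:400),
                       genes = writer_genes())
  freq <- mutation_frequency(m)$per_gene
  bg <- freq[!freq$gene_symbol %in% cfg$cooccur_pair, ]
  ci_half <- 3 * sqrt(cfg$mutation_rate * (1 - cfg$mutation_rate) / 400)
  expect_true(all(abs(bg$frequency - cfg$mutation_rate) <= ci_half))
  pair <- freq[freq$gene_symbol %in% cfg$cooccur_pair, ]
  ci_half_p <- 3 * sqrt(0.08 * 0.92 / 400)
  expect_true(all(abs(pair$frequency - 0.08) <= ci_half_p))
})

test_that("TMB counts non-silent records and scales by capture size", {
  tbl <- tibble::tibble(
    sample_id = c(rep("s1", 4), "s2"),
    gene_symbol = c("METTL3", "WTAP", "ADAR", "CPSF1", "METTL3"),
    variant_class = c("missense", "missense", "missense", "silent", "nonsense"))
  tmb <- compute_tmb(tbl, samples = c("s1", "s2", "s3"))
  expect_equal(tmb$n_nonsilent, c(3L, 1L, 0L))
  expect_equal(tmb$tmb, c(3, 1, 0))
  tmb38 <- compute_tmb(tbl, samples = c("s1", "s2", "s3"), per_mb_size = 38)
  expect_equal(tmb38$tmb, c(3, 1, 0) / 38)
})

test_that("Fisher p equals exhaustive hypergeometric enumeration", {
  # oracle: two-sided Fisher p by summing hypergeometric probabilities of
  # all tables with probability <= observed, margins fixed
  fisher_oracle <- function(n11, n10, n01, n00) {
    m1 <- n11 + n10; m2 <- n01 + n00; k <- n11 + n01; n <- m1 + m2
    support <- max(0, k - m2):min(k, m1)
    pr <- dhyper(support, m1, m2, k)
    obs <- dhyper(n11, m1, m2, k)
    sum(pr[pr <= obs * (1 + 1e-7)])
  }
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    a <- rbinom(n, 1, 0.3); b <- rbinom(n, 1, 0.3)
    m <- cbind(A = a, B = b, C = rbinom(n, 1, 0.5))
    rownames(m) <- paste0("s", 1:n)
    got <- tryCatch(cooccurrence_fisher(m, min_mutated = 1),
                    error = function(e) NULL)
    if (is.null(got)) next
    row <- got[got$gene_a == "A" & got$gene_b == "B", ]
    if (!nrow(row)) next
    expect_equal(row$p_value,
                 fisher_oracle(row$n_both, row$n_a_only, row$n_b_only,
                               row$n_neither),
                 tolerance = 1e-9)
  }
})

test_that("identical mutation profiles are labelled co-occurring", {
  set.seed(72)
  a <- as.integer(seq_len(20) %in% sample(20, 5))
  m <- cbind(A = a, B = a, C = rbinom(20, 1, 0.4))
  rownames(m) <- paste0("s", 1:20)
  res <- cooccurrence_fisher(m, min_mutated = 3)
  row <- res[res$gene_a == "A" & res$gene_b == "B", ]
  expect_equal(row$p_value, 1 / choose(20, 5), tolerance = 1e-9)
  expect_gt(row$odds_ratio, 1)
  expect_equal(row$label, "co_occurring")
})

test_that("perfectly exclusive pairs are labelled exclusive", {
  a <- rep(c(1L, 0L), each = 10)
  m <- cbind(A = a, B = 1L - a)
  rownames(m) <- paste0("s", 1:20)
  res <- cooccurrence_fisher(m, min_mutated = 3)
  expect_lt(res$odds_ratio[1], 1)
  expect_equal(res$label[1], "exclusive")
})

test_that("labels are monotone in p within the pair table", {
  set.seed(73)
  m <- matrix(rbinom(40 * 6, 1, 0.3), 40, 6,
              dimnames = list(paste0("s", 1:40), paste0("g", 1:6)))
  m[, 2] <- m[, 1]  # one strongly dependent pair
  res <- cooccurrence_fisher(m, min_mutated = 1)
  sig <- res$label != "ns"
  if (any(sig) && any(!sig)) {
    expect_lt(max(res$q_value[sig]), min(res$q_value[!sig]) + 1e-12)
  }
  expect_true(all(diff(res$q_value) >= -1e-12))  # sorted by p, BH monotone
})
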