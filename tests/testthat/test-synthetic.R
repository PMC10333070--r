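test_that("config validation rejects degenerate settings", {
  expect_error(cohort_config(n_samples = 0), "Degenerate")
  expect_error(cohort_config(pattern_proportions = c(0.5, 0.5, 0.1, -0.1)),
               "proportions")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(cohort_config(censoring_rate = 1.2), "censoring_rate")
  expect_error(cohort_config(risk_coefficient = Inf), "finite")
})

test_that("near-zero noise makes within-pattern writer rows constant", {
  cfg <- cohort_config(n_samples = 40, n_background_genes = 10,
                       deg_block_size = 5, noise_sd = 1e-9, seed = 3)
  sim <- simulate_expression(cfg)
  w <- sim$expression[writer_genes(), ]
  for (p in 1:4) {
    within_sd <- apply(w[, sim$true_pattern == p, drop = FALSE], 1, sd)
    expect_lt(max(within_sd), 1e-6)
  }
})

test_that("expression generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_samples = 60, n_background_genes = 50,
                       deg_block_size = 10, seed = 11)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$true_pattern, b$true_pattern)
  c2 <- simulate_cohort(cfg)
  d2 <- simulate_cohort(cfg)
  expect_identical(c2$expression, d2$expression)
  expect_identical(c2$clinical, d2$clinical)
  expect_identical(c2$mutations, d2$mutations)
})

test_that("writer sample means sit within 3 standard errors of their targets", {
  cfg <- cohort_config(seed = 21)
  sim <- simulate_expression(cfg)
  w <- sim$expression[writer_genes(), ]
  for (p in 1:4) {
    idx <- sim$true_pattern == p
    se <- cfg$noise_sd / sqrt(sum(idx))
    obs <- rowMeans(w[, idx, drop = FALSE])
    target <- cfg$writer_mean_matrix[p, ]
    # 3 SE per gene; allow the worst of 26 genes a touch over (union bound)
    expect_lt(mean(abs(obs - target) > 3 * se), 0.05)
  }
})

test_that("null risk coefficient decouples score from survival time", {
  cfg <- cohort_config(risk_coefficient = 0, seed = 13)
  score <- rnorm(400)
  surv <- simulate_survival(score, cfg)
  tau <- cor(score, surv$time, method = "kendall")
  expect_lt(abs(tau), 0.1)
})

test_that("positive risk coefficient gives the high-score half worse survival", {
  cfg <- cohort_config(risk_coefficient = 1, seed = 17)
  score <- rnorm(400)
  surv <- simulate_survival(score, cfg)
  hi <- score > median(score)
  med_hi <- attr(km_estimate(surv$time[hi], surv$event[hi]), "median")
  med_lo <- attr(km_estimate(surv$time[!hi], surv$event[!hi]), "median")
  expect_lt(med_hi, med_lo)
})

test_that("censoring rate is tuned to its target", {
  cfg <- cohort_config(censoring_rate = 0.3, seed = 19)
  surv <- simulate_survival(rnorm(400), cfg)
  expect_lt(abs(mean(surv$event) - 0.7), 0.07)
})

test_that("independent planted pair has an odds ratio near 1 across seeds", {
  covered <- vapply(1:100, function(s) {
    cfg <- cohort_config(cooccur_or = 1, seed = s)
    mut <- simulate_mutations(cfg)
    m <- mutation_matrix(mut, samples = sprintf("S%04d", 1:400),
                         genes = cfg$cooccur_pair)
    ci <- fisher.test(table(factor(m[, 1], 0:1), factor(m[, 2], 0:1)))$conf.int
    ci[1] <= 1 && 1 <= ci[2]
  }, logical(1L))
  expect_gte(mean(covered), 0.9)
})

test_that("planted co-occurrence at OR 8 is detectable in most cohorts", {
  hits <- vapply(1:50, function(s) {
    cfg <- cohort_config(seed = s)  # default cooccur_or = 8
    mut <- simulate_mutations(cfg)
    m <- mutation_matrix(mut, samples = sprintf("S%04d", 1:400),
                         genes = cfg$cooccur_pair)
    fisher.test(table(factor(m[, 1], 0:1), factor(m[, 2], 0:1)))$p.value < 0.05
  }, logical(1L))
  expect_gte(mean(hits), 0.8)
})

test_that("zero mutation rates give an empty table; 2x2 cells honour config", {
  cfg <- cohort_config(mutation_rate = 0, cooccur_marginal = 0,
                       cooccur_or = 1, seed = 2)
  expect_equal(nrow(simulate_mutations(cfg)), 0L)

  p <- wmscore:::cooccur_cell_probs(0.08, 0.08, 8)
  expect_equal(sum(p), 1)
  expect_equal(p[1] + p[2], 0.08)  # marginal of gene 1
  expect_equal(p[1] + p[3], 0.08)  # marginal of gene 2
  expect_equal(p[1] * p[4] / (p[2] * p[3]), 8)
})

test_that("cohort components share sample ids and plant the advertised structure", {
  co <- small_cohort()
  n <- co$config$n_samples
  expect_identical(colnames(co$expression), co$clinical$sample_id)
  expect_true(all(co$mutations$sample_id %in% co$clinical$sample_id))
  expect_true(all(co$true_pattern %in% 1:4))
  expect_equal(length(co$true_score), n)
  # reference (immune) pattern carries the lowest latent score
  means <- tapply(co$true_score, co$true_pattern, mean)
  expect_equal(unname(which.min(means)), co$reference_pattern)

  # planted immune signature scores highest in the reference pattern
  es <- ssgsea_scores(co$expression, co$gene_sets["PLANTED_IMMUNE"])
  by_pattern <- tapply(es["PLANTED_IMMUNE", ], co$true_pattern, mean)
  expect_equal(unname(which.max(by_pattern)), co$reference_pattern)
  # and the stromal signature in pattern 2
  es2 <- ssgsea_scores(co$expression, co$gene_sets["PLANTED_STROMAL"])
  by_pattern2 <- tapply(es2["PLANTED_STROMAL", ], co$true_pattern, mean)
  expect_equal(unname(which.max(by_pattern2)), 2L)

  # different seeds: same shapes, different values
  co2 <- simulate_cohort(cohort_config(
    n_samples = 200, n_background_genes = 300, deg_block_size = 60, seed = 100))
  expect_equal(dim(co2$expression), dim(co$expression))
  expect_false(identical(co2$expression, co$expression))
})
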