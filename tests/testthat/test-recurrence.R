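test_that("Poisson-binomial tail equals exhaustive enumeration", {
  set.seed(31)
  for (i in 1:50) {
    T <- sample(1:12, 1)
    q <- runif(T)
    x <- sample(0:T, 1)
    expect_equal(poisson_binomial_tail(q, x), enumerate_poibin_tail(q, x),
                 tolerance = 1e-12)
  }
})

test_that("Poisson-binomial tail reduces to the binomial survival function", {
  set.seed(32)
  for (i in 1:20) {
    T <- sample(2:400, 1); p <- runif(1); x <- sample(0:T, 1)
    expect_equal(poisson_binomial_tail(rep(p, T), x),
                 pbinom(x - 1, T, p, lower.tail = FALSE), tolerance = 1e-10)
  }
  ## documented small cases
  expect_equal(poisson_binomial_tail(c(.5, .5, .5), 2), 0.5)
  expect_equal(poisson_binomial_tail(c(.1, .2, .3), 1), 1 - 0.9 * 0.8 * 0.7)
  expect_equal(poisson_binomial_tail(runif(5), 0), 1)
  expect_error(poisson_binomial_tail(c(.5, .5), 3), "exceeds")
  expect_error(poisson_binomial_tail(c(.5, 1.2), 1), "0, 1")
})

test_that("the refined normal approximation tracks the exact tail", {
  set.seed(33)
  q <- runif(2000, 0, 0.2)
  for (x in c(150, 180, 210, 240)) {
    exact <- poisson_binomial_tail(q, x, method = "dp")
    approx <- poisson_binomial_tail(q, x, method = "rna")
    expect_lt(abs(exact - approx), 0.005)
  }
})

test_that("per-tumour region probability is the complement of no mutation", {
  expect_equal(region_tumor_probability(numeric(0)), 0)
  expect_equal(region_tumor_probability(rep(0, 10)), 0)
  expect_equal(region_tumor_probability(0.37), 0.37)
  expect_equal(region_tumor_probability(rep(0.001, 100)), 1 - 0.999^100)
  expect_error(region_tumor_probability(c(0.5, 1)), "\\[0, 1\\)")
})

test_that("clustering permutation test behaves at its boundaries", {
  ## statistic at its minimum: p = 1 regardless of permutations
  expect_equal(clustering_pvalue(c(10L, 20L, 30L), s = 1000L), 1)
  ## all three mutations coincident in 1,000 bases: analytic null 1e-6
  p <- clustering_pvalue(c(5L, 5L, 5L), s = 1000L, n_perm = 10000L, seed = 2L)
  expect_lte(p, 2 / 10001)
  ## fewer than three mutations: not tested
  expect_true(is.na(clustering_pvalue(c(1L, 1L), s = 1000L)))
  expect_error(clustering_pvalue(c(1L, 2L, 3L), s = 0L), "at least 1")
  ## fixed seed is reproducible bit for bit
  a <- clustering_pvalue(c(4L, 4L, 9L, 20L), 500L, n_perm = 2000L, seed = 7L)
  b <- clustering_pvalue(c(4L, 4L, 9L, 20L), 500L, n_perm = 2000L, seed = 7L)
  expect_identical(a, b)
})

test_that("clustering p-values vary across seeds like binomial sampling", {
  ## true null tail for S >= 1 with m = 3, s = 100: 1 - (99*98)/100^2
  p_true <- 1 - (99 * 98) / 1e4
  ps <- vapply(1:20, function(s) {
    clustering_pvalue(c(1L, 1L, 50L), s = 100L, n_perm = 2000L, seed = s)
  }, numeric(1))
  se <- sqrt(p_true * (1 - p_true) / 2000)
  expect_lt(abs(mean(ps) - p_true), 4 * se / sqrt(20) + 1 / 2001)
  expect_lt(sd(ps), 4 * se)
})

test_that("Fisher combination follows the chi-square(4) survival function", {
  expect_equal(combine_fisher(1, 1), 1)
  x <- -4 * log(0.05)
  expect_equal(combine_fisher(0.05, 0.05), exp(-x / 2) * (1 + x / 2))
  expect_equal(combine_fisher(0.03, NA), 0.03)
  expect_error(combine_fisher(0, 0.5), "0, 1")
  expect_error(combine_fisher(0.5, -1), "0, 1")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_length(bh_fdr(numeric(0)), 0)
})

test_that("an intercept-only cohort refits to its flat rate", {
  cfg <- cohort_config(seed = 21L, n_tumors = 15L,
                       chrom_lengths = c(chr1 = 1.5e6), n_genes = 40L,
                       n_cres = 400L,
                       background_coefs = list(intercept = qlogis(3e-5),
                                               ref_gc = 0, reptime = 0,
                                               coverage = 0, tumor_sd = 0))
  co <- suppressMessages(generate_cohort(cfg))
  regions <- suppressMessages(
    build_regions(co, "cre", chrom_lengths = cfg$chrom_lengths))
  bg <- fit_background(co$snvs, regions, co$tracks, co$genome,
                       co$samples$sample_id)
  ## predicted rate at cohort-typical covariates close to the simulated rate
  p_hat <- predict_base_rates(bg, is_gc = 0.5, reptime = 0, coverage = 8)
  expect_gt(p_hat, 3e-5 / 1.5)
  expect_lt(p_hat, 3e-5 * 1.5)
})

test_that("negative-observation thinning leaves predicted rates unchanged", {
  co <- test_cohort()
  regions <- suppressMessages(
    build_regions(co, "cre", chrom_lengths = co$config$chrom_lengths))
  full <- fit_background(co$snvs, regions, co$tracks, co$genome,
                         co$samples$sample_id)
  thin <- fit_background(co$snvs, regions, co$tracks, co$genome,
                         co$samples$sample_id,
                         negative_sampling_fraction = 0.1, sampling_seed = 5L)
  p_full <- predict_base_rates(full, 1, 0.5, 8)
  p_thin <- predict_base_rates(thin, 1, 0.5, 8)
  expect_lt(abs(p_thin - p_full) / p_full, 0.05)
})

test_that("recurrence results respect their structural invariants", {
  co <- test_cohort()
  regions <- suppressMessages(
    build_regions(co, "cre", chrom_lengths = co$config$chrom_lengths))
  bg <- fit_background(co$snvs, regions, co$tracks, co$genome,
                       co$samples$sample_id)
  rec <- test_recurrence(co$snvs, regions, bg, co$tracks, co$genome,
                         n_perm = 500L, seed = 3L)
  expect_equal(nrow(rec), nrow(regions))
  expect_true(all(rec$n_positions <= rec$n_mutations))
  expect_true(all(rec$n_tumors <= co$config$n_tumors))
  expect_true(all(rec$p_background > 0 & rec$p_background <= 1))
  expect_true(all(rec$p_combined > 0 & rec$p_combined <= 1))
  expect_true(all(rec$q >= rec$p_combined - 1e-12))
  ## clustering run exactly for regions with >= 3 mutations
  expect_identical(!is.na(rec$p_cluster), rec$n_mutations >= 3L)
  ## deterministic under a fixed seed
  rec2 <- test_recurrence(co$snvs, regions, bg, co$tracks, co$genome,
                          n_perm = 500L, seed = 3L)
  expect_identical(rec, rec2)
})

test_that("background model tidiers expose coefficients and fit summary", {
  co <- test_cohort()
  regions <- suppressMessages(
    build_regions(co, "cre", chrom_lengths = co$config$chrom_lengths))
  bg <- fit_background(co$snvs, regions, co$tracks, co$genome,
                       co$samples$sample_id)
  td <- tidy(bg)
  expect_setequal(td$term, c("(Intercept)", "is_gc", "reptime", "coverage"))
  expect_true(all(td$conf.low < td$conf.high))
  gl <- glance(bg)
  expect_identical(gl$kind, "cre")
  expect_true(gl$converged)
})
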