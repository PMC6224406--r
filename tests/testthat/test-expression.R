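sim_counts <- function(n_genes, n_samples, mu, phi, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(if (phi > 0) rnbinom(n_genes * n_samples, mu = mu, size = 1 / phi)
                else rpois(n_genes * n_samples, mu),
                nrow = n_genes,
                dimnames = list(sprintf("g%03d", 1:n_genes),
                                sprintf("S%03d", 1:n_samples)))
    m
  })
}

test_that("dispersion estimation recovers simulated truth", {
  ## Poisson data: estimate collapses to the Poisson limit
  cp <- sim_counts(60, 200, mu = 150, phi = 0, seed = 11)
  expect_lte(suppressMessages(estimate_dispersion(cp)), 0.01)
  ## NB truth 0.2 recovered
  cn <- sim_counts(60, 200, mu = 150, phi = 0.2, seed = 12)
  phi_hat <- suppressMessages(estimate_dispersion(cn))
  expect_gt(phi_hat, 0.1); expect_lt(phi_hat, 0.3)
  ## duplicated identical samples carry no excess variance
  dup <- cbind(cp[, 1, drop = FALSE], cp[, 1, drop = FALSE],
               cp[, 1, drop = FALSE])
  colnames(dup) <- c("a", "b", "c")
  expect_equal(suppressMessages(
    estimate_dispersion(dup, lib = c(a = 1, b = 1, c = 1))), 0)
})

test_that("two-group NB test is symmetric and exact in the Poisson limit", {
  y <- setNames(c(10L, 20L, 30L, 12L, 18L, 31L), paste0("S", 1:6))
  lib <- setNames(rep(1, 6), names(y))
  ## identical groups: unit fold change
  y2 <- setNames(c(10L, 20L, 30L, 10L, 20L, 30L), names(y))
  r <- nb_two_group_test(y2, paste0("S", 1:3), paste0("S", 4:6), 0.1, lib)
  expect_equal(r$fold_change, 1)
  ## swapping groups inverts the fold change, p unchanged
  a <- nb_two_group_test(y, paste0("S", 1:3), paste0("S", 4:6), 0.1, lib)
  b <- nb_two_group_test(y, paste0("S", 4:6), paste0("S", 1:3), 0.1, lib)
  expect_equal(a$p, b$p)
  expect_equal(a$fold_change, 1 / b$fold_change, tolerance = 0.02)
  ## Poisson limit equals the conditional binomial with doubled tails
  y3 <- setNames(c(40L, 52L, 38L, 20L, 22L, 19L), names(y))
  r0 <- nb_two_group_test(y3, paste0("S", 1:3), paste0("S", 4:6), 0, lib)
  s <- sum(y3); s1 <- sum(y3[1:3])
  oracle <- min(1, 2 * min(pbinom(s1, s, 0.5),
                           pbinom(s1 - 1, s, 0.5, lower.tail = FALSE)))
  expect_equal(r0$p, oracle, tolerance = 1e-10)
  ## relabelling samples leaves the p-value unchanged
  y4 <- y3; names(y4) <- paste0("X", 1:6)
  lib2 <- setNames(rep(1, 6), names(y4))
  r4 <- nb_two_group_test(y4, paste0("X", 1:3), paste0("X", 4:6), 0, lib2)
  expect_equal(r4$p, r0$p)
  expect_error(nb_two_group_test(y3, paste0("S", 1:3), paste0("S", 3:6), 0, lib),
               "disjoint")
})

test_that("group selection applies the exclusion cascade", {
  ## region on chr1 [0, 1000); gene body [5000, 8000)
  region <- tibble::tibble(region_id = "r1", chrom = "chr1", start = 0L,
                           end = 1000L,
                           testable = list(tibble::tibble(start = 0L, end = 1000L)))
  region2 <- tibble::tibble(region_id = "r2", chrom = "chr1", start = 2000L,
                            end = 3000L,
                            testable = list(tibble::tibble(start = 2000L, end = 3000L)))
  rset <- dplyr::bind_rows(region, region2)
  gene_table <- tibble::tibble(gene = "g1", chrom = "chr1", start = 5000L,
                               end = 8000L)
  samples <- paste0("S", 1:10)
  snv <- function(s, pos) tibble::tibble(tumor_id = s, chrom = "chr1",
                                         pos = pos, ref = "C", alt = "T")
  snvs <- dplyr::bind_rows(
    snv("S1", 100L), snv("S2", 200L), snv("S3", 300L), snv("S4", 400L),
    snv("S5", 500L), snv("S5", 2500L))  # S5 hits both recurrent regions
  cnv <- tibble::tibble(sample_id = c("S4", "S6"), chrom = "chr1",
                        start = c(4000L, 0L), end = c(9000L, 500L),
                        log2_ratio = c(0.3, -0.4))
  sel <- select_testable(region, "g1", snvs, cnv, rset, gene_table, samples)
  expect_true(sel$testable)
  ## S4 excluded by gene CNV, S5 by multi-region mutation, S6 by region CNV
  expect_setequal(sel$mutated, c("S1", "S2", "S3"))
  expect_false(any(c("S4", "S5", "S6") %in% sel$comparison))
  expect_false(any(sel$mutated %in% sel$comparison))
  ## dropping to two mutated samples makes the region untestable
  sel2 <- select_testable(region, "g1", snvs[1:2, ], cnv, rset, gene_table,
                          samples)
  expect_false(sel2$testable)
  expect_match(sel2$reason, "fewer|<3|2")
})

test_that("expression pipeline fans out per target gene and controls FDR", {
  counts <- sim_counts(30, 40, mu = 100, phi = 0.1, seed = 13)
  regions <- tibble::tibble(
    region_id = c("creA", "creB"), kind = "cre", chrom = "chr1",
    start = c(0L, 5000L), end = c(1000L, 6000L),
    target_genes = list(c("g001", "g002"), "g003"),
    testable = list(tibble::tibble(start = 0L, end = 1000L),
                    tibble::tibble(start = 5000L, end = 6000L)),
    n_testable = c(1000L, 1000L))
  gene_table <- tibble::tibble(gene = c("g001", "g002", "g003"),
                               chrom = "chr2", start = c(1e5, 2e5, 3e5),
                               end = c(1.5e5, 2.5e5, 3.5e5))
  snvs <- tibble::tibble(
    tumor_id = colnames(counts)[1:4], chrom = "chr1",
    pos = c(10L, 20L, 30L, 40L), ref = "C", alt = "T")
  cnv <- tibble::tibble(sample_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        log2_ratio = numeric())
  de <- suppressMessages(test_expression_effects(regions, snvs, cnv, counts,
                                                 gene_table))
  ## region creA interacts with two genes: two result rows
  expect_equal(sum(de$region_id == "creA"), 2L)
  ## creB has no mutated samples: untestable with a reason
  expect_true(all(is.na(de$p[de$region_id == "creB"])))
  ## null data: no candidates expected
  expect_equal(sum(de$candidate, na.rm = TRUE), 0L)
})
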