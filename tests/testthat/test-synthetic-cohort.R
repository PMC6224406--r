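test_that("degenerate configurations are rejected", {
  expect_error(cohort_config(n_tumors = 0), "n_tumors")
  expect_error(cohort_config(n_genes = 0), "n_genes")
  expect_error(cohort_config(chrom_lengths = c(chr1 = -5)), "positive")
  expect_error(cohort_config(fragment_size = 5e6,
                             chrom_lengths = c(chr1 = 1e6)), "fragment_size")
  expect_error(cohort_config(signature_mix = c(S1 = 0.7, S2 = 0.7)), "sum to 1")
  expect_error(cohort_config(driver_spec = tibble::tibble(
    region_id = "x", multiplier = 0.5, concentration = 0)), "multipliers")
  expect_error(cohort_config(driver_spec = tibble::tibble(
    region_id = "x", multiplier = 2, concentration = 1.2)), "concentration")
})

test_that("a null configuration spikes no drivers and unknown ids error", {
  co <- test_cohort()
  expect_length(co$truth$driver_regions, 0)
  cfg_bad <- cohort_config(seed = 1, n_tumors = 5,
                           chrom_lengths = c(chr1 = 1e6), n_genes = 20,
                           n_cres = 50,
                           driver_spec = tibble::tibble(
                             region_id = "cre99999", multiplier = 5,
                             concentration = 0.5))
  expect_error(suppressMessages(generate_cohort(cfg_bad)), "not found")
  ## multipliers of exactly 1 with no hotspot are not drivers
  cfg1 <- cohort_config(seed = 7, n_tumors = 5, chrom_lengths = c(chr1 = 1e6),
                        n_genes = 20, n_cres = 50,
                        driver_spec = tibble::tibble(
                          region_id = "cre00001", multiplier = 1,
                          concentration = 0))
  co1 <- suppressMessages(generate_cohort(cfg1))
  expect_length(co1$truth$driver_regions, 0)
})

test_that("the same seed reproduces the cohort byte for byte", {
  cfg <- cohort_config(seed = 11L, n_tumors = 8L,
                       chrom_lengths = c(chr1 = 8e5), n_genes = 25L,
                       n_cres = 120L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  co1 <- suppressMessages(generate_cohort(cfg, dir = d1))
  co2 <- suppressMessages(generate_cohort(cfg, dir = d2))
  expect_identical(co1$snvs, co2$snvs)
  expect_identical(co1$counts, co2$counts)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("emitted interaction scores and distances straddle the filters", {
  ints <- test_cohort()$interactions
  expect_gt(sum(ints$score >= 5), 0)
  expect_gt(sum(ints$score < 5), 0)
  expect_gt(sum(ints$distance <= 1e6), 0)
  expect_gt(sum(ints$distance > 1e6), 0)
  mp <- suppressMessages(
    mappability_filter(test_cohort()$cres, test_cohort()$mappability))
  expect_lt(nrow(mp), nrow(test_cohort()$cres))  # some fragments <95%
})

test_that("realised mutation load matches the configured rates", {
  co <- test_cohort()
  cfg <- co$config
  bc <- cfg$background_coefs
  ## expectation from the generator's own rate function: per-window class
  ## counts x logistic rate, summed over windows and tumours
  rt <- co$tracks$reptime; cv <- co$tracks$coverage
  expected <- 0; variance <- 0
  for (ch in names(cfg$chrom_lengths)) {
    w <- rt[rt$chrom == ch, ]
    v <- Biostrings::Views(co$genome[[ch]], IRanges::IRanges(w$start + 1, w$end))
    cls <- Biostrings::letterFrequency(v, c("AT", "GC"))
    cvv <- cv$value[cv$chrom == ch]
    for (off in co$truth$tumor_offsets) {
      p_at <- plogis(bc$intercept + bc$reptime * w$value + bc$coverage * cvv + off)
      p_gc <- plogis(bc$intercept + bc$ref_gc + bc$reptime * w$value +
                       bc$coverage * cvv + off)
      expected <- expected + sum(cls[, "A|T"] * p_at + cls[, "G|C"] * p_gc)
      variance <- variance + sum(cls[, "A|T"] * p_at * (1 - p_at) +
                                   cls[, "G|C"] * p_gc * (1 - p_gc))
    }
  }
  observed <- nrow(co$snvs)
  expect_lt(abs(observed - expected), 4 * sqrt(variance))
})

test_that("hotspot spiking concentrates exactly the requested fraction", {
  region <- list(start = 0L, end = 1000L)
  pos <- c(10L, 50L, 100L, 200L, 300L, 400L, 500L, 600L, 700L, 800L)
  expect_identical(spike_hotspot(pos, region, 0, rng_seed = 3), pos)
  all_same <- spike_hotspot(pos[1:5], region, 1, rng_seed = 3)
  expect_length(unique(all_same), 1L)
  expect_identical(5L - length(unique(all_same)), 4L)  # S = m - distinct
  spiked <- spike_hotspot(pos, region, 0.6, rng_seed = 3)
  expect_identical(max(table(spiked)), 6L)
  expect_error(spike_hotspot(pos, list(start = 5L, end = 5L), 0.5), "empty region")
})

test_that("mutation-linked fold changes and null genes behave as configured", {
  co <- test_cohort()
  counts <- co$counts
  lib <- co$truth$library_factors
  ## null cohort: two arbitrary halves of the samples should not differ
  ## beyond sampling noise for any gene (checked on a few genes)
  set.seed(9)
  g <- sample(rownames(counts), 5)
  a <- colnames(counts)[1:10]; b <- colnames(counts)[11:20]
  for (gi in g) {
    xa <- counts[gi, a] / lib[a]; xb <- counts[gi, b] / lib[b]
    se <- sqrt(var(xa) / length(xa) + var(xb) / length(xb))
    expect_lt(abs(mean(xa) - mean(xb)), 4 * se + 1e-9)
  }
})

test_that("writing a cohort emits the full file set", {
  d <- withr::local_tempdir()
  cfg <- cohort_config(seed = 5L, n_tumors = 5L, chrom_lengths = c(chr1 = 6e5),
                       n_genes = 15L, n_cres = 60L)
  co <- suppressMessages(generate_cohort(cfg, dir = d))
  expected <- c("tss.tsv", "interactions.tsv", "reptime.track.tsv",
                "coverage.track.tsv", "mappability.bed", "snvs.maf.tsv",
                "cnv.seg", "counts.tsv", "samples.tsv", "truth.json",
                "annotation.tsv", "genome.fa")
  expect_true(all(expected %in% list.files(d)))
  back <- read_maf(file.path(d, "snvs.maf.tsv"))
  expect_equal(nrow(back), nrow(co$snvs))
  expect_error(write_cohort(co, file.path("/proc", "nope")), "directory")
})
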