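seg <- function(s, chrom, start, end, lr) {
  tibble::tibble(sample_id = s, chrom = chrom, start = start, end = end,
                 log2_ratio = lr)
}

test_that("event calling holds at the log2 and focal-size boundaries", {
  segs <- dplyr::bind_rows(
    seg("A", "chr1", 0L, 2900000L, 0.1613),    # focal amp at threshold
    seg("A", "chr1", 5e6, 5e6 + 3100000L, -0.2),  # event, not focal
    seg("A", "chr2", 0L, 1e6, 0.1))            # below threshold
  ev <- call_cnv_events(segs)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$direction, c("amplification", "deletion"))
  expect_equal(ev$focal, c(TRUE, FALSE))
  expect_equal(nrow(call_cnv_events(segs, focal_only = TRUE)), 1L)
})

test_that("chromosome amplification uses the union of covering events", {
  len <- c(chr1 = 1e6)
  expect_true(chromosome_amplified(seg("A", "chr1", 0L, 950000L, 0.3), len)[["chr1"]])
  ## two disjoint amplifications of 50% + 41% reach 91%
  two <- dplyr::bind_rows(seg("A", "chr1", 0L, 500000L, 0.3),
                          seg("A", "chr1", 500000L, 910000L, 0.25))
  expect_true(chromosome_amplified(two, len)[["chr1"]])
  expect_false(chromosome_amplified(seg("A", "chr1", 0L, 899000L, 0.3), len)[["chr1"]])
  ## overlapping events are not double counted: oracle = per-base bitmap
  set.seed(4)
  rand <- tibble::tibble(sample_id = "A", chrom = "chr1",
                         start = as.integer(runif(20, 0, 9e5)))
  rand$end <- rand$start + as.integer(runif(20, 1e4, 3e5))
  rand$log2_ratio <- 0.3
  bitmap <- logical(1e6)
  for (i in 1:20) bitmap[(rand$start[i] + 1):min(rand$end[i], 1e6)] <- TRUE
  expect_identical(chromosome_amplified(rand, len)[["chr1"]],
                   mean(bitmap) >= 0.9)
  expect_error(chromosome_amplified(rand, c(chr9 = NA)), "missing length")
})

test_that("hyperdiploidy needs two amplified autosomes", {
  len <- c(chr1 = 1e6, chr2 = 1e6, chrX = 1e6)
  meta <- tibble::tibble(sample_id = c("A", "B", "C"),
                         translocations = c("t(4;14)", "", "MYC,t(11;14)"))
  segs <- dplyr::bind_rows(
    seg("A", "chr1", 0L, 950000L, 0.3), seg("A", "chr2", 0L, 930000L, 0.3),
    seg("B", "chr1", 0L, 950000L, 0.3), seg("B", "chrX", 0L, 990000L, 0.3))
  k <- assign_karyotype(segs, meta, len)
  expect_true(k$hd[k$sample_id == "A"])
  expect_false(k$hd[k$sample_id == "B"])  # X does not count
  expect_false(k$hd[k$sample_id == "C"])
  expect_equal(k$translocations[k$sample_id == "C"][[1]], c("MYC", "t(11;14)"))
})

test_that("translocation enrichment reproduces hand-enumerable tables", {
  cohort <- paste0("S", 1:4)
  res <- cnv_translocation_enrichment(c("S1", "S2"), c("S1", "S2"), cohort)
  expect_equal(res$p, 1 / 6)  # C(2,2)C(2,0)/C(4,2)
  expect_equal(res$table[1, 1], 2L)
  ## group at the cohort's translocation fraction: no enrichment signal
  cohort2 <- paste0("S", 1:100)
  res2 <- cnv_translocation_enrichment(paste0("S", 1:10),
                                       paste0("S", seq(1, 100, by = 10)),
                                       cohort2)
  expect_gt(res2$p, 0.3)
  expect_error(cnv_translocation_enrichment("S1", "S1", character()), "empty")
  ## invariant to transposing the table (swap rows and columns together)
  t1 <- fisher_exact(matrix(c(8, 2, 5, 15), 2, byrow = TRUE), "greater")
  t2 <- fisher_exact(t(matrix(c(8, 2, 5, 15), 2, byrow = TRUE)), "greater")
  expect_equal(t1$p, t2$p)
})

test_that("CNV-at-CRE expression tests skip groups below seven samples", {
  counts <- matrix(rpois(30 * 20, 100), nrow = 30,
                   dimnames = list(sprintf("g%03d", 1:30), sprintf("S%03d", 1:20)))
  cre <- tibble::tibble(region_id = "creX", chrom = "chr1", start = 0L,
                        end = 2000L)
  gene_table <- tibble::tibble(gene = "g001", chrom = "chr1", start = 5e5,
                               end = 6e5)
  ## only six samples amplified at the CRE: skipped
  segs6 <- seg(sprintf("S%03d", 1:6), "chr1", 0L, 10000L, 0.4)
  out6 <- suppressMessages(
    cre_cnv_expression(cre, segs6, "g001", counts, gene_table, dispersion = 0.1))
  expect_equal(nrow(out6), 0L)
  ## no CNV at the CRE at all: nothing to test
  far <- seg("S001", "chr2", 0L, 10000L, 0.4)
  expect_equal(nrow(suppressMessages(
    cre_cnv_expression(cre, far, "g001", counts, gene_table, dispersion = 0.1))), 0L)
  ## seven amplified samples produce one amplification row
  segs7 <- seg(sprintf("S%03d", 1:7), "chr1", 0L, 10000L, 0.4)
  out7 <- suppressMessages(
    cre_cnv_expression(cre, segs7, "g001", counts, gene_table, dispersion = 0.1))
  expect_equal(out7$direction, "amplification")
  expect_equal(out7$n_cnv, 7L)
  ## samples whose event also covers the gene are excluded
  both <- seg(sprintf("S%03d", 1:7), "chr1", 0L, 7e5, 0.4)
  outb <- suppressMessages(
    cre_cnv_expression(cre, both, "g001", counts, gene_table, dispersion = 0.1))
  expect_equal(nrow(outb), 0L)
})

test_that("breakpoint windows are inclusive and deduplicated", {
  genes <- tibble::tibble(gene = c("gA", "gB"), chrom = "chr1",
                          start = c(2000000L, 5000000L),
                          end = c(2010000L, 5010000L))
  bp <- tibble::tibble(chrom = "chr1", pos = 1000001L)
  ## gA starts exactly 999,999 bp after the breakpoint
  expect_equal(genes_near_breakpoints(bp, genes)$gene, "gA")
  bp2 <- tibble::tibble(chrom = "chr1", pos = 1000000L)
  expect_equal(nrow(genes_near_breakpoints(bp2, genes)), 1L)  # exactly 1 Mb
  bp3 <- tibble::tibble(chrom = "chr1", pos = 999999L)
  expect_equal(nrow(genes_near_breakpoints(bp3, genes)), 0L)  # 1,000,001 bp
  ## two breakpoints flanking one gene list it once
  flank <- tibble::tibble(chrom = "chr1", pos = c(1500000L, 2500000L))
  expect_equal(genes_near_breakpoints(flank, genes)$gene, "gA")
})
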