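## Mutation -> expression effect testing: conditional negative-binomial
## two-group test with the cohort's CNV / multi-fragment exclusion rules.

#' Effective library factors by trimmed-mean-of-M-values scaling
#'
#' TMM scaling (edgeR's default trims: 30% on M, 5% on A) of raw library
#' sizes, normalised to geometric mean 1.
#'
#' @param counts gene x sample integer matrix.
#' @return named per-sample positive factors (effective relative library
#'   sizes).
#' @export
library_factors <- function(counts) {
  nf <- edgeR::calcNormFactors(counts)
  eff <- colSums(counts) * nf
  f <- eff / geom_mean(eff)
  setNames(f, colnames(counts))
}

## conditional NB log-likelihood of one group's equal-library counts given
## their sum (r = 1/dispersion)
cond_ll_group <- function(y, r) {
  n <- length(y); z <- sum(y)
  sum(lgamma(y + r)) - n * lgamma(r) + lgamma(n * r) - lgamma(z + n * r)
}

#' Common negative-binomial dispersion by conditional maximum likelihood
#'
#' Counts are scaled to a common effective library and the common
#' dispersion maximising the conditional likelihood (given group sums) over
#' all genes and groups is returned.  Zero is allowed (Poisson limit);
#' all-zero genes are skipped.
#'
#' @param counts gene x sample matrix.
#' @param groups factor/character of group labels per sample (a single
#'   group is fine).
#' @param lib optional per-sample library factors; default [library_factors()].
#' @return the estimated dispersion (phi >= 0).
#' @export
estimate_dispersion <- function(counts, groups = NULL, lib = NULL) {
  counts <- as.matrix(counts)
  if (is.null(groups)) groups <- rep("all", ncol(counts))
  if (is.null(lib)) lib <- library_factors(counts)
  pseudo <- round(sweep(counts, 2, lib, "/"))
  keep <- rowSums(pseudo) > 0
  if (!any(keep)) abort("all genes have zero counts")
  if (any(!keep)) rlang::inform(sprintf("skipping %d all-zero gene(s)", sum(!keep)))
  pseudo <- pseudo[keep, , drop = FALSE]
  gidx <- split(seq_len(ncol(pseudo)), groups)
  nll <- function(log_phi) {
    r <- exp(-log_phi)
    -sum(vapply(gidx, function(ix) {
      if (length(ix) < 2L) return(0)
      sum(apply(pseudo[, ix, drop = FALSE], 1L, cond_ll_group, r = r))
    }, numeric(1)))
  }
  opt <- optimize(nll, interval = c(log(1e-6), log(5)))
  phi <- exp(opt$minimum)
  ## boundary: if the optimum sits at the lower edge the Poisson limit wins
  if (phi < 2e-6 || nll(log(1e-6)) <= opt$objective + 1e-8) phi <- 0
  phi
}

#' Conditional negative-binomial two-group test
#'
#' Tests a difference in expression of one gene between a mutated and a
#' comparison sample group.  Counts are scaled to a common effective
#' library; conditioning on the pooled total, the mutated-group sum follows
#' a distribution proportional to
#' `choose(y + r1 - 1, y) * choose(s - y + r2 - 1, s - y)` with
#' `r_g = n_g / dispersion` (exact binomial in the Poisson limit).  The
#' two-sided p doubles the smaller tail (capped at 1).  The reported fold
#' change is the ratio of normalised group means with a prior count of 0.5
#' on each side (display only, never in the statistic).
#'
#' @param y named integer vector of one gene's raw counts.
#' @param mutated,comparison disjoint character vectors of sample ids.
#' @param dispersion common NB dispersion (phi).
#' @param lib named per-sample library factors.
#' @param prior_count stabiliser for the fold-change display.
#' @return one-row tibble: `n_mutated`, `n_comparison`, `fold_change`, `p`.
#' @export
nb_two_group_test <- function(y, mutated, comparison, dispersion, lib,
                              prior_count = 0.5) {
  if (length(intersect(mutated, comparison)) > 0) abort("groups must be disjoint")
  if (any(lib[c(mutated, comparison)] <= 0)) abort("library factors must be positive")
  y1 <- y[mutated]; y2 <- y[comparison]
  l1 <- lib[mutated]; l2 <- lib[comparison]
  m1 <- mean(y1 / l1); m2 <- mean(y2 / l2)
  fc <- (m1 + prior_count) / (m2 + prior_count)

  p1 <- round(sum(y1 / l1)); p2 <- round(sum(y2 / l2))
  s <- p1 + p2
  n1 <- length(y1); n2 <- length(y2)
  if (s == 0) {
    p <- 1
  } else if (dispersion <= 0) {
    pr <- n1 / (n1 + n2)
    lo <- pbinom(p1, s, pr)
    hi <- pbinom(p1 - 1, s, pr, lower.tail = FALSE)
    p <- min(1, 2 * min(lo, hi))
  } else {
    r1 <- n1 / dispersion; r2 <- n2 / dispersion
    ys <- 0:s
    lw <- lgamma(ys + r1) - lgamma(ys + 1) + lgamma(s - ys + r2) - lgamma(s - ys + 1)
    w <- exp(lw - max(lw))
    w <- w / sum(w)
    lo <- sum(w[ys <= p1]); hi <- sum(w[ys >= p1])
    p <- min(1, 2 * min(lo, hi))
  }
  tibble(n_mutated = n1, n_comparison = n2, fold_change = fc, p = p)
}

#' Select the mutated and comparison groups for one region-gene test
#'
#' Applies the exclusion cascade: samples with a CNV event overlapping the
#' target gene or the tested region are excluded from both groups; tumours
#' mutated in more than one recurrently mutated region of the same gene are
#' excluded; the comparison group contains only samples with no mutation in
#' any recurrent region of that gene.  Not testable when fewer than
#' `min_mutated` mutated samples remain.
#'
#' @param region one row of the recurrent-region tibble (with `testable`).
#' @param gene target gene id.
#' @param snvs QC-passed SNV tibble.
#' @param cnv CNV segment tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `log2_ratio`).
#' @param recurrent_regions all recurrently mutated regions interacting
#'   with `gene` (including `region` itself).
#' @param gene_table tibble with `gene`, `chrom`, `start`, `end` gene-body
#'   intervals.
#' @param expression_samples sample ids with expression profiles.
#' @param cnv_threshold event threshold on `|log2_ratio|`.
#' @param min_mutated minimum mutated-group size.
#' @return list with `testable` (logical), `reason`, `mutated`,
#'   `comparison`.
#' @export
select_testable <- function(region, gene, snvs, cnv, recurrent_regions,
                            gene_table, expression_samples,
                            cnv_threshold = 0.1613, min_mutated = 3L) {
  g <- gene_table[gene_table$gene == gene, ]
  if (nrow(g) == 0L) return(list(testable = FALSE, reason = "gene not annotated",
                                 mutated = character(), comparison = character()))
  if (length(expression_samples) == 0L) {
    return(list(testable = FALSE, reason = "no expression-profiled samples",
                mutated = character(), comparison = character()))
  }
  ev <- cnv[abs(cnv$log2_ratio) >= cnv_threshold, , drop = FALSE]
  overlaps_sample <- function(chrom, start, end) {
    sub <- ev[ev$chrom == chrom & ev$start < end & ev$end > start, ]
    unique(sub$sample_id)
  }
  excl_cnv <- union(overlaps_sample(g$chrom[1], g$start[1], g$end[1]),
                    overlaps_sample(region$chrom, region$start, region$end))

  mutated_in <- function(r) {
    tt <- r$testable[[1]]
    sub <- snvs[snvs$chrom == r$chrom, ]
    if (nrow(sub) == 0L) return(character())
    unique(sub$tumor_id[pos_in_intervals(sub$pos - 1L, tt$start, tt$end)])
  }
  mut_sets <- map(seq_len(nrow(recurrent_regions)),
                  ~ mutated_in(recurrent_regions[.x, ]))
  names(mut_sets) <- recurrent_regions$region_id
  n_regions_mut <- table(unlist(mut_sets))
  multi <- names(n_regions_mut)[n_regions_mut > 1]

  mutated <- setdiff(mut_sets[[region$region_id]], c(excl_cnv, multi))
  mutated <- intersect(mutated, expression_samples)
  any_mut <- unique(unlist(mut_sets))
  comparison <- setdiff(expression_samples, c(any_mut, excl_cnv))
  if (length(mutated) < min_mutated) {
    return(list(testable = FALSE,
                reason = sprintf("mutated in %d (<%d) samples", length(mutated),
                                 min_mutated),
                mutated = mutated, comparison = comparison))
  }
  if (length(comparison) < 2L) {
    return(list(testable = FALSE, reason = "comparison group too small",
                mutated = mutated, comparison = comparison))
  }
  list(testable = TRUE, reason = NA_character_, mutated = mutated,
       comparison = comparison)
}

#' Expression-effect testing for all recurrent region-gene pairs
#'
#' Runs [select_testable()] and [nb_two_group_test()] for every
#' (recurrent region, target gene) pair -- regions interacting with several
#' genes are tested once per gene -- BH-adjusts across all tested pairs,
#' and flags candidates with fold change at least `fc_up` or at most
#' `fc_down` and `q < q_max`.
#'
#' @param recurrent_regions recurrent-region tibble (with `target_genes`
#'   and `testable` list columns).
#' @param snvs,cnv,counts,gene_table cohort tables ([select_testable()]).
#' @param dispersion optional common dispersion; estimated from `counts`
#'   when `NULL`.
#' @param fc_up,fc_down,q_max candidate thresholds.
#' @param min_mutated minimum mutated-group size.
#' @return a `de_result` tibble: one row per tested pair plus untested
#'   pairs with their reason; columns `region_id`, `gene`, `n_mutated`,
#'   `n_comparison`, `fold_change`, `p`, `q`, `candidate`, `reason`.
#' @export
test_expression_effects <- function(recurrent_regions, snvs, cnv, counts,
                                    gene_table, dispersion = NULL,
                                    fc_up = 1.2, fc_down = 0.8, q_max = 0.1,
                                    min_mutated = 3L) {
  lib <- library_factors(counts)
  if (is.null(dispersion)) dispersion <- estimate_dispersion(counts, lib = lib)
  pairs <- recurrent_regions |>
    select("region_id", "target_genes") |>
    unnest_longer("target_genes", values_to = "gene") |>
    distinct()
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    rid <- pairs$region_id[i]; gene <- pairs$gene[i]
    region <- recurrent_regions[recurrent_regions$region_id == rid, ]
    rset <- recurrent_regions[map_lgl(recurrent_regions$target_genes,
                                      ~ gene %in% .x), ]
    if (!gene %in% rownames(counts)) {
      rows[[i]] <- tibble(region_id = rid, gene = gene, n_mutated = NA_integer_,
                          n_comparison = NA_integer_, fold_change = NA_real_,
                          p = NA_real_, reason = "gene not in count matrix")
      next
    }
    sel <- select_testable(region, gene, snvs, cnv, rset, gene_table,
                           expression_samples = colnames(counts),
                           min_mutated = min_mutated)
    if (!sel$testable) {
      rows[[i]] <- tibble(region_id = rid, gene = gene,
                          n_mutated = length(sel$mutated),
                          n_comparison = length(sel$comparison),
                          fold_change = NA_real_, p = NA_real_,
                          reason = sel$reason)
      next
    }
    res <- nb_two_group_test(counts[gene, ], sel$mutated, sel$comparison,
                             dispersion, lib)
    rows[[i]] <- tibble(region_id = rid, gene = gene, n_mutated = res$n_mutated,
                        n_comparison = res$n_comparison,
                        fold_change = res$fold_change, p = res$p,
                        reason = NA_character_)
  }
  out <- list_rbind(rows)
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- bh_fdr(out$p[tested])
  out$candidate <- tested & !is.na(out$q) & out$q < q_max &
    (out$fold_change >= fc_up | out$fold_change <= fc_down)
  class(out) <- c("de_result", class(out))
  out
}

#' Gene-body intervals of a synthetic cohort
#'
#' @param cohort a `cohort` object.
#' @return tibble `gene`, `chrom`, `start`, `end` (0-based half-open).
#' @export
gene_bodies <- function(cohort) {
  g <- cohort$genes
  start <- ifelse(g$strand == "+", g$tss0, g$tss0 + 1L - g$body_len)
  tibble(gene = g$gene, chrom = g$chrom,
         start = as.integer(pmax(start, 0L)),
         end = as.integer(pmax(start, 0L) + g$body_len))
}
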