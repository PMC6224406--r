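## Generic cohort statistics: Fisher's exact test, rank-sum mutation-burden
## comparison, interaction-level term enrichment and subgroup scans.

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric p-value; the reported odds ratio is the sample
#' cross-product `ad/bc` (`Inf` when `bc = 0`, `NaN` when both products
#' vanish), not the conditional MLE.
#'
#' @param table 2x2 matrix of non-negative counts (rows = condition,
#'   columns = outcome), or a length-4 vector `(a, b, c, d)` filled by row.
#' @param sided `"greater"`, `"less"` or `"two"`.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_exact <- function(table, sided = c("greater", "less", "two")) {
  sided <- match.arg(sided)
  if (!is.matrix(table)) table <- matrix(table, nrow = 2, byrow = TRUE)
  if (any(table < 0)) abort("counts must be non-negative")
  if (sum(table) == 0) abort("empty table")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  or <- (a * d) / (b * c)
  alt <- switch(sided, greater = "greater", less = "less", two = "two.sided")
  p <- if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    1  # degenerate margin: only one table is possible
  } else {
    fisher.test(table, alternative = alt)$p.value
  }
  list(odds_ratio = or, p = p)
}

#' Mutation-burden comparison per subgroup (Wilcoxon rank-sum)
#'
#' Each subgroup's per-sample mutation counts are compared with all other
#' samples by a two-sided rank-sum test: exact when the smaller side has at
#' most `exact_max` samples and there are no ties, otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param burden named numeric vector of mutation counts per sample.
#' @param subgroups named list: label -> member sample ids.
#' @param exact_max largest group size for the exact test.
#' @return tibble `subgroup`, `n_in`, `n_out`, `median_in`, `median_out`,
#'   `p`.
#' @export
wilcoxon_burden <- function(burden, subgroups, exact_max = 25L) {
  samples <- names(burden)
  rows <- imap(subgroups, function(members, label) {
    members <- intersect(members, samples)
    x <- burden[samples %in% members]
    y <- burden[!samples %in% members]
    if (length(x) < 2L || length(y) < 2L) return(NULL)
    if (sd(c(x, y)) == 0) {
      p <- 1
    } else {
      use_exact <- min(length(x), length(y)) <= exact_max &&
        !any(duplicated(c(x, y)))
      p <- suppressWarnings(
        wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value)
    }
    tibble(subgroup = label, n_in = length(x), n_out = length(y),
           median_in = median(x), median_out = median(y), p = p)
  })
  list_rbind(rows[!vapply(rows, is.null, TRUE)])
}

#' Term enrichment over CRE-promoter interactions
#'
#' Upper-tail hypergeometric test of each annotation term among the
#' significant interactions, with the full retained interaction set as the
#' background universe (enrichment is computed at the interaction level,
#' not the gene level, so promoters contacting many CREs do not inflate
#' term counts).
#'
#' @param significant character ids of significant interactions (subset of
#'   `background`).
#' @param background character ids of all interactions in the universe.
#' @param annotations named list: term -> character ids of annotated
#'   interactions (subsets of `background`).
#' @return tibble per term: `term`, `k` (significant & annotated), `K`
#'   (annotated), `n` (significant), `N` (universe), `p`, `q` (BH).  Terms
#'   with `K = 0` are skipped.
#' @export
interaction_go_enrichment <- function(significant, background, annotations) {
  if (!all(significant %in% background)) {
    abort("significant interactions must be a subset of the background")
  }
  N <- length(background); n <- length(significant)
  rows <- imap(annotations, function(ids, term) {
    ids <- intersect(ids, background)
    K <- length(ids)
    if (K == 0L) {
      rlang::inform(sprintf("term '%s' annotates nothing in the universe; skipped", term))
      return(NULL)
    }
    k <- length(intersect(ids, significant))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term = term, k = k, K = K, n = n, N = N, p = p)
  })
  out <- list_rbind(rows[!vapply(rows, is.null, TRUE)])
  if (nrow(out) > 0) out$q <- bh_fdr(out$p)
  out
}

#' Default term list for interaction-level enrichment
#'
#' The curated set of pathway terms scanned by default, shipped as a
#' configuration file so the term choice stays out of code.  Each term
#' carries the cancer-hallmark group it belongs to; annotations mapping
#' terms to interactions are supplied by the user.
#'
#' @return tibble with columns `term` and `hallmark`.
#' @export
default_go_terms <- function() {
  path <- system.file("extdata", "go_terms.tsv", package = "regdriver",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Per-subgroup enrichment / depletion scan of a binary feature
#'
#' One Fisher's exact test per subgroup of feature presence inside versus
#' outside the subgroup.  Subgroup memberships may overlap (a sample can be
#' hyperdiploid and translocated).  Direction `"less"` detects paucity.
#'
#' @param presence named logical vector of feature presence per sample.
#' @param subgroups named list: label -> member sample ids.
#' @param direction test sidedness per [fisher_exact()].
#' @return tibble per non-empty subgroup: `subgroup`, `n_present_in`,
#'   `n_in`, `n_present_out`, `n_out`, `odds_ratio`, `p`.
#' @export
subgroup_scan <- function(presence, subgroups, direction = c("greater", "less", "two")) {
  direction <- match.arg(direction)
  samples <- names(presence)
  rows <- imap(subgroups, function(members, label) {
    members <- intersect(members, samples)
    if (length(members) == 0L) return(NULL)
    inn <- samples %in% members
    tab <- matrix(c(sum(presence & inn), sum(!presence & inn),
                    sum(presence & !inn), sum(!presence & !inn)),
                  nrow = 2, byrow = TRUE)
    ft <- fisher_exact(tab, sided = direction)
    tibble(subgroup = label, n_present_in = sum(presence & inn),
           n_in = sum(inn), n_present_out = sum(presence & !inn),
           n_out = sum(!inn), odds_ratio = ft$odds_ratio, p = ft$p)
  })
  list_rbind(rows[!vapply(rows, is.null, TRUE)])
}
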