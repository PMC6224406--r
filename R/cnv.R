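## Copy-number event calling, chromosome-level amplification, karyotype
## assignment, CNV-at-CRE expression testing and CNV/translocation
## contingency statistics.

#' Call copy-number events from segments
#'
#' An event is a segment with `|log2_ratio| >= threshold` (default 0.1613);
#' a focal event additionally requires length below `focal_max` (3 Mb).
#'
#' @param segments tibble `sample_id`, `chrom`, `start`, `end`,
#'   `log2_ratio` (0-based half-open).
#' @param focal_only keep only focal events.
#' @param threshold event threshold on `|log2_ratio|`.
#' @param focal_max focal size bound (exclusive), bp.
#' @return the event rows with added `direction` (`amplification` /
#'   `deletion`) and `focal` columns.
#' @export
call_cnv_events <- function(segments, focal_only = FALSE, threshold = 0.1613,
                            focal_max = 3e6) {
  assert_columns(segments, c("sample_id", "chrom", "start", "end", "log2_ratio"),
                 "segments")
  ev <- segments |>
    filter(abs(.data$log2_ratio) >= threshold) |>
    mutate(direction = ifelse(.data$log2_ratio > 0, "amplification", "deletion"),
           focal = (.data$end - .data$start) < focal_max)
  if (focal_only) ev <- filter(ev, .data$focal)
  ev
}

#' Which chromosomes are amplified in one sample?
#'
#' A chromosome counts as amplified when at least `min_fraction` (90%) of
#' its length is covered by the union of amplification events.
#'
#' @param segments one sample's segments.
#' @param chrom_lengths named chromosome lengths.
#' @param threshold event threshold.
#' @param min_fraction coverage fraction required.
#' @return named logical vector over `names(chrom_lengths)`.
#' @export
chromosome_amplified <- function(segments, chrom_lengths, threshold = 0.1613,
                                 min_fraction = 0.9) {
  amp <- segments[segments$log2_ratio >= threshold, , drop = FALSE]
  vapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    if (is.na(len)) abort(sprintf("missing length for chromosome %s", ch))
    a <- amp[amp$chrom == ch, ]
    interval_union_width(pmax(a$start, 0L), pmin(a$end, len)) / len >= min_fraction
  }, logical(1))
}

#' Assign karyotype calls for every sample
#'
#' Hyperdiploidy (HD) is called when at least `min_autosomes` autosomes are
#' >= 90% covered by amplification; translocation labels are passed through
#' from the metadata.
#'
#' @param segments multi-sample segment tibble.
#' @param metadata tibble `sample_id`, `translocations` (separator-joined
#'   labels, empty for none).
#' @param chrom_lengths named lengths; `autosomes` selects which of them
#'   count toward HD.
#' @param autosomes character vector of autosomal chromosome names
#'   (defaults to all of `chrom_lengths` that are not X/Y).
#' @param min_autosomes autosome count for the HD rule.
#' @param sep separator of the translocation label field (comma by
#'   default; translocation names themselves contain semicolons).
#' @return tibble `sample_id`, `hd`, `n_amplified_autosomes`,
#'   `translocations` (list column of labels).
#' @export
assign_karyotype <- function(segments, metadata, chrom_lengths,
                             autosomes = NULL, min_autosomes = 2L, sep = ",") {
  if (is.null(autosomes)) {
    autosomes <- setdiff(names(chrom_lengths),
                         c("chrX", "chrY", "X", "Y"))
  }
  res <- map(metadata$sample_id, function(sid) {
    seg <- segments[segments$sample_id == sid, , drop = FALSE]
    amp <- chromosome_amplified(seg, chrom_lengths)
    n_auto <- sum(amp[autosomes])
    tibble(sample_id = sid, hd = n_auto >= min_autosomes,
           n_amplified_autosomes = as.integer(n_auto))
  })
  out <- list_rbind(res)
  labels <- strsplit(metadata$translocations, sep, fixed = TRUE)
  labels <- map(labels, ~ .x[nzchar(.x)])
  out$translocations <- labels[match(out$sample_id, metadata$sample_id)]
  out
}

#' Expression effect of copy-number change at a CRE
#'
#' Samples are grouped by focal CNV status at the CRE (amplified, deleted,
#' neutral), excluding samples whose target gene itself carries an event or
#' where one event covers both the CRE and the gene.  Each CNV group with
#' at least `min_group` samples (default 7) is tested against the neutral
#' group with the conditional NB test.
#'
#' @param cre one-row region tibble (`region_id`, `chrom`, `start`, `end`).
#' @param segments CNV segments.
#' @param gene target gene id.
#' @param counts expression matrix.
#' @param gene_table gene-body intervals.
#' @param dispersion common NB dispersion (estimated when `NULL`).
#' @param min_group minimum CNV-group size tested.
#' @param threshold,focal_max event definition.
#' @return tibble with one row per tested direction: `region_id`, `gene`,
#'   `direction`, `n_cnv`, `n_neutral`, `fold_change`, `p`; zero rows when
#'   nothing is testable.
#' @export
cre_cnv_expression <- function(cre, segments, gene, counts, gene_table,
                               dispersion = NULL, min_group = 7L,
                               threshold = 0.1613, focal_max = 3e6) {
  lib <- library_factors(counts)
  if (is.null(dispersion)) dispersion <- estimate_dispersion(counts, lib = lib)
  g <- gene_table[gene_table$gene == gene, ]
  focal <- call_cnv_events(segments, focal_only = TRUE, threshold = threshold,
                           focal_max = focal_max)
  ov <- function(d, chrom, start, end) {
    d[d$chrom == chrom & d$start < end & d$end > start, , drop = FALSE]
  }
  at_cre <- ov(focal, cre$chrom, cre$start, cre$end)
  ev_all <- call_cnv_events(segments, threshold = threshold)
  at_gene <- ov(ev_all, g$chrom[1], g$start[1], g$end[1])
  ## exclusion: gene itself altered, or one event spanning CRE and gene
  both <- at_cre[at_cre$chrom == g$chrom[1] &
                   at_cre$start < g$end[1] & at_cre$end > g$start[1], ]
  excl <- union(unique(at_gene$sample_id), unique(both$sample_id))

  amp <- setdiff(unique(at_cre$sample_id[at_cre$direction == "amplification"]), excl)
  del <- setdiff(unique(at_cre$sample_id[at_cre$direction == "deletion"]), excl)
  del <- setdiff(del, amp)  # partition: a sample with both counts as amplified
  neutral <- setdiff(colnames(counts), c(amp, del, excl))
  amp <- intersect(amp, colnames(counts)); del <- intersect(del, colnames(counts))

  test_dir <- function(group, label) {
    if (length(group) < min_group || length(neutral) < 2L) return(NULL)
    res <- nb_two_group_test(counts[gene, ], group, neutral, dispersion, lib)
    tibble(region_id = cre$region_id, gene = gene, direction = label,
           n_cnv = length(group), n_neutral = length(neutral),
           fold_change = res$fold_change, p = res$p)
  }
  out <- bind_rows(test_dir(amp, "amplification"), test_dir(del, "deletion"))
  if (is.null(out)) out <- tibble(region_id = character(), gene = character(),
                                  direction = character(), n_cnv = integer(),
                                  n_neutral = integer(), fold_change = numeric(),
                                  p = numeric())
  out
}

#' Enrichment of translocations in a CNV-defined sample group
#'
#' Builds the 2x2 table (in group / not in group) x (translocated / not)
#' over the cohort and returns the one-sided (greater) Fisher's exact test.
#'
#' @param cnv_group,translocated character vectors of sample ids (subsets
#'   of `cohort_samples`).
#' @param cohort_samples all sample ids.
#' @return list with `table` (2x2 matrix), `odds_ratio` (ad/bc) and `p`.
#' @export
cnv_translocation_enrichment <- function(cnv_group, translocated, cohort_samples) {
  if (length(cohort_samples) == 0L) abort("empty cohort")
  stopifnot(all(cnv_group %in% cohort_samples), all(translocated %in% cohort_samples))
  in_g <- cohort_samples %in% cnv_group
  tr <- cohort_samples %in% translocated
  tab <- matrix(c(sum(in_g & tr), sum(in_g & !tr),
                  sum(!in_g & tr), sum(!in_g & !tr)),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c("in_group", "outside"),
                                translocation = c("yes", "no")))
  ft <- fisher_exact(tab, sided = "greater")
  list(table = tab, odds_ratio = ft$odds_ratio, p = ft$p)
}

#' Genes within a window of structural-variant breakpoints
#'
#' @param breakpoints tibble `chrom`, `pos` (0-based).
#' @param gene_table gene-body intervals (`gene`, `chrom`, `start`, `end`).
#' @param window distance in bp (default 1 Mb, boundary inclusive).
#' @return deduplicated tibble of genes within `window` of any breakpoint.
#' @export
genes_near_breakpoints <- function(breakpoints, gene_table, window = 1e6) {
  hits <- map(seq_len(nrow(breakpoints)), function(i) {
    b <- breakpoints[i, ]
    g <- gene_table[gene_table$chrom == b$chrom, ]
    d <- pmax(g$start - b$pos, b$pos - (g$end - 1L), 0)
    g[d <= window, , drop = FALSE]
  })
  distinct(list_rbind(hits))
}
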