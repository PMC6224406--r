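## Somatic SNV table I/O and record-level QC filters.

MAF_COLS <- c("tumor_id", "chrom", "pos", "ref", "alt",
              "alt_fwd", "alt_rev", "mean_bq", "mean_mq", "alignability")

#' Read / write a MAF-like somatic SNV table
#'
#' Tab-separated, one substitution per row, positions 1-based inclusive.
#' Required columns: `tumor_id`, `chrom`, `pos`, `ref`, `alt`, and the QC
#' metrics `alt_fwd`, `alt_rev` (per-strand alternate read counts),
#' `mean_bq` (mean Phred base quality), `mean_mq` (mean mapping quality),
#' `alignability` (fraction in `[0, 1]`).
#'
#' @param path file path.
#' @return `read_maf()` returns a tibble; `write_maf()` returns `path`
#'   invisibly.
#' @export
read_maf <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(out, MAF_COLS, "MAF-like table")
  out
}

#' @rdname read_maf
#' @param snvs a tibble of SNV records.
#' @export
write_maf <- function(snvs, path) {
  assert_columns(snvs, MAF_COLS, "MAF-like table")
  readr::write_tsv(snvs, path, progress = FALSE)
  invisible(path)
}

#' Apply record-level somatic-variant filters
#'
#' Retains records with at least one alternate read on each strand, mean
#' Phred base quality strictly above 26, mean mapping quality at least 50,
#' and an alignability score of exactly 1.0.  Rejections are attributed to
#' the first failed rule in the fixed order strand, base quality, mapping
#' quality, alignability.
#'
#' @param records SNV tibble with the QC columns of [read_maf()].
#' @return a list with `passed` (tibble), `rejected` (tibble with a
#'   `reject_rule` column) and `rejections` (named integer counts per rule).
#' @export
filter_variants <- function(records) {
  assert_columns(records, MAF_COLS, "records")
  qc <- records[, c("alt_fwd", "alt_rev", "mean_bq", "mean_mq", "alignability")]
  bad <- !complete.cases(qc)
  if (any(bad)) {
    miss <- names(qc)[which(is.na(qc[which(bad)[1], ]))]
    abort(sprintf("record %d is missing QC field(s): %s",
                  which(bad)[1], paste(miss, collapse = ", ")))
  }
  if (any(records$ref == records$alt)) abort("ref and alt must differ")
  rule <- rep(NA_character_, nrow(records))
  rule[is.na(rule) & (records$alt_fwd < 1 | records$alt_rev < 1)] <- "strand"
  rule[is.na(rule) & records$mean_bq <= 26] <- "bq"
  rule[is.na(rule) & records$mean_mq < 50] <- "mq"
  rule[is.na(rule) & records$alignability != 1] <- "alignability"
  rejected <- records[!is.na(rule), , drop = FALSE]
  rejected$reject_rule <- rule[!is.na(rule)]
  counts <- vapply(c("strand", "bq", "mq", "alignability"),
                   function(r) sum(rule == r, na.rm = TRUE), integer(1))
  list(passed = as_tibble(records[is.na(rule), , drop = FALSE]),
       rejected = as_tibble(rejected),
       rejections = counts)
}

#' Estimate WGS sensitivity against a high-coverage callset
#'
#' The sensitivity of a (typically low-coverage) WGS callset for clonal
#' variants is the fraction of high-allele-ratio WES variants it recovers:
#' `|WGS intersect WES(aar > aar_min)| / |WES(aar > aar_min)|`.  Variants
#' match on the full `(chrom, pos, ref, alt)` key.
#'
#' @param wgs,wes tibbles with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`; `wes` additionally needs `allele_ratio`.
#' @param aar_min minimum alternate allele ratio (exclusive) defining the
#'   clonal WES reference set.
#' @return a one-row tibble with `sample_id`, `n_wes_clonal`, `n_recovered`,
#'   `sensitivity` (`NA` when the denominator is empty).
#' @export
estimate_sensitivity <- function(wgs, wes, aar_min = 0.2) {
  stopifnot(aar_min >= 0, aar_min < 1)
  assert_columns(wgs, c("sample_id", "chrom", "pos", "ref", "alt"), "wgs")
  assert_columns(wes, c("sample_id", "chrom", "pos", "ref", "alt", "allele_ratio"), "wes")
  sid <- unique(c(wgs$sample_id, wes$sample_id))
  if (length(sid) != 1L) abort("wgs and wes callsets must come from the same sample")
  clonal <- wes[wes$allele_ratio > aar_min, , drop = FALSE]
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  n <- nrow(clonal)
  hit <- sum(key(clonal) %in% key(wgs))
  tibble(sample_id = sid, n_wes_clonal = n, n_recovered = hit,
         sensitivity = if (n == 0L) NA_real_ else hit / n)
}

#' Cohort-level WGS sensitivity
#'
#' Per-sample sensitivities plus their unweighted mean.
#'
#' @param wgs,wes multi-sample callset tibbles (see [estimate_sensitivity()]).
#' @inheritParams estimate_sensitivity
#' @return a list with `per_sample` (tibble) and `mean` (unweighted mean of
#'   the defined per-sample sensitivities).
#' @export
cohort_sensitivity <- function(wgs, wes, aar_min = 0.2) {
  ids <- sort(unique(wes$sample_id))
  per <- list_rbind(map(ids, function(s) {
    estimate_sensitivity(wgs[wgs$sample_id == s, ], wes[wes$sample_id == s, ], aar_min)
  }))
  list(per_sample = per, mean = mean(per$sensitivity, na.rm = TRUE))
}
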