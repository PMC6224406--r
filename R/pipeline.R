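## End-to-end orchestration: QC -> regions -> background + recurrence ->
## expression effects -> karyotype -> signatures -> cohort statistics.

#' Analysis thresholds
#'
#' All defaults are the pipeline's canonical operating points: interaction
#' score >= 5, promoter-CRE distance <= 1 Mb, mappability >= 95%, CNV event
#' threshold |log2| >= 0.1613 with focal events < 3 Mb, candidate fold
#' changes 1.2 / 0.8, recurrence significance Q < 0.05, expression
#' significance Q < 0.1, at least 3 mutated samples per expression test, at
#' least 7 samples per CNV expression group, 10,000 clustering
#' permutations, and a 0.2 allele-ratio floor for sensitivity estimation.
#'
#' @param ... named overrides of any threshold.
#' @return named list of thresholds.
#' @export
pipeline_thresholds <- function(...) {
  defaults <- list(
    chicago_min = 5, distance_max = 1e6, mappability_min = 0.95,
    focal_log2 = 0.1613, focal_size = 3e6, fc_up = 1.2, fc_down = 0.8,
    q_recurrence = 0.05, q_de = 0.1, min_mutated = 3L, min_cnv_group = 7L,
    n_perm = 10000L, aar_min = 0.2, exposure_floor = 0.06
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) abort(paste0("unknown threshold(s): ", paste(bad, collapse = ", ")))
  if (length(over)) {
    rlang::inform(paste0("threshold override: ",
                         paste(names(over), unlist(over), sep = "=", collapse = ", ")))
  }
  utils::modifyList(defaults, over)
}

#' Run the full analysis on a cohort
#'
#' Executes the stages in dependency order and returns a machine-readable
#' report: QC filtering, promoter/CRE region definition, background model
#' fits, recurrence tests (separate promoter and CRE batches), expression
#' effects of the recurrent regions, karyotype assignment, per-sample
#' signature exposures, and karyotype burden statistics.  Identical seed
#' and inputs give an identical report; every result row carries the
#' configuration hash.
#'
#' @param cohort a `cohort` object (or any list exposing the same tables).
#' @param thresholds a [pipeline_thresholds()] list.
#' @param seed integer seed for all stochastic stages.
#' @return a `regdriver_report` list: `config_hash`, `counts` (per-stage
#'   record counts), `recurrence` (promoter + CRE tibble), `expression`,
#'   `karyotype`, `exposures`, `burden`, `thresholds`.
#' @export
run_pipeline <- function(cohort, thresholds = pipeline_thresholds(), seed = 1L) {
  th <- thresholds
  hash <- rlang::hash(list(th, seed, cohort$config))

  qc <- filter_variants(cohort$snvs)
  snvs <- qc$passed
  chrlen <- cohort$config$chrom_lengths
  tumors <- cohort$samples$sample_id

  rec_all <- list(); regions_by_kind <- list()
  for (kind in c("promoter", "cre")) {
    regions <- suppressMessages(build_regions(
      cohort, kind, chrom_lengths = chrlen, score_min = th$chicago_min,
      distance_max = th$distance_max, mappability_min = th$mappability_min))
    bg <- fit_background(snvs, regions, cohort$tracks, cohort$genome, tumors,
                         annotation = cohort$annotation)
    rec <- test_recurrence(snvs, regions, bg, cohort$tracks, cohort$genome,
                           annotation = cohort$annotation,
                           n_perm = th$n_perm,
                           seed = substream_seed(seed, paste0("recurrence_", kind)))
    rec_all[[kind]] <- rec
    regions_by_kind[[kind]] <- regions
  }
  recurrence <- bind_rows(rec_all) |> mutate(config_hash = hash)

  de_all <- list()
  for (kind in c("promoter", "cre")) {
    rec <- rec_all[[kind]]
    sig_ids <- rec$region_id[!is.na(rec$q) & rec$q < th$q_recurrence]
    if (length(sig_ids) == 0L) next
    sig_regions <- regions_by_kind[[kind]][
      regions_by_kind[[kind]]$region_id %in% sig_ids, ]
    de_all[[kind]] <- suppressMessages(test_expression_effects(
      sig_regions, snvs, cohort$cnv, cohort$counts, gene_bodies(cohort),
      fc_up = th$fc_up, fc_down = th$fc_down, q_max = th$q_de,
      min_mutated = th$min_mutated)) |>
      mutate(kind = kind)
  }
  expression <- if (length(de_all)) {
    bind_rows(de_all) |> mutate(config_hash = hash)
  } else {
    tibble()
  }

  karyotype <- assign_karyotype(cohort$cnv, cohort$samples, chrlen)
  exposures <- suppressMessages(fit_sample_exposures(
    snvs, cohort$genome, cohort$config$signature_catalog,
    exposure_floor = th$exposure_floor))

  burden_counts <- table(factor(snvs$tumor_id, levels = tumors))
  groups <- list(HD = karyotype$sample_id[karyotype$hd])
  for (lab in unique(unlist(karyotype$translocations))) {
    groups[[lab]] <- karyotype$sample_id[map_lgl(karyotype$translocations,
                                                 ~ lab %in% .x)]
  }
  burden <- wilcoxon_burden(setNames(as.numeric(burden_counts), tumors), groups)

  report <- structure(list(
    config_hash = hash,
    thresholds = th,
    seed = seed,
    counts = list(
      snvs_in = nrow(cohort$snvs), snvs_pass = nrow(snvs),
      qc_rejections = qc$rejections,
      regions_promoter = nrow(regions_by_kind$promoter),
      regions_cre = nrow(regions_by_kind$cre),
      significant_promoter = sum(rec_all$promoter$q < th$q_recurrence, na.rm = TRUE),
      significant_cre = sum(rec_all$cre$q < th$q_recurrence, na.rm = TRUE),
      de_tested = if (nrow(expression)) sum(!is.na(expression$p)) else 0L,
      de_candidates = if (nrow(expression)) sum(expression$candidate, na.rm = TRUE) else 0L,
      hd_samples = sum(karyotype$hd)
    ),
    recurrence = recurrence,
    expression = expression,
    karyotype = karyotype,
    exposures = exposures,
    burden = burden
  ), class = "regdriver_report")
  report
}

#' @export
print.regdriver_report <- function(x, ...) {
  c_ <- x$counts
  cat("regdriver pipeline report (config", substr(x$config_hash, 1, 8), ")\n")
  cat(sprintf("  SNVs: %d in, %d pass QC\n", c_$snvs_in, c_$snvs_pass))
  cat(sprintf("  regions: %d promoters, %d CREs\n",
              c_$regions_promoter, c_$regions_cre))
  cat(sprintf("  recurrent (Q < %.2g): %d promoters, %d CREs\n",
              x$thresholds$q_recurrence, c_$significant_promoter, c_$significant_cre))
  cat(sprintf("  expression tests: %d run, %d candidates\n",
              c_$de_tested, c_$de_candidates))
  cat(sprintf("  karyotype: %d HD samples\n", c_$hd_samples))
  invisible(x)
}
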