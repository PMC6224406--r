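## Definition of testable regulatory regions: promoter windows around the
## TSS, CRE fragments retained by interaction-score / distance /
## mappability filters, and coding-sequence masking.

#' Define promoter windows from a TSS table
#'
#' Each promoter spans 400 bp upstream to 250 bp downstream of the
#' annotated TSS (651 bases including the TSS itself), with upstream
#' following gene orientation.  Overlapping windows of the same gene are
#' merged and windows are clipped at chromosome ends when lengths are
#' supplied.
#'
#' @param tss_table tibble with columns `gene`, `chrom`, `tss` (1-based),
#'   `strand` (`+`/`-`).
#' @param upstream,downstream window extents in bp.
#' @param chrom_lengths optional named vector for end clipping.
#' @return tibble with `region_id`, `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `kind = "promoter"`.
#' @export
define_promoters <- function(tss_table, upstream = 400L, downstream = 250L,
                             chrom_lengths = NULL) {
  assert_columns(tss_table, c("gene", "chrom", "tss", "strand"), "tss_table")
  bad <- !tss_table$strand %in% c("+", "-")
  if (any(bad)) {
    abort(sprintf("unknown strand symbol '%s'", tss_table$strand[which(bad)[1]]))
  }
  win <- tss_table |>
    mutate(
      start = ifelse(.data$strand == "+", .data$tss - upstream - 1L,
                     .data$tss - downstream - 1L),
      end = ifelse(.data$strand == "+", .data$tss + downstream,
                   .data$tss + upstream),
      start = pmax(.data$start, 0L)
    )
  if (!is.null(chrom_lengths)) {
    win$end <- pmin(win$end, chrom_lengths[win$chrom])
  }
  merged <- win |>
    group_by(.data$gene, .data$chrom, .data$strand) |>
    group_modify(function(d, key) {
      iranges_to_tbl(IRanges::reduce(as_iranges(d$start, d$end)))
    }) |>
    ungroup() |>
    group_by(.data$gene) |>
    mutate(.n = n(), .i = row_number()) |>
    ungroup() |>
    mutate(region_id = ifelse(.data$.n == 1L, paste0("prom_", .data$gene),
                              paste0("prom_", .data$gene, "_", .data$.i))) |>
    transmute(region_id = .data$region_id, gene_id = .data$gene,
              chrom = .data$chrom, start = as.integer(.data$start),
              end = as.integer(.data$end), strand = .data$strand,
              kind = "promoter")
  arrange(merged, .data$chrom, .data$start)
}

#' Filter promoter-CRE interactions by confidence score and distance
#'
#' Retains interactions with score at least `score_min` (CHiCAGO-style
#' confidence, default 5) and promoter-fragment linear distance at most
#' `distance_max` (default 1 Mb); both boundaries inclusive.
#'
#' @param interactions tibble with at least `score` and `distance` columns.
#' @param score_min,distance_max thresholds.
#' @return the retained rows.
#' @export
filter_interactions <- function(interactions, score_min = 5, distance_max = 1e6) {
  assert_columns(interactions, c("score", "distance"), "interactions")
  if (any(interactions$distance < 0)) abort("negative interaction distance")
  filter(interactions, .data$score >= score_min, .data$distance <= distance_max)
}

#' Drop fragments that are not well mapped
#'
#' A fragment is retained iff at least `min_fraction` (default 95%) of its
#' bases fall inside the supplied well-mapped intervals.  Fragments with no
#' track coverage are treated as 0% well mapped and dropped.
#'
#' @param fragments tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and any id columns.
#' @param well_mapped tibble of well-mapped intervals (`chrom`, `start`,
#'   `end`).
#' @param min_fraction retention threshold.
#' @return the retained fragments with an added `mappable_fraction` column.
#' @export
mappability_filter <- function(fragments, well_mapped, min_fraction = 0.95) {
  assert_columns(fragments, c("chrom", "start", "end"), "fragments")
  assert_columns(well_mapped, c("chrom", "start", "end"), "well_mapped")
  frac <- numeric(nrow(fragments))
  for (ch in unique(fragments$chrom)) {
    fi <- which(fragments$chrom == ch)
    wm <- well_mapped[well_mapped$chrom == ch, ]
    if (nrow(wm) == 0L) next
    q <- as_iranges(fragments$start[fi], fragments$end[fi])
    s <- IRanges::reduce(as_iranges(wm$start, wm$end))
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits) == 0L) next
    ov <- IRanges::width(IRanges::pintersect(
      q[S4Vectors::queryHits(hits)], s[S4Vectors::subjectHits(hits)]))
    acc <- rowsum(ov, S4Vectors::queryHits(hits))
    frac[fi[as.integer(rownames(acc))]] <- acc[, 1] / IRanges::width(q)[as.integer(rownames(acc))]
  }
  fragments$mappable_fraction <- frac
  dropped <- sum(frac < min_fraction)
  if (dropped > 0) {
    rlang::inform(sprintf("mappability filter: dropped %d of %d fragments",
                          dropped, nrow(fragments)))
  }
  fragments[frac >= min_fraction, , drop = FALSE]
}

#' Mask coding bases out of a regulatory region
#'
#' For CRE fragments the testable bases exclude open reading frames
#' (extended by `orf_pad` bp for splice sites) and 5'/3' UTRs.  Promoter
#' windows keep their full extent; coding overlap is instead handled at
#' test time by discarding ORF-overlapping mutations.
#'
#' @param region one-row tibble/list with `chrom`, `start`, `end`.
#' @param annotation tibble with `chrom`, `start`, `end`, `class`
#'   (`ORF`, `UTR5`, `UTR3`).
#' @param kind `"cre"` or `"promoter"`.
#' @param orf_pad bp added to each side of ORFs (CREs only).
#' @return tibble of testable intervals (`start`, `end`), 0-based half-open.
#' @export
mask_coding <- function(region, annotation, kind = c("cre", "promoter"),
                        orf_pad = 5L) {
  kind <- match.arg(kind)
  if (kind == "promoter") {
    return(tibble(start = as.integer(region$start), end = as.integer(region$end)))
  }
  ann <- annotation[annotation$chrom == region$chrom, , drop = FALSE]
  orf <- ann[ann$class == "ORF", , drop = FALSE]
  utr <- ann[ann$class %in% c("UTR5", "UTR3"), , drop = FALSE]
  sub_start <- c(pmax(orf$start - orf_pad, 0L), utr$start)
  sub_end <- c(orf$end + orf_pad, utr$end)
  interval_setdiff(region$start, region$end, sub_start, sub_end)
}

#' Assemble the testable region set for one analysis kind
#'
#' Applies the full region-definition cascade: promoter windows from the
#' TSS table, or CRE fragments surviving the interaction-score/distance and
#' mappability filters, with coding bases masked.
#'
#' @param cohort_inputs list with `tss`, `interactions`, `mappability`,
#'   `annotation` tibbles (e.g. a `cohort` object).
#' @param kind `"promoter"` or `"cre"`.
#' @param chrom_lengths optional named lengths for clipping.
#' @param score_min,distance_max,mappability_min cascade thresholds.
#' @return region tibble with `region_id`, `kind`, `chrom`, `start`, `end`,
#'   `target_genes` (list column), `testable` (list column of interval
#'   tibbles) and `n_testable` (testable base count).
#' @export
build_regions <- function(cohort_inputs, kind = c("promoter", "cre"),
                          chrom_lengths = NULL, score_min = 5,
                          distance_max = 1e6, mappability_min = 0.95) {
  kind <- match.arg(kind)
  ann <- cohort_inputs$annotation
  if (kind == "promoter") {
    prom <- define_promoters(cohort_inputs$tss, chrom_lengths = chrom_lengths)
    regions <- prom |>
      mutate(target_genes = as.list(.data$gene_id)) |>
      select("region_id", "kind", "chrom", "start", "end", "target_genes")
  } else {
    ints <- filter_interactions(cohort_inputs$interactions,
                                score_min = score_min, distance_max = distance_max)
    frags <- ints |>
      group_by(.data$fragment_id, .data$chrom, .data$start, .data$end) |>
      summarise(target_genes = list(unique(.data$gene)),
                scores = list(setNames(.data$score, .data$gene)),
                .groups = "drop")
    frags <- mappability_filter(frags, cohort_inputs$mappability,
                                min_fraction = mappability_min)
    regions <- frags |>
      mutate(region_id = .data$fragment_id, kind = "cre") |>
      select("region_id", "kind", "chrom", "start", "end", "target_genes")
  }
  ## bulk-detect regions clear of any (padded) annotation: full mask
  pad <- 5L
  needs_mask <- rep(FALSE, nrow(regions))
  if (kind == "cre" && nrow(ann) > 0) {
    for (ch in unique(regions$chrom)) {
      ri <- which(regions$chrom == ch)
      a <- ann[ann$chrom == ch, ]
      if (nrow(a) == 0L) next
      needs_mask[ri] <- IRanges::overlapsAny(
        as_iranges(regions$start[ri], regions$end[ri]),
        as_iranges(pmax(a$start - pad, 0L), a$end + pad))
    }
  }
  regions$testable <- map(seq_len(nrow(regions)), function(i) {
    if (!needs_mask[i]) {
      return(tibble(start = as.integer(regions$start[i]),
                    end = as.integer(regions$end[i])))
    }
    mask_coding(regions[i, ], ann, kind = "cre")
  })
  regions$n_testable <- map_int(regions$testable, ~ sum(.x$end - .x$start))
  regions <- regions[regions$n_testable > 0L, , drop = FALSE]
  as_tibble(regions)
}
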