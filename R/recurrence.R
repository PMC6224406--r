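## Background mutation model and per-region recurrence significance.
##
## The count of tumours carrying at least one mutation in a region is
## modelled as Poisson-binomial: each tumour's success probability is
## q_t = 1 - prod_k (1 - p_kt) over the region's testable bases, with the
## per-base probability p_kt from a logistic regression on reference base
## class (A/T vs G/C), replication timing, coverage, and a per-tumour load
## offset.  Positional clustering is tested by permutation, the two
## p-values are combined by Fisher's method, and regions are BH-adjusted
## per batch.

## -- region/covariate bookkeeping -------------------------------------------

## Split each region's testable intervals at covariate-window boundaries and
## attach the window covariates plus A/T / G/C base counts.  One row per
## (region, sub-interval); covariates are piecewise constant within a row.
build_region_cells <- function(regions, tracks, genome) {
  iv <- regions |>
    select("region_id", "chrom", "testable") |>
    unnest("testable")
  ## split at 1-kb window boundaries
  pieces <- pmap(iv, function(region_id, chrom, start, end) {
    first <- floor(start / WINDOW_BP) * WINDOW_BP + WINDOW_BP
    cuts <- if (first >= end) integer(0) else seq.int(first, end, by = WINDOW_BP)
    b <- unique(c(start, cuts[cuts > start & cuts < end], end))
    tibble(region_id = region_id, chrom = chrom,
           start = as.integer(b[-length(b)]), end = as.integer(b[-1]))
  })
  cells <- list_rbind(pieces)
  rt <- tracks$reptime; cv <- tracks$coverage
  key <- paste(cells$chrom, floor(cells$start / WINDOW_BP))
  cells$reptime <- rt$value[match(key, paste(rt$chrom, floor(rt$start / WINDOW_BP)))]
  cells$coverage <- cv$value[match(key, paste(cv$chrom, floor(cv$start / WINDOW_BP)))]
  if (anyNA(cells$reptime) || anyNA(cells$coverage)) {
    abort("covariate tracks do not cover every testable base")
  }
  counts <- matrix(0L, nrow(cells), 2L, dimnames = list(NULL, c("AT", "GC")))
  for (ch in unique(cells$chrom)) {
    idx <- which(cells$chrom == ch)
    v <- Biostrings::Views(genome[[ch]],
                           IRanges::IRanges(cells$start[idx] + 1L, cells$end[idx]))
    counts[idx, ] <- Biostrings::letterFrequency(v, c("AT", "GC"))
  }
  cells$n_at <- counts[, "AT"]
  cells$n_gc <- counts[, "GC"]
  cells
}

## deduplicate calls and map mutations onto region testable bases;
## one row per (region_id, tumor_id, pos0) with ref base class
assign_mutations <- function(snvs, regions) {
  mut <- distinct(snvs, .data$tumor_id, .data$chrom, .data$pos, .data$ref)
  mut$pos0 <- mut$pos - 1L
  iv <- regions |>
    mutate(.region_idx = row_number()) |>
    select(".region_idx", "chrom", "testable") |>
    unnest("testable")
  out <- vector("list", length(unique(iv$chrom)))
  i <- 0L
  for (ch in unique(iv$chrom)) {
    i <- i + 1L
    iv_ch <- iv[iv$chrom == ch, ]
    m_ch <- mut[mut$chrom == ch, ]
    if (nrow(m_ch) == 0L || nrow(iv_ch) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(m_ch$pos0 + 1L, m_ch$pos0 + 1L),
      as_iranges(iv_ch$start, iv_ch$end))
    if (length(hits) == 0L) next
    out[[i]] <- tibble(
      region_idx = iv_ch$.region_idx[S4Vectors::subjectHits(hits)],
      tumor_id = m_ch$tumor_id[S4Vectors::queryHits(hits)],
      chrom = ch,
      pos0 = m_ch$pos0[S4Vectors::queryHits(hits)],
      ref = m_ch$ref[S4Vectors::queryHits(hits)])
  }
  res <- list_rbind(out[!vapply(out, is.null, TRUE)])
  if (is.null(res) || nrow(res) == 0L) {
    return(tibble(region_idx = integer(), tumor_id = character(),
                  chrom = character(), pos0 = integer(), ref = character()))
  }
  distinct(res, .data$region_idx, .data$tumor_id, .data$pos0, .keep_all = TRUE)
}

## drop mutations overlapping plain ORF intervals (promoter test-time rule)
drop_orf_mutations <- function(snvs, annotation) {
  orf <- annotation[annotation$class == "ORF", , drop = FALSE]
  keep <- rep(TRUE, nrow(snvs))
  for (ch in unique(snvs$chrom)) {
    idx <- which(snvs$chrom == ch)
    o <- orf[orf$chrom == ch, ]
    if (nrow(o) == 0L) next
    keep[idx] <- !pos_in_intervals(snvs$pos[idx] - 1L, o$start, o$end)
  }
  snvs[keep, , drop = FALSE]
}

## -- background model -------------------------------------------------------

#' Fit the logistic background mutation model
#'
#' Per-base, per-tumour mutation indicators are regressed on reference base
#' class (G/C vs A/T), replication timing, and coverage, with tumour
#' identity entering as a fixed per-tumour load offset on the logit scale
#' (two-pass scheme).  Observations are aggregated to binomial counts over
#' covariate-constant cells, which makes the fit exact and fast.  Promoters
#' and CREs are fitted separately.
#'
#' @param snvs QC-passed SNV tibble (1-based `pos`).
#' @param regions region tibble from [build_regions()]; all rows must share
#'   one `kind`.
#' @param tracks list with `reptime` and `coverage` interval tibbles.
#' @param genome `DNAStringSet` reference.
#' @param tumors character vector of all tumour ids in the cohort (tumours
#'   with zero mutations still contribute unmutated bases).
#' @param annotation ORF/UTR annotation; required for promoter fits, where
#'   ORF-overlapping mutations are excluded.
#' @param negative_sampling_fraction keep this fraction of unmutated
#'   observations (case-control thinning); the intercept is corrected by
#'   `log(fraction)` so predicted rates stay on the cohort scale.
#' @param sampling_seed seed for the thinning when `fraction < 1`.
#' @return a `background_model` object; see [predict_base_rates()],
#'   [tidy.background_model()].
#' @export
fit_background <- function(snvs, regions, tracks, genome, tumors,
                           annotation = NULL,
                           negative_sampling_fraction = 1,
                           sampling_seed = 1L) {
  stopifnot(length(unique(regions$kind)) == 1L)
  kind <- regions$kind[1]
  f <- negative_sampling_fraction
  stopifnot(f > 0, f <= 1)
  if (kind == "promoter") {
    if (is.null(annotation)) abort("promoter fits require the ORF annotation")
    snvs <- drop_orf_mutations(snvs, annotation)
  }
  cells <- build_region_cells(regions, tracks, genome)
  mut <- assign_mutations(snvs, regions)
  mut$is_gc <- as.integer(mut$ref %in% c("G", "C"))

  ## first pass: per-tumour load offsets on the logit(~log) scale
  loads <- table(factor(mut$tumor_id, levels = tumors))
  off <- log(as.numeric(loads) + 0.5) - log(mean(as.numeric(loads) + 0.5))
  names(off) <- tumors

  ## cell x class x tumour binomial aggregation
  base <- tibble(
    cell = rep(seq_len(nrow(cells)), 2L),
    is_gc = rep(c(0L, 1L), each = nrow(cells)),
    n = c(cells$n_at, cells$n_gc)
  ) |> filter(.data$n > 0L)
  ## mutation counts per (cell, class, tumour): locate each mutation's cell
  mut_cell <- integer(nrow(mut))
  for (ch in unique(mut$chrom)) {
    midx <- which(mut$chrom == ch)
    cidx <- which(cells$chrom == ch)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(mut$pos0[midx] + 1L, mut$pos0[midx] + 1L),
      as_iranges(cells$start[cidx], cells$end[cidx]),
      select = "first")
    mut_cell[midx] <- cidx[hits]
  }
  mut$cell <- mut_cell
  mut_counts <- mut |>
    count(.data$cell, .data$is_gc, .data$tumor_id, name = "k")

  grid <- crossing(base, tumor_id = tumors) |>
    left_join(mut_counts, by = c("cell", "is_gc", "tumor_id")) |>
    mutate(k = ifelse(is.na(.data$k), 0L, .data$k),
           k = pmin(.data$k, .data$n))
  fail <- grid$n - grid$k
  if (f < 1) {
    fail <- withr::with_seed(as.integer(sampling_seed), rbinom(length(fail), fail, f))
  }
  df <- tibble(
    k = grid$k, fail = fail,
    is_gc = grid$is_gc,
    reptime = cells$reptime[grid$cell],
    coverage = cells$coverage[grid$cell],
    off = off[grid$tumor_id]
  ) |> filter(.data$k + .data$fail > 0L)

  fit <- glm(cbind(k, fail) ~ is_gc + reptime + coverage + offset(off),
             family = binomial(), data = df)
  if (!fit$converged) abort("background model did not converge")
  cf <- coef(fit)
  big <- names(cf)[abs(cf) > 20]
  if (length(big)) {
    abort(paste0("background model unstable (possible separation) in: ",
                 paste(big, collapse = ", ")))
  }
  cf[["(Intercept)"]] <- cf[["(Intercept)"]] + log(f)  # case-control correction
  structure(list(
    coefficients = cf,
    vcov = vcov(fit),
    tumor_offsets = off,
    kind = kind,
    sampling_fraction = f,
    deviance = fit$deviance,
    null_deviance = fit$null.deviance,
    df_residual = fit$df.residual,
    n_obs = nrow(df),
    converged = fit$converged
  ), class = "background_model")
}

#' Predict per-base mutation probabilities
#'
#' @param model a `background_model`.
#' @param is_gc 0/1 reference base class.
#' @param reptime,coverage covariate values.
#' @param tumor_id tumour whose load offset to apply (optional; omitted
#'   means the cohort-average tumour).
#' @return numeric vector of probabilities, strictly inside (0, 1).
#' @export
predict_base_rates <- function(model, is_gc, reptime, coverage, tumor_id = NULL) {
  cf <- model$coefficients
  eta <- cf[["(Intercept)"]] + cf[["is_gc"]] * is_gc +
    cf[["reptime"]] * reptime + cf[["coverage"]] * coverage
  if (!is.null(tumor_id)) eta <- eta + unname(model$tumor_offsets[tumor_id])
  plogis(eta)
}

## per-(region, tumour) probability of >= 1 mutation, via the cell table
region_probability_matrix <- function(model, cells) {
  cf <- model$coefficients
  eta_at <- cf[["(Intercept)"]] + cf[["reptime"]] * cells$reptime +
    cf[["coverage"]] * cells$coverage
  eta_gc <- eta_at + cf[["is_gc"]]
  tumors <- names(model$tumor_offsets)
  ridx <- match(cells$region_id, unique(cells$region_id))
  n_regions <- max(ridx)
  q <- matrix(NA_real_, n_regions, length(tumors),
              dimnames = list(unique(cells$region_id), tumors))
  for (t in seq_along(tumors)) {
    o <- model$tumor_offsets[[t]]
    lp <- cells$n_at * log1p(-plogis(eta_at + o)) +
      cells$n_gc * log1p(-plogis(eta_gc + o))
    q[, t] <- 1 - exp(rowsum(lp, ridx)[, 1])
  }
  q
}

#' Probability that a tumour carries at least one mutation in a region
#'
#' `1 - prod(1 - p_k)` over the region's per-base probabilities -- the
#' per-tumour success probability entering the Poisson binomial.
#'
#' @param p_k per-base mutation probabilities, all in `[0, 1)`.
#' @return a single probability.
#' @export
region_tumor_probability <- function(p_k) {
  if (any(p_k < 0 | p_k >= 1)) abort("per-base probabilities must lie in [0, 1)")
  if (length(p_k) == 0L) return(0)
  1 - exp(sum(log1p(-p_k)))
}

## -- Poisson-binomial tail --------------------------------------------------

poibin_pmf_dp <- function(q) {
  f <- 1
  for (qi in q) f <- c(f * (1 - qi), 0) + c(0, f * qi)
  f
}

#' Upper tail of the Poisson-binomial distribution
#'
#' `P(X >= x_obs)` for `X = sum of independent Bernoulli(q_t)`.  Uses the
#' exact dynamic-programming convolution for up to `exact_max` tumours and
#' a skewness-corrected (refined) normal approximation beyond.
#'
#' @param q success probabilities in `[0, 1]`.
#' @param x_obs observed count, `0 <= x_obs <= length(q)`.
#' @param method `"auto"`, `"dp"` (exact) or `"rna"` (refined normal).
#' @param exact_max size limit for the automatic exact path.
#' @return `P(X >= x_obs)`.
#' @export
poisson_binomial_tail <- function(q, x_obs, method = c("auto", "dp", "rna"),
                                  exact_max = 5000L) {
  method <- match.arg(method)
  if (any(q < 0 | q > 1)) abort("q must lie in [0, 1]")
  if (x_obs > length(q)) abort("x_obs exceeds the number of tumours")
  if (x_obs < 0) abort("x_obs must be non-negative")
  if (x_obs == 0L) return(1)
  if (method == "auto") method <- if (length(q) <= exact_max) "dp" else "rna"
  if (method == "dp") {
    f <- poibin_pmf_dp(q)
    p <- sum(f[seq.int(x_obs + 1L, length(f))])
    return(min(max(p, 0), 1))
  }
  mu <- sum(q)
  s2 <- sum(q * (1 - q))
  if (s2 == 0) return(as.numeric(x_obs <= mu))
  s <- sqrt(s2)
  g <- sum(q * (1 - q) * (1 - 2 * q)) / s2^1.5
  x <- (x_obs - 0.5 - mu) / s
  p <- 1 - (pnorm(x) + g * (1 - x^2) * stats::dnorm(x) / 6)
  min(max(p, 0), 1)
}

## -- clustering permutation test --------------------------------------------

## null distribution of the clustering statistic S = m - #distinct for m
## uniform draws (with replacement) over s testable bases
cluster_null_S <- function(m, s, n_perm, seed) {
  withr::with_seed(as.integer(seed), {
    v <- sample.int(s, n_perm * m, replace = TRUE)
    row <- rep(seq_len(n_perm), each = m)
    key <- (row - 1) * as.double(s) + v
    d <- duplicated(key)
    tabulate(row[d], nbins = n_perm)
  })
}

#' Positional-clustering permutation p-value
#'
#' Statistic `S = m - u`: the excess of mutations over distinct mutated
#' positions.  The null redraws the `m` positions independently and
#' uniformly over the region's `s` testable bases `n_perm` times; the
#' p-value is `(1 + #{S_perm >= S_obs}) / (n_perm + 1)` (add-one smoothing,
#' so downstream log-combination never sees zero).  Regions with fewer than
#' three mutations are not tested and return `NA`.
#'
#' @param positions integer vector of mutation positions (any fixed frame).
#' @param s number of testable bases in the region.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return the permutation p-value, or `NA_real_` when `m < 3`.
#' @export
clustering_pvalue <- function(positions, s, n_perm = 10000L, seed = 1L) {
  if (s < 1) abort("region size s must be at least 1")
  m <- length(positions)
  if (m < 3L) return(NA_real_)
  s_obs <- m - length(unique(positions))
  null_S <- cluster_null_S(m, s, n_perm, seed)
  (1 + sum(null_S >= s_obs)) / (n_perm + 1)
}

#' Combine background and clustering p-values by Fisher's method
#'
#' With both present: upper tail of chi-square(4) at
#' `-2 (log p_background + log p_cluster)`.  When the clustering test was
#' not run (`NA`), the background p-value passes through unchanged.
#'
#' @param p_background,p_cluster p-values in `(0, 1]`; `p_cluster` may be
#'   `NA`.
#' @return the combined p-value.
#' @export
combine_fisher <- function(p_background, p_cluster) {
  if (is.na(p_background) || p_background <= 0 || p_background > 1) {
    abort("p_background must lie in (0, 1]")
  }
  if (is.na(p_cluster)) return(p_background)
  if (p_cluster <= 0 || p_cluster > 1) abort("p_cluster must lie in (0, 1]")
  stat <- -2 * (log(p_background) + log(p_cluster))
  pchisq(stat, df = 4, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment with the standard cumulative-minimum monotonicity
#' enforcement.  Promoter and CRE batches should be adjusted separately.
#'
#' @param p numeric vector of p-values.
#' @return q-values, same length/order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  p.adjust(p, method = "BH")
}

## -- per-region recurrence test ---------------------------------------------

#' Test every region for mutational recurrence
#'
#' For each region: counts the (deduplicated) mutations on testable bases,
#' computes the Poisson-binomial tail p-value of the mutated-tumour count
#' against the fitted background, runs the clustering permutation test when
#' at least three mutations are present, combines the two by Fisher's
#' method, and BH-adjusts across the whole batch.
#'
#' @param snvs QC-passed SNV tibble.
#' @param regions region tibble from [build_regions()] (one `kind`).
#' @param model `background_model` fitted on the same kind.
#' @param tracks,genome covariate tracks and reference.
#' @param annotation ORF/UTR annotation (required for promoters).
#' @param n_perm clustering permutations.
#' @param seed seed for the permutation null.
#' @return a `recurrence_result` tibble: `region_id`, `kind`,
#'   `n_mutations` (m), `n_tumors` (x), `n_positions` (u), `p_background`,
#'   `p_cluster`, `p_combined`, `q`.
#' @export
test_recurrence <- function(snvs, regions, model, tracks, genome,
                            annotation = NULL, n_perm = 10000L, seed = 1L) {
  stopifnot(inherits(model, "background_model"))
  kind <- regions$kind[1]
  if (kind == "promoter") {
    if (is.null(annotation)) abort("promoter tests require the ORF annotation")
    snvs <- drop_orf_mutations(snvs, annotation)
  }
  cells <- build_region_cells(regions, tracks, genome)
  mut <- assign_mutations(snvs, regions)
  qmat <- region_probability_matrix(model, cells)

  stats_tbl <- mut |>
    group_by(.data$region_idx) |>
    summarise(m = n(), x = n_distinct(.data$tumor_id),
              u = n_distinct(.data$pos0),
              positions = list(.data$pos0), .groups = "drop")
  out <- tibble(
    region_id = regions$region_id, kind = kind,
    n_mutations = 0L, n_tumors = 0L, n_positions = 0L,
    p_background = NA_real_, p_cluster = NA_real_
  )
  out$n_mutations[stats_tbl$region_idx] <- stats_tbl$m
  out$n_tumors[stats_tbl$region_idx] <- stats_tbl$x
  out$n_positions[stats_tbl$region_idx] <- stats_tbl$u

  qmat <- qmat[match(regions$region_id, rownames(qmat)), , drop = FALSE]
  out$p_background <- vapply(seq_len(nrow(out)), function(i) {
    poisson_binomial_tail(qmat[i, ], out$n_tumors[i])
  }, numeric(1))

  ## clustering: permutation nulls are shared across regions with identical
  ## (m, s) -- the null depends on nothing else
  clus <- tibble(region_idx = stats_tbl$region_idx,
                 m = stats_tbl$m,
                 s = regions$n_testable[stats_tbl$region_idx],
                 s_obs = stats_tbl$m - stats_tbl$u) |>
    filter(.data$m >= 3L)
  if (nrow(clus) > 0) {
    combos <- distinct(clus, .data$m, .data$s)
    for (i in seq_len(nrow(combos))) {
      m_i <- combos$m[i]; s_i <- combos$s[i]
      null_S <- cluster_null_S(m_i, s_i, n_perm,
                               substream_seed(seed, paste0("clus_", m_i, "_", s_i)))
      rows <- clus[clus$m == m_i & clus$s == s_i, ]
      p <- vapply(rows$s_obs, function(so) (1 + sum(null_S >= so)) / (n_perm + 1),
                  numeric(1))
      out$p_cluster[rows$region_idx] <- p
    }
  }
  out$p_combined <- vapply(seq_len(nrow(out)), function(i) {
    combine_fisher(out$p_background[i], out$p_cluster[i])
  }, numeric(1))
  out$q <- bh_fdr(out$p_combined)
  class(out) <- c("recurrence_result", class(out))
  out
}
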