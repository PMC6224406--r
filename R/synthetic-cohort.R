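## Synthetic-cohort generator: emits every input the analysis consumes
## (genome, TSS table, CRE fragments + interactions, covariate tracks,
## mappability, SNVs, CNV segments, expression counts, sample metadata)
## from a single seed, with known ground truth for recovery testing.

#' Configuration for a synthetic cohort
#'
#' Defaults describe the package's reference desk-scale study condition: a
#' 10-Mb two-chromosome genome, 50 tumours, ~2-kb CRE fragments tiled over
#' the genome, and a logistic per-base background mutation model driven by
#' reference base class, replication timing and coverage with per-tumour
#' load offsets.  Driver regions (elevated rate and/or positional
#' hotspotting) and mutation-linked expression effects are spiked via
#' `driver_spec`.
#'
#' @param seed integer; single global seed, all stage randomness is derived
#'   from it deterministically.
#' @param n_tumors number of tumours.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param n_genes number of genes.
#' @param n_cres number of CRE fragments (non-overlapping tiles).
#' @param fragment_size CRE fragment size in bp.
#' @param interaction_score_dist length-2 numeric `(mean, sd)` of the
#'   interaction confidence score; the default straddles the 5.0 threshold.
#' @param background_coefs named list of the true logistic coefficients:
#'   `intercept`, `ref_gc` (G/C vs A/T), `reptime`, `coverage`, and
#'   `tumor_sd` (SD of per-tumour logit offsets).
#' @param driver_spec tibble with columns `region_id`, `multiplier` (rate
#'   multiplier >= 1), `concentration` (fraction of the region's mutations
#'   moved to one shared base, in `[0, 1]`), and optionally
#'   `expression_fold` (target-gene fold change in mutated samples).
#'   Default: no drivers.
#' @param expression_spec list: `mean_log`, `sd_log` (log-normal baseline
#'   means), `dispersion` (common NB dispersion), `lib_sd` (log-normal SD of
#'   library factors).
#' @param cnv_spec list: `focal_rate` (Poisson mean focal events/sample),
#'   `size_meanlog`, `size_sdlog`, `hd_fraction`, `translocation_fraction`,
#'   and optionally `effect_region`, `effect_gene`, `effect_fold`,
#'   `effect_n` for a spiked CRE-amplification expression effect.
#' @param signature_mix named numeric vector of signature weights (sums to
#'   1) over the columns of `signature_catalog`.
#' @param signature_catalog 96 x K probability matrix; defaults to
#'   [synthetic_signature_catalog()].
#' @param qc_fail_rate total fraction of emitted SNVs given a failing QC
#'   field (spread evenly over the four filter rules).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(seed = 1L,
                          n_tumors = 50L,
                          chrom_lengths = c(chr1 = 6e6, chr2 = 4e6),
                          n_genes = 300L,
                          n_cres = 3000L,
                          fragment_size = 2000L,
                          interaction_score_dist = c(mean = 6, sd = 2),
                          background_coefs = list(intercept = -11, ref_gc = 0.3,
                                                  reptime = 0.5, coverage = 0.05,
                                                  tumor_sd = 0.3),
                          driver_spec = NULL,
                          expression_spec = list(mean_log = log(200), sd_log = 0.8,
                                                 dispersion = 0.15, lib_sd = 0.25),
                          cnv_spec = list(focal_rate = 3, size_meanlog = log(8e5),
                                          size_sdlog = 0.6, hd_fraction = 0.4,
                                          translocation_fraction = 0.35),
                          signature_mix = c(S1 = 0.6, S2 = 0.4),
                          signature_catalog = synthetic_signature_catalog(),
                          qc_fail_rate = 0.1) {
  if (n_tumors < 1L) abort("degenerate config: n_tumors must be >= 1")
  if (n_genes < 1L) abort("degenerate config: n_genes must be >= 1")
  if (any(chrom_lengths <= 0)) abort("chromosome lengths must be positive")
  if (fragment_size >= min(chrom_lengths)) {
    abort("fragment_size must be smaller than the shortest chromosome")
  }
  if (abs(sum(signature_mix) - 1) > 1e-8) abort("signature_mix weights must sum to 1")
  if (!all(names(signature_mix) %in% colnames(signature_catalog))) {
    abort("signature_mix names must match catalog columns")
  }
  if (is.null(driver_spec)) {
    driver_spec <- tibble(region_id = character(), multiplier = numeric(),
                          concentration = numeric(), expression_fold = numeric())
  }
  driver_spec <- as_tibble(driver_spec)
  if (!"expression_fold" %in% names(driver_spec)) driver_spec$expression_fold <- 1
  if (nrow(driver_spec) > 0) {
    if (any(driver_spec$multiplier < 1)) abort("driver rate multipliers must be >= 1")
    if (any(driver_spec$concentration < 0 | driver_spec$concentration > 1)) {
      abort("hotspot concentration must lie in [0, 1]")
    }
  }
  structure(list(
    seed = as.integer(seed), n_tumors = as.integer(n_tumors),
    chrom_lengths = chrom_lengths, n_genes = as.integer(n_genes),
    n_cres = as.integer(n_cres), fragment_size = as.integer(fragment_size),
    interaction_score_dist = interaction_score_dist,
    background_coefs = background_coefs, driver_spec = driver_spec,
    expression_spec = expression_spec, cnv_spec = cnv_spec,
    signature_mix = signature_mix, signature_catalog = signature_catalog,
    qc_fail_rate = qc_fail_rate
  ), class = "cohort_config")
}

WINDOW_BP <- 1000L  # covariate tracks are piecewise-constant over 1-kb windows

## ---------------------------------------------------------------------------

make_genome <- function(config) {
  with_stage_seed(config$seed, "genome", {
    seqs <- lapply(config$chrom_lengths, function(len) {
      paste(sample(BASES, len, replace = TRUE), collapse = "")
    })
    Biostrings::DNAStringSet(unlist(seqs))
  })
}

make_genes <- function(config) {
  with_stage_seed(config$seed, "genes", {
    n <- config$n_genes
    probs <- config$chrom_lengths / sum(config$chrom_lengths)
    chrom <- sample(names(config$chrom_lengths), n, replace = TRUE, prob = probs)
    margin <- 25000L
    tss0 <- vapply(chrom, function(ch) {
      as.integer(sample.int(config$chrom_lengths[[ch]] - 2L * margin, 1L)) + margin
    }, integer(1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    body_len <- as.integer(round(rlnorm(n, log(8000), 0.5)))
    tibble(
      gene = sprintf("g%03d", seq_len(n)), chrom = chrom, tss0 = tss0,
      strand = strand, body_len = body_len,
      base_mean = rlnorm(n, config$expression_spec$mean_log,
                         config$expression_spec$sd_log)
    )
  })
}

## ORF/UTR annotation for each gene body, strand-aware: 200-bp 5'UTR at the
## TSS, ORF, 500-bp 3'UTR.
make_annotation <- function(genes, chrom_lengths) {
  rows <- pmap(genes, function(gene, chrom, tss0, strand, body_len, ...) {
    len <- min(body_len, chrom_lengths[[chrom]] - tss0 - 1L)
    u5 <- 200L; u3 <- 500L
    if (len <= u5 + u3 + 100L) len <- u5 + u3 + 100L
    if (strand == "+") {
      s <- tss0
      tibble(chrom = chrom,
             start = c(s, s + u5, s + len - u3),
             end = c(s + u5, s + len - u3, s + len),
             class = c("UTR5", "ORF", "UTR3"))
    } else {
      e <- tss0 + 1L
      tibble(chrom = chrom,
             start = c(e - u5, e - len + u3, e - len),
             end = c(e, e - u5, e - len + u3),
             class = c("UTR5", "ORF", "UTR3"))
    }
  })
  list_rbind(rows) |>
    filter(.data$start >= 0) |>
    arrange(.data$chrom, .data$start)
}

make_cres <- function(config) {
  with_stage_seed(config$seed, "cres", {
    fs <- config$fragment_size
    tiles <- list_rbind(imap(as.list(config$chrom_lengths), function(len, ch) {
      n_tiles <- floor(len / fs)
      tibble(chrom = ch, start = as.integer((seq_len(n_tiles) - 1L) * fs))
    }))
    n <- min(config$n_cres, nrow(tiles))
    keep <- sort(sample.int(nrow(tiles), n))
    tiles[keep, ] |>
      mutate(end = .data$start + fs,
             fragment_id = sprintf("cre%05d", seq_len(n))) |>
      select("fragment_id", "chrom", "start", "end")
  })
}

make_interactions <- function(config, cres, genes) {
  with_stage_seed(config$seed, "interactions", {
    sc <- config$interaction_score_dist
    rows <- pmap(cres, function(fragment_id, chrom, start, end) {
      g <- genes[genes$chrom == chrom, ]
      d_edge <- pmin(abs(g$tss0 - start), abs(g$tss0 - (end - 1L)))
      inside <- g$tss0 >= start & g$tss0 < end
      d_edge[inside] <- 0L
      ## link the two nearest genes plus, occasionally, a remote one so the
      ## 1-Mb distance filter is exercised
      ord <- order(d_edge)
      pick <- head(ord, 2L)
      if (runif(1) < 0.05 && nrow(g) > 5L) pick <- c(pick, tail(ord, 1L))
      tibble(fragment_id = fragment_id, chrom = chrom, start = start, end = end,
             gene = g$gene[pick], distance = d_edge[pick])
    })
    out <- list_rbind(rows)
    out$score <- round(rnorm(nrow(out), sc[["mean"]], sc[["sd"]]), 3)
    out
  })
}

make_tracks <- function(config) {
  with_stage_seed(config$seed, "tracks", {
    win <- list_rbind(imap(as.list(config$chrom_lengths), function(len, ch) {
      starts <- seq(0L, len - 1L, by = WINDOW_BP)
      tibble(chrom = ch, start = as.integer(starts),
             end = as.integer(pmin(starts + WINDOW_BP, len)))
    }))
    n <- nrow(win)
    ## replication timing: slow sinusoid plus noise, standardised
    phase <- stats::ave(seq_len(n), win$chrom, FUN = seq_along)
    rt <- sin(phase / 400) + rnorm(n, 0, 0.4)
    rt <- as.numeric(scale(rt))
    cov <- pmax(rnorm(n, 8, 1.5), 0.5)
    list(reptime = mutate(win, value = round(rt, 4)),
         coverage = mutate(win, value = round(cov, 3)))
  })
}

make_mappability <- function(config) {
  with_stage_seed(config$seed, "mappability", {
    list_rbind(imap(as.list(config$chrom_lengths), function(len, ch) {
      n_holes <- max(1L, round(len / 2.5e5))
      hole_start <- sort(sample.int(len - 4000L, n_holes))
      hole_len <- as.integer(round(runif(n_holes, 300, 3000)))
      holes <- IRanges::reduce(IRanges::IRanges(hole_start + 1L,
                                                pmin(hole_start + hole_len, len)))
      well <- IRanges::setdiff(IRanges::IRanges(1L, len), holes)
      tibble(chrom = ch, start = IRanges::start(well) - 1L, end = IRanges::end(well))
    }))
  })
}

## Per-base rate segments: covariate windows split at driver-region
## boundaries, with A/T and G/C base counts taken from the genome so that
## per-(segment, class, tumour) mutation counts are exactly binomial under
## the configured logistic model.
build_rate_segments <- function(config, genome, tracks, driver_intervals) {
  segs <- list_rbind(imap(as.list(config$chrom_lengths), function(len, ch) {
    breaks <- seq(0L, len, by = WINDOW_BP)
    if (breaks[length(breaks)] != len) breaks <- c(breaks, len)
    di <- driver_intervals[driver_intervals$chrom == ch, ]
    breaks <- sort(unique(c(breaks, di$start, di$end)))
    breaks <- breaks[breaks >= 0 & breaks <= len]
    tibble(chrom = ch, start = breaks[-length(breaks)], end = breaks[-1])
  }))
  segs <- segs[segs$end > segs$start, ]
  ## covariates from the parent window
  win_of <- floor(segs$start / WINDOW_BP)
  key <- paste(segs$chrom, win_of)
  rt <- tracks$reptime; cv <- tracks$coverage
  rt_key <- paste(rt$chrom, floor(rt$start / WINDOW_BP))
  segs$reptime <- rt$value[match(key, rt_key)]
  segs$coverage <- cv$value[match(key, rt_key)]
  ## driver multiplier
  segs$multiplier <- 1
  segs$region_id <- NA_character_
  if (nrow(driver_intervals) > 0) {
    for (i in seq_len(nrow(driver_intervals))) {
      d <- driver_intervals[i, ]
      hit <- segs$chrom == d$chrom & segs$start >= d$start & segs$end <= d$end
      segs$multiplier[hit] <- d$multiplier
      segs$region_id[hit] <- d$region_id
    }
  }
  ## base-class counts
  counts <- matrix(0L, nrow(segs), 2L, dimnames = list(NULL, c("AT", "GC")))
  for (ch in names(config$chrom_lengths)) {
    idx <- which(segs$chrom == ch)
    v <- Biostrings::Views(genome[[ch]],
                           IRanges::IRanges(segs$start[idx] + 1L, segs$end[idx]))
    counts[idx, ] <- Biostrings::letterFrequency(v, c("AT", "GC"))
  }
  segs$n_at <- counts[, "AT"]
  segs$n_gc <- counts[, "GC"]
  segs
}

## draw alt allele for a mutation given its reference context, from the
## configured signature mixture restricted to the compatible channels
draw_alts <- function(ref, five, three, mix96) {
  vapply(seq_along(ref), function(i) {
    alts <- setdiff(BASES, ref[i])
    ch <- sbs_channel_of(rep(ref[i], 3L), alts, rep(five[i], 3L), rep(three[i], 3L))
    w <- mix96[ch]
    w[is.na(w)] <- 0
    if (sum(w) <= 0) w <- rep(1, 3)
    sample(alts, 1L, prob = w)
  }, "")
}

simulate_snvs <- function(config, genome, segs, tumor_offsets, mix96) {
  bc <- config$background_coefs
  tumors <- names(tumor_offsets)
  long <- tibble(
    seg = rep(seq_len(nrow(segs)), 2L),
    is_gc = rep(c(0L, 1L), each = nrow(segs)),
    n = c(segs$n_at, segs$n_gc)
  ) |> filter(.data$n > 0)
  eta0 <- bc$intercept + bc$ref_gc * long$is_gc +
    bc$reptime * segs$reptime[long$seg] + bc$coverage * segs$coverage[long$seg]
  mult <- segs$multiplier[long$seg]

  hits <- with_stage_seed(config$seed, "snv_counts", {
    out <- vector("list", length(tumors))
    for (t in seq_along(tumors)) {
      p <- pmin(plogis(eta0 + tumor_offsets[t]) * mult, 0.45)
      k <- rbinom(nrow(long), long$n, p)
      nz <- which(k > 0L)
      if (length(nz)) {
        out[[t]] <- tibble(tumor_id = tumors[t], row = nz, count = k[nz])
      }
    }
    list_rbind(out[!vapply(out, is.null, TRUE)])
  })
  if (is.null(hits) || nrow(hits) == 0L) {
    return(tibble(tumor_id = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character()))
  }

  ## place mutations on concrete class-compatible bases, per segment x class
  with_stage_seed(config$seed, "snv_positions", {
    chrom_str <- lapply(as.list(genome), as.character)
    hit_seg <- long$seg[hits$row]
    hit_gc <- long$is_gc[hits$row]
    pools <- new.env(parent = emptyenv())
    pos_list <- vector("list", nrow(hits))
    k_out <- integer(nrow(hits))
    for (i in seq_len(nrow(hits))) {
      key <- as.character(hits$row[i])
      pool <- pools[[key]]
      if (is.null(pool)) {
        sg_s <- segs$start[hit_seg[i]]; sg_e <- segs$end[hit_seg[i]]
        ch <- segs$chrom[hit_seg[i]]
        b <- strsplit(substr(chrom_str[[ch]], sg_s + 1L, sg_e), "")[[1]]
        want <- if (hit_gc[i] == 1L) c("G", "C") else c("A", "T")
        pool <- sg_s + which(b %in% want) - 1L  # 0-based genome positions
        pools[[key]] <- pool
      }
      k <- min(hits$count[i], length(pool))
      pos_list[[i]] <- sample(pool, k)
      k_out[i] <- k
    }
    snv <- tibble(
      tumor_id = rep(hits$tumor_id, k_out),
      chrom = rep(segs$chrom[hit_seg], k_out),
      pos0 = unlist(pos_list)
    )
    ## reference context and signature-driven alternate allele
    snv <- annotate_context(snv, genome)
    snv$alt <- draw_alts(snv$ref, snv$five, snv$three, mix96)
    snv |> select("tumor_id", "chrom", "pos0", "ref", "alt")
  })
}

## look up ref base and immediate flanks (0-based positions)
annotate_context <- function(snv, genome) {
  snv$ref <- NA_character_; snv$five <- NA_character_; snv$three <- NA_character_
  for (ch in unique(snv$chrom)) {
    idx <- which(snv$chrom == ch)
    len <- length(genome[[ch]])
    p <- snv$pos0[idx]
    snv$ref[idx] <- as.character(Biostrings::Views(genome[[ch]],
                                                   IRanges::IRanges(p + 1L, p + 1L)))
    ok <- which(p >= 1L & p + 2L <= len)  # both flanks inside the contig
    if (length(ok)) {
      ctx3 <- as.character(Biostrings::Views(genome[[ch]],
                                             IRanges::IRanges(p[ok], p[ok] + 2L)))
      snv$five[idx[ok]] <- substr(ctx3, 1L, 1L)
      snv$three[idx[ok]] <- substr(ctx3, 3L, 3L)
    }
  }
  snv
}

#' Concentrate a fraction of a region's mutations onto one shared base
#'
#' Emulates a mutational hotspot: `round(concentration * m)` of the `m`
#' supplied positions are moved to a single position drawn uniformly from
#' the region; the rest are left where they are.
#'
#' @param positions integer vector of 0-based mutation positions.
#' @param region a list or one-row data frame with `start`, `end` (0-based
#'   half-open).
#' @param concentration fraction in `[0, 1]`.
#' @param rng_seed integer seed.
#' @return integer vector of adjusted positions, same length.
#' @export
spike_hotspot <- function(positions, region, concentration, rng_seed = 1L) {
  stopifnot(concentration >= 0, concentration <= 1)
  if (region$end <= region$start) abort("empty region")
  m <- length(positions)
  if (m == 0L || concentration == 0) return(positions)
  withr::with_seed(as.integer(rng_seed), {
    k <- round(concentration * m)
    if (k > 0L) {
      hotspot <- region$start + sample.int(region$end - region$start, 1L) - 1L
      idx <- sample.int(m, k)
      positions[idx] <- hotspot
    }
    positions
  })
}

apply_hotspots <- function(config, snv, driver_intervals, genome, mix96) {
  spec <- config$driver_spec
  spec <- spec[spec$concentration > 0, , drop = FALSE]
  if (nrow(spec) == 0L || nrow(snv) == 0L) return(snv)
  for (i in seq_len(nrow(spec))) {
    d <- driver_intervals[driver_intervals$region_id == spec$region_id[i], ]
    hit <- which(snv$chrom == d$chrom & snv$pos0 >= d$start & snv$pos0 < d$end)
    if (length(hit) == 0L) next
    new_pos <- spike_hotspot(snv$pos0[hit], d, spec$concentration[i],
                             rng_seed = substream_seed(config$seed,
                                                       paste0("hotspot_", d$region_id)))
    moved <- which(new_pos != snv$pos0[hit])
    snv$pos0[hit] <- new_pos
    if (length(moved)) {
      idx <- hit[moved]
      upd <- annotate_context(snv[idx, ], genome)
      snv$ref[idx] <- upd$ref
      snv$alt[idx] <- with_stage_seed(config$seed, paste0("hotspot_alt_", d$region_id),
                                      draw_alts(upd$ref, upd$five, upd$three, mix96))
    }
  }
  snv
}

add_qc_fields <- function(config, snv) {
  with_stage_seed(config$seed, "qc_fields", {
    n <- nrow(snv)
    r <- config$qc_fail_rate / 4
    fail <- sample(c("none", "strand", "bq", "mq", "align"), n, replace = TRUE,
                   prob = c(1 - config$qc_fail_rate, r, r, r, r))
    depth <- pmax(rpois(n, 6), 2L)
    snv$alt_fwd <- rbinom(n, depth, 0.5) + 1L
    snv$alt_rev <- depth - snv$alt_fwd + 2L
    snv$alt_rev[snv$alt_rev < 1L] <- 1L
    strand_side <- runif(n) < 0.5
    snv$alt_fwd[fail == "strand" & strand_side] <- 0L
    snv$alt_rev[fail == "strand" & !strand_side] <- 0L
    snv$mean_bq <- round(pmax(rnorm(n, 31, 1.5), 27.2), 2)
    snv$mean_bq[fail == "bq"] <- round(runif(sum(fail == "bq"), 20, 26), 2)
    snv$mean_mq <- round(pmin(pmax(rnorm(n, 58, 2), 50), 60), 1)
    snv$mean_mq[fail == "mq"] <- round(runif(sum(fail == "mq"), 30, 49.9), 1)
    snv$alignability <- 1
    snv$alignability[fail == "align"] <- round(runif(sum(fail == "align"), 0.3, 0.99), 2)
    snv
  })
}

simulate_cnv <- function(config, genes, cres, samples) {
  cs <- config$cnv_spec
  chroms <- names(config$chrom_lengths)
  with_stage_seed(config$seed, "cnv", {
    rows <- vector("list", length(samples$sample_id))
    hd <- runif(nrow(samples)) < cs$hd_fraction
    for (i in seq_along(samples$sample_id)) {
      sid <- samples$sample_id[i]
      segs <- list()
      if (hd[i]) {
        for (ch in chroms) {
          len <- config$chrom_lengths[[ch]]
          frac <- runif(1, 0.92, 0.995)
          s <- as.integer(round(runif(1, 0, len * (1 - frac))))
          segs[[length(segs) + 1L]] <- tibble(
            sample_id = sid, chrom = ch, start = s,
            end = as.integer(s + round(len * frac)),
            log2_ratio = round(runif(1, 0.2, 0.45), 4))
        }
      } else if (runif(1) < 0.15) {
        ch <- sample(chroms, 1L)
        len <- config$chrom_lengths[[ch]]
        segs[[length(segs) + 1L]] <- tibble(
          sample_id = sid, chrom = ch, start = 0L,
          end = as.integer(round(len * runif(1, 0.91, 1))),
          log2_ratio = round(runif(1, 0.2, 0.4), 4))
      }
      nf <- rpois(1, cs$focal_rate)
      if (nf > 0) {
        ch <- sample(chroms, nf, replace = TRUE,
                     prob = config$chrom_lengths / sum(config$chrom_lengths))
        size <- as.integer(pmin(pmax(round(rlnorm(nf, cs$size_meanlog, cs$size_sdlog)),
                                     5e4), 5e6))
        st <- vapply(seq_len(nf), function(j) {
          as.integer(sample.int(max(config$chrom_lengths[[ch[j]]] - size[j], 1L), 1L))
        }, integer(1))
        segs[[length(segs) + 1L]] <- tibble(
          sample_id = sid, chrom = ch, start = st, end = st + size,
          log2_ratio = round(sample(c(-1, 1), nf, TRUE) * runif(nf, 0.17, 0.6), 4))
      }
      rows[[i]] <- if (length(segs)) list_rbind(segs) else NULL
    }
    cnv <- list_rbind(rows[!vapply(rows, is.null, TRUE)])
    ## optional spiked CRE-amplification effect: focal amps placed exactly on
    ## one CRE (not reaching its target gene) in a fixed number of samples
    effect <- NULL
    if (!is.null(cs$effect_region)) {
      cre <- cres[cres$fragment_id == cs$effect_region, ]
      if (nrow(cre) != 1L) abort("cnv effect_region not found among CRE fragments")
      n_eff <- min(cs$effect_n %||% 12L, nrow(samples))
      eff_samples <- sample(samples$sample_id, n_eff)
      pad <- 5000L
      cnv <- bind_rows(cnv, tibble(
        sample_id = eff_samples, chrom = cre$chrom,
        start = pmax(cre$start - pad, 0L), end = cre$end + pad,
        log2_ratio = round(runif(n_eff, 0.25, 0.5), 4)))
      effect <- list(region_id = cs$effect_region, gene = cs$effect_gene,
                     fold = cs$effect_fold, samples = eff_samples)
    }
    list(cnv = arrange(cnv, .data$sample_id, .data$chrom, .data$start),
         hd = setNames(hd, samples$sample_id), effect = effect)
  })
}

simulate_expression <- function(config, genes, samples, gene_folds) {
  es <- config$expression_spec
  with_stage_seed(config$seed, "expression", {
    n_s <- nrow(samples)
    lib <- exp(rnorm(n_s, 0, es$lib_sd))
    lib <- lib / geom_mean(lib)
    mu <- outer(genes$base_mean, lib)
    dimnames(mu) <- list(genes$gene, samples$sample_id)
    for (g in names(gene_folds)) {
      eff <- gene_folds[[g]]
      mu[g, eff$samples] <- mu[g, eff$samples] * eff$fold
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / es$dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    list(counts = counts, lib = setNames(lib, samples$sample_id))
  })
}

## ---------------------------------------------------------------------------

#' Generate a complete synthetic cohort with known ground truth
#'
#' Emits every table the analysis pipeline consumes, driven by a single
#' seed.  If `dir` is given, all tables are also written to disk in the
#' package's plain-text formats (see [write_cohort()]).
#'
#' @param config a [cohort_config()].
#' @param dir optional output directory.
#' @return a `cohort` object: a list with elements `genome`
#'   (`DNAStringSet`), `tss`, `interactions`, `cres`, `annotation`,
#'   `tracks` (list of `reptime`, `coverage`), `mappability`, `snvs`
#'   (MAF-like, 1-based positions), `cnv`, `counts` (gene x sample integer
#'   matrix), `samples`, and `truth` (driver regions, true coefficients,
#'   expression effects, karyotypes, exposures).
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  genome <- make_genome(config)
  genes <- make_genes(config)
  annotation <- make_annotation(genes, config$chrom_lengths)
  cres <- make_cres(config)
  interactions <- make_interactions(config, cres, genes)
  tracks <- make_tracks(config)
  mappability <- make_mappability(config)

  tss <- tibble(gene = genes$gene, chrom = genes$chrom,
                tss = genes$tss0 + 1L, strand = genes$strand)

  ## resolve driver region ids to genomic intervals
  spec <- config$driver_spec
  driver_intervals <- tibble(region_id = character(), chrom = character(),
                             start = integer(), end = integer(),
                             multiplier = numeric(), gene = character())
  if (nrow(spec) > 0) {
    promoters <- define_promoters(tss, chrom_lengths = config$chrom_lengths)
    for (i in seq_len(nrow(spec))) {
      id <- spec$region_id[i]
      if (id %in% cres$fragment_id) {
        r <- cres[cres$fragment_id == id, ]
        g <- interactions$gene[interactions$fragment_id == id][1]
      } else if (id %in% promoters$region_id) {
        r <- promoters[promoters$region_id == id, ]
        g <- r$gene_id
      } else {
        abort(sprintf("driver region id '%s' not found among CREs or promoters", id))
      }
      driver_intervals <- bind_rows(driver_intervals, tibble(
        region_id = id, chrom = r$chrom, start = r$start, end = r$end,
        multiplier = spec$multiplier[i], gene = g))
    }
  }

  tumor_ids <- sprintf("T%03d", seq_len(config$n_tumors))
  tumor_offsets <- with_stage_seed(config$seed, "tumor_offsets",
    setNames(rnorm(config$n_tumors, 0, config$background_coefs$tumor_sd), tumor_ids))

  mix96 <- drop(config$signature_catalog[, names(config$signature_mix), drop = FALSE] %*%
                  config$signature_mix)
  segs <- build_rate_segments(config, genome, tracks, driver_intervals)
  snv <- simulate_snvs(config, genome, segs, tumor_offsets, mix96)
  snv <- apply_hotspots(config, snv, driver_intervals, genome, mix96)
  snv <- add_qc_fields(config, snv)
  snvs <- snv |>
    mutate(pos = .data$pos0 + 1L) |>
    select("tumor_id", "chrom", "pos", "ref", "alt", "alt_fwd", "alt_rev",
           "mean_bq", "mean_mq", "alignability") |>
    arrange(.data$chrom, .data$pos, .data$tumor_id)

  ## sample metadata: translocation labels
  samples <- with_stage_seed(config$seed, "metadata", {
    labels <- c("t(4;14)", "t(11;14)", "t(14;16)", "t(14;20)", "MYC")
    has_tr <- runif(config$n_tumors) < config$cnv_spec$translocation_fraction
    tr <- ifelse(has_tr, sample(labels, config$n_tumors, replace = TRUE,
                                prob = c(0.25, 0.35, 0.15, 0.05, 0.2)), "")
    tibble(sample_id = tumor_ids, translocations = tr)
  })

  cnv_out <- simulate_cnv(config, genes, cres, samples)

  ## mutation-linked expression effects from the driver spec
  gene_folds <- list()
  if (nrow(spec) > 0) {
    for (i in seq_len(nrow(spec))) {
      if (spec$expression_fold[i] == 1) next
      d <- driver_intervals[driver_intervals$region_id == spec$region_id[i], ]
      mut <- unique(snvs$tumor_id[snvs$chrom == d$chrom &
                                    snvs$pos - 1L >= d$start & snvs$pos - 1L < d$end])
      gene_folds[[d$gene]] <- list(fold = spec$expression_fold[i], samples = mut)
    }
  }
  if (!is.null(cnv_out$effect)) {
    eff <- cnv_out$effect
    gene_folds[[eff$gene]] <- list(fold = eff$fold, samples = eff$samples)
  }
  expr <- simulate_expression(config, genes, samples, gene_folds)

  truth <- list(
    driver_regions = spec$region_id[spec$multiplier > 1 | spec$concentration > 0],
    driver_intervals = driver_intervals,
    background_coefs = config$background_coefs,
    tumor_offsets = tumor_offsets,
    expression_effects = lapply(gene_folds, `[[`, "fold"),
    effect_samples = lapply(gene_folds, `[[`, "samples"),
    sample_karyotypes = tibble(sample_id = samples$sample_id,
                               hd = unname(cnv_out$hd[samples$sample_id]),
                               translocations = samples$translocations),
    true_exposures = matrix(rep(config$signature_mix, config$n_tumors),
                            nrow = config$n_tumors, byrow = TRUE,
                            dimnames = list(tumor_ids, names(config$signature_mix))),
    cnv_effect = cnv_out$effect,
    library_factors = expr$lib
  )

  cohort <- structure(list(
    config = config, genome = genome, tss = tss, genes = genes,
    annotation = annotation, cres = cres, interactions = interactions,
    tracks = tracks, mappability = mappability, snvs = snvs,
    cnv = cnv_out$cnv, counts = expr$counts, samples = samples, truth = truth
  ), class = "cohort")

  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write a synthetic cohort to disk as plain-text tables
#'
#' Coordinates are 0-based half-open in every file except the MAF-like SNV
#' table and the TSS table, which are 1-based (MAF convention).
#'
#' @param cohort a `cohort` object from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", dir))
  }
  if (file.access(dir, 2L) != 0L) abort(sprintf("output directory '%s' is not writable", dir))
  w <- function(x, f) readr::write_tsv(x, file.path(dir, f), progress = FALSE)
  w(cohort$tss, "tss.tsv")
  w(cohort$interactions, "interactions.tsv")
  w(cohort$tracks$reptime, "reptime.track.tsv")
  w(cohort$tracks$coverage, "coverage.track.tsv")
  readr::write_tsv(cohort$mappability, file.path(dir, "mappability.bed"),
                   col_names = FALSE, progress = FALSE)
  write_maf(cohort$snvs, file.path(dir, "snvs.maf.tsv"))
  w(cohort$cnv, "cnv.seg")
  counts_tbl <- as_tibble(cohort$counts, rownames = "gene")
  w(counts_tbl, "counts.tsv")
  w(cohort$samples, "samples.tsv")
  w(mutate(cohort$annotation, class = .data$class), "annotation.tsv")
  Biostrings::writeXStringSet(cohort$genome, file.path(dir, "genome.fa"))
  truth <- cohort$truth
  truth$driver_intervals <- as.list(truth$driver_intervals)
  truth$true_exposures <- as.data.frame(truth$true_exposures)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$config$n_tumors, "tumours,",
      sum(x$config$chrom_lengths) / 1e6, "Mb genome\n")
  cat("  SNVs:", nrow(x$snvs), " CRE fragments:", nrow(x$cres),
      " genes:", nrow(x$genes), "\n")
  cat("  spiked driver regions:", length(x$truth$driver_regions), "\n")
  invisible(x)
}
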