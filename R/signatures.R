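## 96-channel spectra, signature refitting, AID-motif classification and
## signature-subgroup association tests.

#' Trinucleotide mutation spectrum
#'
#' Counts each substitution into its pyrimidine-centred 96-channel bin
#' (purine-reference mutations are reverse-complemented).  SNVs lacking a
#' full trinucleotide context (contig edges) are skipped.
#'
#' @param snvs tibble with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param genome `DNAStringSet` reference.
#' @return a `spectrum96` named integer vector over the channels of
#'   [sbs_channels()]; the total equals the number of contextable SNVs.
#' @export
trinucleotide_spectrum <- function(snvs, genome) {
  snv <- tibble(chrom = snvs$chrom, pos0 = snvs$pos - 1L, alt = snvs$alt)
  snv <- annotate_context(snv, genome)
  skipped <- sum(is.na(snv$five) | is.na(snv$three))
  if (skipped > 0) {
    rlang::inform(sprintf("skipping %d SNV(s) without full context", skipped))
  }
  ch <- sbs_channel_of(snv$ref, snv$alt, snv$five, snv$three)
  ch <- ch[!is.na(ch)]
  channels <- sbs_channels()$channel
  out <- table(factor(ch, levels = channels))
  structure(setNames(as.integer(out), channels), class = "spectrum96")
}

#' Refit signature exposures against a catalog
#'
#' Non-negative least-squares fit of the normalised spectrum onto the
#' catalog columns; weights below `exposure_floor` are iteratively zeroed
#' and the remaining signatures refitted until the active set is stable.
#'
#' @param spectrum a `spectrum96` or a 96-long non-negative vector
#'   (counts or fractions).
#' @param catalog 96 x K probability matrix (columns sum to 1).
#' @param exposure_floor minimum retained weight (default 0.06).
#' @return an `exposure_profile` list: `weights` (named, length K, zeros
#'   for dropped signatures), `residual` (L2 norm of the unexplained
#'   fraction) and `n_mutations`.
#' @export
refit_exposures <- function(spectrum, catalog, exposure_floor = 0.06) {
  x <- as.numeric(spectrum)
  if (length(x) != nrow(catalog)) abort("spectrum/catalog dimension mismatch")
  total <- sum(x)
  if (total <= 0) abort("all-zero spectrum cannot be refitted")
  v <- x / total
  active <- colnames(catalog)
  repeat {
    fit <- pracma::lsqnonneg(catalog[, active, drop = FALSE], v)
    w <- setNames(fit$x, active)
    keep <- names(w)[w >= exposure_floor]
    if (length(keep) == length(active) || length(keep) == 0L) break
    active <- keep
  }
  weights <- setNames(numeric(ncol(catalog)), colnames(catalog))
  w[w < exposure_floor] <- 0
  weights[names(w)] <- w
  fitted <- drop(catalog %*% weights)
  structure(list(weights = weights,
                 residual = sqrt(sum((v - fitted)^2)),
                 n_mutations = total),
            class = "exposure_profile")
}

#' Per-sample exposure refitting
#'
#' @param snvs multi-sample SNV tibble (`tumor_id` column).
#' @param genome reference `DNAStringSet`.
#' @param catalog signature catalog.
#' @param exposure_floor see [refit_exposures()].
#' @return tibble with one row per sample: `sample_id`, one column per
#'   signature weight, `residual`, `n_mutations`.  Samples with no
#'   contextable mutations are skipped.
#' @export
fit_sample_exposures <- function(snvs, genome, catalog, exposure_floor = 0.06) {
  ids <- sort(unique(snvs$tumor_id))
  rows <- map(ids, function(sid) {
    sp <- suppressMessages(trinucleotide_spectrum(snvs[snvs$tumor_id == sid, ], genome))
    if (sum(sp) == 0) return(NULL)
    ep <- refit_exposures(sp, catalog, exposure_floor)
    bind_cols(tibble(sample_id = sid), as_tibble_row(ep$weights),
              tibble(residual = ep$residual, n_mutations = ep$n_mutations))
  })
  list_rbind(rows[!vapply(rows, is.null, TRUE)])
}

#' Classify mutations by AID motif
#'
#' Canonical AID: `C>T/G` at the C of a `WRCY` motif (W = A/T, R = purine,
#' Y = pyrimidine), strand-symmetrically (i.e. `G>A/C` at the G of the
#' reverse complement `RGYW`).  Non-canonical AID: `A>C/G` with the
#' preceding base W (or `T>G/C` followed by W on the reverse complement).
#' Canonical takes precedence; mutations without sufficient context are
#' labelled `other`.
#'
#' @param snvs tibble with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param genome reference `DNAStringSet`.
#' @return character vector of labels `canonical_AID`, `noncanonical_AID`,
#'   `other`, one per input row.
#' @export
classify_aid <- function(snvs, genome) {
  n <- nrow(snvs)
  ## 7-base window centred on the mutated base (offset 4)
  ctx <- rep(NA_character_, n)
  for (ch in unique(snvs$chrom)) {
    idx <- which(snvs$chrom == ch)
    len <- length(genome[[ch]])
    p <- snvs$pos[idx]  # 1-based
    ok <- p - 3L >= 1L & p + 3L <= len
    if (any(ok)) {
      ctx[idx[ok]] <- as.character(Biostrings::Views(
        genome[[ch]], IRanges::IRanges(p[ok] - 3L, p[ok] + 3L)))
    }
  }
  classify_aid_context(snvs$ref, snvs$alt, ctx)
}

#' Classify one mutation given its 7-base reference window
#'
#' Workhorse behind [classify_aid()]; exposed so motif logic can be tested
#' against enumerated contexts.  The window holds the reference sequence
#' with the mutated base at position 4; `NA` windows yield `other`.
#'
#' @param ref,alt single bases.
#' @param window 7-character reference windows.
#' @return labels as in [classify_aid()].
#' @export
classify_aid_context <- function(ref, alt, window) {
  n <- length(ref)
  lab <- rep("other", n)
  W <- c("A", "T"); R <- c("A", "G"); Y <- c("C", "T")
  at <- function(s, i) substr(s, i, i)
  ok <- !is.na(window) & nchar(window) == 7L
  ## canonical, forward: W R C Y with C mutated (window positions 2,3,4,5)
  can_f <- ok & ref == "C" & alt %in% c("T", "G") &
    at(window, 2) %in% W & at(window, 3) %in% R & at(window, 5) %in% Y
  ## canonical, reverse strand: mutated G, revcomp gives C>T/G in WRCY, i.e.
  ## window positions (6,5,4,3) complemented: comp(6) in W, comp(5) in R,
  ## comp(3) in Y
  can_r <- ok & ref == "G" & alt %in% c("A", "C") &
    COMP[at(window, 6)] %in% W & COMP[at(window, 5)] %in% R &
    COMP[at(window, 3)] %in% Y
  ## non-canonical, forward: W A with A mutated to C/G (preceding base W)
  non_f <- ok & ref == "A" & alt %in% c("C", "G") & at(window, 3) %in% W
  ## non-canonical, reverse: T>G/C with following base complementing to W
  non_r <- ok & ref == "T" & alt %in% c("G", "C") & COMP[at(window, 5)] %in% W
  lab[non_f | non_r] <- "noncanonical_AID"
  lab[can_f | can_r] <- "canonical_AID"  # canonical precedence
  lab
}

#' Association between signature presence and a subgroup
#'
#' One-sided (greater) Fisher's exact test of signature positivity
#' (post-threshold weight > 0) inside versus outside each subgroup.
#'
#' @param presence named logical vector of signature positivity per sample.
#' @param subgroups named list: subgroup label -> character vector of
#'   member sample ids.
#' @return tibble per subgroup: `subgroup`, `n_positive_in`, `n_in`,
#'   `n_positive_out`, `n_out`, `odds_ratio`, `p`.  Empty subgroups are
#'   skipped.
#' @export
signature_subgroup_association <- function(presence, subgroups) {
  samples <- names(presence)
  rows <- imap(subgroups, function(members, label) {
    members <- intersect(members, samples)
    if (length(members) == 0L) return(NULL)
    inn <- samples %in% members
    ## rows = in/out of subgroup, columns = signature positive/negative
    tab <- matrix(c(sum(presence & inn), sum(!presence & inn),
                    sum(presence & !inn), sum(!presence & !inn)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(subgroup = c("in", "out"),
                                  signature = c("pos", "neg")))
    ft <- fisher_exact(tab, sided = "greater")
    tibble(subgroup = label, n_positive_in = sum(presence & inn),
           n_in = sum(inn), n_positive_out = sum(presence & !inn),
           n_out = sum(!inn), odds_ratio = ft$odds_ratio, p = ft$p)
  })
  list_rbind(rows[!vapply(rows, is.null, TRUE)])
}
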