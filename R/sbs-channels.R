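## 96-channel single-base-substitution context machinery, shared by the
## synthetic generator and the signature-refitting module.

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_chr <- function(x) {
  vapply(strsplit(x, ""), function(b) paste(rev(unname(COMP[b])), collapse = ""), "")
}

#' The 96 pyrimidine-centred substitution channels
#'
#' Standard catalog ordering: six substitution types (C>A, C>G, C>T, T>A,
#' T>C, T>G), each expanded over the 16 flanking-base combinations, flanks
#' ordered A, C, G, T.  Channel names follow the `A[C>A]A` convention.
#'
#' @return a 96-row tibble with columns `channel`, `ref`, `alt`, `five`,
#'   `three`.
#' @export
sbs_channels <- function() {
  ref <- rep(c("C", "T"), each = 3)
  alt <- c("A", "G", "T", "A", "C", "G")
  out <- tibble(
    ref   = rep(ref, each = 16L),
    alt   = rep(alt, each = 16L),
    five  = rep(rep(BASES, each = 4L), times = 6L),
    three = rep(BASES, times = 24L)
  )
  out$channel <- paste0(out$five, "[", out$ref, ">", out$alt, "]", out$three)
  out[, c("channel", "ref", "alt", "five", "three")]
}

#' Collapse a substitution to its pyrimidine-centred channel
#'
#' Mutations with a purine reference base are reverse-complemented so every
#' substitution maps to one of the 96 channels.
#'
#' @param ref,alt single reference/alternate bases.
#' @param five,three the bases immediately 5' and 3' of the mutated base on
#'   the reference strand.
#' @return character vector of channel names; `NA` where the context
#'   contains non-ACGT characters.
#' @export
sbs_channel_of <- function(ref, alt, five, three) {
  ok <- ref %in% BASES & alt %in% BASES & five %in% BASES & three %in% BASES
  out <- rep(NA_character_, length(ref))
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; f <- five[ok]; t3 <- three[ok]
  pur <- r %in% c("A", "G")
  r2 <- ifelse(pur, COMP[r], r)
  a2 <- ifelse(pur, COMP[a], a)
  f2 <- ifelse(pur, COMP[t3], f)
  t2 <- ifelse(pur, COMP[f], t3)
  out[ok] <- paste0(f2, "[", r2, ">", a2, "]", t2)
  out
}

#' Build a synthetic 96-channel signature catalog
#'
#' Draws sparse random signature profiles (gamma weights, normalised to sum
#' to one per column).  The catalog is synthetic: it stands in for a
#' reference catalog in tests and simulated cohorts and carries no claim
#' about real mutational processes.
#'
#' @param n_signatures number of signature columns.
#' @param seed integer seed; the default fixes a reproducible catalog.
#' @return a 96 x K numeric matrix with channel rownames and signature
#'   colnames `S1..SK`; every column sums to 1.
#' @export
synthetic_signature_catalog <- function(n_signatures = 5, seed = 73L) {
  ch <- sbs_channels()$channel
  withr::with_seed(seed, {
    m <- matrix(stats::rgamma(96L * n_signatures, shape = 0.25, rate = 1),
                nrow = 96L, dimnames = list(ch, paste0("S", seq_len(n_signatures))))
    sweep(m, 2, colSums(m), "/")
  })
}
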