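## Shared fixtures, built once per test run.

## small reference cohort used by several suites (no spiked drivers)
test_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co)) {
      cfg <- cohort_config(seed = 42L, n_tumors = 20L,
                           chrom_lengths = c(chr1 = 1.5e6, chr2 = 1e6),
                           n_genes = 60L, n_cres = 400L)
      co <<- suppressMessages(generate_cohort(cfg))
    }
    co
  }
})

## tiny deterministic genome for sequence-level tests
toy_genome <- function(seqs) Biostrings::DNAStringSet(seqs)

## exhaustive Poisson-binomial tail by enumerating all 2^T outcomes
enumerate_poibin_tail <- function(q, x_obs) {
  T <- length(q)
  m <- as.matrix(expand.grid(rep(list(0:1), T)))
  lp <- m %*% log(q) + (1 - m) %*% log1p(-q)
  sum(exp(lp[rowSums(m) >= x_obs]))
}

## brute-force regex AID oracle on a 7-base reference window (mutated base
## at position 4); independent formulation of the motif logic
aid_oracle <- function(ref, alt, window) {
  can_f <- grepl("^[AT][AG]C[CT]$", substr(window, 2, 5)) &
    ref == "C" & alt %in% c("T", "G")
  can_r <- grepl("^[AG]G[CT][AT]$", substr(window, 3, 6)) &
    ref == "G" & alt %in% c("A", "C")
  non_f <- grepl("^[AT]A$", substr(window, 3, 4)) & ref == "A" & alt %in% c("C", "G")
  non_r <- grepl("^T[AT]$", substr(window, 4, 5)) & ref == "T" & alt %in% c("G", "C")
  out <- rep("other", length(ref))
  out[non_f | non_r] <- "noncanonical_AID"
  out[can_f | can_r] <- "canonical_AID"
  out
}
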