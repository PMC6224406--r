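---
title: "Finding non-coding driver mutations in regulatory regions: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding non-coding driver mutations in regulatory regions: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regdriver)
```

## The problem

Most somatic mutations in a tumour genome are passengers.  In coding
sequence, recurrence across patients is the classic evidence of positive
selection; in the non-coding genome the search space is so large that naive
recurrence scans are underpowered and confounded by regional variation in
the background mutation rate.  `regdriver` implements a focused strategy:
restrict the search to regulatory elements with a plausible target gene —
promoter windows around annotated TSSs, and fragments that physically
contact a promoter in capture Hi-C — and test each such region for more
mutated tumours, and more positionally coincident mutations, than a
covariate-aware background model predicts.  Regions that pass are then
linked to function by asking whether mutation (SNV or copy-number) of the
region shifts the expression of its target gene.

The package was built around a multiple-myeloma-style study design
(low-coverage tumour WGS, RNA-seq, copy-number segments and translocation
calls on the same patients, B-cell capture Hi-C for the CRE map), but every
stage is generic.

## Region definition

* **Promoters** span 400 bp upstream to 250 bp downstream of each TSS,
  651 bases counting the TSS itself; "upstream" follows gene orientation.
  Overlapping windows of one gene are merged.  The window width counts the
  TSS base — the convention is stated here because tests depend on it.
* **CREs** are restriction-fragment-like intervals retained when they have
  at least one promoter interaction with confidence score ≥ 5 and linear
  distance ≤ 1 Mb (both inclusive), and when ≥ 95% of their bases are well
  mapped.  Fragment–promoter distance is measured from the TSS to the
  nearest fragment edge; the anchor is a design choice (the nearest edge is
  the conservative reading of "linear distance").
* **Masking.**  CRE testable bases exclude open reading frames padded by
  5 bp (splice sites) and 5'/3' UTRs.  Promoter windows are kept whole, but
  mutations overlapping an (unpadded) ORF are discarded at test time — the
  padding is documented for CREs only, so it is not applied to promoters.

Internally all coordinates are 0-based half-open; the MAF-like SNV table
and the TSS table are 1-based at the I/O boundary, matching their format
conventions.

## The recurrence model

For one region and one tumour, the probability that base \(k\) is mutated
is modelled by logistic regression

\[
\operatorname{logit}(p_{k,t}) =
  \beta_0 + \beta_{\mathrm{GC}}\,[\text{ref is G/C}]
  + \beta_{\mathrm{RT}}\,\mathrm{RT}(k) + \beta_{\mathrm{cov}}\,\mathrm{cov}(k)
  + o_t ,
\]

with replication timing and coverage piecewise constant over 1-kb windows
and \(o_t\) a per-tumour load offset.  Promoters and CREs are fitted
separately.  Two implementation points matter:

* **Tumour identity enters as a fixed offset** computed from each tumour's
  observed mutation load (a two-pass scheme) rather than as ~50–800 free
  factor levels.  For rare events the logit link is effectively a log link,
  so a load offset is the natural encoding; coefficient-recovery
  simulations (below) confirm the slopes are unbiased under this scheme.
* **Aggregation.**  Because covariates are constant within a
  (window × base-class × tumour) cell, the Bernoulli observations collapse
  exactly to binomial counts; the fit is exact and fast.  A
  `negative_sampling_fraction` argument reproduces the classic
  case–control thinning of unmutated bases, with the intercept corrected by
  \(\log f\); it exists for compatibility with per-base workflows and is
  validated against the full fit.

The per-tumour, per-region success probability is
\(q_t = 1 - \prod_k (1 - p_{k,t})\): the complement of the no-mutation
product.  The number of mutated tumours \(X = \sum_t \mathrm{Bern}(q_t)\)
is Poisson-binomial; the background p-value is the upper tail
\(P(X \ge x_{\mathrm{obs}})\), computed by exact dynamic-programming
convolution up to 5,000 tumours and by a skewness-corrected normal
approximation beyond (the exact path is cross-checked against full
\(2^T\) enumeration in the tests).

**Clustering.**  With \(m \ge 3\) mutations in a region, the statistic
\(S = m - u\) (mutations minus distinct positions) is compared with
10,000 permutations drawing \(m\) positions uniformly, with replacement,
over the region's testable bases.  The permutation p-value uses add-one
smoothing, \((1 + \#\{S^\ast \ge S\})/(n_{\mathrm{perm}} + 1)\), so the
log-combination below never sees zero.  Replacement matters: the null must
allow coincidences.  Permutation nulls are shared between regions with
identical \((m, s)\) — the null distribution depends on nothing else — which
makes cohort-scale permutation affordable without changing the statistic.

**Combination and FDR.**  The two p-values are combined by Fisher's method
(\(\chi^2_4\) upper tail of \(-2(\ln p_b + \ln p_c)\)); regions without a
clustering test pass the background p-value through.  Promoter and CRE
batches are BH-adjusted separately, significance at \(Q < 0.05\).

### Calibration and the discreteness caveat

The Poisson-binomial tail is a discrete statistic.  `P(p < 0.05)` under the
null equals `P(X ≥ x*)` where `x*` is the smallest count whose tail drops
below 0.05 — by construction that is itself below 0.05, and at realistic
per-region expected counts (a few mutated tumours per region) it is far
below: the test is conservative, typically calling ~1–3% of null regions
at `p < 0.05` and essentially none at `Q < 0.05`.  The validation suite
measures and reports this fraction rather than asserting uniformity; the
practical consequence is that false-positive control is comfortably held,
at some cost in power for marginal signals.  The same conservatism is
inherited by the Fisher combination (the clustering p-value is mostly 1
under the null).

## Expression effects

For each recurrent region × target gene pair, expression of the gene is
compared between mutated and non-mutated tumours:

* samples with a CNV event (|log2 ratio| ≥ 0.1613, aneuploidy included)
  over the gene **or** the region are excluded from both groups;
* when several recurrent CREs contact one promoter, tumours mutated in more
  than one of them are excluded and the comparison group contains only
  tumours mutated in none;
* pairs with fewer than 3 mutated samples after exclusions are not tested.

The test is a conditional negative-binomial two-group test: counts are
scaled to a common effective library (TMM normalisation, via edgeR's
`calcNormFactors`), a common dispersion is estimated by conditional maximum
likelihood (zero, the Poisson limit, is allowed), and conditioning on the
pooled total the mutated-group sum has weights
\(\propto \binom{y + r_1 - 1}{y}\binom{s - y + r_2 - 1}{s - y}\) with
\(r_g = n_g/\phi\).  Two-sided p-values double the smaller tail, capped at
one; in the Poisson limit this is exactly the conditional binomial test,
which the suite verifies to 1e-10.  The reported fold change is the ratio
of normalised group means with a prior count of 0.5 on each side — display
stabilisation only, never part of the statistic.  Candidates need fold
change ≥ 1.2 or ≤ 0.8 and \(Q < 0.1\); promoter-SNV and CRE-SNV batches
are adjusted separately.

Copy-number effects at CREs reuse the same test: samples are grouped by
focal CNV status at the CRE (|log2| ≥ 0.1613 and < 3 Mb), samples whose
target gene itself carries an event (or one event spans both) are excluded,
and any group below 7 samples is skipped.

## Karyotype, signatures, cohort statistics

* A chromosome is amplified when ≥ 90% of its length is covered by the
  union of amplification events; hyperdiploidy = ≥ 2 amplified autosomes.
  The 90% rule is applied to base pairs (cytoband-based alternatives exist;
  base pairs are the unambiguous reading).
* 96-channel spectra use the standard pyrimidine-centred channels;
  exposures are refit by non-negative least squares with iterative zeroing
  of weights below 0.06 (the floor conventionally used for refitting
  tools), and signature "presence" means a post-threshold weight above
  zero.
* Canonical AID mutations are C>T/G at the C of a WRCY motif
  (strand-symmetric); non-canonical are A>C/G preceded by A/T.  Canonical
  takes precedence; the classifier is verified against an independent
  regular-expression oracle over every context.
* Enrichment tests are one-sided Fisher's exact tests (the sidedness the
  source analyses state for signature–subgroup associations, adopted
  uniformly and noted per test); burden comparisons are two-sided Wilcoxon
  rank-sum tests, exact below 26 per group without ties and
  normal-approximated with tie and continuity corrections otherwise; term
  enrichment is an upper-tail hypergeometric at the level of
  CRE–promoter interactions, with all retained interactions as the
  background universe, so promoters contacting many CREs do not inflate
  term counts.

## The synthetic cohort generator

`generate_cohort()` emits every input the pipeline consumes — genome, TSS
table, ORF/UTR annotation, CRE tiles, interaction table, replication-timing
and coverage tracks (piecewise constant over 1 kb), mappability intervals,
a MAF-like SNV table, SEG copy-number segments, an expression count matrix,
and sample metadata — from a single seed, with each stage drawing from a
deterministically derived substream, so outputs are byte-identical across
runs and robust to changes in how much randomness other stages consume.

What it emulates, and its defaults:

* **Mutations** follow exactly the logistic model above (intercept −11,
  G/C effect 0.3, replication-timing effect 0.5, coverage effect 0.05,
  per-tumour offset SD 0.3), giving ~2–3 × 10⁻⁵ mutations per base per
  tumour.  That density is far above a typical WGS somatic rate: the
  reference genome is desk-scale (10 Mb, 50 tumours, ~3,000 CRE tiles of
  2 kb), and the density is chosen so that per-region counts at 10 Mb
  resemble per-region counts of a genome-scale cohort — every downstream
  stage (model fitting, clustering, expression linking) is exercised with
  realistic per-region statistics.  Substitution types are drawn from a
  configurable signature mixture conditioned on the local trinucleotide
  context.
* **Drivers** are spiked by region id with a rate multiplier (≥ 1) and a
  hotspot concentration in [0, 1] — the given fraction of the region's
  mutations is moved to one shared base — optionally with a target-gene
  expression fold change in mutated samples.
* **Interactions and mappability** deliberately straddle their filters
  (scores around 5, some distances beyond 1 Mb, some fragments below 95%
  well-mapped) so the region-definition cascade is always exercised.
* **Expression** is negative-binomial (log-normal baselines, common
  dispersion 0.15, log-normal library factors); **CNVs** mix
  whole-chromosome amplifications (hyperdiploid fraction 0.4 —
  approximately the frequency reported for newly diagnosed myeloma),
  occasional single-chromosome gains, and Poisson-distributed focal events
  with log-normal sizes; ~35% of samples get a translocation label.
* **QC fields** are drawn so that a configurable fraction (default 10%)
  of records fail exactly one of the four record-level filters.

What it does **not** emulate: read-level artefacts (there are no
FASTQ/BAMs), subclonal structure, mutation–CNV timing, linkage between
translocations and expression programs, structural-variant breakpoint
sequences, and genome-scale sparsity.  Passing tests on synthetic cohorts
therefore demonstrate the statistics are implemented correctly and
calibrated under the stated model — not that the model captures every
property of real tumour genomes.

## Validation problem sizes

The test suite validates at sizes chosen to exercise every stage in
minutes on one core: the reference null cohort is 50 tumours / 10 Mb /
≥ 2,000 testable CRE regions; FDR behaviour and driver recovery use 20 and
2 replicate cohorts of 30 tumours / 3 Mb / ~500 regions; coefficient
recovery uses 20 replicates of 30 tumours / 2 Mb; NB calibration uses
2,000 null genes at n = 200.  Spiked effect sizes mirror the motivating
study's headline findings (≥ 10× regional rate, hotspot concentration
≥ 0.5, 4.6-fold down and 2.3-fold up expression effects).

## Numerical choices and degenerate inputs

* Poisson-binomial DP is \(O(T^2)\) in the number of tumours; above 5,000
  the refined normal approximation (continuity- and skewness-corrected) is
  used.
* `combine_fisher` rejects p ≤ 0 — impossible by construction because the
  permutation p has add-one smoothing and the DP tail is ≥ the point mass.
* Dispersion optimisation is on \(\log\phi\) over \([10^{-6}, 5]\); a
  boundary optimum collapses to \(\phi = 0\) (Poisson).
* Fold-change display uses a 0.5 prior count so zero-mean groups yield a
  finite ratio.
* BH ties use the standard cumulative-minimum step-up; a single p-value is
  its own q-value.
* Regions with zero testable bases after masking are dropped; fragments
  with no mappability coverage count as 0% well mapped and are dropped
  with a message.
* Odds ratios are the sample cross-product ad/bc (`Inf` when bc = 0), not
  the conditional MLE that `fisher.test` prints.

## Known limitations

* The per-tumour load offset is a plug-in estimate; its sampling noise is
  not propagated into the background-model covariance (confidence
  intervals for the covariate effects are validated by simulation and are
  accurate at the tested sizes).
* The conservative discreteness of the Poisson-binomial tail (see above)
  costs power for regions whose expected mutated-tumour count is below ~1.
* Common (not per-gene) dispersion in the expression test; with one gene
  tested per region pair there is no shrinkage target, and the
  type-I-error simulations show the common estimate suffices at the
  validated sizes.
* The generator's CNV model places segments independently per sample; it
  does not reproduce recurrent co-amplification structure.
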