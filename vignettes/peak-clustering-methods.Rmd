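---
title: "Methods: multi-phenotype GWAS peak extraction and clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-phenotype GWAS peak extraction and clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwaspeaks)
```

# The problem

Biobank-scale imaging genetics runs thousands of genome-wide association
scans — one per imaging-derived phenotype (IDP) — over tens of millions of
imputed variants. The raw product is unmanageable: a strong causal locus
surfaces as hundreds of correlated supra-threshold variants, repeated
across dozens of phenotypes that share anatomy. `gwaspeaks` implements the
full reduction from dosage-level data to a table of *clusters*: distinct
genomic loci, each anchored by its single most significant
(phenotype, variant) pair, with replication and multiple-testing
annotation. The X chromosome is handled throughout with its own ploidy,
QC and encoding rules.

# Phenotype cleaning

Each phenotype vector passes through, in order:

1. **Outlier masking.** Entries farther than 6 times the median absolute
   deviation from the median are set missing. The MAD here is *unscaled* —
   the plain median of absolute deviations, with no 1.4826 normal
   consistency factor — so the cut sits at 6 raw MADs, not 6 robust SDs.
   When the MAD is zero (a constant-majority vector) the strict inequality
   masks only values that differ from the median, never the whole vector.
   The mask is computed once from the input; it is idempotent for typical
   data (gross outliers barely move the median or MAD), though not by
   construction — a value sitting exactly at the threshold can flip if a
   re-computed MAD shifts beneath it.
2. **Subject exclusion.** Subjects missing 50 or more phenotype values
   (for any reason, including the outlier mask) are dropped.
3. **Cohort split.** The remaining subjects are split uniformly at random
   into discovery and replication cohorts, discovery taking
   `floor(2N/3)`. The split is a function of the seed only. With 34,298
   subjects this yields cohorts of 22,865 and 11,433.
4. **Quantile normalisation** (per cohort). Non-missing entries are
   replaced by Blom normal scores `qnorm((r - 3/8) / (m + 1/4))` of their
   average ranks, giving an exactly rank-preserving, approximately
   standard Gaussian column. Ties share average ranks and map to equal
   scores.
5. **Confound residualisation** (per cohort). Each phenotype is replaced
   by its least-squares residual against an intercept plus the
   user-supplied confound columns, fitted on that phenotype's non-missing
   rows, then rescaled to unit variance. Confound coefficients are
   estimated within each cohort separately: the replication cohort is
   treated as genuinely held out, so no statistic estimated on discovery
   touches it. Rank-deficient confound sets are tolerated (pivoted QR). A
   phenotype numerically exhausted by its confounds (residual SD below
   1e-10) is either an error or set all-missing, by configuration.

Steps 4–5 run after the split on each cohort separately, so the two
cohorts never share normalisation ranks or regression coefficients.

# Variant quality control

Three filters, applied jointly with inclusive boundaries:
MAF ≥ 0.001, INFO ≥ 0.3, and Hardy–Weinberg −log10 p ≤ 7.

* **Allele frequency.** Autosomes and pseudoautosomal regions (PARs)
  count two alleles per sample. On the X non-PAR region males are
  haploid: a male's raw dosage in [0, 1] contributes a single allele, so
  males carry half a female's weight —
  `f = (Σ female dosage + Σ male dosage) / (2 n_f + n_m)`.
* **INFO score.** Defined here as the variance-ratio estimator: empirical
  dosage variance over its Hardy–Weinberg expectation (`2p(1−p)` diploid,
  `p(1−p)` for haploid male calls), computable from dosages alone. On X
  non-PAR the female and male terms are pooled with male contributions
  half-weighted, mirroring the frequency rule. Values are clipped to
  [0, 1.1]; a monomorphic variant has no defined score and fails the
  filter. Numerical agreement with any particular imputation tool's INFO
  variant is not promised — definitions differ across tools — but hard
  calls score 1 and fully uncertain imputations score 0 in all of them.
* **Hardy–Weinberg.** The Levene–Haldane exact test (no mid-p) on hard
  calls: dosages are rounded to the nearest genotype, entries farther than
  0.1 (configurable) from an integer are excluded as uncallable. The
  exact test rather than the chi-square keeps the tail honest at the rare
  frequencies where the filter actually bites. On chromosome X the test
  uses genetic females only, so the male haploid calls can never distort
  it — adding or removing males leaves the statistic unchanged.

Downstream of QC there is a second, stricter tier: hit extraction and
Manhattan exports keep only MAF ≥ 0.01, while full summary statistics
retain everything at MAF ≥ 0.001.

# Association scans and the X chromosome

Each (phenotype, variant) test is a simple ordinary least squares fit of
the residualised, unit-variance phenotype on the encoded dosage with an
intercept. Effects follow the alternate allele: beta is the phenotype
change in SD units per alt-allele copy. Two-sided p-values come from the
Student t tail evaluated in log space, emitted directly as −log10 p (the
raw p is never materialised), capped at 320 by default so round-trips
through text files stay finite.

Encoding: autosomal and PAR dosages are used as-is. Male non-PAR X calls,
raw in [0, 1], are doubled to the (0, 2) coding. This is the full
dosage-compensation convention: X inactivation silences one female copy
per cell, so a hemizygous male is treated like a homozygous female and
per-allele effects remain comparable across sexes. The coding is exactly
scale-equivariant — doubling dosages halves beta and leaves the t
statistic, hence −log10 p, bit-identical.

Design choices worth stating:

* Confounds are removed from phenotypes only, never from genotypes; the
  residual degrees of freedom are `n − 2` (intercept + dosage), ignoring
  the confound df spent upstream. This is mildly anti-conservative at
  small n and negligible at cohort scale; it also keeps the scan exactly
  reproducible by a two-variable OLS oracle.
* Missing dosages are handled by casewise deletion per variant, not mean
  imputation, again so that every emitted number equals the closed-form
  OLS on the observed rows.
* A variant with zero dosage variance in the scan cohort is flagged
  monomorphic and not tested.

# Peak extraction and cross-phenotype clustering

All distance logic lives in genetic-map space: a per-chromosome
piecewise-linear interpolator from bp to cM (positions outside the
anchors extrapolate along the boundary segment, floored at 0 cM). The map
is a required input — cM coordinates depend on the map release, so none
is bundled.

**Within one phenotype** (hit extraction): among supra-threshold records
(−log10 p > 7.5 by default), repeatedly take the most significant, emit
it as a peak, and remove every record within 0.25 cM, until none remain.
Any two peaks of one phenotype are therefore more than 0.25 cM apart.

**Across phenotypes** (clustering): per chromosome, all peaks from all
phenotypes are built into a binary max-heap keyed on −log10 p using the
linear-time bottom-up heapify. While the heap is non-empty: extract the
maximum pair — the new cluster's *lead* — and delete every remaining peak
within 0.25 cM of it (an O(log n) arbitrary-deletion per peak, via a
position-tracking index), assigning those peaks to the cluster. Every
peak lands in exactly one cluster, no member exceeds its lead's
significance, and total work is O(n log n).

Numerical and tie conventions:

* "Within 0.25 cM" is inclusive: a peak exactly at the boundary joins
  the cluster, and membership is decided by the defining inequality
  `|cM − lead cM| ≤ 0.25` itself, not by a derived interval bound, so
  floating-point rounding cannot disagree with the definition.
* Equal −log10 p ties are broken by (chromosome, bp, phenotype)
  ascending. This makes the output a deterministic function of the input
  and lets a naive quadratic greedy reference reproduce it exactly — the
  test suite checks identity on a thousand randomised instances with
  injected ties.
* Cover removal operates on the peak set only, never on raw variants.
* X PAR peaks cluster on the X heap with X-map cM coordinates, so PAR
  and non-PAR leads can share a cluster list.

Cluster tables are ordered by chromosome (1..22, X) and, within a
chromosome, by descending lead significance — which is exactly the heap
extraction order.

**Annotation.** A cluster *replicates* when at least one member pair
reaches two-sided p < 0.05 (strictly; −log10 p > 1.30103) when re-tested
on the held-out replication cohort; members untestable there count as
non-significant. The *Bonferroni* flag marks leads exceeding
`7.5 + log10(n_phenotypes)` — for a 3,935-phenotype panel, 11.09, which
displays as 11.1.

# Sex-stratified scans and Fisher meta-analysis

Female-only and male-only scans of the discovery cohort are combined per
(phenotype, variant) by Fisher's method:

\[
p_{\mathrm{meta}} = S_{\chi^2_4}\!\left(-2(\ln p_f + \ln p_m)\right),
\]

the survival function of a chi-squared with 4 degrees of freedom (2 per
scan). The logarithm is natural — with any other base the statistic would
not be chi-squared. Everything is computed in log space with −log10 p
inputs (`ln p = −ln 10 · nl10p`), so pairs far beyond double-precision
underflow combine exactly; for df 4 the implementation agrees with the
closed form `q(1 − ln q)`, `q = p_f p_m`, to 1e-12 relative across
p ∈ [1e-300, 1]. The combination is deliberately unweighted: it is
insensitive to any relative scaling of effect sizes between the two
scans, so it assumes no dosage-compensation model. No beta-weighted
alternative is offered. Meta output is an ordinary summary-statistics
table (combined −log10 p in the `neglog10p` column, beta/se empty), so
peak extraction and clustering consume it unchanged; meta clustering
reuses the genome-wide 7.5 threshold.

Sex effects are compared two ways: a two-tailed z-test on the beta
difference, `z = (β_f − β_m)/\sqrt{se_f^2 + se_m^2}`, and a
sign-concordance summary over pairs where either sex-specific scan
clears a significance floor (zero betas count as concordant). Meta
clusters are matched to main-scan clusters when leads on the same
chromosome sit within 0.25 cM — inclusive, the same boundary rule as the
cover radius.

# The synthetic cohort

The simulator is the package's stand-in for restricted biobank data, and
it is first-class, tested code. It emulates:

* **LD-blocked genotypes** via a Gaussian copula: each haplotype's latent
  normal is blockwise equicorrelated (`within_block_r`, default 0.6 over
  blocks of 5) and thresholded at the target allele frequency. This gives
  direct control of nearby-variant correlation without coalescent
  machinery; it does not reproduce realistic LD decay, allele-frequency
  spectra, or population structure, and is not meant to.
* **X ploidy**: females diploid everywhere; males haploid (raw dosage in
  [0, 1]) on non-PAR X and diploid on the PARs, with PAR membership
  determined by position against GRCh37 intervals.
* **Imputation uncertainty**: dosages optionally shrink toward the
  Hardy–Weinberg mean (`dosage_noise` w gives INFO ≈ (1 − w)²).
* **Phenotypes** as sparse genetic signal plus shared confounds plus
  unit Gaussian noise, with planted (phenotype, variant, beta) triples
  returned as ground truth. A configurable male multiplier on the
  encoded non-PAR dosage lets full or partial dosage compensation be
  planted.
* A **constant-rate genetic map** (1 cM/Mb by default), so cover
  distances in tests are exactly controllable.

Because the generator is Gaussian and unstructured, passing tests show
that the pipeline's logic and arithmetic are right — they do not show
robustness to population stratification, relatedness, assortment, or
real imputation error.

# Validation choices and problem sizes

The test suite validates against independent oracles: a naive quadratic
greedy for clustering (1,000 random instances up to 500 peaks), solved
normal equations for residualisation and scans, exhaustive enumeration of
allele pairings for the HWE exact test, and closed forms for the Fisher
combination and Blom scores. Null calibration uses 10,000
variant-phenotype tests for scan type-I error, 50,000 pairs for
Fisher-p uniformity, and 10,000 equilibrium variants for the HWE
false-positive rate. The end-to-end recovery study plants 3 causal
variants in each of 20 phenotypes (|β| ∈ [0.15, 0.3], MAF ∈ [0.1, 0.5])
in cohorts of 4,000 across three chromosomes including X, lowers the
genome-wide threshold to 4.5 to match that sample size, and requires
≥ 80% of planted loci to be recovered within 0.25 cM of a replicated
cluster lead over 20 seeds, with essentially no replicated clusters under
the global null. These sizes keep a full run of the suite to a couple of
minutes on one core while leaving each statistical check adequately
powered.

One comparison deserves its rationale spelled out. The power comparison
between the Fisher meta-analysis and the pooled scan plants *equal
per-allele-copy* effects in both sexes — the male effect applies to his
raw 0/1 allele count. Under that (incomplete-compensation) truth the
pooled scan's (0, 2) male coding is mildly misspecified, and the
sex-separated scans followed by Fisher combination match the pooled scan's
median sensitivity. Had the simulation planted effects on the encoded
scale instead (full compensation), the pooled single-slope test would be
exactly correct and strictly the more powerful — an unweighted p-value
combination cannot beat the optimal test in its own model. The interesting
regime, and the one the meta-analysis exists for, is precisely when the
compensation model may be wrong.

# Known limitations

* No mixed-model or relatedness correction: cohorts are assumed
  maximally unrelated; no genomic-control or LD-score diagnostics.
* Confound selection is the user's problem; the package consumes an
  arbitrary confound matrix.
* The INFO estimator is one of several in circulation; boundary-exact
  agreement with external QC tools is not guaranteed.
* Fine-mapping, heritability estimation, and gene/eQTL annotation are
  out of scope; the cluster table is this package's terminal product.
* BGEN is not parsed natively; convert to VCF (DS field) or a dosage
  matrix first.
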