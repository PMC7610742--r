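# gwaspeaks

Multi-phenotype GWAS peak extraction and cross-phenotype locus clustering,
with first-class X-chromosome support.

Imaging genetics at biobank scale runs one genome-wide association scan per
imaging-derived phenotype — thousands of scans over millions of imputed
variants. The raw output is unreadable: every causal locus appears as
hundreds of correlated supra-threshold variants, duplicated across dozens of
anatomically related phenotypes. `gwaspeaks` turns dosage-level data into a
table of distinct **clusters** of association, each anchored by the single
most significant (phenotype, variant) pair at that locus, with replication
and multiple-testing flags. It is aimed at analysts running phenome-wide
scans (brain IDPs or any other dense phenotype panel) who need defensible
locus counting rather than variant-level sprawl.

## What it computes

* **Phenotype cleaning** — outlier masking at 6 unscaled MADs from the
  median; removal of subjects with ≥ 50 missing phenotypes; a seeded
  `floor(2N/3)` discovery/replication split; then per cohort: Blom
  quantile normalisation `Φ⁻¹((r − 3/8)/(m + ¼))`, confound
  residualisation, and unit-variance rescaling.
* **Sex-aware variant QC** — MAF ≥ 0.001, variance-ratio INFO ≥ 0.3, and
  Levene–Haldane exact Hardy–Weinberg −log10 p ≤ 7; on chromosome X, males
  contribute half weight to MAF/INFO on the non-PAR region and the HWE test
  uses females only.
* **Association scans** — per-variant OLS of each cleaned phenotype on
  dosage, effects in SD units per alternate-allele copy, −log10 p computed
  in log space; male non-PAR X genotypes take the (0, 2)
  dosage-compensation coding.
* **Peaks and clusters** — the core algorithm. Within a phenotype: greedy
  extraction of hits above −log10 p = 7.5 with a 0.25 cM exclusion radius.
  Across phenotypes: per chromosome, a binary max-heap keyed on −log10 p;
  repeatedly extract the maximum as a new cluster lead and delete its
  0.25 cM cover from the heap — O(n log n) total, deterministic under a
  (chromosome, bp, phenotype) tie rule. Clusters are flagged *replicated*
  (any member at p < 0.05 in the held-out cohort) and *Bonferroni*
  (lead ≥ 7.5 + log10(#phenotypes); 11.1 for a 3,935-phenotype panel).
* **Sex-stratified meta-analysis** — female-only and male-only scans
  combined by Fisher's method, `S_χ²₄(−2(ln p_f + ln p_m))`, in log space;
  beta-difference z-tests; sign-concordance summaries; matching of meta
  clusters to main-scan clusters within 0.25 cM.
* **A synthetic cohort simulator** — Gaussian-copula LD blocks, correct
  X ploidy (PARs diploid, male non-PAR haploid), planted effects with
  ground truth, confounds, missingness and imputation noise — used by the
  test suite for end-to-end recovery checks.

## Worked example

The whole pipeline runs from a single config, here on a simulated cohort of
2,000 samples, 6 phenotypes with 2 planted causal variants each, on
chromosomes 2 and X:

```r
library(gwaspeaks)

res <- run_pipeline(list(
  simulate = list(n_female = 1000, n_male = 1000,
                  chromosomes = c("2", "X"), n_variants = 80,
                  n_phenotypes = 6, n_causal = 2,
                  effect_range = c(0.2, 0.35), maf_range = c(0.1, 0.5),
                  seed = 101),
  thresholds = list(genomewide = 4.5),   # matched to the small n
  split_seed = 202))

res$clusters
#> <gwas_clusters> 17 clusters over 18 peak (phenotype, variant) pairs
#>   replicated: 15
#>   Bonferroni-significant leads: 12
#> # A tibble: 10 × 12
#>    cluster_id lead_variant_id lead_phenotype_id chromosome        bp ...
#>  1          1 var_2_0036      P006              2            3600000
#>  2          2 var_2_0004      P004              2             400000
#>  3          3 var_2_0007      P006              2             700000
#>  ...
#>  7          7 var_X_0030      P003              X           60614141

glance(res$clusters)
#> # A tibble: 1 × 6
#>   n_clusters n_peaks n_replicated n_bonferroni n_phenotypes n_chromosomes
#> 1         17      18           15           12            6             2
```

Reading this: the 12 planted loci (see `res$truth`) all surface as
replicated cluster leads; the handful of extra clusters are LD satellites —
correlated variants in the same simulated LD block that sit just beyond the
0.25 cM cover of the lead, a behaviour real data shows too. `tidy(res$clusters)`
returns the member-level table, `autoplot(res$clusters)` draws the clusters
in cM space, and `plot_manhattan()` draws a per-phenotype Manhattan plot.
With real files instead of a simulation, the config takes a `paths:` block
(dosage VCF/TSV, phenotype and confound TSVs, sample-sex table, genetic
map), and every stage is also callable directly
(`prep_phenotypes()`, `variant_qc_metrics()`, `linear_scan()`,
`extract_peaks()`, `cluster_peaks()`, `meta_analyse_sex_scans()`, ...) or
from the shell via `inst/cli/gwaspeaks.R`.

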