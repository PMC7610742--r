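#' Sex-aware alternate-allele frequency
#'
#' On autosomes and PARs every sample is diploid and the alternate-allele
#' frequency is `sum(dosage) / (2 * n)`. On the X non-PAR region males are
#' haploid: each male contributes a single allele (his raw dosage in [0, 1]
#' counted once), so males contribute half as much as females to the
#' frequency: `f = (sum_f d + sum_m d) / (2 n_f + n_m)`.
#'
#' @param dosage Numeric dosage vector (raw coding, `NA` = missing).
#' @param sex Character vector, `"female"`/`"male"` per sample.
#' @param region Variant region, see [variant_region()].
#' @return A list with `alt_freq` and `maf = min(f, 1 - f)`.
#' @export
#' @examples
#' allele_freq_sex_aware(c(0, 1, 1), c("female", "female", "male"), "X_nonPAR")
allele_freq_sex_aware <- function(dosage, sex, region = "autosome") {
  obs <- !is.na(dosage)
  if (!any(obs)) abort("All dosages are missing.")
  if (region == "X_nonPAR") {
    f_obs <- obs & sex == "female"
    m_obs <- obs & sex == "male"
    n_alleles <- 2 * sum(f_obs) + sum(m_obs)
    alt_freq <- (sum(dosage[f_obs]) + sum(dosage[m_obs])) / n_alleles
  } else {
    alt_freq <- sum(dosage[obs]) / (2 * sum(obs))
  }
  list(alt_freq = alt_freq, maf = min(alt_freq, 1 - alt_freq))
}

#' Imputation INFO score
#'
#' Variance-ratio estimator of imputation quality: the empirical dosage
#' variance divided by its Hardy-Weinberg expectation, `2p(1-p)` for diploid
#' calls and `p(1-p)` for haploid male non-PAR calls. On the X non-PAR
#' region the female and male terms are pooled with male contributions
#' half-weighted, mirroring the frequency computation. Values are clipped to
#' [0, 1.1]; a monomorphic variant (maf = 0) has an undefined score and
#' returns `NA`.
#'
#' @inheritParams allele_freq_sex_aware
#' @return INFO score in [0, 1.1], or `NA` for maf = 0.
#' @export
info_score <- function(dosage, sex, region = "autosome") {
  freq <- allele_freq_sex_aware(dosage, sex, region)
  p <- freq$alt_freq
  if (freq$maf <= 0) return(NA_real_)
  obs <- !is.na(dosage)
  if (region == "X_nonPAR") {
    f_obs <- obs & sex == "female"
    m_obs <- obs & sex == "male"
    w <- sum(f_obs) + 0.5 * sum(m_obs)
    observed <- (sum((dosage[f_obs] - 2 * p)^2) +
                   0.5 * sum((dosage[m_obs] - p)^2)) / w
    expected <- (2 * p * (1 - p) * sum(f_obs) +
                   p * (1 - p) * 0.5 * sum(m_obs)) / w
  } else {
    observed <- mean((dosage[obs] - 2 * p)^2)
    expected <- 2 * p * (1 - p)
  }
  min(max(observed / expected, 0), 1.1)
}

#' Hardy-Weinberg exact test (Levene-Haldane)
#'
#' Exact test of Hardy-Weinberg proportions from diploid genotype counts:
#' the p-value is the total probability, under the conditional
#' (Levene-Haldane) distribution of heterozygote counts given the allele
#' counts, of all outcomes no more probable than the observed one (no mid-p
#' adjustment). Monomorphic variants have a single attainable configuration
#' and return p = 1.
#'
#' @param n_ref_hom,n_het,n_alt_hom Genotype counts.
#' @return `-log10(p)`.
#' @export
#' @examples
#' hwe_exact_neglog10p(25, 50, 25)
hwe_exact_neglog10p <- function(n_ref_hom, n_het, n_alt_hom) {
  n <- n_ref_hom + n_het + n_alt_hom
  if (n < 2) abort("Need at least 2 genotypes for the exact test.")
  n_alt <- 2 * n_alt_hom + n_het
  n_minor <- min(n_alt, 2 * n - n_alt)
  if (n_minor == 0) return(0)
  # attainable het counts share the parity of the minor-allele count
  h <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(het = h | n, n_alt) up to a constant:
  #   log n! - log nAA! - log nAa! - log naa! + h log 2
  n_min_hom <- (n_minor - h) / 2
  n_maj_hom <- n - h - n_min_hom
  logp <- h * log(2) - lgamma(n_min_hom + 1) - lgamma(h + 1) -
    lgamma(n_maj_hom + 1)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- match(n_het, h)
  if (is.na(obs)) abort("Observed heterozygote count inconsistent with allele counts.")
  p <- sum(prob[prob <= prob[obs] * (1 + 1e-12)])
  -log10(min(p, 1))
}

#' Hardy-Weinberg test from dosages
#'
#' Hard-calls genotypes by rounding dosages to the nearest integer
#' (entries farther than `max_call_distance` from an integer are excluded
#' as uncallable) and applies [hwe_exact_neglog10p()]. On the X chromosome
#' the test uses genetic females only, so adding or removing male samples
#' never changes the result.
#'
#' @inheritParams allele_freq_sex_aware
#' @param max_call_distance Hard-call tolerance (default 0.1).
#' @return `-log10(p)` of the exact test.
#' @export
hwe_from_dosages <- function(dosage, sex, region = "autosome",
                             max_call_distance = 0.1) {
  if (region != "autosome") dosage <- dosage[sex == "female"]
  g <- round(dosage)
  usable <- !is.na(dosage) & abs(dosage - g) <= max_call_distance
  g <- g[usable]
  if (length(g) < 2) abort("Fewer than 2 hard-callable genotypes.")
  hwe_exact_neglog10p(sum(g == 0), sum(g == 1), sum(g == 2))
}

#' Per-variant QC metrics
#'
#' Computes MAF, INFO and the female-only-on-X Hardy-Weinberg exact test for
#' every variant in a dosage set.
#'
#' @param dosages A [dosage_set()].
#' @param max_call_distance Hard-call tolerance for the HWE test.
#' @return A tibble with one row per variant: the variant identity plus
#'   `alt_freq`, `maf`, `info`, `hwe_neglog10p`.
#' @export
variant_qc_metrics <- function(dosages, max_call_distance = 0.1) {
  variants <- dosages$variants
  n_var <- nrow(variants)
  alt_freq <- maf <- info <- hwe <- numeric(n_var)
  for (j in seq_len(n_var)) {
    d <- dosages$dosage[, j]
    region <- variants$region[j]
    fr <- allele_freq_sex_aware(d, dosages$sex, region)
    alt_freq[j] <- fr$alt_freq
    maf[j] <- fr$maf
    info[j] <- info_score(d, dosages$sex, region)
    hwe[j] <- tryCatch(
      hwe_from_dosages(d, dosages$sex, region, max_call_distance),
      error = function(e) NA_real_)
  }
  dplyr::bind_cols(variants,
                   tibble(alt_freq = alt_freq, maf = maf, info = info,
                          hwe_neglog10p = hwe))
}

#' Apply the variant QC filters
#'
#' A variant passes when `maf >= maf_min` AND `info >= info_min` AND
#' `hwe_neglog10p <= hwe_max`; boundary values pass exactly as written.
#' Variants with an undefined INFO (monomorphic) or HWE result fail.
#'
#' @param metrics Tibble from [variant_qc_metrics()].
#' @param maf_min,info_min,hwe_max Filter thresholds (defaults 0.001, 0.3, 7).
#' @return The input tibble plus a logical `pass` column and a `fail_reason`
#'   column (`NA` for passing variants); attribute `"tally"` holds per-rule
#'   rejection counts.
#' @export
apply_variant_filters <- function(metrics, maf_min = 0.001, info_min = 0.3,
                                  hwe_max = 7) {
  fail_maf <- is.na(metrics$maf) | metrics$maf < maf_min
  fail_info <- is.na(metrics$info) | metrics$info < info_min
  fail_hwe <- is.na(metrics$hwe_neglog10p) | metrics$hwe_neglog10p > hwe_max
  reason <- dplyr::case_when(fail_maf ~ "maf", fail_info ~ "info",
                             fail_hwe ~ "hwe", TRUE ~ NA_character_)
  out <- dplyr::mutate(metrics, pass = !(fail_maf | fail_info | fail_hwe),
                       fail_reason = reason)
  attr(out, "tally") <- c(maf = sum(fail_maf), info = sum(fail_info),
                          hwe = sum(fail_hwe), pass = sum(out$pass))
  out
}

#' Tally surviving variants by genome region
#'
#' Bookkeeping helper: aggregates per-region survivor counts and their
#' sums (all X regions; whole genome), verifying that the parts add up.
#'
#' @param counts Named numeric vector or tibble with columns `region`, `n`
#'   giving surviving-variant counts for regions among
#'   `autosome, X_nonPAR, X_PAR` (PAR1/PAR2 may be given together or
#'   separately).
#' @return A tibble with rows for each input region plus `X_total` and
#'   `genome_total`.
#' @export
tally_survivors <- function(counts) {
  if (!is.data.frame(counts)) {
    counts <- tibble(region = names(counts), n = as.numeric(counts))
  }
  x_regions <- grepl("^X_", counts$region)
  x_total <- sum(counts$n[x_regions])
  genome_total <- sum(counts$n[counts$region == "autosome"]) + x_total
  dplyr::bind_rows(counts,
                   tibble(region = c("X_total", "genome_total"),
                          n = c(x_total, genome_total)))
}
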