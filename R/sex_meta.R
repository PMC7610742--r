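#' Fisher's-method combination of two p-values
#'
#' Combines the female- and male-scan p-values for one association:
#' `p_combined = S(-2 (ln p_f + ln p_m))` where `S` is the chi-squared
#' survival function with 4 degrees of freedom (2 per combined scan).
#' Everything is evaluated in log space, and inputs may be given as
#' -log10 p (`ln p = -ln(10) * neglog10p`), so associations far beyond
#' double-precision underflow combine exactly. For df 4 the result equals
#' the closed form `q (1 - ln q)` with `q = p_f p_m`.
#'
#' The combination is unweighted by construction: it is insensitive to any
#' relative scaling of the effect sizes in the two sex-separated scans, so
#' no dosage-compensation model is assumed.
#'
#' @param p_f,p_m Two-sided p-values in (0, 1]; or supply
#' @param neglog10p_f,neglog10p_m -log10 p-values (>= 0) instead.
#' @return A tibble with `p_combined` and `neglog10p_combined` (the former
#'   underflows to 0 for extreme inputs; the latter is always finite).
#' @export
#' @examples
#' fisher_combine(0.05, 0.05)
fisher_combine <- function(p_f = NULL, p_m = NULL,
                           neglog10p_f = NULL, neglog10p_m = NULL) {
  if (is.null(neglog10p_f) != is.null(neglog10p_m) ||
      is.null(p_f) != is.null(p_m)) {
    abort("Supply both members of either the p or the -log10 p pair.")
  }
  if (!is.null(p_f)) {
    if (any(p_f <= 0 | p_m <= 0, na.rm = TRUE)) {
      abort("p-values must be > 0; pass -log10 p inputs to avoid underflow.")
    }
    if (any(p_f > 1 | p_m > 1, na.rm = TRUE)) abort("p-values must be <= 1.")
    ln_f <- log(p_f)
    ln_m <- log(p_m)
  } else {
    if (any(neglog10p_f < 0 | neglog10p_m < 0, na.rm = TRUE)) {
      abort("-log10 p inputs must be >= 0.")
    }
    ln_f <- -log(10) * neglog10p_f
    ln_m <- -log(10) * neglog10p_m
  }
  stat <- -2 * (ln_f + ln_m)
  log_p <- pchisq(stat, df = 4, lower.tail = FALSE, log.p = TRUE)
  tibble(p_combined = exp(log_p), neglog10p_combined = -log_p / log(10))
}

#' Sex-stratified meta-analysis of two scans
#'
#' Joins the female-only and male-only association scans on
#' (phenotype, variant) and combines them with [fisher_combine()]. The
#' output is a summary-statistics table whose `neglog10p` is the combined
#' value (beta/se are not defined for an unweighted p-value combination),
#' so the peak-extraction and clustering stages consume it unchanged.
#'
#' @param female,male Association tibbles from [linear_scan()] on the
#'   female-only and male-only cohorts.
#' @return A tibble with the variant identity, `phenotype_id`, per-sex
#'   `beta_f/se_f/neglog10p_f` and `beta_m/se_m/neglog10p_m`, and the
#'   combined `neglog10p`.
#' @export
meta_analyse_sex_scans <- function(female, male) {
  f <- dplyr::rename(as_tibble(female), beta_f = "beta", se_f = "se",
                     neglog10p_f = "neglog10p", n_f = "n")
  m <- dplyr::select(dplyr::rename(as_tibble(male), beta_m = "beta",
                                   se_m = "se", neglog10p_m = "neglog10p",
                                   n_m = "n"),
                     dplyr::all_of(c("phenotype_id", "variant_id", "beta_m",
                                     "se_m", "neglog10p_m", "n_m")))
  pairs <- dplyr::inner_join(f, m, by = c("phenotype_id", "variant_id"))
  ok <- !is.na(pairs$neglog10p_f) & !is.na(pairs$neglog10p_m)
  comb <- rep(NA_real_, nrow(pairs))
  if (any(ok)) {
    comb[ok] <- fisher_combine(neglog10p_f = pairs$neglog10p_f[ok],
                               neglog10p_m = pairs$neglog10p_m[ok])$neglog10p_combined
  }
  pairs$neglog10p <- comb
  pairs$beta <- NA_real_
  pairs$se <- NA_real_
  pairs$n <- pairs$n_f + pairs$n_m
  pairs
}

#' Two-tailed z-test for a sex difference in effect size
#'
#' Tests whether the female and male effect estimates for the same
#' (phenotype, variant) differ: `z = (beta_f - beta_m) /
#' sqrt(se_f^2 + se_m^2)`, `p = 2 * pnorm(-|z|)`.
#'
#' @param beta_f,se_f,beta_m,se_m Per-sex estimates and standard errors
#'   (vectors; `se` must be > 0).
#' @return A tibble with `z` and `p`.
#' @export
#' @examples
#' beta_diff_ztest(1, sqrt(0.5), 0, sqrt(0.5))
beta_diff_ztest <- function(beta_f, se_f, beta_m, se_m) {
  if (any(se_f <= 0 | se_m <= 0, na.rm = TRUE)) {
    abort("Standard errors must be > 0.")
  }
  z <- (beta_f - beta_m) / sqrt(se_f^2 + se_m^2)
  tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Sign concordance of sex-specific effect sizes
#'
#' Among pairs where at least one sex-specific scan reaches
#' `neglog10p_min`, the fraction whose effect-size signs match. A zero beta
#' is concordant with either sign.
#'
#' @param pairs Tibble with `beta_f, beta_m, neglog10p_f, neglog10p_m`.
#' @param neglog10p_min Significance filter on `max(neglog10p_f,
#'   neglog10p_m)` (default 7.5).
#' @return A list with `concordance` (fraction in [0, 1]), `n_pairs` and
#'   `n_discordant`.
#' @export
sign_concordance <- function(pairs, neglog10p_min = 7.5) {
  keep <- pmax(pairs$neglog10p_f, pairs$neglog10p_m, na.rm = TRUE) >= neglog10p_min
  keep <- keep & !is.na(pairs$beta_f) & !is.na(pairs$beta_m)
  sub <- pairs[which(keep), , drop = FALSE]
  if (nrow(sub) == 0) {
    abort("No pairs pass the significance filter; concordance is undefined.")
  }
  concordant <- sub$beta_f * sub$beta_m >= 0
  list(concordance = mean(concordant), n_pairs = nrow(sub),
       n_discordant = sum(!concordant))
}

#' Match meta-analysis clusters against main-scan clusters
#'
#' A meta-analysis cluster matches when some main-scan cluster on the same
#' chromosome has its lead within `tol_cm` centimorgans (inclusive, the
#' same boundary rule as the cover radius). Reports matched pairs and the
#' orphans on both sides.
#'
#' @param meta_clusters,main_clusters Cluster tables (`$clusters` of a
#'   `gwas_clusters`, or any tibble with `cluster_id, chromosome, lead_cm`).
#' @param tol_cm Matching tolerance in cM (default 0.25).
#' @return A list with `matched` (meta cluster id, main cluster id,
#'   `delta_cm` of the closest match), `meta_only` and `main_only`.
#' @export
cluster_overlap <- function(meta_clusters, main_clusters, tol_cm = 0.25) {
  meta <- extract_cluster_table(meta_clusters)
  main <- extract_cluster_table(main_clusters)
  matched <- tibble(meta_cluster_id = integer(), main_cluster_id = integer(),
                    chromosome = character(), delta_cm = numeric())
  for (i in seq_len(nrow(meta))) {
    cand <- main[main$chromosome == meta$chromosome[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    d <- abs(cand$lead_cm - meta$lead_cm[i])
    j <- which.min(d)
    if (d[j] <= tol_cm) {
      matched <- dplyr::bind_rows(matched, tibble(
        meta_cluster_id = meta$cluster_id[i],
        main_cluster_id = cand$cluster_id[j],
        chromosome = meta$chromosome[i], delta_cm = d[j]))
    }
  }
  list(matched = matched,
       meta_only = meta[!(meta$cluster_id %in% matched$meta_cluster_id), ],
       main_only = main[!(main$cluster_id %in% matched$main_cluster_id), ])
}

extract_cluster_table <- function(x) {
  if (inherits(x, "gwas_clusters")) x <- x$clusters
  x <- as_tibble(x)
  needed <- c("cluster_id", "chromosome", "lead_cm")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Cluster table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x
}
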