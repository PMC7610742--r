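#' Dosage-compensation encoding of X genotypes
#'
#' Under full dosage compensation (X-inactivation), a male's single non-PAR
#' X allele is comparable to a female homozygote, so raw haploid male calls
#' in [0, 1] are scaled by 2 to the (0, 2) coding. All other calls
#' (females, autosomes, PARs) pass through unchanged.
#'
#' @param dosage Raw dosage vector.
#' @param sex `"female"`/`"male"` per sample.
#' @param region Variant region, see [variant_region()].
#' @return Encoded dosage vector in [0, 2].
#' @export
#' @examples
#' encode_x_dosage(c(1, 1), c("male", "female"), "X_nonPAR")
encode_x_dosage <- function(dosage, sex, region = "autosome") {
  if (region == "X_nonPAR") {
    male <- sex == "male"
    if (any(dosage[male] > 1 + 1e-8, na.rm = TRUE)) {
      abort("Raw male non-PAR dosages must lie in [0, 1].")
    }
    dosage[male] <- 2 * dosage[male]
  }
  if (any(dosage < -1e-8 | dosage > 2 + 1e-8, na.rm = TRUE)) {
    abort("Encoded dosages must lie in [0, 2].")
  }
  dosage
}

# two-sided -log10 p from a t statistic, evaluated in log space so it
# stays finite for |t| far beyond double-precision p underflow
neglog10p_from_t <- function(t_stat, df, cap = 320) {
  lp <- pt(abs(t_stat), df = df, lower.tail = FALSE, log.p = TRUE) + log(2)
  pmin(-lp / log(10), cap)
}

#' Per-variant linear association scan
#'
#' Simple OLS of each (already residualised, unit-variance) phenotype on
#' each variant's encoded dosage, with intercept. Effect sizes follow the
#' alternate allele: beta is the phenotype change in SD units per alt-allele
#' copy. Autosomal dosages are used as-is; male non-PAR X dosages are scaled
#' to the (0, 2) coding by [encode_x_dosage()]. Missing dosages are handled
#' by casewise deletion per variant; `se` uses residual df `n - 2`.
#' The two-sided p comes from the Student t tail in log space and is emitted
#' as -log10 p, capped at `cap`.
#'
#' @param pheno Phenotype tibble (`sample_id` + phenotype columns), already
#'   cleaned/residualised.
#' @param dosages A [dosage_set()].
#' @param phenotype_ids Phenotype columns to scan (default: all).
#' @param cohort Optional sample-id subset (e.g. discovery ids).
#' @param cap Cap for -log10 p (default 320).
#' @return A tibble with one row per (phenotype, variant): variant identity
#'   columns plus `phenotype_id, beta, se, neglog10p, n, monomorphic`.
#' @export
linear_scan <- function(pheno, dosages, phenotype_ids = NULL, cohort = NULL,
                        cap = 320) {
  ids <- pheno$sample_id
  if (!is.null(cohort)) ids <- intersect(ids, cohort)
  ids <- intersect(ids, dosages$sample_id)
  if (length(ids) < 3) abort("Fewer than 3 samples in the scan cohort.")
  phenotype_ids <- phenotype_ids %||% setdiff(names(pheno), "sample_id")

  G <- dosages$dosage[match(ids, dosages$sample_id), , drop = FALSE]
  sex <- dosages$sex[match(ids, dosages$sample_id)]
  # encode male non-PAR X columns once for the whole scan
  nonpar <- which(dosages$variants$region == "X_nonPAR")
  if (length(nonpar) > 0 && any(sex == "male")) {
    male <- sex == "male"
    block <- G[male, nonpar, drop = FALSE]
    if (any(block > 1 + 1e-8, na.rm = TRUE)) {
      abort("Raw male non-PAR dosages must lie in [0, 1].")
    }
    G[male, nonpar] <- 2 * block
  }
  Mg <- !is.na(G)
  G0 <- ifelse(Mg, G, 0)

  P <- as.matrix(pheno[match(ids, pheno$sample_id), phenotype_ids, drop = FALSE])
  res <- vector("list", length(phenotype_ids))
  for (k in seq_along(phenotype_ids)) {
    y <- P[, k]
    keep <- !is.na(y)
    yk <- y[keep]
    Gk <- G0[keep, , drop = FALSE]
    Mk <- Mg[keep, , drop = FALSE]
    n <- colSums(Mk)
    sx <- colSums(Gk)
    sxx <- colSums(Gk * Gk)
    sy <- drop(crossprod(Mk, yk))
    syy <- drop(crossprod(Mk, yk^2))
    sxy <- drop(crossprod(Gk, yk))
    sxx_c <- sxx - sx^2 / n
    sxy_c <- sxy - sx * sy / n
    syy_c <- syy - sy^2 / n
    mono <- !(n >= 3) | sxx_c <= 1e-12
    beta <- ifelse(mono, NA_real_, sxy_c / sxx_c)
    rss <- pmax(syy_c - beta^2 * sxx_c, 0)
    df <- n - 2
    sigma2 <- rss / df
    se <- sqrt(sigma2 / sxx_c)
    t_stat <- beta / se
    nl10 <- rep(NA_real_, length(n))
    ok <- !mono & is.finite(t_stat)
    nl10[ok] <- neglog10p_from_t(t_stat[ok], df[ok], cap = cap)
    # a numerically perfect fit (se -> 0) hits the cap rather than NaN
    perfect <- !mono & !is.finite(t_stat) & se < .Machine$double.eps
    nl10[perfect] <- cap
    res[[k]] <- dplyr::bind_cols(
      dosages$variants,
      tibble(phenotype_id = phenotype_ids[k], beta = unname(beta),
             se = unname(ifelse(mono, NA_real_, se)),
             neglog10p = unname(nl10), n = as.integer(unname(n)),
             monomorphic = unname(mono)))
  }
  dplyr::bind_rows(res)
}

#' Minor-allele-frequency hit filter
#'
#' Peak/hit extraction and Manhattan plotting use a stricter MAF cutoff than
#' the summary-statistics output: results whose variant MAF is below
#' `maf_min` (default 0.01) are dropped from the hit set while remaining in
#' the full summary statistics.
#'
#' @param results Association tibble with a `variant_id` column.
#' @param maf_table Tibble with `variant_id` and `maf` (e.g. from
#'   [variant_qc_metrics()]).
#' @param maf_min MAF cutoff (boundary passes).
#' @return The filtered tibble.
#' @export
hit_filter <- function(results, maf_table, maf_min = 0.01) {
  idx <- match(results$variant_id, maf_table$variant_id)
  if (anyNA(idx)) {
    abort(paste0("Variant(s) absent from the MAF table: ",
                 paste(head(unique(results$variant_id[is.na(idx)]), 5),
                       collapse = ", ")))
  }
  results[maf_table$maf[idx] >= maf_min, , drop = FALSE]
}
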