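#' Mask outliers by median absolute deviation
#'
#' Sets to missing every entry whose absolute deviation from the median
#' exceeds 6 times the (unscaled) median absolute deviation. The MAD here is
#' the raw median of absolute deviations, with no normal-consistency factor.
#' With MAD = 0 (constant-majority vectors) the strict inequality means only
#' values that differ from the median are masked, never the whole vector.
#' Idempotent: the median and MAD are computed once on the input.
#'
#' @param values Numeric vector, `NA` allowed.
#' @param n_mad Threshold multiplier (default 6).
#' @return The vector with outliers set to `NA`.
#' @export
#' @examples
#' mask_outliers_mad(c(1, 2, 3, 100))
mask_outliers_mad <- function(values, n_mad = 6) {
  obs <- !is.na(values)
  if (sum(obs) < 2) abort("Need at least 2 non-missing values.")
  med <- median(values[obs])
  mad0 <- median(abs(values[obs] - med))
  out <- obs & abs(values - med) > n_mad * mad0
  values[out] <- NA
  values
}

#' Drop subjects with too many missing phenotypes
#'
#' Removes rows whose missing-phenotype count is greater than or equal to
#' `max_missing` (default 50), preserving row order.
#'
#' @param pheno Phenotype tibble, `sample_id` first column.
#' @param max_missing Missingness cutoff (a row with exactly this many
#'   missing values is dropped).
#' @return The filtered tibble.
#' @export
drop_sparse_subjects <- function(pheno, max_missing = 50) {
  values <- pheno[, setdiff(names(pheno), "sample_id"), drop = FALSE]
  n_missing <- rowSums(is.na(values))
  pheno[n_missing < max_missing, , drop = FALSE]
}

#' Rank-based inverse normal (quantile) transformation
#'
#' Replaces the non-missing entries by Blom normal scores:
#' `qnorm((r - 3/8) / (m + 1/4))` where `r` is the average rank among the
#' `m` non-missing values (ties share their average rank). The result is
#' Gaussian with mean ~0 and SD ~1 and preserves the input's rank order.
#'
#' @param values Numeric vector with at least 3 non-missing entries.
#' @return The transformed vector (missing entries untouched).
#' @export
#' @examples
#' quantile_normalize(c(10, 20, 30))
quantile_normalize <- function(values) {
  obs <- which(!is.na(values))
  m <- length(obs)
  if (m < 3) abort("Need at least 3 non-missing values to quantile normalise.")
  r <- rank(values[obs], ties.method = "average")
  values[obs] <- qnorm((r - 3 / 8) / (m + 1 / 4))
  values
}

#' Residualise phenotypes against confounds
#'
#' Each phenotype column is replaced by its least-squares residual against
#' `[intercept | confounds]` computed on the phenotype's non-missing rows,
#' then rescaled to unit variance. Rank-deficient confound matrices are
#' tolerated (pivoted QR). A phenotype that is (numerically) fully explained
#' by the confounds has no residual variance left; depending on
#' `on_degenerate` this raises an error or sets the column to all-missing.
#'
#' @param pheno Phenotype tibble, `sample_id` first column.
#' @param confounds Tibble/data frame of confound columns, row-aligned to
#'   `pheno` via `sample_id` (or positionally if it has no `sample_id`).
#' @param on_degenerate `"error"` or `"missing"`.
#' @param rescale Rescale residuals to unit variance (default TRUE).
#' @return A tibble of the same shape as `pheno`.
#' @export
residualize <- function(pheno, confounds = NULL,
                        on_degenerate = c("error", "missing"),
                        rescale = TRUE) {
  on_degenerate <- match.arg(on_degenerate)
  ids <- pheno$sample_id
  n <- length(ids)
  if (is.null(confounds)) {
    C <- matrix(1, n, 1)
  } else {
    confounds <- as_tibble(confounds)
    if ("sample_id" %in% names(confounds)) {
      idx <- match(ids, confounds$sample_id)
      if (anyNA(idx)) {
        abort(paste0("Confound matrix missing sample(s): ",
                     paste(head(ids[is.na(idx)], 5), collapse = ", ")))
      }
      confounds <- confounds[idx, setdiff(names(confounds), "sample_id"),
                             drop = FALSE]
    }
    if (nrow(confounds) != n) abort("Confound matrix must be row-aligned to samples.")
    C <- cbind(1, as.matrix(confounds))
  }
  out <- pheno
  for (col in setdiff(names(pheno), "sample_id")) {
    y <- pheno[[col]]
    use <- which(!is.na(y) & complete.cases(C))
    if (length(use) == 0) abort(paste0("Phenotype ", col, ": no usable rows."))
    fit <- lm.fit(C[use, , drop = FALSE], y[use])
    res <- fit$residuals
    s <- sd(res)
    if (!is.finite(s) || s < 1e-10) {
      if (on_degenerate == "error") {
        abort(paste0("Phenotype ", col,
                     " is fully explained by the confounds (zero residual variance)."))
      }
      y[] <- NA
      out[[col]] <- y
      next
    }
    y[] <- NA
    y[use] <- if (rescale) res / s else res
    out[[col]] <- y
  }
  out
}

#' Random discovery/replication split
#'
#' Uniformly random disjoint split of the sample ids, with
#' `floor(fraction * N)` ids in the discovery set; reproducible given the
#' seed.
#'
#' @param sample_ids Unique sample ids.
#' @param fraction Discovery fraction (default 2/3).
#' @param seed Integer seed (mandatory).
#' @return A list of class `cohort_split` with `discovery_ids`,
#'   `replication_ids` and `seed`.
#' @export
#' @examples
#' split_cohorts(as.character(1:9), seed = 1)
split_cohorts <- function(sample_ids, fraction = 2 / 3, seed) {
  if (anyDuplicated(sample_ids)) abort("Sample ids must be unique.")
  n <- length(sample_ids)
  if (n < 2) abort("Need at least 2 samples to split.")
  if (missing(seed)) abort("`seed` is mandatory for a reproducible split.")
  n_disc <- floor(fraction * n)
  perm <- withr::with_seed(seed, sample.int(n))
  structure(list(discovery_ids = as.character(sample_ids[perm[seq_len(n_disc)]]),
                 replication_ids = as.character(sample_ids[perm[-seq_len(n_disc)]]),
                 seed = seed),
            class = "cohort_split")
}

#' Full phenotype-cleaning pipeline
#'
#' Applies, in order: per-phenotype MAD outlier masking; sparse-subject
#' removal; discovery/replication split; then per cohort: Blom quantile
#' normalisation, confound residualisation (coefficients estimated within
#' the cohort) and unit-variance rescaling.
#'
#' @param pheno Phenotype tibble, `sample_id` first column.
#' @param confounds Optional confound tibble (with `sample_id`).
#' @param split A `cohort_split`, or `NULL` to use `seed`/`fraction`.
#' @param seed,fraction Used when `split` is `NULL`.
#' @param max_missing Sparse-subject cutoff, see [drop_sparse_subjects()].
#' @param n_mad Outlier multiplier, see [mask_outliers_mad()].
#' @return A list of class `clean_phenotypes` with elements `discovery` and
#'   `replication` (cleaned tibbles), `split`, and `provenance` (masked
#'   outlier and dropped subject counts, per-phenotype n).
#' @export
prep_phenotypes <- function(pheno, confounds = NULL, split = NULL,
                            seed = NULL, fraction = 2 / 3,
                            max_missing = 50, n_mad = 6) {
  pheno_cols <- setdiff(names(pheno), "sample_id")
  n_missing_before <- sum(is.na(pheno[, pheno_cols]))
  for (col in pheno_cols) {
    pheno[[col]] <- mask_outliers_mad(pheno[[col]], n_mad = n_mad)
  }
  n_masked <- sum(is.na(pheno[, pheno_cols])) - n_missing_before
  n_before <- nrow(pheno)
  pheno <- drop_sparse_subjects(pheno, max_missing = max_missing)
  n_dropped <- n_before - nrow(pheno)
  if (is.null(split)) {
    if (is.null(seed)) abort("Supply either `split` or `seed`.")
    split <- split_cohorts(pheno$sample_id, fraction = fraction, seed = seed)
  }
  clean_one <- function(ids) {
    cohort <- pheno[pheno$sample_id %in% ids, , drop = FALSE]
    for (col in pheno_cols) {
      if (sum(!is.na(cohort[[col]])) >= 3) {
        cohort[[col]] <- quantile_normalize(cohort[[col]])
      }
    }
    residualize(cohort, confounds, on_degenerate = "missing", rescale = TRUE)
  }
  discovery <- clean_one(split$discovery_ids)
  replication <- clean_one(split$replication_ids)
  structure(list(
    discovery = discovery, replication = replication, split = split,
    provenance = list(
      n_outliers_masked = n_masked, n_subjects_dropped = n_dropped,
      n_used = vapply(pheno_cols, function(col) {
        sum(!is.na(discovery[[col]]))
      }, integer(1)),
      max_missing = max_missing, n_mad = n_mad, seed = split$seed
    )
  ), class = "clean_phenotypes")
}
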