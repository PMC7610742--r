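test_that("MAD outlier masking follows the unscaled 6-MAD rule", {
  # median 2.5, unscaled MAD 1.0, |100 - 2.5| = 97.5 > 6
  expect_equal(mask_outliers_mad(c(1, 2, 3, 100)), c(1, 2, 3, NA))
  # constant vector: MAD 0, strict inequality masks nothing
  expect_equal(mask_outliers_mad(c(5, 5, 5, 5)), c(5, 5, 5, 5))
  # MAD 0 with a deviant value: only the deviant is masked
  expect_equal(mask_outliers_mad(c(5, 5, 5, 9)), c(5, 5, 5, NA))
  # already-missing entries stay missing
  expect_equal(mask_outliers_mad(c(1, NA, 3, 100)), c(1, NA, 3, NA))
  expect_error(mask_outliers_mad(c(NA, NA, 1)), "2 non-missing")
})

test_that("MAD masking is idempotent", {
  withr::local_seed(11)
  for (i in 1:20) {
    x <- rnorm(200)
    x[sample.int(200, 5)] <- sample(c(-1, 1), 5, TRUE) * runif(5, 40, 60)
    once <- mask_outliers_mad(x)
    expect_identical(mask_outliers_mad(once), once)
  }
})

test_that("sparse subjects are dropped at the >= 50 missing boundary", {
  n_pheno <- 120
  mk_row <- function(n_missing) {
    v <- rnorm(n_pheno)
    if (n_missing > 0) v[seq_len(n_missing)] <- NA
    v
  }
  pheno <- tibble::as_tibble(rbind(mk_row(50), mk_row(49), mk_row(0)),
                             .name_repair = ~ paste0("P", seq_len(n_pheno)))
  pheno <- dplyr::bind_cols(tibble::tibble(sample_id = c("a", "b", "c")), pheno)
  kept <- drop_sparse_subjects(pheno, max_missing = 50)
  expect_equal(kept$sample_id, c("b", "c"))
  # fully observed matrix passes through unchanged
  full <- pheno[3, ]
  expect_identical(drop_sparse_subjects(full), full)
})

test_that("quantile normalisation produces Blom scores", {
  # m = 3: qnorm((r - 3/8) / 3.25) for r = 1, 2, 3
  got <- quantile_normalize(c(10, 20, 30))
  expect_equal(got, qnorm((1:3 - 3 / 8) / 3.25), tolerance = 1e-12)
  expect_equal(got[2], 0)
  expect_equal(got[1], -0.8694, tolerance = 1e-4)

  # ties share average ranks, hence equal outputs
  tied <- quantile_normalize(c(1, 2, 2, 3))
  expect_equal(tied[2], tied[3])

  # rank invariance: any strictly increasing input maps to the scores of 1..m
  withr::local_seed(3)
  x <- sort(rexp(40)) * 100
  expect_equal(quantile_normalize(x), quantile_normalize(as.numeric(1:40)))

  # missing entries are untouched and excluded from the rank pool
  x <- c(5, NA, 7, 9)
  qn <- quantile_normalize(x)
  expect_true(is.na(qn[2]))
  expect_equal(qn[-2], qnorm((1:3 - 3 / 8) / 3.25))

  expect_error(quantile_normalize(c(1, 2)), "at least 3")
})

test_that("quantile-normalised Gaussians pass a KS test against N(0,1)", {
  withr::local_seed(21)
  x <- rnorm(1500, mean = 50, sd = 9)^2 # heavily non-Gaussian input
  qn <- quantile_normalize(x)
  ks <- suppressWarnings(stats::ks.test(qn, "pnorm"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(qn), 0, tolerance = 1e-8)
  expect_equal(sd(qn), 1, tolerance = 1e-2)
})

test_that("residualisation matches a normal-equations oracle and is orthogonal", {
  withr::local_seed(7)
  n <- 50
  C <- matrix(rnorm(n * 5), n, 5)
  y <- rnorm(n)
  pheno <- tibble::tibble(sample_id = as.character(1:n), y = y)
  confounds <- dplyr::bind_cols(tibble::tibble(sample_id = as.character(1:n)),
                                tibble::as_tibble(C, .name_repair = ~ paste0("c", 1:5)))
  res <- residualize(pheno, confounds, rescale = FALSE)
  coef <- ols_oracle(y, C)
  expected <- y - cbind(1, C) %*% coef
  expect_equal(res$y, drop(expected), tolerance = 1e-10)
  for (j in 1:5) expect_lt(abs(cor(res$y, C[, j])), 1e-8)

  # rescaled version has unit variance
  res_scaled <- residualize(pheno, confounds)
  expect_equal(sd(res_scaled$y), 1, tolerance = 1e-12)
})

test_that("residualisation handles intercept-only, collinearity and re-application", {
  withr::local_seed(8)
  n <- 30
  y <- rnorm(n, mean = 4)
  pheno <- tibble::tibble(sample_id = as.character(1:n), y = y)
  # intercept only = centering + rescale
  res <- residualize(pheno, confounds = NULL)
  expect_equal(res$y, (y - mean(y)) / sd(y - mean(y)), tolerance = 1e-12)

  # phenotype equal to a confound column: degenerate residual
  confounds <- tibble::tibble(sample_id = as.character(1:n), c1 = y)
  expect_error(residualize(pheno, confounds, on_degenerate = "error"),
               "zero residual variance")
  soft <- residualize(pheno, confounds, on_degenerate = "missing")
  expect_true(all(is.na(soft$y)))

  # residualize twice with the same confounds = identity (up to tolerance)
  C <- tibble::tibble(sample_id = as.character(1:n),
                      c1 = rnorm(n), c2 = rnorm(n))
  r1 <- residualize(pheno, C)
  r2 <- residualize(r1, C)
  expect_equal(r2$y, r1$y, tolerance = 1e-10)
})

test_that("cohort splitting is reproducible and respects floor(2N/3)", {
  s <- split_cohorts(as.character(1:9), seed = 4)
  expect_equal(length(s$discovery_ids), 6)
  s3 <- split_cohorts(as.character(1:3), seed = 4)
  expect_equal(c(length(s3$discovery_ids), length(s3$replication_ids)), c(2, 1))
  expect_identical(split_cohorts(as.character(1:100), seed = 12),
                   split_cohorts(as.character(1:100), seed = 12))
  a <- split_cohorts(as.character(1:100), seed = 1)
  expect_length(intersect(a$discovery_ids, a$replication_ids), 0)
  expect_setequal(c(a$discovery_ids, a$replication_ids), as.character(1:100))
  expect_error(split_cohorts("only_one", seed = 1), "at least 2")
})

test_that("the full prep chain cleans, splits and standardises per cohort", {
  withr::local_seed(30)
  n <- 240
  pheno <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                          P1 = rnorm(n)^2, P2 = rexp(n))
  pheno$P1[5] <- 1e6 # gross outlier
  confounds <- tibble::tibble(sample_id = pheno$sample_id, age = rnorm(n))
  prep <- prep_phenotypes(pheno, confounds, seed = 2)
  expect_gte(prep$provenance$n_outliers_masked, 1)
  for (cohort in list(prep$discovery, prep$replication)) {
    for (col in c("P1", "P2")) {
      v <- cohort[[col]][!is.na(cohort[[col]])]
      expect_equal(mean(v), 0, tolerance = 1e-8)
      expect_equal(sd(v), 1, tolerance = 1e-6)
    }
  }
  expect_length(intersect(prep$discovery$sample_id,
                          prep$replication$sample_id), 0)
})
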