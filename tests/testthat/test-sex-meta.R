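test_that("Fisher combination matches the df-4 closed form", {
  # q(1 - ln q) with q = p_f * p_m
  expect_equal(fisher_combine(1, 1)$p_combined, 1)
  q <- 0.05 * 0.05
  expect_equal(fisher_combine(0.05, 0.05)$p_combined, q * (1 - log(q)),
               tolerance = 1e-12)
  expect_equal(fisher_combine(0.05, 0.05)$p_combined, 0.01748,
               tolerance = 1e-4)

  withr::local_seed(61)
  pf <- runif(200)
  pm <- runif(200)
  expect_equal(fisher_combine(pf, pm)$p_combined,
               pf * pm * (1 - log(pf * pm)), tolerance = 1e-12)
})

test_that("log-space inputs survive extreme significance", {
  # p = 1e-300 each: the closed form still holds in -log10 space
  nl <- c(300, 300)
  got <- fisher_combine(neglog10p_f = nl[1], neglog10p_m = nl[2])
  q_ln <- -log(10) * 600
  expected_nl10 <- -(q_ln + log1p(-q_ln)) / log(10)
  expect_equal(got$neglog10p_combined, expected_nl10, tolerance = 1e-10)
  expect_gt(got$neglog10p_combined, 595)
  # and beyond underflow the -log10 output stays finite
  deep <- fisher_combine(neglog10p_f = 1000, neglog10p_m = 1000)
  expect_true(is.finite(deep$neglog10p_combined))
  expect_gt(deep$neglog10p_combined, 1990)
})

test_that("Fisher combination is monotone and rejects invalid p", {
  grid <- seq(0.05, 1, by = 0.05)
  for (p2 in c(0.1, 0.5, 1)) {
    comb <- fisher_combine(grid, rep(p2, length(grid)))$p_combined
    expect_true(all(diff(comb) >= -1e-15))
  }
  expect_error(fisher_combine(0, 0.5), "> 0")
  expect_error(fisher_combine(1.2, 0.5), "<= 1")
  expect_error(fisher_combine(p_f = 0.5), "both members")
})

test_that("the sex-difference z-test matches the normal-tail oracle", {
  expect_equal(beta_diff_ztest(0.3, 0.1, 0.3, 0.2)$p, 1)
  got <- beta_diff_ztest(1, sqrt(0.5), 0, sqrt(0.5))
  expect_equal(got$z, 1, tolerance = 1e-12)
  expect_equal(got$p, 2 * pnorm(-1), tolerance = 1e-12)
  expect_equal(got$p, 0.3173, tolerance = 1e-4)
  # symmetric in the sexes
  expect_equal(beta_diff_ztest(0.2, 0.05, -0.1, 0.07)$p,
               beta_diff_ztest(-0.1, 0.07, 0.2, 0.05)$p)
  expect_error(beta_diff_ztest(1, 0, 0, 1), "> 0")
})

test_that("sign concordance counts matching effect directions", {
  pairs <- tibble::tibble(
    beta_f = c(1, -1, 0.5, 0.2), beta_m = c(2, -3, -0.5, 0.1),
    neglog10p_f = c(9, 9, 9, 9), neglog10p_m = c(1, 1, 1, 1))
  got <- sign_concordance(pairs, neglog10p_min = 7.5)
  expect_equal(got$concordance, 0.75)
  expect_equal(got$n_discordant, 1)
  # zero beta concordant with either sign
  zero <- tibble::tibble(beta_f = 0, beta_m = -1,
                         neglog10p_f = 9, neglog10p_m = 0)
  expect_equal(sign_concordance(zero)$concordance, 1)
  # filter on the max of the two scans
  weak <- dplyr::mutate(pairs, neglog10p_f = 1, neglog10p_m = 1)
  expect_error(sign_concordance(weak), "undefined")
})

test_that("shared-effect simulations give near-perfect sign concordance", {
  withr::local_seed(62)
  n_pairs <- 500
  n_per_sex <- 2000
  beta_true <- 0.15
  sim_one <- function() {
    g_f <- rbinom(n_per_sex, 2, 0.3)
    g_m <- rbinom(n_per_sex, 2, 0.3)
    y_f <- beta_true * g_f + rnorm(n_per_sex)
    y_m <- beta_true * g_m + rnorm(n_per_sex)
    fit <- function(y, g) {
      gc <- g - mean(g)
      b <- sum(gc * y) / sum(gc^2)
      se <- sqrt(sum((y - mean(y) - b * gc)^2) / (n_per_sex - 2) / sum(gc^2))
      t <- b / se
      c(b, -log10(2) - pt(abs(t), n_per_sex - 2, lower.tail = FALSE,
                          log.p = TRUE) / log(10))
    }
    c(fit(y_f, g_f), fit(y_m, g_m))
  }
  draws <- t(replicate(n_pairs, sim_one()))
  pairs <- tibble::tibble(beta_f = draws[, 1], neglog10p_f = draws[, 2],
                          beta_m = draws[, 3], neglog10p_m = draws[, 4])
  got <- sign_concordance(pairs, neglog10p_min = 7.5)
  expect_gt(got$concordance, 0.99)
})

test_that("meta-analysis output feeds the clustering stages unchanged", {
  withr::local_seed(63)
  cfg <- sim_config(n_female = 200, n_male = 200, chromosomes = "X",
                    n_variants = 40, n_phenotypes = 3, n_causal = 1,
                    effect_range = c(0.6, 0.8), maf_range = c(0.3, 0.5),
                    seed = 8)
  sim <- simulate_cohort(cfg)
  ids <- sim$pheno$sample_id
  sex <- sim$dosages$sex
  prep <- residualize(sim$pheno, sim$confounds)
  f_scan <- linear_scan(prep, sim$dosages, cohort = ids[sex == "female"])
  m_scan <- linear_scan(prep, sim$dosages, cohort = ids[sex == "male"])
  meta <- meta_analyse_sex_scans(f_scan, m_scan)
  expect_equal(nrow(meta), nrow(f_scan))
  expect_true(all(c("neglog10p", "beta", "se", "chromosome", "bp") %in%
                    names(meta)))
  pk <- extract_peaks(meta, sim$map, threshold = 4)
  expect_gte(nrow(pk), 1)
  cl <- cluster_peaks(pk)
  expect_gte(nrow(cl$clusters), 1)
})

test_that("meta-analysis of sex-stratified scans is at least as sensitive as pooling", {
  withr::local_seed(64)
  n_rep <- 500
  n_f <- 1500
  n_m <- 1200
  beta <- 0.15
  maf <- 0.3
  delta <- matrix(NA_real_, n_rep, 2)
  for (r in seq_len(n_rep)) {
    # X non-PAR: females diploid, males haploid raw then (0,2)-encoded
    g_f <- rbinom(n_f, 2, maf)
    g_m_raw <- rbinom(n_m, 1, maf)
    g_m <- 2 * g_m_raw
    # equal per-allele-copy effects in both sexes: the pooled scan's (0,2)
    # male coding then overstates the male genetic value (incomplete
    # dosage compensation), while the sex-separated scans fit each slope
    y_f <- beta * g_f + rnorm(n_f)
    y_m <- beta * g_m_raw + rnorm(n_m)
    nl10 <- function(y, g) {
      n <- length(y)
      gc <- g - mean(g)
      if (sum(gc^2) < 1e-12) return(NA_real_)
      b <- sum(gc * y) / sum(gc^2)
      se <- sqrt(sum((y - mean(y) - b * gc)^2) / (n - 2) / sum(gc^2))
      -(pt(abs(b / se), n - 2, lower.tail = FALSE, log.p = TRUE) + log(2)) /
        log(10)
    }
    pooled <- nl10(c(y_f, y_m), c(g_f, g_m))
    meta <- fisher_combine(neglog10p_f = nl10(y_f, g_f),
                           neglog10p_m = nl10(y_m, g_m))$neglog10p_combined
    delta[r, ] <- c(meta, pooled)
  }
  expect_gte(median(delta[, 1], na.rm = TRUE),
             median(delta[, 2], na.rm = TRUE) - 0.1)
})

test_that("cluster overlap matches leads within the inclusive tolerance", {
  main <- tibble::tibble(cluster_id = 1:3, chromosome = c("X", "X", "2"),
                         lead_cm = c(10, 20, 5))
  # identical sets: everything matches
  all_match <- cluster_overlap(main, main)
  expect_equal(nrow(all_match$matched), 3)
  expect_equal(nrow(all_match$meta_only), 0)

  meta <- tibble::tibble(cluster_id = 1:3, chromosome = c("X", "X", "2"),
                         lead_cm = c(10.25, 20.3, 5))
  got <- cluster_overlap(meta, main)
  expect_setequal(got$matched$meta_cluster_id, c(1, 3)) # 0.25 in, 0.3 out
  expect_equal(got$meta_only$cluster_id, 2)
  # chromosomes must agree even when cM is close
  cross <- tibble::tibble(cluster_id = 1, chromosome = "1", lead_cm = 10)
  expect_equal(nrow(cluster_overlap(cross, main)$matched), 0)
})
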